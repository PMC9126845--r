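---
title: "Methods: cohort selection, filtering, consensus classification and mutability burden testing"
author: "hdlexome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort selection, filtering, consensus classification and mutability burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdlexome)
```

# Overview

`hdlexome` implements the analysis chain of a whole-exome study of severe
HDL cholesterol deficiency (hypoalphalipoproteinemia): participants with
abnormally low HDL-C are selected from a lipid-panel registry, their rare
coding variants are filtered through two parallel cascades, surviving
variants are scored by a ten-tool consensus deleteriousness vote, and
per-gene damaging counts are tested against a trinucleotide-context
mutability expectation with a one-sided binomial test. Because low HDL-C
is frequently secondary to hypertriglyceridemia — cholesteryl-ester
transfer from HDL to triglyceride-rich particles produces a hyperbolic
inverse relationship between TG and HDL-C — selection is not a flat HDL-C
cutoff but a quantile *isopleth* in the (TG, HDL-C) plane.

# Cohort selection

## The hyperbolic quantile isopleth

The selection curve has the form

$$ y = m_1 + \frac{m_2\, m_3}{m_2 + x}, $$

with $y$ HDL-C and $x$ TG (both mg/dl). For $m_3 > 0$ the threshold
decreases monotonically in TG, so a hypertriglyceridemic participant must
have disproportionately low HDL-C to be selected. The fitting method for
such a curve at a quantile level $q$ is not uniquely dictated by its
definition; we minimise the pinball (check) loss

$$ \sum_i \rho_q\!\left(y_i - \hat y(x_i)\right), \qquad
   \rho_q(r) = r\,(q - \mathbf 1[r < 0]), $$

which is the standard defining property of a conditional quantile and is
directly testable by coverage: about a fraction $q$ of points should fall
strictly below the fitted curve. The loss is non-smooth and the family is
nonlinear in $m_2$, so we search over $(m_1, \log m_2, c = m_2 m_3)$ with
Nelder–Mead from a multistart grid of $m_2$ values spanning the TG range,
then polish the winner with restarted simplices (restarting escapes
collapsed simplices near the optimum). On noiseless data generated from
the family the fit recovers the constants to well below $10^{-4}$
relative error; on 10,000 noisy points the 10th-percentile curve covers
9–10% of points (both checked in the test suite and recomputed by
`scripts/acceptance.R`). Degenerate inputs are handled explicitly:
constant TG makes $m_2$ unidentifiable and is an error; constant HDL-C
legitimately collapses to $m_3 \approx 0$, a flat threshold.

Selection uses a *strict* inequality — a participant exactly on the curve
stays in the population — because the target is the set strictly below the
quantile threshold.

## Friedewald LDL-C and subphenotype groups

LDL-C, where not measured directly, is estimated as
$\mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/5$ (mg/dl), undefined at
TG $\ge$ 400 mg/dl. Selected participants are partitioned into four
dyslipidemia subphenotypes by TG $\ge$ 150 (the NCEP ATP III
hypertriglyceridemia cutoff) and LDL-C $\ge$ 160 mg/dl: isolated low
HDL-C; low HDL-C with high LDL-C; with high TG; and combined
hyperlipidemia. For participants under 18 a caller-supplied sex/age
percentile table can replace the adult 160 cutoff; without one the adult
cutoff is applied with a notice, since no canonical pediatric table ships
with the package. Group summaries use per-variable complete-case
denominators, and between-group tests follow the transform table used for
cohort description: log for BMI, TC and TG, square root for LDL-C, Welch's
unpaired t-test for continuous variables (robust to unequal variances, and
asymptotically equivalent to Student's under equal variance), Fisher's
exact test for categorical ones.

# Variant filtering

Two cascades mirror the two analysis arms. Every drop records exactly one
reason — the first failed rule in a fixed order — so stage tallies are
reproducible and always conserve counts.

**Candidate branch** (variant catalogue and carrier association): drop
synonymous / intronic / intergenic / UTR consequences; require QUAL > 40
(strict), DP ≥ 20, GQ ≥ 60 whenever the caller set intersects
{GATK-UG, GATK-HC, Freebayes}, and more than one caller (singleton-caller
calls are treated as artifactual — the filter's contract is that a cohort
of single-caller variants is emptied); remove the top half, rounded up, of
a user-supplied ranked common-variant list (the vendor list used in
practice is proprietary, so the package accepts any ranked list and
results are documented as list-dependent); remove platform-specific
variants carried by more than 40% of samples; and apply gnomAD MAF cutoffs
of 0.01 for the heterozygous analysis and 0.05 for the homozygous one.
An absent population frequency is treated as 0 — a novel variant — and
MAF comparisons are `<=` at the cutoff.

**Burden branch**: VQSR pass, DP ≥ 8, GQ ≥ 20, MQ ≥ 40, at least three
alt-supporting reads, outside low-complexity regions; rarity at one of
the thresholds {1e-5, 1e-4, 1e-3} simultaneously in ExAC, 1000 Genomes
and ESP; and a damaging consequence class. Loss-of-function covers
stop-gain, stop-loss, frameshift indels, splice-site disruption and
start-loss; damaging missense (D-Mis) is missense called deleterious by
MetaSVM.

# Consensus damage classification

Ten prediction tools (SIFT, PolyPhen-2 HVAR, MutationTaster,
MutationAssessor, FATHMM, PROVEAN, MetaSVM, MetaLR, M-CAP, FATHMM-MKL)
each contribute 1 point for a damaging call, 0.5 for an
intermediate/equivocal call and 0 otherwise; missing calls score 0 rather
than renormalising, keeping the 0–10 scale fixed (half-point totals such
as 9.5 are therefore meaningful). Within the assessed set — all variants
surviving the candidate branch of the current run — each variant's
mid-rank percentile is the fraction of variants with strictly smaller
vote count plus half the ties, which makes classification invariant under
duplication of the assessed set. Classes: probably damaging at or above
the 80th percentile; undetermined between the 50th and 80th; likely
benign below the 50th; and a variant above the 50th percentile with an
*unequivocal* ClinVar pathogenic entry (a label matching
pathogenic/likely-pathogenic with no benign, conflicting or uncertain
token) is upgraded to pathogenic. A sub-50th-percentile variant is never
upgraded, whatever its ClinVar entry. Occurrences are counted per
carrier–variant pair, homozygous carriage counting once (a flag to double
would be a one-line change; once is the default because a recessive
genotype is still one observation of the variant in that person).

# Mutability model and burden test

## Trinucleotide-context mutability

For a coding sequence of length $L$ (with one flanking base each side)
every one of the $3L$ single-nucleotide substitutions is classified by
translating its codon in frame: start-loss, stop-gain and stop-loss count
toward LoF; amino-acid changes are missense; the rest synonymous. Summing
the per-context substitution rates within a class gives the per-gene,
per-class de novo mutability. The class sums partition the total — an
invariant the tests check against a brute-force enumeration oracle.
Frameshift and splice events are not derivable from an SNV context model;
they enter as an additive term defaulting to 1.25 times the nonsense SNV
mutability, and a configurable fraction (default 0.35) of the missense
mutability is counted as damaging missense. Both constants only shape
relative expectations, which is all the burden test consumes. A per-gene
coverage factor in [0, 1] — operationalised as the fraction of coding
bases with depth ≥ 10 in at least 90% of samples, supplied by the caller
— scales all classes; genes scaled to zero carry no information and are
excluded from testing.

The package ships a deliberately synthetic rate table
(`inst/extdata/rates_synthetic.tsv`, 96 pyrimidine-centred rows expanded
to 192 by strand symmetry): transitions 4× transversions, CpG transitions
10× again, a mild symmetric flank modulation. Empirical per-context
estimates are not redistributable here; any table in the same format can
be substituted.

## Expected counts and the binomial tail

With $N$ the total number of damaging heterozygous carrier-occurrences
across tested genes,

$$ \mathbb E[\text{gene}_i] \;=\; N \cdot
   \frac{\text{mutability}_i}{\sum_j \text{mutability}_j}, $$

and enrichment is judged by the one-sided tail
$P(X \ge \text{observed})$, $X \sim \mathrm{Binom}(N, p_i)$, computed via
the binomial survival function rather than naive summation (the tests
retain a term-by-term oracle and require $10^{-10}$ relative agreement).
Expected counts are pinned to sum to $N$ exactly. Genome-wide
significance divides $\alpha$ by the number of genes with positive
adjusted mutability — a Bonferroni-style rule chosen because the study
design offers no empirical null to calibrate a threshold against. Q–Q
diagnostics plot observed against expected $-\log_{10} p$ with uniform
order-statistic means $i/(n+1)$ as expected quantiles.

## Gene-set over-representation

For recessive-genotype gene lists, each gene set is tested by the
one-sided hypergeometric (Fisher) upper tail on hits versus the
remainder of a user-declared universe, with expected hits
$|\text{set}| \cdot |\text{hits}| / |\text{universe}|$, fold enrichment
hits/expected, and Benjamini–Hochberg q-values across sets.

# The synthetic cohort generator

The generator is first-class, tested code: it produces the statistical
structure the analysis assumes, plus a truth table for recovery tests.

* **Lipids.** TG is log-normal (median 150 mg/dl, log-sd 0.8 — a
  right-skewed distribution consistent with a low-HDL referral
  population); HDL-C is the truth hyperbola
  $20 + 50 \cdot 30 / (50 + \mathrm{TG})$ plus centred Gaussian noise
  (sd 4 mg/dl), floored at 1 mg/dl; LDL-C is Gaussian (128 ± 45 mg/dl,
  floored at 20); TC is *constructed* as LDL + HDL + TG/5 so the
  Friedewald identity is exact wherever defined. The hyperbola constants
  are synthetic defaults: the study's fitted isopleth is unpublished, so
  self-consistency — not the study's curve — is what tests can check.
* **Variants.** Damaging occurrences are Poisson per (participant, gene)
  with mean $T p_g m_g / n$, where $T$ = 2 (the null mean per gene)
  × the roster size, $p_g$ is the gene's damaging-mutability share and
  $m_g \ge 1$ a planted multiplier — i.e. exactly the burden model's
  null/alternative. Each occurrence is a singleton variant; its class is
  LoF or D-Mis in proportion to the gene's class mutabilities, and a
  D-Mis record carries a deleterious MetaSVM call because that call
  *defines* the class. Benign background variants (synonymous, tolerated
  missense, intronic, UTR) are added per gene with small carrier counts
  and commoner population frequencies. QC fields are drawn so that a few
  percent of records fail each filter; 2% of carrier genotypes are
  homozygous; tool votes follow the design's operating points
  (damaging-vote probability 0.85 given truly damaging, 0.15 given
  benign, with a share of the vote mass cast as half-point equivocal
  calls).
* **Determinism.** All randomness flows from the design seed through
  fixed stage order, and the generator restores the caller's RNG state.

What the generator does *not* emulate: linkage disequilibrium,
relatedness (the real cohort's five kinships), sequencing-read noise,
population stratification, or per-gene coverage variation. Passing
calibration and recovery tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to those
real-data features.

# Problem sizes and numerical choices

The calibration suite uses the default study-scale conditions — 204
participants, a 200-gene roster, null mean 2 damaging occurrences per
gene — for the null type-I check (fraction of genes with $p < 0.05$
within $0.05 \pm 3\sqrt{0.05\cdot 0.95/200}$; the binomial test is
discrete and mildly conservative, so the observed fraction typically sits
below 0.05) and for the planted-recovery check (one gene at 8× its null
rate recovered at genome-wide significance in at least 90% of 50
replicates). Isopleth self-fits use 500 noiseless and 10,000 noisy
points. Unit tests use smaller rosters (12–60 genes, 150–450-base coding
sequences) purely to keep mutability enumeration cheap; the model is
size-independent. Tolerances: $10^{-10}$ relative for the binomial
oracle, $10^{-4}$ relative for noiseless isopleth recovery, $10^{-12}$
for the expected-count sum. Tie-breaks: drop reasons use a fixed rule
order; vote percentiles use mid-rank; the common-variant list removes the
top half rounded up.

# Known limitations

* The percentile reference population for classification is the current
  run's filtered set; results are therefore run-composition-dependent, as
  any relative cutoff is.
* The common-variant list and the mutation-rate table are inputs; the
  shipped versions are synthetic stand-ins labelled as such.
* Whether the candidate-branch MAF filter should use overall or
  population-specific gnomAD frequencies is an open choice; the default
  is overall.
* The burden test treats occurrences as independent across participants
  and genes; relatedness or shared haplotypes would inflate it.
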