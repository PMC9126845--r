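Package: hdlexome
Title: Exome Analysis of Severe HDL Cholesterol Deficiency Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-exome studies of hypoalphalipoproteinemia
    (low plasma HDL cholesterol). Implements cohort selection below a
    fitted hyperbolic quantile isopleth in the triglyceride/HDL-C plane,
    dyslipidemia subphenotype grouping, two rare-variant filter cascades
    (a candidate-gene branch and a binomial-burden branch), a ten-tool
    consensus deleteriousness classification with ClinVar overlay, a
    trinucleotide-context mutability model yielding per-gene expected
    damaging-variant counts, a one-sided binomial gene-burden test with
    Q-Q diagnostics, and Fisher/FDR gene-set over-representation. A
    seeded synthetic-cohort generator produces lipid panels and annotated
    variant calls with known truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
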