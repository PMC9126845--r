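## The two post-variant-calling filter cascades.
##
## Candidate branch: drop synonymous/intronic/intergenic/UTR, require
## QUAL > 40, DP >= 20, GQ >= 60 when called by GATK-UG / GATK-HC /
## Freebayes, and more than one caller; then remove the top half of a
## ranked common-variant list, apply gnomAD MAF cutoffs (0.01 het /
## 0.05 hom) and drop platform-specific variants carried by more than 40%
## of samples.
##
## Burden branch: VQSR pass, DP >= 8, GQ >= 20, MQ >= 40, >= 3 supporting
## reads, outside low-complexity regions; then rarity (MAF <= 1e-5 / 1e-4 /
## 1e-3 in ExAC, 1000 Genomes and ESP simultaneously) and consequence class
## LoF or damaging-missense.
##
## Every drop carries exactly one reason code (the first failed rule in a
## fixed order) so stage tallies are reproducible and conserve counts.

firstReason <- function(checks) {
  ## checks: named list of logical "passes" vectors, in rule order
  reason <- rep(NA_character_, length(checks[[1]]))
  for (nm in names(checks)) {
    fail <- is.na(reason) & !checks[[nm]]
    reason[fail] <- nm
  }
  reason
}

#' Candidate-branch QC filter
#'
#' Keeps a variant iff QUAL > 40, DP >= 20, GQ >= 60 whenever its caller
#' set intersects {GATK-UG, GATK-HC, Freebayes}, it was called by more than
#' one caller, and its consequence is coding-relevant (not synonymous,
#' intronic, intergenic or UTR). The drop reason is the first failed rule
#' in that order (`"QUAL"`, `"DP"`, `"GQ"`, `"caller_count"`,
#' `"consequence"`).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @return data.frame with `key`, `keep` (logical) and `reason` (`NA` when
#'   kept).
#' @export
candidateQcFilter <- function(cohort) {
  v <- variantData(cohort)
  if (any(is.na(v$qual)) || any(is.na(v$dp)))
    stop("QUAL and DP are mandatory VCF fields and must not be missing")
  callers <- strsplit(ifelse(is.na(v$callers), "", v$callers), ",",
                      fixed = TRUE)
  gqNeeded <- vapply(callers, function(cs)
    any(cs %in% c("GATK-UG", "GATK-HC", "Freebayes")), logical(1))
  checks <- list(
    QUAL = v$qual > 40,
    DP = v$dp >= 20,
    GQ = !gqNeeded | (!is.na(v$gq) & v$gq >= 60),
    caller_count = lengths(callers) > 1,
    consequence = !(v$consequence %in%
                      c("synonymous", "intronic", "intergenic", "UTR"))
  )
  keep <- Reduce(`&`, checks)
  data.frame(key = v$key, keep = keep, reason = firstReason(checks),
             stringsAsFactors = FALSE)
}

#' Remove the most common variants from a ranked list
#'
#' Given a list of variant keys ranked most- to least-common (e.g. a
#' platform vendor's common-variant catalogue), removes cohort variants
#' whose key falls in the top half of the list, rounding half up (top 3 of
#' a 5-key list). An empty list is the identity.
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param rankedCommon Character vector of keys, most common first.
#' @return A [VariantCohort][variantCohort] without the listed variants.
#' @export
commonVariantFilter <- function(cohort, rankedCommon) {
  if (!length(rankedCommon)) return(cohort)
  top <- rankedCommon[seq_len(ceiling(length(rankedCommon) / 2))]
  subsetVariants(cohort, setdiff(variantKeys(cohort), top))
}

#' gnomAD MAF filter for the candidate branch
#'
#' A variant is retained for the heterozygous analysis iff its gnomAD MAF
#' is at or below `hetCutoff` (default 0.01), and for the homozygous
#' analysis iff the MAF is at or below `homCutoff` (default 0.05) and at
#' least one homozygous genotype is present. Absent MAF is treated as 0
#' (novel variant).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param hetCutoff,homCutoff MAF cutoffs (fractions).
#' @return data.frame with `key`, `keepHet`, `keepHom`.
#' @export
mafFilter <- function(cohort, hetCutoff = 0.01, homCutoff = 0.05) {
  v <- variantData(cohort)
  maf <- ifelse(is.na(v$maf_gnomad), 0, v$maf_gnomad)
  hasHom <- rowSums(genotypes(cohort) == 2L) > 0
  data.frame(key = v$key,
             keepHet = maf <= hetCutoff,
             keepHom = maf <= homCutoff & hasHom,
             stringsAsFactors = FALSE)
}

#' Remove platform-specific variants
#'
#' Drops variants carried (het or hom) by more than `shareCutoff` of the
#' samples — such calls are platform artifacts rather than real rare
#' variation.
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param shareCutoff Fraction of samples (default 0.40).
#' @return A filtered [VariantCohort][variantCohort].
#' @export
platformFilter <- function(cohort, shareCutoff = 0.40) {
  n <- length(sampleIds(cohort))
  if (n == 0) stop("cohort has no samples")
  carriers <- rowSums(genotypes(cohort) > 0L)
  subsetVariants(cohort, variantKeys(cohort)[carriers <= shareCutoff * n])
}

#' Burden-branch QC filter
#'
#' Keeps a variant iff it passed VQSR, DP >= 8, GQ >= 20, MQ >= 40, at
#' least three alt-supporting reads, and it does not fall in a
#' low-complexity region. Drop reasons, in order: `"VQSR"`, `"DP"`,
#' `"GQ"`, `"MQ"`, `"supporting_reads"`, `"LCR"`.
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @return data.frame with `key`, `keep`, `reason`.
#' @export
burdenQcFilter <- function(cohort) {
  v <- variantData(cohort)
  checks <- list(
    VQSR = !is.na(v$vqsr_pass) & v$vqsr_pass,
    DP = !is.na(v$dp) & v$dp >= 8,
    GQ = !is.na(v$gq) & v$gq >= 20,
    MQ = !is.na(v$mq) & v$mq >= 40,
    supporting_reads = !is.na(v$alt_reads) & v$alt_reads >= 3,
    LCR = !is.na(v$lcr_flag) & !v$lcr_flag
  )
  keep <- Reduce(`&`, checks)
  data.frame(key = v$key, keep = keep, reason = firstReason(checks),
             stringsAsFactors = FALSE)
}

#' Rarity filter across three reference databases
#'
#' Keeps a variant iff its MAF is at or below `threshold` in every one of
#' ExAC, 1000 Genomes and ESP. An absent value counts as 0 (novel).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param threshold MAF threshold (one of the configured ascending set,
#'   canonically 1e-5, 1e-4 or 1e-3).
#' @return Logical keep vector, one per variant.
#' @export
rareFilter <- function(cohort, threshold) {
  v <- variantData(cohort)
  zf <- function(x) ifelse(is.na(x), 0, x)
  zf(v$maf_exac) <= threshold & zf(v$maf_1kg) <= threshold &
    zf(v$maf_esp) <= threshold
}

#' Consequence class: LoF / D-Mis / other
#'
#' Loss-of-function covers stop-gain, stop-loss, frameshift indels, splice
#' site disruption and start-loss. Damaging missense (D-Mis) is a missense
#' variant called deleterious by MetaSVM. Everything else — including an
#' unrecognised consequence label, which is reported with a warning — is
#' `"other"`.
#'
#' @param cohort A [VariantCohort][variantCohort], or a data.frame with
#'   `consequence` and `metasvm_call` columns.
#' @return Character vector in `{"LoF", "D-Mis", "other"}`.
#' @export
consequenceClass <- function(cohort) {
  v <- if (is(cohort, "VariantCohort")) variantData(cohort) else cohort
  unknown <- !(v$consequence %in% consequenceLevels()) & !is.na(v$consequence)
  if (any(unknown))
    warning("unknown consequence label(s) treated as 'other': ",
            paste(unique(v$consequence[unknown]), collapse = ", "))
  ifelse(v$consequence %in% lofConsequences(), "LoF",
         ifelse(!is.na(v$consequence) & v$consequence == "missense" &
                  !is.na(v$metasvm_call) & v$metasvm_call == "deleterious",
                "D-Mis", "other"))
}

#' In-cohort minor allele frequency
#'
#' `(n_het + 2 * n_hom) / (2 * n_samples)` — the alternate-allele fraction
#' among the cohort's chromosomes.
#'
#' @param nHet,nHom Counts of heterozygous and homozygous carriers.
#' @param nSamples Cohort size.
#' @return Allele frequency in \[0,1\].
#' @examples
#' cohortMaf(17, 1, 204)  # 0.0466
#' @export
cohortMaf <- function(nHet, nHom, nSamples) {
  if (nSamples <= 0) stop("nSamples must be positive")
  if (any(nHet + nHom > nSamples) || any(c(nHet, nHom) < 0))
    stop("need 0 <= nHet + nHom <= nSamples")
  (nHet + 2 * nHom) / (2 * nSamples)
}

#' Run the full candidate-branch cascade with stage tallies
#'
#' Applies, in order: the candidate QC filter, the ranked common-variant
#' removal, the platform-share filter, and the gnomAD MAF filter for the
#' chosen analysis (heterozygous or homozygous). Returns the surviving
#' cohort plus a per-stage tally (input, dropped, output counts conserve).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param config A [PipelineConfig][pipelineConfig].
#' @param rankedCommon Optional ranked common-variant key list.
#' @param analysis `"het"` or `"hom"`.
#' @return List with `cohort` (filtered) and `tally` (data.frame of stage,
#'   input, dropped, output).
#' @export
candidateBranch <- function(cohort, config = pipelineConfig(),
                            rankedCommon = character(), analysis = "het") {
  stages <- list()
  note <- function(stage, before, after)
    data.frame(stage = stage, input = before, dropped = before - after,
               output = after)
  n0 <- nVariants(cohort)
  qc <- candidateQcFilter(cohort)
  cohort <- subsetVariants(cohort, qc$key[qc$keep])
  stages$qc <- note("qc", n0, nVariants(cohort))

  n0 <- nVariants(cohort)
  cohort <- commonVariantFilter(cohort, rankedCommon)
  stages$common <- note("common_list", n0, nVariants(cohort))

  n0 <- nVariants(cohort)
  cohort <- platformFilter(cohort, config@platformShare)
  stages$platform <- note("platform_share", n0, nVariants(cohort))

  n0 <- nVariants(cohort)
  mk <- mafFilter(cohort, config@mafHet, config@mafHom)
  keep <- if (analysis == "het") mk$keepHet else mk$keepHom
  cohort <- subsetVariants(cohort, mk$key[keep])
  stages$maf <- note("maf", n0, nVariants(cohort))

  list(cohort = cohort, tally = do.call(rbind, unname(stages)))
}

#' Run the burden-branch filters
#'
#' Applies the burden QC filter, the three-database rarity filter at
#' `threshold`, and restricts to damaging consequence classes (LoF and
#' D-Mis).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param threshold Rarity threshold (see [rareFilter()]).
#' @param classes Damaging classes to retain.
#' @return List with `cohort` (filtered) and `tally`.
#' @export
burdenBranch <- function(cohort, threshold = 1e-3,
                         classes = c("LoF", "D-Mis")) {
  stages <- list()
  note <- function(stage, before, after)
    data.frame(stage = stage, input = before, dropped = before - after,
               output = after)
  n0 <- nVariants(cohort)
  qc <- burdenQcFilter(cohort)
  cohort <- subsetVariants(cohort, qc$key[qc$keep])
  stages$qc <- note("qc", n0, nVariants(cohort))

  n0 <- nVariants(cohort)
  cohort <- subsetVariants(cohort,
                           variantKeys(cohort)[rareFilter(cohort, threshold)])
  stages$rare <- note("rare", n0, nVariants(cohort))

  n0 <- nVariants(cohort)
  cls <- consequenceClass(cohort)
  cohort <- subsetVariants(cohort, variantKeys(cohort)[cls %in% classes])
  stages$class <- note("damaging_class", n0, nVariants(cohort))

  list(cohort = cohort, tally = do.call(rbind, unname(stages)))
}
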