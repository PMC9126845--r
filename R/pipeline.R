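## Convenience wrappers running entire branches end to end.

#' Candidate-gene branch: filter then classify
#'
#' Runs [candidateBranch()] and classifies the surviving variants with
#' [percentileClassify()] (percentiles relative to the surviving set).
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param config A [PipelineConfig][pipelineConfig].
#' @param rankedCommon Optional ranked common-variant key list.
#' @param analysis `"het"` or `"hom"`.
#' @return List with `cohort`, `tally` and `classified`.
#' @export
runCandidateClassification <- function(cohort, config = pipelineConfig(),
                                       rankedCommon = character(),
                                       analysis = "het") {
  br <- candidateBranch(cohort, config, rankedCommon, analysis)
  classified <- if (nVariants(br$cohort))
    percentileClassify(br$cohort, config@percentileUpper,
                       config@percentileLower)
  else NULL
  c(br, list(classified = classified))
}

#' Burden branch: filter then test
#'
#' Runs [burdenBranch()] at the chosen rarity threshold and hands the
#' survivors to [runBurden()].
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param geneMut data.frame from [geneMutability()].
#' @param threshold Rarity threshold (see [rareFilter()]).
#' @param alpha Significance level before Bonferroni division.
#' @param classes Damaging classes retained.
#' @return List with `results` (see [runBurden()]), `tally`, and the
#'   filtered `cohort`.
#' @export
runBurdenPipeline <- function(cohort, geneMut, threshold = 1e-3,
                              alpha = 0.05, classes = c("LoF", "D-Mis")) {
  br <- burdenBranch(cohort, threshold, classes)
  results <- runBurden(br$cohort, geneMut, alpha)
  list(results = results, tally = br$tally, cohort = br$cohort)
}
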