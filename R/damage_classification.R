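## Consensus deleteriousness classification. Ten prediction tools each cast
## a vote (damaging = 1, equivocal = 0.5, tolerated = 0, missing = 0; the
## 0-10 scale stays fixed rather than renormalising for missing calls).
## Variants are ranked by vote count within the assessed set and classified
## by mid-rank percentile: >= 80th probably damaging, [50th, 80th)
## undetermined, < 50th likely benign; a variant above the 50th percentile
## with an unequivocal ClinVar pathogenic entry is upgraded to pathogenic.

voteLevels <- c("damaging", "tolerated", "equivocal", "missing")
voteScore <- c(damaging = 1, equivocal = 0.5, tolerated = 0, missing = 0)

#' Consensus vote count over the ten prediction tools
#'
#' Sums per-tool scores: damaging 1, equivocal 0.5, tolerated 0, missing 0
#' (missing calls are reported with a message). Half-point totals such as
#' 9.5 arise from equivocal calls.
#'
#' @param x A [VariantCohort][variantCohort], or a data.frame/matrix whose
#'   columns are exactly the ten configured tools (see [toolNames()]).
#' @return Numeric vector of vote counts in \[0, 10\].
#' @export
damageVoteCount <- function(x) {
  votes <- if (is(x, "VariantCohort")) variantData(x)[, toolNames()]
           else x
  extra <- setdiff(colnames(votes), toolNames())
  if (length(extra))
    stop("votes from unconfigured tool(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(toolNames(), colnames(votes))
  if (length(miss))
    stop("missing tool column(s): ", paste(miss, collapse = ", "))
  votes <- as.matrix(as.data.frame(votes)[, toolNames()])
  bad <- !(votes %in% voteLevels)
  if (any(bad))
    stop("invalid tool call value(s): ",
         paste(unique(votes[bad]), collapse = ", "))
  nMissing <- sum(votes == "missing")
  if (nMissing > 0)
    message(nMissing, " missing tool call(s) scored 0")
  out <- matrix(voteScore[votes], nrow = nrow(votes))
  rowSums(out)
}

## "unequivocal ClinVar pathogenic": label contains pathogenic / likely
## pathogenic with no benign / conflicting / uncertain token
isUnequivocalPathogenic <- function(label) {
  !is.na(label) & grepl("pathogenic", label, ignore.case = TRUE) &
    !grepl("benign|conflict|uncertain", label, ignore.case = TRUE)
}

#' Percentile-based four-way damage classification
#'
#' Computes each variant's mid-rank percentile of the consensus vote count
#' within the assessed set (fraction of variants with strictly smaller
#' count plus half the ties), then assigns: `pathogenic` when the
#' percentile exceeds `percentileLower` and ClinVar is unequivocally
#' pathogenic; otherwise `probably_damaging` at or above
#' `percentileUpper`; `undetermined` in between; `likely_benign` below
#' `percentileLower`. Percentiles are relative to the supplied set — pass
#' the set that survived the candidate-branch filters for the current run.
#'
#' @param cohort A [VariantCohort][variantCohort] (non-empty).
#' @param percentileUpper,percentileLower Class boundaries (defaults 0.80
#'   and 0.50).
#' @param clinvar Optional named character vector overriding the cohort's
#'   ClinVar labels (names are variant keys).
#' @return data.frame with `key`, `gene`, `votes`, `percentile`, `class`.
#' @export
percentileClassify <- function(cohort, percentileUpper = 0.80,
                               percentileLower = 0.50, clinvar = NULL) {
  if (nVariants(cohort) == 0)
    stop("percentiles are undefined on an empty assessed set")
  v <- variantData(cohort)
  votes <- damageVoteCount(cohort)
  perc <- (rank(votes, ties.method = "average") - 0.5) / length(votes)
  labels <- v$clinvar
  if (!is.null(clinvar))
    labels <- unname(clinvar[v$key])
  pathogenic <- perc > percentileLower & isUnequivocalPathogenic(labels)
  class <- ifelse(pathogenic, "pathogenic",
           ifelse(perc >= percentileUpper, "probably_damaging",
           ifelse(perc >= percentileLower, "undetermined", "likely_benign")))
  data.frame(key = v$key, gene = v$gene, votes = votes, percentile = perc,
             class = class, stringsAsFactors = FALSE)
}

damagingClasses <- c("pathogenic", "probably_damaging")

#' Per-gene damaging-variant occurrence counts
#'
#' Counts carrier-occurrences (one per carrier per variant; homozygous
#' carriage counts once) of pathogenic or probably-damaging variants in
#' the listed genes. Genes with zero occurrences are omitted.
#'
#' @param classified Output of [percentileClassify()].
#' @param cohort The matching [VariantCohort][variantCohort].
#' @param geneList Character vector of candidate gene symbols.
#' @return Named integer vector, gene -> occurrence count, sorted
#'   decreasing.
#' @export
perGeneDamagingCounts <- function(classified, cohort, geneList) {
  if (!length(geneList)) return(setNames(integer(0), character(0)))
  dmg <- classified$class %in% damagingClasses & classified$gene %in% geneList
  if (!any(dmg)) return(setNames(integer(0), character(0)))
  carriers <- rowSums(genotypes(cohort)[classified$key[dmg], ,
                                        drop = FALSE] > 0L)
  counts <- tapply(carriers, classified$gene[dmg], sum)
  sort(setNames(as.integer(counts), names(counts)), decreasing = TRUE)
}

#' Distribution of damaging candidate-gene variants per participant
#'
#' Histogram over participants of the number of pathogenic or
#' probably-damaging variants carried among the listed genes (variants,
#' not genes, are counted; a homozygous genotype counts once). Includes
#' `k = 0`, so counts sum to the cohort size.
#'
#' @inheritParams perGeneDamagingCounts
#' @return Named integer vector: k -> number of participants with exactly
#'   k damaging variants.
#' @export
perPersonDamagingHistogram <- function(classified, cohort, geneList) {
  dmg <- classified$class %in% damagingClasses & classified$gene %in% geneList
  perPerson <- if (any(dmg))
    colSums(genotypes(cohort)[classified$key[dmg], , drop = FALSE] > 0L)
  else rep(0L, length(sampleIds(cohort)))
  tab <- table(factor(perPerson, levels = 0:max(perPerson)))
  setNames(as.integer(tab), names(tab))
}

#' Carrier versus noncarrier lipid comparison
#'
#' Partitions the cohort by carriage of at least one pathogenic or
#' probably-damaging variant in a gene set and compares a lipid variable
#' between carriers and noncarriers via [compareDistributions()] under the
#' study's transform table.
#'
#' @inheritParams perGeneDamagingCounts
#' @param participants data.frame with an `id` column matching the
#'   cohort's sample ids and the lipid variable.
#' @param geneSet Character vector of gene symbols defining carriage.
#' @param variable Column name of the lipid variable (e.g. `"ldl"`).
#' @param transform Transform passed to [compareDistributions()].
#' @return List with carrier/noncarrier n, mean, sd, and the two-sided p.
#' @export
carrierAssociation <- function(classified, cohort, participants, geneSet,
                               variable, transform = "none") {
  dmg <- classified$class %in% damagingClasses & classified$gene %in% geneSet
  carrierIds <- if (any(dmg))
    sampleIds(cohort)[colSums(genotypes(cohort)[classified$key[dmg], ,
                                                drop = FALSE] > 0L) > 0]
  else character(0)
  isCarrier <- participants$id %in% carrierIds
  if (!any(isCarrier)) stop("no carriers of the gene set in the cohort")
  if (all(isCarrier)) stop("no noncarriers of the gene set in the cohort")
  a <- participants[[variable]][isCarrier]
  b <- participants[[variable]][!isCarrier]
  list(nCarrier = sum(isCarrier), nNoncarrier = sum(!isCarrier),
       carrierMean = mean(a, na.rm = TRUE), carrierSd = sd(a, na.rm = TRUE),
       noncarrierMean = mean(b, na.rm = TRUE),
       noncarrierSd = sd(b, na.rm = TRUE),
       p = compareDistributions(a, b, transform))
}
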