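## Central S4 classes. Variant payloads ride in a plain data.frame slot with
## a fixed column schema (see annotationColumns()) plus an integer dosage
## matrix; the classes exist to enforce the invariants the pipeline assumes.

#' Names of the ten deleteriousness prediction tools
#'
#' The consensus vote is taken over exactly these ten tools: SIFT,
#' PolyPhen-2 (HVAR), MutationTaster, MutationAssessor, FATHMM, PROVEAN,
#' MetaSVM, MetaLR, M-CAP and FATHMM-MKL. Annotation tables must carry one
#' column per tool, each entry one of `"damaging"`, `"tolerated"`,
#' `"equivocal"` or `"missing"`.
#'
#' @return Character vector of length 10 (annotation column names).
#' @export
toolNames <- function() {
  c("sift", "polyphen_hvar", "mutation_taster", "mutation_assessor",
    "fathmm", "provean", "metasvm", "metalr", "mcap", "fathmm_mkl")
}

## columns every annotation table / variants slot must carry, beyond the
## VCF fixed fields (chrom, pos, ref, alt, key, qual, dp, mq)
annotationColumns <- function() {
  c("gene", "consequence", "gq", "callers", "alt_reads", "lcr_flag",
    "vqsr_pass", "maf_gnomad", "maf_exac", "maf_1kg", "maf_esp",
    toolNames(), "metasvm_call", "clinvar")
}

variantColumns <- function() {
  c("chrom", "pos", "ref", "alt", "key", "qual", "dp", "mq",
    annotationColumns(), "annotated")
}

consequenceLevels <- function() {
  c("missense", "stop-gain", "stop-loss", "frameshift-indel", "splice-site",
    "start-loss", "synonymous", "intronic", "intergenic", "UTR",
    "other-indel")
}

lofConsequences <- function() {
  c("stop-gain", "stop-loss", "frameshift-indel", "splice-site",
    "start-loss")
}

callerNames <- function() {
  c("GATK-UG", "GATK-HC", "Freebayes", "Samtools", "VarDict")
}

#' @rdname PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  selectionQuantile = "numeric",
  mafHet = "numeric",
  mafHom = "numeric",
  burdenThresholds = "numeric",
  platformShare = "numeric",
  percentileUpper = "numeric",
  percentileLower = "numeric",
  alpha = "numeric",
  seed = "integer",
  paths = "list"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  frac1 <- c(selectionQuantile = object@selectionQuantile,
             mafHet = object@mafHet, mafHom = object@mafHom,
             platformShare = object@platformShare, alpha = object@alpha)
  bad <- frac1 < 0 | frac1 > 1
  if (any(bad))
    msg <- c(msg, paste0("fractions outside [0,1]: ",
                         paste(names(frac1)[bad], collapse = ", ")))
  if (!(object@percentileLower > 0 &&
        object@percentileLower < object@percentileUpper &&
        object@percentileUpper < 1))
    msg <- c(msg, "need 0 < lower percentile < upper percentile < 1")
  if (is.unsorted(object@burdenThresholds, strictly = TRUE))
    msg <- c(msg, "burdenThresholds must be sorted strictly ascending")
  if (any(object@burdenThresholds < 0 | object@burdenThresholds > 1))
    msg <- c(msg, "burdenThresholds must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis chain. Defaults are the
#' study's operating points: selection below the 10th-percentile isopleth,
#' gnomAD MAF cutoffs 0.01 (heterozygous) / 0.05 (homozygous), burden-branch
#' rarity thresholds 1e-5 / 1e-4 / 1e-3, removal of variants carried by more
#' than 40% of samples, and consensus-percentile class boundaries at the
#' 80th and 50th percentiles.
#'
#' @param selectionQuantile Isopleth quantile level (fraction in (0,1)).
#' @param mafHet,mafHom gnomAD MAF cutoffs for the heterozygous and
#'   homozygous candidate analyses.
#' @param burdenThresholds Ascending MAF thresholds for the burden branch.
#' @param platformShare Carrier-share cutoff for platform-specific variants.
#' @param percentileUpper,percentileLower Consensus-vote percentile cutoffs
#'   separating probably-damaging / undetermined / likely-benign.
#' @param alpha Significance level before per-gene Bonferroni division.
#' @param seed Integer seed recorded alongside the configuration.
#' @param paths Optional named list of file paths (gene lists, rate table,
#'   gene sets).
#' @return A `PipelineConfig` object.
#' @seealso [readPipelineConfig()] to load one from YAML.
#' @export
pipelineConfig <- function(selectionQuantile = 0.10,
                           mafHet = 0.01, mafHom = 0.05,
                           burdenThresholds = c(1e-5, 1e-4, 1e-3),
                           platformShare = 0.40,
                           percentileUpper = 0.80, percentileLower = 0.50,
                           alpha = 0.05, seed = 1L, paths = list()) {
  new("PipelineConfig",
      selectionQuantile = selectionQuantile, mafHet = mafHet,
      mafHom = mafHom, burdenThresholds = as.numeric(burdenThresholds),
      platformShare = platformShare, percentileUpper = percentileUpper,
      percentileLower = percentileLower, alpha = alpha,
      seed = as.integer(seed), paths = paths)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      "  isopleth quantile : ", object@selectionQuantile, "\n",
      "  MAF het/hom       : ", object@mafHet, "/", object@mafHom, "\n",
      "  burden thresholds : ",
      paste(format(object@burdenThresholds, scientific = TRUE),
            collapse = ", "), "\n",
      "  platform share    : ", object@platformShare, "\n",
      "  percentiles       : ", object@percentileLower, "-",
      object@percentileUpper, "\n",
      "  alpha / seed      : ", object@alpha, " / ", object@seed, "\n",
      sep = "")
})

#' @rdname IsoplethModel-class
#' @exportClass IsoplethModel
setClass("IsoplethModel", representation(
  m1 = "numeric", m2 = "numeric", m3 = "numeric", q = "numeric"
))

setValidity("IsoplethModel", function(object) {
  msg <- character()
  if (object@m2 <= 0) msg <- c(msg, "m2 must be positive")
  if (object@q <= 0 || object@q >= 1) msg <- c(msg, "q must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Hyperbolic quantile isopleth in the TG / HDL-C plane
#'
#' The selection curve has the form `y = m1 + m2 * m3 / (m2 + x)` with `y`
#' HDL-C and `x` triglycerides, both mg/dl. With `m3 > 0` the threshold
#' decreases monotonically in TG, capturing the inverse hyperbolic TG-HDL
#' relationship; `q` records the quantile level the curve was fitted at.
#'
#' @param m1,m2,m3 Curve constants (mg/dl; `m2 > 0`).
#' @param q Quantile level in (0,1).
#' @return An `IsoplethModel` object.
#' @seealso [fitIsopleth()], [isoplethThreshold()], [selectBelowIsopleth()].
#' @export
isoplethModel <- function(m1, m2, m3, q = 0.10) {
  new("IsoplethModel", m1 = m1, m2 = m2, m3 = m3, q = q)
}

setMethod("show", "IsoplethModel", function(object) {
  cat(sprintf(
    "IsoplethModel: HDL-C = %.4g + (%.4g * %.4g)/(%.4g + TG) at q = %.3g\n",
    object@m1, object@m2, object@m3, object@m2, object@q))
})

#' @rdname MutationRateTable-class
#' @exportClass MutationRateTable
setClass("MutationRateTable", representation(
  rates = "numeric"   # named, key "<5'><ref><3'>><alt>", length 192
))

setValidity("MutationRateTable", function(object) {
  msg <- character()
  if (length(object@rates) != 192)
    msg <- c(msg, sprintf("expected 192 context rates, got %d",
                          length(object@rates)))
  if (any(object@rates <= 0)) msg <- c(msg, "all rates must be positive")
  want <- contextKeys()
  miss <- setdiff(want, names(object@rates))
  if (length(miss))
    msg <- c(msg, paste0("missing contexts: ",
                         paste(head(miss, 5), collapse = ", "),
                         if (length(miss) > 5) ", ..."))
  if (length(msg)) msg else TRUE
})

## all 64 * 3 substitution keys
contextKeys <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, ref = b, p3 = b, alt = b,
                   stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  paste0(g$p5, g$ref, g$p3, ">", g$alt)
}

setMethod("show", "MutationRateTable", function(object) {
  cat(sprintf(
    "MutationRateTable: 192 trinucleotide substitution rates, range [%.3g, %.3g] per site per generation\n",
    min(object@rates), max(object@rates)))
})

#' Look up trinucleotide substitution rates
#'
#' @param x A `MutationRateTable`.
#' @param p5,ref,p3,alt Vectors of single bases (5' flank, reference,
#'   3' flank, alternate).
#' @return Numeric vector of rates per site per generation.
#' @export
contextRate <- function(x, p5, ref, p3, alt) {
  stopifnot(is(x, "MutationRateTable"))
  unname(x@rates[paste0(p5, ref, p3, ">", alt)])
}

#' @rdname VariantCohort-class
#' @exportClass VariantCohort
setClass("VariantCohort", representation(
  variants = "data.frame",
  genotypes = "matrix"    # integer dosage, rows = variant key, cols = sample
))

setValidity("VariantCohort", function(object) {
  v <- object@variants
  g <- object@genotypes
  msg <- character()
  miss <- setdiff(variantColumns(), names(v))
  if (length(miss))
    msg <- c(msg, paste0("variants missing columns: ",
                         paste(miss, collapse = ", ")))
  if (nrow(v) != nrow(g))
    msg <- c(msg, "genotype rows must match variant rows")
  else if (nrow(v) && !identical(rownames(g), v$key))
    msg <- c(msg, "genotype rownames must equal variant keys")
  if (nrow(v)) {
    if (anyDuplicated(v$key))
      msg <- c(msg, "duplicate variant keys")
    if (any(v$pos < 1)) msg <- c(msg, "positions must be >= 1 (1-based)")
    if (!all(g %in% 0:2)) msg <- c(msg, "dosages must be 0, 1 or 2")
    mafs <- as.matrix(v[, c("maf_gnomad", "maf_exac", "maf_1kg", "maf_esp")])
    if (any(mafs < 0 | mafs > 1, na.rm = TRUE))
      msg <- c(msg, "population MAFs must lie in [0,1]")
    both <- !is.na(v$alt_reads) & !is.na(v$dp)
    if (any(v$alt_reads[both] > v$dp[both]))
      msg <- c(msg, "alt-supporting reads exceed DP")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a variant cohort
#'
#' A `VariantCohort` pairs a per-allele variant table (VCF fixed fields plus
#' the annotation payload: gene, consequence, QC metrics, caller set,
#' population MAFs, ten prediction-tool calls, MetaSVM call, ClinVar label)
#' with an integer allele-dosage matrix (0 = reference, 1 = heterozygous,
#' 2 = homozygous alternate), one row per variant and one column per
#' participant. Multi-allelic sites are represented decomposed, one row per
#' alternate allele.
#'
#' @param variants data.frame with the columns listed by
#'   `hdlexome:::variantColumns()`.
#' @param genotypes Integer matrix of dosages with rownames equal to
#'   `variants$key` and one column per participant id.
#' @return A `VariantCohort` object.
#' @seealso [readVariants()], [writeVariants()], [simulateVariants()].
#' @export
variantCohort <- function(variants, genotypes) {
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- variants$key
  new("VariantCohort", variants = variants, genotypes = genotypes)
}

setMethod("show", "VariantCohort", function(object) {
  cat(sprintf("VariantCohort: %d variants x %d participants\n",
              nrow(object@variants), ncol(object@genotypes)))
  if (nrow(object@variants)) {
    tab <- sort(table(object@variants$consequence), decreasing = TRUE)
    cat("  consequences: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n", sep = "")
  }
})

#' Accessors for VariantCohort
#'
#' `variantData()` returns the variant table, `genotypes()` the dosage
#' matrix, `sampleIds()` the participant ids, `variantKeys()` the
#' `chrom:pos:ref:alt` keys, and `nVariants()` the record count.
#'
#' @param x A `VariantCohort`.
#' @return See details per accessor.
#' @name VariantCohort-accessors
NULL

#' @rdname VariantCohort-accessors
#' @export
variantData <- function(x) x@variants

#' @rdname VariantCohort-accessors
#' @export
genotypes <- function(x) x@genotypes

#' @rdname VariantCohort-accessors
#' @export
sampleIds <- function(x) colnames(x@genotypes)

#' @rdname VariantCohort-accessors
#' @export
variantKeys <- function(x) x@variants$key

#' @rdname VariantCohort-accessors
#' @export
nVariants <- function(x) nrow(x@variants)

#' Subset a cohort to a set of variant keys
#'
#' @param x A `VariantCohort`.
#' @param keys Character vector of `chrom:pos:ref:alt` keys (order kept as
#'   in the cohort).
#' @return A `VariantCohort` restricted to `keys`.
#' @export
subsetVariants <- function(x, keys) {
  keep <- x@variants$key %in% keys
  variantCohort(x@variants[keep, , drop = FALSE],
                x@genotypes[keep, , drop = FALSE])
}
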