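## Readers / writers for every external format the pipeline touches.
## Coordinates are 1-based fully closed throughout, as in VCF. Annotations
## travel in a sidecar tab-delimited table keyed by chrom:pos:ref:alt;
## embedding ten tool calls and four MAF sources in INFO would be lossy.

#' Build a chrom:pos:ref:alt variant key
#'
#' @param chrom,pos,ref,alt Vectors of the four key components.
#' @return Character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a cohort from a VCF plus annotation sidecar
#'
#' Reads a VCF v4.2 file (per-sample GT; INFO keys DP, MQ, AC) through
#' `VariantAnnotation::readVcf` and joins the annotation table on the
#' `chrom:pos:ref:alt` key. Multi-allelic sites are decomposed on read, one
#' record per alternate allele, since every downstream rule is per-allele.
#' Records without an annotation row are kept with `annotated = FALSE` and
#' all tool votes `"missing"` — never silently defaulted to passing values.
#'
#' @param vcfPath Path to a plain-text VCF.
#' @param annotationPath Path to the tab-delimited annotation table with a
#'   `key` column plus the columns listed by `hdlexome:::annotationColumns()`.
#' @return A [VariantCohort][variantCohort].
#' @export
readVariants <- function(vcfPath, annotationPath) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = "cohort")),
    error = function(e) {
      stop("failed to parse VCF '", vcfPath, "': ", conditionMessage(e),
           call. = FALSE)
    })
  rr <- SummarizedExperiment::rowRanges(vcf)
  nSite <- length(rr)
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  siteIdx <- rep(seq_len(nSite), nAlt)
  altIdx <- sequence(nAlt)

  info <- VariantAnnotation::info(vcf)
  fixed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[siteIdx],
    pos = GenomicRanges::start(rr)[siteIdx],
    ref = as.character(VariantAnnotation::ref(vcf))[siteIdx],
    alt = unlist(lapply(altList, as.character), use.names = FALSE),
    qual = as.numeric(VariantAnnotation::fixed(vcf)$QUAL)[siteIdx],
    dp = as.integer(info$DP)[siteIdx],
    mq = as.numeric(info$MQ)[siteIdx],
    stringsAsFactors = FALSE)
  fixed$key <- variantKey(fixed$chrom, fixed$pos, fixed$ref, fixed$alt)

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  tokens <- strsplit(as.vector(gt), "[/|]")
  dim(tokens) <- dim(gt)
  dos <- matrix(0L, nrow(fixed), length(samples),
                dimnames = list(fixed$key, samples))
  for (r in seq_len(nrow(fixed))) {
    want <- as.character(altIdx[r])
    dos[r, ] <- vapply(tokens[siteIdx[r], ],
                       function(tk) sum(tk == want), integer(1))
  }

  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  need <- c("key", annotationColumns())
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(ann$key[duplicated(ann$key)])
  if (length(dup))
    stop("duplicate annotation keys: ", paste(dup, collapse = ", "))

  m <- match(fixed$key, ann$key)
  out <- cbind(fixed, ann[m, annotationColumns(), drop = FALSE])
  rownames(out) <- NULL
  out$annotated <- !is.na(m)
  for (tool in toolNames())
    out[[tool]][is.na(m)] <- "missing"
  out$metasvm_call[is.na(m)] <- "missing"
  out$lcr_flag <- as.logical(out$lcr_flag)
  out$vqsr_pass <- as.logical(out$vqsr_pass)
  variantCohort(out, dos)
}

#' Write a cohort as VCF plus annotation sidecar
#'
#' Emits a minimal VCF v4.2 (GT genotypes; INFO DP, MQ, AC) and the
#' tab-delimited annotation table that [readVariants()] consumes. Records
#' are written already decomposed, one line per alternate allele.
#'
#' @param cohort A [VariantCohort][variantCohort].
#' @param vcfPath,annotationPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeVariants <- function(cohort, vcfPath, annotationPath) {
  v <- variantData(cohort)
  g <- genotypes(cohort)
  samples <- colnames(g)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  ord <- order(v$chrom, v$pos)
  body <- vapply(ord, function(i) {
    info <- sprintf("DP=%d;MQ=%g;AC=%d", v$dp[i], v$mq[i], sum(g[i, ]))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
            format(v$qual[i]), "PASS", info, "GT", gtStr[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcfPath)

  ann <- v[, c("key", annotationColumns()), drop = FALSE]
  write.table(ann, annotationPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = vcfPath, annotation = annotationPath))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Duplicate members within a set are dropped.
#'
#' @param gmtPath Path to a GMT file.
#' @return Named list of character vectors of member symbols, with set
#'   descriptions in `attr(, "description")`. An empty file gives an empty
#'   list.
#' @export
readGeneSets <- function(gmtPath) {
  lines <- readLines(gmtPath)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line ", i, " has fewer than 3 columns")
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line ", i, " (set '", parts[1], "') has no members")
    sets[[parts[1]]] <- members
    desc[parts[1]] <- parts[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of unique, non-empty symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a trinucleotide substitution-rate table
#'
#' Expects tab-delimited rows of (5' base, ref base, 3' base, alt base,
#' rate per site per generation). A full 192-row table is validated as-is;
#' a 96-row pyrimidine-centred table (ref C or T) is expanded to 192 by
#' strand symmetry (each context also keyed by its reverse complement).
#'
#' @param path Path to the rate table.
#' @return A [MutationRateTable][MutationRateTable-class].
#' @export
readRateTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("p5", "ref", "p3", "alt", "rate")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("rate table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$rate <= 0))
    stop("rate table contains non-positive rates")
  keys <- paste0(tab$p5, tab$ref, tab$p3, ">", tab$alt)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    agg <- tapply(tab$rate, keys, function(r) length(unique(r)))
    conflict <- dup[agg[dup] > 1]
    if (length(conflict))
      stop("conflicting duplicate context rows: ",
           paste(conflict, collapse = ", "))
    keep <- !duplicated(keys)
    tab <- tab[keep, ]
    keys <- keys[keep]
  }
  rates <- setNames(tab$rate, keys)
  if (all(tab$ref %in% c("C", "T")) && length(rates) == 96) {
    rc <- c(A = "T", C = "G", G = "C", T = "A")
    mirror <- setNames(tab$rate, paste0(
      rc[tab$p3], rc[tab$ref], rc[tab$p5], ">", rc[tab$alt]))
    rates <- c(rates, mirror)
  }
  missing <- setdiff(contextKeys(), names(rates))
  if (length(missing))
    stop("rate table missing ", length(missing), " contexts: ",
         paste(head(missing, 8), collapse = ", "),
         if (length(missing) > 8) ", ...")
  new("MutationRateTable", rates = rates[contextKeys()])
}

#' Built-in synthetic substitution-rate model
#'
#' A deterministic stand-in for an empirical trinucleotide mutation-rate
#' table (the genuine per-context estimates are not redistributable here).
#' Transitions run fourfold faster than transversions, CpG transitions
#' (C>T with a 3' G, and the strand mirror G>A with a 5' C) tenfold faster
#' again, with a mild deterministic flank modulation so contexts are
#' distinguishable. The table is strand-symmetric by construction.
#'
#' @return A [MutationRateTable][MutationRateTable-class] with 192 entries.
#' @export
makeRateTable <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, ref = b, p3 = b, alt = b,
                   stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  transition <- (g$ref == "A" & g$alt == "G") |
    (g$ref == "G" & g$alt == "A") |
    (g$ref == "C" & g$alt == "T") | (g$ref == "T" & g$alt == "C")
  rate <- ifelse(transition, 4e-8, 1e-8)
  cpg <- (g$ref == "C" & g$p3 == "G" & g$alt == "T") |
    (g$ref == "G" & g$p5 == "C" & g$alt == "A")
  rate[cpg] <- 1e-7
  ## symmetric flank modulation: weight(p5, p3) == weight(rc(p3), rc(p5))
  w <- c(A = 1, C = 2, G = 2, T = 1)
  rate <- rate * (1 + 0.05 * (w[g$p5] + w[g$p3]))
  new("MutationRateTable",
      rates = setNames(as.numeric(rate),
                       paste0(g$p5, g$ref, g$p3, ">", g$alt))[contextKeys()])
}

#' Write a rate table to disk
#'
#' @param rates A [MutationRateTable][MutationRateTable-class].
#' @param path Output path (tab-delimited, 192 rows).
#' @return Invisibly, `path`.
#' @export
writeRateTable <- function(rates, path) {
  keys <- names(rates@rates)
  tab <- data.frame(p5 = substr(keys, 1, 1), ref = substr(keys, 2, 2),
                    p3 = substr(keys, 3, 3), alt = substr(keys, 5, 5),
                    rate = unname(rates@rates))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a participants table
#'
#' Tab-delimited lipid panel and demographics: `id`, `sex` ("F"/"M"),
#' `age` (years), `ethnicity`, `tc`, `tg`, `hdl`, `ldl`, `prebeta`
#' (mg/dl; `ldl`/`prebeta` may be NA), `bmi`, clinical flags (`cad`, `mi`,
#' `diabetes`, `hypertension`, `smoker`; logical or NA) and `group`
#' (1-4 or NA).
#'
#' @param path File path.
#' @param participants data.frame in the layout above.
#' @return `readParticipants` returns the data.frame; `writeParticipants`
#'   returns `path` invisibly.
#' @export
readParticipants <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  for (fl in c("cad", "mi", "diabetes", "hypertension", "smoker"))
    if (fl %in% names(p)) p[[fl]] <- as.logical(p[[fl]])
  p
}

#' @rdname readParticipants
#' @export
writeParticipants <- function(participants, path) {
  write.table(participants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipelineConfig()]; unknown keys
#' are an error so typos never silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A [PipelineConfig][pipelineConfig].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, y)
}
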