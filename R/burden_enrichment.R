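## Mutability-calibrated gene burden testing. Per-gene expected damaging
## counts follow the de novo expectation model: each gene's share of the
## total damaging count N is its trinucleotide-context mutability divided
## by the summed mutability of all tested genes, and enrichment is judged
## by a one-sided binomial tail P(X >= observed) with X ~ Binom(N, p_i).

#' Per-class SNV mutability of a coding sequence
#'
#' Enumerates all `3L` single-nucleotide substitutions of an `L`-base
#' coding sequence (supplied with one flanking base on each side for
#' trinucleotide context), classifies each by its coding consequence under
#' the standard genetic code read in frame from position 1, and sums the
#' context substitution rates per class. Start-loss (first codon ATG
#' destroyed), stop-gain and stop-loss all count toward LoF. Frameshift
#' and splice contributions are not derivable from an SNV context model;
#' they enter as the additive factor in [geneMutability()].
#'
#' @param cds Character scalar: the coding sequence with one extra base at
#'   each end (total length `L + 2`, `L` divisible by 3, bases ACGT only).
#' @param rates A [MutationRateTable][MutationRateTable-class].
#' @param class One of `"LoF"`, `"missense"`, `"synonymous"`, `"other"`,
#'   `"total"`.
#' @return Per-generation probability of a de novo substitution of that
#'   class.
#' @export
snvMutabilityFromCds <- function(cds, rates,
                                 class = c("LoF", "missense", "synonymous",
                                           "other", "total")) {
  class <- match.arg(class)
  s <- strsplit(toupper(cds), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence contains ambiguity codes or invalid bases")
  L <- length(s) - 2L
  if (L < 3 || L %% 3 != 0)
    stop("coding length (", L, ") must be positive and divisible by 3")
  coding <- s[2:(L + 1)]
  codons <- paste0(coding[seq(1, L, 3)], coding[seq(2, L, 3)],
                   coding[seq(3, L, 3)])
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")

  pos <- rep(seq_len(L), each = 3)
  ref <- coding[pos]
  alt <- unlist(lapply(coding, function(b) bases[bases != b]),
                use.names = FALSE)
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  refCodon <- codons[ci]
  altCodon <- refCodon
  substr(altCodon, off, off) <- alt
  refAA <- unname(code[refCodon])
  altAA <- unname(code[altCodon])

  cls <- ifelse(ci == 1L & refCodon == "ATG", "LoF",            # start-loss
         ifelse(refAA == "*" & altAA != "*", "LoF",             # stop-loss
         ifelse(altAA == "*" & refAA != "*", "LoF",             # stop-gain
         ifelse(refAA == altAA, "synonymous", "missense"))))
  r <- contextRate(rates, s[pos], ref, s[pos + 2L], alt)
  if (class == "total") return(sum(r))
  sum(r[cls == class])
}

#' Per-gene mutability table
#'
#' Computes LoF, damaging-missense and synonymous SNV mutabilities for each
#' roster gene from its coding sequence, inflates the LoF class by
#' `indelFactor` times the nonsense SNV mutability to stand in for
#' frameshift and splice events, takes `dmisFraction` of the missense
#' mutability as the damaging-missense share, and applies any per-gene
#' coverage factor. The `damaging` column (LoF + D-Mis) drives
#' [expectedCounts()].
#'
#' @param roster data.frame with `gene` and `cds` columns (sequences with
#'   one flanking base each side, as for [snvMutabilityFromCds()]).
#' @param rates A [MutationRateTable][MutationRateTable-class].
#' @param indelFactor Frameshift/splice add-on as a multiple of the SNV
#'   LoF mutability (default 1.25).
#' @param dmisFraction Fraction of missense mutability counted as damaging
#'   missense (default 0.35).
#' @param coverage Optional named numeric in \[0,1\]: per-gene fraction of
#'   coding bases adequately covered (depth >= 10 in >= 90% of samples);
#'   defaults to 1 for all genes.
#' @return data.frame with `gene`, `lof`, `dmis`, `synonymous`, `damaging`
#'   and `coverage` columns.
#' @export
geneMutability <- function(roster, rates, indelFactor = 1.25,
                           dmisFraction = 0.35, coverage = NULL) {
  lofSnv <- vapply(roster$cds, snvMutabilityFromCds, numeric(1),
                   rates = rates, class = "LoF")
  mis <- vapply(roster$cds, snvMutabilityFromCds, numeric(1),
                rates = rates, class = "missense")
  syn <- vapply(roster$cds, snvMutabilityFromCds, numeric(1),
                rates = rates, class = "synonymous")
  out <- data.frame(gene = roster$gene,
                    lof = unname(lofSnv * (1 + indelFactor)),
                    dmis = unname(mis * dmisFraction),
                    synonymous = unname(syn),
                    stringsAsFactors = FALSE)
  out$damaging <- out$lof + out$dmis
  cov <- rep(1, nrow(out))
  if (!is.null(coverage)) {
    m <- match(out$gene, names(coverage))
    cov[!is.na(m)] <- coverage[m[!is.na(m)]]
  }
  out <- coverageAdjust(out, cov)
  out
}

#' Apply a coverage adjustment to gene mutabilities
#'
#' Multiplies each class mutability by the fraction of the gene's coding
#' bases adequately covered. Genes scaled to zero are flagged with a
#' warning — they carry no information and are excluded from testing.
#'
#' @param geneMut data.frame as from [geneMutability()].
#' @param coveredFraction Numeric in \[0,1\], recycled over genes.
#' @return `geneMut` with scaled mutabilities and a `coverage` column.
#' @export
coverageAdjust <- function(geneMut, coveredFraction) {
  if (any(coveredFraction < 0 | coveredFraction > 1))
    stop("coverage fractions must lie in [0,1]")
  for (cl in c("lof", "dmis", "synonymous", "damaging"))
    geneMut[[cl]] <- geneMut[[cl]] * coveredFraction
  geneMut$coverage <- coveredFraction
  if (any(geneMut$damaging == 0))
    warning(sum(geneMut$damaging == 0),
            " gene(s) with zero adjusted mutability excluded from testing")
  geneMut
}

#' Expected damaging counts under the mutability model
#'
#' `p_i = mutability_i / sum(mutability)`, `expected_i = N * p_i`, so the
#' expected counts sum to `N` by construction.
#'
#' @param N Total damaging variant count across genes.
#' @param mutability Named numeric vector of adjusted per-gene
#'   mutabilities (at least one positive).
#' @return data.frame with `gene`, `p` and `expected`.
#' @export
expectedCounts <- function(N, mutability) {
  if (N < 0) stop("N must be non-negative")
  if (all(mutability <= 0)) stop("all gene mutabilities are zero")
  p <- mutability / sum(mutability)
  p <- p / sum(p)
  expected <- N * p
  s <- sum(expected)
  if (s > 0) expected <- expected * (N / s)   # pin the sum to N exactly
  data.frame(gene = names(mutability), p = unname(p),
             expected = unname(expected), stringsAsFactors = FALSE)
}

#' One-sided binomial burden p-value
#'
#' `P(X >= observed)` for `X ~ Binomial(N, p)`, computed through the
#' binomial survival function, which stays accurate for small `p` and
#' large `N` where naive term summation loses precision.
#'
#' @param observed Observed damaging count (0..N; vectorised).
#' @param N Total damaging count.
#' @param p Per-gene success probability.
#' @return One-sided p-value in (0, 1\].
#' @export
binomialBurden <- function(observed, N, p) {
  if (any(observed < 0) || any(observed > N))
    stop("observed must lie in [0, N]")
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  stats::pbinom(observed - 1, size = N, prob = p, lower.tail = FALSE)
}

#' Gene-burden test across a cohort
#'
#' Takes a cohort already restricted by [burdenBranch()] (burden QC,
#' rarity at the chosen threshold, LoF / D-Mis classes), counts damaging
#' heterozygous carrier-occurrences per gene, sets `N` to their total,
#' computes mutability-proportional expectations and one-sided binomial
#' p-values, and flags genes passing the Bonferroni-style threshold
#' `alpha / (number of genes with positive adjusted mutability)`.
#'
#' @param cohort A filtered [VariantCohort][variantCohort].
#' @param geneMut data.frame from [geneMutability()].
#' @param alpha Significance level before Bonferroni division.
#' @return data.frame sorted ascending by p: `gene`, `observed`,
#'   `expected`, `p_i`, `p`, `significant`, plus attributes `N` and
#'   `threshold`.
#' @export
runBurden <- function(cohort, geneMut, alpha = 0.05) {
  tested <- geneMut[geneMut$damaging > 0, , drop = FALSE]
  if (!nrow(tested)) stop("no genes with positive adjusted mutability")
  v <- variantData(cohort)
  hetPerVariant <- rowSums(genotypes(cohort) == 1L)
  inRoster <- v$gene %in% tested$gene
  if (any(!inRoster & hetPerVariant > 0))
    warning(sum(!inRoster), " variant(s) in genes without mutability ",
            "estimates ignored")
  obs <- tapply(hetPerVariant[inRoster], v$gene[inRoster], sum)
  observed <- setNames(rep(0L, nrow(tested)), tested$gene)
  observed[names(obs)] <- as.integer(obs)
  N <- sum(observed)
  if (N == 0)
    warning("no retained damaging heterozygous occurrences; all p = 1")
  exp <- expectedCounts(N, setNames(tested$damaging, tested$gene))
  pv <- binomialBurden(unname(observed), N, exp$p)
  thr <- alpha / nrow(tested)
  out <- data.frame(gene = tested$gene, observed = unname(observed),
                    expected = exp$expected, p_i = exp$p, p = pv,
                    significant = pv < thr, stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$observed), ]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "threshold") <- thr
  out
}

#' Q-Q coordinates for a set of p-values
#'
#' Observed p-values sorted ascending against uniform order-statistic
#' means `i/(n+1)`, both on the -log10 scale. Zero p-values are clamped to
#' the smallest positive double with a message.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return data.frame with `expected` and `observed` (-log10 scale),
#'   ascending in `expected`.
#' @export
qqPoints <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0,1]")
  if (any(pvalues == 0)) {
    message(sum(pvalues == 0), " zero p-value(s) clamped")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  n <- length(pvalues)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(pvalues)))
}

#' Gene-set over-representation with FDR
#'
#' For each set: hits are the intersection with the hit list, the expected
#' hit count is `setSize * |hitList| / universe`, fold enrichment is
#' hits/expected, the raw p is the one-sided (greater) Fisher exact /
#' hypergeometric upper tail, and q-values are Benjamini-Hochberg across
#' all sets.
#'
#' @param hitList Character vector of hit gene symbols.
#' @param sets Named list of gene sets (see [readGeneSets()]).
#' @param universe Total number of genes in the reference universe.
#' @return data.frame sorted by q then p: `set`, `setSize`, `hits`,
#'   `expected`, `fold`, `p`, `q`, `hitGenes`.
#' @export
overrepresentation <- function(hitList, sets, universe) {
  hitList <- unique(hitList)
  nHit <- length(hitList)
  if (universe < nHit) stop("universe smaller than the hit list")
  sizes <- lengths(sets)
  if (any(sizes > universe))
    stop("gene set(s) larger than the universe: ",
         paste(names(sets)[sizes > universe], collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    hits <- intersect(hitList, members)
    k <- length(hits)
    expected <- length(members) * nHit / universe
    p <- stats::phyper(k - 1, length(members), universe - length(members),
                       nHit, lower.tail = FALSE)
    data.frame(set = nm, setSize = length(members), hits = k,
               expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, hitGenes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p), c("set", "setSize", "hits", "expected",
                                    "fold", "p", "q", "hitGenes")]
  rownames(out) <- NULL
  out
}
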