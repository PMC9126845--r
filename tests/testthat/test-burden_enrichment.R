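# independent brute-force oracle: classify one substitution by translating
# whole codons with seqinr, looping positions explicitly
oracleMutability <- function(cds, rates, class) {
  s <- strsplit(toupper(cds), "")[[1]]
  L <- length(s) - 2
  total <- 0
  for (i in seq_len(L)) {
    codonStart <- 2 + 3 * ((i - 1) %/% 3)
    off <- (i - 1) %% 3 + 1
    refCodon <- s[codonStart:(codonStart + 2)]
    for (alt in setdiff(c("A", "C", "G", "T"), s[i + 1])) {
      altCodon <- refCodon
      altCodon[off] <- alt
      refAA <- seqinr::translate(tolower(refCodon))
      altAA <- seqinr::translate(tolower(altCodon))
      cls <-
        if ((i - 1) %/% 3 == 0 && paste(refCodon, collapse = "") == "ATG")
          "LoF"
        else if (refAA == "*" && altAA != "*") "LoF"
        else if (altAA == "*" && refAA != "*") "LoF"
        else if (refAA == altAA) "synonymous"
        else "missense"
      if (cls == class)
        total <- total + contextRate(rates, s[i], s[i + 1], s[i + 2], alt)
    }
  }
  total
}

test_that("SNV mutability partitions over consequence classes", {
  set.seed(51)
  rates <- makeRateTable()
  for (rep in 1:3) {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * 20 + 2, replace = TRUE),
                 collapse = "")
    parts <- vapply(c("LoF", "missense", "synonymous", "other"),
                    function(cl) snvMutabilityFromCds(cds, rates, cl),
                    numeric(1))
    expect_equal(sum(parts), snvMutabilityFromCds(cds, rates, "total"),
                 tolerance = 1e-12)
  }
  expect_error(snvMutabilityFromCds("AACGTX", rates), "ambiguity")
  expect_error(snvMutabilityFromCds(paste(rep("A", 12), collapse = ""),
                                    makeRateTable()), "divisible by 3")
})

test_that("a lone TGG codon under uniform rates yields stop-gain 2r", {
  r <- 3e-8
  uni <- uniformRateTable(r)
  # flanked single codon TGG; TGG->TAG and TGG->TGA are the only stops
  expect_equal(snvMutabilityFromCds("ATGGA", uni, "LoF"), 2 * r,
               tolerance = 1e-15)
})

test_that("mutability matches the brute-force enumeration oracle", {
  skip_if_not_installed("seqinr")
  rates <- makeRateTable()
  # GGG codon: all four third-position states synonymous, six missense
  expect_equal(snvMutabilityFromCds("AGGGT", rates, "missense"),
               oracleMutability("AGGGT", rates, "missense"),
               tolerance = 1e-14)
  set.seed(52)
  cds <- paste(sample(c("A", "C", "G", "T"), 3 * 12 + 2, replace = TRUE),
               collapse = "")
  for (cl in c("LoF", "missense", "synonymous"))
    expect_equal(snvMutabilityFromCds(cds, rates, cl),
                 oracleMutability(cds, rates, cl), tolerance = 1e-12)
})

test_that("coverage adjustment scales all classes and flags dead genes", {
  roster <- makeGeneRoster(3, seed = 53, minLen = 150, maxLen = 300)
  gm <- geneMutability(roster, makeRateTable())
  half <- coverageAdjust(gm, 0.5)
  expect_equal(half$damaging, gm$damaging * 0.5)
  expect_equal(half$lof, gm$lof * 0.5)
  same <- coverageAdjust(gm, 1)
  expect_equal(same$damaging, gm$damaging)
  expect_warning(dead <- coverageAdjust(gm, c(1, 0, 1)), "zero adjusted")
  expect_equal(dead$damaging[2], 0)
  expect_error(coverageAdjust(gm, 1.2), "\\[0,1\\]")
})

test_that("expected counts are mutability shares of N, summing exactly", {
  ec <- expectedCounts(10, c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(ec$expected, c(2, 3, 5))
  expect_equal(expectedCounts(7, c(only = 0.1))$expected, 7)
  set.seed(54)
  mut <- runif(300, 1e-7, 1e-4)
  names(mut) <- paste0("g", seq_along(mut))
  ec2 <- expectedCounts(357, mut)
  expect_lt(abs(sum(ec2$expected) - 357), 1e-12)
  expect_error(expectedCounts(5, c(a = 0, b = 0)), "zero")
})

test_that("binomial tail agrees with term-by-term summation", {
  oracleTail <- function(obs, N, p) {
    if (obs == 0) return(1)
    k <- obs:N
    sum(exp(lchoose(N, k) + k * log(p) + (N - k) * log1p(-p)))
  }
  expect_equal(round(binomialBurden(3, 10, 0.1), 4), 0.0702)
  expect_equal(binomialBurden(0, 10, 0.1), 1)
  expect_equal(binomialBurden(10, 10, 1), 1)
  set.seed(55)
  for (i in 1:200) {
    N <- sample(1000, 1)
    p <- 10^runif(1, -6, -0.3)
    obs <- sample(0:min(N, 25), 1)
    mine <- binomialBurden(obs, N, p)
    orac <- oracleTail(obs, N, p)
    expect_lt(abs(mine - orac), 1e-10 * orac)
  }
  expect_error(binomialBurden(11, 10, 0.1), "observed")
})

test_that("binomial p is monotone in observed and in p_i", {
  ps <- binomialBurden(0:20, 50, 0.05)
  expect_true(all(diff(ps) < 0))
  grid <- vapply(c(0.01, 0.05, 0.1, 0.3), function(p)
    binomialBurden(5, 50, p), numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("the burden test flags a planted gene and handles edge cases", {
  roster <- makeGeneRoster(30, seed = 56, minLen = 150, maxLen = 450)
  rates <- makeRateTable()
  gm <- geneMutability(roster, rates)
  pG <- gm$damaging / sum(gm$damaging)
  target <- gm$gene[which.min(abs(pG - 1 / 30))]
  d <- simulationDesign(nParticipants = 100, roster = roster,
                        enrichment = setNames(10, target), seed = 56)
  p <- simulateLipids(d)
  sv <- simulateVariants(d, p, rates, geneMut = gm)
  res <- runBurdenPipeline(sv$cohort, gm, threshold = 1e-3)$results
  expect_equal(res$gene[1], target)
  expect_true(res$significant[1])
  expect_equal(attr(res, "threshold"), 0.05 / 30)
  expect_equal(sum(res$expected), attr(res, "N"), tolerance = 1e-12)

  # single tested gene holding every variant: p_i = 1, p-value 1
  one <- gm[gm$gene == roster$gene[1], ]
  cohort1 <- mkCohort(2, gene = roster$gene[1],
                      consequence = "stop-gain")
  r1 <- runBurden(cohort1, one)
  expect_equal(r1$p, 1)
  expect_equal(r1$p_i, 1)
})

test_that("Q-Q points use i/(n+1) uniform quantiles on -log10 scale", {
  one <- qqPoints(0.5)
  expect_equal(one$expected, log10(2))
  expect_equal(one$observed, log10(2))
  n <- 19
  diag <- qqPoints(seq_len(n) / (n + 1))
  expect_equal(diag$expected, diag$observed)
  set.seed(57)
  u <- runif(1000)
  qq <- qqPoints(u)
  expect_lt(median(abs(qq$observed - qq$expected)), 0.1)
  expect_message(z <- qqPoints(c(0, 0.5)), "clamped")
  expect_true(all(is.finite(z$observed)))
  expect_error(qqPoints(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("over-representation matches the hypergeometric oracle with BH", {
  sets <- list(atExpectation = paste0("g", 1:20),
               enriched = paste0("g", 1:20))
  hitsAt <- c(paste0("g", 1:2), paste0("x", 1:8))     # 2 of 20
  outAt <- overrepresentation(hitsAt, sets["atExpectation"], 100)
  expect_equal(outAt$expected, 2)
  expect_equal(outAt$fold, 1)
  expect_gt(outAt$p, 0.5)

  hitsEnr <- c(paste0("g", 1:8), paste0("x", 1:2))    # 8 of 20
  outEnr <- overrepresentation(hitsEnr, sets["enriched"], 100)
  expect_equal(outEnr$fold, 4)
  oracle <- sum(dhyper(8:10, 20, 80, 10))
  expect_equal(outEnr$p, oracle, tolerance = 1e-12)
  expect_equal(outEnr$q, outEnr$p)                    # single set: q = p
  expect_equal(outEnr$hitGenes, paste(sort(paste0("g", 1:8)),
                                      collapse = ","))

  # BH q-values are monotone step-up over the p-ordering
  set.seed(58)
  many <- lapply(1:15, function(i) sample(paste0("g", 1:60), 10))
  names(many) <- paste0("S", 1:15)
  out <- overrepresentation(paste0("g", 1:12), many, 100)
  expect_true(all(diff(out$q[order(out$p)]) >= -1e-12))
  expect_true(all(out$q >= out$p - 1e-12))
  expect_error(overrepresentation(paste0("g", 1:5), list(S = paste0("g", 1:30)),
                                  20), "larger than the universe")
})
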