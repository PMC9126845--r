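# helper: a cohort of n variants with prescribed vote counts, built by
# setting floor(v) tools damaging and one equivocal for half points
cohortWithVotes <- function(votes, clinvar = NA_character_, gene = "GENE001",
                            geno = NULL, samples = c("S1", "S2")) {
  n <- length(votes)
  args <- list(n = n, samples = samples, geno = geno, gene = gene,
               clinvar = clinvar)
  cohort <- do.call(mkCohort, args)
  v <- variantData(cohort)
  for (i in seq_len(n)) {
    full <- floor(votes[i])
    if (full > 0) for (tool in toolNames()[seq_len(full)])
      v[[tool]][i] <- "damaging"
    if (votes[i] - full == 0.5)
      v[[toolNames()[full + 1]]][i] <- "equivocal"
  }
  variantCohort(v, genotypes(cohort))
}

test_that("vote counts score damaging 1, equivocal 0.5, missing 0", {
  allDmg <- mkCohort(1)
  v <- variantData(allDmg)
  for (tool in toolNames()) v[[tool]] <- "damaging"
  expect_equal(damageVoteCount(variantCohort(v, genotypes(allDmg))), 10)

  v2 <- v; v2$sift <- "equivocal"
  expect_equal(damageVoteCount(variantCohort(v2, genotypes(allDmg))), 9.5)

  v3 <- variantData(mkCohort(1))
  for (tool in toolNames()) v3[[tool]] <- "missing"
  expect_message(
    z <- damageVoteCount(variantCohort(v3, genotypes(allDmg))), "missing")
  expect_equal(z, 0)

  badName <- matrix("damaging", 1, 10,
                    dimnames = list(NULL, c(toolNames()[-1], "cadd")))
  expect_error(damageVoteCount(badName), "unconfigured")
  badValue <- variantData(mkCohort(1)); badValue$sift <- "harmful"
  expect_error(damageVoteCount(variantCohort(badValue, genotypes(allDmg))),
               "invalid tool call")
})

test_that("percentile classification follows the 80/50 rules with ClinVar", {
  # 20 distinct vote counts 0.5..10 -> mid-rank percentile (k - 0.5)/20
  votes <- seq(0.5, 10, by = 0.5)
  cl <- c(rep(NA_character_, 20))
  cl[13] <- "Pathogenic"       # percentile 0.625: upgraded
  cl[8] <- "Pathogenic"        # percentile 0.375: stays likely_benign
  out <- percentileClassify(cohortWithVotes(votes, clinvar = cl))
  expect_equal(out$percentile, (seq_len(20) - 0.5) / 20)
  expect_equal(out$class[18], "probably_damaging")   # 0.875
  expect_equal(out$class[13], "pathogenic")
  expect_equal(out$class[8], "likely_benign")
  expect_equal(out$class[12], "undetermined")        # 0.575, no ClinVar
  expect_equal(out$class[1], "likely_benign")

  # equivocal ClinVar wording never upgrades
  cl2 <- rep("Conflicting interpretations of pathogenicity", 20)
  out2 <- percentileClassify(cohortWithVotes(votes, clinvar = cl2))
  expect_false(any(out2$class == "pathogenic"))
  expect_error(percentileClassify(subsetVariants(cohortWithVotes(votes),
                                                 character(0))),
               "empty")
})

test_that("classification partitions and is duplication-invariant", {
  set.seed(11)
  votes <- sample(seq(0, 10, 0.5), 60, replace = TRUE)
  cohort <- cohortWithVotes(votes)
  out <- percentileClassify(cohort)
  expect_equal(nrow(out), 60)
  expect_equal(sum(table(out$class)), 60)

  v <- variantData(cohort); v$pos <- v$pos + 1000L
  v$key <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  doubled <- variantCohort(rbind(variantData(cohort), v),
                           rbind(genotypes(cohort), genotypes(cohort)))
  out2 <- percentileClassify(doubled)
  expect_equal(out2$percentile[1:60], out$percentile)
  expect_equal(out2$class[1:60], out$class)

  # <= 20% + tie mass at the 80th-percentile vote value is damaging
  frac <- mean(out$class %in% c("probably_damaging", "pathogenic"))
  boundary <- min(out$votes[out$percentile >= 0.8])
  expect_lte(frac, 0.20 + mean(out$votes == boundary) + 1e-12)
})

test_that("raising a single tool vote never lowers a variant's class", {
  rankOf <- function(cls) match(cls, c("likely_benign", "undetermined",
                                       "probably_damaging", "pathogenic"))
  set.seed(12)
  votes <- sample(seq(0, 9.5, 0.5), 40, replace = TRUE)
  cl <- ifelse(runif(40) < 0.2, "Pathogenic", NA_character_)
  cohort <- cohortWithVotes(votes, clinvar = cl)
  base <- percentileClassify(cohort)
  for (i in c(3, 17, 25)) {
    v <- variantData(cohort)
    tool <- toolNames()[which(v[i, toolNames()] != "damaging")[1]]
    v[[tool]][i] <- "damaging"
    up <- percentileClassify(variantCohort(v, genotypes(cohort)))
    expect_gte(rankOf(up$class[i]), rankOf(base$class[i]))
  }
})

classifiedFor <- function(cohort, class) {
  v <- variantData(cohort)
  data.frame(key = v$key, gene = v$gene, votes = 10,
             percentile = 0.9, class = class, stringsAsFactors = FALSE)
}

test_that("per-gene occurrence counts are carrier-variant pairs", {
  g <- matrix(0L, 3, 4)
  g[1, 1:3] <- 1L          # damaging, 3 carriers
  g[2, 4] <- 2L            # damaging hom, counts once
  g[3, 1:2] <- 1L          # undetermined
  cohort <- mkCohort(3, gene = c("A", "A", "B"), geno = g,
                     samples = sprintf("S%d", 1:4))
  out <- classifiedFor(cohort, c("probably_damaging", "pathogenic",
                                 "undetermined"))
  counts <- perGeneDamagingCounts(out, cohort, c("A", "B"))
  expect_equal(counts, c(A = 4L))            # zero-count B omitted
  expect_length(perGeneDamagingCounts(out, cohort, character(0)), 0)
  expect_length(perGeneDamagingCounts(out, cohort, "Z"), 0)
})

test_that("per-person histogram counts variants and includes zero", {
  g <- matrix(0L, 4, 3)
  g[1, 2] <- 1L; g[2, 3] <- 1L; g[3, 3] <- 1L; g[4, 3] <- 1L
  cohort <- mkCohort(4, gene = "A", geno = g,
                     samples = c("S1", "S2", "S3"))
  out <- classifiedFor(cohort, "probably_damaging")
  h <- perPersonDamagingHistogram(out, cohort, "A")
  expect_equal(h, c("0" = 1L, "1" = 1L, "2" = 0L, "3" = 1L))
  expect_equal(sum(h), 3)
  none <- perPersonDamagingHistogram(out, cohort, "Z")
  expect_equal(none, c("0" = 3L))
})

test_that("carrier association recovers a planted lipid shift", {
  d <- tinyDesign(seed = 13, nParticipants = 204)
  carrierIdx <- 1:38
  g <- matrix(0L, 1, 204); g[1, carrierIdx] <- 1L
  hits <- 0; shifts <- numeric(100)
  for (r in 1:100) {
    p <- simulateLipids(d, seed = 7000 + r)
    p$ldl[carrierIdx] <- p$ldl[carrierIdx] - 30
    cohort <- mkCohort(1, gene = "A", geno = g, samples = p$id)
    out <- classifiedFor(cohort, "probably_damaging")
    ca <- carrierAssociation(out, cohort, p, "A", "ldl", "none")
    if (ca$p < 0.05) hits <- hits + 1
    shifts[r] <- ca$carrierMean - ca$noncarrierMean
  }
  expect_gte(hits, 80)
  se <- sd(shifts) / sqrt(100)
  expect_lt(abs(mean(shifts) + 30), 2 * se * 10)  # vs per-replicate sd

  p <- simulateLipids(d)
  cohortAll <- mkCohort(1, gene = "A", geno = matrix(1L, 1, 204),
                        samples = p$id)
  outAll <- classifiedFor(cohortAll, "probably_damaging")
  expect_error(carrierAssociation(outAll, cohortAll, p, "A", "ldl"),
               "noncarriers")
  expect_error(carrierAssociation(outAll, cohortAll, p, "Z", "ldl"),
               "no carriers")

  # identical carrier and noncarrier values give p = 1
  p$ldl <- 120
  cohort1 <- mkCohort(1, gene = "A", geno = g, samples = p$id)
  out1 <- classifiedFor(cohort1, "probably_damaging")
  expect_equal(carrierAssociation(out1, cohort1, p, "A", "ldl")$p, 1)
})
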