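## Seeded synthetic cohort generator. Lipids follow the inverse hyperbolic
## TG / HDL-C law the selection isopleth assumes; variant counts follow the
## burden model's own expectation (Poisson per participant x gene with mean
## proportional to trinucleotide-context mutability times a planted
## multiplier), so the burden test's null and alternative are both
## realisable and a truth table supports recovery tests.

## evaluate expr under a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic gene roster
#'
#' Random coding sequences (lengths a multiple of 3 between `minLen` and
#' `maxLen`, plus one flanking base each side) named `GENE001`, ... —
#' synthetic stand-ins, not real loci.
#'
#' @param nGenes Number of genes.
#' @param seed Integer seed.
#' @param minLen,maxLen Coding-length bounds in bases.
#' @return data.frame with `gene`, `cds` and `length` columns.
#' @export
makeGeneRoster <- function(nGenes = 200, seed = 1L, minLen = 300,
                           maxLen = 1500) {
  withSeed(seed, {
    lens <- 3L * sample(seq(minLen %/% 3L, maxLen %/% 3L), nGenes,
                        replace = TRUE)
    cds <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L + 2L, replace = TRUE),
            collapse = ""), character(1))
    data.frame(gene = sprintf("GENE%03d", seq_len(nGenes)), cds = cds,
               length = lens, stringsAsFactors = FALSE)
  })
}

#' @rdname SimulationDesign-class
#' @exportClass SimulationDesign
setClass("SimulationDesign", representation(
  nParticipants = "integer", femaleFraction = "numeric",
  tgMeanlog = "numeric", tgSdlog = "numeric",
  m1 = "numeric", m2 = "numeric", m3 = "numeric",
  hdlNoiseSd = "numeric", ldlMean = "numeric", ldlSd = "numeric",
  ageMean = "numeric", ageSd = "numeric",
  roster = "data.frame", enrichment = "numeric",
  toolSensitivity = "numeric", toolFalsePositive = "numeric",
  equivocalShare = "numeric", meanDamagingPerGene = "numeric",
  benignPerGene = "numeric", homFraction = "numeric", seed = "integer"
))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (length(object@enrichment) && any(object@enrichment < 1))
    msg <- c(msg, "enrichment multipliers must be >= 1")
  pr <- c(object@femaleFraction, object@toolSensitivity,
          object@toolFalsePositive, object@equivocalShare,
          object@homFraction)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@m2 <= 0) msg <- c(msg, "m2 must be positive")
  if (length(object@enrichment) &&
      !all(names(object@enrichment) %in% object@roster$gene))
    msg <- c(msg, "enrichment names must be roster genes")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort design
#'
#' Fixes every generative choice of the simulator. Defaults mirror the
#' study conditions this package targets: 204 participants (34.3% female),
#' log-normal triglycerides (median 150 mg/dl, log-sd 0.8), HDL-C on a
#' synthetic hyperbola `20 + 50*30/(50 + TG)` plus 4 mg/dl noise, total
#' cholesterol built as `LDL + HDL + TG/5` so the Friedewald identity is
#' exact below 400 mg/dl TG, a 200-gene roster, a mean of 2 damaging
#' variant occurrences per gene cohort-wide under the null, 2% homozygous
#' carriage, and prediction tools voting damaging with probability 0.85 on
#' truly damaging and 0.15 on benign variants. The isopleth constants are
#' synthetic defaults, not the study's (unpublished) fitted curve.
#'
#' @param nParticipants Cohort size.
#' @param femaleFraction Fraction of females.
#' @param tgMeanlog,tgSdlog Log-scale TG distribution parameters (mg/dl).
#' @param m1,m2,m3 Truth hyperbola constants (mg/dl; `m2 > 0`).
#' @param hdlNoiseSd HDL-C noise sd (mg/dl); 0 puts everyone exactly on
#'   the hyperbola.
#' @param ldlMean,ldlSd LDL-C distribution (mg/dl).
#' @param ageMean,ageSd Age distribution (years).
#' @param roster Gene roster (see [makeGeneRoster()]); built from
#'   `nGenes` and `seed` when omitted.
#' @param nGenes Roster size when `roster` is omitted.
#' @param enrichment Named numeric: gene -> rate multiplier (>= 1).
#' @param toolSensitivity,toolFalsePositive Probability a tool votes
#'   damaging given a truly damaging / benign variant.
#' @param equivocalShare Share of the residual vote mass cast as
#'   equivocal (half-point) calls.
#' @param meanDamagingPerGene Null mean damaging occurrences per gene,
#'   cohort-wide.
#' @param benignPerGene Mean benign/synonymous background variants per
#'   gene.
#' @param homFraction Probability a carrier genotype is homozygous.
#' @param seed Integer seed; all stage randomness derives from it.
#' @return A `SimulationDesign` object.
#' @export
simulationDesign <- function(nParticipants = 204, femaleFraction = 0.343,
                             tgMeanlog = log(150), tgSdlog = 0.8,
                             m1 = 20, m2 = 50, m3 = 30,
                             hdlNoiseSd = 4, ldlMean = 128, ldlSd = 45,
                             ageMean = 50, ageSd = 15.7,
                             roster = NULL, nGenes = 200,
                             enrichment = setNames(numeric(0), character(0)),
                             toolSensitivity = 0.85,
                             toolFalsePositive = 0.15,
                             equivocalShare = 0.30,
                             meanDamagingPerGene = 2,
                             benignPerGene = 4,
                             homFraction = 0.02, seed = 1L) {
  if (nParticipants <= 0) stop("nParticipants must be positive")
  if (is.null(roster)) roster <- makeGeneRoster(nGenes, seed = seed)
  if (!nrow(roster)) stop("gene roster must be non-empty")
  new("SimulationDesign",
      nParticipants = as.integer(nParticipants),
      femaleFraction = femaleFraction, tgMeanlog = tgMeanlog,
      tgSdlog = tgSdlog, m1 = m1, m2 = m2, m3 = m3,
      hdlNoiseSd = hdlNoiseSd, ldlMean = ldlMean, ldlSd = ldlSd,
      ageMean = ageMean, ageSd = ageSd, roster = roster,
      enrichment = enrichment, toolSensitivity = toolSensitivity,
      toolFalsePositive = toolFalsePositive,
      equivocalShare = equivocalShare,
      meanDamagingPerGene = meanDamagingPerGene,
      benignPerGene = benignPerGene, homFraction = homFraction,
      seed = as.integer(seed))
}

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: %d participants, %d genes, seed %d\n",
    object@nParticipants, nrow(object@roster), object@seed))
  if (length(object@enrichment))
    cat("  planted enrichment: ",
        paste(names(object@enrichment), object@enrichment, sep = " x",
              collapse = ", "), "\n", sep = "")
})

#' Simulate lipid panels
#'
#' Draws triglycerides log-normally, places HDL-C on the truth hyperbola
#' `m1 + m2*m3/(m2 + TG)` plus centred noise (floored at 1 mg/dl), draws
#' LDL-C independently, and constructs TC as `LDL + HDL + TG/5` so the
#' Friedewald estimate is exact wherever it is defined (TG < 400 mg/dl).
#'
#' @param design A [SimulationDesign][simulationDesign].
#' @param seed Seed for this stage (defaults to the design seed).
#' @return data.frame of participants (`id`, `sex`, `age`, `ethnicity`,
#'   lipids in mg/dl, `bmi`, clinical flags, `group = NA`), with the
#'   pre-noise HDL-C in `attr(, "latentHdl")`.
#' @export
simulateLipids <- function(design, seed = design@seed) {
  n <- design@nParticipants
  withSeed(seed, {
    tg <- rlnorm(n, design@tgMeanlog, design@tgSdlog)
    latent <- design@m1 + design@m2 * design@m3 / (design@m2 + tg)
    hdl <- pmax(latent + rnorm(n, 0, design@hdlNoiseSd), 1)
    ldl <- pmax(rnorm(n, design@ldlMean, design@ldlSd), 20)
    tc <- ldl + hdl + tg / 5
    p <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      sex = ifelse(runif(n) < design@femaleFraction, "F", "M"),
      age = round(pmin(pmax(rnorm(n, design@ageMean, design@ageSd), 8), 86),
                  1),
      ethnicity = sample(c("European", "Mexican", "EastAsian", "Indian",
                           "AfricanAmerican", "Other"), n, replace = TRUE,
                         prob = c(0.765, 0.108, 0.039, 0.029, 0.015, 0.044)),
      tc = tc, tg = tg, hdl = hdl, ldl = ldl,
      prebeta = round(pmax(rnorm(n, 4.3, 1.4), 0.5), 2),
      bmi = round(rlnorm(n, log(28), 0.18), 1),
      cad = runif(n) < 0.086, mi = runif(n) < 0.055,
      diabetes = runif(n) < 0.059, hypertension = runif(n) < 0.287,
      smoker = runif(n) < 0.086,
      group = NA_integer_, stringsAsFactors = FALSE)
    attr(p, "latentHdl") <- latent
    p
  })
}

#' @rdname TruthTable-class
#' @exportClass TruthTable
setClass("TruthTable", representation(
  variants = "data.frame",     # key, gene, damaging
  multipliers = "numeric",     # named, per roster gene
  damagingCounts = "integer"   # named, truly damaging occurrences per gene
))

setValidity("TruthTable", function(object) {
  if (anyDuplicated(object@variants$key))
    "every simulated variant must appear exactly once" else TRUE
})

setMethod("show", "TruthTable", function(object) {
  cat(sprintf(
    "TruthTable: %d variants (%d truly damaging), %d genes, %d planted\n",
    nrow(object@variants), sum(object@variants$damaging),
    length(object@multipliers), sum(object@multipliers > 1)))
})

#' @rdname TruthTable-class
#' @param x A `TruthTable`.
#' @export
truthVariants <- function(x) x@variants

#' @rdname TruthTable-class
#' @export
truthMultipliers <- function(x) x@multipliers

#' @rdname TruthTable-class
#' @export
truthDamagingCounts <- function(x) x@damagingCounts

sampleVotes <- function(n, pDamaging, eqShare, forced = NULL) {
  ## one tool column: damaging w.p. pDamaging, equivocal with eqShare of
  ## the same order of mass, tolerated otherwise
  u <- runif(n)
  out <- ifelse(u < pDamaging, "damaging",
                ifelse(u < pDamaging * (1 + eqShare), "equivocal",
                       "tolerated"))
  if (!is.null(forced)) out[forced] <- "damaging"
  out
}

#' Simulate annotated variant calls with a truth table
#'
#' Damaging occurrences are Poisson per (participant, gene) with mean
#' `T * p_g * multiplier_g / n`, where `T = meanDamagingPerGene * nGenes`
#' and `p_g` is the gene's share of summed damaging mutability — exactly
#' the burden module's expectation model, scaled over the cohort's
#' chromosomes. Each occurrence becomes a singleton variant (LoF or
#' damaging-missense in proportion to the gene's class mutabilities;
#' damaging-missense records carry a deleterious MetaSVM call, which is
#' what defines the class). Benign background variants (synonymous or
#' tolerated missense) are added per gene with small carrier counts.
#' Every record receives QC fields, population MAFs, ten tool votes from
#' the design's operating points, an occasional ClinVar label, and
#' genotypes (heterozygous, homozygous with probability `homFraction`).
#'
#' @param design A [SimulationDesign][simulationDesign].
#' @param participants Participants from [simulateLipids()] (non-empty).
#' @param rates A [MutationRateTable][MutationRateTable-class].
#' @param seed Seed for this stage (defaults to design seed + 1).
#' @param geneMut Optional precomputed [geneMutability()] table for the
#'   design's roster, to avoid recomputation across replicates.
#' @return List with `cohort` (a [VariantCohort][variantCohort]) and
#'   `truth` (a `TruthTable`).
#' @export
simulateVariants <- function(design, participants, rates = makeRateTable(),
                             seed = design@seed + 1L, geneMut = NULL) {
  if (!nrow(participants)) stop("participant collection is empty")
  roster <- design@roster
  if (is.null(geneMut)) geneMut <- geneMutability(roster, rates)
  geneMut <- geneMut[match(roster$gene, geneMut$gene), ]
  n <- nrow(participants)
  nGenes <- nrow(roster)
  mult <- setNames(rep(1, nGenes), roster$gene)
  mult[names(design@enrichment)] <- design@enrichment
  pG <- geneMut$damaging / sum(geneMut$damaging)
  lambda <- design@meanDamagingPerGene * nGenes * pG * mult / n

  withSeed(seed, {
    counts <- matrix(rpois(nGenes * n, rep(lambda, n)), nrow = nGenes)
    idx <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[idx]
    dmgGene <- rep(idx[, 1], reps)
    dmgCarrier <- rep(idx[, 2], reps)
    nDmg <- length(dmgGene)

    ## damaging consequence: LoF vs D-Mis in proportion to mutability
    pLof <- geneMut$lof[dmgGene] / geneMut$damaging[dmgGene]
    isLof <- runif(nDmg) < pLof
    lofLabel <- sample(lofConsequences(), nDmg, replace = TRUE,
                       prob = c(0.45, 0.05, 0.25, 0.20, 0.05))
    consD <- ifelse(isLof, lofLabel, "missense")

    ## benign background, small random carrier sets
    nBen <- rpois(nGenes, design@benignPerGene)
    benGene <- rep(seq_len(nGenes), nBen)
    nB <- length(benGene)
    consB <- sample(c("synonymous", "missense", "intronic", "UTR"), nB,
                    replace = TRUE, prob = c(0.40, 0.40, 0.15, 0.05))

    gene <- c(roster$gene[dmgGene], roster$gene[benGene])
    cons <- c(consD, consB)
    damagingTruth <- rep(c(TRUE, FALSE), c(nDmg, nB))
    nv <- nDmg + nB

    ## positions: unique within gene, mapped onto a per-gene block
    geneIdx <- c(dmgGene, benGene)
    cdsPos <- integer(nv)
    for (g in unique(geneIdx)) {
      at <- which(geneIdx == g)
      cdsPos[at] <- sample(roster$length[g], length(at))
    }
    pos <- geneIdx * 100000L + cdsPos
    ref <- substr(roster$cds[geneIdx], cdsPos + 1L, cdsPos + 1L)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    fs <- cons == "frameshift-indel"
    alt[fs] <- paste0(ref[fs], sample(c("A", "C", "G", "T"), sum(fs),
                                      replace = TRUE))

    ## QC payload
    dp <- rpois(nv, 55) + 5L
    qual <- round(runif(nv, 30, 2000), 1)
    gq <- sample(c(99, 80, 50, 15), nv, replace = TRUE,
                 prob = c(0.80, 0.10, 0.07, 0.03))
    mq <- round(pmin(rnorm(nv, 58, 4), 60), 1)
    altReads <- rbinom(nv, dp, 0.5)
    onecaller <- runif(nv) < 0.05
    callers <- vapply(seq_len(nv), function(i) {
      if (onecaller[i]) sample(callerNames(), 1)
      else paste(sort(sample(callerNames(), sample(2:5, 1))),
                 collapse = ",")
    }, character(1))
    vqsr <- runif(nv) < 0.97
    lcr <- runif(nv) < 0.03

    ## population MAFs: damaging ultra-rare or novel, benign commoner
    zero <- runif(nv) < ifelse(damagingTruth, 0.60, 0.05)
    base <- ifelse(damagingTruth, 10^runif(nv, -6, -3.2),
                   10^runif(nv, -3.3, -0.5))
    base[zero] <- 0
    jitterMaf <- function(x) pmin(x * runif(nv, 0.5, 1.5), 0.5)
    mafGnomad <- base
    mafExac <- jitterMaf(base)
    maf1kg <- jitterMaf(base)
    mafEsp <- jitterMaf(base)

    ## ten tool votes; a damaging-missense record is *defined* by its
    ## deleterious MetaSVM call, so that tool is forced for those records
    votes <- matrix("", nv, 10, dimnames = list(NULL, toolNames()))
    pDmg <- ifelse(damagingTruth, design@toolSensitivity,
                   design@toolFalsePositive)
    for (tool in toolNames()) {
      forced <- if (tool == "metasvm") which(damagingTruth &
                                               cons == "missense") else NULL
      votes[, tool] <- sampleVotes(nv, pDmg, design@equivocalShare, forced)
    }
    metasvmCall <- ifelse(votes[, "metasvm"] == "damaging", "deleterious",
                          "tolerated")
    clinvar <- rep("", nv)
    u <- runif(nv)
    clinvar[damagingTruth & u < 0.04] <- "Pathogenic"
    clinvar[damagingTruth & u >= 0.04 & u < 0.06] <- "Likely benign"
    clinvar[!damagingTruth & u < 0.05] <- "Benign"

    key <- variantKey("1", pos, ref, alt)
    variants <- data.frame(
      chrom = "1", pos = pos, ref = ref, alt = alt, key = key,
      qual = qual, dp = dp, mq = mq, gene = gene, consequence = cons,
      gq = gq, callers = callers, alt_reads = altReads, lcr_flag = lcr,
      vqsr_pass = vqsr, maf_gnomad = mafGnomad, maf_exac = mafExac,
      maf_1kg = maf1kg, maf_esp = mafEsp, stringsAsFactors = FALSE)
    variants <- cbind(variants, as.data.frame(votes,
                                              stringsAsFactors = FALSE))
    variants$metasvm_call <- metasvmCall
    variants$clinvar <- clinvar
    variants$annotated <- TRUE

    ## genotypes: damaging records are singletons of their drawn carrier;
    ## benign records hit 1 + Pois(0.7) random participants
    g <- matrix(0L, nv, n, dimnames = list(key, participants$id))
    dose <- function(k) if (runif(1) < design@homFraction) 2L else 1L
    for (i in seq_len(nDmg)) g[i, dmgCarrier[i]] <- dose(i)
    for (i in seq_len(nB)) {
      carriers <- sample(n, min(n, 1L + rpois(1, 0.7)))
      g[nDmg + i, carriers] <- vapply(carriers, dose, integer(1))
    }

    dmgCount <- setNames(integer(nGenes), roster$gene)
    tab <- table(roster$gene[dmgGene])
    dmgCount[names(tab)] <- as.integer(tab)
    truth <- new("TruthTable",
                 variants = data.frame(key = key, gene = gene,
                                       damaging = damagingTruth,
                                       stringsAsFactors = FALSE),
                 multipliers = mult, damagingCounts = dmgCount)
    list(cohort = variantCohort(variants, g), truth = truth)
  })
}

#' Write a truth table to TSV
#'
#' @param truth A `TruthTable`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTruthTable <- function(truth, path) {
  v <- truth@variants
  v$multiplier <- truth@multipliers[v$gene]
  write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
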