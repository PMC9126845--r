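# Programmatic fixtures: a one-call builder for small variant cohorts with
# sensible passing defaults, so each test overrides only the field under
# scrutiny.

defaultVariantTable <- function(n) {
  v <- data.frame(
    chrom = rep("1", n), pos = seq_len(n), ref = rep("A", n),
    alt = rep("G", n), key = rep(NA_character_, n), qual = rep(100, n),
    dp = rep(50L, n), mq = rep(60, n),
    gene = rep("GENE001", n), consequence = rep("missense", n),
    gq = rep(99, n), callers = rep("GATK-HC,Samtools", n),
    alt_reads = rep(25L, n), lcr_flag = rep(FALSE, n),
    vqsr_pass = rep(TRUE, n), maf_gnomad = rep(0, n),
    maf_exac = rep(0, n), maf_1kg = rep(0, n), maf_esp = rep(0, n),
    stringsAsFactors = FALSE)
  for (tool in toolNames()) v[[tool]] <- rep("tolerated", n)
  v$metasvm_call <- rep("tolerated", n)
  v$clinvar <- rep(NA_character_, n)
  v$annotated <- rep(TRUE, n)
  v
}

# build a VariantCohort of n variants; ... overrides columns (recycled);
# default genotypes: every variant het in the first sample only
mkCohort <- function(n = 1, samples = c("S1", "S2"), geno = NULL, ...) {
  v <- defaultVariantTable(n)
  ov <- list(...)
  for (nm in names(ov)) v[[nm]] <- rep(ov[[nm]], length.out = n)
  if (!"alt_reads" %in% names(ov))
    v$alt_reads <- pmin(v$alt_reads, v$dp)
  v$key <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  if (is.null(geno)) {
    geno <- matrix(0L, n, length(samples))
    geno[, 1] <- 1L
  }
  colnames(geno) <- samples
  variantCohort(v, geno)
}

# small simulation design for unit tests (short genes keep mutability
# enumeration cheap)
tinyDesign <- function(seed = 1L, nGenes = 15, nParticipants = 60, ...) {
  simulationDesign(nParticipants = nParticipants,
                   roster = makeGeneRoster(nGenes, seed = seed,
                                           minLen = 150, maxLen = 450),
                   seed = seed, ...)
}

# rate table with every context at the same rate r
uniformRateTable <- function(r = 1e-8) {
  keys <- hdlexome:::contextKeys()
  methods::new("MutationRateTable", rates = stats::setNames(rep(r, 192), keys))
}
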