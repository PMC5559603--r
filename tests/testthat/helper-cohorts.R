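# Shared fixture builders and independent oracles, all generated in code.

# hand-built genotype container for exact-value tests
toy_genotypes <- function(dosages, chrom = "chr1",
                          pos = seq_len(ncol(dosages)) * 1000L,
                          ancestral = NULL, block = 1L) {
  n <- nrow(dosages); m <- ncol(dosages)
  samples <- sprintf("S%03d", seq_len(n))
  snp_id <- if (!is.null(colnames(dosages))) colnames(dosages) else
    sprintf("snp%03d", seq_len(m))
  dimnames(dosages) <- list(samples, snp_id)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     ref = "A", alt = "G",
                     ancestral = if (is.null(ancestral))
                       rep(NA_character_, m) else ancestral,
                     maf = pmin(af, 1 - af),
                     block = rep_len(block, m), stringsAsFactors = FALSE)
  structure(list(dosages = dosages, snps = snps, samples = samples),
            class = "reqtl_genotypes")
}

# hand-built expression container: values is a named list of
# samples x probes matrices (one per condition); genes anchored at `anchor`
toy_expression <- function(values, chrom = "chr1", anchor = NULL) {
  genes <- colnames(values[[1]])
  if (is.null(rownames(values[[1]]))) {
    sn <- sprintf("S%03d", seq_len(nrow(values[[1]])))
    values <- lapply(values, function(m) { rownames(m) <- sn; m })
  }
  if (is.null(anchor)) anchor <- rep(1000L, length(genes))
  pm <- data.frame(probe = genes, gene = genes, chrom = chrom,
                   anchor_pos = anchor, stringsAsFactors = FALSE)
  structure(list(values = values, probe_map = pm,
                 samples = rownames(values[[1]])),
            class = "cond_expression")
}

# independent exact HWE oracle: absolute conditional probabilities of the
# heterozygote count via the factorial formula (no normalization step)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  h <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(logp)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# independent two-sided Fisher oracle for a 2x2 table via hypergeometric
# enumeration
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  p_obs <- pr[match(tab[1, 1], a)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# independent one-sided exact binomial oracle (successes >= k)
binom_oracle <- function(k, n, p = 0.5) {
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log(1 - p)))
}

# small cohort with one planted effect per architecture, reused across files
cached_arch_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gt <- simulate_genotypes(300, 12, 5, maf_range = c(0.2, 0.5),
                               within_block_r2 = 0.9, seed = 101)
      eff <- random_effects(gt, n_per_architecture = 1, n_constant = 2,
                            beta = 1, seed = 102)
      ex <- simulate_expression(gt, eff, n_null_genes = 3, seed = 103)
      eg <- call_egenes(map_egenes(ex, gt, n_max = 300, seed = 104))
      memo <<- list(gt = gt, eff = eff, ex = ex, sig = eg)
    }
    memo
  }
})
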