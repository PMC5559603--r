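test_that("generators are deterministic given a seed", {
  g1 <- simulate_genotypes(40, 8, 3, seed = 7)
  g2 <- simulate_genotypes(40, 8, 3, seed = 7)
  expect_identical(g1, g2)
  eff <- random_effects(g1, 1, 1, seed = 8)
  expect_identical(simulate_expression(g1, eff, n_null_genes = 2, seed = 9),
                   simulate_expression(g1, eff, n_null_genes = 2, seed = 9))
  expect_identical(simulate_selection_scores(g1, seed = 10),
                   simulate_selection_scores(g1, seed = 10))
  expect_identical(
    simulate_gwas_catalog(g1, g1$snps$snp_id[1], n_background = 5, seed = 11),
    simulate_gwas_catalog(g1, g1$snps$snp_id[1], n_background = 5, seed = 11))
})

test_that("perfect-LD blocks give identical dosages up to allele relabeling", {
  gt <- simulate_genotypes(100, 2, 3, within_block_r2 = 1, seed = 1)
  for (b in 1:2) {
    idx <- which(gt$snps$block == b)
    d0 <- gt$dosages[, idx[1]]
    for (j in idx[-1]) {
      dj <- gt$dosages[, j]
      expect_true(identical(dj, d0) || identical(dj, 2 - d0))
      expect_equal(ld_r2(d0, dj), 1)
    }
  }
})

test_that("allele frequency and HWE hold at large n", {
  gt <- simulate_genotypes(6000, 20, 3, maf_range = c(0.3, 0.3),
                           within_block_r2 = 0.8, seed = 2)
  expect_true(all(abs(gt$snps$maf - 0.3) < 0.01))
  hwe_p <- apply(gt$dosages, 2, function(g)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_lte(mean(hwe_p <= 0.001), 0.005)
})

test_that("realized within-block r2 matches the requested value", {
  gt <- simulate_genotypes(4000, 10, 4, maf_range = c(0.2, 0.5),
                           within_block_r2 = 0.6, seed = 3)
  r2 <- unlist(lapply(1:10, function(b) {
    idx <- which(gt$snps$block == b)
    pairs <- utils::combn(idx, 2)
    apply(pairs, 2, function(ij) ld_r2(gt$dosages[, ij[1]],
                                       gt$dosages[, ij[2]]))
  }))
  expect_equal(mean(r2), 0.6, tolerance = 0.05)
  # cross-block independence
  r2x <- ld_r2(gt$dosages[, 1], gt$dosages[, 5])
  expect_lt(r2x, 0.05)
})

test_that("planted slopes are recovered by an independent OLS fit", {
  gt <- simulate_genotypes(500, 3, 3, maf_range = c(0.3, 0.5), seed = 4)
  eff <- data.frame(gene = "g1", snp_id = gt$snps$snp_id[2],
                    architecture = "active-transient", beta = 0.8,
                    treatment = "LPS", de_pattern = "none")
  ex <- simulate_expression(gt, eff, noise_sd = 1, seed = 5)
  g <- gt$dosages[, eff$snp_id]
  fit90 <- summary(lm(ex$values[["LPS90"]][, "g1"] ~ g))$coefficients
  expect_lt(abs(fit90["g", 1] - 0.8), 3 * fit90["g", 2])
  fit0 <- summary(lm(ex$values[["baseline"]][, "g1"] ~ g))$coefficients
  expect_lt(abs(fit0["g", 1]), 3 * fit0["g", 2])
  # noiseless limit: every condition's slope matches its generative value
  ex0 <- simulate_expression(gt, data.frame(
    gene = "g1", snp_id = gt$snps$snp_id[2], architecture = "constant",
    beta = 1, treatment = "all", de_pattern = "none"),
    noise_sd = 1e-8, seed = 6)
  for (cn in reqtl_conditions()) {
    b <- coef(lm(ex0$values[[cn]][, "g1"] ~ g))[2]
    expect_equal(unname(b), 1, tolerance = 1e-6)
  }
})

test_that("planted-slope coverage: OLS within 3 SE for >= 99% of 200 genes", {
  gt <- simulate_genotypes(500, 8, 3, maf_range = c(0.2, 0.5), seed = 7)
  snp <- gt$snps$snp_id[seq(2, 8 * 3, by = 3)]
  eff <- data.frame(gene = sprintf("g%03d", 1:200),
                    snp_id = rep_len(snp, 200),
                    architecture = "constant", beta = 0.8,
                    treatment = "all", de_pattern = "none")
  ex <- simulate_expression(gt, eff, noise_sd = 1, seed = 8)
  ok <- vapply(seq_len(200), function(k) {
    g <- gt$dosages[, eff$snp_id[k]]
    fit <- summary(lm(ex$values[["baseline"]][, eff$gene[k]] ~ g))$coefficients
    abs(fit[2, 1] - 0.8) < 3 * fit[2, 2]
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("null genes give uniform association p-values", {
  gt <- simulate_genotypes(200, 40, 1, maf_range = c(0.2, 0.5), seed = 9)
  ex <- simulate_expression(gt, NULL, n_null_genes = 800, seed = 10)
  # each null gene against its anchor block's SNP, simple OLS oracle
  p <- vapply(seq_len(800), function(k) {
    gene <- ex$probe_map$gene[k]
    snp <- which(gt$snps$pos == ex$probe_map$anchor_pos[k] &
                   gt$snps$chrom == ex$probe_map$chrom[k])[1]
    y <- ex$values[["baseline"]][, gene]
    g <- gt$dosages[, snp]
    r <- cor(y, g)
    tt <- r * sqrt((length(y) - 2) / (1 - r^2))
    2 * pt(abs(tt), length(y) - 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("congruent and divergent DE patterns plant the advertised shifts", {
  gt <- simulate_genotypes(200, 3, 3, seed = 11)
  eff <- data.frame(gene = c("gc", "gd"), snp_id = gt$snps$snp_id[c(2, 5)],
                    architecture = "active-transient", beta = 0.8,
                    treatment = "LPS", de_pattern = c("congruent", "divergent"))
  ex <- simulate_expression(gt, eff, noise_sd = 0.1, seed = 12)
  m90 <- colMeans(ex$values[["LPS90"]]) - colMeans(ex$values[["baseline"]])
  m6 <- colMeans(ex$values[["LPS6h"]]) - colMeans(ex$values[["LPS90"]])
  expect_equal(unname(m90["gc"]), 1.5, tolerance = 0.2)   # up at 90 min
  expect_equal(unname(m6["gc"]), -1.5, tolerance = 0.2)   # back down at 6 h
  expect_equal(unname(m90["gd"]), 0, tolerance = 0.2)     # mismatched profile
  expect_equal(unname(m6["gd"]), 1.5, tolerance = 0.2)
})

test_that("selection scores carry the planted magnitude inflation", {
  snps <- data.frame(snp_id = sprintf("s%05d", 1:11000))
  tgt <- snps$snp_id[1:1000]
  # no shift: target indistinguishable from background
  sc0 <- simulate_selection_scores(snps, target_set = tgt, shift = 0,
                                   seed = 14)
  expect_gt(wilcox.test(abs(sc0$ihs[1:1000]),
                        abs(sc0$ihs[-(1:1000)]))$p.value, 0.01)
  # shift 2: high-|iHS| proportion clearly above the N(0,1) tail 0.1336
  sc2 <- simulate_selection_scores(snps, target_set = tgt, shift = 2,
                                   seed = 14)
  prop_bg <- mean(abs(sc2$ihs[-(1:1000)]) > 1.5)
  prop_tg <- mean(abs(sc2$ihs[1:1000]) > 1.5)
  expect_lt(abs(prop_bg - 2 * pnorm(-1.5)), 0.02)
  expect_gt(prop_tg, prop_bg + 0.3)
  expect_error(simulate_selection_scores(snps, target_set = "nope"),
               "unknown SNP")
})

test_that("gwas catalog tags leads through real LD partners", {
  gt <- simulate_genotypes(150, 10, 3, within_block_r2 = 1, seed = 15)
  leads <- gt$snps$snp_id[c(2, 5, 8, 11, 14)]
  cat5 <- simulate_gwas_catalog(gt, leads, r2_of_tag = 1,
                                n_background = 100, seed = 16)
  expect_equal(nrow(cat5), 105)
  ov <- gwas_ld_overlap(data.frame(gene = paste0("g", 1:5), snp_id = leads),
                        cat5, gt, r2_threshold = 0.8)
  expect_setequal(unique(ov$lead_snp), leads)
  expect_equal(nrow(ov[!startsWith(ov$trait, "bg"), ]), 5)
  # no tagged leads: the downstream overlap query has no lead set
  cat0 <- simulate_gwas_catalog(gt, character(), n_background = 20, seed = 17)
  ov0 <- gwas_ld_overlap(data.frame(gene = character(),
                                    snp_id = character()), cat0, gt)
  expect_equal(nrow(ov0), 0)
})
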