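test_that("dosage r2 behaves like squared Pearson correlation", {
  g <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)            # allele-coding flip
  expect_equal(ld_r2(g, c(0, 1, 0, 1, 0, 1)), 0)
  expect_true(is.na(ld_r2(g, rep(1, 6))))     # constant vector signaled
  expect_error(ld_r2(g, g[1:3]), "length")
})

test_that("locus scores take the max |score| over the LD proxy set", {
  gt <- simulate_genotypes(200, 2, 3, within_block_r2 = 1, seed = 30)
  ids <- gt$snps$snp_id
  scores <- data.frame(snp_id = ids,
                       ihs = c(1.2, -1.8, 0.3, 0.4, NA, 0.1),
                       sds = c(NA, NA, NA, 0.5, 1.1, -2.2))
  cfg <- null_resample_config()
  ls1 <- locus_score(ids[1], gt, scores, cfg)
  expect_equal(ls1$proxy_count, 3)            # perfect-LD block of 3
  expect_equal(ls1$max_abs_ihs, 1.8)
  expect_true(is.na(ls1$max_abs_sds))         # all SDS missing in block 1
  ls2 <- locus_score(ids[4], gt, scores, cfg)
  expect_equal(ls2$max_abs_sds, 2.2)
  expect_equal(ls2$ld_bin, 2)                 # count 3 falls in the 3-5 bin
  # MAF 0.12 sits in the (0.10, 0.15] bin (index 3 at width 0.05)
  expect_equal(reqtlkit:::.maf_bin(0.12, 0.05), 3)
  expect_equal(reqtlkit:::.ld_bin(c(0, 2, 3, 5, 6, 10, 11, 20, 21, 50, 51),
                                  c(2, 5, 10, 20, 50, Inf)),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6))
})

test_that("matched resampling preserves bins and calibrates its p-value", {
  set.seed(31)
  pool <- data.frame(lead_snp = sprintf("s%04d", 1:2000),
                     proxy_count = sample(1:8, 2000, TRUE),
                     max_abs_ihs = abs(rnorm(2000)),
                     max_abs_sds = abs(rnorm(2000)),
                     maf = runif(2000, 0.05, 0.5))
  pool$maf_bin <- reqtlkit:::.maf_bin(pool$maf, 0.05)
  pool$ld_bin <- reqtlkit:::.ld_bin(pool$proxy_count, c(2, 5, 10, 20, 50, Inf))
  cfg <- null_resample_config(n_resamples = 500, seed = 32)
  # degenerate: all scores equal -> every null draw equals the observed
  pool_eq <- pool; pool_eq$max_abs_ihs <- 2
  res_eq <- matched_resample_test(pool_eq[1:50, ], pool_eq,
                                  "proportion_high_ihs", cfg)
  expect_equal(res_eq$observed, 1)
  expect_equal(res_eq$perm_p, 1)
  expect_equal(res_eq$null_min, res_eq$null_max)
  # null calibration: targets drawn from the pool itself
  pp <- vapply(1:100, function(k) {
    cfgk <- null_resample_config(n_resamples = 200, seed = 1000 + k)
    tgt <- pool[sample.int(2000, 40), ]
    matched_resample_test(tgt, pool, "proportion_high_ihs", cfgk)$perm_p
  }, numeric(1))
  expect_gt(mean(pp), 0.35)
  expect_lt(mean(pp), 0.65)
  expect_true(all(pp >= 1 / 201 & pp <= 1))
  # an empty matching cell is a hard error naming the cell
  tgt_bad <- pool[1, ]; tgt_bad$maf_bin <- 99
  expect_error(matched_resample_test(tgt_bad, pool, "median_abs_sds", cfg),
               "99")
})

test_that("planted score inflation is detected against the matched null", {
  gt <- simulate_genotypes(50, 400, 2, seed = 33)
  targets <- gt$snps$snp_id[seq(1, 160, by = 2)]
  scores <- simulate_selection_scores(gt, target_set = targets, shift = 2,
                                      seed = 34)
  cfg <- null_resample_config(n_resamples = 2000, seed = 35)
  pool <- locus_score_table(gt$snps$snp_id, gt, scores, cfg)
  tgt <- pool[match(targets, pool$lead_snp), ]
  res <- matched_resample_test(tgt, pool, "proportion_high_ihs", cfg)
  expect_lte(res$perm_p, 0.001)
  expect_gt(res$observed, res$null_max)
  res_sds <- matched_resample_test(tgt, pool, "median_abs_sds", cfg)
  expect_lte(res_sds$perm_p, 0.001)
})

test_that("derived-allele direction follows the response amplitude rule", {
  mk_rq <- function(b0, b1) data.frame(
    gene = "g", condition = "LPS90", lead_snp = "s1",
    beta_baseline = b0, beta_stim = b1, significant = TRUE)
  de <- list(LPS = data.frame(gene = "g", log2fc = 2, p = 1e-6))
  de_dn <- list(LPS = data.frame(gene = "g", log2fc = -2, p = 1e-6))
  gt_anc_ref <- toy_genotypes(cbind(s1 = c(0, 1, 2, 1)), ancestral = "A")
  gt_anc_alt <- toy_genotypes(cbind(s1 = c(0, 1, 2, 1)), ancestral = "G")
  gt_anc_na <- toy_genotypes(cbind(s1 = c(0, 1, 2, 1)))
  # derived = alt (dosage-counted): delta_beta +0.5, gene induced -> increasing
  expect_equal(derived_direction(mk_rq(0, 0.5), gt_anc_ref, de, de)$direction,
               "increasing")
  expect_equal(derived_direction(mk_rq(0, -0.5), gt_anc_ref, de, de)$direction,
               "decreasing")
  # gene suppressed: negative delta_beta amplifies the suppression
  expect_equal(derived_direction(mk_rq(0, -0.5), gt_anc_ref, de_dn,
                                 de_dn)$direction, "increasing")
  # ancestral = alt flips the orientation of the slopes
  expect_equal(derived_direction(mk_rq(0, 0.5), gt_anc_alt, de, de)$direction,
               "decreasing")
  expect_equal(derived_direction(mk_rq(0, 0.5), gt_anc_na, de, de)$direction,
               "unclassifiable")
})

test_that("flipping every ancestral assignment swaps the direction counts", {
  gt <- simulate_genotypes(200, 30, 3, maf_range = c(0.2, 0.5),
                           ancestral_major_prob = 0.5, seed = 36)
  set.seed(37)
  rq <- data.frame(gene = sprintf("g%02d", 1:30), condition = "LPS90",
                   lead_snp = gt$snps$snp_id[seq(2, 90, by = 3)],
                   beta_baseline = rnorm(30, 0, 0.3),
                   beta_stim = rnorm(30, 0, 0.3), significant = TRUE)
  de <- list(LPS = data.frame(gene = rq$gene, log2fc = rnorm(30),
                              p = rep(1e-4, 30)))
  d1 <- derived_direction(rq, gt, de, de)
  gt_fl <- gt
  gt_fl$snps$ancestral <- ifelse(gt$snps$ancestral == gt$snps$ref,
                                 gt$snps$alt, gt$snps$ref)
  d2 <- derived_direction(rq, gt_fl, de, de)
  t1 <- direction_binomial(d1); t2 <- direction_binomial(d2)
  expect_equal(t1$n_increasing, t2$n_decreasing)
  expect_equal(t1$n_decreasing, t2$n_increasing)
})
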