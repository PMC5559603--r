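test_that("slope-comparison z-test matches the closed form", {
  bc <- beta_comparison(0.8, 0.1, 0.3, 0.2)
  expect_equal(bc$z, 0.5 / sqrt(0.05), tolerance = 1e-10)
  expect_equal(bc$p, 2 * pnorm(-0.5 / sqrt(0.05)), tolerance = 1e-12)
  expect_equal(round(bc$p, 5), 0.02535)
  # identity, antisymmetry, scale invariance
  expect_equal(beta_comparison(0.4, 0.1, 0.4, 0.3)$z, 0)
  expect_equal(beta_comparison(0.4, 0.1, 0.4, 0.3)$p, 1)
  ba <- beta_comparison(0.8, 0.1, 0.3, 0.2)
  ab <- beta_comparison(0.3, 0.2, 0.8, 0.1)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  sc <- beta_comparison(0.8 * 3, 0.1 * 3, 0.3 * 3, 0.2 * 3)
  expect_equal(sc$z, ba$z)
  expect_error(beta_comparison(1, 0, 2, 0), "zero")
})

test_that("reQTL calling separates response from constant eQTLs", {
  co <- cached_arch_cohort()
  rq <- call_reqtls(co$sig, co$ex, co$gt)
  dyn <- encode_dynamics(rq, co$sig)
  truth <- co$eff
  resp <- truth$gene[truth$architecture != "constant"]
  cons <- truth$gene[truth$architecture == "constant"]
  called <- unique(rq$gene[rq$significant])
  expect_true(all(resp %in% called))
  expect_false(any(cons %in% called))
  # planted dynamics category equals architecture for every reQTL gene
  m <- merge(dyn, truth[, c("gene", "architecture")])
  arch_of <- function(cat) sub("^(\\w+)-(\\w+)$", "\\2-\\1", cat)
  expect_identical(arch_of(m$category), m$architecture)
  # ceQTL/reQTL disjointness and constant recovery
  ce <- call_ceqtls(co$sig, co$ex, co$gt)
  expect_length(intersect(ce$gene[ce$is_ceqtl], called), 0)
  expect_true(all(cons %in% ce$gene))
})

test_that("specificity flags reflect planted treatment and time structure", {
  co <- cached_arch_cohort()
  rq <- call_reqtls(co$sig, co$ex, co$gt)
  sp <- classify_specificity(rq, co$ex, co$gt)
  truth <- co$eff
  # every planted effect targets a single treatment -> treatment-specific
  expect_true(all(sp$treatment_specific, na.rm = TRUE))
  # prolonged effects act equally at both time points -> not time-specific
  prolonged <- truth$gene[grepl("prolonged", truth$architecture)]
  expect_false(any(sp$timepoint_specific[sp$gene %in% prolonged]))
  transient <- truth$gene[grepl("transient", truth$architecture)]
  expect_true(all(sp$timepoint_specific[sp$gene %in% transient]))
})

test_that("identical slopes across treatments are never treatment-specific", {
  gt <- simulate_genotypes(300, 4, 3, maf_range = c(0.3, 0.5), seed = 201)
  # responds identically under all three treatments
  eff <- data.frame(gene = "g1", snp_id = gt$snps$snp_id[2],
                    architecture = "active-prolonged", beta = 1,
                    treatment = "all", de_pattern = "none")
  ex <- simulate_expression(gt, eff, n_null_genes = 2, seed = 202)
  sig <- call_egenes(map_egenes(ex, gt, n_max = 300, seed = 203))
  rq <- call_reqtls(sig, ex, gt)
  sp <- classify_specificity(rq, ex, gt)
  expect_true(any(sp$gene == "g1"))
  expect_false(any(sp$treatment_specific[sp$gene == "g1"]))
  expect_false(any(sp$timepoint_specific[sp$gene == "g1"]))
})

test_that("dynamics codes map to the six categories", {
  sets <- data.frame(
    gene = c("a", "a", "b", "c", "c", "c"),
    condition = c("LPS90", "baseline", "LPS6h", "baseline", "MDP90", "MDP6h"))
  rq <- data.frame(gene = c("a", "b", "c"),
                   condition = c("LPS90", "LPS6h", "MDP90"),
                   lead_snp = "s", p_beta = c(1e-8, 1e-6, 1e-7),
                   significant = TRUE)
  dyn <- encode_dynamics(rq, sets)
  expect_identical(dyn$code[dyn$gene == "a"], "1-1-0")
  expect_identical(dyn$category[dyn$gene == "a"], "late-suppressive")
  expect_identical(dyn$code[dyn$gene == "b"], "0-0-1")
  expect_identical(dyn$category[dyn$gene == "b"], "late-active")
  expect_identical(dyn$code[dyn$gene == "c"], "1-1-1")
  expect_identical(dyn$category[dyn$gene == "c"], "always-on-excluded")
  # 0-0-0 is an internal inconsistency
  bad <- data.frame(gene = "z", condition = "RNA90", lead_snp = "s",
                    p_beta = 1e-9, significant = TRUE)
  expect_error(encode_dynamics(bad, sets), "inconsistency")
})

test_that("ceQTL floor is monotone and strong reQTLs are never ceQTLs", {
  co <- cached_arch_cohort()
  strict <- call_ceqtls(co$sig, co$ex, co$gt, p_floor = 0.05)
  relaxed <- call_ceqtls(co$sig, co$ex, co$gt, p_floor = 0.005)
  s_set <- strict$gene[which(strict$is_ceqtl)]
  r_set <- relaxed$gene[which(relaxed$is_ceqtl)]
  expect_true(all(s_set %in% r_set))
  rq <- call_reqtls(co$sig, co$ex, co$gt)
  expect_length(intersect(s_set, rq$gene[rq$significant]), 0)
})

test_that("Fisher and binomial exact tests match enumeration oracles", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
               tolerance = 1e-12)
  expect_equal(round(fisher.test(tab)$p.value, 5), 0.48571)
  # all congruent vs all incongruent at n = 10 each
  tab2 <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher.test(tab2)$p.value, 2 * choose(10, 10) /
                 choose(20, 10) * choose(10, 0), tolerance = 1e-12)
  expect_equal(binom.test(8, 10, alternative = "greater")$p.value,
               56 / 1024, tolerance = 1e-12)
  expect_equal(binom_oracle(8, 10), 56 / 1024, tolerance = 1e-12)
  expect_gt(binom.test(5, 10, alternative = "greater")$p.value, 0.5)
  expect_equal(binom.test(10, 10, alternative = "greater")$p.value, 2^-10,
               tolerance = 1e-12)
})

test_that("congruence encoding and enrichment follow the DE codes", {
  co <- cached_arch_cohort()
  rq <- call_reqtls(co$sig, co$ex, co$gt)
  dyn <- encode_dynamics(rq, co$sig)
  de_early <- de_late <- list()
  for (t in reqtl_treatments()) {
    de_early[[t]] <- differential_expression(co$ex, "baseline",
                                             condition_name(t, "90"))
    de_late[[t]] <- differential_expression(co$ex, condition_name(t, "90"),
                                            condition_name(t, "6h"))
  }
  cg <- congruence_enrichment(dyn, de_early, de_late)
  # all planted effects carry congruent DE -> every record congruent
  expect_true(all(cg$records$congruent))
  expect_true(all(cg$enrichment$n_congruent == cg$enrichment$n_total))
  avs <- active_vs_suppressive_test(dyn)
  expect_equal(avs$n_active + avs$n_suppressive, nrow(dyn))
  expect_equal(avs$p,
               binom.test(avs$n_active, nrow(dyn),
                          alternative = "greater")$p.value)
})

test_that("the DE-as-trait cross-check correlates with the slope test", {
  co <- cached_arch_cohort()
  rq <- call_reqtls(co$sig, co$ex, co$gt)
  ps <- pdiff_similarity(rq, co$ex, co$gt)
  expect_true(all(ps$table$p_diff < 0.05, na.rm = TRUE))
})
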