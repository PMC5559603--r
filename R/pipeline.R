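# End-to-end pipeline on a synthetic cohort: generation -> QC ->
# normalization -> per-condition eQTL mapping -> reQTL/ceQTL calling ->
# dynamics and congruence -> selection enrichment -> derived-allele
# direction -> GWAS overlap -> replication-style summaries.

#' Run the full reQTL discovery pipeline on a synthetic cohort
#'
#' Generates a cohort with planted effects and runs every stage of the
#' inference chain.  Deterministic given `seed`: running twice with the
#' same arguments returns identical results.
#'
#' @param n_samples Cohort size (default 134).
#' @param n_blocks,snps_per_block LD-block layout of the genotypes.
#' @param n_per_architecture,n_constant Planted effects per response
#'   architecture and planted constant eQTLs.
#' @param n_null_genes Pure-noise genes.
#' @param beta Planted slope.
#' @param noise_sd Expression noise SD.
#' @param maf_range,within_block_r2 Genotype generator settings.
#' @param n_min,n_max Adaptive permutation settings per gene.
#' @param fdr eGene FDR (default 0.05).
#' @param alpha reQTL family-wise level (default 0.05).
#' @param selection_shift Magnitude inflation planted on reQTL lead SNPs in
#'   the simulated selection scores (default 2).
#' @param n_resamples Matched resamples for the selection test.
#' @param n_gwas_background Background rows in the simulated GWAS catalog.
#' @param seed Master seed; all stages derive their streams from it.
#' @return A list with the intermediate and final tables of every stage:
#'   `genotypes`, `expression`, `effects` (planted truth), `egenes` (all
#'   tests), `sig_egenes`, `reqtls`, `specificity`, `ceqtls`, `dynamics`,
#'   `congruence`, `active_vs_suppressive`, `de_early`, `de_late`,
#'   `locus_scores`, `selection_ihs`, `selection_sds`, `direction`,
#'   `direction_test`, `gwas_catalog`, `gwas_overlap`, `relaxed`,
#'   `replication`, `qq`.
#' @export
run_reqtl_pipeline <- function(n_samples = 134, n_blocks = 80,
                               snps_per_block = 8,
                               n_per_architecture = 5, n_constant = 10,
                               n_null_genes = 20, beta = 0.8,
                               noise_sd = 1, maf_range = c(0.1, 0.5),
                               within_block_r2 = 0.9, n_min = 100,
                               n_max = 1000, fdr = 0.05, alpha = 0.05,
                               selection_shift = 2, n_resamples = 1000,
                               n_gwas_background = 50, seed = 1) {
  seed <- as.integer(seed)
  gt0 <- simulate_genotypes(n_samples, n_blocks, snps_per_block,
                            maf_range = maf_range,
                            within_block_r2 = within_block_r2,
                            seed = seed)
  effects <- random_effects(gt0, n_per_architecture = n_per_architecture,
                            n_constant = n_constant, beta = beta,
                            seed = seed + 1L)
  expr <- simulate_expression(gt0, effects, n_null_genes = n_null_genes,
                              noise_sd = noise_sd, seed = seed + 2L)

  gt <- genotype_qc(gt0)
  expr <- quantile_normalize(expr)

  egenes_all <- map_egenes(expr, gt, n_min = n_min, n_max = n_max,
                           seed = seed + 3L)
  sig_egenes <- call_egenes(egenes_all, fdr = fdr)

  reqtls <- call_reqtls(sig_egenes, expr, gt, correction = "bonferroni",
                        alpha = alpha)
  specificity <- classify_specificity(reqtls, expr, gt, alpha = alpha)
  baseline_eg <- sig_egenes[sig_egenes$condition == "baseline", ,
                            drop = FALSE]
  ceqtls <- call_ceqtls(baseline_eg, expr, gt, p_floor = 0.05)
  dynamics <- encode_dynamics(reqtls, sig_egenes)

  de_early <- de_late <- list()
  for (t in reqtl_treatments()) {
    de_early[[t]] <- differential_expression(expr, "baseline",
                                             condition_name(t, "90"))
    de_late[[t]] <- differential_expression(expr, condition_name(t, "90"),
                                            condition_name(t, "6h"))
  }
  congruence <- tryCatch(
    congruence_enrichment(dynamics, de_early, de_late),
    error = function(e) NULL)
  avs <- tryCatch(active_vs_suppressive_test(dynamics),
                  error = function(e) NULL)

  # selection enrichment: reQTL leads as targets, genome-wide pool
  reqtl_leads <- unique(reqtls$lead_snp[reqtls$significant])
  scores <- simulate_selection_scores(gt, target_set = reqtl_leads,
                                      shift = selection_shift,
                                      seed = seed + 4L)
  cfg <- null_resample_config(n_resamples = n_resamples, seed = seed + 5L)
  pool <- locus_score_table(gt$snps$snp_id, gt, scores, cfg)
  sel_ihs <- sel_sds <- NULL
  if (length(reqtl_leads)) {
    tgt <- pool[match(reqtl_leads, pool$lead_snp), , drop = FALSE]
    sel_ihs <- matched_resample_test(tgt, pool, "proportion_high_ihs", cfg)
    sel_sds <- matched_resample_test(tgt, pool, "median_abs_sds", cfg)
    sel_ihs$null <- sel_sds$null <- NULL
  }

  # derived-allele direction: DE vs baseline at both time points
  de_vs_base_late <- list()
  for (t in reqtl_treatments())
    de_vs_base_late[[t]] <- differential_expression(
      expr, "baseline", condition_name(t, "6h"))
  direction <- tryCatch(
    derived_direction(reqtls, gt, de_early, de_vs_base_late),
    error = function(e) NULL)
  dir_test <- if (!is.null(direction))
    tryCatch(direction_binomial(direction), error = function(e) NULL)

  # GWAS-catalog overlap: tag a subset of reQTL leads
  tagged <- if (length(reqtl_leads))
    reqtl_leads[seq_len(min(5, length(reqtl_leads)))] else character(0)
  catalog <- simulate_gwas_catalog(gt, tagged_leads = tagged,
                                   r2_of_tag = 0.5,
                                   n_background = n_gwas_background,
                                   seed = seed + 6L)
  leads_df <- unique(data.frame(
    gene = reqtls$gene[reqtls$significant],
    snp_id = reqtls$lead_snp[reqtls$significant],
    stringsAsFactors = FALSE))
  all_tests <- attr(sig_egenes, "all_tests")
  baseline_nominal <- data.frame(
    gene = all_tests$gene[all_tests$condition == "baseline"],
    p = all_tests$p_nominal[all_tests$condition == "baseline"],
    stringsAsFactors = FALSE)
  overlap <- gwas_ld_overlap(leads_df, catalog, gt,
                             baseline_stats = baseline_nominal)

  relaxed <- relaxed_sets(reqtls,
                          call_ceqtls(baseline_eg, expr, gt,
                                      p_floor = 0.005))

  # replication-style summary: baseline eGene leads re-examined at 6 h LPS
  rep_p <- vapply(seq_len(nrow(baseline_eg)), function(k) {
    st <- lead_condition_stats(expr, gt, baseline_eg$gene[k],
                               baseline_eg$lead_snp[k],
                               conditions = "LPS6h")
    st$p[1]
  }, numeric(1))
  rep_p <- rep_p[!is.na(rep_p)]
  replication <- if (length(rep_p) >= 10) storey_pi1(rep_p) else NULL

  gwas_p <- setNames(catalog$p, catalog$snp_id)
  qq <- qq_enrichment(gwas_p,
                      list(reqtl_linked = unique(overlap$gwas_snp),
                           background = catalog$snp_id))

  list(genotypes = gt, expression = expr, effects = effects,
       egenes = all_tests, sig_egenes = sig_egenes, reqtls = reqtls,
       specificity = specificity, ceqtls = ceqtls, dynamics = dynamics,
       congruence = congruence, active_vs_suppressive = avs,
       de_early = de_early, de_late = de_late, locus_scores = pool,
       selection_ihs = sel_ihs, selection_sds = sel_sds,
       direction = direction, direction_test = dir_test,
       gwas_catalog = catalog, gwas_overlap = overlap, relaxed = relaxed,
       replication = replication, qq = qq)
}
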