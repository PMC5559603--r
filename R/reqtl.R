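# Slope-comparison reQTL calling, treatment/time-point specificity,
# constant-eQTL (ceQTL) definition, temporal-dynamics classification and
# DE-congruence enrichment.

#' Compare two regression slopes with a z-test
#'
#' The z statistic is `(beta_a - beta_b) / sqrt(se_a^2 + se_b^2)` and the
#' p-value the two-sided standard-normal tail.  Vectorized.
#'
#' @param beta_a,se_a,beta_b,se_b Slopes and their standard errors.
#' @return A list with `z` and `p`.
#' @examples
#' beta_comparison(0.8, 0.1, 0.3, 0.2)  # z = 2.236..., p = 0.0253...
#' @export
beta_comparison <- function(beta_a, se_a, beta_b, se_b) {
  if (any(se_a < 0 | se_b < 0, na.rm = TRUE)) stop("negative standard error")
  if (any(se_a == 0 & se_b == 0, na.rm = TRUE))
    stop("both standard errors are zero: z undefined")
  z <- (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Association of one SNP with one gene in every condition
#'
#' Refits the single-SNP regression of expression on dosage in each of the
#' seven conditions, giving the slope/SE pairs consumed by all
#' slope-comparison tests.
#'
#' @inheritParams cis_scan
#' @param snp_id SNP identifier.
#' @return data.frame with one row per condition: `condition`, `snp_id`,
#'   `gene`, `beta`, `se`, `p`, `n`, `degenerate`.
#' @export
lead_condition_stats <- function(expr, gt, gene, snp_id,
                                 conditions = reqtl_conditions()) {
  .check_condition(conditions)
  j <- match(snp_id, gt$snps$snp_id)
  if (is.na(j)) stop("unknown SNP: ", snp_id)
  pm <- expr$probe_map
  i <- match(gene, pm$gene)
  if (is.na(i)) stop("gene not in probe map: ", gene)
  g_all <- gt$dosages[, j]
  rows <- lapply(conditions, function(cn) {
    y <- expr$values[[cn]][, pm$probe[i]]
    use <- !is.na(y)
    g <- g_all[use]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (var(g) <= 0 || sum(use) < 3)
      return(data.frame(condition = cn, snp_id = snp_id, gene = gene,
                        beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = sum(use), degenerate = NA,
                        stringsAsFactors = FALSE))
    fa <- .fast_assoc(y[use], matrix(g, ncol = 1))
    data.frame(condition = cn, snp_id = snp_id, gene = gene,
               beta = fa$beta[1], se = fa$se[1], p = fa$p[1], n = fa$n,
               degenerate = fa$degenerate[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# cache of per-(gene, lead) condition stats used by the calling functions
.lead_stats_table <- function(expr, gt, genes, leads) {
  key <- paste(genes, leads)
  uniq <- !duplicated(key)
  tabs <- Map(function(g, s) lead_condition_stats(expr, gt, g, s),
              genes[uniq], leads[uniq])
  names(tabs) <- key[uniq]
  tabs[key]
}

#' Call reQTLs by baseline-vs-stimulated slope comparison
#'
#' For each stimulated condition, every gene that is a significant eGene in
#' that condition *or* at baseline is tested: the lead SNP's slope in the
#' stimulated condition is compared with its slope recomputed in the
#' baseline condition via [beta_comparison()].  The lead SNP is the
#' stimulated condition's lead when the gene is an eGene there, otherwise
#' the baseline lead (this is what makes purely suppressive reQTLs --
#' eQTLs present at baseline and lost under stimulation -- detectable at
#' all).  The multiple-testing family is all such
#' (gene, stimulated-condition) tests; `bonferroni` is the primary
#' correction, `bh` the relaxed variant used for enrichment-set
#' construction.
#'
#' @param sig_egenes Significant eGene table (from [call_egenes()]),
#'   covering the baseline and stimulated conditions.
#' @param expr,gt Expression and genotype objects.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha Significance level after correction (default 0.05).
#' @return data.frame with one row per test: `gene`, `condition`,
#'   `lead_snp`, `lead_source` (`stim` or `baseline`), `beta_baseline`,
#'   `se_baseline`, `beta_stim`, `se_stim`, `z`, `p_beta`, `p_adj`,
#'   `significant`.  Tests with a degenerate (zero-SE) fit are excluded
#'   and counted in attribute `"n_degenerate"`.
#' @export
call_reqtls <- function(sig_egenes, expr, gt,
                        correction = c("bonferroni", "bh"), alpha = 0.05) {
  correction <- match.arg(correction)
  base <- sig_egenes[sig_egenes$condition == "baseline", , drop = FALSE]
  eg <- do.call(rbind, lapply(stimulated_conditions(), function(cn) {
    st <- sig_egenes[sig_egenes$condition == cn, , drop = FALSE]
    extra <- base[!(base$gene %in% st$gene), , drop = FALSE]
    rbind(
      if (nrow(st)) data.frame(gene = st$gene, condition = cn,
                               lead_snp = st$lead_snp,
                               lead_source = "stim",
                               stringsAsFactors = FALSE),
      if (nrow(extra)) data.frame(gene = extra$gene, condition = cn,
                                  lead_snp = extra$lead_snp,
                                  lead_source = "baseline",
                                  stringsAsFactors = FALSE))
  }))
  if (is.null(eg) || !nrow(eg))
    return(data.frame(gene = character(), condition = character(),
                      lead_snp = character(), lead_source = character(),
                      beta_baseline = numeric(),
                      se_baseline = numeric(), beta_stim = numeric(),
                      se_stim = numeric(), z = numeric(), p_beta = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  tabs <- .lead_stats_table(expr, gt, eg$gene, eg$lead_snp)
  rows <- vector("list", nrow(eg))
  for (k in seq_len(nrow(eg))) {
    st <- tabs[[k]]
    b0 <- st[st$condition == "baseline", ]
    bs <- st[st$condition == eg$condition[k], ]
    if (is.na(b0$se) || is.na(bs$se))
      stop("baseline or stimulated fit unavailable for ", eg$gene[k],
           " at ", eg$lead_snp[k])
    rows[[k]] <- data.frame(
      gene = eg$gene[k], condition = eg$condition[k],
      lead_snp = eg$lead_snp[k], lead_source = eg$lead_source[k],
      beta_baseline = b0$beta, se_baseline = b0$se,
      beta_stim = bs$beta, se_stim = bs$se,
      degenerate = isTRUE(b0$degenerate) || isTRUE(bs$degenerate),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_deg <- sum(out$degenerate | out$se_baseline == 0 | out$se_stim == 0)
  out <- out[!(out$degenerate | out$se_baseline == 0 | out$se_stim == 0), ,
             drop = FALSE]
  out$degenerate <- NULL
  if (nrow(out)) {
    bc <- beta_comparison(out$beta_baseline, out$se_baseline,
                          out$beta_stim, out$se_stim)
    out$z <- bc$z
    out$p_beta <- bc$p
    out$p_adj <- if (correction == "bonferroni")
      pmin(out$p_beta * nrow(out), 1) else p.adjust(out$p_beta, "BH")
    out$significant <- out$p_adj < alpha
  }
  rownames(out) <- NULL
  attr(out, "n_degenerate") <- n_deg
  attr(out, "correction") <- correction
  out
}

#' Treatment and time-point specificity of reQTLs
#'
#' A significant reQTL of one treatment/time point is *treatment-specific*
#' when its slope differs from the slopes of both other treatments at the
#' same time point (two z-tests, both required to be significant after
#' Bonferroni correction over all cross-treatment tests); it is
#' *time-point-specific* when its slope differs from the same treatment's
#' other time point (one z-test, Bonferroni over all cross-time tests).
#' The two comparison types form separate Bonferroni families.
#'
#' @param reqtls Output of [call_reqtls()]; only rows with
#'   `significant == TRUE` are classified.
#' @param expr,gt Expression and genotype objects.
#' @param alpha Family-wise level (default 0.05).
#' @param treatment_rule `"both"` (default) requires both cross-treatment
#'   tests to be significant; `"either"` only one.
#' @return The significant reQTL rows with logical columns
#'   `treatment_specific` and `timepoint_specific` added (NA when a needed
#'   fit is unavailable).
#' @export
classify_specificity <- function(reqtls, expr, gt, alpha = 0.05,
                                 treatment_rule = c("both", "either")) {
  treatment_rule <- match.arg(treatment_rule)
  rq <- reqtls[reqtls$significant, , drop = FALSE]
  if (!nrow(rq)) {
    rq$treatment_specific <- logical(0)
    rq$timepoint_specific <- logical(0)
    return(rq)
  }
  tabs <- .lead_stats_table(expr, gt, rq$gene, rq$lead_snp)
  trt <- condition_treatment(rq$condition)
  tp <- condition_timepoint(rq$condition)
  # cross-treatment tests: two per reQTL
  p_trt <- matrix(NA_real_, nrow(rq), 2)
  for (k in seq_len(nrow(rq))) {
    st <- tabs[[k]]
    own <- st[st$condition == rq$condition[k], ]
    others <- setdiff(.treatments, trt[k])
    for (m in 1:2) {
      oc <- condition_name(others[m], tp[k])
      ot <- st[st$condition == oc, ]
      if (!is.na(own$se) && !is.na(ot$se) && (own$se > 0 || ot$se > 0))
        p_trt[k, m] <- beta_comparison(own$beta, own$se, ot$beta, ot$se)$p
    }
  }
  m_trt <- sum(!is.na(p_trt))
  sig_trt <- p_trt * m_trt < alpha
  rq$treatment_specific <- if (treatment_rule == "both")
    sig_trt[, 1] & sig_trt[, 2] else sig_trt[, 1] | sig_trt[, 2]
  # cross-time tests: one per reQTL
  p_time <- rep(NA_real_, nrow(rq))
  for (k in seq_len(nrow(rq))) {
    st <- tabs[[k]]
    own <- st[st$condition == rq$condition[k], ]
    oc <- condition_name(trt[k], setdiff(.timepoints, tp[k]))
    ot <- st[st$condition == oc, ]
    if (!is.na(own$se) && !is.na(ot$se) && (own$se > 0 || ot$se > 0))
      p_time[k] <- beta_comparison(own$beta, own$se, ot$beta, ot$se)$p
  }
  m_time <- sum(!is.na(p_time))
  rq$timepoint_specific <- p_time * m_time < alpha
  rownames(rq) <- NULL
  attr(rq, "p_treatment") <- p_trt
  attr(rq, "p_timepoint") <- p_time
  rq
}

#' Call constant eQTLs (ceQTLs)
#'
#' A baseline eGene is a ceQTL when the z-test comparing its lead SNP's
#' baseline slope with the slope in each of the six stimulated conditions
#' gives a nominal (uncorrected) p-value above `p_floor` in every
#' comparison (default 0.05; 0.005 defines the relaxed set).
#'
#' @param baseline_egenes Significant eGene rows of the baseline condition.
#' @param expr,gt Expression and genotype objects.
#' @param p_floor Nominal p-value floor (default 0.05).
#' @return data.frame with `gene`, `lead_snp`, the six per-condition
#'   `p_beta` values (`p_min` is their minimum) and `is_ceqtl`.  Genes with
#'   an untestable condition are flagged `is_ceqtl = NA`.
#' @export
call_ceqtls <- function(baseline_egenes, expr, gt, p_floor = 0.05) {
  eg <- baseline_egenes[baseline_egenes$condition == "baseline", ,
                        drop = FALSE]
  if (!nrow(eg))
    return(data.frame(gene = character(), lead_snp = character(),
                      p_min = numeric(), is_ceqtl = logical(),
                      stringsAsFactors = FALSE))
  tabs <- .lead_stats_table(expr, gt, eg$gene, eg$lead_snp)
  stim <- stimulated_conditions()
  pmat <- matrix(NA_real_, nrow(eg), 6, dimnames = list(NULL, stim))
  for (k in seq_len(nrow(eg))) {
    st <- tabs[[k]]
    b0 <- st[st$condition == "baseline", ]
    for (cn in stim) {
      bs <- st[st$condition == cn, ]
      if (!is.na(b0$se) && !is.na(bs$se) && (b0$se > 0 || bs$se > 0))
        pmat[k, cn] <- beta_comparison(b0$beta, b0$se, bs$beta, bs$se)$p
    }
  }
  complete <- rowSums(is.na(pmat)) == 0
  p_min <- apply(pmat, 1, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  is_ceqtl <- ifelse(complete, p_min > p_floor, NA)
  out <- data.frame(gene = eg$gene, lead_snp = eg$lead_snp,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pmat))
  out$p_min <- p_min
  out$is_ceqtl <- is_ceqtl
  if (any(!complete))
    message(sum(!complete), " baseline eGene(s) not callable as ceQTL")
  rownames(out) <- NULL
  out
}

.category_map <- c("0-1-0" = "transient-active",
                   "1-0-1" = "transient-suppressive",
                   "0-0-1" = "late-active",
                   "1-1-0" = "late-suppressive",
                   "0-1-1" = "prolonged-active",
                   "1-0-0" = "prolonged-suppressive",
                   "1-1-1" = "always-on-excluded")

#' Temporal-dynamics classification of reQTLs
#'
#' Each reQTL gene is encoded by whether it has a genome-wide-significant
#' eQTL at baseline, 90 min and 6 h (membership in the FDR-controlled eGene
#' set of the respective condition, for the reQTL's treatment).  A gene
#' that is a significant reQTL in several treatments is assigned the
#' treatment with the best (smallest) slope-comparison p-value.  The binary
#' code maps to six categories -- transiently active `0-1-0`, transiently
#' suppressive `1-0-1`, late active `0-0-1`, late suppressive `1-1-0`,
#' prolonged active `0-1-1`, prolonged suppressive `1-0-0` -- while `1-1-1`
#' (significant at all three time points) is excluded from the six-way
#' classification and labelled `always-on-excluded`.  Code `0-0-0` cannot
#' occur for a reQTL and raises an error.
#'
#' @param reqtls Output of [call_reqtls()] (significant rows are used).
#' @param egene_sets The significant eGene table from [call_egenes()]
#'   covering all seven conditions.
#' @return data.frame with one row per reQTL gene: `gene`, `treatment`,
#'   `lead_snp`, `p_beta`, `sig_baseline`, `sig_90`, `sig_6h`, `code`,
#'   `category`.
#' @export
encode_dynamics <- function(reqtls, egene_sets) {
  rq <- reqtls[reqtls$significant, , drop = FALSE]
  if (!nrow(rq))
    return(data.frame(gene = character(), treatment = character(),
                      lead_snp = character(), p_beta = numeric(),
                      sig_baseline = logical(), sig_90 = logical(),
                      sig_6h = logical(), code = character(),
                      category = character(), stringsAsFactors = FALSE))
  rq$treatment <- condition_treatment(rq$condition)
  # best-p treatment per gene
  best <- rq[order(rq$gene, rq$p_beta), ]
  best <- best[!duplicated(best$gene), ]
  in_set <- function(gene, cond)
    any(egene_sets$gene == gene & egene_sets$condition == cond)
  rows <- lapply(seq_len(nrow(best)), function(k) {
    g <- best$gene[k]; t <- best$treatment[k]
    s0 <- in_set(g, "baseline")
    s90 <- in_set(g, condition_name(t, "90"))
    s6 <- in_set(g, condition_name(t, "6h"))
    code <- paste(as.integer(c(s0, s90, s6)), collapse = "-")
    if (code == "0-0-0")
      stop("internal inconsistency: reQTL gene ", g,
           " is in no eGene set of treatment ", t)
    data.frame(gene = g, treatment = t, lead_snp = best$lead_snp[k],
               p_beta = best$p_beta[k], sig_baseline = s0, sig_90 = s90,
               sig_6h = s6, code = code,
               category = unname(.category_map[code]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# expected DE code (d1, d2 in the 0/1/2 encoding) per temporal class
.congruent_codes <- function(category) {
  class <- sub("-(active|suppressive)$", "", category)
  switch(class,
         transient = list(d1 = 1L, d2 = 2L),
         late = list(d1 = 0L, d2 = 1L),
         prolonged = list(d1 = 1L, d2 = c(0L, 1L)),
         NULL)
}

#' Differential-expression congruence of reQTL dynamics
#'
#' Encodes, per reQTL gene, the significance of differential expression
#' between baseline and 90 min (`d1`: 0/1) and between 90 min and 6 h
#' (`d2`: 0 not significant, 1 significant in the same direction as the
#' 90-min change, 2 significant in the opposite direction), at nominal
#' `de_p`.  A gene's DE pattern is *congruent* with its dynamics category
#' when the code matches the category's expectation: transient `1-2`, late
#' `0-1`, prolonged `1-0` or `1-1`.  Per category, a two-sided Fisher's
#' exact test compares the congruent proportion (same code) against the
#' pooled remaining categories.
#'
#' @param dynamics Output of [encode_dynamics()] (rows with category
#'   `always-on-excluded` are ignored).
#' @param de_early Named list (by treatment) of
#'   [differential_expression()] tables for the 90 min - baseline
#'   contrast.
#' @param de_late Same for the 6 h - 90 min contrast.
#' @param de_p Nominal DE significance cutoff (default 0.01).
#' @return A list with `records` (per-gene codes and congruence) and
#'   `enrichment` (per-category counts and Fisher p).
#' @export
congruence_enrichment <- function(dynamics, de_early, de_late,
                                  de_p = 0.01) {
  dyn <- dynamics[dynamics$category != "always-on-excluded", , drop = FALSE]
  if (!nrow(dyn)) stop("no classifiable dynamics records")
  rec <- lapply(seq_len(nrow(dyn)), function(k) {
    t <- dyn$treatment[k]; g <- dyn$gene[k]
    e <- de_early[[t]]; l <- de_late[[t]]
    ie <- match(g, e$gene); il <- match(g, l$gene)
    if (is.na(ie) || is.na(il))
      stop("missing DE result for gene ", g, " under ", t)
    d1 <- as.integer(e$p[ie] < de_p)
    d2 <- if (l$p[il] >= de_p) 0L else
      if (sign(l$log2fc[il]) == sign(e$log2fc[ie])) 1L else 2L
    cc <- .congruent_codes(dyn$category[k])
    data.frame(gene = g, treatment = t, category = dyn$category[k],
               d1 = d1, d2 = d2,
               congruent = d1 == cc$d1 && d2 %in% cc$d2,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  cats <- intersect(unname(.category_map), unique(rec$category))
  enr <- lapply(cats, function(cat) {
    cc <- .congruent_codes(cat)
    match_code <- rec$d1 == cc$d1 & rec$d2 %in% cc$d2
    own <- rec$category == cat
    a <- sum(own & match_code); b <- sum(own & !match_code)
    c_ <- sum(!own & match_code); d <- sum(!own & !match_code)
    fp <- if (sum(own) == 0 || sum(!own) == 0) NA_real_ else
      fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(category = cat, n_congruent = a, n_total = sum(own),
               rest_match = c_, rest_total = sum(!own), fisher_p = fp,
               stringsAsFactors = FALSE)
  })
  list(records = rec, enrichment = do.call(rbind, enr))
}

#' Active vs suppressive reQTL counts
#'
#' One-sided exact binomial test of whether active reQTLs (absent at
#' baseline, gained under stimulation) outnumber suppressive reQTLs
#' (present at baseline, lost under stimulation) among the six-way
#' classified records, under a null proportion of 0.5.
#'
#' @param dynamics Output of [encode_dynamics()].
#' @return list with `n_active`, `n_suppressive`, `p` (one-sided).
#' @export
active_vs_suppressive_test <- function(dynamics) {
  act <- grepl("-active$", dynamics$category)
  sup <- grepl("-suppressive$", dynamics$category)
  n_act <- sum(act); n_sup <- sum(sup)
  if (n_act + n_sup == 0) stop("no active or suppressive records")
  p <- binom.test(n_act, n_act + n_sup, 0.5,
                  alternative = "greater")$p.value
  list(n_active = n_act, n_suppressive = n_sup, p = p)
}

#' Similarity with the differential-expression-as-trait approach
#'
#' Cross-check of the slope-comparison test: for each significant reQTL the
#' per-sample expression difference (stimulated minus baseline) is mapped
#' as a quantitative trait on the lead SNP, and the resulting p-values
#' (`p_diff`) are compared with the slope-comparison `p_beta` by Spearman
#' correlation.
#'
#' @param reqtls Output of [call_reqtls()].
#' @param expr,gt Expression and genotype objects.
#' @return list with `rho` (Spearman correlation of `p_beta` and `p_diff`)
#'   and the per-reQTL `table`.
#' @export
pdiff_similarity <- function(reqtls, expr, gt) {
  rq <- reqtls[reqtls$significant, , drop = FALSE]
  if (!nrow(rq)) stop("no significant reQTLs to cross-check")
  pm <- expr$probe_map
  p_diff <- vapply(seq_len(nrow(rq)), function(k) {
    probe <- pm$probe[match(rq$gene[k], pm$gene)]
    d <- expr$values[[rq$condition[k]]][, probe] -
      expr$values[["baseline"]][, probe]
    g <- gt$dosages[, match(rq$lead_snp[k], gt$snps$snp_id)]
    use <- !is.na(d)
    g <- g[use]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (var(g) <= 0) return(NA_real_)
    .fast_assoc(d[use], matrix(g, ncol = 1))$p[1]
  }, numeric(1))
  tab <- data.frame(gene = rq$gene, condition = rq$condition,
                    p_beta = rq$p_beta, p_diff = p_diff,
                    stringsAsFactors = FALSE)
  ok <- complete.cases(tab[, c("p_beta", "p_diff")])
  list(rho = suppressWarnings(cor(tab$p_beta[ok], tab$p_diff[ok],
                                  method = "spearman")),
       table = tab)
}
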