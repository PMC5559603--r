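# Genotype QC, probe filtering, quantile normalization and paired
# differential expression.

#' QC thresholds
#'
#' Container for the quality-control thresholds applied to genotypes and
#' expression probes: SNPs are kept when the exact Hardy-Weinberg p-value
#' exceeds `hwe_p_min`, the call rate exceeds `call_rate_min` and the minor
#' allele frequency exceeds `maf_min`; probes are kept when detected
#' (detection p below `probe_detect_p`) in at least
#' `probe_detect_min_samples` samples pooled over conditions, and values of
#' probes whose interindividual standard deviation exceeds `probe_sd_cap`
#' in a condition are masked to `NA` there.
#'
#' @param hwe_p_min Hardy-Weinberg exact-test p-value floor (default 1e-5).
#' @param call_rate_min Minimum per-SNP call rate (default 0.98).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param probe_detect_p Detection p-value cutoff (default 0.01).
#' @param probe_detect_min_samples Minimum number of samples detected
#'   (default 10).
#' @param probe_sd_cap Interindividual standard deviation above which a
#'   probe's values are masked (default 5).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-5, call_rate_min = 0.98,
                          maf_min = 0.05, probe_detect_p = 0.01,
                          probe_detect_min_samples = 10, probe_sd_cap = 5) {
  stopifnot(hwe_p_min > 0, hwe_p_min < 1, call_rate_min >= 0,
            call_rate_min <= 1, maf_min >= 0, maf_min < 0.5)
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 maf_min = maf_min, probe_detect_p = probe_detect_p,
                 probe_detect_min_samples = probe_detect_min_samples,
                 probe_sd_cap = probe_sd_cap),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from genotype counts,
#' using the conditional distribution of the heterozygote count given the
#' allele counts: the p-value is the total probability of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_test(25, 50, 25)   # exactly HWE: p = 1
#' hwe_test(50, 0, 50)    # maximal heterozygote deficit
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) %% 1 != 0))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype observation required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  nmin <- min(nA, na)
  h <- seq(nmin %% 2, nmin, by = 2)
  # log P(h) up to a constant: n! 2^h / ((nA-h)/2)! h! ((na-h)/2)!
  lp <- h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Retains SNPs passing Hardy-Weinberg, call-rate and MAF filters.
#' Hardy-Weinberg counts are taken from dosages rounded to hard calls; MAF
#' is computed from mean dosage over non-missing samples.
#'
#' @param gt A `reqtl_genotypes` object.
#' @param thr A [qc_thresholds()] object.
#' @return The filtered `reqtl_genotypes`; counts of SNPs removed per
#'   criterion are attached as attribute `"qc_report"`.
#' @export
genotype_qc <- function(gt, thr = qc_thresholds()) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  if (nrow(gt$snps) == 0) stop("empty genotype matrix")
  dos <- gt$dosages
  n <- nrow(dos)
  call_rate <- 1 - colSums(is.na(dos)) / n
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(dos)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- hard[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(0)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  fail_hwe <- hwe_p <= thr$hwe_p_min
  fail_cr <- call_rate <= thr$call_rate_min
  fail_maf <- maf <= thr$maf_min
  keep <- !(fail_hwe | fail_cr | fail_maf)
  out <- gt
  out$dosages <- dos[, keep, drop = FALSE]
  out$snps <- gt$snps[keep, , drop = FALSE]
  rownames(out$snps) <- NULL
  attr(out, "qc_report") <- list(
    n_input = ncol(dos), n_kept = sum(keep),
    removed_hwe = sum(fail_hwe), removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf))
  if (!sum(keep)) message("genotype_qc: no SNPs passed the filters")
  out
}

#' Filter expression probes by detection and variability
#'
#' Keeps probes detected (detection p below `thr$probe_detect_p`) in at
#' least `thr$probe_detect_min_samples` sample/condition observations
#' pooled over all conditions.  Within each condition, probes whose
#' interindividual standard deviation exceeds `thr$probe_sd_cap` have all
#' values of that condition masked to `NA` (the probe is retained).
#'
#' @param expr A `cond_expression` object.
#' @param detection_p Either a samples x probes matrix of detection
#'   p-values (pooled across conditions) or a named list of such matrices,
#'   one per condition, aligned with `expr`.
#' @param thr A [qc_thresholds()] object.
#' @return The filtered `cond_expression`; dropped-probe counts are
#'   attached as attribute `"qc_report"`.
#' @export
filter_probes <- function(expr, detection_p, thr = qc_thresholds()) {
  stopifnot(inherits(expr, "cond_expression"))
  probes <- expr$probe_map$probe
  mats <- if (is.matrix(detection_p)) list(detection_p) else detection_p
  det_count <- setNames(numeric(length(probes)), probes)
  for (m in mats) {
    if (!is.matrix(m) || ncol(m) != length(probes) ||
        nrow(m) != length(expr$samples))
      stop("detection_p must be aligned samples x probes")
    det_count <- det_count + colSums(m < thr$probe_detect_p)
  }
  keep <- det_count >= thr$probe_detect_min_samples
  out <- expr
  out$probe_map <- expr$probe_map[keep, , drop = FALSE]
  rownames(out$probe_map) <- NULL
  n_masked <- 0L
  for (cn in names(out$values)) {
    v <- out$values[[cn]][, keep, drop = FALSE]
    sds <- apply(v, 2, sd, na.rm = TRUE)
    mask <- !is.na(sds) & sds > thr$probe_sd_cap
    if (any(mask)) { v[, mask] <- NA_real_; n_masked <- n_masked + sum(mask) }
    out$values[[cn]] <- v
  }
  attr(out, "qc_report") <- list(n_input = length(probes),
                                 n_kept = sum(keep),
                                 removed_detection = sum(!keep),
                                 masked_high_sd = n_masked)
  out
}

#' Collapse multi-probe genes to their lead probe
#'
#' For genes measured by several probes, keeps the probe with the best
#' (smallest) average detection p-value across samples and drops the
#' rest; single-probe genes pass through unchanged.
#'
#' @param expr A `cond_expression` object whose probe map may contain
#'   several probes per gene.
#' @param detection_p samples x probes matrix of detection p-values
#'   aligned with `expr`.
#' @return The `cond_expression` restricted to one probe per gene.
#' @export
collapse_probes <- function(expr, detection_p) {
  stopifnot(inherits(expr, "cond_expression"))
  if (!is.matrix(detection_p) || ncol(detection_p) != nrow(expr$probe_map))
    stop("detection_p must be aligned samples x probes")
  score <- colMeans(detection_p)
  keep <- unlist(lapply(split(seq_len(nrow(expr$probe_map)),
                              expr$probe_map$gene),
                        function(i) i[which.min(score[i])]))
  keep <- sort(unname(keep))
  out <- expr
  out$probe_map <- expr$probe_map[keep, , drop = FALSE]
  rownames(out$probe_map) <- NULL
  out$values <- lapply(expr$values, function(m) m[, keep, drop = FALSE])
  out
}

#' Residualize expression on covariates
#'
#' Regresses every probe, in every condition, on the supplied covariate
#' matrix and keeps the residuals (plus the probe's mean).  Use before
#' [cis_scan()]/[map_egenes()] when the cohort carries structure the
#' default covariate-free eQTL model should not absorb into genotype
#' effects.
#'
#' @param expr A `cond_expression` object.
#' @param covariates samples x covariates numeric matrix, aligned with
#'   `expr$samples`.
#' @return The `cond_expression` with residualized values.
#' @export
residualize_expression <- function(expr, covariates) {
  stopifnot(inherits(expr, "cond_expression"))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(expr$samples))
    stop("covariates must have one row per sample")
  X <- cbind(1, covariates)
  out <- expr
  out$values <- lapply(expr$values, function(m) {
    res <- m
    for (j in seq_len(ncol(m))) {
      y <- m[, j]
      use <- !is.na(y) & complete.cases(X)
      fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
      res[use, j] <- fit$residuals + mean(y[use])
    }
    res
  })
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample's expression values onto the identical empirical
#' distribution (the rank-wise mean of the samples' sorted values), with
#' ties resolved by average rank.  A thin wrapper around
#' [limma::normalizeQuantiles()] transposed to the samples x probes layout
#' used here.
#'
#' @param x A samples x probes numeric matrix, or a `cond_expression`
#'   object (each condition is normalized independently).
#' @return Same shape as the input.
#' @examples
#' quantile_normalize(rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "cond_expression")) {
    x$values <- lapply(x$values, quantile_normalize)
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (any(rowSums(!is.na(x)) == 0))
    stop("sample with all-missing values cannot be quantile normalized")
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Paired differential expression between two conditions
#'
#' Per gene, the log2 fold change is the paired mean difference
#' (`cond_b - cond_a`; expression is assumed to be on the log2 scale) and
#' the p-value comes from a paired t-test, with Benjamini-Hochberg
#' adjustment across genes.  Zero-variance differences are handled
#' explicitly: all-zero differences give p = 1, constant nonzero
#' differences the smallest representable p.
#'
#' @param expr A `cond_expression` object.
#' @param cond_a,cond_b Condition names; the contrast is `cond_b - cond_a`.
#' @param fc_threshold,fdr Optional absolute log2 fold-change and BH-FDR
#'   thresholds; when both are given a `significant` flag is added.
#' @return data.frame with `gene`, `log2fc`, `p`, `q`, `n` and (optionally)
#'   `significant`.
#' @export
differential_expression <- function(expr, cond_a, cond_b,
                                    fc_threshold = NULL, fdr = NULL) {
  stopifnot(inherits(expr, "cond_expression"))
  .check_condition(c(cond_a, cond_b))
  a <- expr$values[[cond_a]]; b <- expr$values[[cond_b]]
  d <- b - a
  n_eff <- colSums(!is.na(d))
  if (all(n_eff < 3)) stop("fewer than 3 paired samples in every gene")
  mu <- colMeans(d, na.rm = TRUE)
  s <- apply(d, 2, sd, na.rm = TRUE)
  p <- rep(NA_real_, ncol(d))
  ok <- n_eff >= 3
  zero_var <- ok & (is.na(s) | s == 0)
  p[zero_var & mu == 0] <- 1
  p[zero_var & mu != 0] <- .Machine$double.xmin
  reg <- ok & !zero_var
  tstat <- mu[reg] / (s[reg] / sqrt(n_eff[reg]))
  p[reg] <- 2 * pt(abs(tstat), n_eff[reg] - 1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = expr$probe_map$gene, log2fc = mu, p = p, q = q,
                    n = n_eff, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(fc_threshold) && !is.null(fdr))
    out$significant <- !is.na(out$p) & abs(out$log2fc) > fc_threshold &
      out$q < fdr
  out
}
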