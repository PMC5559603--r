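# Per-condition cis-eQTL scan: simple linear regression of expression on
# dosage for every SNP within 1 Mb of the probe anchor, adaptive
# permutations with a beta-approximated empirical p-value per gene, and
# Benjamini-Hochberg eGene calling per condition.

# Vectorized simple OLS of y on each column of G (no missing values).
# Returns beta, se, t, p, df plus a degenerate flag for (near-)perfect fits.
.fast_assoc <- function(y, G) {
  n <- length(y)
  yc <- y - mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(Gc^2)
  sxy <- as.vector(crossprod(Gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  df <- n - 2
  degenerate <- rss <= 1e-12 * max(syy, .Machine$double.eps)
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, beta / se, Inf * sign(beta))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[degenerate] <- .Machine$double.xmin
  list(beta = beta, se = se, t = tstat, p = p, df = df, n = n,
       degenerate = degenerate)
}

# minimum nominal p implied by the maximum squared correlation
.r2_to_p <- function(r2, n) {
  r2 <- pmin(pmax(r2, 0), 1)
  tstat <- sqrt(r2 * (n - 2) / pmax(1 - r2, 1e-300))
  2 * pt(tstat, n - 2, lower.tail = FALSE)
}

# expression vector and cis dosage matrix for one (gene, condition):
# NA samples dropped, missing dosages mean-imputed, monomorphic SNPs removed
.gene_data <- function(expr, gt, gene, condition, window_bp, min_n = 10) {
  .check_condition(condition)
  pm <- expr$probe_map
  i <- match(gene, pm$gene)
  if (is.na(i)) stop("gene not in probe map: ", gene)
  y <- expr$values[[condition]][, pm$probe[i]]
  use <- !is.na(y)
  if (sum(use) < min_n)
    stop("fewer than ", min_n, " samples with expression for ", gene,
         " in ", condition)
  snps <- gt$snps
  cis <- which(snps$chrom == pm$chrom[i] &
                 snps$pos >= pm$anchor_pos[i] - window_bp &
                 snps$pos <= pm$anchor_pos[i] + window_bp)
  if (!length(cis)) {
    message("no cis SNPs within ", window_bp, " bp of ", gene)
    return(NULL)
  }
  G <- gt$dosages[use, cis, drop = FALSE]
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0)) {
      v <- G[, j]; v[is.na(v)] <- mean(v, na.rm = TRUE); G[, j] <- v
    }
  }
  v <- apply(G, 2, var)
  mono <- !is.na(v) & v <= 0
  if (any(mono) || anyNA(v)) {
    drop <- mono | is.na(v)
    G <- G[, !drop, drop = FALSE]; cis <- cis[!drop]
  }
  if (!ncol(G)) {
    message("all cis SNPs monomorphic for ", gene, " in ", condition)
    return(NULL)
  }
  list(y = y[use], G = G, snp = snps[cis, , drop = FALSE],
       n_monomorphic = sum(mono))
}

#' cis-eQTL scan for one gene in one condition
#'
#' Regresses expression on dosage for every SNP within `window_bp` of the
#' gene's probe anchor (same chromosome, window inclusive on both sides).
#' Samples with missing expression are dropped; missing dosages are
#' mean-imputed per SNP; monomorphic SNPs are skipped and counted in the
#' `"n_monomorphic"` attribute.
#'
#' @param expr A `cond_expression` object.
#' @param gt A `reqtl_genotypes` object.
#' @param gene Gene name (must be in the probe map).
#' @param condition Condition name.
#' @param window_bp cis window half-width in bp (default 1 Mb).
#' @param min_n Minimum number of samples with expression.
#' @return data.frame with one row per tested SNP: `snp_id`, `gene`,
#'   `condition`, `beta`, `se`, `t`, `p`, `df`, `n`, `degenerate`; or
#'   `NULL` (with a message) when no testable cis SNP exists.
#' @export
cis_scan <- function(expr, gt, gene, condition, window_bp = 1e6,
                     min_n = 10) {
  gd <- .gene_data(expr, gt, gene, condition, window_bp, min_n)
  if (is.null(gd)) return(NULL)
  fa <- .fast_assoc(gd$y, gd$G)
  out <- data.frame(snp_id = gd$snp$snp_id, gene = gene,
                    condition = condition, beta = fa$beta, se = fa$se,
                    t = fa$t, p = fa$p, df = fa$df, n = fa$n,
                    degenerate = fa$degenerate,
                    pos = gd$snp$pos, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_monomorphic") <- gd$n_monomorphic
  out
}

# maximum-likelihood Beta fit to permuted minimum p-values,
# initialized from method-of-moments; NULL on failure
.fit_beta <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  common <- m * (1 - m) / v - 1
  if (common <= 0) common <- 1
  init <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(optim(init, nll, method = "Nelder-Mead",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  exp(fit$par)
}

#' Adaptive permutation pass for one gene
#'
#' Estimates the empirical p-value of a gene's best cis association by
#' permuting expression across samples.  Each permutation records the
#' minimum nominal p over all cis SNPs.  With `adaptive = TRUE` the scheme
#' mirrors an adaptive `n_min`/`n_max` setting: permutation stops (at a
#' multiple of the internal chunk size of 100) once at least `n_min`
#' permuted minima beat the observed minimum, and always at `n_max`.  A
#' Beta distribution is then fitted to the permuted minima by maximum
#' likelihood (method-of-moments start) and the reported `p_perm` is its
#' CDF at the observed minimum; if the fit fails, the empirical estimator
#' `(r + 1) / (N + 1)` is used with a warning.
#'
#' @inheritParams cis_scan
#' @param n_min Adaptive stopping count (default 100).
#' @param n_max Maximum number of permutations (default 10000).
#' @param adaptive Stop early once `n_min` permuted minima beat the
#'   observed one (default `TRUE`); `FALSE` always runs `n_max`.
#' @param seed Integer seed; permutations are deterministic given it.
#' @return One-row data.frame: `gene`, `condition`, `lead_snp` (minimum
#'   nominal p, ties broken by smallest position), `beta`, `se`, `p_nominal`
#'   (the lead's), `n_cis`, `p_perm`, `p_empirical`, `shape1`, `shape2`,
#'   `n_perm`, `beta_ok`; or `NULL` when the gene has no testable cis SNP.
#' @export
permutation_pass <- function(expr, gt, gene, condition, window_bp = 1e6,
                             n_min = 100, n_max = 10000, adaptive = TRUE,
                             min_n = 10, seed = NULL) {
  if (n_min < 1 || n_max < n_min) stop("need 1 <= n_min <= n_max")
  gd <- .gene_data(expr, gt, gene, condition, window_bp, min_n)
  if (is.null(gd)) return(NULL)
  if (!is.null(seed)) set.seed(seed)
  n <- length(gd$y)
  ys <- as.vector(scale(gd$y))
  if (anyNA(ys)) stop("expression has zero variance for ", gene)
  Gs <- scale(gd$G)
  robs <- as.vector(crossprod(Gs, ys)) / (n - 1)
  p_obs_all <- .r2_to_p(robs^2, n)
  lead <- order(p_obs_all, gd$snp$pos)[1]
  p_obs <- p_obs_all[lead]

  chunk <- 100L
  minp <- numeric(0)
  total <- 0L
  while (total < n_max) {
    b <- min(chunk, n_max - total)
    pm <- replicate(b, sample.int(n))
    Yp <- matrix(ys[pm], n, b)
    R <- crossprod(Gs, Yp) / (n - 1)
    r2max <- apply(R^2, 2, max)
    minp <- c(minp, .r2_to_p(r2max, n))
    total <- total + b
    if (adaptive && sum(minp <= p_obs) >= n_min) break
  }
  hits <- sum(minp <= p_obs)
  p_emp <- (hits + 1) / (total + 1)
  ab <- .fit_beta(minp)
  if (is.null(ab)) {
    warning("Beta fit failed for ", gene, " (", condition,
            "); using empirical permutation p")
    p_perm <- p_emp; shape1 <- NA_real_; shape2 <- NA_real_; ok <- FALSE
  } else {
    p_perm <- pbeta(max(p_obs, 1e-300), ab[1], ab[2])
    shape1 <- ab[1]; shape2 <- ab[2]; ok <- TRUE
  }
  fa <- .fast_assoc(gd$y, gd$G[, lead, drop = FALSE])
  data.frame(gene = gene, condition = condition,
             lead_snp = gd$snp$snp_id[lead],
             beta = fa$beta[1], se = fa$se[1], p_nominal = p_obs,
             n_cis = ncol(gd$G), p_perm = max(p_perm, .Machine$double.xmin),
             p_empirical = p_emp, shape1 = shape1, shape2 = shape2,
             n_perm = total, beta_ok = ok, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Permutation pass over many genes and conditions
#'
#' Runs [permutation_pass()] for every requested (gene, condition) pair
#' with a deterministic per-pair seed stream derived from `seed`
#' (permutations are independent across conditions and genes).
#'
#' @inheritParams permutation_pass
#' @param conditions Conditions to scan (default all seven).
#' @param genes Genes to scan (default all in the probe map).
#' @return data.frame with one row per (gene, condition) that had a
#'   testable cis SNP (columns as in [permutation_pass()]).
#' @export
map_egenes <- function(expr, gt, conditions = reqtl_conditions(),
                       genes = NULL, window_bp = 1e6, n_min = 100,
                       n_max = 1000, adaptive = TRUE, min_n = 10,
                       seed = 1) {
  .check_condition(conditions)
  if (is.null(genes)) genes <- expr$probe_map$gene
  out <- vector("list", length(conditions) * length(genes))
  k <- 0L
  for (ci in seq_along(conditions)) {
    for (gi in seq_along(genes)) {
      k <- k + 1L
      out[[k]] <- permutation_pass(
        expr, gt, genes[gi], conditions[ci], window_bp = window_bp,
        n_min = n_min, n_max = n_max, adaptive = adaptive, min_n = min_n,
        seed = .pass_seed(seed, ci, gi))
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# deterministic sub-seed per (condition, gene) pass, kept below 2^31
.pass_seed <- function(seed, cond_idx, gene_idx) {
  as.integer((as.numeric(seed) * 48271 + cond_idx * 1299709 +
                gene_idx * 7919) %% 2147483647)
}

#' Call eGenes at a given FDR
#'
#' Benjamini-Hochberg step-up over beta-approximated permutation p-values,
#' applied within each condition separately.
#'
#' @param egenes data.frame from [map_egenes()] (one row per gene and
#'   condition).
#' @param fdr FDR threshold (default 0.05).
#' @return The input with a `q` column added, restricted to rows with
#'   `q < fdr`.  The full adjusted table is attached as attribute
#'   `"all_tests"`.
#' @export
call_egenes <- function(egenes, fdr = 0.05) {
  stopifnot(is.data.frame(egenes), all(c("p_perm", "condition") %in%
                                         names(egenes)))
  q <- rep(NA_real_, nrow(egenes))
  for (cn in unique(egenes$condition)) {
    i <- egenes$condition == cn
    q[i] <- p.adjust(egenes$p_perm[i], method = "BH")
  }
  egenes$q <- q
  sig <- egenes[!is.na(q) & q < fdr, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all_tests") <- egenes
  sig
}
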