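# Replication statistics (Storey's pi1, nominal replication), GWAS-catalog
# LD overlap, relaxed reQTL/ceQTL set construction, and stratified Q-Q
# enrichment curves.

#' Storey's pi1 replication estimate
#'
#' Estimates pi0, the proportion of truly null tests, from the p-value
#' distribution: `pi0(lambda) = #[p > lambda] / ((1 - lambda) * m)`,
#' clipped to \[0, 1\]; replication is reported as `pi1 = 1 - pi0`.  The
#' default uses the single estimator at `lambda = 0.5`.  With
#' `smooth = TRUE`, pi0 is evaluated on the grid
#' `lambda = 0.05, 0.10, ..., 0.95` and a cubic smoothing spline through
#' `pi0(lambda)` is evaluated at the largest lambda, as in the
#' qvalue-package smoother.
#'
#' @param pvals Vector of p-values in (0, 1]; at least 10 required.
#' @param lambda Tuning parameter in (0, 1) for the single-lambda
#'   estimator (default 0.5).
#' @param smooth Use the grid-and-smoother variant instead.
#' @return list of class `replication_result`: `pi0`, `pi1`, `lambda`,
#'   `m`, `nominal_rate` (fraction of p < 0.05).
#' @examples
#' storey_pi1(runif(1000))$pi1  # ~0 for uniform p
#' @export
storey_pi1 <- function(pvals, lambda = 0.5, smooth = FALSE) {
  pvals <- pvals[!is.na(pvals)]
  m <- length(pvals)
  if (m < 10) stop("at least 10 p-values required")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (smooth) {
    grid <- seq(0.05, 0.95, by = 0.05)
    pi0g <- vapply(grid, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- smooth.spline(grid, pi0g, df = 3)
    pi0 <- predict(fit, x = max(grid))$y
    lambda <- max(grid)
  } else {
    stopifnot(lambda > 0, lambda < 1)
    pi0 <- mean(pvals > lambda) / (1 - lambda)
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda, m = m,
                 nominal_rate = mean(pvals < 0.05)),
            class = "replication_result")
}

#' Nominal replication rate
#'
#' Fraction of p-values below `alpha` (default 0.05); used when the
#' replication panel is too small for a stable pi0 estimate.
#'
#' @param pvals Vector of p-values.
#' @param alpha Nominal cutoff.
#' @return Fraction in \[0, 1\].
#' @export
nominal_replication_rate <- function(pvals, alpha = 0.05) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values supplied")
  mean(pvals < alpha)
}

#' LD overlap between lead eSNPs and GWAS-catalog associations
#'
#' A catalog association coincides with a lead eSNP when the catalog SNP's
#' genotype r-squared with the lead exceeds `r2_threshold`.  Catalog SNPs
#' are matched into the genotype matrix by identifier first, then by
#' (chrom, pos) when those columns are present; unresolvable rows are
#' skipped and counted.  When `baseline_stats` is given (a data.frame with
#' `gene` and nominal baseline `p`), each record is flagged
#' `baseline_absent` when the lead's baseline association p exceeds 0.01,
#' marking eQTLs only visible under stimulation.
#'
#' @param leads data.frame with `gene` and `snp_id` (lead eSNP per gene).
#' @param catalog data.frame with `trait`, `snp_id`, `p` (e.g. from
#'   [simulate_gwas_catalog()]); optionally `chrom`, `pos`.
#' @param gt A `reqtl_genotypes` object.
#' @param r2_threshold LD threshold (default 0.8).
#' @param baseline_stats Optional data.frame with `gene` and baseline `p`.
#' @param baseline_p_absent Cutoff above which the baseline eQTL counts as
#'   absent (default 0.01).
#' @return data.frame with one row per overlapping (lead, catalog) pair:
#'   `gene`, `lead_snp`, `gwas_snp`, `trait`, `r2`, `baseline_absent`.
#'   Unresolvable catalog rows are counted in attribute `"n_unresolved"`.
#' @export
gwas_ld_overlap <- function(leads, catalog, gt, r2_threshold = 0.8,
                            baseline_stats = NULL,
                            baseline_p_absent = 0.01) {
  snps <- gt$snps
  ci <- match(catalog$snp_id, snps$snp_id)
  if (anyNA(ci) && all(c("chrom", "pos") %in% names(catalog))) {
    miss <- which(is.na(ci))
    ci[miss] <- match(paste(catalog$chrom[miss], catalog$pos[miss]),
                      paste(snps$chrom, snps$pos))
  }
  n_unres <- sum(is.na(ci))
  rows <- list()
  for (k in seq_len(nrow(leads))) {
    li <- match(leads$snp_id[k], snps$snp_id)
    if (is.na(li)) next
    for (r in which(!is.na(ci))) {
      j <- ci[r]
      if (snps$chrom[j] != snps$chrom[li]) next
      r2 <- if (j == li) 1 else ld_r2(gt$dosages[, li], gt$dosages[, j])
      if (!is.na(r2) && r2 > r2_threshold) {
        absent <- NA
        if (!is.null(baseline_stats)) {
          ib <- match(leads$gene[k], baseline_stats$gene)
          if (!is.na(ib)) absent <- baseline_stats$p[ib] > baseline_p_absent
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = leads$gene[k], lead_snp = leads$snp_id[k],
          gwas_snp = catalog$snp_id[r], trait = catalog$trait[r],
          r2 = r2, baseline_absent = absent, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), lead_snp = character(),
               gwas_snp = character(), trait = character(), r2 = numeric(),
               baseline_absent = logical(), stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- n_unres
  out
}

#' Relaxed reQTL and ceQTL sets for enrichment analyses
#'
#' The relaxed reQTL set takes all slope-comparison tests significant after
#' Benjamini-Hochberg FDR 5% (instead of Bonferroni); the relaxed ceQTL set
#' takes baseline eGenes whose six stimulated-vs-baseline comparisons all
#' have nominal p above 0.005 (instead of 0.05).
#'
#' @param reqtl_tests Full test table from [call_reqtls()] (any
#'   correction; the BH adjustment is recomputed here).
#' @param ceqtl_table Output of [call_ceqtls()] run with
#'   `p_floor = 0.005`, or the raw table whose `p_min` column is compared
#'   against the relaxed floor.
#' @param fdr BH threshold for the reQTL set (default 0.05).
#' @param p_floor Relaxed ceQTL floor (default 0.005).
#' @return list with `reqtl_set` (data.frame of gene/condition rows) and
#'   `ceqtl_set` (character vector of genes).
#' @export
relaxed_sets <- function(reqtl_tests, ceqtl_table, fdr = 0.05,
                         p_floor = 0.005) {
  q <- p.adjust(reqtl_tests$p_beta, method = "BH")
  reqtl_set <- reqtl_tests[!is.na(q) & q < fdr, , drop = FALSE]
  rownames(reqtl_set) <- NULL
  ceqtl_set <- ceqtl_table$gene[!is.na(ceqtl_table$p_min) &
                                  ceqtl_table$p_min > p_floor]
  list(reqtl_set = reqtl_set, ceqtl_set = ceqtl_set)
}

#' Stratified Q-Q enrichment curves
#'
#' For each annotated SNP set, the observed GWAS p-values of the set's
#' members are ranked and paired with uniform expected quantiles
#' `(i - 0.5) / n`, both on the -log10 scale.  The returned table is the
#' Q-Q curve; an enriched set runs above the diagonal.
#'
#' @param gwas_pvals Named numeric vector of GWAS p-values (names are SNP
#'   ids).
#' @param annotated_sets Named list of SNP-id sets.
#' @param p_input_cut Optional cutoff: only associations with
#'   `p < p_input_cut` enter the curves.
#' @return data.frame with `set`, `rank`, `expected`, `observed`
#'   (-log10 scales).  Sets with no member among `gwas_pvals` are skipped
#'   with a message.
#' @export
qq_enrichment <- function(gwas_pvals, annotated_sets, p_input_cut = NULL) {
  if (!is.null(p_input_cut))
    gwas_pvals <- gwas_pvals[gwas_pvals < p_input_cut]
  out <- list()
  for (nm in names(annotated_sets)) {
    p <- gwas_pvals[intersect(names(gwas_pvals), annotated_sets[[nm]])]
    if (!length(p)) {
      message("qq_enrichment: set '", nm, "' has no scored member; skipped")
      next
    }
    p <- sort(unname(p))
    n <- length(p)
    out[[nm]] <- data.frame(set = nm, rank = seq_len(n),
                            expected = -log10((seq_len(n) - 0.5) / n),
                            observed = -log10(p), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(set = character(), rank = integer(),
                      expected = numeric(), observed = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
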