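# LD utilities, per-locus selection-score statistics, the MAF/LD-matched
# resampling null with permutation p-values, and the derived-allele
# response-direction analysis.

#' Genotype LD as squared Pearson correlation
#'
#' r-squared between two dosage vectors on pairwise-complete observations.
#' LD is computed on unphased dosages, not haplotypes; under
#' Hardy-Weinberg the difference from haplotype r-squared is negligible.
#'
#' @param g1,g2 Numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA` when either vector is constant
#'   after pairwise-complete filtering.
#' @examples
#' ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 0, 1))  # 0
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  use <- !is.na(g1) & !is.na(g2)
  if (sum(use) < 2) stop("fewer than 2 pairwise-complete observations")
  g1 <- g1[use]; g2 <- g2[use]
  if (var(g1) == 0 || var(g2) == 0) return(NA_real_)
  cor(g1, g2)^2
}

#' Configuration of the MAF/LD-matched resampling null
#'
#' @param maf_bin_width MAF bin width (default 0.05).
#' @param ld_count_breaks Upper bounds of the LD-proxy-count bins; the
#'   default partitions counts into 0-2, 3-5, 6-10, 11-20, 21-50 and >50.
#' @param n_resamples Number of matched resamples (default 10000).
#' @param r2_threshold LD threshold defining proxies (default 0.8).
#' @param ihs_high_cut |iHS| cutoff defining a high score (default 1.5).
#' @param seed Integer seed for resampling.
#' @return A list of class `null_resample_config`.
#' @export
null_resample_config <- function(maf_bin_width = 0.05,
                                 ld_count_breaks = c(2, 5, 10, 20, 50, Inf),
                                 n_resamples = 10000,
                                 r2_threshold = 0.8,
                                 ihs_high_cut = 1.5,
                                 seed = 1) {
  stopifnot(maf_bin_width > 0, n_resamples >= 1,
            all(diff(ld_count_breaks) > 0))
  structure(list(maf_bin_width = maf_bin_width,
                 ld_count_breaks = ld_count_breaks,
                 n_resamples = n_resamples, r2_threshold = r2_threshold,
                 ihs_high_cut = ihs_high_cut, seed = seed),
            class = "null_resample_config")
}

.maf_bin <- function(maf, width) pmax(ceiling(maf / width), 1L)

.ld_bin <- function(count, breaks) findInterval(count, c(0, breaks[-length(breaks)] + 1))

#' Per-locus selection-score statistic
#'
#' For a lead SNP, the proxy set is the lead plus every SNP whose genotype
#' r-squared with it exceeds `cfg$r2_threshold` (within `max_dist_bp` on
#' the same chromosome).  The locus statistic is the maximum |iHS| and
#' |SDS| over non-missing scores in the proxy set; the locus is also
#' assigned a MAF bin (from the lead's MAF) and an LD bin (from the proxy
#' count).
#'
#' @param lead Lead SNP id.
#' @param gt A `reqtl_genotypes` object.
#' @param scores Score table (`snp_id`, `ihs`, `sds`), e.g. from
#'   [simulate_selection_scores()].
#' @param cfg A [null_resample_config()].
#' @param max_dist_bp Maximum distance at which proxies are sought
#'   (default 1 Mb).
#' @return One-row data.frame: `lead_snp`, `proxy_count`, `max_abs_ihs`,
#'   `max_abs_sds`, `maf`, `maf_bin`, `ld_bin` (score maxima are `NA` when
#'   all proxies lack that score).
#' @export
locus_score <- function(lead, gt, scores, cfg = null_resample_config(),
                        max_dist_bp = 1e6) {
  i <- match(lead, gt$snps$snp_id)
  if (is.na(i)) stop("unknown lead SNP: ", lead)
  snps <- gt$snps
  near <- which(snps$chrom == snps$chrom[i] &
                  abs(snps$pos - snps$pos[i]) <= max_dist_bp)
  near <- setdiff(near, i)
  r2 <- vapply(near, function(j) ld_r2(gt$dosages[, i], gt$dosages[, j]),
               numeric(1))
  proxies <- c(i, near[!is.na(r2) & r2 > cfg$r2_threshold])
  sc <- scores[match(snps$snp_id[proxies], scores$snp_id), , drop = FALSE]
  max_abs <- function(x) if (all(is.na(x))) NA_real_ else max(abs(x), na.rm = TRUE)
  data.frame(lead_snp = lead, proxy_count = length(proxies),
             max_abs_ihs = max_abs(sc$ihs), max_abs_sds = max_abs(sc$sds),
             maf = snps$maf[i],
             maf_bin = .maf_bin(snps$maf[i], cfg$maf_bin_width),
             ld_bin = .ld_bin(length(proxies), cfg$ld_count_breaks),
             stringsAsFactors = FALSE)
}

#' Locus scores for a set of lead SNPs
#'
#' @param leads Character vector of lead SNP ids.
#' @inheritParams locus_score
#' @return data.frame with one row per lead (see [locus_score()]).
#' @export
locus_score_table <- function(leads, gt, scores,
                              cfg = null_resample_config(),
                              max_dist_bp = 1e6) {
  out <- do.call(rbind, lapply(leads, locus_score, gt = gt,
                               scores = scores, cfg = cfg,
                               max_dist_bp = max_dist_bp))
  rownames(out) <- NULL
  out
}

#' MAF/LD-matched resampling test for selection enrichment
#'
#' Compares a summary statistic of the target loci -- the proportion with
#' |iHS| above `cfg$ihs_high_cut`, or the median of maximum |SDS| -- with
#' its distribution over `cfg$n_resamples` random sets drawn from `pool`.
#' Each resample draws, for every target locus, one pool locus uniformly
#' from the same (MAF bin, LD bin) cell, with replacement, so the matched
#' bin multiset of every resample equals the target's exactly.  The
#' permutation p-value is `(1 + #[null >= observed]) / (n_resamples + 1)`,
#' never zero.
#'
#' @param target,pool Locus-score tables from [locus_score_table()]; every
#'   target (MAF, LD) cell must be represented in the pool.
#' @param statistic `"proportion_high_ihs"` or `"median_abs_sds"`.
#' @param cfg A [null_resample_config()]; `cfg$seed` makes resampling
#'   deterministic.
#' @param keep_draws Also return the resamples x targets matrix of drawn
#'   scores plus the matched cell of each target column (for auditing the
#'   bin-matching invariant).
#' @return list with `observed`, `null_min`, `null_max`, `null_mean`,
#'   `perm_p`, `n_resamples`, the vector of `null` statistics, and (with
#'   `keep_draws`) `draws` and `target_cells`.
#' @export
matched_resample_test <- function(target, pool,
                                  statistic = c("proportion_high_ihs",
                                                "median_abs_sds"),
                                  cfg = null_resample_config(),
                                  keep_draws = FALSE) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "proportion_high_ihs") "max_abs_ihs" else "max_abs_sds"
  tgt <- target[!is.na(target[[col]]), , drop = FALSE]
  if (!nrow(tgt)) stop("no target locus has a non-missing score")
  n_dropped <- nrow(target) - nrow(tgt)
  pl <- pool[!is.na(pool[[col]]), , drop = FALSE]
  key <- function(d) paste(d$maf_bin, d$ld_bin, sep = ":")
  pool_cells <- split(pl[[col]], key(pl))
  tkey <- key(tgt)
  missing_cells <- setdiff(unique(tkey), names(pool_cells))
  if (length(missing_cells))
    stop("pool has no locus in matched cell(s) (maf_bin:ld_bin) ",
         paste(missing_cells, collapse = ", "))
  stat_fun <- if (statistic == "proportion_high_ihs")
    function(x) mean(x > cfg$ihs_high_cut) else function(x) median(x)
  observed <- stat_fun(tgt[[col]])
  set.seed(cfg$seed)
  B <- cfg$n_resamples
  draws <- matrix(NA_real_, B, nrow(tgt))
  for (k in seq_len(nrow(tgt))) {
    cell <- pool_cells[[tkey[k]]]
    draws[, k] <- if (length(cell) == 1) rep(cell, B) else
      cell[sample.int(length(cell), B, replace = TRUE)]
  }
  null <- if (statistic == "proportion_high_ihs")
    rowMeans(draws > cfg$ihs_high_cut) else apply(draws, 1, median)
  out <- list(observed = observed, null_min = min(null),
              null_max = max(null), null_mean = mean(null),
              perm_p = (1 + sum(null >= observed)) / (B + 1),
              n_resamples = B, n_target = nrow(tgt),
              n_dropped_missing = n_dropped, null = null)
  if (keep_draws) {
    out$draws <- draws
    out$target_cells <- tkey
  }
  out
}

#' Derived-allele direction of reQTL response effects
#'
#' Orients each reQTL's slopes so that they count copies of the derived
#' (non-ancestral) allele, then compares the sign of the response effect
#' `delta_beta = beta_stim - beta_baseline` (derived-oriented) with the
#' population response direction `d` -- the sign of the gene's expression
#' change under the reQTL's condition.  The derived allele has *increasing*
#' activity when the signs agree (it amplifies the induction, or amplifies
#' the suppression, of the gene) and *decreasing* activity when they
#' oppose.  Records with an unknown ancestral allele or `d = 0` are
#' `unclassifiable`.
#'
#' @param reqtls Output of [call_reqtls()] (significant rows are used).
#' @param gt A `reqtl_genotypes` object (supplies ancestral alleles; the
#'   dosage coding counts the alternate allele).
#' @param de_early Named list (by treatment) of
#'   [differential_expression()] tables for the stimulated-vs-baseline
#'   contrast at 90 min.
#' @param de_late Same at 6 h (vs baseline).
#' @param restrict_significant_de If `TRUE`, only genes with significant DE
#'   (`de_p`) contribute a direction; default `FALSE` (the log fold change
#'   is used regardless of significance).
#' @param de_p DE cutoff used when `restrict_significant_de = TRUE`.
#' @return data.frame with one row per significant reQTL: `gene`,
#'   `condition`, `lead_snp`, `delta_beta` (derived-oriented),
#'   `response_direction` and `direction`
#'   (`increasing` / `decreasing` / `unclassifiable`).
#' @export
derived_direction <- function(reqtls, gt, de_early, de_late,
                              restrict_significant_de = FALSE,
                              de_p = 0.01) {
  rq <- reqtls[reqtls$significant, , drop = FALSE]
  if (!nrow(rq)) stop("no significant reQTLs")
  snps <- gt$snps
  rows <- lapply(seq_len(nrow(rq)), function(k) {
    i <- match(rq$lead_snp[k], snps$snp_id)
    anc <- snps$ancestral[i]
    flip <- if (is.na(anc)) NA else
      if (anc == snps$alt[i]) TRUE else if (anc == snps$ref[i]) FALSE else NA
    trt <- condition_treatment(rq$condition[k])
    tp <- condition_timepoint(rq$condition[k])
    de <- if (tp == "90") de_early[[trt]] else de_late[[trt]]
    ide <- match(rq$gene[k], de$gene)
    lfc <- if (is.na(ide)) NA_real_ else de$log2fc[ide]
    if (restrict_significant_de && !is.na(ide) && de$p[ide] >= de_p)
      lfc <- 0
    dbeta <- rq$beta_stim[k] - rq$beta_baseline[k]
    if (isTRUE(flip)) dbeta <- -dbeta
    d <- if (is.na(lfc)) 0 else sign(lfc)
    dir <- if (is.na(flip) || d == 0 || dbeta == 0) "unclassifiable" else
      if (sign(dbeta) == d) "increasing" else "decreasing"
    data.frame(gene = rq$gene[k], condition = rq$condition[k],
               lead_snp = rq$lead_snp[k],
               delta_beta = if (is.na(flip)) NA_real_ else dbeta,
               response_direction = d, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial test for excess of increasing-activity reQTLs
#'
#' One-sided exact binomial test of the number of `increasing` records
#' among all classifiable records, against a null proportion of 0.5.
#'
#' @param records Output of [derived_direction()].
#' @return list with `n_increasing`, `n_decreasing`, `p`.
#' @export
direction_binomial <- function(records) {
  n_inc <- sum(records$direction == "increasing")
  n_dec <- sum(records$direction == "decreasing")
  if (n_inc + n_dec == 0) stop("no classifiable direction records")
  list(n_increasing = n_inc, n_decreasing = n_dec,
       p = binom.test(n_inc, n_inc + n_dec, 0.5,
                      alternative = "greater")$p.value)
}
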