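# Synthetic cohort generators: genotypes in LD blocks, seven-condition
# expression with planted eQTL/reQTL architectures, selection-score tables,
# and a toy GWAS catalog.  All generators are deterministic given `seed`.

.architectures <- c("constant",
                    "active-transient", "active-late", "active-prolonged",
                    "suppressive-transient", "suppressive-late",
                    "suppressive-prolonged")

#' Planted effect architectures
#'
#' @return Character vector of the recognized eQTL/reQTL architectures:
#'   `constant` plus the six response classes (active/suppressive crossed
#'   with transient/late/prolonged).
#' @export
effect_architectures <- function() .architectures

# Solve the per-haplotype copy-error rate e such that two SNPs generated by
# copying a founder allele (frequency f) with independent symmetric errors
# have pairwise genotype correlation sqrt(r2), while each SNP's realized
# allele frequency equals `maf`.  f is then (maf - e) / (1 - 2e).
.solve_copy_error <- function(maf, r2) {
  if (r2 >= 1 - 1e-12) return(0)
  target <- sqrt(r2)
  corr_at <- function(e) {
    f <- (maf - e) / (1 - 2 * e)
    co <- f * (1 - e)^2 + (1 - f) * e^2 - maf^2
    co / (maf * (1 - maf))
  }
  if (r2 <= 1e-12) return(maf) # f -> 0, SNPs independent of founder
  uniroot(function(e) corr_at(e) - target,
          lower = 1e-9, upper = maf - 1e-9, tol = 1e-12)$root
}

#' Simulate genotypes in LD blocks
#'
#' Generates hard-call dosages (0/1/2, counting the alternate allele) for
#' diploid samples.  SNPs are organized into independent LD blocks; within a
#' block every haplotype is a copy of a block founder haplotype with a
#' per-SNP error rate tuned so the expected pairwise genotype r-squared
#' equals `within_block_r2`.  Haplotypes are drawn independently per sample,
#' so genotypes are in Hardy-Weinberg equilibrium at the realized allele
#' frequency.  Each block is placed on one chromosome with a large gap
#' (`block_spacing_bp`) to the next, so a 1 Mb cis window never spans two
#' blocks.
#'
#' The ancestral allele of each SNP is the major allele with probability
#' `ancestral_major_prob`, the minor allele otherwise, and missing with
#' probability `ancestral_missing_prob` (applied first).
#'
#' @param n_samples Number of diploid samples (>= 2).
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block SNPs per block.
#' @param maf_range Interval within (0, 0.5] from which each block's target
#'   minor allele frequency is drawn uniformly.
#' @param within_block_r2 Expected pairwise genotype r-squared within a
#'   block, in \[0, 1\].
#' @param missing_rate Fraction of dosage entries set to `NA` at random.
#' @param ancestral_major_prob Probability that the ancestral allele is the
#'   major allele.
#' @param ancestral_missing_prob Probability that the ancestral state is
#'   unknown (recorded as `NA`).
#' @param block_spacing_bp Distance between the first SNPs of consecutive
#'   blocks (default 3 Mb, keeping blocks more than 1 Mb apart).
#' @param snp_spacing_bp Distance between consecutive SNPs within a block.
#' @param chrom Chromosome label used for all blocks.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `reqtl_genotypes`: a list with `dosages`
#'   (samples x SNPs matrix), `snps` (per-SNP metadata data.frame with
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`, `ancestral`, `maf`, `block`)
#'   and `samples`.
#' @examples
#' gt <- simulate_genotypes(50, 4, 3, seed = 1)
#' dim(gt$dosages)
#' @export
simulate_genotypes <- function(n_samples, n_blocks, snps_per_block,
                               maf_range = c(0.05, 0.5),
                               within_block_r2 = 0.8,
                               missing_rate = 0,
                               ancestral_major_prob = 0.8,
                               ancestral_missing_prob = 0,
                               block_spacing_bp = 3e6,
                               snp_spacing_bp = 1000,
                               chrom = "chr1",
                               seed = NULL) {
  if (n_samples < 2 || n_blocks < 1 || snps_per_block < 1)
    stop("n_samples, n_blocks and snps_per_block must be positive (n_samples >= 2)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (within_block_r2 < 0 || within_block_r2 > 1)
    stop("within_block_r2 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  n_snps <- n_blocks * snps_per_block
  samples <- sprintf("S%04d", seq_len(n_samples))
  dos <- matrix(NA_real_, n_samples, n_snps)
  pos <- integer(n_snps)
  block <- rep(seq_len(n_blocks), each = snps_per_block)
  bases <- c("A", "C", "G", "T")

  for (b in seq_len(n_blocks)) {
    maf <- runif(1, maf_range[1], maf_range[2])
    e <- .solve_copy_error(maf, within_block_r2)
    f <- if (e >= maf) 0 else (maf - e) / (1 - 2 * e)
    idx <- which(block == b)
    # founder allele per haplotype (2 per sample), then per-SNP copy errors
    hap1 <- rbinom(n_samples, 1, f)
    hap2 <- rbinom(n_samples, 1, f)
    for (j in idx) {
      if (e > 0) {
        a1 <- abs(hap1 - rbinom(n_samples, 1, e))
        a2 <- abs(hap2 - rbinom(n_samples, 1, e))
      } else {
        a1 <- hap1; a2 <- hap2
      }
      dos[, j] <- a1 + a2
      pos[j] <- (b - 1L) * as.integer(block_spacing_bp) +
        (j - idx[1]) * as.integer(snp_spacing_bp) + 1L
    }
  }

  # random allele relabeling: with prob 1/2 the alternate allele is the
  # founder-minor allele's complement, i.e. dosage flips to 2 - d
  flip <- runif(n_snps) < 0.5
  dos[, flip] <- 2 - dos[, flip]

  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  alt_freq <- colMeans(dos) / 2
  maf_emp <- pmin(alt_freq, 1 - alt_freq)

  major_is_alt <- alt_freq > 0.5
  anc_major <- runif(n_snps) < ancestral_major_prob
  ancestral <- ifelse(xor(major_is_alt, !anc_major), alt, ref)
  ancestral[runif(n_snps) < ancestral_missing_prob] <- NA_character_

  if (missing_rate > 0) {
    miss <- runif(length(dos)) < missing_rate
    dos[miss] <- NA_real_
  }

  snp_id <- sprintf("snp%06d", seq_len(n_snps))
  dimnames(dos) <- list(samples, snp_id)
  snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, ancestral = ancestral,
                     maf = maf_emp, block = block,
                     stringsAsFactors = FALSE)
  structure(list(dosages = dos, snps = snps, samples = samples),
            class = "reqtl_genotypes")
}

#' @export
print.reqtl_genotypes <- function(x, ...) {
  cat("reqtl_genotypes:", length(x$samples), "samples x",
      nrow(x$snps), "SNPs in", length(unique(x$snps$block)), "LD block(s)\n")
  invisible(x)
}

# slopes for the seven conditions implied by one planted effect
.architecture_betas <- function(architecture, beta, treatments) {
  base <- switch(architecture,
                 "constant" = beta,
                 "active-transient" = 0, "active-late" = 0,
                 "active-prolonged" = 0,
                 "suppressive-transient" = beta, "suppressive-late" = beta,
                 "suppressive-prolonged" = beta,
                 stop("unknown architecture: ", architecture))
  out <- setNames(rep(base, 7), .conditions)
  if (architecture == "constant") return(out)
  for (t in treatments) {
    tp <- switch(architecture,
                 "active-transient"      = c(beta, 0),
                 "active-late"           = c(0, beta),
                 "active-prolonged"      = c(beta, beta),
                 "suppressive-transient" = c(0, beta),
                 "suppressive-late"      = c(beta, 0),
                 "suppressive-prolonged" = c(0, 0))
    out[condition_name(t, "90")] <- tp[1]
    out[condition_name(t, "6h")] <- tp[2]
  }
  out
}

# condition-wise mean shifts implementing congruent or divergent
# differential expression for one planted effect
.de_shifts <- function(architecture, de_pattern, shift, treatments) {
  out <- setNames(rep(0, 7), .conditions)
  if (architecture == "constant" || de_pattern == "none") return(out)
  class <- sub("^(active|suppressive)-", "", architecture)
  prof <- switch(de_pattern,
    congruent = switch(class, transient = c(shift, 0), late = c(0, shift),
                       prolonged = c(shift, shift)),
    divergent = switch(class, transient = c(0, shift), late = c(shift, shift),
                       prolonged = c(0, shift)),
    stop("unknown de_pattern: ", de_pattern))
  for (t in treatments) {
    out[condition_name(t, "90")] <- prof[1]
    out[condition_name(t, "6h")] <- prof[2]
  }
  out
}

#' Simulate seven-condition expression with planted eQTL effects
#'
#' Expression of gene g in condition c for sample i is
#' `intercept + beta[g, c] * (dosage[i] - mean(dosage)) + de_shift[g, c] +
#' N(0, noise_sd)`: the genetic term uses mean-centered dosage, so planted
#' slopes never move condition means and the planted
#' differential-expression profiles are exactly the `de_shift` values.
#' The per-condition slopes `beta[g, c]` are implied by each planted
#' effect's architecture and the mean shifts `de_shift[g, c]` by its
#' differential-expression pattern.  Genes without a planted effect are pure
#' noise around `intercept`.  Values are on a log2-like scale, so a mean
#' shift is a log fold change.
#'
#' Architectures (for a response effect with slope `beta` under treatment T):
#' active effects have slope 0 at baseline and `beta` at the time points
#' where they are on (transient: 90 min only; late: 6 h only; prolonged:
#' both); suppressive effects have slope `beta` at baseline (and in all
#' untargeted conditions) and lose it at the corresponding time points
#' (transient: off at 90 min, back at 6 h; late: off at 6 h; prolonged: off
#' at both).  `constant` plants the same slope in all seven conditions.
#'
#' A `congruent` DE pattern shifts the gene's mean with the same temporal
#' profile as the effect (up at 90 min for transient, at 6 h for late, at
#' both for prolonged, by `de_shift_size` log units); `divergent` plants a
#' mismatched profile; `none` plants no shift.
#'
#' @param gt A `reqtl_genotypes` object.
#' @param effects A data.frame with one row per planted effect and columns
#'   `gene`, `snp_id`, `architecture` (see [effect_architectures()]),
#'   `beta`, `treatment` (one of `LPS`/`RNA`/`MDP` or `"all"`; ignored for
#'   `constant`), `de_pattern` (`congruent`/`divergent`/`none`).  May have
#'   zero rows.
#' @param n_null_genes Number of additional pure-noise genes.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param intercept Baseline mean expression.
#' @param de_shift_size Mean shift (log units) used for planted DE
#'   patterns.  The default 1.5 clears a log2 fold-change threshold of 1 at
#'   the default noise level.
#' @param seed Integer seed.
#' @return An object of class `cond_expression`: list with `values` (named
#'   list, one samples x probes matrix per condition), `probe_map`
#'   (data.frame `probe`, `gene`, `chrom`, `anchor_pos`), and `samples`.
#'   The generating truth (per-gene condition slopes and shifts) is
#'   attached as attribute `"truth"`.
#' @examples
#' gt <- simulate_genotypes(60, 3, 3, seed = 1)
#' eff <- data.frame(gene = "g1", snp_id = gt$snps$snp_id[2],
#'                   architecture = "active-transient", beta = 1,
#'                   treatment = "LPS", de_pattern = "congruent")
#' ex <- simulate_expression(gt, eff, n_null_genes = 2, seed = 2)
#' names(ex$values)
#' @export
simulate_expression <- function(gt, effects, n_null_genes = 0, noise_sd = 1,
                                intercept = 5, de_shift_size = 1.5,
                                seed = NULL) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(effects)) effects <- data.frame()
  if (nrow(effects)) {
    need <- c("gene", "snp_id", "architecture", "beta", "de_pattern")
    miss <- setdiff(need, names(effects))
    if (length(miss)) stop("effects lacks column(s): ", paste(miss, collapse = ", "))
    if (is.null(effects$treatment)) effects$treatment <- "all"
    unknown <- setdiff(effects$snp_id, gt$snps$snp_id)
    if (length(unknown)) stop("effects reference unknown SNP(s): ",
                              paste(unknown, collapse = ", "))
    bad <- setdiff(effects$architecture, .architectures)
    if (length(bad)) stop("unknown architecture(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(effects$gene)) stop("one planted effect per gene, please")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- length(gt$samples)
  eff_genes <- if (nrow(effects)) effects$gene else character(0)
  null_genes <- if (n_null_genes > 0) sprintf("nullgene%04d", seq_len(n_null_genes)) else character(0)
  genes <- c(eff_genes, null_genes)
  G <- length(genes)
  if (G == 0) stop("no genes: supply effects and/or n_null_genes > 0")

  beta_mat <- matrix(0, 7, G, dimnames = list(.conditions, genes))
  shift_mat <- matrix(0, 7, G, dimnames = list(.conditions, genes))
  gene_snp <- setNames(rep(NA_character_, G), genes)
  if (nrow(effects)) {
    for (k in seq_len(nrow(effects))) {
      trt <- effects$treatment[k]
      trts <- if (identical(trt, "all") || is.na(trt)) .treatments else
        strsplit(trt, ",", fixed = TRUE)[[1]]
      g <- effects$gene[k]
      beta_mat[, g] <- .architecture_betas(effects$architecture[k],
                                           effects$beta[k], trts)
      shift_mat[, g] <- .de_shifts(effects$architecture[k],
                                   effects$de_pattern[k], de_shift_size, trts)
      gene_snp[g] <- effects$snp_id[k]
    }
  }

  # anchor effect genes at their SNP; null genes cycle through block centers
  snps <- gt$snps
  anchor_pos <- integer(G); anchor_chr <- character(G)
  blocks <- unique(snps$block)
  centers <- vapply(blocks, function(b) {
    i <- which(snps$block == b); i[ceiling(length(i) / 2)]
  }, integer(1))
  nb <- 0L
  for (j in seq_len(G)) {
    if (!is.na(gene_snp[j])) {
      i <- match(gene_snp[j], snps$snp_id)
    } else {
      nb <- nb + 1L
      i <- centers[((nb - 1L) %% length(centers)) + 1L]
    }
    anchor_pos[j] <- snps$pos[i]; anchor_chr[j] <- snps$chrom[i]
  }

  dose_imp <- gt$dosages
  if (anyNA(dose_imp)) {
    for (j in which(colSums(is.na(dose_imp)) > 0)) {
      v <- dose_imp[, j]; v[is.na(v)] <- mean(v, na.rm = TRUE); dose_imp[, j] <- v
    }
  }
  # center the genetic term so planted slopes leave condition means -- and
  # hence the planted differential-expression profiles -- untouched
  dose_imp <- sweep(dose_imp, 2, colMeans(dose_imp))

  values <- vector("list", 7); names(values) <- .conditions
  for (cn in .conditions) {
    m <- matrix(rnorm(n * G, 0, noise_sd), n, G,
                dimnames = list(gt$samples, genes))
    m <- m + intercept
    m <- sweep(m, 2, shift_mat[cn, ], "+")
    has_b <- which(beta_mat[cn, ] != 0)
    for (j in has_b)
      m[, j] <- m[, j] + beta_mat[cn, j] * dose_imp[, gene_snp[genes[j]]]
    values[[cn]] <- m
  }

  probe_map <- data.frame(probe = genes, gene = genes, chrom = anchor_chr,
                          anchor_pos = anchor_pos, stringsAsFactors = FALSE)
  out <- structure(list(values = values, probe_map = probe_map,
                        samples = gt$samples),
                   class = "cond_expression")
  attr(out, "truth") <- list(effects = effects, beta = beta_mat,
                             shift = shift_mat, gene_snp = gene_snp)
  out
}

#' @export
print.cond_expression <- function(x, ...) {
  cat("cond_expression:", length(x$samples), "samples x",
      nrow(x$probe_map), "probes in", length(x$values), "conditions\n")
  invisible(x)
}

#' Simulate a per-SNP selection-score table (iHS, SDS)
#'
#' Background scores are independent standard normal for both statistics;
#' SNPs in `target_set` have the magnitude of both scores inflated by
#' `shift` (the sign is kept), planting an enrichment detectable by
#' [matched_resample_test()].
#'
#' @param snps A `reqtl_genotypes` object or its `snps` data.frame.
#' @param target_set SNP ids to inflate (must be a subset of `snps`).
#' @param shift Non-negative magnitude inflation for target SNPs.
#' @param score_missing_rate Fraction of entries set missing per statistic.
#' @param seed Integer seed.
#' @return data.frame with columns `snp_id`, `ihs`, `sds`.
#' @export
simulate_selection_scores <- function(snps, target_set = character(),
                                      shift = 0, score_missing_rate = 0,
                                      seed = NULL) {
  if (inherits(snps, "reqtl_genotypes")) snps <- snps$snps
  unknown <- setdiff(target_set, snps$snp_id)
  if (length(unknown)) stop("target_set contains unknown SNP(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(snps)
  ihs <- rnorm(m); sds <- rnorm(m)
  tgt <- snps$snp_id %in% target_set
  ihs[tgt] <- ihs[tgt] + sign(ihs[tgt]) * shift
  sds[tgt] <- sds[tgt] + sign(sds[tgt]) * shift
  if (score_missing_rate > 0) {
    ihs[runif(m) < score_missing_rate] <- NA_real_
    sds[runif(m) < score_missing_rate] <- NA_real_
  }
  data.frame(snp_id = snps$snp_id, ihs = ihs, sds = sds,
             stringsAsFactors = FALSE)
}

#' Simulate a GWAS-catalog-style association table
#'
#' For each SNP in `tagged_leads` the catalog receives one row at a partner
#' SNP from the same LD block whose realized genotype r-squared with the
#' lead is at least `r2_of_tag` (an error is raised if no partner reaches
#' it).  `n_background` additional rows are placed at SNPs from blocks that
#' contain no tagged lead, hence uncorrelated with every lead.
#'
#' @param gt A `reqtl_genotypes` object.
#' @param tagged_leads SNP ids to tag through LD.
#' @param r2_of_tag Minimum realized r-squared between lead and its catalog
#'   partner.
#' @param n_background Number of background (untagged) catalog rows.
#' @param seed Integer seed.
#' @return data.frame with columns `trait`, `snp_id`, `p`.
#' @export
simulate_gwas_catalog <- function(gt, tagged_leads = character(),
                                  r2_of_tag = 0.8, n_background = 0,
                                  seed = NULL) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  unknown <- setdiff(tagged_leads, gt$snps$snp_id)
  if (length(unknown)) stop("tagged_leads contains unknown SNP(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  snps <- gt$snps
  rows <- list()
  k <- 0L
  for (lead in tagged_leads) {
    i <- match(lead, snps$snp_id)
    mates <- setdiff(which(snps$block == snps$block[i]), i)
    if (!length(mates)) stop("no block partner available for ", lead)
    r2 <- vapply(mates, function(j) ld_r2(gt$dosages[, i], gt$dosages[, j]),
                 numeric(1))
    ok <- mates[!is.na(r2) & r2 >= r2_of_tag - 1e-12]
    if (!length(ok)) stop("no block partner of ", lead,
                          " reaches r2 >= ", r2_of_tag)
    j <- ok[which.max(r2[match(ok, mates)])]
    k <- k + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(trait = sprintf("trait_%03d", k),
                 snp_id = snps$snp_id[j],
                 p = 10^(-runif(1, 5, 12)), stringsAsFactors = FALSE)
  }
  if (n_background > 0) {
    lead_blocks <- unique(snps$block[match(tagged_leads, snps$snp_id)])
    cand <- which(!(snps$block %in% lead_blocks))
    if (!length(cand)) stop("no background blocks free of tagged leads")
    j <- sample(cand, n_background, replace = n_background > length(cand))
    rows[[length(rows) + 1L]] <-
      data.frame(trait = sprintf("bgtrait_%03d", seq_len(n_background)),
                 snp_id = snps$snp_id[j],
                 p = 10^(-runif(n_background, 5, 12)),
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait = character(), snp_id = character(),
                      p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Draw a random set of planted effects over distinct LD blocks
#'
#' Convenience builder for simulation studies: assigns each effect its own
#' LD block (the block-center SNP becomes the eQTL variant) and cycles
#' through treatments for the response architectures.
#'
#' @param gt A `reqtl_genotypes` object with at least
#'   `n_constant + n_per_architecture * 6` blocks (plus blocks left free for
#'   null genes).
#' @param n_per_architecture Effects planted per response architecture.
#' @param n_constant Constant (condition-shared) eQTLs planted.
#' @param beta Planted slope.
#' @param de_pattern DE pattern given to every response effect.
#' @param seed Integer seed.
#' @return An `effects` data.frame suitable for [simulate_expression()].
#' @export
random_effects <- function(gt, n_per_architecture = 5, n_constant = 5,
                           beta = 0.8, de_pattern = "congruent",
                           seed = NULL) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  if (!is.null(seed)) set.seed(seed)
  archs <- c(rep(setdiff(.architectures, "constant"),
                 each = n_per_architecture),
             rep("constant", n_constant))
  n_eff <- length(archs)
  snps <- gt$snps
  blocks <- unique(snps$block)
  if (length(blocks) < n_eff)
    stop("need at least ", n_eff, " LD blocks, have ", length(blocks))
  use <- sample(blocks, n_eff)
  snp_id <- vapply(use, function(b) {
    i <- which(snps$block == b); snps$snp_id[i[ceiling(length(i) / 2)]]
  }, character(1))
  data.frame(gene = sprintf("gene%04d", seq_len(n_eff)),
             snp_id = snp_id,
             architecture = archs,
             beta = beta,
             treatment = rep(.treatments, length.out = n_eff),
             de_pattern = ifelse(archs == "constant", "none", de_pattern),
             stringsAsFactors = FALSE)
}
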