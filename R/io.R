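# Readers and writers for the on-disk formats: VCF 4.2 with a DS (dosage)
# FORMAT field and an INFO/AA ancestral-allele tag, per-condition
# expression TSVs, a BED-like probe map, score and catalog TSVs, and a
# JSON provenance sidecar.

.fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "."
  out
}

#' Write genotypes as VCF 4.2 with dosage field
#'
#' Emits one sample column per individual with a `DS` (dosage) FORMAT
#' field, and the ancestral allele in the `AA` INFO tag.  Missing dosages
#' become `.`.
#'
#' @param gt A `reqtl_genotypes` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  snps <- gt$snps
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=reqtlkit",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the alternate allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t"))
  info <- ifelse(is.na(snps$ancestral), "AA=.",
                 paste0("AA=", snps$ancestral))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i], snps$snp_id[i], snps$ref[i],
            snps$alt[i], ".", "PASS", info[i], "DS",
            .fmt_num(gt$dosages[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a dosage VCF
#'
#' Parses a VCF (via the vcfR package) carrying a `DS` FORMAT field and an
#' optional `AA` INFO tag, reconstructing a `reqtl_genotypes` object.  The
#' LD-block annotation is not recoverable from VCF and is set to `NA`; MAF
#' is recomputed from the dosages.
#'
#' @param path VCF file path.
#' @return A `reqtl_genotypes` object.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  aa <- vcfR::extract.info(v, element = "AA")
  aa[aa == "."] <- NA_character_
  dos <- t(ds)
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  snps <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], ancestral = aa,
                     maf = pmin(alt_freq, 1 - alt_freq),
                     block = NA_integer_, stringsAsFactors = FALSE)
  colnames(dos) <- snps$snp_id
  structure(list(dosages = dos, snps = snps, samples = rownames(dos)),
            class = "reqtl_genotypes")
}

#' Write and read a genotype dosage TSV (SNPs x samples)
#'
#' The TSV carries the per-SNP metadata columns (`snp_id`, `chrom`, `pos`,
#' `ref`, `alt`, `ancestral`, `maf`, `block`) followed by one dosage column
#' per sample.
#'
#' @param gt A `reqtl_genotypes` object.
#' @param path File path.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` returns a `reqtl_genotypes` object.
#' @export
write_genotypes_tsv <- function(gt, path) {
  stopifnot(inherits(gt, "reqtl_genotypes"))
  tab <- cbind(gt$snps, as.data.frame(t(gt$dosages)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt", "ancestral",
                 "maf", "block")
  snps <- tab[, meta_cols]
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  colnames(dos) <- snps$snp_id
  structure(list(dosages = dos, snps = snps, samples = rownames(dos)),
            class = "reqtl_genotypes")
}

#' Write and read seven-condition expression as TSVs
#'
#' Writes one probes x samples TSV per condition
#' (`<prefix>_<condition>.tsv`) plus a BED-like probe map
#' (`<prefix>_probes.bed`: chrom, anchor_pos - 1, anchor_pos, probe,
#' gene).
#'
#' @param expr A `cond_expression` object.
#' @param prefix Path prefix for the output files.
#' @return `write_expression_tsv()` returns the written paths invisibly;
#'   `read_expression_tsv()` returns a `cond_expression` object.
#' @export
write_expression_tsv <- function(expr, prefix) {
  stopifnot(inherits(expr, "cond_expression"))
  paths <- character(0)
  for (cn in names(expr$values)) {
    p <- paste0(prefix, "_", cn, ".tsv")
    tab <- cbind(data.frame(probe = colnames(expr$values[[cn]])),
                 as.data.frame(t(expr$values[[cn]])))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  bed <- data.frame(chrom = expr$probe_map$chrom,
                    start = expr$probe_map$anchor_pos - 1L,
                    end = expr$probe_map$anchor_pos,
                    probe = expr$probe_map$probe,
                    gene = expr$probe_map$gene)
  bp <- paste0(prefix, "_probes.bed")
  write.table(bed, bp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(paths, bp))
}

#' @rdname write_expression_tsv
#' @param conditions Conditions to read (default all seven).
#' @export
read_expression_tsv <- function(prefix, conditions = reqtl_conditions()) {
  bed <- read.delim(paste0(prefix, "_probes.bed"), header = FALSE,
                    stringsAsFactors = FALSE)
  probe_map <- data.frame(probe = bed[[4]], gene = bed[[5]],
                          chrom = bed[[1]], anchor_pos = bed[[3]],
                          stringsAsFactors = FALSE)
  values <- list()
  for (cn in conditions) {
    tab <- read.delim(paste0(prefix, "_", cn, ".tsv"),
                      stringsAsFactors = FALSE)
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(m) <- tab$probe
    values[[cn]] <- m[, probe_map$probe, drop = FALSE]
  }
  structure(list(values = values, probe_map = probe_map,
                 samples = rownames(values[[1]])),
            class = "cond_expression")
}

#' Write a generic result table as TSV
#'
#' @param tab A data.frame (e.g. score table, catalog, association
#'   results).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a JSON provenance sidecar
#'
#' Records the seeds and parameters of a simulation or analysis run next
#' to its outputs.
#'
#' @param params Named list of parameters (scalars, vectors, nested
#'   lists).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_provenance_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
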