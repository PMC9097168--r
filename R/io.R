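# Plain-text readers/writers for the pipeline's file formats: variant
# catalog TSV, eQTL tables, BED windows (0-based half-open), GWAS summary
# TSV and the 0/1 haplotype matrix.

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write / read a variant catalog TSV
#'
#' @param catalog catalog data frame.
#' @param path file path.
#' @return the path (write) or the catalog data frame (read).
#' @export
write_catalog <- function(catalog, path) .write_tsv(catalog, path)

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  d <- .read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "af_global",
            paste0("af_", c("AFR", "AMR", "EAS", "EUR", "SAS")),
            "gt_altai", "gt_vindija", "gt_denisova",
            "dp_altai", "dp_vindija", "dp_denisova")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_config("catalog file lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Write / read sweep windows as BED
#'
#' Three-column BED (0-based half-open) with the source label in column 4.
#'
#' @param windows window data frame (`chrom`, `start`, `end`, optional
#'   `source`).
#' @param path file path.
#' @return the path (write) or the window data frame (read).
#' @export
write_bed <- function(windows, path) {
  cols <- intersect(c("chrom", "start", "end", "source"), names(windows))
  utils::write.table(windows[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop_config("BED needs at least three columns")
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "source"
  if (any(d$start >= d$end)) stop_config("BED intervals must satisfy start < end")
  d
}

#' Write / read a GWAS summary TSV
#'
#' Columns: `SNP`, `beta`, `se`, `pval`, `effect_allele`, `other_allele`,
#' `eaf`, plus optional `n` and `trait`.
#'
#' @param gwas GWAS summary data frame.
#' @param path file path.
#' @return the path (write) or the data frame (read).
#' @export
write_gwas <- function(gwas, path) .write_tsv(gwas, path)

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  d <- .read_tsv(path)
  need <- c("SNP", "beta", "se", "pval", "effect_allele", "other_allele", "eaf")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_config("GWAS file lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$se <= 0, na.rm = TRUE)) stop_config("GWAS se must be positive")
  d
}

#' Write / read an eQTL association TSV
#' @param eqtls eQTL data frame.
#' @param path file path.
#' @return the path (write) or the data frame (read).
#' @export
write_eqtls <- function(eqtls, path) .write_tsv(eqtls, path)

#' @rdname write_eqtls
#' @export
read_eqtls <- function(path) {
  d <- .read_tsv(path)
  need <- c("variant_id", "gene_id", "tissue", "slope", "pval_nominal")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_config("eQTL file lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Write / read a haplotype panel as a 0/1 matrix TSV
#'
#' The first three columns are `vid`, `chrom`, `pos` (plus `rsid`), followed
#' by one 0/1 column per haplotype.
#'
#' @param panel a `haplotype_panel`.
#' @param path file path.
#' @return the path (write) or a `haplotype_panel` (read).
#' @export
write_panel <- function(panel, path) {
  d <- data.frame(vid = panel$vid, chrom = panel$chrom, pos = panel$pos,
                  rsid = panel$rsid, t(panel$H), check.names = FALSE,
                  stringsAsFactors = FALSE)
  .write_tsv(d, path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- .read_tsv(path, check.names = FALSE)
  meta <- c("vid", "chrom", "pos", "rsid")
  H <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  if (!all(H %in% c(0L, 1L))) stop_config("haplotype matrix must be 0/1")
  storage.mode(H) <- "integer"
  colnames(H) <- d$vid
  structure(list(H = H, chrom = d$chrom, pos = d$pos, vid = d$vid,
                 rsid = d$rsid), class = "haplotype_panel")
}
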