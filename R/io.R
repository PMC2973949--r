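#' Read genotypes from VCF or the package TSV dialect
#'
#' VCF sites are restricted to biallelic SNPs; multiallelic or non-SNP sites
#' are skipped and counted.  Diploid calls are mapped ref/ref to 0, het to
#' 0.5, alt/alt to 1 and no-calls to `NA`.  The TSV dialect has marker ids as
#' the header row, sample ids in the first column and cells in
#' \{0, 0.5, 1, NA\}; marker chromosome/position metadata may be supplied as
#' a sidecar TSV with columns `id`, `chrom`, `pos`.
#'
#' @param path path to a `.vcf`, `.vcf.gz` or TSV genotype file.
#' @param format `"vcf"` or `"tsv"`; guessed from the file name by default.
#' @param markers_path optional marker-metadata sidecar TSV (TSV format only).
#' @return A [snp_genotypes] object.
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           markers_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") load_genotypes_vcf(path) else
    load_genotypes_tsv(path, markers_path)
}

load_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(n_skipped, " multiallelic or non-SNP site(s) skipped")
  if (!any(snp)) stop_input("no usable biallelic SNP sites in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  # normalize separators, map allele pairs to dosage fractions
  code <- function(s) {
    s <- gsub("\\|", "/", s)
    out <- rep(NA_real_, length(s))
    out[s %in% "0/0"] <- 0
    out[s %in% c("0/1", "1/0")] <- 0.5
    out[s %in% "1/1"] <- 1
    out
  }
  gmat <- apply(gt, 2, code)
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = sum(snp))
  ids <- fix[snp, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])[noid]
  markers <- data.frame(id = ids, chrom = fix[snp, "CHROM"],
                        pos = as.integer(fix[snp, "POS"]),
                        ref = ref[snp], alt = alt[snp],
                        stringsAsFactors = FALSE)
  snp_genotypes(t(gmat), colnames(gt), markers)
}

load_genotypes_tsv <- function(path, markers_path = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 2L) stop_input("TSV has no marker columns: ", path)
  sample_ids <- dt[[1]]
  g <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  markers <- NULL
  if (!is.null(markers_path)) {
    mk <- data.table::fread(markers_path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    idx <- match(colnames(g), mk$id)
    if (anyNA(idx)) stop_input("marker sidecar is missing ids present in ", path)
    markers <- data.frame(id = colnames(g), chrom = as.character(mk$chrom[idx]),
                          pos = as.integer(mk$pos[idx]), stringsAsFactors = FALSE)
  }
  snp_genotypes(g, sample_ids, markers)
}

#' Write genotypes in the package TSV dialect
#'
#' @param G [snp_genotypes].
#' @param path output path; missing entries are written as `NA`.
#' @param markers_path optional path for the marker-metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(G, path, markers_path = NULL) {
  df <- data.frame(sample_id = G$sample_ids, G$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(markers_path))
    data.table::fwrite(G$markers[, c("id", "chrom", "pos")], markers_path,
                       sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export genotypes as a minimal plain-text VCF
#'
#' Dosage fractions are written as unphased diploid calls; entries that are
#' not exact 0/0.5/1 values (for example mean-imputed ones) cannot be
#' represented and raise an error.
#'
#' @param G [snp_genotypes].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  g <- G$genotypes
  if (!all(is.na(g) | g %in% c(0, 0.5, 1)))
    stop_input("matrix contains imputed (non 0/0.5/1) values; cannot write VCF")
  mk <- G$markers
  ref <- if ("ref" %in% names(mk)) mk$ref else rep("A", nrow(mk))
  alt <- if ("alt" %in% names(mk)) mk$alt else rep("T", nrow(mk))
  gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
  gt[t(g) == 0] <- "0/0"; gt[t(g) == 0.5] <- "0/1"; gt[t(g) == 1] <- "1/1"
  body <- cbind(mk$chrom, mk$pos, mk$id, ref, alt, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a per-marker QC report
#'
#' @param qc data frame as attached by [qc_filter()] (attribute `report`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  data.table::fwrite(qc, path, sep = "\t", quote = FALSE)
  invisible(path)
}
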