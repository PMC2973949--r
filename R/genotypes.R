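#' SNP genotype matrix
#'
#' Container for diploid biallelic genotypes coded on the dosage-fraction
#' scale: `0` (reference homozygote), `0.5` (heterozygote), `1` (alternate
#' homozygote), with `NA` as the missing sentinel.  Rows are individuals,
#' columns are markers.
#'
#' @param genotypes numeric matrix, n samples x m markers, entries in
#'   \{0, 0.5, 1, NA\}.
#' @param sample_ids character vector of n unique sample identifiers.
#' @param markers data frame with one row per marker and at least columns
#'   `id` (unique), `chrom`, `pos` (1-based, non-negative integer).  Optional
#'   columns `ref`/`alt` carry alleles.
#'
#' @return An object of class `snp_genotypes`.
#' @export
snp_genotypes <- function(genotypes, sample_ids = rownames(genotypes),
                          markers = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (n < 2L) stop_input("need at least 2 samples, got ", n)
  if (m < 1L) stop_input("need at least 1 marker, got ", m)
  # hard calls are 0/0.5/1; mean-imputed dosages inside [0,1] are tolerated
  ok <- is.na(genotypes) | (genotypes >= 0 & genotypes <= 1)
  if (!all(ok)) {
    bad <- unique(genotypes[!ok])
    stop_input("genotype values must lie in [0, 1] or be NA; found: ",
               paste(head(bad, 5), collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop_input("sample_ids length != number of rows")
  if (anyDuplicated(sample_ids)) stop_input("sample_ids must be unique")
  if (is.null(markers)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("M%06d", seq_len(m))
    markers <- data.frame(id = ids, chrom = "1",
                          pos = seq_len(m), stringsAsFactors = FALSE)
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (nrow(markers) != m) stop_input("markers table rows != number of columns")
  if (!all(c("id", "chrom", "pos") %in% names(markers)))
    stop_input("markers table needs columns id, chrom, pos")
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (anyDuplicated(markers$id)) stop_input("marker ids must be unique")
  if (any(markers$pos < 0, na.rm = TRUE)) stop_input("marker pos must be >= 0")
  dimnames(genotypes) <- list(sample_ids, markers$id)
  structure(list(genotypes = genotypes, sample_ids = sample_ids,
                 markers = markers),
            class = "snp_genotypes")
}

#' @export
print.snp_genotypes <- function(x, ...) {
  g <- x$genotypes
  miss <- mean(is.na(g))
  cat(sprintf("snp_genotypes: %d samples x %d markers (%.2f%% missing)\n",
              nrow(g), ncol(g), 100 * miss))
  invisible(x)
}

#' @export
dim.snp_genotypes <- function(x) dim(x$genotypes)

#' Subset markers of a genotype matrix
#'
#' @param G `snp_genotypes`.
#' @param markers integer indices or character marker ids to keep, in the
#'   order given.
#' @return `snp_genotypes` restricted to the requested markers.
#' @export
subset_markers <- function(G, markers) {
  if (is.character(markers)) {
    idx <- match(markers, G$markers$id)
    if (anyNA(idx)) stop_input("unknown marker ids: ",
                               paste(head(markers[is.na(idx)], 5), collapse = ", "))
  } else idx <- as.integer(markers)
  if (length(idx) < 1L) stop_input("empty marker selection")
  if (any(idx < 1L | idx > ncol(G$genotypes)))
    stop_input("marker index out of range")
  snp_genotypes(G$genotypes[, idx, drop = FALSE], G$sample_ids,
                G$markers[idx, , drop = FALSE])
}
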