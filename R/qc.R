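#' Quality-control filter on minor allele frequency and missingness
#'
#' Retains exactly the markers whose empirical minor allele frequency
#' (computed from non-missing calls and folded to be at most 0.5) is strictly
#' greater than `maf_min` and whose missing fraction is strictly less than
#' `miss_max`.  Marker order is preserved.  A per-marker report is attached
#' as attribute `"report"` with columns `id`, `maf`, `missing_rate`, `kept`.
#'
#' @param G [snp_genotypes].
#' @param maf_min minor-allele-frequency threshold (default 0.01).
#' @param miss_max missing-rate threshold (default 0.10).
#' @return Filtered [snp_genotypes] with the QC report attached.
#' @export
qc_filter <- function(G, maf_min = 0.01, miss_max = 0.10) {
  stopifnot(inherits(G, "snp_genotypes"))
  if (maf_min < 0 || maf_min >= 0.5) stop_input("maf_min must be in [0, 0.5)")
  if (miss_max <= 0 || miss_max > 1) stop_input("miss_max must be in (0, 1]")
  g <- G$genotypes
  n <- nrow(g)
  n_obs <- colSums(!is.na(g))
  miss_rate <- 1 - n_obs / n
  # allele frequency = mean(2g)/2 over observed calls, folded
  p <- colMeans(g, na.rm = TRUE)
  p[n_obs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min & miss_rate < miss_max
  report <- data.frame(id = G$markers$id, maf = maf, missing_rate = miss_rate,
                       kept = keep, stringsAsFactors = FALSE)
  if (!any(keep))
    stop_input("no markers pass QC (maf_min = ", maf_min,
               ", miss_max = ", miss_max, ")")
  out <- subset_markers(G, which(keep))
  attr(out, "report") <- report
  out
}

#' Replace missing genotypes with the per-marker mean of observed calls
#'
#' Imputed entries are means of the non-missing calls at that marker and can
#' therefore fall outside \{0, 0.5, 1\}; downstream code treats genotypes as
#' continuous dosages.
#'
#' @param G [snp_genotypes].
#' @return [snp_genotypes] without missing entries.
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "snp_genotypes"))
  g <- G$genotypes
  if (!anyNA(g)) return(G)
  n_obs <- colSums(!is.na(g))
  if (any(n_obs == 0))
    stop_input("marker(s) with no observed calls: ",
               paste(head(G$markers$id[n_obs == 0], 5), collapse = ", "),
               "; run qc_filter() first")
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  g[idx] <- mu[(idx - 1L) %/% nrow(g) + 1L]
  out <- G
  out$genotypes <- g
  out
}

#' @rdname impute_missing
#' @export
has_missing <- function(G) anyNA(G$genotypes)
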