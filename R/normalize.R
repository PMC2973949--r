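#' Posterior allele frequency with pseudocounts
#'
#' Shrinkage estimate of the alternate-allele frequency at one marker,
#' `(1 + sum(2 g)) / (2 + 2 n)` over the non-missing genotypes `g` of the
#' `n` observed individuals (allele counts are `2 g` on the dosage-fraction
#' coding).  The +1/+2 pseudocounts keep the estimate strictly inside (0, 1)
#' even for monomorphic markers, so the normalization scale below never
#' degenerates.
#'
#' @param g numeric vector of genotypes in \[0, 1\]; `NA`s are dropped.
#' @return The posterior frequency, a scalar in (0, 1).
#' @export
posterior_allele_freq <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop_input("no observed genotypes")
  (1 + sum(2 * g)) / (2 + 2 * length(g))
}

#' Center and scale a genotype matrix
#'
#' Each marker column is centered by its mean and divided by
#' `sqrt(p (1 - p))` where `p` is its [posterior_allele_freq()].  Missing
#' entries are excluded from the mean and frequency computations and end up
#' as exact zeros (the column center) in the normalized matrix.  Markers
#' that are constant across all observed calls carry no information and are
#' dropped; their indices are recorded.
#'
#' @param G [snp_genotypes] (raw or imputed).
#' @return An object of class `normalized_genotypes` with elements `X`
#'   (n x m' matrix, column means 0), `posterior_freqs`, `kept_markers`
#'   (column indices of `G` that survived), `markers`, `sample_ids` and a
#'   `provenance` list (dropped-marker ids, missingness handled).
#' @export
normalize_genotypes <- function(G) {
  stopifnot(inherits(G, "snp_genotypes"))
  g <- G$genotypes
  n <- nrow(g)
  n_obs <- colSums(!is.na(g))
  if (any(n_obs == 0))
    stop_input("marker(s) with no observed calls; run qc_filter() first")
  mu <- colMeans(g, na.rm = TRUE)
  p <- (1 + colSums(2 * g, na.rm = TRUE)) / (2 + 2 * n_obs)
  constant <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]; all(x == x[1])
  }, logical(1))
  keep <- which(!constant)
  if (length(keep) == 0L) stop_input("all markers are constant")
  X <- sweep(g[, keep, drop = FALSE], 2, mu[keep])
  X <- sweep(X, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  X[is.na(X)] <- 0
  dimnames(X) <- list(G$sample_ids, G$markers$id[keep])
  structure(list(X = X, posterior_freqs = p[keep], kept_markers = keep,
                 markers = G$markers[keep, , drop = FALSE],
                 sample_ids = G$sample_ids,
                 provenance = list(n_input = ncol(g),
                                   dropped_constant = G$markers$id[constant],
                                   had_missing = anyNA(g))),
            class = "normalized_genotypes")
}

#' @export
print.normalized_genotypes <- function(x, ...) {
  cat(sprintf("normalized_genotypes: %d samples x %d markers (%d constant dropped)\n",
              nrow(x$X), ncol(x$X), length(x$provenance$dropped_constant)))
  invisible(x)
}
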