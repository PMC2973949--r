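#' PCA-based marker informativeness scores
#'
#' Comparator method: recodes genotypes to +1 (reference homozygote),
#' 0 (heterozygote), -1 (alternate homozygote), centers each marker, and
#' scores marker `j` by the sum of its squared entries across the top
#' `n_pcs` right-singular vectors of the recoded matrix.  The recoded matrix
#' is centered but not variance-scaled.
#'
#' @param G [snp_genotypes], complete (impute first).
#' @param n_pcs number of principal components to sum over.
#' @return `marker_ranking` with the PCA scores.
#' @export
pca_marker_scores <- function(G, n_pcs) {
  stopifnot(inherits(G, "snp_genotypes"))
  g <- G$genotypes
  if (anyNA(g)) stop_input("missing genotypes; run impute_missing() first")
  n <- nrow(g); m <- ncol(g)
  if (n_pcs < 1L || n_pcs > min(n, m))
    stop_input("n_pcs must be in [1, min(n, m)]")
  Z <- 1 - 2 * g                      # 0 -> +1, 0.5 -> 0, 1 -> -1
  Z <- sweep(Z, 2, colMeans(Z))
  # right-singular directions via the small n x n Gram matrix
  ee <- eigen(tcrossprod(Z), symmetric = TRUE)
  d2 <- ee$values[seq_len(n_pcs)]
  U <- ee$vectors[, seq_len(n_pcs), drop = FALSE]
  pos <- d2 > max(d2, 0) * 1e-12
  Vt <- crossprod(U[, pos, drop = FALSE], Z) /
    sqrt(d2[pos])                     # n_pcs x m matrix of loadings
  S <- colSums(Vt^2)
  structure(list(scores = S, weights = NULL,
                 order = order(-S, seq_len(m)),
                 zero_fraction = mean(S == 0),
                 markers = G$markers, marker_ids = G$markers$id,
                 n_pcs = n_pcs),
            class = "marker_ranking")
}

#' Redundancy pruning by column-pivoted QR
#'
#' Greedy selection of the `n_keep` least linearly redundant markers among a
#' candidate list: column-pivoted QR factorization of the centered candidate
#' genotype submatrix returns pivots in order of residual norm, so exactly
#' collinear duplicates are pushed to the end.  Deterministic.
#'
#' @param G [snp_genotypes], complete.
#' @param candidates ordered candidate marker indices (or ids).
#' @param n_keep how many markers to retain.
#' @return Candidate marker indices in pivot order, length `n_keep` (or the
#'   numerical rank, with a warning, if smaller).
#' @export
qr_prune <- function(G, candidates, n_keep) {
  stopifnot(inherits(G, "snp_genotypes"))
  if (is.character(candidates)) candidates <- match(candidates, G$markers$id)
  if (anyNA(candidates)) stop_input("unknown candidate marker ids")
  if (n_keep > length(candidates))
    stop_input("n_keep exceeds the number of candidates")
  g <- G$genotypes[, candidates, drop = FALSE]
  if (anyNA(g)) stop_input("missing genotypes; run impute_missing() first")
  M <- sweep(g, 2, colMeans(g))
  qq <- qr(M, LAPACK = TRUE)
  rk <- sum(abs(diag(qr.R(qq))) > max(dim(M)) * .Machine$double.eps *
              max(abs(diag(qr.R(qq))), 1e-300))
  if (rk < n_keep) {
    warning("candidate submatrix has rank ", rk, " < n_keep = ", n_keep,
            "; returning ", rk, " markers", call. = FALSE)
    n_keep <- rk
  }
  candidates[qq$pivot[seq_len(n_keep)]]
}

#' Principal-component coordinates of individuals
#'
#' Top eigenvectors of the individual-by-individual covariance of the
#' column-centered genotype matrix; the standard PCA view of population
#' structure used as the contrast to the Laplacian eigenmap.
#'
#' @param G [snp_genotypes] or `normalized_genotypes`; for raw genotypes
#'   the columns are centered only.
#' @param n_pcs number of components.
#' @return n x n_pcs matrix of PC coordinates (unit-norm eigenvectors).
#' @export
pc_coordinates <- function(G, n_pcs = 2L) {
  X <- if (inherits(G, "normalized_genotypes")) G$X
  else {
    g <- G$genotypes
    if (anyNA(g)) stop_input("missing genotypes; run impute_missing() first")
    sweep(g, 2, colMeans(g))
  }
  ee <- eigen(tcrossprod(X), symmetric = TRUE)
  out <- ee$vectors[, seq_len(n_pcs), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(n_pcs))
  fix_signs(out)
}
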