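#' Sparse elastic-net marker loadings on Laplacian eigenfunctions
#'
#' For each retained eigenfunction `phi_k` solves the elastic net
#' `min_v ||phi_k - X v||^2 + lambda1 ||v||_1 + lambda2 ||v||_2^2` by cyclic
#' coordinate descent with an active-set strategy.  The K problems are
#' independent and solved separately.  The l1 term drives the loadings of
#' uninformative markers to exact zeros; the l2 term adds the grouping
#' behavior of ridge regression.
#'
#' @param X `normalized_genotypes` or plain n x m matrix.
#' @param Phi n x K matrix of non-trivial eigenfunctions (or a
#'   `lap_embedding`, whose coordinates are used).
#' @param lambda1 non-negative l1 penalty.
#' @param lambda2 non-negative l2 penalty.
#' @param tol convergence tolerance on the largest absolute coefficient
#'   change in a full sweep (default 1e-7).
#' @param max_sweeps sweep cap (default 1e5).
#' @param v_init optional m x K warm-start matrix.
#' @return Object of class `sparse_loadings`: `V` (m x K), `lambda1`,
#'   `lambda2`, `objective` (per column), `sparsity` (fraction of exact
#'   zeros per column), `sweeps`, `converged`.
#' @export
fit_sparse_loadings <- function(X, Phi, lambda1, lambda2 = lambda1,
                                tol = 1e-7, max_sweeps = 1e5, v_init = NULL) {
  marker_ids <- NULL
  if (inherits(X, "normalized_genotypes")) { marker_ids <- colnames(X$X); X <- X$X }
  if (inherits(Phi, "lap_embedding")) Phi <- Phi$coords
  Phi <- as.matrix(Phi)
  if (nrow(X) != nrow(Phi))
    stop_input("X and Phi disagree on the number of samples")
  if (lambda1 < 0 || lambda2 < 0) stop_input("penalties must be non-negative")
  K <- ncol(Phi); m <- ncol(X)
  V <- matrix(0, m, K)
  obj <- numeric(K); sw <- integer(K); conv <- logical(K); spars <- numeric(K)
  for (k in seq_len(K)) {
    init <- if (!is.null(v_init)) v_init[, k] else NULL
    fit <- enet_cd_cpp(X, Phi[, k], lambda1, lambda2, tol,
                       as.integer(max_sweeps), init)
    if (!fit$converged)
      stop_numeric("coordinate descent did not converge for eigenfunction ",
                   k, " within ", max_sweeps, " sweeps (last max coefficient",
                   " change ", signif(fit$final_delta, 3), ")")
    V[, k] <- fit$v
    obj[k] <- fit$objective
    sw[k] <- fit$sweeps
    conv[k] <- fit$converged
    spars[k] <- mean(fit$v == 0)
  }
  rownames(V) <- marker_ids
  colnames(V) <- colnames(Phi)
  structure(list(V = V, lambda1 = lambda1, lambda2 = lambda2,
                 objective = obj, sparsity = spars, sweeps = sw,
                 converged = conv),
            class = "sparse_loadings")
}

#' @export
print.sparse_loadings <- function(x, ...) {
  cat(sprintf("sparse_loadings: %d markers x %d eigenfunctions, lambda1 = %g, lambda2 = %g\n",
              nrow(x$V), ncol(x$V), x$lambda1, x$lambda2))
  cat(sprintf("  zero fraction per column: %s\n",
              paste(sprintf("%.3f", x$sparsity), collapse = ", ")))
  invisible(x)
}

#' Smallest l1 penalty that zeroes every loading
#'
#' At `lambda1 >= 2 * max_j |x_j' phi_k|` the soft-threshold update kills
#' every coefficient, so this is the top of the useful penalty range.
#'
#' @inheritParams fit_sparse_loadings
#' @return Scalar penalty bound over all K columns.
#' @export
lambda1_max <- function(X, Phi) {
  if (inherits(X, "normalized_genotypes")) X <- X$X
  if (inherits(Phi, "lap_embedding")) Phi <- Phi$coords
  2 * max(abs(crossprod(X, as.matrix(Phi))))
}

#' Tune lambda1 to a target number of selected markers
#'
#' Bisects `lambda1` on a log scale (with `lambda2 = ratio * lambda1`)
#' until the number of markers with a non-zero loading on at least one
#' eigenfunction is close to `target`.  The zero count is non-increasing in
#' `lambda1`, so bisection is well behaved; fits are warm-started.
#'
#' @inheritParams fit_sparse_loadings
#' @param target desired number of markers with positive rank statistic.
#' @param lambda2_ratio `lambda2 / lambda1` (default 1).
#' @param rel_tol stop when within this relative distance of `target`.
#' @param max_iter bisection cap.
#' @param tol coordinate-descent tolerance used during the search.
#' @param final_tol tolerance of the final refit at the chosen penalty.
#' @return List with `lambda1`, `lambda2`, `n_nonzero` and the final
#'   `sparse_loadings` fit (refit at `final_tol`).
#' @export
tune_lambda1 <- function(X, Phi, target, lambda2_ratio = 1, rel_tol = 0.15,
                         max_iter = 14, tol = 1e-6, final_tol = 1e-7) {
  if (inherits(X, "normalized_genotypes")) X <- X$X
  if (inherits(Phi, "lap_embedding")) Phi <- Phi$coords
  m <- ncol(X)
  if (target < 1 || target > m) stop_input("target must be in [1, m]")
  hi <- lambda1_max(X, Phi)
  lo <- hi * 1e-4
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    fit <- fit_sparse_loadings(X, Phi, mid, lambda2_ratio * mid, tol = tol,
                               v_init = if (is.null(best)) NULL else best$fit$V)
    nz <- sum(rowSums(fit$V != 0) > 0)
    if (is.null(best) || abs(nz - target) < abs(best$n_nonzero - target))
      best <- list(lambda1 = mid, n_nonzero = nz, fit = fit)
    if (abs(nz - target) <= rel_tol * target) {
      best <- list(lambda1 = mid, n_nonzero = nz, fit = fit)
      break
    }
    if (nz > target) lo <- mid else hi <- mid
  }
  final <- fit_sparse_loadings(X, Phi, best$lambda1,
                               lambda2_ratio * best$lambda1,
                               tol = final_tol, v_init = best$fit$V)
  list(lambda1 = best$lambda1, lambda2 = lambda2_ratio * best$lambda1,
       n_nonzero = sum(rowSums(final$V != 0) > 0), fit = final)
}

#' Rank markers by the weighted squared-loading statistic
#'
#' The rank statistic of marker `j` is `S_j = sum_k w_k v_jk^2`.  Weights
#' are either `"uniform"` (default), `"eigen_variance"` (proportional to
#' `1 / (1 + lambda_k)`, a proxy for the share of structure carried by each
#' eigenfunction; requires `eigenvalues`), or an explicit non-negative
#' vector.  Ties are broken by ascending marker index, making the order a
#' deterministic total order.
#'
#' @param V [fit_sparse_loadings()] result or m x K matrix.
#' @param weights `"uniform"`, `"eigen_variance"` or numeric vector.
#' @param eigenvalues eigenvalues for the `"eigen_variance"` mode.
#' @param markers optional marker metadata carried into the result.
#' @return Object of class `marker_ranking`: `scores`, `weights`, `order`
#'   (permutation, descending score), `zero_fraction`.
#' @export
rank_markers <- function(V, weights = "uniform", eigenvalues = NULL,
                         markers = NULL) {
  if (inherits(V, "sparse_loadings")) V <- V$V
  V <- as.matrix(V)
  K <- ncol(V)
  if (is.character(weights)) {
    weights <- match.arg(weights, c("uniform", "eigen_variance"))
    w <- if (weights == "uniform") rep(1, K) else {
      if (is.null(eigenvalues) || length(eigenvalues) != K)
        stop_input("eigen_variance weights need one eigenvalue per column")
      1 / (1 + eigenvalues)
    }
  } else {
    w <- as.numeric(weights)
    if (length(w) != K) stop_input("need one weight per eigenfunction")
    if (any(w < 0) || all(w == 0)) stop_input("weights must be non-negative, not all zero")
  }
  w <- w / sum(w)
  S <- as.vector(V^2 %*% w)
  ord <- order(-S, seq_along(S))
  structure(list(scores = S, weights = w, order = ord,
                 zero_fraction = mean(S == 0),
                 markers = markers, marker_ids = rownames(V)),
            class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, ...) {
  cat(sprintf("marker_ranking: %d markers, %.1f%% with zero score\n",
              length(x$scores), 100 * x$zero_fraction))
  invisible(x)
}

#' Select the top-ranked markers
#'
#' @param ranking [rank_markers()] result.
#' @param n_top panel size; truncated with a warning if fewer markers have a
#'   positive score.
#' @return Integer marker indices, highest score first.
#' @export
select_top <- function(ranking, n_top) {
  stopifnot(inherits(ranking, "marker_ranking"))
  if (n_top <= 0) stop_input("n_top must be positive")
  n_pos <- sum(ranking$scores > 0)
  if (n_top > n_pos) {
    warning("only ", n_pos, " markers have positive scores; truncating panel",
            call. = FALSE)
    n_top <- n_pos
  }
  ranking$order[seq_len(n_top)]
}

#' Re-embed from a selected marker panel (sparse Laplacian eigenfunctions)
#'
#' Runs the identical normalize / correlation / graph / spectrum pipeline on
#' the selected marker subset, producing SLAP coordinates comparable to the
#' full-panel LAP coordinates.  Selecting every marker reproduces the full
#' embedding exactly.
#'
#' @param G [snp_genotypes] with all markers.
#' @param selected marker indices (or ids) of the panel.
#' @param ... embedding parameters passed to [laplacian_embedding()].
#' @return `lap_embedding` with `source = "sparse"`.
#' @export
sparse_eigenfunctions <- function(G, selected, ...) {
  if (length(selected) < 1L) stop_input("empty marker panel")
  laplacian_embedding(subset_markers(G, selected), source = "sparse", ...)
}
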