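#' Pearson correlation between individuals
#'
#' Standard sample correlation between the rows (individuals) of the
#' normalized genotype matrix.
#'
#' @param X `normalized_genotypes` or a plain numeric matrix with
#'   individuals as rows.
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(X) {
  ids <- NULL
  if (inherits(X, "normalized_genotypes")) { ids <- X$sample_ids; X <- X$X }
  if (ncol(X) < 2L) stop_input("need at least 2 markers for correlations")
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    who <- if (is.null(ids)) which(s == 0) else ids[s == 0]
    stop_input("zero-variance individual row(s): ",
               paste(head(who, 5), collapse = ", "))
  }
  Y <- (X - rowMeans(X)) / s
  R <- tcrossprod(Y) / (ncol(X) - 1)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  if (!is.null(ids)) dimnames(R) <- list(ids, ids)
  R
}

#' Genetic distance from individual correlations
#'
#' The default metric is `d = sqrt(1 - r)`, mapping perfectly correlated
#' individuals to 0 and perfectly anticorrelated ones to `sqrt(2)`;
#' `"one_minus_r"` is the linear alternative.
#'
#' @param R correlation matrix from [sample_correlation()].
#' @param formula `"sqrt_1_minus_r"` (default) or `"one_minus_r"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
genetic_distance <- function(R, formula = c("sqrt_1_minus_r", "one_minus_r")) {
  formula <- match.arg(formula)
  if (any(abs(R) > 1 + 1e-10))
    stop_input("correlations outside [-1, 1]")
  D <- pmax(1 - R, 0)
  if (formula == "sqrt_1_minus_r") D <- sqrt(D)
  diag(D) <- 0
  D
}

#' Quantile specification for the neighborhood radius
#'
#' The radius epsilon of the neighborhood graph may be given either as an
#' absolute distance or as a quantile of the off-diagonal pairwise
#' distances.  When resolved from a quantile the radius is floored at
#' `connect_factor` times the graph's connectivity radius (the longest edge
#' of a minimum spanning tree of the distance matrix), so the resulting
#' graph is always connected; an absolute radius is used exactly as given
#' and may yield a disconnected graph, which is an error downstream.
#'
#' @param q quantile in (0, 1) of off-diagonal distances (default 0.05).
#' @param connect_factor multiplier (> 1) on the connectivity radius floor.
#' @return An `eps_quantile` specification object.
#' @export
eps_quantile <- function(q = 0.05, connect_factor = 1.05) {
  if (q <= 0 || q >= 1) stop_input("epsilon quantile must be in (0, 1)")
  structure(list(q = q, connect_factor = connect_factor),
            class = "eps_quantile")
}

# longest edge of a minimum spanning tree (Prim), the smallest radius at
# which the epsilon-graph is connected
connectivity_radius <- function(D) {
  n <- nrow(D)
  in_tree <- rep(FALSE, n)
  dmin <- D[1, ]
  in_tree[1] <- TRUE
  mx <- 0
  for (i in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(dmin[cand])]
    mx <- max(mx, dmin[j])
    in_tree[j] <- TRUE
    dmin <- pmin(dmin, D[j, ])
  }
  mx
}

#' Build the epsilon-neighborhood Gaussian kernel graph
#'
#' Edge weights are `w_ij = exp(-d_ij^2 / t)` for pairs with `d_ij <= eps`
#' (and `i != j`), zero otherwise.  `t` is the global diffusion scale of the
#' heat kernel; `eps` bounds each individual's neighborhood in the metric.
#'
#' @param D distance matrix from [genetic_distance()].
#' @param t diffusion scale, positive (default 1).
#' @param epsilon absolute radius (numeric) or an [eps_quantile()] spec.
#' @return An object of class `weight_graph`: `W` (weights), `degrees`,
#'   `t`, `epsilon` (resolved), `epsilon_spec`, `n_edges`.
#' @export
build_weight_graph <- function(D, t = 1, epsilon = eps_quantile()) {
  if (t <= 0) stop_input("diffusion scale t must be positive")
  n <- nrow(D)
  spec <- epsilon
  if (inherits(epsilon, "eps_quantile")) {
    qv <- unname(quantile(D[upper.tri(D)], epsilon$q))
    eps <- max(qv, epsilon$connect_factor * connectivity_radius(D))
  } else {
    eps <- as.numeric(epsilon)
    if (length(eps) != 1L || !is.finite(eps) || eps <= 0)
      stop_input("epsilon must be a single positive radius or eps_quantile()")
  }
  W <- exp(-D^2 / t)
  W[D > eps] <- 0
  diag(W) <- 0
  deg <- rowSums(W)
  if (any(deg == 0))
    stop_input(sum(deg == 0), " isolated vertex/vertices at epsilon = ",
               signif(eps, 4), "; increase epsilon")
  structure(list(W = W, degrees = deg, t = t, epsilon = eps,
                 epsilon_spec = spec, n_edges = sum(W > 0) / 2),
            class = "weight_graph")
}

#' @export
print.weight_graph <- function(x, ...) {
  cat(sprintf("weight_graph: %d vertices, %d edges, t = %g, epsilon = %.4g\n",
              nrow(x$W), x$n_edges, x$t, x$epsilon))
  cat(sprintf("  degrees: min %.3g / median %.3g / max %.3g\n",
              min(x$degrees), median(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Spectrum of the normalized graph Laplacian
#'
#' Computes the `K + 1` smallest eigenpairs (including the trivial one at
#' eigenvalue 0) of the symmetric normalized Laplacian
#' `L_sym = I - D^(-1/2) W D^(-1/2)`, which is symmetric positive
#' semi-definite with eigenvalues in \[0, 2\].  The random-walk normalization
#' `D^(-1) L` shares the same spectrum; its eigenfunctions are returned as
#' `D^(-1/2)` times the symmetric ones (rescaled to unit norm), making the
#' trivial eigenfunction constant.
#'
#' @param Wg [build_weight_graph()] result.
#' @param K number of non-trivial eigenpairs wanted (`K + 1 <= n`).
#' @param normalization `"symmetric"` (default) or `"random_walk"`.
#' @return Object of class `laplacian_spectrum`: `values` (ascending,
#'   length K+1), `vectors` (n x (K+1), unit columns, largest-magnitude
#'   entry positive), `normalization`, `trivial_index = 1`.
#' @export
laplacian_spectrum <- function(Wg, K = 2L,
                               normalization = c("symmetric", "random_walk")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(Wg, "weight_graph"))
  n <- nrow(Wg$W)
  if (K < 1L) stop_input("K must be >= 1")
  if (K + 1L > n) stop_input("K + 1 eigenpairs requested but only ", n,
                             " vertices")
  dis <- 1 / sqrt(Wg$degrees)
  L <- diag(n) - (dis %o% dis) * Wg$W
  L <- (L + t(L)) / 2
  ee <- eigen(L, symmetric = TRUE)
  values <- rev(ee$values)
  vectors <- ee$vectors[, n:1, drop = FALSE]
  n_zero <- sum(values < 1e-8)
  if (n_zero > 1L)
    stop_input("graph is disconnected: ", n_zero,
               " components (eigenvalue-0 multiplicity); increase epsilon")
  values <- values[seq_len(K + 1L)]
  vectors <- vectors[, seq_len(K + 1L), drop = FALSE]
  if (normalization == "random_walk") {
    vectors <- vectors * dis
    nrm <- sqrt(colSums(vectors^2))
    vectors <- sweep(vectors, 2, nrm, "/")
  }
  vectors <- fix_signs(vectors)
  structure(list(values = values, vectors = vectors,
                 normalization = normalization, trivial_index = 1L,
                 degrees = Wg$degrees),
            class = "laplacian_spectrum")
}

# sign convention: the entry of largest magnitude in each column is positive
fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

# Canonical orientation inside near-degenerate eigenvalue blocks.  Consecutive
# retained eigenvalues closer than `reltol` span a subspace whose basis is
# arbitrary up to rotation; project a fixed reference set (centered
# sample-index ramp and its square) onto the block and take the QR frame, so
# two embeddings of the same samples -- e.g. a full-panel and a selected-panel
# run -- come out dimension-wise comparable.  The gap is measured relative to
# max(lambda, 0.1) on the [0, 2] scale of the normalized Laplacian: the floor
# groups near-zero cluster modes, whose relative gaps are dominated by noise,
# the same way in dense full-panel and sparse subset graphs.
canonical_orientation <- function(Phi, values, reltol = 0.25) {
  K <- ncol(Phi)
  if (K < 2L || reltol <= 0) return(fix_signs(Phi))
  n <- nrow(Phi)
  ramp <- seq_len(n) - (n + 1) / 2
  refs <- cbind(ramp, ramp^2 - mean(ramp^2))
  blocks <- list(); cur <- 1L; b <- 1L
  for (k in 2:K) {
    gap <- abs(values[k] - values[k - 1]) / max(abs(values[k]), 0.1)
    if (gap < reltol) cur <- c(cur, k) else { blocks[[b]] <- cur; b <- b + 1L; cur <- k }
  }
  blocks[[b]] <- cur
  for (bl in blocks) {
    if (length(bl) < 2L) next
    r <- min(length(bl), ncol(refs))
    A <- crossprod(Phi[, bl, drop = FALSE], refs[, seq_len(r), drop = FALSE])
    Q <- qr.Q(qr(A), complete = TRUE)
    Phi[, bl] <- Phi[, bl, drop = FALSE] %*% Q
  }
  fix_signs(Phi)
}

#' Low-dimensional Laplacian eigenmap coordinates
#'
#' Drops the trivial eigenfunction and returns the `K` eigenfunctions of
#' smallest non-zero eigenvalue as coordinates LAP1..LAPK.  Output is
#' deterministic: each column's largest-magnitude entry is positive, and
#' near-degenerate eigenvalue blocks (relative gap below `degenerate_tol`)
#' are rotated to a canonical orientation fixed by the sample ordering, so
#' repeated runs and re-embeddings from marker subsets are comparable
#' dimension by dimension.
#'
#' @param spec [laplacian_spectrum()] result holding at least K non-trivial
#'   pairs.
#' @param K embedding dimension.
#' @param source `"full"` or `"sparse"` provenance tag.
#' @param degenerate_tol relative eigenvalue gap under which two consecutive
#'   eigenfunctions are treated as a degenerate pair (default 0.25); set 0
#'   to disable the canonical rotation.
#' @param params list echoed into the result.
#' @return Object of class `lap_embedding` with `coords` (n x K, columns
#'   LAP1..LAPK), `eigenvalues`, `source`, `params`.
#' @export
lap_embed <- function(spec, K = 2L, source = "full", degenerate_tol = 0.25,
                      params = list()) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  avail <- ncol(spec$vectors) - 1L
  if (K > avail) stop_input("K = ", K, " but spectrum holds only ", avail,
                            " non-trivial eigenpairs")
  idx <- seq_len(K) + 1L
  coords <- canonical_orientation(spec$vectors[, idx, drop = FALSE],
                                  spec$values[idx], degenerate_tol)
  colnames(coords) <- paste0(if (source == "sparse") "SLAP" else "LAP",
                             seq_len(K))
  structure(list(coords = coords, eigenvalues = spec$values[idx],
                 source = source,
                 params = c(params, list(degenerate_tol = degenerate_tol))),
            class = "lap_embedding")
}

#' @export
print.lap_embedding <- function(x, ...) {
  cat(sprintf("lap_embedding (%s): %d samples x %d dimensions\n",
              x$source, nrow(x$coords), ncol(x$coords)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Full embedding pipeline from raw genotypes
#'
#' Convenience chain: normalize, individual correlations, genetic distance,
#' epsilon-graph, Laplacian spectrum, eigenmap.  All steps are available
#' individually; this wrapper guarantees the full-panel and selected-panel
#' embeddings run through identical code.
#'
#' @param G [snp_genotypes] (missing entries allowed; they are excluded from
#'   the normalization statistics).
#' @param K embedding dimension (default 2).
#' @param t diffusion scale (default 1).
#' @param epsilon radius or [eps_quantile()] spec.
#' @param distance distance formula, see [genetic_distance()].
#' @param normalization Laplacian normalization.
#' @param degenerate_tol see [lap_embed()].
#' @param source provenance tag for the embedding.
#' @return [lap_embed()] result.
#' @export
laplacian_embedding <- function(G, K = 2L, t = 1, epsilon = eps_quantile(),
                                distance = "sqrt_1_minus_r",
                                normalization = "symmetric",
                                degenerate_tol = 0.25, source = "full") {
  X <- normalize_genotypes(G)
  R <- sample_correlation(X)
  D <- genetic_distance(R, distance)
  Wg <- build_weight_graph(D, t = t, epsilon = epsilon)
  sp <- laplacian_spectrum(Wg, K = K, normalization = normalization)
  lap_embed(sp, K = K, source = source, degenerate_tol = degenerate_tol,
            params = list(t = t, epsilon = Wg$epsilon, distance = distance,
                          normalization = normalization))
}
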