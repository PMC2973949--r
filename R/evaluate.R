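#' Mantel permutation test of distance-matrix congruence
#'
#' The raw statistic is the cross-product sum over unordered pairs,
#' `z_raw = sum_{i<j} D1_ij D2_ij`.  The null distribution is obtained by
#' jointly permuting the rows and columns of `D2`; the standardized score is
#' `(z_raw - mean) / sd` of the permutation distribution and the one-sided
#' p-value is `(1 + #permutations >= z_raw) / (n_perm + 1)`.
#'
#' @param D1,D2 symmetric distance matrices with zero diagonal, same size.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return Object of class `mantel_result`: `z_raw`, `z_score`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
mantel_z <- function(D1, D2, n_perm = 999L, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (!all(dim(D1) == dim(D2))) stop_input("distance matrices differ in size")
  if (max(abs(D1 - t(D1))) > 1e-8 || max(abs(D2 - t(D2))) > 1e-8)
    stop_input("distance matrices must be symmetric")
  if (any(abs(diag(D1)) > 1e-8) || any(abs(diag(D2)) > 1e-8))
    stop_input("distance matrices must have zero diagonal")
  ut <- upper.tri(D1)
  z_raw <- sum(D1[ut] * D2[ut])
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    sum(D1[ut] * D2[p, p][ut])
  }, numeric(1)))
  s <- sd(perm_stats)
  if (!is.finite(s) || s == 0)
    stop_input("zero permutation variance (constant distance matrix)")
  structure(list(z_raw = z_raw,
                 z_score = (z_raw - mean(perm_stats)) / s,
                 p_value = (1 + sum(perm_stats >= z_raw)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: z_raw = %.4g, z_score = %.3f, p = %.4g (%d permutations)\n",
              x$z_raw, x$z_score, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-dimension correlation between two embeddings
#'
#' Pearson correlation between matching coordinate columns after sign
#' alignment (a column of `E2` is flipped when its raw correlation with the
#' `E1` column is negative), so values lie in \[0, 1\].
#'
#' @param E1,E2 `lap_embedding` objects or coordinate matrices over the same
#'   samples with the same number of dimensions.
#' @return Named numeric vector of per-dimension correlations.
#' @export
eigenmap_correlation <- function(E1, E2) {
  if (inherits(E1, "lap_embedding")) E1 <- E1$coords
  if (inherits(E2, "lap_embedding")) E2 <- E2$coords
  if (!all(dim(E1) == dim(E2))) stop_input("embeddings differ in shape")
  out <- vapply(seq_len(ncol(E1)), function(k) {
    if (sd(E1[, k]) == 0 || sd(E2[, k]) == 0)
      stop_input("zero-variance embedding column ", k)
    abs(cor(E1[, k], E2[, k]))
  }, numeric(1))
  names(out) <- paste0("dim", seq_len(ncol(E1)))
  out
}

#' Pairwise LD (r-squared) summary of a marker panel
#'
#' Squared Pearson correlation between genotype columns for every unordered
#' pair in the panel (missing data pairwise-deleted; this is composite LD on
#' unphased genotypes).  Pairs are counted into the bins
#' `[0, 0.1), [0.1, 0.2), ..., [0.9, 1]`; pairs involving a marker that is
#' monomorphic (undefined correlation) are reported separately.
#'
#' @param G [snp_genotypes].
#' @param panel marker indices or ids (at least 2).
#' @param bin_edges interior bin edges (default `seq(0.1, 0.9, 0.1)`).
#' @return List with `bins` (data frame: bin label, count), `n_undefined`,
#'   `n_pairs`.
#' @export
ld_r2_summary <- function(G, panel, bin_edges = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(G, "snp_genotypes"))
  if (length(panel) < 2L) stop_input("panel needs at least 2 markers")
  g <- subset_markers(G, panel)$genotypes
  r2 <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
  vals <- r2[upper.tri(r2)]
  n_pairs <- length(vals)
  undef <- is.na(vals)
  edges <- c(0, bin_edges, 1 + 1e-12)
  cnt <- as.vector(table(cut(vals[!undef], breaks = edges, right = FALSE,
                             include.lowest = TRUE)))
  lab <- c(sprintf("r2 < %.1f", edges[2]),
           sprintf("%.1f <= r2 < %.1f", head(edges[-1], -2),
                   edges[c(-1, -2)][seq_len(length(edges) - 3)]),
           sprintf("r2 >= %.1f", edges[length(edges) - 1]))
  list(bins = data.frame(bin = lab, count = cnt, stringsAsFactors = FALSE),
       n_undefined = sum(undef), n_pairs = n_pairs)
}

#' Membership prediction with a radial-kernel support vector machine
#'
#' Repeatedly splits the samples into equal stratified train/test halves,
#' trains a radial-basis-kernel SVM on the panel's genotype columns and
#' reports mean overall accuracy and per-class error across repeats.  The
#' kernel width defaults to the median heuristic, `gamma = 1 / median`
#' squared pairwise feature distance.
#'
#' @param G [snp_genotypes], complete (impute first).
#' @param panel marker indices or ids; must be non-empty.
#' @param labels class label per sample (at least 2 classes, each with at
#'   least 2 samples).
#' @param split_seed RNG seed for the splits.
#' @param n_repeats number of random splits (default 10).
#' @param cost SVM regularization constant (default 1).
#' @param features `"raw"` genotype coding (default) or `"normalized"`.
#' @return Object of class `prediction_report`: `overall_accuracy` (mean),
#'   `per_class_error`, `accuracies` (per repeat), `classifier_config`.
#' @export
membership_prediction <- function(G, panel, labels, split_seed = 1L,
                                  n_repeats = 10L, cost = 1,
                                  features = c("raw", "normalized")) {
  features <- match.arg(features)
  stopifnot(inherits(G, "snp_genotypes"))
  if (length(panel) < 1L) stop_input("empty marker panel")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop_input("need at least 2 classes")
  if (any(table(labels) < 2L))
    stop_input("every class needs at least 2 samples")
  Gp <- subset_markers(G, panel)
  x <- if (features == "raw") {
    if (anyNA(Gp$genotypes)) stop_input("missing genotypes; impute first")
    Gp$genotypes
  } else normalize_genotypes(Gp)$X
  # median heuristic on a bounded subsample
  idx <- if (nrow(x) > 400) seq(1, nrow(x), length.out = 400) else seq_len(nrow(x))
  med <- median(dist(x[idx, , drop = FALSE])^2)
  gamma <- if (med > 0) 1 / med else 1 / ncol(x)
  res <- with_seed(split_seed, {
    lapply(seq_len(n_repeats), function(rep) {
      test <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
        sample(ix, floor(length(ix) / 2))
      }), use.names = FALSE)
      train <- setdiff(seq_along(labels), test)
      fit <- e1071::svm(x = x[train, , drop = FALSE], y = labels[train],
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      pred <- predict(fit, x[test, , drop = FALSE])
      truth <- labels[test]
      err <- vapply(levels(labels), function(cl) {
        mean(pred[truth == cl] != cl)
      }, numeric(1))
      list(acc = mean(pred == truth), err = err)
    })
  })
  acc <- vapply(res, `[[`, numeric(1), "acc")
  err <- rowMeans(vapply(res, `[[`, numeric(nlevels(labels)), "err"))
  structure(list(overall_accuracy = mean(acc), accuracies = acc,
                 per_class_error = err,
                 classifier_config = list(kernel = "radial", cost = cost,
                                          gamma = gamma, features = features,
                                          n_repeats = n_repeats,
                                          split_seed = split_seed)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: mean accuracy %.3f over %d stratified splits\n",
              x$overall_accuracy, x$classifier_config$n_repeats))
  invisible(x)
}

#' Rosenberg informativeness for assignment (In)
#'
#' Mutual-information-style statistic per marker:
#' `In = -sum_a pbar_a log pbar_a + (1/P) sum_pops sum_a p_pa log p_pa`
#' with natural logarithms, the convention `0 log 0 = 0`, allele
#' frequencies computed from non-missing calls, and `pbar` the unweighted
#' average across the P populations.  Zero when every population shares the
#' same allele frequencies; `log 2` when two populations are fixed for
#' opposite alleles.
#'
#' @param G [snp_genotypes].
#' @param labels population label per sample (at least 2 populations).
#' @return Numeric vector of In values (one per marker), non-negative.
#' @export
informativeness_for_assignment <- function(G, labels) {
  stopifnot(inherits(G, "snp_genotypes"))
  labels <- factor(labels)
  P <- nlevels(labels)
  if (P < 2L) stop_input("need at least 2 populations")
  g <- G$genotypes
  freqs <- vapply(levels(labels), function(l) {
    colMeans(g[labels == l, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(g)))                      # m x P alternate-allele freqs
  if (ncol(g) == 1L) freqs <- matrix(freqs, nrow = 1)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  pbar <- rowMeans(freqs)
  In <- -(xlx(pbar) + xlx(1 - pbar)) +
    rowMeans(xlx(freqs) + xlx(1 - freqs))
  pmax(In, 0)
}

#' Circular association between two angle vectors
#'
#' Fisher-Lee circular correlation coefficient,
#' `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by the root product
#' of the two marginal sums of squares.  Invariant to rotating either set
#' of angles; reflection flips the sign.
#'
#' @param a,b angle vectors in radians.
#' @return Coefficient in \[-1, 1\].
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_input("angle vectors differ in length")
  sa <- sin(outer(a, a, "-")); sb <- sin(outer(b, b, "-"))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

#' Angular position of samples in a 2-D embedding
#'
#' @param E `lap_embedding` or 2-column coordinate matrix.
#' @return `atan2(dim2, dim1)` per sample.
#' @export
embedding_angle <- function(E) {
  if (inherits(E, "lap_embedding")) E <- E$coords
  if (ncol(E) < 2L) stop_input("need a 2-D embedding")
  atan2(E[, 2], E[, 1])
}
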