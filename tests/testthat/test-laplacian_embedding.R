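test_that("individual correlations match the brute-force Pearson formula", {
  set.seed(21)
  X <- matrix(rnorm(24), 4, 6)
  R <- sample_correlation(X)
  for (i in 1:4) for (j in 1:4)
    expect_equal(R[i, j], if (i == j) 1 else brute_pearson(X[i, ], X[j, ]),
                 tolerance = 1e-12)

  # duplicated individuals and perfect anticorrelation
  X2 <- rbind(c(1, -1, 0), c(1, -1, 0), c(-1, 1, 0))
  R2 <- sample_correlation(X2)
  expect_equal(R2[1, 2], 1)
  expect_equal(R2[1, 3], -1)

  expect_error(sample_correlation(rbind(c(0, 0, 0), c(1, 2, 3))),
               "zero-variance")
})

test_that("genetic distance maps correlations as specified", {
  R <- matrix(c(1, -1, -1, 1), 2)
  D <- genetic_distance(R)
  expect_equal(D[1, 1], 0)
  expect_equal(D[1, 2], sqrt(2))
  # monotone decreasing in r
  r <- seq(-1, 1, by = 0.1)
  d <- sqrt(1 - r)
  expect_true(all(diff(d) < 0))
  expect_error(genetic_distance(matrix(c(1, 1.5, 1.5, 1), 2)), "outside")
  # linear alternative
  expect_equal(genetic_distance(R, "one_minus_r")[1, 2], 2)
})

test_that("weight graph applies the thresholded Gaussian kernel", {
  D <- matrix(c(0, 0.2, 0.9,
                0.2, 0, 0.5,
                0.9, 0.5, 0), 3, byrow = TRUE)
  Wg <- build_weight_graph(D, t = 1, epsilon = 0.6)
  expect_equal(Wg$W[1, 2], exp(-0.04))
  expect_equal(Wg$W[1, 3], 0)                 # just above epsilon
  expect_equal(Wg$W[2, 3], exp(-0.25))
  expect_equal(diag(Wg$W), rep(0, 3))
  expect_equal(Wg$degrees, rowSums(Wg$W))

  # d = sqrt(t) gives weight exp(-1)
  D2 <- matrix(0.5, 4, 4); diag(D2) <- 0
  Wg2 <- build_weight_graph(D2, t = 0.25, epsilon = 0.5)
  expect_equal(Wg2$W[1, 2], exp(-1))

  # isolated vertex under an absolute radius is an error
  D3 <- matrix(c(0, 0.1, 2, 0.1, 0, 2, 2, 2, 0), 3)
  expect_error(build_weight_graph(D3, epsilon = 0.5), "isolated")

  # the quantile spec floors epsilon at the connectivity radius
  Wg3 <- build_weight_graph(D3, epsilon = eps_quantile(0.05))
  expect_true(all(rowSums(Wg3$W) > 0))
  expect_gte(Wg3$epsilon, 2)
})

test_that("triangle graph has normalized eigenvalues 0, 1.5, 1.5", {
  D <- matrix(0, 3, 3)
  sp <- laplacian_spectrum(build_weight_graph(D, epsilon = 1), K = 2)
  expect_equal(sp$values, c(0, 1.5, 1.5), tolerance = 1e-10)
})

test_that("disconnected graphs report their component count", {
  D <- matrix(2, 6, 6)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1; diag(D) <- 0
  Wg <- build_weight_graph(D, epsilon = 0.5)
  expect_error(laplacian_spectrum(Wg, K = 2), "2 components")
})

test_that("spectrum satisfies the eigen equation, PSD range and normalization equivalence", {
  set.seed(55)
  for (rep in 1:6) {
    n <- 12
    P <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(dist(P))
    Wg <- build_weight_graph(D, t = 1, epsilon = eps_quantile(0.3))
    sp <- laplacian_spectrum(Wg, K = n - 1)
    # residuals of the eigen equation against an independently built L_sym
    dis <- 1 / sqrt(Wg$degrees)
    L <- diag(n) - outer(dis, dis) * Wg$W
    for (k in seq_len(n)) {
      expect_lt(max(abs(L %*% sp$vectors[, k] - sp$values[k] * sp$vectors[, k])),
                1e-8)
    }
    expect_lt(max(abs(crossprod(sp$vectors) - diag(n))), 1e-8)
    # PSD and the [0, 2] range for the symmetric normalization
    expect_gt(min(sp$values), -1e-10)
    expect_lt(max(sp$values), 2 + 1e-10)
    # trivial eigenfunction proportional to D^(1/2) 1
    v0 <- sqrt(Wg$degrees); v0 <- v0 / sqrt(sum(v0^2))
    expect_lt(min(max(abs(sp$vectors[, 1] - v0)),
                  max(abs(sp$vectors[, 1] + v0))), 1e-8)
    # the random-walk normalization shares the spectrum exactly
    sp_rw <- laplacian_spectrum(Wg, K = n - 1, normalization = "random_walk")
    expect_equal(sp_rw$values, sp$values, tolerance = 1e-8)
    # and its trivial eigenfunction is constant
    expect_lt(diff(range(sp_rw$vectors[, 1])), 1e-6)
  }
})

test_that("PSD holds across many random graphs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    Wg <- build_weight_graph(D, t = runif(1, 0.5, 2),
                             epsilon = eps_quantile(runif(1, 0.2, 0.8)))
    dis <- 1 / sqrt(Wg$degrees)
    L <- diag(n) - outer(dis, dis) * Wg$W
    expect_gt(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("embedding separates clusters, excludes the trivial mode, and is deterministic", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  lab <- rep(1:3, each = 8)
  P <- centers[lab, ] + matrix(rnorm(48, sd = 0.4), 24, 2)
  D <- as.matrix(dist(P))
  Wg <- build_weight_graph(D, t = 4, epsilon = eps_quantile(0.3))
  sp <- laplacian_spectrum(Wg, K = 3)
  emb <- lap_embed(sp, K = 2)
  # within-cluster pairwise distances below between-cluster ones
  dd <- as.matrix(dist(emb$coords))
  same <- outer(lab, lab, "==") & upper.tri(dd)
  diff_ <- outer(lab, lab, "!=") & upper.tri(dd)
  expect_lt(max(dd[same]), min(dd[diff_]))
  # determinism
  emb2 <- lap_embed(laplacian_spectrum(Wg, K = 3), K = 2)
  expect_identical(emb$coords, emb2$coords)
  # trivial mode (constant under random-walk normalization) never appears
  sp_rw <- laplacian_spectrum(Wg, K = 2, normalization = "random_walk")
  expect_lt(diff(range(sp_rw$vectors[, sp_rw$trivial_index])), 1e-6)
  expect_error(lap_embed(sp, K = 5), "non-trivial")
})

test_that("complete-graph limit separates two discrete populations", {
  bn <- simulate_discrete_pops(2, 0.25, 25, 400, seed = 91)
  X <- normalize_genotypes(bn$genotypes)
  D <- genetic_distance(sample_correlation(X))
  Wg <- build_weight_graph(D, t = 100, epsilon = max(D) + 1)
  emb <- lap_embed(laplacian_spectrum(Wg, K = 2), K = 2)
  expect_gt(silhouette_mean(emb$coords, bn$deme_labels), 0)
})
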