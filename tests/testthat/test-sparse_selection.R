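test_that("large lambda1 kills every loading exactly", {
  set.seed(61)
  X <- matrix(rnorm(20 * 30), 20, 30)
  phi <- rnorm(20)
  l1 <- 2 * max(abs(crossprod(X, phi))) * 1.001
  fit <- fit_sparse_loadings(X, cbind(phi), l1, 0)
  expect_identical(unname(fit$V[, 1]), rep(0, 30))
  expect_equal(fit$sparsity, 1)
})

test_that("the unpenalized limit reproduces least squares", {
  set.seed(62)
  X <- matrix(rnorm(15 * 4), 15, 4)
  phi <- rnorm(15)
  fit <- fit_sparse_loadings(X, cbind(phi), 0, 0, tol = 1e-10)
  ols <- solve(crossprod(X), crossprod(X, phi))
  expect_equal(unname(fit$V[, 1]), as.vector(ols), tolerance = 1e-8)
})

test_that("orthonormal designs recover the closed-form soft threshold", {
  set.seed(63)
  X <- qr.Q(qr(matrix(rnorm(8 * 4), 8, 4)))
  Phi <- cbind(rnorm(8), rnorm(8))
  for (l1 in c(0.05, 0.2, 0.8)) {
    fit <- fit_sparse_loadings(X, Phi, l1, 0, tol = 1e-10)
    expected <- soft_thr(crossprod(X, Phi), l1 / 2)
    expect_equal(unname(fit$V), unname(expected), tolerance = 1e-8)
  }
})

test_that("coordinate descent matches a proximal-gradient oracle and beats trivial candidates", {
  set.seed(64)
  X <- matrix(rnorm(20 * 30), 20, 30)
  phi <- as.vector(X[, 1:3] %*% c(1, -2, 1.5) + rnorm(20, sd = 0.5))
  settings <- list(c(0.5, 0), c(2, 1), c(5, 5), c(0.1, 2), c(10, 0.1))
  sv <- svd(X)
  ols <- sv$v %*% ((1 / sv$d) * crossprod(sv$u, phi))  # min-norm LS solution
  for (s in settings) {
    fit <- fit_sparse_loadings(X, cbind(phi), s[1], s[2], tol = 1e-9)
    obj_cd <- enet_objective(X, phi, fit$V[, 1], s[1], s[2])
    oracle <- enet_prox_gradient(X, phi, s[1], s[2])
    obj_or <- enet_objective(X, phi, oracle, s[1], s[2])
    expect_lt(abs(obj_cd - obj_or), 1e-5)
    expect_equal(obj_cd, fit$objective[1], tolerance = 1e-8)
    # no spurious minima above the trivial candidates
    expect_lte(obj_cd, enet_objective(X, phi, rep(0, 30), s[1], s[2]) + 1e-10)
    expect_lte(obj_cd, enet_objective(X, phi, ols, s[1], s[2]) + 1e-10)
  }
})

test_that("the solution path sparsity is monotone in lambda1", {
  set.seed(65)
  X <- matrix(rnorm(25 * 40), 25, 40)
  phi <- rnorm(25)
  lmax <- lambda1_max(X, cbind(phi))
  nz <- sapply(exp(seq(log(lmax * 1e-3), log(lmax), length.out = 10)),
               function(l1) sum(fit_sparse_loadings(X, cbind(phi),
                                                    l1, l1)$V != 0))
  expect_true(all(diff(nz) <= 0))
  expect_equal(nz[10], 0)
})

test_that("coordinate descent agrees with glmnet on a shared problem", {
  skip_if_not_installed("glmnet")
  set.seed(66)
  n <- 40; m <- 25
  X <- matrix(rnorm(n * m), n, m)
  phi <- as.vector(X[, 1:2] %*% c(2, -1) + rnorm(n, sd = 0.3))
  # pure lasso: glmnet minimizes (1/2n)||y - Xb||^2 + lambda ||b||_1
  l1 <- 4
  gfit <- glmnet::glmnet(X, phi, alpha = 1, lambda = l1 / (2 * n),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-16)
  fit <- fit_sparse_loadings(X, cbind(phi), l1, 0, tol = 1e-12)
  expect_equal(unname(fit$V[, 1]), as.vector(gfit$beta), tolerance = 1e-6)
  # elastic net: glmnet scales its ridge term by the internal sd(y)
  # normalization, so compensate when mapping (lambda, alpha)
  l2 <- 2
  sy <- sd(phi) * sqrt((n - 1) / n)
  lam <- (l1 + 2 * l2 * sy) / (2 * n)
  alpha <- l1 / (l1 + 2 * l2 * sy)
  gfit2 <- glmnet::glmnet(X, phi, alpha = alpha, lambda = lam,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-16)
  fit2 <- fit_sparse_loadings(X, cbind(phi), l1, l2, tol = 1e-12)
  expect_equal(unname(fit2$V[, 1]), as.vector(gfit2$beta), tolerance = 1e-3)
})

test_that("rank statistic, ordering and tie-breaks follow the definition", {
  V <- rbind(c(1, 0), c(0, 2), c(1, 1))
  rk <- rank_markers(V, c(0.7, 0.3))
  expect_equal(rk$scores, c(0.7, 1.2, 1.0))
  expect_equal(rk$order, c(2, 3, 1))

  # zero rows score zero and rank last
  V2 <- rbind(c(0, 0), c(1, 0.5), c(0, 0))
  rk2 <- rank_markers(V2, "uniform")
  expect_equal(rk2$scores[c(1, 3)], c(0, 0))
  expect_equal(rk2$order, c(2, 1, 3))         # ties broken by index
  expect_equal(rk2$zero_fraction, 2 / 3)

  # K = 1 reduces to squared loadings
  V3 <- cbind(c(0.5, -2, 1))
  rk3 <- rank_markers(V3, "uniform")
  expect_equal(rk3$scores, c(0.25, 4, 1))
  expect_equal(rk3$order, order(-abs(V3[, 1])))

  # eigen_variance weights are 1/(1+lambda), normalized
  rk4 <- rank_markers(V, "eigen_variance", eigenvalues = c(0.2, 0.6))
  w <- (1 / c(1.2, 1.6)) / sum(1 / c(1.2, 1.6))
  expect_equal(rk4$scores, as.vector(V^2 %*% w))

  expect_error(rank_markers(V, c(1, 2, 3)), "one weight per")
  expect_error(rank_markers(V, c(0, 0)), "not all zero")
})

test_that("select_top is deterministic and guards panel size", {
  V <- cbind(c(0.3, 0.3, 0.1, 0, 0.5))
  rk <- rank_markers(V, "uniform")
  expect_equal(select_top(rk, 3), c(5, 1, 2))
  expect_warning(panel <- select_top(rk, 5), "truncating")
  expect_equal(panel, c(5, 1, 2, 3))
  expect_error(select_top(rk, 0), "positive")
  expect_equal(select_top(rk, 4), c(5, 1, 2, 3))
})

test_that("selecting every marker reproduces the full embedding exactly", {
  bn <- simulate_discrete_pops(3, 0.15, 20, 250, seed = 71)
  full <- laplacian_embedding(bn$genotypes, K = 2)
  sub <- sparse_eigenfunctions(bn$genotypes,
                               seq_len(ncol(bn$genotypes$genotypes)), K = 2)
  expect_identical(unname(full$coords), unname(sub$coords))
  expect_equal(sub$source, "sparse")
})

test_that("an informative panel beats a random panel of the same size", {
  bn <- simulate_discrete_pops(2, 0.2, 30, 1000, seed = 72)
  full <- laplacian_embedding(bn$genotypes, K = 2)
  X <- normalize_genotypes(bn$genotypes)
  tuned <- tune_lambda1(X, full, target = 120)
  panel <- X$kept_markers[select_top(rank_markers(tuned$fit), 60)]
  slap <- sparse_eigenfunctions(bn$genotypes, panel, K = 2)
  c_top <- eigenmap_correlation(full, slap)[1]
  set.seed(1)
  rnd <- sample(ncol(bn$genotypes$genotypes), 60)
  c_rnd <- eigenmap_correlation(full,
                                sparse_eigenfunctions(bn$genotypes, rnd,
                                                      K = 2))[1]
  expect_gt(c_top, c_rnd)
  expect_gt(c_top, 0.9)
})

test_that("genome_scan reduces to the direct ranking for one group and is seeded", {
  bn <- simulate_discrete_pops(2, 0.2, 25, 300, seed = 73)
  emb <- laplacian_embedding(bn$genotypes, K = 2)
  X <- normalize_genotypes(bn$genotypes)
  l1 <- 0.05 * lambda1_max(X, emb)
  direct <- rank_markers(fit_sparse_loadings(X, emb$coords, l1, l1))
  cfg <- scan_config(group_size = 1000, keep_fraction = 0.2, seed = 5)
  scan <- genome_scan(bn$genotypes, emb, cfg, l1)
  expect_equal(scan$scores[X$kept_markers], direct$scores, tolerance = 1e-12)
  expect_equal(scan$rounds, 0L)
  # determinism under a fixed seed when the scan actually partitions
  cfg2 <- scan_config(group_size = 100, keep_fraction = 0.3, seed = 9)
  s1 <- genome_scan(bn$genotypes, emb, cfg2, l1)
  s2 <- genome_scan(bn$genotypes, emb, cfg2, l1)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$order, s2$order)
})

test_that("genome_scan keeps most of the directly top-ranked markers", {
  bn <- simulate_discrete_pops(3, 0.2, 40, 2400, seed = 74)
  emb <- laplacian_embedding(bn$genotypes, K = 2)
  X <- normalize_genotypes(bn$genotypes)
  l1 <- 0.05 * lambda1_max(X, emb)
  direct <- rank_markers(fit_sparse_loadings(X, emb$coords, l1, l1))
  top_direct <- X$kept_markers[direct$order[seq_len(100)]]
  scan <- genome_scan(bn$genotypes, emb,
                      scan_config(group_size = 800, keep_fraction = 0.2,
                                  seed = 3), l1)
  top_scan <- scan$order[seq_len(100)]
  expect_gte(length(intersect(top_direct, top_scan)), 80)
})

test_that("ld-aware partitioning splits duplicated neighbors apart", {
  set.seed(75)
  g <- matrix(rbinom(40 * 60, 2, 0.4) / 2, 40, 60)
  g[, 2] <- g[, 1]            # exact duplicates at adjacent positions
  G <- make_genotypes(g)
  for (seed in 1:5) {
    set.seed(seed)
    groups <- sparselap:::partition_markers(seq_len(60), G$markers,
                                            group_size = 20, ld_aware = TRUE)
    grp_of <- rep(NA_integer_, 60)
    for (k in seq_along(groups)) grp_of[groups[[k]]] <- k
    expect_false(grp_of[1] == grp_of[2])
  }
})

test_that("PCA marker scores follow the +1/0/-1 recoding", {
  bn <- simulate_discrete_pops(2, 0.3, 100, 50, seed = 76)
  rk <- pca_marker_scores(bn$genotypes, 1)
  # brute force: the top marker carries the largest frequency contrast
  g <- bn$genotypes$genotypes
  dfreq <- abs(colMeans(g[bn$deme_labels == 1, ]) -
                 colMeans(g[bn$deme_labels == 2, ]))
  expect_equal(rk$order[1], unname(which.max(dfreq)))

  # constant marker scores zero; duplicated markers score identically
  g2 <- cbind(g[, 1:4], rep(0.5, nrow(g)), g[, 1])
  rk2 <- pca_marker_scores(make_genotypes(g2), 2)
  expect_equal(unname(rk2$scores[5]), 0, tolerance = 1e-20)
  expect_equal(unname(rk2$scores[1]), unname(rk2$scores[6]), tolerance = 1e-10)
  expect_error(pca_marker_scores(bn$genotypes, 1000), "n_pcs")
})

test_that("qr pruning drops duplicates and lowers panel redundancy", {
  set.seed(78)
  bn <- simulate_discrete_pops(2, 0.2, 60, 520, seed = 79)
  g <- bn$genotypes$genotypes
  g[, 251:500] <- g[, 1:250]     # half the candidates are exact duplicates
  G <- make_genotypes(g)
  pruned <- qr_prune(G, 1:500, 100)
  orig <- ifelse(pruned > 250, pruned - 250, pruned)
  expect_false(any(duplicated(orig)))

  # full retention on a full-rank submatrix is a permutation
  keep_all <- qr_prune(G, 501:520, 20)
  expect_setequal(keep_all, 501:520)

  # pruning cannot increase the worst pairwise r2 relative to the unpruned head
  r2max <- function(idx) {
    r <- cor(g[, idx]); max(r[upper.tri(r)]^2)
  }
  expect_lte(r2max(pruned), r2max(1:100))

  # rank-deficient requests warn and truncate
  gd <- cbind(g[, 1:3], g[, 1:3])
  expect_warning(pp <- qr_prune(make_genotypes(gd), 1:6, 5), "rank")
  expect_lte(length(pp), 4)
})

test_that("sparse selection picks block representatives where PCA picks blocks", {
  fx <- ld_block_fixture(seed = 80, n = 90, m_indep = 700, n_blocks = 25,
                         block_size = 4, noise = 0)
  G <- fx$G
  emb <- laplacian_embedding(G, K = 2)
  X <- normalize_genotypes(G)
  tuned <- tune_lambda1(X, emb, target = 120)
  q <- 25
  top_sparse <- X$kept_markers[select_top(rank_markers(tuned$fit), q)]
  top_pca <- pca_marker_scores(G, 2)$order[seq_len(q)]
  within_pairs <- function(idx) {
    b <- fx$block_id[idx]
    sum(duplicated(b[!is.na(b)]))
  }
  expect_lt(within_pairs(top_sparse), within_pairs(top_pca))
})
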