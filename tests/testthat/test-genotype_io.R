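test_that("VCF calls map to dosage fractions and bad sites are skipped", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"))
  expect_message(G <- load_genotypes(path), "2 multiallelic or non-SNP")
  expect_equal(ncol(G$genotypes), 3L)          # rs4 (multiallelic), rs5 (indel) gone
  expect_equal(unname(G$genotypes["A", ]), c(0, 0.5, 1))
  expect_equal(unname(G$genotypes["B", c("rs1", "rs2")]), c(0.5, 1))
  expect_true(is.na(G$genotypes["B", "rs3"]))
  expect_equal(G$markers$pos, c(100L, 200L, 300L))
})

test_that("TSV writer round-trips through the reader", {
  G <- random_genotypes(8, 12, seed = 11)
  G$genotypes[2, 3] <- NA
  gp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(G, gp, mp)
  G2 <- load_genotypes(gp, format = "tsv", markers_path = mp)
  expect_equal(G2$genotypes, G$genotypes)
  expect_equal(G2$sample_ids, G$sample_ids)
  expect_equal(G2$markers[c("id", "chrom", "pos")],
               G$markers[c("id", "chrom", "pos")])
})

test_that("VCF export round-trips hard calls", {
  G <- random_genotypes(5, 6, seed = 12)
  G$genotypes[1, 2] <- NA
  vp <- tempfile(fileext = ".vcf")
  write_vcf(G, vp)
  G2 <- load_genotypes(vp)
  expect_equal(unname(G2$genotypes), unname(G$genotypes))
})

test_that("qc_filter applies both rules strictly and matches a recount", {
  set.seed(99)
  # monomorphic marker removed at any maf_min >= 0
  g <- cbind(rep(0, 20), rbinom(20, 2, 0.5) / 2)
  g[1:2, 2] <- c(0, 1)
  G <- make_genotypes(g)
  kept <- qc_filter(G, maf_min = 0)
  expect_equal(kept$markers$id, "M0002")

  # 3 of 20 missing (15%) fails miss_max = 0.10
  g2 <- matrix(rbinom(40, 2, 0.4) / 2, 20, 2)
  g2[1:2, ] <- rbind(c(0, 0), c(1, 1))
  g2[1:3, 1] <- NA
  G2 <- make_genotypes(g2)
  kept2 <- qc_filter(G2, maf_min = 0, miss_max = 0.10)
  expect_equal(kept2$markers$id, "M0002")

  # hand-set frequencies against an independent recount of both rules
  freqs <- c(0.005, 0.02, 0.05, 0.009, 0.3, 0.5, 0.011, 0.8, 0.995, 0.0101)
  set.seed(42)
  g3 <- sapply(freqs, function(p) rbinom(400, 2, p) / 2)
  G3 <- make_genotypes(g3)
  kept3 <- qc_filter(G3, maf_min = 0.01, miss_max = 0.10)
  p_obs <- colMeans(g3)
  expect_brute <- which(pmin(p_obs, 1 - p_obs) > 0.01)
  expect_equal(kept3$markers$id, G3$markers$id[expect_brute])
  rep <- attr(kept3, "report")
  expect_equal(sum(rep$kept), length(expect_brute))

  # idempotence
  expect_equal(qc_filter(kept3, 0.01, 0.10)$genotypes, kept3$genotypes)

  # removing everything is an error naming the thresholds
  expect_error(qc_filter(make_genotypes(cbind(rep(0, 10), rep(1, 10)))),
               "maf_min")
})

test_that("impute_missing fills marker means and leaves the rest alone", {
  g <- cbind(c(0, NA, 1), c(0, 0.5, 1))
  G <- impute_missing(make_genotypes(g))
  expect_equal(unname(G$genotypes[, 1]), c(0, 0.5, 1))
  expect_equal(unname(G$genotypes[, 2]), c(0, 0.5, 1))

  g2 <- cbind(c(1, 1, 0.5, NA, NA), c(0, 0, 0.5, 1, 1))
  G2 <- impute_missing(make_genotypes(g2))
  expect_equal(unname(G2$genotypes[4:5, 1]), rep(2.5 / 3, 2))

  G3 <- random_genotypes(6, 4, seed = 5)
  expect_identical(impute_missing(G3)$genotypes, G3$genotypes)

  gbad <- cbind(rep(NA_real_, 4), c(0, 0.5, 1, 0))
  expect_error(impute_missing(make_genotypes(gbad)), "qc_filter")
})

test_that("posterior allele frequency follows the pseudocount formula", {
  expect_equal(posterior_allele_freq(c(0, 0.5, 1)), 0.5)
  expect_equal(posterior_allele_freq(rep(0, 4)), 0.1)
  expect_equal(posterior_allele_freq(1), 3 / 4)
  expect_error(posterior_allele_freq(NA_real_), "no observed")
  # shrinkage keeps the estimate strictly inside (0,1)
  set.seed(1)
  for (i in 1:50) {
    g <- rbinom(sample(1:30, 1), 2, runif(1)) / 2
    p <- posterior_allele_freq(g)
    expect_gt(p, 0); expect_lt(p, 1)
  }
})

test_that("normalization centers, scales by posterior frequency, drops constants", {
  set.seed(77)
  X <- normalize_genotypes(make_genotypes(cbind(c(0, 0.5, 1), c(0, 1, 1))))
  expect_equal(unname(X$X[, 1]), c(-1, 0, 1))

  # constant marker dropped and recorded
  g <- cbind(rep(0.5, 5), rbinom(5, 2, 0.5) / 2)
  g[1:2, 2] <- c(0, 1)
  Xc <- normalize_genotypes(make_genotypes(g))
  expect_equal(ncol(Xc$X), 1L)
  expect_equal(Xc$provenance$dropped_constant, "M0001")
  expect_equal(Xc$kept_markers, 2L)

  # element-wise brute force on a 5 x 8 fixture, plus centering identity
  G <- random_genotypes(5, 8, seed = 31)
  Xn <- normalize_genotypes(G)
  g5 <- G$genotypes[, Xn$kept_markers, drop = FALSE]
  for (j in seq_len(ncol(g5))) {
    p <- (1 + sum(2 * g5[, j])) / (2 + 2 * nrow(g5))
    expected <- (g5[, j] - mean(g5[, j])) / sqrt(p * (1 - p))
    expect_equal(unname(Xn$X[, j]), unname(expected), tolerance = 1e-12)
  }
  expect_lt(max(abs(colSums(Xn$X))), 1e-10)
  expect_true(all(Xn$posterior_freqs > 0 & Xn$posterior_freqs < 1))
})

test_that("normalize after impute equals normalize alone on complete data", {
  G <- random_genotypes(10, 15, seed = 8)
  expect_equal(normalize_genotypes(impute_missing(G))$X,
               normalize_genotypes(G)$X)
})

test_that("construction invariants are enforced", {
  expect_error(make_genotypes(matrix(c(0, 2), 2, 1)), "must lie in")
  expect_error(snp_genotypes(matrix(0.5, 1, 3)), "at least 2 samples")
  expect_error(snp_genotypes(matrix(c(0, 1), 2, 1),
                             sample_ids = c("a", "a")), "unique")
})
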