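# Fixtures and independent oracles shared across test files.  Everything is
# generated in code under fixed seeds; nothing is read from disk.

# --- small genotype builders -----------------------------------------------

make_genotypes <- function(g, sample_ids = NULL, chrom = NULL, pos = NULL) {
  g <- as.matrix(g)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(g)))
  markers <- data.frame(
    id = sprintf("M%04d", seq_len(ncol(g))),
    chrom = if (is.null(chrom)) rep("1", ncol(g)) else chrom,
    pos = if (is.null(pos)) seq_len(ncol(g)) * 100L else pos,
    stringsAsFactors = FALSE)
  snp_genotypes(g, sample_ids, markers)
}

# random hard-call genotype matrix with target allele frequencies
random_genotypes <- function(n, m, seed, freqs = NULL) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(m, 0.15, 0.85)
  g <- sapply(freqs, function(p) rbinom(n, 2, p) / 2)
  # re-draw monomorphic columns deterministically
  for (j in which(apply(g, 2, function(x) length(unique(x)) == 1)))
    g[1:2, j] <- c(0, 1)
  make_genotypes(g)
}

# genotypes with duplicated-marker LD blocks appended to independent loci:
# `n_blocks` blocks of `block_size` near-copies of structure-informative loci
ld_block_fixture <- function(seed = 421, n = 150, m_indep = 1800,
                             n_blocks = 60, block_size = 5, fst = 0.15,
                             noise = 0.02) {
  base <- simulate_discrete_pops(3, fst, n / 3, m_indep, seed = seed)
  g <- base$genotypes$genotypes
  set.seed(seed + 1)
  # pick informative templates: largest between-pop frequency spread
  pop <- base$deme_labels
  spread <- apply(g, 2, function(x) {
    f <- tapply(x, pop, mean); max(f) - min(f)
  })
  templates <- order(-spread)[seq_len(n_blocks)]
  blocks <- lapply(templates, function(j) {
    sapply(seq_len(block_size), function(k) {
      x <- g[, j]
      flip <- runif(n) < noise
      x[flip] <- sample(c(0, 0.5, 1), sum(flip), replace = TRUE)
      x
    })
  })
  gb <- cbind(g, do.call(cbind, blocks))
  block_id <- c(rep(NA_integer_, m_indep),
                rep(seq_len(n_blocks), each = block_size))
  list(G = make_genotypes(gb), labels = pop, block_id = block_id)
}

# --- independent oracles ----------------------------------------------------

brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

soft_thr <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# elastic-net objective
enet_objective <- function(X, y, v, lambda1, lambda2) {
  r <- y - X %*% v
  sum(r^2) + lambda1 * sum(abs(v)) + lambda2 * sum(v^2)
}

# projected (proximal) gradient descent oracle for the elastic net,
# independent of the coordinate-descent implementation under test
enet_prox_gradient <- function(X, y, lambda1, lambda2, iters = 20000) {
  L <- 2 * (svd(X, nu = 0, nv = 0)$d[1]^2 + lambda2)
  s <- 1 / L
  v <- rep(0, ncol(X)); vz <- v; tk <- 1
  for (i in seq_len(iters)) {            # FISTA
    grad <- -2 * crossprod(X, y - X %*% vz) + 2 * lambda2 * vz
    vn <- soft_thr(vz - s * grad, s * lambda1)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    vz <- vn + ((tk - 1) / tn) * (vn - v)
    v <- vn; tk <- tn
  }
  as.vector(v)
}

# mean silhouette width of a labeled point set (Euclidean)
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  sil <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# --- cached full-scale ring runs (shared by the acceptance tests) ----------

.ring_cache <- new.env(parent = emptyenv())

ring_run_cached <- function(seed, ...) {
  key <- paste0("seed", seed)
  if (is.null(.ring_cache[[key]]))
    .ring_cache[[key]] <- ring_study(seed, mantel = (seed == 1L), ...)
  .ring_cache[[key]]
}

# --- tiny text fixtures -----------------------------------------------------

write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t./.",
    "1\t400\trs4\tT\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t500\trs5\tTA\tT\t.\tPASS\t.\tGT\t0/0\t1/1"),
    path)
  path
}
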