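#' Ring-species validation study
#'
#' Runs the full simulate-and-validate workflow on the stepping-stone ring
#' with isolated outlier demes: simulate (100 ring demes + 2 outliers, 10
#' diploids per deme, 10,000 independent loci by default), embed with the
#' top two Laplacian eigenfunctions, fit sparse loadings (tuning `lambda1`
#' so that about `target_factor * n_top` markers carry a positive rank
#' statistic), select the top `n_top` markers, re-embed from the panel
#' alone, and report the sign-aligned per-dimension correlations between the
#' sparse (SLAP) and full (LAP) eigenfunctions, optionally with the Mantel
#' congruence test of the two embeddings' distance matrices and the PCA
#' contrast.
#'
#' QC is applied with `maf_min = 0`: the simulated loci are conditioned to
#' segregate, and an outlier deme of 10 diploids sits at pooled MAF just
#' below 0.01, so the default cut for real array data would remove exactly
#' the outlier-diagnostic variants the study is about.
#'
#' @param seed simulation seed.
#' @param n_top panel size (default 300).
#' @param n_demes,samples_per_deme,n_loci,migration_frac,n_outlier_demes
#'   passed to [simulate_ring()].
#' @param K embedding dimension (default 2).
#' @param target_factor lambda tuning target as a multiple of `n_top`.
#' @param mantel run the Mantel test between the LAP and SLAP pairwise
#'   distance matrices (default TRUE).
#' @param n_perm Mantel permutations.
#' @param pca also compute PC1/PC2 and the ring-recovery contrast statistics
#'   (default TRUE).
#' @return List with the simulation, both embeddings, the panel, the
#'   per-dimension `correlations`, circular ring-recovery statistics for
#'   LAP and (optionally) PCA, outlier-separation summaries, and the
#'   Mantel result.
#' @export
ring_study <- function(seed, n_top = 300L, n_demes = 100L,
                       samples_per_deme = 10L, n_loci = 10000L,
                       migration_frac = 0.1, n_outlier_demes = 2L, K = 2L,
                       target_factor = 2, mantel = TRUE, n_perm = 999L,
                       pca = TRUE) {
  sim <- simulate_ring(n_demes = n_demes, samples_per_deme = samples_per_deme,
                       n_loci = n_loci, migration_frac = migration_frac,
                       n_outlier_demes = n_outlier_demes, seed = seed)
  G <- qc_filter(sim$genotypes, maf_min = 0)
  lap <- laplacian_embedding(G, K = K)
  X <- normalize_genotypes(G)
  tuned <- tune_lambda1(X, lap, target = min(ncol(X$X), target_factor * n_top))
  ranking <- rank_markers(tuned$fit, "uniform")
  panel_kept <- select_top(ranking, n_top)
  panel <- X$kept_markers[panel_kept]
  slap <- sparse_eigenfunctions(G, panel, K = K)
  correlations <- eigenmap_correlation(lap, slap)
  ring <- !sim$is_outlier
  ring_angle <- sim$deme_angle[ring]
  circ_lap <- abs(circular_correlation(ring_angle,
                                       embedding_angle(lap)[ring]))
  out <- list(sim = sim, genotypes = G, lap = lap, slap = slap,
              panel = panel, panel_ids = G$markers$id[panel],
              lambda1 = tuned$lambda1, n_nonzero = tuned$n_nonzero,
              correlations = correlations, circ_lap = circ_lap)
  if (pca) {
    pcs <- pc_coordinates(G, 2L)
    out$circ_pca <- abs(circular_correlation(ring_angle,
                                             atan2(pcs[ring, 2], pcs[ring, 1])))
    norms <- sqrt(rowSums(pcs^2))
    out$pca_outlier_norms <- vapply(
      unique(sim$deme_labels[sim$is_outlier]),
      function(d) mean(norms[sim$deme_labels == d]), numeric(1))
    out$pca_ring_norm_q99 <- unname(quantile(norms[ring], 0.99))
    out$pcs <- pcs
  }
  # outlier separation in the LAP plane
  co <- lap$coords
  ring_pts <- co[ring, , drop = FALSE]
  nn <- as.matrix(dist(ring_pts)); diag(nn) <- Inf
  out$ring_median_nn <- median(apply(nn, 1, min))
  out$outlier_min_dist <- vapply(
    unique(sim$deme_labels[sim$is_outlier]), function(d) {
      o <- co[sim$deme_labels == d, , drop = FALSE]
      min(as.matrix(dist(rbind(o, ring_pts)))[seq_len(nrow(o)),
                                              -seq_len(nrow(o))])
    }, numeric(1))
  if (mantel)
    out$mantel <- mantel_z(as.matrix(dist(lap$coords)),
                           as.matrix(dist(slap$coords)),
                           n_perm = n_perm, seed = seed)
  out
}
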