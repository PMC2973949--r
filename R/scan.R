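#' Configuration for the stepwise whole-genome scan
#'
#' @param group_size markers per group (default 10000).
#' @param keep_fraction fraction of each group's top markers merged into the
#'   next round (default 0.1).
#' @param ld_aware if `TRUE`, markers are dealt round-robin along each
#'   chromosome in position order, so physically adjacent (high-LD) markers
#'   land in different groups; otherwise the partition is uniformly random.
#' @param max_rounds cap on merge rounds (default 10).
#' @param seed RNG seed for the random partitions.
#' @return A `scan_config` list.
#' @export
scan_config <- function(group_size = 10000L, keep_fraction = 0.1,
                        ld_aware = FALSE, max_rounds = 10L, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction >= 1)
    stop_input("keep_fraction must be in (0, 1)")
  if (group_size < 2L) stop_input("group_size must be >= 2")
  structure(list(group_size = as.integer(group_size),
                 keep_fraction = keep_fraction, ld_aware = isTRUE(ld_aware),
                 max_rounds = as.integer(max_rounds), seed = as.integer(seed)),
            class = "scan_config")
}

# Partition marker indices into groups of roughly group_size.  ld_aware deals
# markers round-robin along each chromosome (position order, ties by index),
# which places adjacent -- and duplicated -- markers in different groups.
partition_markers <- function(idx, markers, group_size, ld_aware) {
  n_groups <- max(2L, ceiling(length(idx) / group_size))
  if (ld_aware) {
    ord <- order(markers$chrom[idx], markers$pos[idx], idx)
    grp <- integer(length(idx))
    for (ch in split(seq_along(ord), markers$chrom[idx][ord]))
      grp[ord[ch]] <- (seq_along(ch) - 1L) %% n_groups + 1L
  } else {
    grp <- sample(rep_len(seq_len(n_groups), length(idx)))
  }
  split(idx, grp)
}

#' Stepwise whole-genome marker scan
#'
#' For marker sets too large to fit in one sparse regression, partitions the
#' markers into groups, fits sparse loadings against the same top
#' eigenfunctions within each group, keeps the top `keep_fraction` of each
#' group, merges the survivors and repeats until the merged set fits in one
#' group (or `max_rounds` is hit); the final ranking is fitted on the merged
#' set.  Markers eliminated along the way get score zero.  With
#' `m <= group_size` this reduces exactly to the direct ranking.
#'
#' @param G [snp_genotypes].
#' @param Phi eigenfunctions (`lap_embedding` or matrix) from the full data.
#' @param cfg [scan_config()].
#' @param lambda1,lambda2 elastic-net penalties used in every fit.
#' @param weights rank-statistic weights, see [rank_markers()].
#' @return [rank_markers()]-style `marker_ranking` over all m markers.
#' @export
genome_scan <- function(G, Phi, cfg = scan_config(), lambda1, lambda2 = lambda1,
                        weights = "uniform") {
  stopifnot(inherits(G, "snp_genotypes"), inherits(cfg, "scan_config"))
  if (inherits(Phi, "lap_embedding")) Phi <- Phi$coords
  K <- ncol(Phi)
  if (cfg$group_size < 2L * K) stop_input("group_size must be >= 2K")
  m <- ncol(G$genotypes)
  fit_scores <- function(idx) {
    Xs <- normalize_genotypes(subset_markers(G, idx))
    fit <- fit_sparse_loadings(Xs, Phi, lambda1, lambda2)
    S <- rank_markers(fit, weights)$scores
    out <- numeric(length(idx))
    out[Xs$kept_markers] <- S
    out
  }
  with_seed(cfg$seed, {
    active <- seq_len(m)
    rounds <- 0L
    while (length(active) > cfg$group_size && rounds < cfg$max_rounds) {
      rounds <- rounds + 1L
      groups <- partition_markers(active, G$markers, cfg$group_size,
                                  cfg$ld_aware)
      survivors <- unlist(lapply(groups, function(idx) {
        S <- fit_scores(idx)
        n_keep <- max(1L, ceiling(cfg$keep_fraction * length(idx)))
        idx[order(-S, idx)[seq_len(n_keep)]]
      }), use.names = FALSE)
      survivors <- sort(survivors)
      if (length(survivors) < 2L * K)
        stop_input("fewer than 2K markers survived round ", rounds,
                   "; increase keep_fraction")
      active <- survivors
    }
    S_all <- numeric(m)
    S_all[active] <- fit_scores(active)
    structure(list(scores = S_all, weights = NULL,
                   order = order(-S_all, seq_len(m)),
                   zero_fraction = mean(S_all == 0),
                   markers = G$markers, marker_ids = G$markers$id,
                   rounds = rounds, final_set = active),
              class = "marker_ranking")
  })
}
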