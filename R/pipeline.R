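#' Default run configuration
#'
#' Nested list of every tunable parameter used by the high-level commands,
#' overridable by a YAML file and/or a list of overrides (overrides win).
#'
#' @param yaml_path optional YAML config file.
#' @param overrides optional named list merged over the file values.
#' @return Nested configuration list.
#' @export
sparselap_config <- function(yaml_path = NULL, overrides = NULL) {
  cfg <- list(
    qc = list(maf_min = 0.01, miss_max = 0.10),
    distance = list(formula = "sqrt_1_minus_r"),
    kernel = list(t = 1, epsilon_quantile = 0.05, epsilon = NULL),
    spectrum = list(K = 2L, normalization = "symmetric",
                    degenerate_tol = 0.25),
    penalties = list(lambda1 = NULL, lambda2_ratio = 1),
    weights = list(mode = "uniform"),
    select = list(n_top = 300L, target_factor = 2),
    scan = list(group_size = 10000L, keep_fraction = 0.1, ld_aware = FALSE,
                max_rounds = 10L),
    evaluation = list(n_perm = 999L, n_repeats = 10L, svm_cost = 1),
    seed = 1L)
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop_input("config file not found: ", yaml_path)
    cfg <- modifyList(cfg, yaml::read_yaml(yaml_path))
  }
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

resolve_epsilon <- function(cfg) {
  if (!is.null(cfg$kernel$epsilon)) as.numeric(cfg$kernel$epsilon)
  else eps_quantile(cfg$kernel$epsilon_quantile)
}

prepare_genotypes <- function(G, cfg, apply_qc = TRUE) {
  if (!inherits(G, "snp_genotypes")) G <- load_genotypes(G)
  if (apply_qc) G <- qc_filter(G, cfg$qc$maf_min, cfg$qc$miss_max)
  impute_missing(G)
}

write_run_log <- function(out_dir, command, cfg, extra = list()) {
  log <- c(list(command = command, package_version =
                  as.character(utils::packageVersion("sparselap")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                config = cfg), extra)
  jsonlite::write_json(log, file.path(out_dir, paste0(command, "_log.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

#' Embed genotypes and write the coordinates
#'
#' QC, imputation, normalization, graph construction, Laplacian spectrum and
#' eigenmap in one call; writes `embedding.tsv` (sample_id, LAP1..LAPK), a
#' config echo and a run log to `out_dir`, plus an optional biplot PNG when
#' `labels` are given and ggplot2 is installed.
#'
#' @param G [snp_genotypes] or a genotype file path.
#' @param out_dir output directory (created if needed).
#' @param config configuration from [sparselap_config()].
#' @param labels optional per-sample labels (vector, or a 2-column TSV path
#'   `sample_id`, `label`) for the biplot coloring.
#' @param plot whether to attempt the PNG biplot (default FALSE).
#' @param apply_qc run [qc_filter()] first (default TRUE).
#' @return The `lap_embedding`, invisibly; outputs on disk.
#' @export
run_embed <- function(G, out_dir, config = sparselap_config(), labels = NULL,
                      plot = FALSE, apply_qc = TRUE) {
  if (!is.null(labels) && is.character(labels) && length(labels) == 1L &&
      !file.exists(labels))
    stop_input("labels file not found: ", labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- prepare_genotypes(G, config, apply_qc)
  emb <- laplacian_embedding(G, K = config$spectrum$K,
                             t = config$kernel$t,
                             epsilon = resolve_epsilon(config),
                             distance = config$distance$formula,
                             normalization = config$spectrum$normalization,
                             degenerate_tol = config$spectrum$degenerate_tol)
  df <- data.frame(sample_id = G$sample_ids, emb$coords,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, file.path(out_dir, "embedding.tsv"), sep = "\t",
                     quote = FALSE)
  write_run_log(out_dir, "embed", config,
                list(n_samples = nrow(emb$coords),
                     epsilon_resolved = emb$params$epsilon))
  if (plot) plot_embedding(emb, labels = resolve_labels(labels, G$sample_ids),
                           path = file.path(out_dir, "embedding.png"))
  invisible(emb)
}

resolve_labels <- function(labels, sample_ids) {
  if (is.null(labels)) return(NULL)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lt <- data.table::fread(labels, data.table = FALSE)
    labels <- lt[[2]][match(sample_ids, lt[[1]])]
  }
  labels
}

#' Select an informative-marker panel
#'
#' Fits sparse loadings of every marker on the top eigenfunctions (tuning
#' `lambda1` to yield about `target_factor * n_top` selected markers when
#' not fixed in the config), ranks markers by the weighted squared-loading
#' statistic and writes a scores TSV (rank, marker, chrom, pos, score) plus
#' a panel file (one marker id per line).  Dispatches to [genome_scan()]
#' when the marker count exceeds `scan$group_size`, and to
#' [pca_marker_scores()] (optionally followed by [qr_prune()]) when
#' `method = "pca"`.
#'
#' @param G [snp_genotypes] or path.
#' @param out_dir output directory.
#' @param config configuration list.
#' @param n_top panel size (defaults to `config$select$n_top`).
#' @param method `"sparse_lap"` (default) or `"pca"`.
#' @param n_pcs PCs for the PCA method (default `config$spectrum$K`).
#' @param qr_keep optional: after PCA scoring, QR-prune the top candidates
#'   down to this many markers.
#' @param apply_qc run QC first (default TRUE).
#' @return List with `ranking`, `panel` (indices), `panel_ids`, and for the
#'   sparse method `lambda1` and the `embedding`, invisibly.
#' @export
run_select <- function(G, out_dir, config = sparselap_config(),
                       n_top = config$select$n_top,
                       method = c("sparse_lap", "pca"),
                       n_pcs = config$spectrum$K, qr_keep = NULL,
                       apply_qc = TRUE) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- prepare_genotypes(G, config, apply_qc)
  m <- ncol(G$genotypes)
  lambda1 <- config$penalties$lambda1
  emb <- NULL
  if (method == "pca") {
    ranking <- pca_marker_scores(G, n_pcs)
  } else {
    emb <- laplacian_embedding(G, K = config$spectrum$K, t = config$kernel$t,
                               epsilon = resolve_epsilon(config),
                               distance = config$distance$formula,
                               normalization = config$spectrum$normalization,
                               degenerate_tol = config$spectrum$degenerate_tol)
    X <- normalize_genotypes(G)
    if (m > config$scan$group_size) {
      if (is.null(lambda1))
        lambda1 <- 0.01 * lambda1_max(X, emb)
      ranking <- genome_scan(G, emb,
                             scan_config(config$scan$group_size,
                                         config$scan$keep_fraction,
                                         config$scan$ld_aware,
                                         config$scan$max_rounds,
                                         config$seed),
                             lambda1 = lambda1,
                             lambda2 = config$penalties$lambda2_ratio * lambda1,
                             weights = config$weights$mode)
    } else {
      if (is.null(lambda1)) {
        target <- min(m, max(ceiling(config$select$target_factor * n_top),
                             ceiling(0.01 * m)))
        tuned <- tune_lambda1(X, emb, target,
                              lambda2_ratio = config$penalties$lambda2_ratio)
        lambda1 <- tuned$lambda1
        fit <- tuned$fit
      } else {
        fit <- fit_sparse_loadings(X, emb, lambda1,
                                   config$penalties$lambda2_ratio * lambda1)
      }
      S <- numeric(m)
      rk <- rank_markers(fit, config$weights$mode,
                         eigenvalues = emb$eigenvalues)
      S[X$kept_markers] <- rk$scores
      ranking <- structure(list(scores = S, weights = rk$weights,
                                order = order(-S, seq_len(m)),
                                zero_fraction = mean(S == 0),
                                markers = G$markers,
                                marker_ids = G$markers$id),
                           class = "marker_ranking")
    }
  }
  panel <- select_top(ranking, n_top)
  if (method == "pca" && !is.null(qr_keep))
    panel <- qr_prune(G, panel, qr_keep)
  panel_ids <- G$markers$id[panel]
  scores_df <- data.frame(rank = seq_len(m),
                          marker = G$markers$id[ranking$order],
                          chrom = G$markers$chrom[ranking$order],
                          pos = G$markers$pos[ranking$order],
                          score = ranking$scores[ranking$order],
                          stringsAsFactors = FALSE)
  data.table::fwrite(scores_df, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE)
  writeLines(panel_ids, file.path(out_dir, "panel.txt"))
  write_run_log(out_dir, "select", config,
                list(method = method, n_top = length(panel),
                     lambda1 = lambda1))
  invisible(list(ranking = ranking, panel = panel, panel_ids = panel_ids,
                 lambda1 = lambda1, embedding = emb, genotypes = G))
}

#' Validate a marker panel against the full data
#'
#' Re-embeds from the panel, and reports per-dimension eigenmap
#' correlations, the Mantel test between the two embeddings' pairwise
#' distance matrices, the panel's LD r-squared bin summary and (when labels
#' are provided) SVM membership prediction.  The report is returned and
#' written as JSON.
#'
#' @param G [snp_genotypes] or path (all markers).
#' @param panel marker ids (or a panel file path) to validate.
#' @param out_dir output directory.
#' @param config configuration list.
#' @param labels optional per-sample class labels (vector or TSV path).
#' @param apply_qc run QC first (default TRUE).
#' @return Report list, invisibly; `validation.json` on disk.
#' @export
run_validate <- function(G, panel, out_dir, config = sparselap_config(),
                         labels = NULL, apply_qc = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- prepare_genotypes(G, config, apply_qc)
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- readLines(panel)
  emb_args <- list(K = config$spectrum$K, t = config$kernel$t,
                   epsilon = resolve_epsilon(config),
                   distance = config$distance$formula,
                   normalization = config$spectrum$normalization,
                   degenerate_tol = config$spectrum$degenerate_tol)
  full <- do.call(laplacian_embedding, c(list(G), emb_args))
  sparse <- do.call(sparse_eigenfunctions, c(list(G, panel), emb_args))
  corrs <- eigenmap_correlation(full, sparse)
  D1 <- as.matrix(dist(full$coords))
  D2 <- as.matrix(dist(sparse$coords))
  mt <- mantel_z(D1, D2, n_perm = config$evaluation$n_perm,
                 seed = config$seed)
  ld <- ld_r2_summary(G, panel)
  labels <- resolve_labels(labels, G$sample_ids)
  pred <- if (!is.null(labels))
    membership_prediction(G, panel, labels, split_seed = config$seed,
                          n_repeats = config$evaluation$n_repeats,
                          cost = config$evaluation$svm_cost) else NULL
  report <- list(
    n_panel = length(panel),
    eigenmap_correlation = as.list(corrs),
    mantel = list(z_raw = mt$z_raw, z_score = mt$z_score,
                  p_value = mt$p_value, n_perm = mt$n_perm),
    ld_r2 = list(bins = ld$bins, n_undefined = ld$n_undefined,
                 n_pairs = ld$n_pairs),
    prediction = if (!is.null(pred))
      list(overall_accuracy = pred$overall_accuracy,
           per_class_error = as.list(pred$per_class_error)) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write_run_log(out_dir, "validate", config, list(n_panel = length(panel)))
  invisible(report)
}

#' Biplot of the first two embedding dimensions
#'
#' @param E `lap_embedding`.
#' @param labels optional color labels.
#' @param path optional PNG output path (requires ggplot2).
#' @return The ggplot object, or `NULL` when ggplot2 is unavailable.
#' @export
plot_embedding <- function(E, labels = NULL, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not installed; skipping plot", call. = FALSE)
    return(invisible(NULL))
  }
  co <- E$coords
  df <- data.frame(x = co[, 1], y = co[, 2],
                   label = if (is.null(labels)) "all" else as.factor(labels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = colnames(co)[1], y = colnames(co)[2], color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
  p
}
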