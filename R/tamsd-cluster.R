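#' Classify tracks by k-means on their time-averaged MSD
#'
#' Computes per-track TAMSD at lags `1..max_lag` frames, takes log10,
#' standardizes each lag column, and runs k-means with `nstart` restarts under
#' a fixed seed. The number of groups `k` is supplied by the caller — in the
#' standard workflow it is taken from [select_model()]'s selected component
#' count, never refit here. Clusters are reported in descending mean-TAMSD
#' order (cluster 1 = most mobile).
#'
#' If fewer distinct TAMSD feature vectors than `k` exist, each distinct
#' vector forms its own cluster and the remaining clusters stay empty, with a
#' warning.
#'
#' @param ts A filtered [track_tbl()].
#' @param k Number of groups (>= 1); normally `select_model(...)$selected_k`.
#' @param max_lag Number of TAMSD lags used as features (default 4).
#' @param nstart k-means restarts (default 10).
#' @param seed Integer seed for the k-means initialization.
#' @return An object of class `tamsd_clusters`: list with `labels` (tibble:
#'   track_id, cluster), `curves` (tibble: cluster, lag_frames, lag_s,
#'   mean_tamsd), `occupancy` (fractions summing to 1), `k`.
#' @export
cluster_tamsd <- function(ts, k, max_lag = 4, nstart = 10, seed = NULL) {
  if (k < 1) abort("`k` must be >= 1")
  tam <- compute_tamsd(ts, max_lag = max_lag)
  wide <- tam |>
    select("track_id", "lag_frames", "msd_um2") |>
    tidyr::pivot_wider(names_from = "lag_frames", values_from = "msd_um2",
                       names_prefix = "lag_")
  if (nrow(wide) < k) abort(sprintf("k = %d exceeds the %d clusterable tracks", k, nrow(wide)))
  feats <- log10(pmax(as.matrix(wide[, -1]), 1e-12))
  # standardize; constant columns map to 0 rather than NaN
  feats <- apply(feats, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = nrow(wide))

  uniq <- unique(feats)
  if (nrow(uniq) < k) {
    warn(sprintf("only %d distinct TAMSD profiles for k = %d; %d cluster(s) left empty",
                 nrow(uniq), k, k - nrow(uniq)))
    cl <- match(apply(feats, 1, paste, collapse = "|"),
                apply(uniq, 1, paste, collapse = "|"))
  } else {
    cl <- with_seed_if(seed, kmeans(feats, centers = k, nstart = nstart)$cluster)
  }

  labelled <- tibble(track_id = wide$track_id, raw_cluster = cl)
  mean_by_cluster <- tam |>
    inner_join(labelled, by = "track_id") |>
    group_by(.data$raw_cluster) |>
    summarise(overall = mean(.data$msd_um2))
  # relabel so cluster 1 has the largest mean TAMSD
  remap <- mean_by_cluster |>
    arrange(dplyr::desc(.data$overall)) |>
    mutate(cluster = dplyr::row_number())
  labelled <- labelled |>
    inner_join(remap[, c("raw_cluster", "cluster")], by = "raw_cluster") |>
    select("track_id", "cluster")
  curves <- tam |>
    inner_join(labelled, by = "track_id") |>
    group_by(.data$cluster, .data$lag_frames, .data$lag_s) |>
    summarise(mean_tamsd = mean(.data$msd_um2), .groups = "drop") |>
    arrange(.data$cluster, .data$lag_frames)
  occ <- labelled |>
    dplyr::count(.data$cluster) |>
    mutate(fraction = .data$n / sum(.data$n))
  occupancy <- setNames(rep(0, k), seq_len(k))
  occupancy[as.character(occ$cluster)] <- occ$fraction

  structure(list(labels = labelled, curves = curves,
                 occupancy = occupancy, k = k),
            class = "tamsd_clusters")
}

#' @export
print.tamsd_clusters <- function(x, ...) {
  cat(sprintf("TAMSD clustering: k = %d, %d tracks\n", x$k, nrow(x$labels)))
  cat("Occupancy:", paste(sprintf("%.1f%%", 100 * x$occupancy), collapse = ", "), "\n")
  invisible(x)
}
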