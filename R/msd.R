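# displacement pairs at an exact frame lag; gap-closed tracks contribute only
# pairs whose frame indices differ by exactly `lag` frames
displacement_pairs <- function(ts, lag, exclude_last_point = FALSE) {
  df <- as_tibble(ts)
  if (nrow(df) == 0) {
    return(tibble(track_id = character(), sq_um2 = numeric()))
  }
  a <- df |> select("track_id", "frame", "x_um", "y_um")
  b <- a |> mutate(frame = .data$frame - as.integer(lag)) |>
    rename(x2 = "x_um", y2 = "y_um")
  pairs <- inner_join(a, b, by = c("track_id", "frame"))
  if (exclude_last_point && nrow(pairs) > 0) {
    last <- df |> group_by(.data$track_id) |>
      summarise(last_frame = max(.data$frame))
    pairs <- pairs |> left_join(last, by = "track_id") |>
      filter(.data$frame + lag < .data$last_frame)
  }
  pairs |>
    mutate(sq_um2 = (.data$x2 - .data$x_um)^2 + (.data$y2 - .data$y_um)^2) |>
    select("track_id", "frame", "sq_um2")
}

#' Ensemble mean squared displacement
#'
#' For each lag `m = 1..max_lag` frames, averages the squared displacement
#' over all pairs of localizations within a track whose frame indices differ
#' by exactly `m` (so gap-closed tracks never contribute spurious jumps).
#' Pairs ending at a track's final localization are excluded by default to
#' avoid track-ending artifacts.
#'
#' @param ts A [track_tbl()] (normally after [filter_tracks()]).
#' @param max_lag Largest lag in frames (default 4, i.e. lags 24/48/72/96 ms
#'   at a 24 ms frame interval).
#' @param exclude_last_point Drop pairs whose second localization is the
#'   track's last (default `TRUE`).
#' @return A tibble of class `msd_curve` with columns `lag_frames`, `lag_s`,
#'   `msd_um2`, `n_pairs`; lags with no usable pairs are omitted with a
#'   warning.
#' @export
compute_msd <- function(ts, max_lag = 4, exclude_last_point = TRUE) {
  dt <- frame_interval(ts)
  rows <- purrr::map(seq_len(max_lag), function(m) {
    p <- displacement_pairs(ts, m, exclude_last_point = exclude_last_point)
    if (nrow(p) == 0) return(NULL)
    tibble(lag_frames = m, lag_s = m * dt,
           msd_um2 = mean(p$sq_um2), n_pairs = nrow(p))
  })
  empty <- purrr::map_lgl(rows, is.null)
  if (any(empty)) {
    warn(sprintf("no displacement pairs at lag(s) %s; omitted",
                 paste(which(empty), collapse = ", ")))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no displacement pairs at any requested lag")
  structure(out, class = c("msd_curve", class(out)),
            frame_interval = dt, scope = "ensemble")
}

#' Per-track time-averaged MSD
#'
#' Computes the time-averaged MSD (TAMSD) of each track at lags `1..max_lag`
#' frames, with the same exact-frame-lag pairing and last-point exclusion as
#' [compute_msd()]. Tracks too short to supply a pair at every lag are
#' excluded with a warning.
#'
#' @inheritParams compute_msd
#' @return A tibble of class `msd_curve` (per-track scope) with columns
#'   `track_id`, `lag_frames`, `lag_s`, `msd_um2`, `n_pairs`.
#' @export
compute_tamsd <- function(ts, max_lag = 4, exclude_last_point = TRUE) {
  dt <- frame_interval(ts)
  per_lag <- purrr::map(seq_len(max_lag), function(m) {
    displacement_pairs(ts, m, exclude_last_point = exclude_last_point) |>
      group_by(.data$track_id) |>
      summarise(msd_um2 = mean(.data$sq_um2), n_pairs = n()) |>
      mutate(lag_frames = m, lag_s = m * dt)
  })
  out <- bind_rows(per_lag)
  complete_ids <- out |> group_by(.data$track_id) |>
    summarise(nl = dplyr::n_distinct(.data$lag_frames)) |>
    filter(.data$nl == max_lag) |> pull("track_id")
  n_dropped <- length(setdiff(unique(as_tibble(ts)$track_id), complete_ids))
  if (n_dropped > 0) {
    warn(sprintf("%d track(s) too short for TAMSD at all %d lags; excluded",
                 n_dropped, max_lag))
  }
  out <- out |> filter(.data$track_id %in% complete_ids) |>
    select("track_id", "lag_frames", "lag_s", "msd_um2", "n_pairs") |>
    arrange(.data$track_id, .data$lag_frames)
  structure(out, class = c("msd_curve", class(out)),
            frame_interval = dt, scope = "per_track")
}

#' Linear MSD fit for the ensemble diffusion coefficient
#'
#' Ordinary least squares of `MSD = 4 * D * tau + b` over the MSD curve's
#' lags; the slope/4 estimates the diffusion coefficient of simple 2D
#' Brownian motion and the intercept `b` absorbs static localization error
#' (`b = 4 * sigma^2`).
#'
#' @param msd An ensemble `msd_curve` from [compute_msd()].
#' @return A list of class `msd_fit` with elements `d` (um^2/s), `intercept`
#'   (um^2), `stderr_d`, `r_squared`, `n_lags`, and the underlying `lm` fit.
#' @export
fit_msd_linear <- function(msd) {
  if (nrow(msd) < 2) abort("need at least 2 lags for a linear MSD fit")
  fit <- lm(msd_um2 ~ lag_s, data = msd)
  # noiseless curves fit perfectly; the summary warning for that is expected
  sm <- suppressWarnings(summary(fit))
  structure(list(d = unname(coef(fit)[2]) / 4,
                 intercept = unname(coef(fit)[1]),
                 stderr_d = sm$coefficients[2, 2] / 4,
                 r_squared = sm$r.squared,
                 n_lags = nrow(msd),
                 lm_fit = fit),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("Linear MSD fit: D = %.4g um^2/s (se %.2g), intercept = %.4g um^2, R^2 = %.4f (%d lags)\n",
              x$d, x$stderr_d, x$intercept, x$r_squared, x$n_lags))
  invisible(x)
}
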