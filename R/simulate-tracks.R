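#' Simulate 2D Brownian tracks from a static diffusive-state mixture
#'
#' Each track is assigned one diffusive state for its whole lifetime with
#' probability `fractions[i]` (a static mixture: no state switching). True
#' per-frame displacements per axis are Gaussian with variance `2 * D_i * dt`,
#' and independent Gaussian static localization error (sd `localization_sigma`
#' per axis) is added to every stored position, so the expected single-frame
#' mean square displacement of state i is `4 * D_i * dt + 4 * sigma^2`.
#'
#' Track start frames are drawn uniformly from `frame_range`, emulating
#' molecules appearing throughout an acquisition whose photobleaching window
#' has already passed; ground-truth state labels are retained in a `state`
#' column.
#'
#' @param n_tracks Number of tracks (>= 1).
#' @param d Vector of per-state diffusion coefficients, um^2/s (all >= 0).
#' @param fractions Per-state occupancy probabilities, summing to 1 within
#'   1e-9. Default: single state.
#' @param frame_interval Frame interval in seconds (default 0.024, i.e. 20 ms
#'   exposure plus transfer time).
#' @param localization_sigma Per-axis static localization error, um.
#' @param track_length Either `"geometric"` (geometric lengths with mean
#'   `mean_length`, truncated at `min_length`) or `"fixed"` (all tracks have
#'   `mean_length` frames).
#' @param mean_length Mean (or fixed) track length in frames.
#' @param min_length Minimum track length for the geometric model.
#' @param confine_radius Optional circular confinement radius, um; steps are
#'   reflected at the boundary. `NULL` (default) = free diffusion.
#' @param frame_range Integer range (inclusive) from which start frames are
#'   drawn.
#' @param condition Condition label stored on the result.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A [track_tbl()] with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `t_s` and ground-truth `state` (1-based index into `d`, ordered as given).
#' @examples
#' ts <- simulate_tracks(50, d = c(0.5, 0.01), fractions = c(0.5, 0.5), seed = 1)
#' dplyr::count(ts, state)
#' @export
simulate_tracks <- function(n_tracks, d, fractions = NULL,
                            frame_interval = 0.024,
                            localization_sigma = 0.02,
                            track_length = c("geometric", "fixed"),
                            mean_length = 12, min_length = 5,
                            confine_radius = NULL,
                            frame_range = c(500L, 9000L),
                            condition = NA_character_,
                            seed = NULL) {
  track_length <- match.arg(track_length)
  if (!is.numeric(n_tracks) || n_tracks < 1) abort("`n_tracks` must be >= 1")
  n_tracks <- as.integer(n_tracks)
  if (any(!is.finite(d)) || any(d < 0)) abort("diffusion constants must be finite and >= 0")
  k <- length(d)
  if (is.null(fractions)) fractions <- rep(1 / k, k)
  if (length(fractions) != k) abort("`fractions` must match length of `d`")
  if (any(fractions < 0)) abort("`fractions` must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1 (within 1e-9)")
  stopifnot_scalar_number(frame_interval, "frame_interval", 0, strict = TRUE)
  stopifnot_scalar_number(localization_sigma, "localization_sigma", 0)
  if (min_length < 2) abort("`min_length` must be >= 2")

  with_seed_if(seed, {
    state <- sample.int(k, n_tracks, replace = TRUE, prob = fractions)
    len <- if (track_length == "fixed") {
      rep(as.integer(mean_length), n_tracks)
    } else {
      # truncated geometric: min_length + Geom(p), mean = mean_length
      if (mean_length <= min_length) abort("`mean_length` must exceed `min_length`")
      p <- 1 / (mean_length - min_length + 1)
      as.integer(min_length + rgeom(n_tracks, p))
    }
    start_frame <- sample(seq.int(frame_range[1], frame_range[2]),
                          n_tracks, replace = TRUE)
    total <- sum(len)
    idx <- rep.int(seq_len(n_tracks), len)
    within <- sequence(len) - 1L
    first <- cumsum(c(1L, head(len, -1L)))
    step_sd <- sqrt(2 * d[state] * frame_interval)

    if (is.null(confine_radius)) {
      dx <- rnorm(total, 0, rep.int(step_sd, len))
      dy <- rnorm(total, 0, rep.int(step_sd, len))
      dx[first] <- 0; dy[first] <- 0
      csx <- cumsum(dx); csy <- cumsum(dy)
      x0 <- runif(n_tracks, 0, 5); y0 <- runif(n_tracks, 0, 5)
      x <- rep.int(x0, len) + csx - rep.int(csx[first], len)
      y <- rep.int(y0, len) + csy - rep.int(csy[first], len)
    } else {
      stopifnot_scalar_number(confine_radius, "confine_radius", 0, strict = TRUE)
      x <- numeric(total); y <- numeric(total)
      for (i in seq_len(n_tracks)) {
        L <- len[i]
        r0 <- confine_radius * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        px <- numeric(L); py <- numeric(L)
        px[1] <- r0 * cos(th); py[1] <- r0 * sin(th)
        if (L > 1) {
          sx <- rnorm(L - 1, 0, step_sd[i]); sy <- rnorm(L - 1, 0, step_sd[i])
          for (j in 2:L) {
            nx <- px[j - 1] + sx[j - 1]; ny <- py[j - 1] + sy[j - 1]
            rr <- sqrt(nx^2 + ny^2)
            if (rr > confine_radius) {      # radial reflection at the boundary
              sc <- abs(2 * confine_radius - rr) / rr
              if (sc > confine_radius / rr) sc <- confine_radius / rr
              nx <- nx * sc; ny <- ny * sc
            }
            px[j] <- nx; py[j] <- ny
          }
        }
        sel <- which(idx == i)
        x[sel] <- px; y[sel] <- py
      }
    }

    if (localization_sigma > 0) {
      x <- x + rnorm(total, 0, localization_sigma)
      y <- y + rnorm(total, 0, localization_sigma)
    }

    df <- tibble(track_id = sprintf("sim_%05d", idx),
                 frame = rep.int(start_frame, len) + within,
                 x_um = x, y_um = y,
                 state = rep.int(state, len))
    ts <- track_tbl(df, frame_interval = frame_interval, condition = condition,
                    provenance = sprintf(
                      "simulate_tracks(n=%d, k=%d, seed=%s)", n_tracks, k,
                      if (is.null(seed)) "NULL" else seed))
    ts
  })
}
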