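# Shared helpers: direct draws from the exponential-mixture model of square
# displacements, hand-built deterministic tracks, and a brute-force
# maximum-likelihood grid search used as the independent oracle for the
# least-squares CDF fits.

# draw square displacements directly from the k-state model (scales
# a_i = 4 D_i tau) and package them as an sqd_sample
draw_sqd <- function(n, a, fractions, seed, tau = 0.024) {
  set.seed(seed)
  comp <- sample.int(length(a), n, replace = TRUE, prob = fractions)
  x <- sort(stats::rexp(n, rate = 1 / a[comp]))
  structure(tibble::tibble(sq_um2 = x, cdf = seq_len(n) / n),
            class = c("sqd_sample", class(tibble::tibble())),
            lag_frames = 1L, lag_s = tau, n = n)
}

# an sqd_sample whose empirical CDF equals the model CDF exactly (noiseless)
exact_sqd <- function(a, n = 500, tau = 0.024) {
  u <- seq_len(n) / (n + 1)
  x <- -a * log(1 - u)
  structure(tibble::tibble(sq_um2 = x, cdf = 1 - exp(-x / a)),
            class = c("sqd_sample", class(tibble::tibble())),
            lag_frames = 1L, lag_s = tau, n = n)
}

# deterministic track moving `step` um per frame along x
line_track <- function(n_frames, step, frame_interval = 0.024, id = "line",
                       first_frame = 0L) {
  track_tbl(tibble::tibble(track_id = id,
                           frame = first_frame + seq_len(n_frames) - 1L,
                           x_um = step * (seq_len(n_frames) - 1),
                           y_um = 0),
            frame_interval = frame_interval)
}

# brute-force log-likelihood grid search for a 1- or 2-component exponential
# mixture; returns scales (descending) and fraction of the first component
mle_grid_search <- function(x, k, n_grid = 80, f_step = 0.02) {
  m <- mean(x)
  a_grid <- exp(seq(log(m / 500), log(m * 5), length.out = n_grid))
  if (k == 1) {
    ll <- vapply(a_grid, function(a) sum(stats::dexp(x, 1 / a, log = TRUE)),
                 numeric(1))
    return(list(a = a_grid[which.max(ll)], f = 1,
                log_step = log(a_grid[2] / a_grid[1])))
  }
  stopifnot(k == 2)
  dens <- exp(-outer(x, 1 / a_grid)) / rep(a_grid, each = length(x))
  f_grid <- seq(f_step, 1 - f_step, by = f_step)
  best <- list(ll = -Inf)
  for (i in seq_len(n_grid - 1)) {
    for (j in seq((i + 1), n_grid)) {
      di <- dens[, i]; dj <- dens[, j]
      for (f in f_grid) {
        ll <- sum(log(f * dj + (1 - f) * di))
        if (ll > best$ll) best <- list(ll = ll, a = c(a_grid[j], a_grid[i]), f = f)
      }
    }
  }
  list(a = best$a, f = best$f, log_step = log(a_grid[2] / a_grid[1]))
}

# printed 1:1 kinetic parameter sets (ka in 1/(M s), kd in 1/s, KD in uM)
binding_param_sets <- function() {
  tibble::tribble(
    ~pair,        ~ka,     ~kd,   ~kd_um,
    "kite-kleisin", 7.42e4, 0.16,  2.17,
    "smc-kleisin",  2.78e4, 0.138, 4.94,
    "nuclease-kleisin", 2.25e4, 0.136, 6
  )
}
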