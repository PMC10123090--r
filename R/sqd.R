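#' Pooled square displacements and their empirical CDF
#'
#' Pools the squared displacements at a single frame lag across all tracks,
#' sorts them, and attaches the empirical CDF (`rank / n`). This is the input
#' of the diffusive-state mixture decomposition: under a static mixture of 2D
#' Brownian states the square displacement at lag `tau` is exponentially
#' distributed within each state with mean `4 * D_i * tau` (plus `4 * sigma^2`
#' localization-error offset).
#'
#' @param ts A filtered [track_tbl()].
#' @param lag Lag in frames (default 1); only pairs whose frame indices differ
#'   by exactly `lag` contribute, so gap-closed pairs are never counted.
#' @return A tibble of class `sqd_sample` with columns `sq_um2` (sorted
#'   ascending) and `cdf`; attributes `lag_frames`, `lag_s`, `n`.
#' @export
compute_sqd <- function(ts, lag = 1) {
  dt <- frame_interval(ts)
  p <- displacement_pairs(ts, lag, exclude_last_point = FALSE)
  n <- nrow(p)
  if (n == 0) abort("no displacements at the requested lag")
  if (n < 100) warn(sprintf("only %d displacements: mixture fits will be unreliable", n))
  x <- sort(p$sq_um2)
  out <- tibble(sq_um2 = x, cdf = seq_len(n) / n)
  structure(out, class = c("sqd_sample", class(out)),
            lag_frames = lag, lag_s = lag * dt, n = n)
}

# mixture CDF of square displacements: F(x) = 1 - sum_i f_i exp(-x / a_i),
# a_i = 4 D_i tau + 4 sigma_eff^2
sqd_model_cdf <- function(x, d, fractions, tau, sigma_eff = 0) {
  a <- 4 * d * tau + 4 * sigma_eff^2
  1 - colSums(fractions * exp(-outer(1 / pmax(a, 1e-300), x)))
}

# theta = (log a_1..k, logit-weights w_1..k-1); softmax fractions
sqd_unpack <- function(theta, k) {
  a <- exp(theta[seq_len(k)])
  if (k == 1) return(list(a = a, f = 1))
  w <- c(theta[(k + 1):(2 * k - 1)], 0)
  e <- exp(w - max(w))
  list(a = a, f = e / sum(e))
}

sqd_rss <- function(theta, x, ecdf, k) {
  p <- sqd_unpack(theta, k)
  pred <- 1 - as.vector(exp(-x %*% t(1 / p$a)) %*% p$f)
  sum((pred - ecdf)^2)
}

# rank-decimated evaluation grid: keeps the exact (x_(r), r/n) pairs at
# ~`m` equally spaced ranks so optimization cost is independent of n
sqd_grid <- function(x, ecdf, m) {
  n <- length(x)
  if (n <= m) return(list(x = cbind(x), ecdf = ecdf))
  idx <- unique(round(seq(1, n, length.out = m)))
  list(x = cbind(x[idx]), ecdf = ecdf[idx])
}

# quantile-block starting values: split the sorted sample into k rank blocks
# and use block means as exponential scales, equal fractions
sqd_starts <- function(x, k, n_starts, seed) {
  n <- length(x)
  blocks <- split(x, cut(seq_len(n), k, labels = FALSE))
  a0 <- pmax(purrr::map_dbl(blocks, mean), 1e-12)
  base <- c(log(a0), rep(0, k - 1))
  starts <- list(base)
  if (n_starts > 1) {
    extra <- with_seed_if(seed, purrr::map(seq_len(n_starts - 1), function(i) {
      base + c(rnorm(k, 0, 1.2), rnorm(k - 1, 0, 0.7))
    }))
    starts <- c(starts, extra)
  }
  starts
}

#' Fit a k-component exponential mixture to the SQD empirical CDF
#'
#' Least-squares fit of
#' `F(x) = 1 - sum_i f_i * exp(-x / (4 * D_i * tau + 4 * sigma_eff^2))`
#' to the empirical CDF of pooled square displacements, with the fractions
#' constrained to sum to 1 by a softmax parameterization and `D_i >= 0` by a
#' log parameterization. Optimization is multi-start Nelder-Mead (quantile
#' block starts plus perturbed restarts; `k = 1` uses 1-D golden-section
#' search) followed by a BFGS polish. The BIC of the Gaussian-residual form
#' `n * log(rss / n) + n_params * log(n)` is attached for model selection.
#'
#' @param sqd An `sqd_sample` from [compute_sqd()].
#' @param k Number of diffusive states (1-3 in practice).
#' @param fixed_d Optional vector of `k` diffusion coefficients to hold fixed;
#'   only the fractions are then fitted (`n_params = k - 1`).
#' @param sigma_eff Shared static localization error entering every component
#'   as a `4 * sigma_eff^2` offset; fixed, default 0.
#' @param n_starts Number of optimizer starts (default 8).
#' @param seed Seed for the perturbed restarts.
#' @param grid_points Maximum number of rank-decimated empirical-CDF points
#'   the optimizer evaluates (default 1000; the exact `(x, rank/n)` pairs at
#'   equally spaced ranks are kept, so no smoothing is involved). The
#'   reported `rss` and `bic` are always recomputed on the full sample.
#' @return An object of class `sqd_mixture_fit`: a list with `k`, `d`
#'   (um^2/s, sorted descending), `fractions` (same order, summing to 1),
#'   `labels` (`"fast mobile"`, `"slow mobile"`, `"immobile"` by descending D),
#'   `rss`, `n`, `n_params`, `bic`, `lag_s`, `sigma_eff`, `convergence`.
#' @examples
#' ts <- simulate_tracks(300, d = c(0.5, 0.01), fractions = c(0.6, 0.4),
#'                       localization_sigma = 0, seed = 1)
#' fit <- fit_sqd_mixture(compute_sqd(ts), k = 2, seed = 1)
#' tidy(fit)
#' @export
fit_sqd_mixture <- function(sqd, k, fixed_d = NULL, sigma_eff = 0,
                            n_starts = 8, seed = NULL, grid_points = 1000) {
  if (!inherits(sqd, "sqd_sample")) abort("`sqd` must come from compute_sqd()")
  if (k < 1) abort("`k` must be >= 1")
  x <- sqd$sq_um2
  ecdf <- sqd$cdf
  n <- attr(sqd, "n")
  tau <- attr(sqd, "lag_s")
  off <- 4 * sigma_eff^2

  if (!is.null(fixed_d)) {
    if (length(fixed_d) != k) abort("`fixed_d` must have length k")
    a_fix <- 4 * fixed_d * tau + off
    if (k == 1) {
      pred <- 1 - exp(-x / a_fix)
      rss <- sum((pred - ecdf)^2)
      return(new_sqd_fit(fixed_d, 1, rss, n, k - 1, tau, sigma_eff, 0L))
    }
    obj <- function(w) {
      e <- exp(c(w, 0) - max(c(w, 0)))
      f <- e / sum(e)
      pred <- 1 - colSums(f * exp(-outer(1 / a_fix, x)))
      sum((pred - ecdf)^2)
    }
    op <- optim(rep(0, k - 1), obj, method = if (k == 2) "BFGS" else "BFGS")
    e <- exp(c(op$par, 0) - max(c(op$par, 0)))
    return(new_sqd_fit(fixed_d, e / sum(e), op$value, n, k - 1, tau,
                       sigma_eff, op$convergence))
  }

  if (k == 1) {
    # single exponential: 1-D search over log-scale, then polish
    obj1 <- function(la) sum((1 - exp(-x / exp(la)) - ecdf)^2)
    lo <- log(max(min(x[x > 0], na.rm = TRUE) / 10, 1e-12))
    hi <- log(max(mean(x) * 100, 1e-10))
    op <- optimize(obj1, c(lo, hi), tol = 1e-12)
    la <- optim(op$minimum, obj1, method = "BFGS",
                control = list(reltol = 1e-14))
    a <- exp(la$par)
    d <- max((a - off) / (4 * tau), 0)
    return(new_sqd_fit(d, 1, la$value, n, 1L, tau, sigma_eff, la$convergence))
  }

  g <- sqd_grid(x, ecdf, grid_points)
  starts <- sqd_starts(x, k, n_starts, seed)
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      optim(s, sqd_rss, x = g$x, ecdf = g$ecdf, k = k, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) abort("SQD mixture fit failed to converge from any start")
  polish <- tryCatch(
    optim(best$par, sqd_rss, x = g$x, ecdf = g$ecdf, k = k, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish

  p <- sqd_unpack(best$par, k)
  d <- pmax((p$a - off) / (4 * tau), 0)
  rss_full <- sqd_rss(best$par, cbind(x), ecdf, k)
  new_sqd_fit(d, p$f, rss_full, n, 2L * k - 1L, tau, sigma_eff,
              best$convergence)
}

new_sqd_fit <- function(d, fractions, rss, n, n_params, tau, sigma_eff,
                        convergence) {
  ord <- order(d, decreasing = TRUE)
  d <- unname(d[ord])
  fractions <- unname(fractions[ord])
  k <- length(d)
  labels <- c("fast mobile", "slow mobile", "immobile")[seq_len(min(k, 3))]
  if (k > 3) labels <- c(labels, paste0("component ", 4:k))
  bic <- if (rss > 0) n * log(rss / n) + n_params * log(n) else -Inf
  structure(list(k = k, d = d, fractions = fractions, labels = labels,
                 rss = rss, n = n, n_params = n_params, bic = bic,
                 lag_s = tau, sigma_eff = sigma_eff,
                 convergence = convergence),
            class = "sqd_mixture_fit")
}

#' @export
print.sqd_mixture_fit <- function(x, ...) {
  cat(sprintf("SQD mixture fit: k = %d, n = %d, rss = %.3g, BIC = %.4g\n",
              x$k, x$n, x$rss, x$bic))
  for (i in seq_len(x$k)) {
    cat(sprintf("  %-11s D = %.4g um^2/s, fraction = %.1f%%\n",
                x$labels[i], x$d[i], 100 * x$fractions[i]))
  }
  invisible(x)
}
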