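#' Global SQD fit with shared diffusion constants across conditions
#'
#' Minimizes the summed CDF residual sum of squares over several conditions
#' with one shared vector of k diffusion constants and condition-specific
#' fraction vectors, so population fractions can be compared directly between
#' conditions (e.g. wild type vs mutants). All samples must share the same
#' lag time. With a single condition this reduces exactly to
#' [fit_sqd_mixture()].
#'
#' @param samples Named list of `sqd_sample` objects (>= 1 condition), all at
#'   the same lag.
#' @param k Number of shared diffusive states.
#' @param sigma_eff,n_starts,seed As in [fit_sqd_mixture()].
#' @return An object of class `sqd_global_fit`: list with shared `d` (sorted
#'   descending), `fractions` (tibble: condition, label, d, fraction),
#'   `rss_by_condition`, `total_rss`, `k`, `lag_s`.
#' @export
global_fit_sqd <- function(samples, k, sigma_eff = 0, n_starts = 8,
                           seed = NULL) {
  if (!is.list(samples) || length(samples) == 0) {
    abort("`samples` must be a non-empty list of sqd_sample objects")
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("condition_", seq_along(samples))
  }
  taus <- purrr::map_dbl(samples, attr, "lag_s")
  if (max(taus) - min(taus) > 1e-12) {
    abort("all conditions must be sampled at the same lag time")
  }
  tau <- taus[[1]]
  nc <- length(samples)

  if (nc == 1) {
    fit <- fit_sqd_mixture(samples[[1]], k, sigma_eff = sigma_eff,
                           n_starts = n_starts, seed = seed)
    return(structure(list(
      d = fit$d,
      fractions = tibble(condition = names(samples)[1], label = fit$labels,
                         d = fit$d, fraction = fit$fractions),
      rss_by_condition = setNames(fit$rss, names(samples)[1]),
      total_rss = fit$rss, k = k, lag_s = tau,
      condition_fits = setNames(list(fit), names(samples))),
      class = "sqd_global_fit"))
  }

  xs <- purrr::map(samples, ~ .x$sq_um2)
  es <- purrr::map(samples, ~ .x$cdf)
  grids <- purrr::map2(xs, es, sqd_grid, m = 1000)
  off <- 4 * sigma_eff^2
  nw <- if (k > 1) k - 1 else 0

  # theta = (log a_1..k, then per-condition softmax weights); evaluated on
  # rank-decimated grids, final rss reported on the full samples
  objective <- function(theta) {
    a <- exp(theta[seq_len(k)])
    tot <- 0
    for (ci in seq_len(nc)) {
      f <- if (k == 1) 1 else {
        w <- c(theta[k + (ci - 1) * nw + seq_len(nw)], 0)
        e <- exp(w - max(w))
        e / sum(e)
      }
      g <- grids[[ci]]
      pred <- 1 - as.vector(exp(-g$x %*% t(1 / a)) %*% f)
      tot <- tot + sum((pred - g$ecdf)^2)
    }
    tot
  }

  # start from per-condition individual fits: average log-scales, keep each
  # condition's own fractions
  ind <- purrr::map(samples, fit_sqd_mixture, k = k, sigma_eff = sigma_eff,
                    n_starts = n_starts, seed = seed)
  a_start <- exp(rowMeans(purrr::map_dfc(
    ind, ~ log(pmax(4 * .x$d * tau + off, 1e-12)))))
  w_start <- unlist(purrr::map(ind, function(fit) {
    if (k == 1) return(numeric(0))
    f <- pmax(fit$fractions, 1e-6)
    log(f[-k] / f[k])
  }))
  base <- c(log(a_start), w_start)
  starts <- list(base)
  if (n_starts > 1) {
    starts <- c(starts, with_seed_if(seed, purrr::map(
      seq_len(min(n_starts, 4) - 1),
      ~ base + rnorm(length(base), 0, 0.5))))
  }
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      optim(s, objective, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) abort("global SQD fit failed to converge")
  polish <- tryCatch(
    optim(best$par, objective, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish

  a <- unname(exp(best$par[seq_len(k)]))
  d <- pmax((a - off) / (4 * tau), 0)
  ord <- order(d, decreasing = TRUE)
  labels <- c("fast mobile", "slow mobile", "immobile")[seq_len(min(k, 3))]
  if (k > 3) labels <- c(labels, paste0("component ", 4:k))

  frac_rows <- list(); rss_c <- numeric(nc)
  for (ci in seq_len(nc)) {
    f <- if (k == 1) 1 else {
      w <- c(best$par[k + (ci - 1) * nw + seq_len(nw)], 0)
      e <- exp(w - max(w))
      e / sum(e)
    }
    pred <- 1 - colSums(f * exp(-outer(1 / a, xs[[ci]])))
    rss_c[ci] <- sum((pred - es[[ci]])^2)
    frac_rows[[ci]] <- tibble(condition = names(samples)[ci],
                              label = labels, d = d[ord],
                              fraction = unname(f[ord]))
  }
  structure(list(d = d[ord],
                 fractions = bind_rows(frac_rows),
                 rss_by_condition = setNames(rss_c, names(samples)),
                 total_rss = sum(rss_c), k = k, lag_s = tau),
            class = "sqd_global_fit")
}

#' @export
print.sqd_global_fit <- function(x, ...) {
  cat(sprintf("Global SQD fit: k = %d shared states, %d condition(s), total rss = %.3g\n",
              x$k, length(x$rss_by_condition), x$total_rss))
  cat("Shared D (um^2/s):", paste(signif(x$d, 4), collapse = ", "), "\n")
  print(x$fractions)
  invisible(x)
}
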