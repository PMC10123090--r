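#' Verify an SQD mixture fit against the jump-distance distribution
#'
#' Histograms the jump distances (per-frame step lengths) at the fit's lag
#' and overlays the Rayleigh-mixture density implied by the fitted CDF model,
#' `p(r) = sum_i f_i * (2 r / a_i) * exp(-r^2 / a_i)` with
#' `a_i = 4 * D_i * tau + 4 * sigma_eff^2`. Parameters are held fixed at the
#' fitted values: the result is a goodness report, not a refit. Bins use the
#' Freedman-Diaconis rule by default; empty bins are merged into their
#' neighbours so the chi-square statistic is well defined.
#'
#' @param ts The [track_tbl()] the fit was made on.
#' @param fit An `sqd_mixture_fit`.
#' @param lag Frame lag (must match the fit's lag).
#' @param breaks Histogram rule (passed to [graphics::hist()] breaks
#'   computation): `"FD"` (default), `"Sturges"`, a number of bins, or a
#'   vector of break points.
#' @return An object of class `jump_distance_report`: list with `bins`
#'   (tibble: r_lo, r_um, r_hi, count, expected, density, predicted_density),
#'   `chi2`, `df`, `r_squared`, `n`.
#' @export
fit_jump_distance <- function(ts, fit, lag = 1, breaks = "FD") {
  if (!inherits(fit, "sqd_mixture_fit")) abort("`fit` must be an sqd_mixture_fit")
  tau <- lag * frame_interval(ts)
  if (abs(tau - fit$lag_s) > 1e-12) {
    abort("`lag` does not match the lag of the mixture fit")
  }
  p <- displacement_pairs(ts, lag, exclude_last_point = FALSE)
  r <- sqrt(p$sq_um2)
  n <- length(r)
  if (n == 0) abort("no displacements at the requested lag")

  br <- if (is.character(breaks)) {
    if (toupper(breaks) == "FD") {
      h <- 2 * stats::IQR(r) / n^(1 / 3)
      if (h <= 0) h <- diff(range(r)) / 30
      seq(0, max(r) + h, by = h)
    } else {
      pretty(range(r), n = grDevices::nclass.Sturges(r))
    }
  } else if (length(breaks) == 1) {
    seq(0, max(r), length.out = breaks + 1)
  } else breaks
  counts <- graphics::hist(r, breaks = br, plot = FALSE)$counts

  a <- 4 * fit$d * tau + 4 * fit$sigma_eff^2
  # P(bin) from the exponential CDF of r^2
  cdf_r <- function(q) 1 - colSums(fit$fractions * exp(-outer(1 / pmax(a, 1e-300), q^2)))
  prob <- diff(cdf_r(br))

  # merge empty observed bins into the previous non-empty bin
  grp <- cumsum(c(TRUE, counts[-length(counts)] > 0))
  mcount <- as.numeric(tapply(counts, grp, sum))
  mprob <- as.numeric(tapply(prob, grp, sum))
  mlo <- as.numeric(tapply(br[-length(br)], grp, min))
  mhi <- as.numeric(tapply(br[-1], grp, max))
  if (length(mcount) < 5) abort("fewer than 5 usable jump-distance bins")

  expected <- n * mprob
  keep <- expected > 0
  chi2 <- sum((mcount[keep] - expected[keep])^2 / expected[keep])
  width <- mhi - mlo
  dens <- mcount / (n * width)
  pred_dens <- mprob / width
  ss_res <- sum((dens - pred_dens)^2)
  ss_tot <- sum((dens - mean(dens))^2)
  r2 <- 1 - ss_res / ss_tot

  structure(list(
    bins = tibble(r_lo = mlo, r_um = (mlo + mhi) / 2, r_hi = mhi,
                  count = mcount, expected = expected,
                  density = dens, predicted_density = pred_dens),
    chi2 = chi2, df = sum(keep) - 1L, r_squared = r2, n = n),
    class = "jump_distance_report")
}

#' @export
print.jump_distance_report <- function(x, ...) {
  cat(sprintf("Jump-distance goodness report: %d jumps, %d bins, chi^2 = %.3g (df %d), R^2 = %.4f\n",
              x$n, nrow(x$bins), x$chi2, x$df, x$r_squared))
  invisible(x)
}
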