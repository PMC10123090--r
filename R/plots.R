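#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot an MSD curve with its linear fit
#' @param object An `msd_curve` from [compute_msd()].
#' @param fit Optional `msd_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$lag_s, y = .data$msd_um2)) +
    geom_point(size = 2) +
    labs(x = expression(tau ~ "(s)"), y = expression(MSD ~ (mu * m^2)),
         title = "Mean squared displacement") +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + geom_abline(intercept = fit$intercept, slope = 4 * fit$d,
                         linetype = 2)
  }
  p
}

#' Plot the empirical SQD CDF with a fitted mixture model
#' @param object An `sqd_sample` from [compute_sqd()].
#' @param fit Optional `sqd_mixture_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.sqd_sample <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$sq_um2, y = .data$cdf)) +
    geom_line() +
    labs(x = expression("square displacement" ~ (mu * m^2)),
         y = "cumulative probability",
         title = "SQD empirical CDF") +
    theme_minimal()
  if (!is.null(fit)) {
    xg <- seq(0, max(object$sq_um2), length.out = 400)
    pred <- tibble(sq_um2 = xg,
                   cdf = sqd_model_cdf(xg, fit$d, fit$fractions,
                                       fit$lag_s, fit$sigma_eff))
    p <- p + geom_line(data = pred, colour = "red", linetype = 2)
  }
  p
}

#' Plot a jump-distance histogram against the model prediction
#' @param object A `jump_distance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.jump_distance_report <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$r_um)) +
    geom_col(aes(y = .data$density), width = object$bins$r_hi - object$bins$r_lo,
             fill = "grey80", colour = "grey40") +
    geom_line(aes(y = .data$predicted_density), colour = "red") +
    labs(x = expression("jump distance" ~ (mu * m)), y = "density",
         title = sprintf("Jump distances vs fitted mixture (R² = %.3f)",
                         object$r_squared)) +
    theme_minimal()
}

#' Plot a sensorgram with its 1:1 fit
#' @param object A `sensorgram`.
#' @param fit Optional `binding_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.sensorgram <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$t_s, y = .data$response,
                          colour = .data$phase)) +
    geom_point(size = 0.4) +
    labs(x = "time (s)", y = "response", title = "Sensorgram") +
    theme_minimal()
  if (!is.null(fit)) {
    assoc <- object[object$phase == "association", ]
    dis <- object[object$phase == "dissociation", ]
    ta <- assoc$t_s - assoc$t_s[1]
    td <- dis$t_s - dis$t_s[1]
    pred <- rbind(
      tibble(t_s = assoc$t_s, phase = "association",
             response = fit$association$y0 +
               fit$association$a * (1 - exp(-fit$kobs * ta))),
      tibble(t_s = dis$t_s, phase = "dissociation",
             response = fit$dissociation$y0 +
               fit$dissociation$a * exp(-fit$kd * td)))
    p <- p + geom_line(data = pred, colour = "black", linetype = 2)
  }
  p
}

#' Plot a rate table with its Hill fit
#' @param object A `rate_table`.
#' @param fit Optional `hill_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.rate_table <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$substrate_mM, y = .data$rate)) +
    geom_point() +
    labs(x = "[ATP] (mM)", y = "rate (nmol/min)",
         title = "ATPase substrate titration") +
    theme_minimal()
  if (!is.null(fit)) {
    sg <- seq(0, max(object$substrate_mM), length.out = 200)
    pred <- tibble(substrate_mM = sg,
                   rate = fit$vmax * sg^fit$n_h /
                     (fit$k_half^fit$n_h + sg^fit$n_h))
    p <- p + geom_line(data = pred, colour = "red")
  }
  p
}

#' Plot per-cluster mean TAMSD curves
#' @param object A `tamsd_clusters` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.tamsd_clusters <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$lag_s, y = .data$mean_tamsd,
             colour = factor(.data$cluster))) +
    geom_line() + geom_point() +
    labs(x = expression(tau ~ "(s)"), y = expression(TAMSD ~ (mu * m^2)),
         colour = "cluster", title = "Mean TAMSD per cluster") +
    theme_minimal()
}
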