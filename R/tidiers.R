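#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname sptmix-tidiers
#' @title Broom-style tidiers for sptmix fit objects
#' @description `tidy()` returns one row per estimated component or
#'   parameter; `glance()` returns a one-row model summary.
#' @param x A fitted object (`sqd_mixture_fit`, `sqd_model_selection`,
#'   `sqd_global_fit`, `msd_fit`, `binding_fit`, `hill_fit`,
#'   `tamsd_clusters`).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method
tidy.sqd_mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), label = x$labels,
         d = x$d, fraction = x$fractions)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.sqd_mixture_fit <- function(x, ...) {
  tibble(k = x$k, rss = x$rss, bic = x$bic, n = x$n,
         n_params = x$n_params, lag_s = x$lag_s)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.sqd_model_selection <- function(x, ...) x$comparisons

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.sqd_model_selection <- function(x, ...) {
  tibble(selected_k = x$selected_k, alpha = x$alpha, bic_drop = x$bic_drop,
         k_fitted = length(x$fits))
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.sqd_global_fit <- function(x, ...) x$fractions

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.sqd_global_fit <- function(x, ...) {
  tibble(k = x$k, n_conditions = length(x$rss_by_condition),
         total_rss = x$total_rss, lag_s = x$lag_s)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.msd_fit <- function(x, ...) {
  tibble(term = c("d", "intercept"),
         estimate = c(x$d, x$intercept),
         std.error = c(x$stderr_d, summary(x$lm_fit)$coefficients[1, 2]))
}

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.msd_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_lags = x$n_lags)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("ka", "kd", "kobs", "KD"),
         estimate = c(x$ka, x$kd, x$kobs, x$KD),
         unit = c("1/(M s)", "1/s", "1/s", "M"))
}

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.binding_fit <- function(x, ...) {
  tibble(KD_uM = x$KD_uM, chi2 = x$chi2, r_squared = x$r_squared,
         analyte_conc = x$analyte_conc)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.hill_fit <- function(x, ...) {
  terms <- c("vmax", "k_half", "n_h")
  est <- c(x$vmax, x$k_half, x$n_h)
  se <- rep(NA_real_, 3)
  nm <- c(vmax = "vmax", khalf = "k_half", nh = "n_h")
  got <- nm[names(x$stderrs)]
  se[match(got, terms)] <- unname(x$stderrs)
  tibble(term = terms, estimate = est, std.error = se)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
glance.hill_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, fixed_nh = x$fixed_nh)
}

#' @rdname sptmix-tidiers
#' @exportS3Method
tidy.tamsd_clusters <- function(x, ...) {
  tibble(cluster = seq_len(x$k),
         occupancy = unname(x$occupancy))
}
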