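#' Hydrolysis rates from plate time courses, control-corrected
#'
#' For each well, the initial linear phase is located by sliding a window of
#' `window` points along the time course and keeping the window with maximal
#' R^2 of the linear regression; the regression slope over that window is the
#' raw rate. Rates of the control series (ATP auto-hydrolysis and no-substrate
#' control) are computed the same way and subtracted from every sample rate.
#' Corrected rates may legitimately come out negative when a sample's
#' activity is below the controls' (at the detection limit); they are retained
#' and flagged, never clipped.
#'
#' @param timecourses Data frame with columns `id`, `role` (one of
#'   `"sample"`, `"auto_hydrolysis"`, `"no_substrate"`), `substrate_mM`
#'   (samples only; controls may be NA), `time_min`, `value` (released
#'   phosphate, nmol). All series must share the time grid.
#' @param window Sliding-window length in points; default the full course
#'   (a single global regression). Must be >= 3.
#' @return A tibble of class `rate_table` with one row per sample well:
#'   `id`, `substrate_mM`, `replicate`, `rate` (corrected, nmol/min),
#'   `rate_raw`, `negative` (flag).
#' @export
preprocess_rates <- function(timecourses, window = NULL) {
  req <- c("id", "role", "time_min", "value")
  missing_cols <- setdiff(req, names(timecourses))
  if (length(missing_cols) > 0) {
    abort(sprintf("timecourses missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  grids <- timecourses |> group_by(.data$id) |>
    summarise(g = paste(signif(sort(.data$time_min), 10), collapse = ","))
  if (length(unique(grids$g)) > 1) abort("all time courses must share one time grid")

  slope_of <- function(df) {
    df <- arrange(df, .data$time_min)
    np <- nrow(df)
    w <- if (is.null(window)) np else as.integer(window)
    if (w < 3) abort("regression window must span at least 3 points")
    if (w > np) abort("regression window longer than the time course")
    best <- NULL
    for (s in seq_len(np - w + 1)) {
      seg <- df[s:(s + w - 1), ]
      f <- lm(value ~ time_min, data = seg)
      r2 <- suppressWarnings(summary(f)$r.squared)
      if (is.nan(r2)) r2 <- 0
      if (is.null(best) || r2 > best$r2) best <- list(r2 = r2, slope = unname(coef(f)[2]))
    }
    best$slope
  }

  rates <- timecourses |>
    group_by(.data$id, .data$role,
             substrate_mM = if ("substrate_mM" %in% names(timecourses))
               .data$substrate_mM else NA_real_) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(rate_raw = purrr::map_dbl(.data$data, slope_of)) |>
    select(-"data")

  # one mean rate per control role, summed (auto-hydrolysis + no-substrate)
  ctrl_tbl <- rates |> filter(.data$role != "sample") |>
    group_by(.data$role) |> summarise(r = mean(.data$rate_raw))
  ctrl <- sum(ctrl_tbl$r)
  out <- rates |>
    filter(.data$role == "sample") |>
    mutate(rate = .data$rate_raw - ctrl,
           negative = .data$rate < 0) |>
    group_by(.data$substrate_mM) |>
    mutate(replicate = dplyr::row_number()) |>
    ungroup() |>
    select("id", "substrate_mM", "replicate", "rate", "rate_raw", "negative")
  if (any(out$negative)) {
    warn(sprintf("%d corrected rate(s) are negative (activity below controls); retained and flagged",
                 sum(out$negative)))
  }
  structure(out, class = c("rate_table", class(out)),
            control_rate = ctrl)
}

#' Fit the Hill equation to a rate table
#'
#' Least-squares fit of `v = vmax * S^n_h / (k_half^n_h + S^n_h)`; with
#' `fix_nh = 1` this is the Michaelis-Menten model with `Km = k_half`.
#' Starting values come from the data (`vmax` from the top of the curve,
#' `k_half` from the substrate level nearest half-max).
#'
#' @param rates A `rate_table` (or any data frame with `substrate_mM` and
#'   `rate`), >= 4 substrate levels.
#' @param fix_nh Optional fixed Hill coefficient (e.g. 1 for pure
#'   Michaelis-Menten); `NULL` (default) fits it.
#' @return An object of class `hill_fit`: list with `vmax` (nmol/min),
#'   `k_half` (mM), `n_h`, `stderrs`, `r_squared`, `fixed_nh`, and the
#'   underlying `nls` fit.
#' @examples
#' rt <- simulate_rate_curve(0.023, 0.5, 0.97)
#' fit_hill(rt)
#' @export
fit_hill <- function(rates, fix_nh = NULL) {
  if (!all(c("substrate_mM", "rate") %in% names(rates))) {
    abort("`rates` needs columns `substrate_mM` and `rate`")
  }
  s <- rates$substrate_mM
  v <- rates$rate
  if (length(unique(s)) < 4) abort("need at least 4 substrate levels")
  if (max(abs(v)) < 1e-12 || sd(v) < 1e-12 * max(abs(v), 1)) {
    abort("all rates are ~0: Hill parameters unidentifiable")
  }
  vmax0 <- max(v)
  k0 <- s[which.min(abs(v - vmax0 / 2))]
  if (k0 <= 0) k0 <- stats::median(s[s > 0])
  df <- tibble(s = s, v = v)
  fit <- if (is.null(fix_nh)) {
    minpack.lm::nlsLM(v ~ vmax * s^nh / (khalf^nh + s^nh), data = df,
                      start = list(vmax = vmax0, khalf = k0, nh = 1),
                      lower = c(1e-12, 1e-9, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
  } else {
    nh_fixed <- fix_nh
    minpack.lm::nlsLM(v ~ vmax * s^nh_fixed / (khalf^nh_fixed + s^nh_fixed),
                      data = df,
                      start = list(vmax = vmax0, khalf = k0),
                      lower = c(1e-12, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
  }
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, 2]
  res <- resid(fit)
  r2 <- 1 - sum(res^2) / sum((v - mean(v))^2)
  structure(list(vmax = unname(cf["vmax"]), k_half = unname(cf["khalf"]),
                 n_h = if (is.null(fix_nh)) unname(cf["nh"]) else fix_nh,
                 stderrs = se, r_squared = r2,
                 fixed_nh = !is.null(fix_nh), nls_fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: vmax = %.4g nmol/min, K_half = %.4g mM, n_h = %.3f%s, R^2 = %.4f\n",
              x$vmax, x$k_half, x$n_h, if (x$fixed_nh) " (fixed)" else "",
              x$r_squared))
  invisible(x)
}

#' Primer efficiency from a calibration dilution series
#'
#' Linear regression of Ct on log10 template input; the per-cycle
#' amplification efficiency is `E = 10^(-1 / slope)`. A slope of
#' `-1 / log10(2) = -3.3219` corresponds to perfect doubling (`E = 2`).
#'
#' @param dilution_series Data frame with columns `log10_dilution` and `ct`,
#'   >= 3 points.
#' @return List with `efficiency`, `slope`, `r_squared`.
#' @examples
#' ds <- tibble::tibble(log10_dilution = -(0:4),
#'                      ct = 18 + 3.3219 * (0:4))
#' primer_efficiency(ds)$efficiency  # 2
#' @export
primer_efficiency <- function(dilution_series) {
  if (!all(c("log10_dilution", "ct") %in% names(dilution_series))) {
    abort("`dilution_series` needs columns `log10_dilution` and `ct`")
  }
  if (nrow(dilution_series) < 3) abort("need at least 3 dilution points")
  fit <- lm(ct ~ log10_dilution, data = dilution_series)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("dilution-series slope is non-negative: more template must lower Ct")
  list(efficiency = 10^(-1 / slope), slope = slope,
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Relative copy number from paired Ct values
#'
#' Efficiency-corrected relative quantification of a target amplicon against
#' a reference amplicon from the same sample:
#' `ratio = E_tgt^(-Ct_tgt) / E_ref^(-Ct_ref) * (d_ref / v_ref) / (d_tgt / v_tgt)`,
#' which reduces to the classical `2^(-dCt)` when both efficiencies are 2 and
#' dilution factors and volumes are equal. Replicates are paired by index;
#' the replicate mean and sd of the ratio are reported per sample.
#'
#' @param ct A `ct_table` (or data frame) with columns `sample`, `target`
#'   (`"target"`/`"reference"`), `replicate`, `ct`, and optionally `dilution`
#'   and `volume`.
#' @param efficiency_target,efficiency_ref Per-cycle amplification
#'   efficiencies, in (1, 2] (default 2).
#' @return A tibble of class `copy_ratio` with columns `sample`, `ratio`,
#'   `sd`, `n_replicates`, `efficiency_target`, `efficiency_ref`.
#' @export
relative_copy_number <- function(ct, efficiency_target = 2,
                                 efficiency_ref = 2) {
  req <- c("sample", "target", "replicate", "ct")
  missing_cols <- setdiff(req, names(ct))
  if (length(missing_cols) > 0) {
    abort(sprintf("Ct table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (e in c(efficiency_target, efficiency_ref)) {
    if (e <= 1 || e > 2) abort("amplification efficiencies must lie in (1, 2]")
  }
  df <- as_tibble(ct)
  if (!"dilution" %in% names(df)) df$dilution <- 1
  if (!"volume" %in% names(df)) df$volume <- 1
  tgt <- df |> filter(.data$target == "target")
  ref <- df |> filter(.data$target == "reference")
  paired <- inner_join(tgt, ref, by = c("sample", "replicate"),
                       suffix = c("_t", "_r"))
  if (nrow(paired) == 0) abort("no paired target/reference measurements (missing reference?)")
  paired <- paired |>
    mutate(ratio = efficiency_target^(-.data$ct_t) / efficiency_ref^(-.data$ct_r) *
             (.data$dilution_r / .data$volume_r) /
             (.data$dilution_t / .data$volume_t))
  out <- paired |>
    group_by(.data$sample) |>
    summarise(sd = sd(.data$ratio),
              ratio = mean(.data$ratio),
              n_replicates = n()) |>
    select("sample", "ratio", "sd", "n_replicates") |>
    mutate(efficiency_target = efficiency_target,
           efficiency_ref = efficiency_ref)
  structure(out, class = c("copy_ratio", class(out)))
}
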