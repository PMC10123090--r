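#' Fit the 1:1 association phase of a sensorgram
#'
#' Nonlinear least squares of the single-exponential association model
#' `Y = Y0 + a * (1 - exp(-kobs * t))`, where `kobs = ka * conc + kd` is the
#' observed rate. Time is re-zeroed to the start of the segment. Initial
#' guesses come from the plateau (`a`) and a log-linearization of the early
#' response (`kobs`). A flat segment (amplitude indistinguishable from zero)
#' is flagged as unidentifiable rather than fitted.
#'
#' @param seg Data frame with columns `t_s` and `response`, containing the
#'   association segment only (a full `sensorgram` is filtered to its
#'   `"association"` phase automatically). At least 10 samples.
#' @return List of class `phase_fit` with `y0`, `a`, `rate` (`kobs`, 1/s),
#'   `chi2` (unit-weight residual sum of squares), `r_squared`,
#'   `identifiable`, and the underlying `nls` fit.
#' @export
fit_association <- function(seg) {
  seg <- extract_phase(seg, "association")
  tt <- seg$t_s - seg$t_s[1]
  y <- seg$response
  if (length(y) < 10) abort("association segment must have >= 10 samples")

  amp0 <- max(y) - y[1]
  if (!is.finite(amp0) || abs(amp0) < 1e-12 ||
      sd(y) < 1e-9 * max(abs(y), 1)) {
    return(unidentifiable_phase(y, "flat association segment: amplitude ~ 0, kobs unidentifiable"))
  }
  kobs0 <- guess_rate(tt, (max(y) + 1e-12 * abs(amp0)) - y, amp0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + a * (1 - exp(-kobs * tt)),
                      start = list(y0 = y[1], a = amp0, kobs = kobs0),
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf(
        "association fit did not converge (starts: y0=%.3g, a=%.3g, kobs=%.3g): %s",
        y[1], amp0, kobs0, conditionMessage(e)))
    })
  phase_fit_result(fit, y, rate_name = "kobs")
}

#' Fit the dissociation phase of a sensorgram
#'
#' Nonlinear least squares of the exponential decay
#' `Y = Y0 + a * exp(-kd * t)` with time re-zeroed to the segment start. A
#' constant segment (`kd = 0` or amplitude ~ 0) is flagged unidentifiable.
#'
#' @param seg Data frame with `t_s`, `response` (dissociation segment; a full
#'   `sensorgram` is filtered automatically).
#' @return List of class `phase_fit` with `y0`, `a`, `rate` (`kd`, 1/s),
#'   `chi2`, `r_squared`, `identifiable`, and the `nls` fit.
#' @export
fit_dissociation <- function(seg) {
  seg <- extract_phase(seg, "dissociation")
  tt <- seg$t_s - seg$t_s[1]
  y <- seg$response
  if (length(y) < 10) abort("dissociation segment must have >= 10 samples")

  amp0 <- y[1] - min(y)
  if (!is.finite(amp0) || abs(amp0) < 1e-12 ||
      sd(y) < 1e-9 * max(abs(y), 1)) {
    return(unidentifiable_phase(y, "constant dissociation segment: kd unidentifiable"))
  }
  kd0 <- guess_rate(tt, y - (min(y) - 1e-12 * abs(amp0)), amp0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + a * exp(-kd * tt),
                      start = list(y0 = min(y), a = amp0, kd = kd0),
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf(
        "dissociation fit did not converge (starts: y0=%.3g, a=%.3g, kd=%.3g): %s",
        min(y), amp0, kd0, conditionMessage(e)))
    })
  phase_fit_result(fit, y, rate_name = "kd")
}

extract_phase <- function(seg, phase) {
  if ("phase" %in% names(seg)) seg <- seg[seg$phase == phase, , drop = FALSE]
  if (!all(c("t_s", "response") %in% names(seg))) {
    abort("segment needs columns `t_s` and `response`")
  }
  if (any(seg$t_s < 0)) abort("negative times are not allowed")
  seg
}

# crude exponential-rate guess from log-linearized decay toward the asymptote
guess_rate <- function(tt, decay, amp) {
  ok <- decay > amp * 1e-3 & tt > 0
  if (sum(ok) >= 3) {
    sl <- unname(coef(lm(log(decay[ok]) ~ tt[ok]))[2])
    if (is.finite(sl) && sl < 0) return(-sl)
  }
  1 / max(tt[length(tt)] / 5, 1e-6)
}

phase_fit_result <- function(fit, y, rate_name) {
  cf <- coef(fit)
  res <- resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(y0 = unname(cf["y0"]), a = unname(cf["a"]),
                 rate = unname(cf[rate_name]), rate_name = rate_name,
                 chi2 = sum(res^2),
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
                 identifiable = TRUE, nls_fit = fit),
            class = "phase_fit")
}

unidentifiable_phase <- function(y, msg) {
  warn(msg)
  structure(list(y0 = mean(y), a = 0, rate = NA_real_, rate_name = NA_character_,
                 chi2 = sum((y - mean(y))^2), r_squared = NA_real_,
                 identifiable = FALSE, nls_fit = NULL),
            class = "phase_fit")
}

#' Association rate constant from observed rates
#'
#' Inverts `kobs = ka * conc + kd`. A single `(kobs, conc)` pair gives
#' `ka = (kobs - kd) / conc`; several pairs give the slope of the linear
#' regression of `kobs` on concentration, whose intercept is returned as a
#' consistency diagnostic against the supplied `kd`.
#'
#' @param kobs Observed association rate(s), 1/s.
#' @param conc Matching analyte concentration(s), M.
#' @param kd Dissociation rate constant, 1/s.
#' @return List with `ka` (1/(M s)), and for the regression route `intercept`
#'   (compare to `kd`) and `r_squared`.
#' @export
estimate_ka <- function(kobs, conc, kd) {
  if (length(kobs) != length(conc) || length(kobs) < 1) {
    abort("`kobs` and `conc` must be equal-length, non-empty vectors")
  }
  if (length(kobs) == 1) {
    if (conc <= 0) abort("analyte concentration must be > 0")
    if (kobs <= kd) {
      abort(sprintf("kobs (%.4g) <= kd (%.4g) at positive concentration: unphysical", kobs, kd))
    }
    return(list(ka = (kobs - kd) / conc, intercept = NA_real_,
                r_squared = NA_real_))
  }
  fit <- lm(kobs ~ conc)
  sl <- unname(coef(fit)[2])
  if (sl <= 0) abort("regression of kobs on concentration has non-positive slope: unphysical")
  list(ka = sl, intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Equilibrium dissociation constant
#'
#' `KD = kd / ka`, in molar.
#'
#' @param ka Association rate constant, 1/(M s) (> 0).
#' @param kd Dissociation rate constant, 1/s.
#' @return KD in M (multiply by 1e6 for micromolar).
#' @examples
#' 1e6 * compute_kd(7.42e4, 0.16)  # ~2.16 uM
#' @export
compute_kd <- function(ka, kd) {
  if (ka <= 0) abort("`ka` must be > 0")
  kd / ka
}

#' Full 1:1 kinetic analysis of a sensorgram
#'
#' Fits the association and dissociation phases, derives
#' `ka = (kobs - kd) / conc` using the dissociation-phase `kd` (the
#' single-concentration route used per sensor), and reports
#' `KD = kd / ka`.
#'
#' @param sg A `sensorgram` (from [simulate_sensorgram()] or
#'   [read_sensorgram_csv()]) with a `phase` column.
#' @param analyte_conc Analyte concentration in M; defaults to the
#'   sensorgram's own attribute.
#' @return An object of class `binding_fit`: list with `ka`, `kd`, `kobs`,
#'   `KD` (M), `KD_uM`, `y0`, `a`, `chi2`, `r_squared`, and the two
#'   `phase_fit`s.
#' @examples
#' sg <- simulate_sensorgram(7.42e4, 0.16, 2e-6, rmax = 1)
#' fit_sensorgram(sg)
#' @export
fit_sensorgram <- function(sg, analyte_conc = attr(sg, "analyte_conc")) {
  if (is.null(analyte_conc)) abort("`analyte_conc` is required")
  assoc <- fit_association(sg)
  dissoc <- fit_dissociation(sg)
  if (!assoc$identifiable || !dissoc$identifiable) {
    abort("sensorgram phases are unidentifiable; cannot derive rate constants")
  }
  ka <- estimate_ka(assoc$rate, analyte_conc, dissoc$rate)$ka
  kd <- dissoc$rate
  structure(list(ka = ka, kd = kd, kobs = assoc$rate,
                 KD = compute_kd(ka, kd), KD_uM = 1e6 * compute_kd(ka, kd),
                 y0 = assoc$y0, a = assoc$a,
                 chi2 = assoc$chi2 + dissoc$chi2,
                 r_squared = min(assoc$r_squared, dissoc$r_squared),
                 association = assoc, dissociation = dissoc,
                 analyte_conc = analyte_conc),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit: ka = %.4g /(M s), kd = %.4g /s, kobs = %.4g /s\n",
              x$ka, x$kd, x$kobs))
  cat(sprintf("  KD = %.4g M (%.3g uM); R^2 = %.4f\n", x$KD, x$KD_uM, x$r_squared))
  invisible(x)
}

#' Read a sensorgram CSV
#'
#' Expects columns `t_s,response` and either a `phase` column or explicit
#' `t_assoc` giving the association-phase duration.
#'
#' @param path CSV path.
#' @param analyte_conc Analyte concentration, M.
#' @param t_assoc If no `phase` column is present, times `<= t_assoc` are the
#'   association phase and later times the dissociation phase.
#' @return A `sensorgram` tibble.
#' @export
read_sensorgram_csv <- function(path, analyte_conc, t_assoc = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("t_s", "response") %in% names(df))) {
    abort("sensorgram CSV needs columns `t_s` and `response`")
  }
  if (!"phase" %in% names(df)) {
    if (is.null(t_assoc)) abort("supply `t_assoc` when the CSV has no `phase` column")
    df$phase <- ifelse(df$t_s <= t_assoc, "association", "dissociation")
  }
  structure(as_tibble(df), class = c("sensorgram", class(as_tibble(df))),
            analyte_conc = analyte_conc)
}
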