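#' Simulate a 1:1 bio-layer interferometry sensorgram
#'
#' Generates the association and dissociation phases of the standard 1:1
#' Langmuir binding model. The association phase follows
#' `R(t) = R_eq * (1 - exp(-kobs * t))` with `kobs = ka * conc + kd` and
#' `R_eq = rmax * conc / (conc + kd / ka)`; the dissociation phase follows
#' `R(t) = R0 * exp(-kd * t)` from the response `R0` reached at the end of
#' association. Optional additive Gaussian noise emulates instrument noise.
#'
#' @param ka Association rate constant, 1/(M s) (> 0).
#' @param kd Dissociation rate constant, 1/s (>= 0).
#' @param analyte_conc Analyte concentration, M (>= 0).
#' @param rmax Response at analyte saturation, response units.
#' @param t_assoc,t_dissoc Phase durations, seconds (> 0).
#' @param sample_rate Samples per second.
#' @param noise_sd Additive Gaussian noise sd, response units.
#' @param seed Integer seed.
#' @return A tibble of class `sensorgram` with columns `t_s` (time since the
#'   start of the run), `response`, `phase` (`"association"`/`"dissociation"`),
#'   and attributes `analyte_conc`, `truth` (the generating parameters) and
#'   `phase_boundaries`.
#' @examples
#' sg <- simulate_sensorgram(7.42e4, 0.16, 2e-6, rmax = 1)
#' head(sg)
#' @export
simulate_sensorgram <- function(ka, kd, analyte_conc, rmax = 1,
                                t_assoc = 300, t_dissoc = 180,
                                sample_rate = 10, noise_sd = 0, seed = NULL) {
  stopifnot_scalar_number(ka, "ka", 0, strict = TRUE)
  stopifnot_scalar_number(kd, "kd", 0)
  stopifnot_scalar_number(analyte_conc, "analyte_conc", 0)
  stopifnot_scalar_number(t_assoc, "t_assoc", 0, strict = TRUE)
  stopifnot_scalar_number(t_dissoc, "t_dissoc", 0, strict = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)

  kobs <- ka * analyte_conc + kd
  r_eq <- if (analyte_conc > 0 || kd == 0) {
    rmax * analyte_conc / (analyte_conc + kd / ka)
  } else 0
  ta <- seq(0, t_assoc, by = 1 / sample_rate)
  resp_a <- r_eq * (1 - exp(-kobs * ta))
  r0 <- resp_a[length(resp_a)]
  td <- seq(0, t_dissoc, by = 1 / sample_rate)[-1]
  resp_d <- r0 * exp(-kd * td)

  out <- tibble(
    t_s = c(ta, t_assoc + td),
    response = c(resp_a, resp_d),
    phase = rep(c("association", "dissociation"), c(length(ta), length(td))))
  if (noise_sd > 0) {
    out$response <- with_seed_if(seed, out$response + rnorm(nrow(out), 0, noise_sd))
  }
  structure(out,
            class = c("sensorgram", class(out)),
            analyte_conc = analyte_conc,
            phase_boundaries = c(assoc_start = 0, assoc_end = t_assoc,
                                 dissoc_end = t_assoc + t_dissoc),
            truth = list(ka = ka, kd = kd, kobs = kobs, r_eq = r_eq,
                         rmax = rmax, analyte_conc = analyte_conc))
}

#' Simulate an enzyme-kinetic rate curve (Hill model)
#'
#' Rates follow `v(S) = vmax * S^n_h / (k_half^n_h + S^n_h) + background_rate`
#' with optional additive Gaussian noise; `n_h = 1` gives Michaelis-Menten
#' kinetics with `Km = k_half`. The background term emulates substrate
#' auto-hydrolysis that downstream preprocessing subtracts.
#'
#' @param vmax Maximal rate, nmol/min (>= 0).
#' @param k_half Substrate concentration at half-maximal rate, mM (> 0).
#' @param n_h Hill coefficient (> 0).
#' @param substrate Substrate grid, mM.
#' @param background_rate Background (auto-hydrolysis) rate, nmol/min.
#' @param noise_sd Additive noise sd, nmol/min.
#' @param replicates Replicate measurements per substrate level.
#' @param seed Integer seed.
#' @return A tibble of class `rate_table` with columns `substrate_mM`,
#'   `replicate`, `rate` (nmol/min); generating parameters kept in the
#'   `truth` attribute.
#' @export
simulate_rate_curve <- function(vmax, k_half, n_h,
                                substrate = seq(0, 5, by = 0.25),
                                background_rate = 0, noise_sd = 0,
                                replicates = 1, seed = NULL) {
  stopifnot_scalar_number(vmax, "vmax", 0)
  stopifnot_scalar_number(k_half, "k_half", 0, strict = TRUE)
  stopifnot_scalar_number(n_h, "n_h", 0, strict = TRUE)
  if (any(substrate < 0)) abort("substrate concentrations must be >= 0")

  s <- rep(substrate, each = replicates)
  v <- vmax * s^n_h / (k_half^n_h + s^n_h) + background_rate
  if (noise_sd > 0) v <- with_seed_if(seed, v + rnorm(length(v), 0, noise_sd))
  out <- tibble(substrate_mM = s,
                replicate = rep(seq_len(replicates), times = length(substrate)),
                rate = v)
  structure(out, class = c("rate_table", class(out)),
            truth = list(vmax = vmax, k_half = k_half, n_h = n_h,
                         background_rate = background_rate))
}

#' Simulate a qPCR Ct table with a known copy ratio
#'
#' Generates paired target/reference Ct values for a sample whose target
#' amplicon is present at `true_copy_ratio` times the reference amplicon.
#' Template loaded into the reaction is `n0 * ratio * dilution / volume`
#' (the dilution factor is the fraction of material retained; the purification
#' volume divides the concentration), and for a primer of per-cycle efficiency
#' E the threshold cycle satisfies `Ct = (log(threshold) - log(loaded))/log(E)`,
#' anchored so that the reference amplicon crosses at `ct_ref`. With equal
#' efficiencies, dilutions and volumes this reduces to
#' `Ct_target = ct_ref - log_E(ratio)`.
#'
#' @param true_copy_ratio True target/reference copy ratio (> 0).
#' @param efficiency_target,efficiency_ref Per-cycle amplification
#'   efficiencies, in (1, 2].
#' @param ct_ref Reference-amplicon threshold cycle.
#' @param dilution_target,dilution_ref Dilution factors (fraction retained).
#' @param volume_target,volume_ref Sample volumes used for DNA purification.
#' @param noise_sd Gaussian Ct noise sd, cycles.
#' @param replicates Technical replicates (>= 1).
#' @param sample Sample label.
#' @param seed Integer seed.
#' @return A tibble of class `ct_table` with columns `sample`, `target`
#'   (`"target"`/`"reference"`), `replicate`, `ct`, `dilution`, `volume`.
#' @export
simulate_qpcr <- function(true_copy_ratio,
                          efficiency_target = 2, efficiency_ref = 2,
                          ct_ref = 20,
                          dilution_target = 1, dilution_ref = 1,
                          volume_target = 1, volume_ref = 1,
                          noise_sd = 0, replicates = 3,
                          sample = "sample_1", seed = NULL) {
  stopifnot_scalar_number(true_copy_ratio, "true_copy_ratio", 0, strict = TRUE)
  for (e in c(efficiency_target, efficiency_ref)) {
    if (e <= 1 || e > 2) abort("amplification efficiencies must lie in (1, 2]")
  }
  if (replicates < 1) abort("`replicates` must be >= 1")

  # loaded_ref = n0 * d_r / v_r; loaded_tgt = n0 * ratio * d_t / v_t;
  # Ct = (log(thr) - log(loaded)) / log(E), thr anchored by ct_ref
  log_thr <- ct_ref * log(efficiency_ref) + log(dilution_ref / volume_ref)
  ct_tgt <- (log_thr -
               log(true_copy_ratio * dilution_target / volume_target)) /
    log(efficiency_target)

  out <- tibble(
    sample = sample,
    target = rep(c("target", "reference"), each = replicates),
    replicate = rep(seq_len(replicates), 2),
    ct = c(rep(ct_tgt, replicates), rep(ct_ref, replicates)),
    dilution = rep(c(dilution_target, dilution_ref), each = replicates),
    volume = rep(c(volume_target, volume_ref), each = replicates))
  if (noise_sd > 0) {
    out$ct <- with_seed_if(seed, out$ct + rnorm(nrow(out), 0, noise_sd))
  }
  structure(out, class = c("ct_table", class(out)),
            truth = list(true_copy_ratio = true_copy_ratio,
                         efficiency_target = efficiency_target,
                         efficiency_ref = efficiency_ref))
}
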