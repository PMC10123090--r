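make_courses <- function(slopes, noise_sd = 0, seed = NULL, n_min = 60) {
  tmin <- seq(0, n_min - 1)
  df <- purrr::imap_dfr(slopes, function(sl, nm) {
    tibble::tibble(id = nm,
                   role = if (grepl("ctrl", nm)) sub("_ctrl.*", "", nm) else "sample",
                   substrate_mM = if (grepl("ctrl", nm)) NA_real_ else
                     as.numeric(sub("s", "", sub("_.*", "", nm))),
                   time_min = tmin, value = sl * tmin)
  })
  if (noise_sd > 0) {
    set.seed(seed)
    df$value <- df$value + stats::rnorm(nrow(df), 0, noise_sd)
  }
  df
}

test_that("control-corrected rates are the slope differences", {
  tc <- tibble::tibble(
    id = rep(c("w1", "auto", "nosub"), each = 10),
    role = rep(c("sample", "auto_hydrolysis", "no_substrate"), each = 10),
    substrate_mM = rep(c(1, NA, NA), each = 10),
    time_min = rep(0:9, 3),
    value = c(0.01 * (0:9), 0.002 * (0:9), 0 * (0:9)))
  rt <- preprocess_rates(tc)
  expect_equal(rt$rate, 0.008, tolerance = 1e-12)
  expect_false(rt$negative)
})

test_that("a sample identical to its control corrects to zero rate", {
  tc <- tibble::tibble(
    id = rep(c("w1", "auto"), each = 10),
    role = rep(c("sample", "auto_hydrolysis"), each = 10),
    substrate_mM = rep(c(1, NA), each = 10),
    time_min = rep(0:9, 2), value = rep(0.005 * (0:9), 2))
  expect_equal(preprocess_rates(tc)$rate, 0, tolerance = 1e-12)
})

test_that("negative corrected rates are retained and flagged, never clipped", {
  tc <- tibble::tibble(
    id = rep(c("w1", "auto"), each = 10),
    role = rep(c("sample", "auto_hydrolysis"), each = 10),
    substrate_mM = rep(c(1, NA), each = 10),
    time_min = rep(0:9, 2),
    value = c(0.001 * (0:9), 0.004 * (0:9)))
  expect_warning(rt <- preprocess_rates(tc), "negative")
  expect_equal(rt$rate, -0.003, tolerance = 1e-12)
  expect_true(rt$negative)
})

test_that("preprocessing validates its window and time grids", {
  tc <- make_courses(c(s1_w = 0.01, auto_ctrl = 0.002))
  expect_error(preprocess_rates(tc, window = 2), "3 points")
  bad <- tc
  bad$time_min[bad$id == "s1_w"] <- bad$time_min[bad$id == "s1_w"] + 0.5
  expect_error(preprocess_rates(bad), "time grid")
})

test_that("window-based rates are unbiased under noise across seeds", {
  errs <- purrr::map_dbl(1:20, function(s) {
    tc <- make_courses(c(s1_w = 0.01, auto_ctrl = 0.002), noise_sd = 0.005,
                       seed = s)
    rt <- suppressWarnings(preprocess_rates(tc, window = 30))
    rt$rate - 0.008
  })
  expect_lt(abs(mean(errs)), 0.05 * 0.008)
})

test_that("noiseless Hill parameters are recovered essentially exactly", {
  rt <- simulate_rate_curve(0.023, 0.5, 0.97)
  fit <- fit_hill(rt)
  expect_equal(fit$vmax, 0.023, tolerance = 1e-6)
  expect_equal(fit$k_half, 0.5, tolerance = 1e-6)
  expect_equal(fit$n_h, 0.97, tolerance = 1e-6)
  expect_gte(fit$r_squared, 1 - 1e-10)
  # the fitted curve passes through vmax/2 at k_half by construction
  v_at_khalf <- fit$vmax * fit$k_half^fit$n_h /
    (fit$k_half^fit$n_h + fit$k_half^fit$n_h)
  expect_equal(v_at_khalf, fit$vmax / 2)
})

test_that("fixing n_h = 1 recovers the Michaelis constant from MM data", {
  rt <- simulate_rate_curve(0.04, 0.8, 1)
  fit <- fit_hill(rt, fix_nh = 1)
  expect_equal(fit$k_half, 0.8, tolerance = 1e-8)
  expect_equal(fit$n_h, 1)
  expect_true(fit$fixed_nh)
})

test_that("unidentifiable or underdetermined rate tables are refused", {
  flat <- tibble::tibble(substrate_mM = 0:5, rate = 0)
  expect_error(fit_hill(flat), "unidentifiable")
  short <- tibble::tibble(substrate_mM = c(0, 1, 2), rate = c(0, 1, 1.5))
  expect_error(fit_hill(short), "4 substrate levels")
})

test_that("primer efficiency follows E = 10^(-1/slope)", {
  perfect <- tibble::tibble(log10_dilution = -(0:4),
                            ct = 18 + (0:4) / log10(2))
  suppressWarnings(pe <- primer_efficiency(perfect))
  expect_equal(pe$efficiency, 2, tolerance = 1e-12)
  expect_equal(pe$slope, -1 / log10(2), tolerance = 1e-12)

  s35 <- tibble::tibble(log10_dilution = -(0:3), ct = 20 + 3.5 * (0:3))
  suppressWarnings(pe2 <- primer_efficiency(s35))
  expect_equal(pe2$efficiency, 1.930698, tolerance = 1e-6)

  # synthetic series generated from E = 1.9 inverts exactly
  e <- 1.9
  series <- tibble::tibble(log10_dilution = -(0:4),
                           ct = 15 + (0:4) / log10(e))
  suppressWarnings(pe3 <- primer_efficiency(series))
  expect_equal(pe3$efficiency, 1.9, tolerance = 1e-12)

  up <- tibble::tibble(log10_dilution = -(0:3), ct = 20 - (0:3))
  expect_error(primer_efficiency(up), "slope")
  expect_error(primer_efficiency(perfect[1:2, ]), "3 dilution")
})

test_that("copy ratios follow the efficiency-corrected delta-Ct arithmetic", {
  # dCt = 0, E = 2, equal factors -> ratio 1
  eq <- simulate_qpcr(1, 2, 2)
  expect_equal(relative_copy_number(eq)$ratio, 1, tolerance = 1e-12)
  # one-cycle advantage at E = 2 -> ratio 2
  ct <- tibble::tibble(sample = "s", target = c("target", "reference"),
                       replicate = 1L, ct = c(19, 20))
  expect_equal(relative_copy_number(ct)$ratio, 2, tolerance = 1e-12)
  # generator inversion with mixed efficiencies, dilutions and volumes
  sim <- simulate_qpcr(5, efficiency_target = 1.9, efficiency_ref = 2,
                       dilution_target = 0.1, dilution_ref = 0.2,
                       volume_target = 2, volume_ref = 1)
  out <- relative_copy_number(sim, 1.9, 2)
  expect_equal(out$ratio, 5, tolerance = 1e-6)
  expect_equal(out$sd, 0)
  expect_error(
    relative_copy_number(dplyr::filter(sim, target == "target")),
    "reference")
})
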