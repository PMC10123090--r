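test_that("deterministic straight-line motion gives MSD(m dt) = (m*s)^2 exactly", {
  tr <- line_track(12, step = 0.05)
  msd <- compute_msd(tr, max_lag = 4)
  expect_equal(msd$msd_um2, (0.05 * 1:4)^2, tolerance = 1e-12)
  tam <- compute_tamsd(tr, max_lag = 4)
  expect_equal(tam$msd_um2, (0.05 * 1:4)^2, tolerance = 1e-12)
})

test_that("a stationary track has zero TAMSD at every lag", {
  tr <- line_track(10, step = 0)
  tam <- compute_tamsd(tr)
  expect_equal(tam$msd_um2, rep(0, 4))
})

test_that("the four default lags are 24/48/72/96 ms at a 24 ms frame interval", {
  ts <- simulate_tracks(50, d = 0.1, frame_interval = 0.024, seed = 1)
  msd <- compute_msd(filter_tracks(ts))
  expect_equal(msd$lag_s, c(0.024, 0.048, 0.072, 0.096))
})

test_that("pairs ending at a track's final localization are excluded on request", {
  # a stationary track with one huge final jump: the artifact only shows up
  # when the last point is included
  df <- tibble::tibble(track_id = "a", frame = 0:5, x_um = c(0, 0, 0, 0, 0, 10),
                       y_um = 0)
  ts <- track_tbl(df, 0.024)
  with_excl <- compute_msd(ts, max_lag = 1, exclude_last_point = TRUE)
  without <- compute_msd(ts, max_lag = 1, exclude_last_point = FALSE)
  expect_equal(with_excl$msd_um2, 0)
  expect_gt(without$msd_um2, 0)
  expect_equal(with_excl$n_pairs, without$n_pairs - 1L)
})

test_that("gap-closed tracks contribute no pairs at the gap", {
  df <- tibble::tibble(track_id = "g", frame = c(0L, 1L, 4L, 5L),
                       x_um = c(0, 1, 2, 3), y_um = 0)
  ts <- track_tbl(df, 0.024)
  msd1 <- compute_msd(ts, max_lag = 1, exclude_last_point = FALSE)
  expect_equal(msd1$n_pairs, 2L)   # 0->1 and 4->5 only
})

test_that("ensemble MSD of single-state Brownian tracks matches 4*D*tau at all lags", {
  d <- 0.1
  ts <- simulate_tracks(2500, d = d, localization_sigma = 0, seed = 10)
  ts <- filter_tracks(ts)
  msd <- compute_msd(ts)
  expect_equal(msd$msd_um2, 4 * d * msd$lag_s, tolerance = 0.03)
})

test_that("linear MSD fit inverts exact Brownian curves and reads out noise intercepts", {
  dt <- 0.024
  exact <- structure(tibble::tibble(lag_frames = 1:4, lag_s = dt * 1:4,
                                    msd_um2 = 4 * 1.0 * dt * 1:4,
                                    n_pairs = 100L),
                     class = c("msd_curve", class(tibble::tibble())),
                     frame_interval = dt, scope = "ensemble")
  f <- fit_msd_linear(exact)
  expect_equal(f$d, 1.0, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  withoff <- exact
  withoff$msd_um2 <- withoff$msd_um2 + 4 * 0.02^2
  f2 <- fit_msd_linear(withoff)
  expect_equal(f2$intercept, 0.0016, tolerance = 1e-12)
  expect_equal(f2$d, 1.0, tolerance = 1e-12)

  expect_error(fit_msd_linear(exact[1, ]), "2 lags")
})

test_that("fitted D is unbiased for simulated Brownian motion", {
  ts <- simulate_tracks(2000, d = 0.241, localization_sigma = 0, seed = 77)
  fit <- fit_msd_linear(compute_msd(filter_tracks(ts)))
  expect_equal(fit$d, 0.241, tolerance = 0.03)
})

test_that("mean of per-track TAMSDs agrees with the ensemble MSD (ergodicity)", {
  ts <- simulate_tracks(1200, d = 0.2, localization_sigma = 0,
                        track_length = "fixed", mean_length = 15, seed = 31)
  msd <- compute_msd(ts)
  tam <- compute_tamsd(ts)
  tam_mean <- tam |>
    dplyr::group_by(lag_frames) |>
    dplyr::summarise(m = mean(msd_um2))
  expect_equal(tam_mean$m, msd$msd_um2, tolerance = 0.05)
})

test_that("tracks too short for every TAMSD lag are excluded with a warning", {
  ts <- rbind_tracks <- track_tbl(
    tibble::tibble(track_id = c(rep("long", 8), rep("short", 5)),
                   frame = c(0:7, 0:4),
                   x_um = stats::rnorm(13), y_um = stats::rnorm(13)),
    0.024)
  expect_warning(tam <- compute_tamsd(ts, max_lag = 4), "too short")
  expect_equal(unique(tam$track_id), "long")
})
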