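test_that("pooled square displacements carry the rank/n empirical CDF", {
  df <- tibble::tibble(track_id = c("a", "a", "b", "b"),
                       frame = c(0L, 1L, 0L, 1L),
                       x_um = c(0, 1, 0, sqrt(2)), y_um = 0)
  ts <- track_tbl(df, 0.024)
  expect_warning(sqd <- compute_sqd(ts), "unreliable")
  expect_equal(sqd$sq_um2, c(1, 2))
  expect_equal(sqd$cdf, c(0.5, 1.0))
})

test_that("gap-closed displacement pairs never enter the SQD sample", {
  df <- tibble::tibble(track_id = "g", frame = c(0L, 1L, 3L),
                       x_um = c(0, 1, 5), y_um = 0)
  ts <- track_tbl(df, 0.024)
  expect_warning(sqd <- compute_sqd(ts, lag = 1), "unreliable")
  expect_equal(attr(sqd, "n"), 1L)
  expect_equal(sqd$sq_um2, 1)
})

test_that("the empirical CDF of simulated single-state data stays inside the DKW band", {
  d <- 0.15; dt <- 0.024
  ts <- simulate_tracks(1500, d = d, localization_sigma = 0,
                        frame_interval = dt, seed = 8)
  sqd <- compute_sqd(filter_tracks(ts))
  n <- attr(sqd, "n")
  band <- sqrt(log(2 / 0.001) / (2 * n))
  truth <- 1 - exp(-sqd$sq_um2 / (4 * d * dt))
  expect_lt(max(abs(sqd$cdf - truth)), band)
})

test_that("a single-component fit inverts noiseless exponential CDF values", {
  a <- 4 * 0.3 * 0.024
  sqd <- exact_sqd(a)
  fit <- fit_sqd_mixture(sqd, k = 1)
  expect_equal(fit$d, 0.3, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$fractions, 1)
})

test_that("two well-separated states are recovered from direct model draws", {
  a <- 4 * c(1.0, 0.01) * 0.024
  sqd <- draw_sqd(1e4, a, c(0.5, 0.5), seed = 15)
  fit <- fit_sqd_mixture(sqd, k = 2, seed = 1)
  expect_equal(fit$d[1], 1.0, tolerance = 0.10)
  expect_equal(fit$d[2], 0.01, tolerance = 0.10)
  expect_equal(fit$fractions[1], 0.5, tolerance = 0.05)
})

test_that("mixture fits are consistent: median relative D error < 10% over seeds", {
  errs <- purrr::map_dfr(1:8, function(s) {
    sqd <- draw_sqd(1e4, 4 * c(0.5, 0.02) * 0.024, c(0.6, 0.4), seed = s)
    fit <- fit_sqd_mixture(sqd, k = 2, seed = s)
    tibble::tibble(e1 = abs(fit$d[1] - 0.5) / 0.5,
                   e2 = abs(fit$d[2] - 0.02) / 0.02)
  })
  expect_lt(median(errs$e1), 0.10)
  expect_lt(median(errs$e2), 0.10)
})

test_that("every mixture fit satisfies the structural invariants", {
  for (s in 1:5) {
    k <- sample(1:3, 1)
    a <- sort(4 * stats::runif(k, 0.01, 1) * 0.024, decreasing = TRUE)
    sqd <- draw_sqd(3000, a, rep(1 / k, k), seed = s)
    fit <- fit_sqd_mixture(sqd, k = k, seed = s)
    expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
    expect_true(all(diff(fit$d) <= 0))
    expect_true(all(fit$fractions >= 0))
    expect_equal(fit$n_params, 2 * k - 1)
    expect_equal(fit$bic, fit$n * log(fit$rss / fit$n) + fit$n_params * log(fit$n))
  }
})

test_that("fixing the diffusion constants fits only the fractions", {
  a <- 4 * c(0.5, 0.01) * 0.024
  sqd <- draw_sqd(8000, a, c(0.7, 0.3), seed = 22)
  fit <- fit_sqd_mixture(sqd, k = 2, fixed_d = c(0.5, 0.01))
  expect_equal(fit$d, c(0.5, 0.01))
  expect_equal(fit$n_params, 1)
  expect_equal(fit$fractions[1], 0.7, tolerance = 0.05)
})

test_that("least-squares CDF fits agree with a brute-force likelihood grid search", {
  # single component: the grid-search MLE (~ the sample mean) and the LS
  # estimate must land within one grid step of each other
  sqd1 <- draw_sqd(2000, 4 * 0.2 * 0.024, 1, seed = 31)
  ls1 <- fit_sqd_mixture(sqd1, k = 1)
  or1 <- mle_grid_search(sqd1$sq_um2, k = 1)
  expect_lt(abs(log((4 * ls1$d[1] * 0.024) / or1$a)), or1$log_step + 1e-9)

  # two components
  sqd2 <- draw_sqd(2000, 4 * c(1.0, 0.01) * 0.024, c(0.5, 0.5), seed = 32)
  ls2 <- fit_sqd_mixture(sqd2, k = 2, seed = 1)
  or2 <- mle_grid_search(sqd2$sq_um2, k = 2)
  a_ls <- 4 * ls2$d * 0.024
  expect_lt(abs(log(a_ls[1] / or2$a[1])), 2 * or2$log_step + 1e-9)
  expect_lt(abs(log(a_ls[2] / or2$a[2])), 2 * or2$log_step + 1e-9)
  expect_equal(ls2$fractions[1], or2$f, tolerance = 0.06)
})
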