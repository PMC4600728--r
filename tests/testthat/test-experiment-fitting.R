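test_that("synthetic decay curves behave at their anchors", {
  crv <- synth_decay_curve(12, c(0, 0.01, 0.1))
  expect_identical(crv$intensity[1], 1)
  expect_error(synth_decay_curve(12, c(0, 0.01), noise_sd = -1), "noise_sd")
  expect_error(synth_decay_curve(-1, c(0, 0.1)), "rate")
  a <- synth_decay_curve(5, seq(0, 1, 0.1), noise_sd = 0.05, seed = 3)
  b <- synth_decay_curve(5, seq(0, 1, 0.1), noise_sd = 0.05, seed = 3)
  expect_identical(a$intensity, b$intensity)
})

test_that("noise-free decays refit to the exact rate with vanishing error", {
  crv <- synth_decay_curve(12, seq(0.002, 0.4, length.out = 14))
  fit <- fit_monoexponential_mc(crv, n_mc = 50)
  expect_equal(fit$rate, 12, tolerance = 1e-9)
  expect_equal(fit$rate_sd, 0)
})

test_that("the fitted rate is invariant to intensity scaling", {
  crv <- synth_decay_curve(7, seq(0.002, 0.5, length.out = 12),
                           noise_sd = 0.02, seed = 5)
  f1 <- fit_monoexponential_mc(crv, n_mc = 60, seed = 1)
  crv2 <- dplyr::mutate(crv, intensity = intensity * 37.5)
  attr(crv2, "noise_sd") <- 0.02 * 37.5
  f2 <- fit_monoexponential_mc(crv2, n_mc = 60, seed = 1)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-9)
})

test_that("Monte-Carlo rate errors match the analytic linearized standard error", {
  times <- seq(0.005, 0.5, length.out = 20)
  sd0 <- 0.02
  crv <- synth_decay_curve(8, times, noise_sd = 0, seed = NULL)
  attr(crv, "noise_sd") <- sd0
  fit <- fit_monoexponential_mc(crv, n_mc = 500, seed = 11)
  # oracle: first-order error propagation through the Jacobian of
  # y = A exp(-R t) at the true parameters
  Jmat <- cbind(exp(-8 * times), -1 * times * exp(-8 * times))
  cov <- sd0^2 * solve(crossprod(Jmat))
  se_analytic <- sqrt(cov[2, 2])
  expect_equal(fit$rate_sd, se_analytic, tolerance = 0.2)
  # and against a repeated-simulation oracle: scatter of independent refits
  set.seed(12)
  rates <- vapply(1:200, function(i) {
    fit_monoexponential_mc(
      synth_decay_curve(8, times, noise_sd = sd0), n_mc = 50,
      noise_sd = 0)$rate
  }, numeric(1))
  expect_equal(fit$rate_sd, sd(rates), tolerance = 0.2)
})

test_that("the printed base rates differ by 8.5 per second", {
  times <- seq(0.004, 0.6, length.out = 16)
  f_mpd <- fit_monoexponential_mc(synth_decay_curve(3.5, times), n_mc = 50)
  f_cub <- fit_monoexponential_mc(synth_decay_curve(12, times), n_mc = 50)
  expect_equal(f_cub$rate - f_mpd$rate, 8.5, tolerance = 1e-8)
})

test_that("all-nonpositive intensities fail cleanly", {
  bad <- tibble::tibble(time_s = c(0.1, 0.2, 0.3), intensity = c(-1, -2, 0))
  expect_error(fit_monoexponential_mc(bad, n_mc = 50), "fit failure")
  expect_error(fit_monoexponential_mc(
    synth_decay_curve(1, c(0, 0.1, 0.2)), n_mc = 10), "n_mc")
})

test_that("REDOR dephasing is zero without coupling and matches the Bessel curve", {
  mas <- 40e3
  times <- (1:12) * 2 / mas
  expect_equal(redor_dephasing(0, times, mas)$dephasing, rep(0, 12))
  crv <- redor_dephasing(10e3, times, mas)
  expect_lt(max(abs(crv$dephasing - redor_universal(10e3, times))), 1e-3)
  expect_error(redor_dephasing(10e3, numeric(0)), "empty")
})

test_that("the long-time REDOR tail oscillates about one", {
  mas <- 40e3
  tail_times <- (40:100) * 2 / mas
  tail_vals <- redor_dephasing(12e3, tail_times, mas)$dephasing
  expect_lt(abs(mean(tail_vals) - 1), 0.02)
  expect_gt(max(tail_vals), 1)
  expect_lt(min(tail_vals), 1)
})

test_that("a single unit RF scale equals the ideal simulation exactly", {
  mas <- 39.5e3
  times <- (1:8) * 2 / mas
  ideal <- redor_dephasing(9e3, times, mas)
  unit_rf <- redor_dephasing(9e3, times, mas,
                             rf = rf_inhomogeneity(scales = 1, weights = 1))
  expect_identical(ideal$dephasing, unit_rf$dephasing)
  # a spread profile damps the oscillation relative to ideal at long times
  spread <- redor_dephasing(9e3, (20:28) * 2 / mas, mas,
                            rf = rf_inhomogeneity())
  ideal_l <- redor_dephasing(9e3, (20:28) * 2 / mas, mas)
  expect_lt(sd(spread$dephasing), sd(ideal_l$dephasing))
})

test_that("chi-square REDOR fitting round-trips and is convex near the minimum", {
  mas <- 39.5e3
  times <- (1:10) * 2 / mas
  obs <- synth_redor_curve(10e3, times, mas)
  grid <- seq(6e3, 14e3, by = 500)
  fit <- redor_fit_chi2(obs, grid, noise_sd = 0)
  expect_equal(fit$coupling, 10e3, tolerance = 0.01)
  expect_true(fit$refined)
  chi2 <- fit$chi2_profile$chi2
  i <- which.min(chi2)
  expect_gt(diff(diff(chi2[(i - 1):(i + 1)])), 0)
  # minimum at the grid edge warns and skips refinement
  expect_warning(redor_fit_chi2(obs, seq(11e3, 15e3, 500), noise_sd = 0),
                 "grid edge")
})

test_that("REDOR Monte-Carlo errors agree with a bootstrap-over-timepoints oracle", {
  mas <- 39.5e3
  times <- (1:12) * 2 / mas
  obs <- synth_redor_curve(10e3, times, mas, noise_sd = 0.02, seed = 21)
  grid <- seq(7e3, 13e3, by = 250)
  fit <- redor_fit_chi2(obs, grid, n_mc = 200, noise_inflation = 1, seed = 22)
  # bootstrap oracle: resample time points with replacement, refit on grid
  sims <- vapply(grid, function(D) {
    redor_dephasing(D, times, mas)$dephasing
  }, numeric(length(times)))
  set.seed(23)
  refine_min <- function(chi2) {
    i <- which.min(chi2)
    if (i == 1 || i == length(chi2)) return(grid[i])
    x <- grid[(i - 1):(i + 1)]; yv <- chi2[(i - 1):(i + 1)]
    den <- yv[1] - 2 * yv[2] + yv[3]
    if (den <= 0) return(grid[i])
    x[2] + 0.5 * (yv[1] - yv[3]) / den * (x[3] - x[1]) / 2
  }
  boot <- vapply(1:200, function(i) {
    idx <- sample(length(times), replace = TRUE)
    refine_min(colSums((obs$dephasing[idx] - sims[idx, , drop = FALSE])^2))
  }, numeric(1))
  expect_equal(fit$coupling_sd, sd(boot), tolerance = 0.25)
})

test_that("coupling-to-S2 conversion hits its closed-form anchors", {
  d_rigid <- dipolar_coupling_constant(1.02, units = "Hz")
  expect_equal(coupling_to_s2(d_rigid), 1)
  expect_equal(coupling_to_s2(0), 0)
  # identity on S2 through the sqrt(S2) coupling scaling
  for (s2 in c(0.25, 0.5, 0.9)) {
    expect_equal(coupling_to_s2(sqrt(s2) * d_rigid), s2, tolerance = 1e-12)
  }
  expect_warning(s2c <- coupling_to_s2(1.05 * d_rigid), "clipped")
  expect_equal(s2c, 1)
  # rigid-limit constant against an independent evaluation with pinned
  # constants
  d_oracle <- 1e-7 * 2.6752218744e8 * 2.7126189e7 * 1.054571817e-34 /
    (1.02e-10)^3 / (2 * pi)
  expect_equal(d_rigid, d_oracle, tolerance = 1e-3)
})
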