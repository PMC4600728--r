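test_that("sphere vectors are unit, conventional and quasi-uniform", {
  expect_equal(sphere_vectors(1), matrix(c(0, 0, 1), 1, 3))
  u <- sphere_vectors(100)
  expect_equal(rowSums(u^2), rep(1, 100), tolerance = 1e-12)
  ev <- eigen(crossprod(u) / 100, symmetric = TRUE)$values
  expect_true(all(abs(ev - 1 / 3) < 0.01))
  # isotropy: mean pairwise P2 near the 10^6-draw Monte-Carlo expectation (0)
  set.seed(1)
  a <- matrix(rnorm(3e6), ncol = 3); a <- a / sqrt(rowSums(a^2))
  b <- matrix(rnorm(3e6), ncol = 3); b <- b / sqrt(rowSums(b^2))
  mc <- mean(p2(rowSums(a * b)))
  dots <- tcrossprod(u)
  mean_pair <- mean(p2(dots[upper.tri(dots)]))
  expect_lt(abs(mean_pair - mc), 0.02)
  expect_error(sphere_vectors(0), "positive integer")
})

test_that("lag grids are strictly increasing, start at zero and are log-dense", {
  lg <- lag_grid(100000)
  expect_equal(lg[1], 0L)
  expect_true(all(diff(lg) > 0))
  expect_lte(max(lg), (100000 - 1) / 5)
  expect_equal(lag_grid(2), c(0L, 1L))
})

test_that("identity rotation series give g_rock = 1 at every lag", {
  mats <- array(diag(3), c(3, 3, 20))
  rs <- structure(list(matrices = mats, time_step = 1e-9, molecule_id = 1,
                       fit_rmsd = rep(0, 20), process = NULL),
                  class = "rotation_series")
  cf <- rocking_correlation(rs)
  expect_equal(cf$value, rep(1, nrow(cf)), tolerance = 1e-12)
})

test_that("g_rock equals the direct nested-loop double sum on a toy series", {
  pr <- rocking_process("restrained_diffusion", angular_stddev = 0.3,
                        relaxation_time = 3e-9)
  rs <- simulate_rocking_series(pr, 10, 1e-9, seed = 13)
  vecs <- sphere_vectors(7)
  lags <- c(0L, 1L, 2L, 5L, 9L)
  cf <- rocking_correlation(rs, vectors = vecs, lags = lags)
  oracle <- nested_loop_corr(rs$matrices, vecs, lags)
  expect_equal(cf$value, oracle, tolerance = 1e-12)
  expect_equal(cf$n_origins, c(10L, 9L, 8L, 5L, 1L))
})

test_that("g_rock is invariant to a global rotation of all matrices", {
  pr <- rocking_process("restrained_diffusion", angular_stddev = 0.1,
                        relaxation_time = 5e-8)
  rs <- simulate_rocking_series(pr, 2000, 1e-9, seed = 14)
  cf1 <- rocking_correlation(rs)
  G <- rotation_about_axis(c(2, -1, 1), 1.1)
  rs2 <- rs
  for (f in 1:2000) rs2$matrices[, , f] <- G %*% rs$matrices[, , f]
  cf2 <- rocking_correlation(rs2)
  expect_lt(max(abs(cf1$value - cf2$value)), 0.005)
})

test_that("empty or out-of-range lag grids are rejected", {
  pr <- rocking_process("restrained_diffusion", angular_stddev = 0.1,
                        relaxation_time = 5e-8)
  rs <- simulate_rocking_series(pr, 10, 1e-9, seed = 1)
  expect_error(rocking_correlation(rs, lags = integer(0)), "empty lag grid")
  expect_error(rocking_correlation(rs, lags = c(0L, 10L)), "lags must lie")
})

test_that("identical curves aggregate to themselves with no outliers", {
  pr <- rocking_process("restrained_diffusion", angular_stddev = 0.1,
                        relaxation_time = 5e-8)
  rs <- simulate_rocking_series(pr, 500, 1e-9, seed = 15)
  cf <- rocking_correlation(rs)
  curves <- dplyr::bind_rows(
    dplyr::mutate(cf, molecule = 1),
    dplyr::mutate(cf, molecule = 2),
    dplyr::mutate(cf, molecule = 3))
  attr(curves, "time_step") <- 1e-9
  agg <- aggregate_and_flag(curves)
  expect_false(any(agg$flags$outlier))
  expect_equal(agg$mean$value, cf$value, tolerance = 1e-12)
})

test_that("a single divergent curve among identical ones is flagged", {
  lg <- lag_grid(500) * 1e-9
  base <- tibble::tibble(lag_s = lg, value = 0.98 + 0.02 * exp(-lg / 5e-8),
                         n_origins = 1L)
  curves <- dplyr::bind_rows(lapply(1:9, function(m) {
    dplyr::mutate(base, molecule = m)
  }))
  dead <- dplyr::mutate(base, value = exp(-lg / 2e-8), molecule = 10)
  curves <- dplyr::bind_rows(curves, dead)
  attr(curves, "time_step") <- 1e-9
  agg <- aggregate_and_flag(curves)
  expect_identical(which(agg$flags$outlier), 10L)
  expect_equal(agg$mean$value, base$value, tolerance = 1e-12)
})

test_that("inconsistent lag grids are a hard error", {
  a <- tibble::tibble(lag_s = c(0, 1e-9, 2e-9), value = 1, n_origins = 1L,
                      molecule = 1)
  b <- tibble::tibble(lag_s = c(0, 1e-9, 3e-9), value = 1, n_origins = 1L,
                      molecule = 2)
  expect_error(aggregate_and_flag(dplyr::bind_rows(a, b)), "common lag grid")
})

test_that("molecule-averaged curves match a longer single-molecule run", {
  pr <- rocking_process("restrained_diffusion", angular_stddev = 0.12,
                        relaxation_time = 2e-8)
  short <- lapply(1:24, function(m) {
    simulate_rocking_series(pr, 2000, 1e-9, seed = 100 + m)
  })
  lags <- lag_grid(2000)
  curves <- dplyr::bind_rows(lapply(seq_along(short), function(m) {
    dplyr::mutate(rocking_correlation(short[[m]], lags = lags), molecule = m)
  }))
  attr(curves, "time_step") <- 1e-9
  agg <- aggregate_and_flag(curves)
  long <- rocking_correlation(
    simulate_rocking_series(pr, 20000, 1e-9, seed = 999), lags = lags)
  expect_lt(max(abs(agg$mean$value - long$value)), 0.01)
})
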