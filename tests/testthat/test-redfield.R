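cond600 <- spectrometer_conditions(600e6, 39.5e3, 15e3)

test_that("R1rho vanishes in the fast-motion limit at fixed amplitude", {
  rates <- vapply(10^seq(-12, -10, by = 0.5), function(tau) {
    as.numeric(r1rho_redfield(model_free(0.985, tau), cond600))
  }, numeric(1))
  expect_lt(rates[1], 1e-3)
  expect_true(all(diff(rates) > 0))
})

test_that("R1rho is exactly linear in (1 - S2) at fixed tau", {
  tau <- 4e-7
  r1 <- as.numeric(r1rho_redfield(model_free(0.99, tau), cond600))
  r2 <- as.numeric(r1rho_redfield(model_free(0.98, tau), cond600))
  r4 <- as.numeric(r1rho_redfield(model_free(0.96, tau), cond600))
  expect_equal(r2 / r1, 2, tolerance = 1e-9)
  expect_equal(r4 / r1, 4, tolerance = 1e-9)
})

test_that("rotary-resonance conditions trigger warnings", {
  expect_warning(spectrometer_conditions(600e6, 15e3, 15e3),
                 "rotary-resonance")
  expect_warning(spectrometer_conditions(600e6, 20e3, 40e3),
                 "rotary-resonance")
  cond_rr <- suppressWarnings(spectrometer_conditions(600e6, 15e3, 15e3))
  expect_warning(r1rho_redfield(model_free(0.98, 1e-7), cond_rr),
                 "rotary-resonance")
})

test_that("a slow correlation time attaches a Redfield-validity advisory", {
  r <- r1rho_redfield(model_free(0.985, 4e-5), cond600)
  expect_false(is.null(attr(r, "redfield_advisory")))
  r_fast <- r1rho_redfield(model_free(0.985, 1e-8), cond600)
  expect_null(attr(r_fast, "redfield_advisory"))
})

test_that("dipolar and csa contributions add to the default", {
  m <- model_free(0.985, 4e-7)
  both <- as.numeric(r1rho_redfield(m, cond600))
  dip <- as.numeric(r1rho_redfield(m, cond600, interactions = "dipolar"))
  csa <- as.numeric(r1rho_redfield(m, cond600, interactions = "csa"))
  expect_equal(dip + csa, both, tolerance = 1e-12)
  expect_gt(dip, csa)
})

test_that("every rate-surface row is unimodal in tau", {
  surf <- rate_surface(seq(0.95, 0.99, by = 0.01),
                       10^seq(-9, -4, by = 0.1), cond600)
  for (s2 in unique(surf$s2)) {
    r <- surf$r1rho[surf$s2 == s2]
    d <- diff(r)
    flips <- sum(d[-length(d)] > 0 & d[-1] < 0)
    expect_true(all(d[seq_len(which.max(r) - 1)] > 0))
    expect_true(all(d[seq(which.max(r), length(d))] < 0))
    expect_lte(flips, 1)
  }
})

test_that("iso-rate contour points re-evaluate to the target rate within 0.5%", {
  contour <- iso_rate_contour(12, seq(0.97, 0.99, by = 0.01), cond600)
  expect_gt(nrow(contour), 0)
  for (i in seq_len(nrow(contour))) {
    r <- as.numeric(r1rho_redfield(
      model_free(contour$s2[i], contour$tau_s[i]), cond600))
    expect_equal(r, 12, tolerance = 0.005)
  }
  expect_warning(iso_rate_contour(1e5, c(0.98, 0.99), cond600),
                 "exceeds the surface maximum")
})

test_that("branch solving round-trips and handles tangency and no-solution", {
  sol <- solve_tau_branches(12, 0.985, cond600)
  expect_true(sol$solvable)
  for (tau in c(sol$tau_fast, sol$tau_slow)) {
    r <- as.numeric(r1rho_redfield(model_free(0.985, tau), cond600))
    expect_equal(r, 12, tolerance = 1e-3)
  }
  expect_lt(sol$tau_fast, sol$tau_slow)
  # tangency: target equal to the maximum gives coincident roots
  tangent <- solve_tau_branches(sol$rate_max, 0.985, cond600)
  expect_true(tangent$solvable)
  expect_equal(tangent$tau_fast, tangent$tau_slow, tolerance = 1e-6)
  # above the maximum: explicit no-solution marker, not an exception
  none <- solve_tau_branches(sol$rate_max * 1.1, 0.985, cond600)
  expect_false(none$solvable)
  expect_true(is.na(none$tau_slow))
})

test_that("including a nanosecond fast component changes rocking R1rho by < 2%", {
  slow_only <- model_free(1 - 0.018, 4e-7)
  with_fast <- structure(list(
    s2 = 1 - 0.018 - 0.003,
    components = tibble::tibble(amplitude = c(0.003, 0.018),
                                tau = c(1e-9, 4e-7))), class = "model_free")
  r_slow <- as.numeric(r1rho_redfield(slow_only, cond600))
  r_both <- as.numeric(r1rho_redfield(with_fast, cond600))
  expect_lt(abs(r_both - r_slow) / r_slow, 0.02)
})

test_that("rocking_r1rho maps c_s and tau_s and returns zero when c_s = 0", {
  fit <- structure(list(c_f = 0.002, c_s = 0.018, tau_f = 1e-9, tau_s = 4e-7,
                        plateau = 0.98, residual_norm = 0,
                        fitted = NULL, curve = NULL), class = "biexp_fit")
  cond <- cond600
  expect_equal(as.numeric(rocking_r1rho(fit, cond)),
               as.numeric(r1rho_redfield(model_free(1 - 0.018, 4e-7), cond)),
               tolerance = 1e-12)
  fit0 <- fit; fit0$c_s <- 0
  expect_message(r0 <- rocking_r1rho(fit0, cond), "no slow rocking")
  expect_equal(r0, 0)
  # a plateau of 0.982 with a slow time of a few hundred ns lands in the
  # 3-15 s^-1 decade (loose check against the chain-A scale)
  for (tau in c(2e-7, 4e-7, 6e-7)) {
    fit_a <- fit; fit_a$c_s <- 0.018; fit_a$tau_s <- tau
    r <- as.numeric(rocking_r1rho(fit_a, cond))
    expect_gt(r, 3); expect_lt(r, 15)
  }
})
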