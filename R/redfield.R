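# Redfield-theory 15N R1rho under magic-angle spinning with an on-resonance
# spin-lock: NH dipolar + 15N CSA, model-free spectral densities. The secular
# (near-zero-frequency) term of the static expressions is redistributed by MAS
# over the rotor sidebands of the spin-lock frequency: J(0) is replaced by
#   (1/3)[J(w1-wr) + J(w1+wr)] + (1/6)[J(w1-2wr) + J(w1+2wr)]
# (rank-2 Wigner weights 2/3 and 1/3 split over the +/- sidebands), while the
# high-frequency (R1-type) terms are unchanged. The resulting coefficients are
# pinned against an independent numerical two-site-jump propagation in the
# test suite.

# shared low-frequency sideband combination
j_sidebands <- function(J, w1, wr) {
  (1 / 3) * (J(abs(w1 - wr)) + J(w1 + wr)) +
    (1 / 6) * (J(abs(w1 - 2 * wr)) + J(w1 + 2 * wr))
}

#' Redfield 15N R1rho under MAS with on-resonance spin-lock
#'
#' Rotating-frame relaxation rate of spin-locked 15N magnetization for the
#' supplied motional model, NH dipolar and/or 15N CSA interactions:
#' \deqn{R_{1\rho} = \frac{d^2}{4}\left[2\,\tilde J + \frac{1}{2}J(\omega_H -
#' \omega_N) + \frac{3}{2}J(\omega_N) + 3J(\omega_H) + 3J(\omega_H +
#' \omega_N)\right] + c^2\left[\frac{2}{3}\tilde J +
#' \frac{1}{2}J(\omega_N)\right]}
#' where \eqn{\tilde J} is the MAS sideband combination
#' \eqn{(1/3)[J(\omega_1 \mp \omega_r)] + (1/6)[J(\omega_1 \mp 2\omega_r)]}
#' summed over both signs. Returns only the contribution of the supplied
#' motion (e.g. the rocking component).
#'
#' A warning is raised at rotary resonance (`nu_1 = nu_r` or `2 nu_r` within
#' 1 Hz); a Redfield-validity advisory (condition attribute
#' `redfield_advisory`) is attached when a correlation time exceeds the
#' inverse of the smallest sampled gap frequency, where perturbation theory
#' becomes unreliable.
#'
#' @param motion A `"model_free"`, `"multiexp_fit"` or `"biexp_fit"`.
#' @param cond A [spectrometer_conditions()].
#' @param interactions Character subset of `c("dipolar", "csa")`.
#' @return R1rho in s^-1 (numeric scalar, possibly with advisory attribute).
#' @export
#' @examples
#' cond <- spectrometer_conditions(600e6, 39.5e3, 15e3)
#' r1rho_redfield(model_free(0.985, 400e-9), cond)
r1rho_redfield <- function(motion, cond,
                           interactions = c("dipolar", "csa")) {
  stopifnot(inherits(cond, "spectrometer_conditions"))
  interactions <- match.arg(interactions, several.ok = TRUE)
  if (!inherits(motion, "model_free")) motion <- as_model_free(motion)
  if (any(motion$components$amplitude < 0)) {
    stop("negative motional amplitude", call. = FALSE)
  }
  w1 <- cond$omega_1; wr <- cond$omega_r
  if (abs(cond$spinlock - cond$mas_rate) <= 1 ||
      abs(cond$spinlock - 2 * cond$mas_rate) <= 1) {
    warning("rotary-resonance condition: Redfield spin-lock expression invalid",
            call. = FALSE)
  }
  J <- function(w) spectral_density(motion, w)
  Jt <- j_sidebands(J, w1, wr)
  wH <- cond$omega_H; wN <- cond$omega_N
  r <- 0
  if ("dipolar" %in% interactions) {
    r <- r + (cond$d^2 / 4) *
      (2 * Jt + 0.5 * J(wH - wN) + 1.5 * J(wN) + 3 * J(wH) + 3 * J(wH + wN))
  }
  if ("csa" %in% interactions) {
    r <- r + cond$c_csa^2 * ((2 / 3) * Jt + 0.5 * J(wN))
  }
  min_gap <- min(abs(w1 - wr), abs(w1 - 2 * wr), w1 + wr)
  if (any(motion$components$tau > 1 / min_gap)) {
    attr(r, "redfield_advisory") <-
      "correlation time exceeds the Redfield validity scale 1/min(|w1 - n*wr|)"
  }
  r
}

#' Rocking contribution to R1rho from a correlation-function fit
#'
#' Maps a bi-exponential-with-base rocking fit into the Redfield expression
#' using the slow component only: `1 - S2 = c_s`, `tau = tau_s`. The small
#' fast component (tau_f around a nanosecond) is excluded by construction
#' since it contributes negligibly to R1rho.
#'
#' @param fit A `"biexp_fit"` from [fit_biexp_base()].
#' @param cond A [spectrometer_conditions()].
#' @param ... Passed to [r1rho_redfield()].
#' @return R1rho contribution in s^-1 (0 when `c_s` is zero).
#' @export
rocking_r1rho <- function(fit, cond, ...) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (fit$c_s <= 0) {
    message("c_s = 0: no slow rocking component, contribution is 0")
    return(0)
  }
  motion <- model_free(1 - fit$c_s, fit$tau_s)
  r1rho_redfield(motion, cond, ...)
}

#' R1rho rate surface over order parameter and correlation time
#'
#' Evaluates [r1rho_redfield()] on a grid of (S2, tau) for single-Lorentzian
#' model-free motion, the map used to read amplitudes and timescales off
#' iso-rate contours of measured base rates.
#'
#' @param s2_grid Monotone grid of order parameters (in (0, 1)).
#' @param tau_grid Monotone grid of correlation times, seconds.
#' @param cond A [spectrometer_conditions()].
#' @param interactions Passed to [r1rho_redfield()].
#' @return Tibble of class `"rate_surface"`: `s2`, `tau_s`, `r1rho`.
#' @export
rate_surface <- function(s2_grid, tau_grid, cond,
                         interactions = c("dipolar", "csa")) {
  stopifnot(!is.unsorted(s2_grid), !is.unsorted(tau_grid))
  grid <- tidyr::expand_grid(s2 = s2_grid, tau_s = tau_grid)
  grid$r1rho <- purrr::map2_dbl(grid$s2, grid$tau_s, function(s2, tau) {
    as.numeric(r1rho_redfield(model_free(s2, tau), cond, interactions))
  })
  attr(grid, "conditions") <- cond
  class(grid) <- c("rate_surface", class(grid))
  grid
}

#' Iso-rate contour of the R1rho surface
#'
#' For each S2, solves for the correlation times at which the rate equals
#' `rate` (two branches when the target is below the row maximum). Solutions
#' are found with [solve_tau_branches()], so re-evaluating the returned
#' points through [r1rho_redfield()] reproduces the target rate to solver
#' tolerance.
#'
#' @param rate Target rate, s^-1.
#' @param s2_grid Order-parameter grid.
#' @param cond A [spectrometer_conditions()].
#' @param tau_range Search range for tau, seconds.
#' @param ... Passed to [r1rho_redfield()].
#' @return Tibble `s2`, `branch` ("fast"/"slow"), `tau_s`; rows only where a
#'   solution exists. Empty (with a warning) when the target exceeds the
#'   maximum everywhere.
#' @export
iso_rate_contour <- function(rate, s2_grid, cond,
                             tau_range = c(1e-12, 1e-2), ...) {
  rows <- purrr::map(s2_grid, function(s2) {
    sol <- solve_tau_branches(rate, s2, cond, tau_range = tau_range, ...)
    if (!sol$solvable) return(NULL)
    tibble::tibble(s2 = s2, branch = c("fast", "slow"),
                   tau_s = c(sol$tau_fast, sol$tau_slow))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("requested contour rate exceeds the surface maximum everywhere",
            call. = FALSE)
  }
  out
}

#' Solve the two correlation-time branches for a target R1rho
#'
#' For fixed S2 the Redfield R1rho is unimodal in tau: it vanishes in the
#' fast and slow limits and peaks in between. This locates the maximizing tau
#' on a log grid plus golden-section refinement, then bisects on each side
#' for the target rate. When the target exceeds the maximum, a no-solution
#' result is returned (not an error).
#'
#' @param target_rate Target rate, s^-1 (> 0).
#' @param s2 Order parameter.
#' @param cond A [spectrometer_conditions()].
#' @param tau_range Log-search range for tau, seconds.
#' @param tol Relative rate tolerance of the root finding.
#' @param ... Passed to [r1rho_redfield()].
#' @return List of class `"tau_branches"`: `solvable`, `tau_fast`, `tau_slow`,
#'   `tau_max`, `rate_max`, `target_rate`, `s2`.
#' @export
solve_tau_branches <- function(target_rate, s2, cond,
                               tau_range = c(1e-12, 1e-2), tol = 1e-6, ...) {
  stopifnot(target_rate > 0, s2 > 0, s2 < 1)
  f <- function(lt) {
    as.numeric(r1rho_redfield(model_free(s2, exp(lt)), cond, ...))
  }
  lr <- log(tau_range)
  opt <- stats::optimize(f, lr, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  lt_max <- opt$maximum
  rate_max <- opt$objective
  if (target_rate > rate_max * (1 - 1e-12)) {
    near <- abs(target_rate - rate_max) / rate_max < 1e-9
    return(structure(list(
      solvable = near, tau_fast = if (near) exp(lt_max) else NA_real_,
      tau_slow = if (near) exp(lt_max) else NA_real_,
      tau_max = exp(lt_max), rate_max = rate_max,
      target_rate = target_rate, s2 = s2), class = "tau_branches"))
  }
  g <- function(lt) f(lt) - target_rate
  fast <- stats::uniroot(g, c(lr[1], lt_max), tol = tol)$root
  slow <- stats::uniroot(g, c(lt_max, lr[2]), tol = tol)$root
  structure(list(solvable = TRUE, tau_fast = exp(fast), tau_slow = exp(slow),
                 tau_max = exp(lt_max), rate_max = rate_max,
                 target_rate = target_rate, s2 = s2),
            class = "tau_branches")
}

#' @export
print.tau_branches <- function(x, ...) {
  cat("<tau_branches> S2 =", format(x$s2), " target =",
      format(x$target_rate), "s^-1\n")
  if (x$solvable) {
    cat(sprintf("  fast branch tau = %.4g s\n  slow branch tau = %.4g s\n",
                x$tau_fast, x$tau_slow))
  } else {
    cat(sprintf("  no solution: target exceeds maximum %.4g s^-1 (at tau = %.4g s)\n",
                x$rate_max, x$tau_max))
  }
  invisible(x)
}
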