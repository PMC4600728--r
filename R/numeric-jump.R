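# Numerical two-site-jump model of 15N R1rho under MAS + spin-lock: explicit
# propagation of spin-locked magnetization under the MAS-modulated dipolar +
# CSA offsets with stochastic two-site exchange (exchange-superoperator /
# stochastic-Liouville formulation on the Bloch vector), powder averaged.
# Valid outside the Redfield regime; serves as the independent oracle for the
# Redfield expressions.

#' Two-site-jump motional model
#'
#' NH vector exchanging between two orientations separated by angle Phi with
#' equal populations and symmetric exchange rate `k_ex` (each direction). The
#' order parameter is \eqn{S^2 = (1+3\cos^2\Phi)/4} and the model-free
#' correlation time of the exchange is \eqn{\tau = 1/(2 k_{ex})}.
#'
#' @param phi_deg Jump angle in degrees.
#' @param k_ex Exchange rate, s^-1.
#' @return Object of class `"jump_model"` with derived `s2` and `tau`.
#' @export
jump_model <- function(phi_deg, k_ex) {
  stopifnot(phi_deg >= 0, phi_deg <= 180, k_ex >= 0)
  structure(list(phi_deg = phi_deg, k_ex = k_ex,
                 s2 = two_site_s2(phi_deg),
                 tau = if (k_ex > 0) 1 / (2 * k_ex) else Inf),
            class = "jump_model")
}

#' Redfield-equivalent model-free motion of a jump model
#'
#' The mapping used when comparing the numerical model with Redfield theory:
#' `s2 = (1+3cos^2 Phi)/4`, `tau = 1/(2 k_ex)`.
#'
#' @param x A [jump_model()].
#' @param ... Unused.
#' @export
as_model_free.jump_model <- function(x, ...) {
  model_free(x$s2, x$tau)
}

#' Numerical R1rho for two-site orientational exchange under MAS
#'
#' Propagates spin-locked 15N magnetization under the time-dependent secular
#' NH-dipolar and 15N-CSA offsets (MAS modulation, CSA tensor collinear with
#' the NH bond) with symmetric two-site exchange, using an exact per-step
#' Bloch rotation and a Strang-split exchange superoperator. The signal is
#' sampled at rotor-period boundaries, powder averaged over a deterministic
#' quasi-uniform orientation grid and over the two proton spin manifolds, and
#' the decay rate extracted by a log-linear fit.
#'
#' Only the near-rotary-resonance (secular) relaxation pathway is modelled;
#' the high-frequency (R1-type) terms, negligible for the slow motions this
#' model targets, are not included.
#'
#' @param model A [jump_model()].
#' @param cond A [spectrometer_conditions()].
#' @param n_orient Powder orientations (default 144).
#' @param steps_per_period Rotor-period discretisation (default 100; raised
#'   automatically so that `k_ex * dt <= 1/6`).
#' @param max_time Spin-lock duration to simulate, seconds (default 0.05).
#' @param r2_warn Log-linear fit R^2 below which the decay is flagged as
#'   non-exponential.
#' @return R1rho in s^-1, with attributes `r_squared` and `flagged`.
#' @export
r1rho_numeric_jump <- function(model, cond, n_orient = 144,
                               steps_per_period = 100, max_time = 0.05,
                               r2_warn = 0.98) {
  stopifnot(inherits(model, "jump_model"),
            inherits(cond, "spectrometer_conditions"))
  if (n_orient < 1) stop("n_orient must be positive", call. = FALSE)
  t_r <- 1 / cond$mas_rate
  n_steps <- max(steps_per_period, ceiling(6 * model$k_ex * t_r))
  dt <- t_r / n_steps
  n_periods <- max(10L, as.integer(floor(max_time / t_r)))
  beta_m <- acos(1 / sqrt(3))
  cb_m <- cos(beta_m); sb_m <- sin(beta_m)
  phi2 <- model$phi_deg * pi / 180 / 2
  v1 <- c(-sin(phi2), 0, cos(phi2))
  v2 <- c(+sin(phi2), 0, cos(phi2))
  # signed interaction scales for the two 1H spin manifolds; the CSA share
  # (2/3)*delta_sigma*omega_N converts the axially symmetric tensor to its
  # P2(cos theta) offset
  c_csa_p2 <- (2 / 3) * cond$delta_sigma_n * 1e-6 * cond$omega_N
  scales <- c(cond$d + c_csa_p2, -cond$d + c_csa_p2)
  t_mid <- (seq_len(n_steps) - 0.5) * dt
  grid <- rotation_grid(n_orient)

  # fit each crystallite/manifold decay (mono-exponential to Redfield
  # accuracy), then powder-average the rates: this is the quantity the
  # powder-averaged Redfield expression describes
  tt <- (0:n_periods) * t_r
  X <- cbind(1, tt)
  rates <- numeric(0); r2s <- numeric(0)
  for (R in grid) {
    u1 <- as.numeric(R %*% v1); u2 <- as.numeric(R %*% v2)
    p2_site <- function(u) {
      b <- acos(min(1, max(-1, u[3]))); ph <- atan2(u[2], u[1])
      ct <- cb_m * cos(b) - sb_m * sin(b) * cos(cond$omega_r * t_mid + ph)
      (3 * ct^2 - 1) / 2
    }
    p21 <- p2_site(u1); p22 <- p2_site(u2)
    for (sc in scales) {
      sig <- propagate_jump_mx(sc * p21, sc * p22, cond$omega_1,
                               dt, model$k_ex, n_periods)
      ok <- sig > 0
      fit <- stats::lm.fit(X[ok, , drop = FALSE], log(sig[ok]))
      rates <- c(rates, -fit$coefficients[2])
      # judge exponentiality only where the decay is appreciable; flat
      # crystallites carry no shape information
      if (sig[1] > 0 && (sig[1] - sig[length(sig)]) / sig[1] > 0.02) {
        ss_res <- sum(fit$residuals^2)
        ss_tot <- sum((log(sig[ok]) - mean(log(sig[ok])))^2)
        r2s <- c(r2s, if (ss_tot > 1e-20) 1 - ss_res / ss_tot else 1)
      }
    }
  }
  rate <- mean(rates)
  r2 <- if (length(r2s)) stats::median(r2s) else 1
  flagged <- is.finite(r2) && r2 < r2_warn && rate > 1e-3
  structure(as.numeric(rate), r_squared = r2, flagged = flagged)
}
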