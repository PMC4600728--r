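# Generative models of rigid-body rocking. These are stand-ins: the motivating
# observations come from crystal MD, which gives no generative model, so two
# canonical stochastic processes are provided with exactly known statistics.

#' Rocking process specification
#'
#' Two ground-truth generators for the orientation of a molecule in its
#' lattice site:
#'
#' * `"two_site_jump"`: exchange between two orientations obtained by rotating
#'   the reference orientation by -Phi/2 and +Phi/2 about a fixed axis, with
#'   exponentially distributed dwell times (symmetric exchange, equal
#'   populations, rate `exchange_rate` for each direction). A probe vector
#'   perpendicular to the jump axis reorients by exactly Phi, for which the
#'   order parameter is \eqn{S^2 = (1 + 3\cos^2\Phi)/4}; the isotropic-vector
#'   plateau of the molecular rotation is [jump_plateau_isotropic()].
#' * `"restrained_diffusion"`: independent Ornstein-Uhlenbeck processes on the
#'   three components of a rotation vector (standard deviation
#'   `angular_stddev` radians per axis, memory time `relaxation_time`),
#'   composed through the exponential map each frame. Stationary; a good model
#'   of small-amplitude diffusive rocking for sigma below about 0.3 rad. The
#'   stationary isotropic order parameter is [ou_plateau_s2()].
#'
#' @param kind `"two_site_jump"` or `"restrained_diffusion"`.
#' @param jump_angle_phi Jump angle Phi in degrees (two-site).
#' @param exchange_rate Exchange rate k in s^-1 (two-site; the correlation time
#'   of symmetric exchange is 1/(2k)).
#' @param angular_stddev Per-axis standard deviation of the rotation vector,
#'   radians (restrained diffusion).
#' @param relaxation_time OU memory time in seconds (restrained diffusion).
#' @param axis Jump axis (two-site), default z.
#' @return Object of class `"rocking_process"`.
#' @export
rocking_process <- function(kind = c("restrained_diffusion", "two_site_jump"),
                            jump_angle_phi = NULL, exchange_rate = NULL,
                            angular_stddev = NULL, relaxation_time = NULL,
                            axis = c(0, 0, 1)) {
  kind <- match.arg(kind)
  if (kind == "two_site_jump") {
    if (is.null(jump_angle_phi) || is.null(exchange_rate) ||
        jump_angle_phi < 0 || exchange_rate < 0) {
      stop("two_site_jump needs jump_angle_phi >= 0 (deg) and exchange_rate >= 0 (1/s)",
           call. = FALSE)
    }
  } else {
    if (is.null(angular_stddev) || is.null(relaxation_time) ||
        angular_stddev < 0 || relaxation_time <= 0) {
      stop("restrained_diffusion needs angular_stddev >= 0 (rad) and relaxation_time > 0 (s)",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, jump_angle_phi = jump_angle_phi,
                 exchange_rate = exchange_rate,
                 angular_stddev = angular_stddev,
                 relaxation_time = relaxation_time, axis = axis),
            class = "rocking_process")
}

#' Two-site-jump order parameter of a vector
#'
#' \eqn{S^2 = (1 + 3\cos^2\Phi)/4} for a vector exchanging between two
#' orientations separated by angle Phi with equal populations.
#'
#' @param phi_deg Jump angle in degrees.
#' @return Order parameter in `[0.25, 1]`.
#' @export
two_site_s2 <- function(phi_deg) (1 + 3 * cos(phi_deg * pi / 180)^2) / 4

#' Isotropic-vector plateau of a molecular two-site rotation jump
#'
#' When a whole molecule jumps between two orientations related by a rotation
#' of angle beta, a probe vector at angle alpha to the rotation axis reorients
#' by less than beta; averaging \eqn{P_2} over an isotropic vector set gives
#' the plateau \eqn{(1 + \chi_2(\beta)/5)/2} with \eqn{\chi_2} the rank-2
#' rotation character. This differs from [two_site_s2()], which applies to a
#' single vector jumping by exactly beta (equivalently, to probe vectors
#' perpendicular to the jump axis).
#'
#' @param beta_deg Molecular jump rotation angle, degrees.
#' @return Isotropic plateau value.
#' @export
jump_plateau_isotropic <- function(beta_deg) {
  (1 + chi2_character(beta_deg * pi / 180) / 5) / 2
}

#' Stationary isotropic order parameter of the restrained-diffusion process
#'
#' For a rotation vector r ~ N(0, sigma^2 I3) (random axis, chi-distributed
#' angle), the orientational average of the rank-2 Wigner matrix is g I with
#' \eqn{g = [1 + 2(1-\sigma^2)e^{-\sigma^2/2} + 2(1-4\sigma^2)e^{-2\sigma^2}]/5},
#' and the isotropic-vector plateau between two independent stationary
#' orientations is \eqn{S^2 = g^2}. Exact for the unwrapped Gaussian rotation
#' vector; excellent for sigma below ~0.5 rad.
#'
#' @param sigma Per-axis rotation-vector standard deviation, radians.
#' @return Plateau order parameter.
#' @export
ou_plateau_s2 <- function(sigma) {
  g <- (1 + 2 * (1 - sigma^2) * exp(-sigma^2 / 2) +
          2 * (1 - 4 * sigma^2) * exp(-2 * sigma^2)) / 5
  g^2
}

#' Rotation-vector spread for a target rocking order parameter
#'
#' Inverts [ou_plateau_s2()] numerically.
#'
#' @param s2 Target plateau order parameter, in (0, 1].
#' @return Per-axis sigma in radians.
#' @export
sigma_for_plateau <- function(s2) {
  stopifnot(s2 > 0, s2 <= 1)
  if (s2 == 1) return(0)
  stats::uniroot(function(s) ou_plateau_s2(s) - s2, c(1e-6, 1.5),
                 tol = 1e-12)$root
}

#' Simulate a rigid-body rocking rotation series
#'
#' Generates a sequence of proper rotations about a fixed pivot according to a
#' [rocking_process()]. For the two-site jump, dwell times in each site are
#' exponential with the given exchange rate; for restrained diffusion, each
#' rotation-vector component follows a stationary AR(1) (exact OU
#' discretisation) with the stated standard deviation and memory time.
#'
#' @param process A [rocking_process()].
#' @param n_frames Number of frames (>= 2).
#' @param time_step Frame spacing in seconds (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"rotation_series"`: list with `matrices`
#'   (array `3 x 3 x n_frames`), `time_step`, `molecule_id`, `fit_rmsd`
#'   (NA for generated series) and the generating `process`.
#' @export
simulate_rocking_series <- function(process, n_frames, time_step, seed = NULL) {
  stopifnot(inherits(process, "rocking_process"),
            n_frames >= 2, time_step > 0)
  if (!is.null(seed)) set.seed(seed)
  mats <- array(0, c(3, 3, n_frames))
  if (process$kind == "two_site_jump") {
    phi <- process$jump_angle_phi * pi / 180
    k <- process$exchange_rate
    Rs <- list(rotation_about_axis(process$axis, -phi / 2),
               rotation_about_axis(process$axis, +phi / 2))
    state <- sample.int(2, 1)
    if (k == 0 || phi == 0) {
      states <- rep(state, n_frames)
    } else {
      # exponential dwell times, alternating sites
      t_total <- n_frames * time_step
      n_guess <- max(16, ceiling(3 * k * t_total))
      dwells <- stats::rexp(n_guess, rate = k)
      while (sum(dwells) < t_total) {
        dwells <- c(dwells, stats::rexp(n_guess, rate = k))
      }
      jump_times <- cumsum(dwells)
      frame_t <- (seq_len(n_frames) - 1) * time_step
      n_jumps_before <- findInterval(frame_t, jump_times)
      states <- 1 + (state - 1 + n_jumps_before) %% 2
    }
    for (f in seq_len(n_frames)) mats[, , f] <- Rs[[states[f]]]
  } else {
    sig <- process$angular_stddev
    tau <- process$relaxation_time
    if (sig == 0) {
      for (f in seq_len(n_frames)) mats[, , f] <- diag(3)
    } else {
      a <- exp(-time_step / tau)
      b <- sig * sqrt(1 - a^2)
      r <- matrix(0, n_frames, 3)
      r[1, ] <- stats::rnorm(3, 0, sig)
      eps <- matrix(stats::rnorm(3 * (n_frames - 1), 0, 1), n_frames - 1, 3)
      for (f in 2:n_frames) r[f, ] <- a * r[f - 1, ] + b * eps[f - 1, ]
      for (f in seq_len(n_frames)) mats[, , f] <- rotvec_to_matrix(r[f, ])
    }
  }
  structure(list(matrices = mats, time_step = time_step,
                 molecule_id = NA_integer_, fit_rmsd = rep(NA_real_, n_frames),
                 process = process),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat("<rotation_series> ", dim(x$matrices)[3], " frames, dt = ",
      format(x$time_step), " s\n", sep = "")
  invisible(x)
}
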