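# Physical constants (CODATA 2018) used throughout the relaxation machinery.
# Pinned here so every rate computed by the package traces to one set of values.

#' Physical constants used by latticerock
#'
#' CODATA 2018 values for the gyromagnetic ratios of 1H and 15N, the reduced
#' Planck constant and the magnetic constant, as a named list. All relaxation
#' and dipolar-coupling computations in the package draw on these values.
#'
#' @return Named list with elements `gamma_1H` (rad s^-1 T^-1), `gamma_15N`
#'   (rad s^-1 T^-1, negative), `hbar` (J s), `mu0_over_4pi` (T m A^-1).
#' @export
#' @examples
#' nmr_constants()$gamma_1H
nmr_constants <- function() {
  list(
    gamma_1H     = 2.6752218744e8,
    gamma_15N    = -2.7126189e7,
    hbar         = 1.054571817e-34,
    mu0_over_4pi = 1e-7
  )
}

#' NH dipolar coupling constant
#'
#' Rigid-limit one-bond 1H-15N dipolar coupling constant
#' \eqn{d = (\mu_0/4\pi)\,\gamma_H |\gamma_N| \hbar / r_{NH}^3},
#' in angular frequency units.
#'
#' @param r_nh N-H internuclear distance in Angstrom (default 1.02).
#' @param units `"rad_s"` (default) or `"Hz"` (d / 2 pi).
#' @return Coupling constant (positive scalar).
#' @export
#' @examples
#' dipolar_coupling_constant(1.02, units = "Hz") # ~ 11.5 kHz
dipolar_coupling_constant <- function(r_nh = 1.02, units = c("rad_s", "Hz")) {
  units <- match.arg(units)
  stopifnot(is.numeric(r_nh), r_nh > 0)
  k <- nmr_constants()
  d <- k$mu0_over_4pi * k$gamma_1H * abs(k$gamma_15N) * k$hbar / (r_nh * 1e-10)^3
  if (units == "Hz") d / (2 * pi) else d
}

#' Spectrometer and interaction conditions
#'
#' Bundle of the experimental conditions that fix all relaxation computations:
#' static field (given as the 1H Larmor frequency), magic-angle-spinning rate,
#' on-resonance 15N spin-lock field, N-H bond length and 15N CSA.
#'
#' The defaults are the measurement conditions used throughout the package's
#' worked examples: 600 MHz 1H, 39.5 kHz MAS, 15 kHz spin-lock, r_NH = 1.02 A,
#' axially symmetric 15N CSA of -170 ppm.
#'
#' A warning is raised when the spin-lock field sits near the rotary-resonance
#' conditions nu_1 = nu_r or nu_1 = 2 nu_r, where simple spin-lock relaxation
#' expressions break down.
#'
#' @param proton_larmor 1H Larmor frequency in Hz.
#' @param mas_rate MAS rotation rate nu_r in Hz.
#' @param spinlock 15N spin-lock radio-frequency field strength nu_1 in Hz.
#' @param r_nh N-H distance in Angstrom.
#' @param delta_sigma_n 15N CSA anisotropy in ppm (axially symmetric tensor,
#'   unique axis taken collinear with the NH bond).
#' @param rotary_warn_hz Half-width (Hz) of the window around the rotary
#'   resonances that triggers a warning.
#' @return Object of class `"spectrometer_conditions"`: a list with the inputs
#'   plus derived angular frequencies `omega_H`, `omega_N` (rad/s, magnitudes),
#'   `omega_1`, `omega_r`, the dipolar constant `d` and CSA constant `c_csa`
#'   (both rad/s).
#' @export
#' @examples
#' cond <- spectrometer_conditions()
#' cond$omega_N / (2 * pi) # 15N Larmor frequency, Hz
spectrometer_conditions <- function(proton_larmor = 600e6,
                                    mas_rate = 39.5e3,
                                    spinlock = 15e3,
                                    r_nh = 1.02,
                                    delta_sigma_n = -170,
                                    rotary_warn_hz = 1) {
  stopifnot(proton_larmor > 0, mas_rate > 0, spinlock > 0, r_nh > 0)
  if (abs(spinlock - mas_rate) <= rotary_warn_hz ||
      abs(spinlock - 2 * mas_rate) <= rotary_warn_hz) {
    warning("spin-lock field at (or within ", rotary_warn_hz,
            " Hz of) a rotary-resonance condition nu_1 = nu_r or 2 nu_r",
            call. = FALSE)
  }
  k <- nmr_constants()
  omega_H <- 2 * pi * proton_larmor
  omega_N <- omega_H * abs(k$gamma_15N) / k$gamma_1H
  structure(
    list(
      proton_larmor = proton_larmor,
      mas_rate = mas_rate,
      spinlock = spinlock,
      r_nh = r_nh,
      delta_sigma_n = delta_sigma_n,
      omega_H = omega_H,
      omega_N = omega_N,
      omega_1 = 2 * pi * spinlock,
      omega_r = 2 * pi * mas_rate,
      d = dipolar_coupling_constant(r_nh),
      c_csa = abs(delta_sigma_n) * 1e-6 * omega_N / sqrt(3)
    ),
    class = "spectrometer_conditions"
  )
}

#' @export
print.spectrometer_conditions <- function(x, ...) {
  cat("<spectrometer_conditions>\n")
  cat(sprintf("  1H Larmor      : %.1f MHz\n", x$proton_larmor / 1e6))
  cat(sprintf("  15N Larmor     : %.2f MHz\n", x$omega_N / (2 * pi * 1e6)))
  cat(sprintf("  MAS rate       : %.1f kHz\n", x$mas_rate / 1e3))
  cat(sprintf("  spin-lock      : %.1f kHz\n", x$spinlock / 1e3))
  cat(sprintf("  r_NH           : %.3f A  (d/2pi = %.2f kHz)\n",
              x$r_nh, x$d / (2 * pi * 1e3)))
  cat(sprintf("  15N CSA        : %.0f ppm\n", x$delta_sigma_n))
  invisible(x)
}
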