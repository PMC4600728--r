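# Synthetic experimental curves with controlled noise: mono-exponential
# relaxation decays and REDOR dephasing curves.

#' Synthetic mono-exponential decay curve
#'
#' Intensities `amplitude * exp(-rate * t)` plus zero-mean Gaussian noise.
#'
#' @param rate Decay rate constant, s^-1 (>= 0).
#' @param time_points Strictly increasing sampling times, seconds.
#' @param noise_sd Gaussian noise standard deviation (intensity units, >= 0).
#' @param seed Optional integer seed.
#' @param amplitude Initial intensity (default 1).
#' @return Tibble of class `"decay_curve"` with columns `time_s`, `intensity`
#'   and attribute `noise_sd`.
#' @export
synth_decay_curve <- function(rate, time_points, noise_sd = 0, seed = NULL,
                              amplitude = 1) {
  stopifnot(rate >= 0, length(time_points) >= 1,
            !is.unsorted(time_points, strictly = TRUE))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- amplitude * exp(-rate * time_points)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  out <- tibble::tibble(time_s = as.numeric(time_points), intensity = y)
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("decay_curve", class(out))
  out
}

#' Synthetic REDOR dephasing curve
#'
#' Noise-free dephasing from [redor_dephasing()] plus Gaussian noise.
#'
#' @param d_eff Effective (motionally averaged) dipolar coupling, Hz.
#' @param recoupling_times Recoupling times, seconds (multiples of the rotor
#'   period for a faithful REDOR sampling, but any non-negative times work).
#' @param mas_rate MAS rate in Hz (sets the rotor period).
#' @param noise_sd Gaussian noise sd on Delta S / S0.
#' @param seed Optional seed.
#' @param rf Optional [rf_inhomogeneity()] mixture.
#' @return Tibble of class `"redor_curve"` with columns `time_s`, `dephasing`,
#'   attributes `noise_sd` and `mas_rate`.
#' @export
synth_redor_curve <- function(d_eff, recoupling_times, mas_rate = 39.5e3,
                              noise_sd = 0, seed = NULL, rf = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ideal <- redor_dephasing(d_eff, recoupling_times, mas_rate = mas_rate, rf = rf)
  if (!is.null(seed)) set.seed(seed)
  y <- ideal$dephasing
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  out <- tibble::tibble(time_s = ideal$time_s, dephasing = y)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "mas_rate") <- mas_rate
  class(out) <- c("redor_curve", class(out))
  out
}
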