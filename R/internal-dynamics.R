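# Site-specific internal dynamics: symmetry superposition into a common
# molecular frame, NH vector extraction, Bruschweiler-Wright order parameters,
# NH correlation functions, multi-exponential spectral-density fits, 15N R1.

#' Superpose all molecules into the template frame
#'
#' Applies the inverse of each molecule's stored lattice transform so that
#' every copy is expressed in the common template frame, enabling per-residue
#' series to be concatenated across symmetry-equivalent molecules into one
#' long array.
#'
#' @param traj A `"rock_trajectory"`.
#' @param transforms Optional list of per-molecule `list(R, t)` transforms;
#'   defaults to the transforms stored on the trajectory.
#' @return A `"rock_trajectory"` with all molecules in the template frame.
#' @export
symmetry_superpose <- function(traj, transforms = NULL) {
  stopifnot(inherits(traj, "rock_trajectory"))
  if (is.null(transforms)) transforms <- traj$transforms
  if (is.null(transforms)) {
    stop("no symmetry transforms available on the trajectory", call. = FALSE)
  }
  d <- dim(traj$coords)
  if (length(transforms) != d[3]) {
    stop("missing transform: need one per molecule", call. = FALSE)
  }
  out <- traj
  for (m in seq_len(d[3])) {
    tr <- transforms[[m]]
    Rinv <- t(tr$R)
    for (f in seq_len(d[4])) {
      out$coords[, , m, f] <-
        t(Rinv %*% (t(traj$coords[, , m, f]) - tr$t))
    }
  }
  out$transforms <- rep(list(list(R = diag(3), t = c(0, 0, 0))), d[3])
  out
}

#' Extract NH bond unit vectors
#'
#' Unit vectors from backbone N to amide H per residue, molecule and frame.
#'
#' @param traj A `"rock_trajectory"` containing matched "N" and "H" atoms.
#' @return Object of class `"vector_series"`: list with `vectors` (array
#'   `n_frames x 3 x n_residues x n_molecules`), `residues`, `time_step`,
#'   `n_frames`, `n_molecules`.
#' @export
nh_vectors <- function(traj) {
  stopifnot(inherits(traj, "rock_trajectory"))
  n_idx <- which(traj$atoms$atom == "N")
  h_idx <- which(traj$atoms$atom == "H")
  if (length(n_idx) == 0 || length(n_idx) != length(h_idx)) {
    stop("trajectory must contain matched N and H atoms", call. = FALSE)
  }
  res_n <- traj$atoms$residue[n_idx]
  res_h <- traj$atoms$residue[h_idx]
  h_idx <- h_idx[match(res_n, res_h)]
  d <- dim(traj$coords)
  n_res <- length(n_idx)
  v <- traj$coords[h_idx, , , , drop = FALSE] -
    traj$coords[n_idx, , , , drop = FALSE]
  nrm <- sqrt(v[, 1, , , drop = FALSE]^2 + v[, 2, , , drop = FALSE]^2 +
                v[, 3, , , drop = FALSE]^2)
  if (any(nrm == 0)) stop("zero-length NH vector", call. = FALSE)
  for (k in 1:3) v[, k, , ] <- v[, k, , ] / nrm[, 1, , ]
  # reorder to frames x 3 x residues x molecules
  v <- aperm(v, c(4, 2, 1, 3))
  structure(list(vectors = v, residues = res_n, time_step = traj$time_step,
                 n_frames = d[4], n_molecules = d[3]),
            class = "vector_series")
}

#' @export
print.vector_series <- function(x, ...) {
  cat("<vector_series> ", length(x$residues), " residues x ",
      x$n_molecules, " molecules x ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Order parameters by the Bruschweiler-Wright formula
#'
#' \deqn{S^2 = \frac{3}{2}\left(\langle x^2\rangle^2 + \langle y^2\rangle^2 +
#' \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
#' 2\langle yz\rangle^2\right) - \frac{1}{2}}
#' from the time-averaged Cartesian second moments of the bond unit vector,
#' with the per-residue samples of all symmetry-equivalent molecules pooled
#' into one long array. (The Cartesian and spherical-harmonic forms of the
#' formula are algebraically identical.)
#'
#' @param series A `"vector_series"`, or a plain `n x 3` matrix of unit
#'   vectors for a single site.
#' @return Tibble (`residue`, `s2`), or a scalar for matrix input.
#' @export
s2_bruschweiler_wright <- function(series) {
  s2_of_mat <- function(V) {
    xx <- mean(V[, 1]^2); yy <- mean(V[, 2]^2); zz <- mean(V[, 3]^2)
    xy <- mean(V[, 1] * V[, 2]); xz <- mean(V[, 1] * V[, 3])
    yz <- mean(V[, 2] * V[, 3])
    1.5 * (xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2)) - 0.5
  }
  if (is.matrix(series)) {
    stopifnot(ncol(series) == 3, nrow(series) >= 2)
    return(s2_of_mat(series))
  }
  stopifnot(inherits(series, "vector_series"))
  n_res <- length(series$residues)
  s2 <- vapply(seq_len(n_res), function(r) {
    V <- series$vectors[, , r, ]                 # frames x 3 x molecules
    dim(V) <- c(series$n_frames, 3, series$n_molecules)
    V <- do.call(rbind, lapply(seq_len(series$n_molecules),
                               function(m) V[, , m]))
    s2_of_mat(V)
  }, numeric(1))
  tibble::tibble(residue = series$residues, s2 = s2)
}

#' Per-residue NH vector correlation functions
#'
#' P2 autocorrelation of the NH unit vector on the lag grid, averaged over all
#' time origins and over symmetry-equivalent molecules (correlations are never
#' taken across molecule boundaries).
#'
#' @param series A `"vector_series"`.
#' @param lags Integer frame-lag grid, default [lag_grid()].
#' @param origin_stride Stride over time origins.
#' @return A `"corr_fn"` tibble with a `residue` column.
#' @export
vector_correlation <- function(series, lags = NULL, origin_stride = 1) {
  stopifnot(inherits(series, "vector_series"))
  n <- series$n_frames
  if (is.null(lags)) lags <- lag_grid(n)
  lags <- as.integer(lags)
  if (length(lags) == 0) stop("empty lag grid", call. = FALSE)
  if (any(lags < 0) || any(lags >= n)) {
    stop("lags must lie in [0, n_frames)", call. = FALSE)
  }
  n_res <- length(series$residues)
  out <- vector("list", n_res)
  for (r in seq_len(n_res)) {
    acc <- numeric(length(lags)); n_org <- integer(length(lags))
    for (m in seq_len(series$n_molecules)) {
      V <- series$vectors[, , r, m]
      dim(V) <- c(n, 3)
      for (i in seq_along(lags)) {
        lg <- lags[i]
        org <- seq.int(1L, n - lg, by = origin_stride)
        dot <- rowSums(V[org, , drop = FALSE] * V[org + lg, , drop = FALSE])
        acc[i] <- acc[i] + sum((3 * dot^2 - 1) / 2)
        n_org[i] <- n_org[i] + length(org)
      }
    }
    cf <- new_corr_fn(lags * series$time_step, acc / n_org, n_org,
                      series$time_step)
    cf$residue <- series$residues[r]
    out[[r]] <- cf
  }
  res <- dplyr::bind_rows(out)
  attr(res, "time_step") <- series$time_step
  class(res) <- c("corr_fn", class(res))
  res
}

#' Multi-exponential fit of a correlation function
#'
#' Non-negative least squares over a fixed log-spaced dictionary of
#' correlation times (plus a free constant), followed by pruning to at most
#' `max_terms` components. Correlation times are capped at `tau_cap`
#' (by default the trajectory length): motions slower than the trajectory
#' cannot be distinguished from the constant.
#'
#' Individual (amplitude, tau) pairs of a multi-exponential are not uniquely
#' identifiable; the reconstruction of the curve is (see the package
#' vignette), and downstream spectral densities depend only on it.
#'
#' @param curve A `"corr_fn"` tibble (single curve).
#' @param max_terms Maximum number of exponential components (default 6).
#' @param tau_cap Upper bound on correlation times, seconds; default the
#'   longest lag divided by `max_frac`-style coverage, i.e. the curve extent.
#' @param dictionary_size Number of dictionary correlation times (default 40).
#' @return Object of class `"multiexp_fit"`: `components` tibble
#'   (`amplitude`, `tau`), constant `a0`, `residual_norm`, `fitted`.
#' @export
fit_multiexp <- function(curve, max_terms = 6, tau_cap = NULL,
                         dictionary_size = 40) {
  stopifnot(is.data.frame(curve), all(c("lag_s", "value") %in% names(curve)))
  if (nrow(curve) < 2 * max_terms) {
    stop("need >= ", 2 * max_terms, " lag points", call. = FALSE)
  }
  if (all(curve$value == 0)) stop("all-zero curve cannot be fitted", call. = FALSE)
  ts <- attr(curve, "time_step")
  if (is.null(ts)) ts <- min(curve$lag_s[curve$lag_s > 0])
  if (is.null(tau_cap)) tau_cap <- max(curve$lag_s) * 5
  taus <- exp(seq(log(ts), log(tau_cap), length.out = dictionary_size))
  A <- cbind(1, exp(-outer(curve$lag_s, taus, "/")))
  sol <- pracma::lsqnonneg(A, curve$value)
  amp <- sol$x[-1]
  keep <- which(amp > 0)
  if (length(keep) > max_terms) {
    keep <- keep[order(amp[keep], decreasing = TRUE)][seq_len(max_terms)]
    A2 <- cbind(1, A[, 1 + keep, drop = FALSE])
    sol2 <- pracma::lsqnonneg(A2, curve$value)
    a0 <- sol2$x[1]; amp_k <- sol2$x[-1]; tau_k <- taus[keep]
  } else {
    a0 <- sol$x[1]; amp_k <- amp[keep]; tau_k <- taus[keep]
  }
  ord <- order(tau_k)
  comp <- tibble::tibble(amplitude = amp_k[ord], tau = tau_k[ord])
  # local refinement of the dictionary solution: free (a0, amplitudes,
  # log-taus) within bounds, removing dictionary quantisation
  refine <- function(a0, comp) {
    n_c <- nrow(comp)
    p0 <- c(a0, comp$amplitude, log(comp$tau))
    resid_fn <- function(p) {
      curve$value - (p[1] + as.numeric(
        exp(-outer(curve$lag_s, exp(p[n_c + 2:(n_c + 1)]), "/")) %*%
          p[2:(n_c + 1)]))
    }
    ref <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn,
        lower = c(0, rep(0, n_c), rep(log(ts) - 1, n_c)),
        upper = c(Inf, rep(Inf, n_c), rep(log(tau_cap), n_c)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ref)) return(list(a0 = a0, comp = comp))
    p <- unname(ref$par)
    out <- tibble::tibble(amplitude = p[2:(n_c + 1)],
                          tau = exp(p[n_c + 2:(n_c + 1)]))
    out <- out[out$amplitude > 1e-12, , drop = FALSE]
    list(a0 = p[1], comp = out[order(out$tau), ])
  }
  # merge components closer than a factor 2 in tau (amplitude-weighted
  # geometric mean): nearby pairs are not identifiable and would otherwise
  # split the amplitude of a single physical component
  merge_close <- function(comp) {
    if (nrow(comp) < 2) return(comp)
    groups <- cumsum(c(1, diff(log(comp$tau)) > log(2)))
    dplyr::summarise(dplyr::group_by(comp, grp = groups),
                     tau = exp(sum(.data$amplitude * log(.data$tau)) /
                                 sum(.data$amplitude)),
                     amplitude = sum(.data$amplitude),
                     .groups = "drop")[, c("amplitude", "tau")]
  }
  if (nrow(comp) > 0) {
    r1 <- refine(a0, comp)
    merged <- merge_close(r1$comp)
    if (nrow(merged) < nrow(r1$comp)) {
      r1 <- refine(r1$a0, merged)
    }
    a0 <- r1$a0; comp <- r1$comp
  }
  fitted <- a0 + if (nrow(comp) > 0) {
    as.numeric(exp(-outer(curve$lag_s, comp$tau, "/")) %*% comp$amplitude)
  } else 0
  structure(
    list(components = comp, a0 = a0,
         residual_norm = sqrt(sum((curve$value - fitted)^2)),
         fitted = fitted, tau_cap = tau_cap, curve = curve),
    class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit> constant a0 =", format(x$a0, digits = 4), "\n")
  print(x$components)
  invisible(x)
}

#' Model-free motional description
#'
#' Order parameter plus the time-modulated components of a P2-normalized
#' correlation function, \eqn{C(\tau) = S^2 + \sum_i c_i e^{-\tau/\tau_i}}.
#'
#' @param s2 Order parameter in `[0, 1]`.
#' @param tau Correlation time(s), seconds, one per component.
#' @param c_i Component amplitudes; default `1 - s2` split equally.
#' @return Object of class `"model_free"`.
#' @export
model_free <- function(s2, tau, c_i = NULL) {
  stopifnot(s2 >= 0, s2 <= 1, all(tau > 0))
  if (is.null(c_i)) c_i <- rep((1 - s2) / length(tau), length(tau))
  stopifnot(length(c_i) == length(tau), all(c_i >= 0))
  if (abs(s2 + sum(c_i) - 1) > 1e-6) {
    stop("S2 + sum(c_i) must equal 1 for a normalized correlation function",
         call. = FALSE)
  }
  structure(list(s2 = s2,
                 components = tibble::tibble(amplitude = c_i, tau = tau)),
            class = "model_free")
}

#' Convert a fitted object to a model-free description
#'
#' @param x A `"multiexp_fit"`, `"biexp_fit"`, `"jump_model"` or
#'   `"model_free"` object.
#' @param ... Method arguments; `fit_biexp_base` fits accept `drop_fast` to
#'   drop the fast component (used when mapping rocking fits into slow-motion
#'   relaxation, where a ~ns fast component contributes negligibly).
#' @return A `"model_free"` object.
#' @export
as_model_free <- function(x, ...) UseMethod("as_model_free")

#' @export
as_model_free.model_free <- function(x, ...) x

#' @export
as_model_free.multiexp_fit <- function(x, ...) {
  structure(list(s2 = x$a0, components = x$components), class = "model_free")
}

#' @export
as_model_free.biexp_fit <- function(x, drop_fast = FALSE, ...) {
  if (drop_fast) {
    comp <- tibble::tibble(amplitude = x$c_s, tau = x$tau_s)
    s2 <- 1 - x$c_s
  } else {
    comp <- tibble::tibble(amplitude = c(x$c_f, x$c_s),
                           tau = c(x$tau_f, x$tau_s))
    s2 <- x$plateau
  }
  structure(list(s2 = s2, components = comp), class = "model_free")
}

#' Spectral density of the time-modulated motion
#'
#' \deqn{J(\omega) = \frac{2}{5}\sum_i \frac{c_i \tau_i}{1 + (\omega\tau_i)^2}}
#' Only the decaying portion of the correlation function contributes; the
#' plateau (S2) does not. The 2/5 factor is carried inside J, consistent with
#' P2-normalized correlation functions (C(0) = 1).
#'
#' @param motion A `"model_free"`, `"multiexp_fit"` or `"biexp_fit"` object.
#' @param omega Angular frequency (rad/s), vectorized.
#' @return J(omega) in s/rad.
#' @export
spectral_density <- function(motion, omega) {
  if (!inherits(motion, "model_free")) motion <- as_model_free(motion)
  comp <- motion$components
  if (any(comp$tau < 0)) stop("negative correlation time", call. = FALSE)
  vapply(omega, function(w) {
    (2 / 5) * sum(comp$amplitude * comp$tau / (1 + (w * comp$tau)^2))
  }, numeric(1))
}

#' Longitudinal 15N relaxation rate R1
#'
#' Standard NH-dipolar plus 15N-CSA Redfield expression
#' \deqn{R_1 = \frac{d^2}{4}\left[J(\omega_H - \omega_N) + 3J(\omega_N) +
#' 6J(\omega_H + \omega_N)\right] + c^2 J(\omega_N)}
#' with \eqn{c = \Delta\sigma\,\omega_N/\sqrt{3}}.
#'
#' @param motion Motional model (see [spectral_density()]).
#' @param cond A [spectrometer_conditions()].
#' @return R1 in s^-1.
#' @export
r1_nitrogen <- function(motion, cond) {
  stopifnot(inherits(cond, "spectrometer_conditions"))
  J <- function(w) spectral_density(motion, w)
  wH <- cond$omega_H; wN <- cond$omega_N
  (cond$d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) +
    cond$c_csa^2 * J(wN)
}

#' Global scaling factor between two order-parameter profiles
#'
#' Closed-form least-squares factor \eqn{\alpha = \arg\min_\alpha
#' \sum_r (S^2_{a,r} - \alpha S^2_{b,r})^2} over shared residues, with the RMS
#' deviation before and after scaling.
#'
#' @param profile_a,profile_b Tibbles with columns `residue`, `s2`.
#' @return List with `alpha`, `rms_before`, `rms_after`, `n_shared`.
#' @export
global_s2_scaling <- function(profile_a, profile_b) {
  stopifnot(all(c("residue", "s2") %in% names(profile_a)),
            all(c("residue", "s2") %in% names(profile_b)))
  shared <- dplyr::inner_join(profile_a, profile_b, by = "residue",
                              suffix = c("_a", "_b"))
  shared <- shared[stats::complete.cases(shared), ]
  if (nrow(shared) < 5) stop("need >= 5 shared residues", call. = FALSE)
  alpha <- sum(shared$s2_a * shared$s2_b) / sum(shared$s2_b^2)
  list(alpha = alpha,
       rms_before = sqrt(mean((shared$s2_a - shared$s2_b)^2)),
       rms_after = sqrt(mean((shared$s2_a - alpha * shared$s2_b)^2)),
       n_shared = nrow(shared))
}
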