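# Orientational correlation functions: the isotropic rocking correlation
# g_rock(tau) from rotation series, NH vector correlation functions, lag
# grids, outlier flagging and curve aggregation.

#' Logarithmic lag grid
#'
#' Frame-lag grid for correlation functions: lag 0 plus approximately
#' `per_decade` log-spaced unique integer lags per decade from one frame up to
#' `max_frac` of the trajectory length.
#'
#' @param n_frames Trajectory length in frames.
#' @param per_decade Grid density (default 25 points per decade).
#' @param max_frac Longest lag as a fraction of the trajectory (default 1/5).
#' @return Strictly increasing integer vector of frame lags, starting at 0.
#' @export
lag_grid <- function(n_frames, per_decade = 25, max_frac = 1 / 5) {
  stopifnot(n_frames >= 2, per_decade > 0, max_frac > 0, max_frac <= 1)
  max_lag <- max(1, floor((n_frames - 1) * max_frac))
  if (max_lag == 1) return(c(0L, 1L))
  raw <- 10^seq(0, log10(max_lag), by = 1 / per_decade)
  c(0L, unique(as.integer(round(raw))))
}

# P2 correlation of a rotation series through an explicit vector set.
# mats: 3 x 3 x n array; vectors: k x 3; lags: integer frame lags.
# Vectorized over origins: precompute V = R(t) u_k for all t, k.
p2_rotation_correlation <- function(mats, vectors, lags, origin_stride = 1) {
  n <- dim(mats)[3]
  k <- nrow(vectors)
  U <- t(vectors)                                  # 3 x k
  # Vx/Vy/Vz: n x k matrices of rotated-vector components
  flat <- matrix(aperm(mats, c(3, 2, 1)), n, 9)    # columns: R[i,j] j fast? see below
  # aperm gives index order (frame, col, row): column index = (row-1)*3 + col
  Rx1 <- flat[, 1]; Rx2 <- flat[, 2]; Rx3 <- flat[, 3]   # row 1 of R
  Ry1 <- flat[, 4]; Ry2 <- flat[, 5]; Ry3 <- flat[, 6]
  Rz1 <- flat[, 7]; Rz2 <- flat[, 8]; Rz3 <- flat[, 9]
  Vx <- Rx1 %o% U[1, ] + Rx2 %o% U[2, ] + Rx3 %o% U[3, ]
  Vy <- Ry1 %o% U[1, ] + Ry2 %o% U[2, ] + Ry3 %o% U[3, ]
  Vz <- Rz1 %o% U[1, ] + Rz2 %o% U[2, ] + Rz3 %o% U[3, ]
  vals <- numeric(length(lags))
  n_org <- integer(length(lags))
  for (i in seq_along(lags)) {
    lg <- lags[i]
    org <- seq.int(1L, n - lg, by = origin_stride)
    a <- org; b <- org + lg
    dot <- Vx[a, , drop = FALSE] * Vx[b, , drop = FALSE] +
      Vy[a, , drop = FALSE] * Vy[b, , drop = FALSE] +
      Vz[a, , drop = FALSE] * Vz[b, , drop = FALSE]
    vals[i] <- mean((3 * dot^2 - 1) / 2)
    n_org[i] <- length(org)
  }
  list(values = vals, n_origins = n_org)
}

new_corr_fn <- function(lag_s, value, n_origins, time_step) {
  out <- tibble::tibble(lag_s = lag_s, value = value, n_origins = n_origins)
  attr(out, "time_step") <- time_step
  class(out) <- c("corr_fn", class(out))
  out
}

#' Isotropic rocking correlation function
#'
#' Applies the per-frame rotation matrices to a quasi-uniform set of dipolar
#' probe vectors and computes
#' \deqn{g_{rock}(\tau) = \langle P_2( (\Xi(t)u_k) \cdot (\Xi(t+\tau)u_k) )
#' \rangle_{t,k},}
#' the average running over all time origins (optionally strided) and all
#' vectors. `g_rock(0) = 1` by construction.
#'
#' @param series A `"rotation_series"`, or a `"rotation_series_set"` (a curve
#'   is returned per molecule as a row-bound tibble with a `molecule` column).
#' @param vectors Unit-vector set, default [sphere_vectors()]`(100)`.
#' @param lags Integer frame-lag grid, default [lag_grid()].
#' @param origin_stride Stride over time origins (1 = every origin; larger
#'   values trade averaging for speed on long inputs).
#' @return A `"corr_fn"` tibble (`lag_s`, `value`, `n_origins`), with a
#'   `molecule` column when a set is supplied.
#' @export
rocking_correlation <- function(series, vectors = sphere_vectors(100),
                                lags = NULL, origin_stride = 1) {
  if (inherits(series, "rotation_series_set")) {
    curves <- purrr::map(series, function(s) {
      cf <- rocking_correlation(s, vectors, lags, origin_stride)
      cf$molecule <- s$molecule_id
      cf
    })
    out <- dplyr::bind_rows(curves)
    attr(out, "time_step") <- series[[1]]$time_step
    class(out) <- c("corr_fn", class(out))
    return(out)
  }
  stopifnot(inherits(series, "rotation_series"))
  n <- dim(series$matrices)[3]
  if (is.null(lags)) lags <- lag_grid(n)
  lags <- as.integer(lags)
  if (length(lags) == 0) stop("empty lag grid", call. = FALSE)
  if (any(lags < 0) || any(lags >= n)) {
    stop("lags must lie in [0, n_frames)", call. = FALSE)
  }
  nrm <- sqrt(rowSums(vectors^2))
  vectors <- vectors / nrm
  r <- p2_rotation_correlation(series$matrices, vectors, lags, origin_stride)
  new_corr_fn(lags * series$time_step, r$values, r$n_origins, series$time_step)
}

#' Aggregate correlation curves and flag outliers
#'
#' Computes each curve's root-mean-square deviation from the pointwise median
#' curve; a curve is an outlier when its RMSD exceeds `k_mad` times the median
#' of all RMSDs. The mean curve is taken over non-outliers.
#'
#' @param curves A `"corr_fn"` tibble with a `molecule` column (as returned by
#'   [rocking_correlation()] on a set), or a list of `"corr_fn"` tibbles.
#' @param k_mad Outlier multiplier (default 3).
#' @return List with `mean` (a `"corr_fn"`), `flags` (tibble `molecule`,
#'   `rmsd`, `outlier`).
#' @export
aggregate_and_flag <- function(curves, k_mad = 3) {
  if (is.list(curves) && !is.data.frame(curves)) {
    curves <- dplyr::bind_rows(
      purrr::imap(curves, function(cf, i) {
        if (is.null(cf$molecule)) cf$molecule <- i
        cf
      }))
  }
  stopifnot(is.data.frame(curves), "molecule" %in% names(curves))
  ts <- attr(curves, "time_step")
  wide <- tidyr::pivot_wider(curves[, c("lag_s", "molecule", "value")],
                             names_from = "molecule", values_from = "value")
  if (anyNA(wide)) stop("curves are not on a common lag grid", call. = FALSE)
  n_curve <- ncol(wide) - 1
  if (n_curve < 2) stop("need >= 2 curves", call. = FALSE)
  V <- as.matrix(wide[, -1])
  med <- apply(V, 1, stats::median)
  rmsd <- unname(sqrt(colMeans((V - med)^2)))
  thr <- k_mad * stats::median(rmsd)
  outlier <- rmsd > thr
  keep <- if (all(outlier)) !outlier | TRUE else !outlier
  mean_v <- rowMeans(V[, keep, drop = FALSE])
  n_org <- curves |>
    dplyr::filter(.data$molecule == curves$molecule[[1]]) |>
    dplyr::pull(.data$n_origins)
  list(
    mean = new_corr_fn(wide$lag_s, mean_v, n_org * sum(keep), ts),
    flags = tibble::tibble(molecule = as.integer(colnames(wide)[-1]),
                           rmsd = rmsd, outlier = outlier)
  )
}

#' Bi-exponential-with-flat-base fit of a correlation function
#'
#' Least-squares fit of
#' \deqn{g(\tau) = (1 - c_f - c_s) + c_f e^{-\tau/\tau_f} + c_s e^{-\tau/\tau_s}}
#' with bounds \eqn{c_f, c_s \ge 0} and \eqn{\tau_f, \tau_s} between the time
#' step and the curve length. A multi-start strategy over a log-spaced
#' (tau_f, tau_s) initialisation grid is used and the best-residual solution
#' returned, with components ordered so that tau_f <= tau_s. The flat base
#' `1 - c_f - c_s` is the plateau, reported as the rocking order parameter.
#'
#' Two labelling rules keep `c_s` attached to the physically dominant slow
#' component: components whose time constants differ by less than a factor
#' of two are merged (a mono-exponential curve would otherwise split its
#' amplitude), and a component slower than -- but far weaker than (amplitude
#' below a quarter of) -- the dominant decay is folded into it, since such
#' faint ultra-slow terms arise from correlation-tail drift on finite
#' trajectories rather than from a separate motion.
#'
#' @param curve A `"corr_fn"` tibble (single curve).
#' @param n_starts Number of log-spaced starts per tau axis (default 6).
#' @return Object of class `"biexp_fit"`: list with `c_f`, `c_s`, `tau_f`,
#'   `tau_s`, `plateau`, `residual_norm`, `fitted`, `curve`.
#' @export
fit_biexp_base <- function(curve, n_starts = 6) {
  stopifnot(is.data.frame(curve), all(c("lag_s", "value") %in% names(curve)))
  if (nrow(curve) < 7) stop("need >= 7 lag points", call. = FALSE)
  if (!all(is.finite(curve$value))) stop("curve values must be finite", call. = FALSE)
  tau_min <- attr(curve, "time_step")
  if (is.null(tau_min)) tau_min <- min(curve$lag_s[curve$lag_s > 0])
  t_max <- max(curve$lag_s)
  lg <- curve$lag_s
  y <- curve$value

  model <- function(p) {
    cf <- p[1]; cs <- p[2]; tf <- exp(p[3]); ts_ <- exp(p[4])
    (1 - cf - cs) + cf * exp(-lg / tf) + cs * exp(-lg / ts_)
  }
  resid_fn <- function(p) y - model(p)

  taus <- exp(seq(log(tau_min), log(t_max), length.out = n_starts))
  c0 <- max(1e-4, min(0.5, 1 - min(y)))
  best <- NULL
  for (tf0 in taus) for (ts0 in taus) {
    if (ts0 < tf0) next
    p0 <- c(c0 / 2, c0 / 2, log(tf0), log(ts0))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn,
        lower = c(0, 0, log(tau_min), log(tau_min)),
        upper = c(1, 1, log(t_max), log(t_max)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    stop("bi-exponential fit failed to converge from any start (",
         n_starts^2, " starts, tau in [", format(tau_min), ", ",
         format(t_max), "])", call. = FALSE)
  }
  p <- best$fit$par
  comp <- tibble::tibble(c = p[1:2], tau = exp(p[3:4]))
  comp <- comp[order(comp$tau), ]
  # component labelling: (a) a mono-exponential curve makes the two
  # components degenerate -- merge them so c_s carries the full amplitude;
  # (b) a low-amplitude component *slower* than the dominant one is
  # correlation-tail drift (finite trajectories sample the slow decay a
  # limited number of times), not a separate motion -- fold it into the slow
  # term rather than letting it claim the c_s label
  merge_slow <- (comp$tau[2] > 0 && comp$tau[1] / comp$tau[2] > 0.5) ||
    (sum(comp$c) > 1e-6 && comp$c[2] < 0.25 * comp$c[1])
  if (merge_slow) {
    w <- comp$c
    tau_m <- if (sum(w) > 0) exp(sum(w * log(comp$tau)) / sum(w)) else comp$tau[2]
    comp <- tibble::tibble(c = c(0, sum(w)), tau = c(tau_min, tau_m))
  }
  out <- structure(
    list(c_f = comp$c[1], c_s = comp$c[2],
         tau_f = comp$tau[1], tau_s = comp$tau[2],
         plateau = 1 - sum(comp$c), residual_norm = best$rn,
         fitted = model(p), curve = curve),
    class = "biexp_fit")
  out
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit>\n")
  cat(sprintf("  plateau (S2_rock) : %.4f\n", x$plateau))
  cat(sprintf("  c_f = %.4g  tau_f = %.4g s\n", x$c_f, x$tau_f))
  cat(sprintf("  c_s = %.4g  tau_s = %.4g s\n", x$c_s, x$tau_s))
  cat(sprintf("  residual norm     : %.3g\n", x$residual_norm))
  invisible(x)
}
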