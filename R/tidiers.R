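# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bi-exponential-with-base fit
#'
#' @param x A `"biexp_fit"`.
#' @param ... Unused.
#' @return Tibble with one row per term (`term`, `estimate`).
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c_f", "tau_f", "c_s", "tau_s", "plateau"),
    estimate = c(x$c_f, x$tau_f, x$c_s, x$tau_s, x$plateau))
}

#' @rdname tidy.biexp_fit
#' @return For `glance()`: one-row tibble with `plateau`, `tau_s`,
#'   `residual_norm`, `n_lags`.
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(plateau = x$plateau, tau_s = x$tau_s,
                 residual_norm = x$residual_norm, n_lags = nrow(x$curve))
}

#' Tidy a multi-exponential fit
#'
#' @param x A `"multiexp_fit"`.
#' @param ... Unused.
#' @return Tibble of components (`amplitude`, `tau`) plus the constant as a
#'   `term = "a0"` row.
#' @export
tidy.multiexp_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "a0", estimate = x$a0),
    tibble::tibble(term = paste0("c", seq_len(nrow(x$components))),
                   estimate = x$components$amplitude,
                   tau = x$components$tau))
}

#' @rdname tidy.multiexp_fit
#' @export
glance.multiexp_fit <- function(x, ...) {
  tibble::tibble(a0 = x$a0, n_components = nrow(x$components),
                 residual_norm = x$residual_norm)
}

#' Tidy a mono-exponential decay fit
#'
#' @param x A `"decay_fit"`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std_error`).
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("rate", "amplitude"),
                 estimate = c(x$rate, x$amplitude),
                 std_error = c(x$rate_sd, NA_real_))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, rate_sd = x$rate_sd, n_points = nrow(x$curve),
                 n_mc = x$n_mc)
}

#' Tidy a REDOR chi-square fit
#'
#' @param x A `"redor_fit"`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std_error`).
#' @export
tidy.redor_fit <- function(x, ...) {
  tibble::tibble(term = "coupling_hz", estimate = x$coupling,
                 std_error = x$coupling_sd)
}

#' @rdname tidy.redor_fit
#' @export
glance.redor_fit <- function(x, ...) {
  tibble::tibble(coupling_hz = x$coupling, coupling_sd = x$coupling_sd,
                 refined = x$refined, n_grid = nrow(x$chi2_profile))
}

#' Plot a correlation function
#'
#' Log-lag plot of one or more correlation curves; curves are coloured by
#' molecule or residue when such a column is present.
#'
#' @param object A `"corr_fn"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.corr_fn <- function(object, ...) {
  df <- dplyr::filter(object, .data$lag_s > 0)
  grp <- intersect(c("molecule", "residue"), names(df))
  p <- if (length(grp)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$value,
                                     group = .data[[grp[1]]],
                                     colour = factor(.data[[grp[1]]])))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$value))
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (s)", y = "P2 correlation",
                  colour = if (length(grp)) grp[1] else NULL) +
    ggplot2::theme_minimal()
}

#' Plot an R1rho rate surface
#'
#' Filled raster of log10(R1rho) over (tau, S2).
#'
#' @param object A `"rate_surface"` tibble from [rate_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tau_s, .data$s2,
                                       fill = log10(.data$r1rho))) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "correlation time (s)", y = expression(S^2),
                  fill = expression(log[10](R[1 * rho]))) +
    ggplot2::theme_minimal()
}

#' Plot a bi-exponential-with-base fit over its curve
#'
#' @param object A `"biexp_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biexp_fit <- function(object, ...) {
  df <- tibble::tibble(lag_s = object$curve$lag_s,
                       value = object$curve$value,
                       fitted = object$fitted) |>
    dplyr::filter(.data$lag_s > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (s)", y = expression(g[rock](tau))) +
    ggplot2::theme_minimal()
}

#' Plot per-residue order-parameter profiles
#'
#' @param ... Named tibbles with columns `residue`, `s2` (one line each).
#' @return A ggplot.
#' @export
plot_s2_profiles <- function(...) {
  profs <- list(...)
  if (is.null(names(profs)) || any(names(profs) == "")) {
    names(profs) <- paste0("profile_", seq_along(profs))
  }
  df <- dplyr::bind_rows(purrr::imap(profs, function(p, nm) {
    tibble::tibble(dataset = nm, residue = p$residue, s2 = p$s2)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, .data$s2,
                                   colour = .data$dataset)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "residue", y = expression(S^2)) +
    ggplot2::theme_minimal()
}
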