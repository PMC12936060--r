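# Reduction of fitted cross-basis coefficients to exposure-response and
# lag-response curves with delta-method standard errors.

# Cross-basis coefficient block reshaped to an (df_var x df_lag) matrix;
# column order is exposure-major, so j varies slowest.
cb_beta_matrix <- function(beta_cb, spec) {
  J <- spline_df(spec$var_spec)
  K <- spline_df(spec$lag_spec)
  t(matrix(beta_cb, nrow = K, ncol = J))
}

# Exposure-major gradient layout: column (j-1)*K + k holds dB_j * m_k.
expand_gradient <- function(dB, m) {
  J <- ncol(dB); K <- length(m)
  dB[, rep(seq_len(J), each = K), drop = FALSE] *
    matrix(m[rep(seq_len(K), times = J)], nrow(dB), J * K, byrow = TRUE)
}

#' Overall cumulative exposure-response curve
#'
#' Reduces the fitted cross-basis coefficients to the net-across-lags log
#' relative risk at each grid temperature versus a reference temperature:
#' `log RR(x) = (B(x) - B(ref)) %*% Theta`, with
#' `Theta_j = sum_k beta_jk * M_k` and `M` the cumulative lag weights.
#' Standard errors come from the corresponding quadratic form in the
#' cross-basis covariance.
#'
#' @param fit A [fit_dlnm()] object.
#' @param grid Temperatures at which to evaluate; default a 0.1 deg C grid
#'   spanning the temperatures used in the fit.
#' @param reference Reference temperature (must lie inside the exposure
#'   basis boundary knots). Defaults to the median used temperature.
#'
#' @return A tibble of class `er_curve` with columns `temperature`,
#'   `log_rr`, `se` and `extrapolated` (outside the boundary knots).
#' @export
overall_cumulative <- function(fit, grid = NULL, reference = NULL) {
  stopifnot(inherits(fit, "dlnm_fit"))
  spec <- fit$cb_spec
  bk <- spec$var_spec$boundary_knots
  if (is.null(grid)) {
    grid <- seq(bk[1L], bk[2L], by = 0.1)
  }
  if (is.null(reference)) {
    reference <- stats::median(fit$temps_used)
  }
  if (reference < bk[1L] || reference > bk[2L]) {
    stop("`reference` (", reference, ") lies outside the exposure basis ",
         "boundary knots [", bk[1L], ", ", bk[2L], "].", call. = FALSE)
  }
  M <- cumulative_lag_weights(spec)
  bmat <- cb_beta_matrix(fit$beta_cb, spec)
  theta <- as.numeric(bmat %*% M)
  dB <- ns_basis(grid, spec$var_spec) -
    matrix(ns_basis(reference, spec$var_spec), length(grid),
           spline_df(spec$var_spec), byrow = TRUE)
  log_rr <- as.numeric(dB %*% theta)
  G <- expand_gradient(dB, M)
  se <- sqrt(pmax(rowSums((G %*% fit$vcov_cb) * G), 0))
  out <- tibble::tibble(
    temperature = grid, log_rr = log_rr, se = se,
    extrapolated = grid < bk[1L] | grid > bk[2L]
  )
  class(out) <- c("er_curve", class(out))
  attr(out, "reference") <- reference
  attr(out, "obs_median") <- stats::median(fit$temps_used)
  out
}

#' Lag-specific response at a fixed temperature
#'
#' The log relative risk contributed by each lag `l = 0..max_lag` for a day
#' at `at_temperature` versus the reference:
#' `eta(x, l) = sum_jk beta_jk (B_j(x) - B_j(ref)) C_k(l)`, with
#' delta-method standard errors.
#'
#' @param fit A [fit_dlnm()] object.
#' @param at_temperature Temperature (deg C) of the lag-response curve.
#' @param reference Reference temperature (inside the boundary knots).
#'
#' @return A tibble of class `lag_curve` with columns `lag`, `log_rr`, `se`.
#' @export
lag_response <- function(fit, at_temperature, reference = NULL) {
  stopifnot(inherits(fit, "dlnm_fit"))
  spec <- fit$cb_spec
  bk <- spec$var_spec$boundary_knots
  if (is.null(reference)) reference <- stats::median(fit$temps_used)
  if (reference < bk[1L] || reference > bk[2L]) {
    stop("`reference` (", reference, ") lies outside the exposure basis ",
         "boundary knots [", bk[1L], ", ", bk[2L], "].", call. = FALSE)
  }
  C <- lag_basis_matrix(spec)
  dB <- ns_basis(at_temperature, spec$var_spec) -
    ns_basis(reference, spec$var_spec)
  bmat <- cb_beta_matrix(fit$beta_cb, spec)
  log_rr <- as.numeric(C %*% t(dB %*% bmat))
  # gradient for lag l: entries dB_j * C_k(l), exposure-major
  se <- vapply(seq_len(nrow(C)), function(i) {
    g <- expand_gradient(dB, C[i, ])
    sqrt(max(as.numeric(g %*% fit$vcov_cb %*% t(g)), 0))
  }, numeric(1))
  out <- tibble::tibble(lag = 0:spec$max_lag, log_rr = log_rr, se = se)
  class(out) <- c("lag_curve", class(out))
  attr(out, "at_temperature") <- at_temperature
  attr(out, "reference") <- reference
  out
}

#' Relative risks with Wald confidence bounds
#'
#' Adds `rr`, `rr_low` and `rr_high` columns to an exposure-response or
#' lag-response curve: `RR = exp(log_rr)` with bounds
#' `exp(log_rr +/- z * se)` on the log scale.
#'
#' @param curve An `er_curve` or `lag_curve` tibble.
#' @param level Confidence level in (0, 1).
#'
#' @return The input with added `rr`, `rr_low`, `rr_high` columns.
#' @export
curve_confidence <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "er_curve") || inherits(curve, "lag_curve"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1).",
                                     call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  dplyr::mutate(curve,
                rr = exp(.data$log_rr),
                rr_low = exp(.data$log_rr - z * .data$se),
                rr_high = exp(.data$log_rr + z * .data$se))
}

#' Write a curve table to delimited text
#'
#' Emits `temperature` (or `lag`), `rr`, `rr_low`, `rr_high` columns,
#' suitable for re-plotting exposure-response or lag-response figures.
#'
#' @param curve An `er_curve` or `lag_curve`.
#' @param path Output file path (CSV).
#' @param level Confidence level for the bounds.
#' @return The written tibble, invisibly.
#' @export
write_curve_table <- function(curve, path, level = 0.95) {
  out <- curve_confidence(curve, level)
  axis <- if (inherits(curve, "lag_curve")) "lag" else "temperature"
  out <- dplyr::select(tibble::as_tibble(out),
                       dplyr::all_of(c(axis, "rr", "rr_low", "rr_high")))
  readr::write_csv(out, path)
  invisible(out)
}
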