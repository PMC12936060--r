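#' Locate the minimum mortality temperature on a curve
#'
#' Grid argmin of the cumulative log relative risk within a search range.
#' Ties (within numerical tolerance) are broken toward the temperature
#' closest to the median of the observed distribution.
#'
#' @param curve An `er_curve` from [overall_cumulative()].
#' @param search_range Optional length-2 temperature interval; default the
#'   full curve grid.
#'
#' @return The MMT (deg C), a single number.
#' @export
find_mmt <- function(curve, search_range = NULL) {
  stopifnot(inherits(curve, "er_curve"))
  grid <- curve$temperature
  log_rr <- curve$log_rr
  if (!is.null(search_range)) {
    keep <- grid >= search_range[1L] & grid <= search_range[2L]
    if (!any(keep)) {
      stop("no grid points inside `search_range`.", call. = FALSE)
    }
    grid <- grid[keep]; log_rr <- log_rr[keep]
  }
  obs_median <- attr(curve, "obs_median") %||% stats::median(grid)
  pick_argmin(grid, log_rr, obs_median)
}

# Shared argmin with the flat-tie rule.
pick_argmin <- function(grid, values, center) {
  m <- min(values)
  tol <- 1e-12 * max(1, abs(m))
  cand <- which(values - m <= tol)
  grid[cand[which.min(abs(grid[cand] - center))]]
}

#' Percentile of a temperature in the observed distribution
#'
#' `100 *` the empirical cumulative distribution function at `mmt`: the
#' percentage of days with temperature at or below it.
#'
#' @param mmt Temperature (deg C).
#' @param temps Observed daily temperatures.
#' @return A percent in `[0, 100]`.
#' @export
mmt_percentile <- function(mmt, temps) {
  if (!length(temps)) stop("`temps` is empty.", call. = FALSE)
  100 * mean(temps <= mmt)
}

#' Approximate parametric bootstrap for the MMT
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' fitted cross-basis block with its estimated covariance, recomputes the
#' overall cumulative curve and its argmin for each draw, and summarises
#' the draws into an empirical confidence interval and standard error. The
#' MMT percentile (MMTP) and its interval are read off the same draws
#' against the observed temperature distribution.
#'
#' @param fit A [fit_dlnm()] object.
#' @param temps Temperature distribution used for the MMTP and the default
#'   search grid; defaults to the temperatures used in the fit.
#' @param n_sim Number of bootstrap draws.
#' @param level Confidence level.
#' @param seed Integer seed (draws are deterministic given it).
#' @param grid_step Search grid resolution (deg C).
#' @param repair_vcov If the covariance has (numerically) negative
#'   eigenvalues, clip them to zero instead of erroring.
#'
#' @return A one-row tibble of class `mmt_result`: `mmt`, `mmt_low`,
#'   `mmt_high`, `mmt_se`, `mmtp`, `mmtp_low`, `mmtp_high`, `n_sim`, `seed`.
#' @export
mmt_bootstrap <- function(fit, temps = NULL, n_sim = 1000L, level = 0.95,
                          seed = 1L, grid_step = 0.1, repair_vcov = FALSE) {
  stopifnot(inherits(fit, "dlnm_fit"))
  if (is.null(temps)) temps <- fit$temps_used
  spec <- fit$cb_spec
  V <- (fit$vcov_cb + t(fit$vcov_cb)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    if (!repair_vcov) {
      stop("cross-basis covariance is not positive semi-definite; ",
           "set `repair_vcov = TRUE` to clip negative eigenvalues.",
           call. = FALSE)
    }
    message("clipping ", sum(ev$values < 0),
            " negative eigenvalue(s) of the covariance to zero.")
  }
  lam <- pmax(ev$values, 0)
  V <- ev$vectors %*% (lam * t(ev$vectors))
  bk <- spec$var_spec$boundary_knots
  grid <- seq(bk[1L], bk[2L], by = grid_step)
  B <- ns_basis(grid, spec$var_spec)
  M <- cumulative_lag_weights(spec)
  obs_median <- stats::median(fit$temps_used)
  J <- spline_df(spec$var_spec); K <- spline_df(spec$lag_spec)
  # Theta(beta) is linear: Theta = R beta with R the (J x JK) reduction map.
  R <- expand_gradient(diag(J), M)
  theta_hat <- as.numeric(R %*% fit$beta_cb)
  mmt_hat <- pick_argmin(grid, as.numeric(B %*% theta_hat), obs_median)
  draws <- with_seed(seed, {
    MASS::mvrnorm(n_sim, mu = fit$beta_cb, Sigma = V)
  })
  thetas <- draws %*% t(R)            # n_sim x J
  curves <- B %*% t(thetas)           # grid x n_sim
  mmts <- vapply(seq_len(n_sim), function(i) {
    pick_argmin(grid, curves[, i], obs_median)
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile7(mmts, c(alpha, 1 - alpha))
  out <- tibble::tibble(
    mmt = mmt_hat,
    mmt_low = ci[1L], mmt_high = ci[2L],
    mmt_se = stats::sd(mmts),
    mmtp = mmt_percentile(mmt_hat, temps),
    mmtp_low = mmt_percentile(ci[1L], temps),
    mmtp_high = mmt_percentile(ci[2L], temps),
    n_sim = as.integer(n_sim), seed = as.integer(seed)
  )
  class(out) <- c("mmt_result", class(out))
  attr(out, "draws") <- mmts
  out
}
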