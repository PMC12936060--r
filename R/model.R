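#' Regression model specification
#'
#' Settings for the quasi-Poisson time-series regression: seasonal/long-term
#' control by a natural cubic spline of the day index with
#' `time_df_per_year` degrees of freedom per year, day-of-week indicators,
#' and IRLS convergence control.
#'
#' @param time_df_per_year Degrees of freedom per year for the time spline
#'   (> 0); the total is `round(time_df_per_year * n_days / 365.25)`.
#' @param dow_reference Reference weekday (omitted indicator), one of
#'   "Monday".."Sunday". The choice does not affect fitted means or any
#'   downstream risk estimate.
#' @param max_iterations IRLS iteration cap.
#' @param convergence_tol Relative deviance-change tolerance.
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(time_df_per_year = 10, dow_reference = "Sunday",
                       max_iterations = 100L, convergence_tol = 1e-9) {
  if (time_df_per_year <= 0) {
    stop("`time_df_per_year` must be > 0.", call. = FALSE)
  }
  if (convergence_tol <= 0) stop("`convergence_tol` must be > 0.",
                                 call. = FALSE)
  if (!dow_reference %in% WEEKDAYS) {
    stop("`dow_reference` must be one of: ",
         paste(WEEKDAYS, collapse = ", "), ".", call. = FALSE)
  }
  structure(
    list(time_df_per_year = time_df_per_year, dow_reference = dow_reference,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol),
    class = "model_spec"
  )
}

#' Assemble the regression design matrix
#'
#' Columns: intercept, the cross-basis block, a natural cubic spline of the
#' day index with `round(time_df_per_year * n_days / 365.25)` degrees of
#' freedom (internal knots at equally spaced quantiles of the day index,
#' boundary knots at the first/last day), and six weekday indicators with
#' the reference level omitted. Rows flagged incomplete in the cross-basis
#' are excluded.
#'
#' @param data Tibble with `date`, `tmean`, `deaths`.
#' @param cb A [build_cross_basis()] object aligned with `data` by date.
#' @param spec A [model_spec()].
#'
#' @return List with elements `X` (design matrix), `y` (counts), `dates`,
#'   `cb_cols` (column indices of the cross-basis block) and `time_df`.
#' @export
assemble_design <- function(data, cb, spec = model_spec()) {
  stopifnot(inherits(cb, "cross_basis"), inherits(spec, "model_spec"))
  check_daily_series(data, need_deaths = TRUE, allow_gaps = TRUE)
  if (nrow(data) != length(cb$dates) || any(data$date != cb$dates)) {
    mism <- if (nrow(data) != length(cb$dates)) {
      data$date[1L]
    } else {
      data$date[which(data$date != cb$dates)[1L]]
    }
    stop("`data` and `cb` are misaligned; first mismatching date: ",
         format(mism), ".", call. = FALSE)
  }
  if (any(data$deaths < 0) || any(data$deaths != round(data$deaths))) {
    stop("`deaths` must be non-negative integers.", call. = FALSE)
  }
  n <- nrow(data)
  day_idx <- seq_len(n)
  time_df <- max(2L, as.integer(round(spec$time_df_per_year * n / 365.25)))
  time_basis <- splines::ns(day_idx, df = time_df)
  colnames(time_basis) <- paste0("time", seq_len(ncol(time_basis)))
  wd <- factor(weekday_name(data$date), levels = WEEKDAYS)
  wd <- stats::relevel(wd, ref = spec$dow_reference)
  dow <- stats::model.matrix(~wd)[, -1L, drop = FALSE]
  colnames(dow) <- sub("^wd", "dow_", colnames(dow))
  X <- cbind("(Intercept)" = 1, cb$values, unclass(time_basis), dow)
  keep <- cb$complete
  list(X = X[keep, , drop = FALSE], y = data$deaths[keep],
       dates = data$date[keep],
       cb_cols = 1L + seq_len(ncol(cb$values)), time_df = time_df)
}

#' Fit a quasi-Poisson regression by IRLS
#'
#' Point estimates maximise the Poisson log-likelihood with a log link
#' (iteratively reweighted least squares on a weighted QR decomposition);
#' the dispersion `phi` is the Pearson chi-square divided by residual
#' degrees of freedom, and the coefficient covariance is
#' `phi * (X' W X)^-1` at the final weights.
#'
#' @param X Design matrix (full column rank on the used rows).
#' @param y Non-negative integer counts.
#' @param spec A [model_spec()] (iteration/tolerance control).
#' @param cb_cols Column indices of the cross-basis block for which the
#'   covariance block is extracted (defaults to all columns).
#'
#' @return An object of class `qp_fit`: coefficients, `vcov_cb`,
#'   `dispersion`, `fitted`, `weights`, `n_used`, `rank`, `converged`.
#' @export
fit_quasipoisson <- function(X, y, spec = model_spec(),
                             cb_cols = seq_len(ncol(X))) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (any(y < 0)) stop("`y` must be non-negative.", call. = FALSE)
  fit <- stats::glm.fit(
    x = X, y = y, family = stats::poisson(),
    etastart = log(y + 0.5),
    control = stats::glm.control(epsilon = spec$convergence_tol,
                                 maxit = spec$max_iterations)
  )
  p <- ncol(X)
  if (fit$rank < p) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(aliased, collapse = ", "), ".", call. = FALSE)
  }
  if (!fit$converged) {
    warning("IRLS did not converge within ", spec$max_iterations,
            " iterations.", call. = FALSE)
  }
  mu <- fit$fitted.values
  n <- length(y)
  dispersion <- sum((y - mu)^2 / mu) / (n - p)
  cov_unscaled <- chol2inv(qr.R(fit$qr))
  o <- order(fit$qr$pivot)
  cov_unscaled <- cov_unscaled[o, o, drop = FALSE]
  vcov_full <- dispersion * cov_unscaled
  dimnames(vcov_full) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  structure(
    list(coefficients = beta,
         vcov_cb = vcov_full[cb_cols, cb_cols, drop = FALSE],
         vcov_full = vcov_full,
         dispersion = dispersion,
         fitted = mu, weights = fit$weights,
         n_used = n, rank = fit$rank, converged = fit$converged,
         deviance = fit$deviance),
    class = "qp_fit"
  )
}

#' Fit the temperature-mortality model to a daily series
#'
#' Chains [build_cross_basis()], [assemble_design()] and
#' [fit_quasipoisson()]: a quasi-Poisson regression of daily deaths on the
#' exposure-lag cross-basis, a natural cubic spline of time (default 10 df
#' per year) and day-of-week indicators.
#'
#' @param data Tibble with `date`, `tmean`, `deaths`.
#' @param cb_spec A [cross_basis_spec()]; defaults to temperature knots at
#'   the 10th/75th/90th percentiles and a log-spaced lag spline to 21 days.
#' @param spec A [model_spec()].
#' @param periods Optional period labels passed to [build_cross_basis()].
#'
#' @return An object of class `dlnm_fit` carrying the coefficient vector,
#'   the cross-basis coefficient block and its covariance, the dispersion,
#'   and the data needed for prediction and attribution.
#' @export
#' @examples
#' fx <- madrid_like()
#' temps <- simulate_temperature(400, fx$temperature, seed = 7)
#' sim <- simulate_mortality(temps, fx$surface, fx$baseline, seed = 8)
#' fit <- fit_dlnm(sim)
#' glance(fit)
fit_dlnm <- function(data, cb_spec = NULL, spec = model_spec(),
                     periods = NULL) {
  check_daily_series(data, need_deaths = TRUE,
                     allow_gaps = !is.null(periods))
  if (is.null(cb_spec)) {
    cb_spec <- cross_basis_spec(temperature_spline_spec(data$tmean))
  }
  cb <- build_cross_basis(data, cb_spec, periods = periods)
  design <- assemble_design(data, cb, spec)
  qp <- fit_quasipoisson(design$X, design$y, spec,
                         cb_cols = design$cb_cols)
  structure(
    list(qp = qp,
         beta_cb = qp$coefficients[design$cb_cols],
         vcov_cb = qp$vcov_cb,
         dispersion = qp$dispersion,
         n_used = qp$n_used,
         converged = qp$converged,
         cb_spec = cb_spec,
         model_spec = spec,
         time_df = design$time_df,
         data = data,
         complete = cb$complete,
         temps_used = data$tmean[cb$complete]),
    class = "dlnm_fit"
  )
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat("<dlnm_fit> ", x$n_used, " days used, ",
      length(x$qp$coefficients), " coefficients, dispersion ",
      format(x$dispersion, digits = 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}
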