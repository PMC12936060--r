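#' Temperature component ranges
#'
#' Splits the observed temperature axis into the four standard components
#' around the MMT using the period's empirical percentiles: extreme cold
#' (below P5), moderate cold (P5 to MMT), moderate heat (MMT to P95) and
#' extreme heat (above P95). Under the default tail-inclusive convention the
#' extreme components extend to minus/plus infinity so every temperature
#' except the MMT itself belongs to exactly one component; set
#' `tail_inclusive = FALSE` for the literal P1-P5 / P95-P99 reading, which
#' leaves the beyond-P1/P99 tails unattributed.
#'
#' @param temps Observed daily temperatures of the period.
#' @param mmt The period's minimum mortality temperature. When it falls
#'   outside (P5, P95) — possible for nearly flat curves — the moderate
#'   component on the crossed side becomes empty and a warning is issued.
#' @param tail_inclusive Include the beyond-P1/P99 tails in the extreme
#'   components (default) or cut them at P1/P99.
#'
#' @return A tibble with columns `component`, `lower`, `upper`.
#' @export
component_ranges <- function(temps, mmt, tail_inclusive = TRUE) {
  q <- quantile7(temps, c(0.01, 0.05, 0.95, 0.99))
  p1 <- q[1L]; p5 <- q[2L]; p95 <- q[3L]; p99 <- q[4L]
  if (!(p5 < mmt && mmt < p95)) {
    warning("`mmt` (", format(mmt), ") lies outside (P5, P95) = (",
            format(p5), ", ", format(p95), "); the moderate component on ",
            "the crossed side is empty.", call. = FALSE)
  }
  # degenerate MMTs empty the moderate component on the side they cross
  cold_cut <- min(p5, mmt)
  heat_cut <- max(p95, mmt)
  tibble::tibble(
    component = c("extreme_cold", "moderate_cold", "moderate_heat",
                  "extreme_heat"),
    lower = c(if (tail_inclusive) -Inf else min(p1, cold_cut),
              cold_cut, mmt, heat_cut),
    upper = c(cold_cut, mmt, heat_cut,
              if (tail_inclusive) Inf else max(p99, heat_cut))
  )
}

# Membership in a component range. Ranges on the cold side of the MMT are
# closed below / open above ([lower, upper)); heat-side ranges are open
# below / closed above ((lower, upper]). The MMT itself belongs to none.
in_component <- function(x, lower, upper, mmt) {
  if (upper <= mmt) {
    x >= lower & x < upper
  } else {
    x > lower & x <= upper
  }
}

check_component_ranges <- function(ranges) {
  if (!is.data.frame(ranges) ||
      !all(c("component", "lower", "upper") %in% names(ranges))) {
    stop("`ranges` must be a tibble with `component`, `lower`, `upper`.",
         call. = FALSE)
  }
  if (any(ranges$lower > ranges$upper)) {
    stop("each range must satisfy lower <= upper (zero width = empty).",
         call. = FALSE)
  }
  if (nrow(ranges) > 1L) {
    o <- order(ranges$lower)
    lo <- ranges$lower[o]; hi <- ranges$upper[o]
    if (any(lo[-1L] < hi[-length(hi)])) {
      stop("component ranges overlap.", call. = FALSE)
    }
  }
  invisible(ranges)
}

# Fitted lag-specific log-RR for every day: H[t, l+1] = eta(x_t, l).
fitted_eta_matrix <- function(fit, tmean, reference,
                              beta_cb = fit$beta_cb) {
  spec <- fit$cb_spec
  dB <- ns_basis(tmean, spec$var_spec) -
    matrix(ns_basis(reference, spec$var_spec), length(tmean),
           spline_df(spec$var_spec), byrow = TRUE)
  C <- lag_basis_matrix(spec)
  dB %*% cb_beta_matrix(beta_cb, spec) %*% t(C)
}

# Shared backward-perspective exponent: for each complete day t,
# sum_l eta(x_{t-l}, l) * member(x_{t-l}).
backward_exponent <- function(H, member, max_lag, complete) {
  n <- nrow(H)
  keep <- which(complete)
  expo <- numeric(length(keep))
  for (l in 0:max_lag) {
    src <- keep - l
    expo <- expo + H[cbind(src, l + 1L)] * member[src]
  }
  list(keep = keep, expo = expo)
}

#' Per-day attributable fractions, backward perspective
#'
#' Attributes each day's deaths to the temperatures its population
#' experienced over the preceding lag window:
#' `AF_t = 1 - exp(-sum_{l=0..L} eta(x_{t-l}, l) * I[x_{t-l} in restrict])`
#' with `eta` the fitted lag-specific log relative risk versus the
#' reference. Days without a complete lag history are excluded.
#'
#' @param fit A [fit_dlnm()] object.
#' @param data Daily series; defaults to the data the model was fitted to.
#' @param reference Reference temperature, normally the period MMT; must be
#'   inside the observed range.
#' @param restrict Optional single component range (one row of
#'   [component_ranges()]); `NULL` attributes across all temperatures.
#' @param mmt Reference used to classify range membership sides; defaults
#'   to `reference`.
#'
#' @return Tibble with `date` and `af` for each included day.
#' @export
backward_af_series <- function(fit, data = fit$data, reference,
                               restrict = NULL, mmt = reference) {
  stopifnot(inherits(fit, "dlnm_fit"))
  check_daily_series(data, allow_gaps = TRUE)
  rng <- range(data$tmean)
  if (reference < rng[1L] || reference > rng[2L]) {
    stop("`reference` (", reference, ") lies outside the observed ",
         "temperature range.", call. = FALSE)
  }
  H <- fitted_eta_matrix(fit, data$tmean, reference)
  member <- if (is.null(restrict)) {
    rep(TRUE, nrow(data))
  } else {
    in_component(data$tmean, restrict$lower, restrict$upper, mmt)
  }
  complete <- if (nrow(data) == length(fit$complete)) {
    fit$complete
  } else {
    seq_len(nrow(data)) > fit$cb_spec$max_lag
  }
  be <- backward_exponent(H, member, fit$cb_spec$max_lag, complete)
  tibble::tibble(date = data$date[be$keep], af = 1 - exp(-be$expo))
}

#' Attributable numbers and fractions by temperature component
#'
#' Point estimates of the deaths attributable to each of the four
#' temperature components: `AN_c = sum_t deaths_t * AF_t(component c)` and
#' `AF_c = 100 * AN_c / total deaths` over the days with complete lag
#' history.
#'
#' @param fit A [fit_dlnm()] object.
#' @param data Daily series with deaths; defaults to the fitted data.
#' @param mmt The period MMT, used as the risk reference and to orient the
#'   component ranges.
#' @param ranges A [component_ranges()] tibble.
#'
#' @return A tibble of class `attrib_result`: `component`, `an`, `af`.
#' @export
component_af <- function(fit, data = fit$data, mmt, ranges) {
  check_component_ranges(ranges)
  check_daily_series(data, need_deaths = TRUE, allow_gaps = TRUE)
  afs <- purrr::map(seq_len(nrow(ranges)), function(i) {
    backward_af_series(fit, data, reference = mmt,
                       restrict = ranges[i, ], mmt = mmt)
  })
  keep_dates <- afs[[1L]]$date
  deaths <- data$deaths[match(keep_dates, data$date)]
  total <- sum(deaths)
  out <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    an <- sum(deaths * afs[[i]]$af)
    tibble::tibble(component = ranges$component[i], an = an,
                   af = 100 * an / total)
  })
  class(out) <- c("attrib_result", class(out))
  attr(out, "total_deaths") <- total
  out
}

#' Attributable fractions with Monte-Carlo empirical confidence intervals
#'
#' Resamples the cross-basis coefficients from their estimated multivariate
#' normal sampling distribution, recomputes every component's attributable
#' fraction for each draw (the MMT is held fixed at its central estimate),
#' and reports empirical quantile intervals around the point estimates.
#'
#' @inheritParams component_af
#' @param n_sim Number of coefficient draws.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param repair_vcov Clip negative covariance eigenvalues instead of
#'   erroring.
#'
#' @return A tibble of class `attrib_result` with columns `component`,
#'   `an`, `af`, `af_low`, `af_high`; attributes carry `total_deaths`,
#'   `n_sim` and `seed`.
#' @export
attrib_eci <- function(fit, data = fit$data, mmt, ranges, n_sim = 1000L,
                       level = 0.95, seed = 1L, repair_vcov = FALSE) {
  check_component_ranges(ranges)
  check_daily_series(data, need_deaths = TRUE, allow_gaps = TRUE)
  point <- component_af(fit, data, mmt, ranges)
  V <- (fit$vcov_cb + t(fit$vcov_cb)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    if (!repair_vcov) {
      stop("cross-basis covariance is not positive semi-definite; ",
           "set `repair_vcov = TRUE` to clip negative eigenvalues.",
           call. = FALSE)
    }
  }
  V <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  draws <- with_seed(seed, MASS::mvrnorm(n_sim, mu = fit$beta_cb, Sigma = V))
  complete <- if (nrow(data) == length(fit$complete)) {
    fit$complete
  } else {
    seq_len(nrow(data)) > fit$cb_spec$max_lag
  }
  members <- purrr::map(seq_len(nrow(ranges)), function(i) {
    in_component(data$tmean, ranges$lower[i], ranges$upper[i], mmt)
  })
  deaths_all <- data$deaths
  # basis pieces are draw-independent; only the coefficient reshuffle varies
  spec <- fit$cb_spec
  dB <- ns_basis(data$tmean, spec$var_spec) -
    matrix(ns_basis(mmt, spec$var_spec), nrow(data),
           spline_df(spec$var_spec), byrow = TRUE)
  Ct <- t(lag_basis_matrix(spec))
  af_draws <- matrix(NA_real_, n_sim, nrow(ranges))
  for (s in seq_len(n_sim)) {
    H <- dB %*% cb_beta_matrix(draws[s, ], spec) %*% Ct
    for (i in seq_len(nrow(ranges))) {
      be <- backward_exponent(H, members[[i]], fit$cb_spec$max_lag,
                              complete)
      d <- deaths_all[be$keep]
      af_draws[s, i] <- 100 * sum(d * (1 - exp(-be$expo))) / sum(d)
    }
  }
  alpha <- (1 - level) / 2
  ci <- apply(af_draws, 2L, quantile7, probs = c(alpha, 1 - alpha))
  out <- dplyr::mutate(point, af_low = ci[1L, ], af_high = ci[2L, ])
  class(out) <- c("attrib_result", class(out))
  attr(out, "total_deaths") <- attr(point, "total_deaths")
  attr(out, "n_sim") <- as.integer(n_sim)
  attr(out, "seed") <- as.integer(seed)
  out
}
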