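#' Temperature process parameters
#'
#' Describes a daily mean temperature process: a seasonal sinusoid, a slow
#' linear warming trend and stationary AR(1) noise. The marginal standard
#' deviation of the noise equals `noise_sd` regardless of `ar_coefficient`.
#'
#' @param mean_level Long-run mean temperature (deg C).
#' @param seasonal_amplitude Amplitude of the annual sinusoid (deg C, >= 0).
#' @param phase_day Phase shift of the sinusoid in days; with a 1 January
#'   start the default puts the seasonal peak in mid-July.
#' @param ar_coefficient Lag-1 autocorrelation of the noise, in (-1, 1).
#' @param noise_sd Stationary (marginal) standard deviation of the noise
#'   (deg C, >= 0).
#' @param trend_per_year Linear trend (deg C per year).
#'
#' @return An object of class `temperature_model`.
#' @export
#' @examples
#' temperature_model(mean_level = 14, seasonal_amplitude = 9)
temperature_model <- function(mean_level = 14,
                              seasonal_amplitude = 9,
                              phase_day = 105,
                              ar_coefficient = 0.7,
                              noise_sd = 2.5,
                              trend_per_year = 0) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (seasonal_amplitude < 0) {
    stop("`seasonal_amplitude` must be >= 0.", call. = FALSE)
  }
  if (abs(ar_coefficient) >= 1) {
    stop("`ar_coefficient` must lie strictly inside (-1, 1).", call. = FALSE)
  }
  structure(
    list(mean_level = mean_level, seasonal_amplitude = seasonal_amplitude,
         phase_day = phase_day, ar_coefficient = ar_coefficient,
         noise_sd = noise_sd, trend_per_year = trend_per_year),
    class = "temperature_model"
  )
}

#' Simulate a daily mean temperature series
#'
#' Generates `T_t = mean + trend * t / 365.25 +
#' amplitude * sin(2 * pi * (t - phase) / 365.25) + e_t` on real Gregorian
#' dates, where `e_t` is stationary AR(1) noise with marginal standard
#' deviation `noise_sd`.
#'
#' @param n_days Number of days to simulate (>= 1).
#' @param model A [temperature_model()].
#' @param seed Integer seed; the same seed and model always reproduce the
#'   same series.
#' @param start_date First calendar date of the series.
#'
#' @return A tibble with columns `date` and `tmean`.
#' @export
#' @examples
#' simulate_temperature(10, temperature_model(noise_sd = 0), seed = 1)
simulate_temperature <- function(n_days, model = temperature_model(),
                                 seed = 1L,
                                 start_date = as.Date("2000-01-01")) {
  stopifnot(inherits(model, "temperature_model"))
  if (length(n_days) != 1L || !is.finite(n_days) || n_days < 1) {
    stop("`n_days` must be a positive integer.", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  t_idx <- seq_len(n_days)
  deterministic <- model$mean_level +
    model$trend_per_year * t_idx / 365.25 +
    model$seasonal_amplitude * sin(2 * pi * (t_idx - model$phase_day) / 365.25)
  noise <- with_seed(seed, {
    rho <- model$ar_coefficient
    innov_sd <- model$noise_sd * sqrt(1 - rho^2)
    e <- numeric(n_days)
    e[1L] <- stats::rnorm(1L, sd = model$noise_sd)
    if (n_days > 1L) {
      z <- stats::rnorm(n_days - 1L, sd = innov_sd)
      for (i in 2:n_days) e[i] <- rho * e[i - 1L] + z[i - 1L]
    }
    e
  })
  tibble::tibble(
    date = start_date + (t_idx - 1L),
    tmean = deterministic + noise
  )
}

#' True exposure-lag-response surface
#'
#' Defines the data-generating exposure-response as a piecewise-linear "V"
#' anchored at a known minimum mortality temperature: the cumulative log
#' relative risk rises linearly to `cold_log_rr_at_p1` at temperature `p1`
#' and to `heat_log_rr_at_p99` at `p99`, extrapolating linearly beyond the
#' anchors. The cumulative effect is spread over lags 0..21 by separate
#' cold and heat lag-weight vectors, each summing to one.
#'
#' @param true_mmt Temperature of minimum mortality (deg C).
#' @param cold_log_rr_at_p1 Cumulative log-RR at `p1` relative to
#'   `true_mmt` (>= 0).
#' @param heat_log_rr_at_p99 Cumulative log-RR at `p99` (>= 0).
#' @param cold_lag_weights,heat_lag_weights Length-22 non-negative weight
#'   vectors over lags 0..21, each summing to 1 (tolerance 1e-12).
#' @param p1,p99 Anchor temperatures (deg C) with `p1 < true_mmt < p99`.
#'
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(true_mmt, cold_log_rr_at_p1, heat_log_rr_at_p99,
                         cold_lag_weights, heat_lag_weights, p1, p99) {
  check_weights <- function(w, what) {
    if (length(w) != 22L) {
      stop("`", what, "` must have length 22 (lags 0..21).", call. = FALSE)
    }
    if (any(w < 0)) stop("`", what, "` must be non-negative.", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-12) {
      stop("`", what, "` must sum to 1 (within 1e-12).", call. = FALSE)
    }
    w
  }
  if (cold_log_rr_at_p1 < 0 || heat_log_rr_at_p99 < 0) {
    stop("log-RR parameters must be >= 0.", call. = FALSE)
  }
  if (!(p1 < true_mmt)) {
    stop("`p1` must be below `true_mmt`.", call. = FALSE)
  }
  if (!(p99 > true_mmt)) {
    stop("`p99` must be above `true_mmt`.", call. = FALSE)
  }
  structure(
    list(true_mmt = true_mmt,
         cold_log_rr_at_p1 = cold_log_rr_at_p1,
         heat_log_rr_at_p99 = heat_log_rr_at_p99,
         cold_lag_weights = check_weights(cold_lag_weights, "cold_lag_weights"),
         heat_lag_weights = check_weights(heat_lag_weights, "heat_lag_weights"),
         p1 = p1, p99 = p99),
    class = "true_surface"
  )
}

#' Evaluate the true cumulative log relative risk
#'
#' @param x Temperatures (deg C) at which to evaluate.
#' @param surface A [true_surface()].
#' @param p1,p99 Anchor temperatures; default to those stored in `surface`.
#'
#' @return Numeric vector of cumulative log-RR values, zero at `true_mmt`.
#' @export
true_log_rr <- function(x, surface, p1 = surface$p1, p99 = surface$p99) {
  stopifnot(inherits(surface, "true_surface"))
  if (!(p1 < surface$true_mmt)) {
    stop("`p1` must be below `true_mmt`.", call. = FALSE)
  }
  if (!(p99 > surface$true_mmt)) {
    stop("`p99` must be above `true_mmt`.", call. = FALSE)
  }
  mmt <- surface$true_mmt
  cold <- surface$cold_log_rr_at_p1 * (mmt - x) / (mmt - p1)
  heat <- surface$heat_log_rr_at_p99 * (x - mmt) / (p99 - mmt)
  ifelse(x < mmt, cold, ifelse(x > mmt, heat, 0))
}

# Cold/heat parts of the true response, used by the generator and oracle.
true_response_parts <- function(x, surface) {
  f <- true_log_rr(x, surface)
  list(cold = ifelse(x < surface$true_mmt, f, 0),
       heat = ifelse(x > surface$true_mmt, f, 0))
}

#' Baseline mortality process parameters
#'
#' @param baseline_daily_deaths Expected deaths per day at the seasonal
#'   midpoint with no temperature effect (> 0).
#' @param seasonal_log_amplitude Amplitude of the annual baseline cycle on
#'   the log scale (winter-peaking cosine).
#' @param peak_day Day index at which the baseline seasonal cycle peaks.
#' @param dow_log_effects Length-7 vector of log-scale day-of-week effects,
#'   ordered Monday..Sunday.
#' @param overdispersion Variance inflation factor phi >= 1; counts are
#'   Poisson when 1, otherwise negative binomial with variance `phi * mu`.
#'
#' @return An object of class `baseline_model`.
#' @export
baseline_model <- function(baseline_daily_deaths = 45,
                           seasonal_log_amplitude = 0.1,
                           peak_day = 15,
                           dow_log_effects = rep(0, 7),
                           overdispersion = 1.5) {
  if (baseline_daily_deaths <= 0) {
    stop("`baseline_daily_deaths` must be > 0.", call. = FALSE)
  }
  if (overdispersion < 1) stop("`overdispersion` must be >= 1.", call. = FALSE)
  if (length(dow_log_effects) != 7L) {
    stop("`dow_log_effects` must have length 7 (Monday..Sunday).",
         call. = FALSE)
  }
  structure(
    list(baseline_daily_deaths = baseline_daily_deaths,
         seasonal_log_amplitude = seasonal_log_amplitude,
         peak_day = peak_day,
         dow_log_effects = dow_log_effects,
         overdispersion = overdispersion),
    class = "baseline_model"
  )
}

# Distributed true exponent per day: sum over lags of
# w_cold(l) f_cold(x_{t-l}) + w_heat(l) f_heat(x_{t-l}).
# The first 21 days use the available truncated history with weights
# renormalised (per part) to sum 1.
true_exponent_series <- function(tmean, surface) {
  n <- length(tmean)
  parts <- true_response_parts(tmean, surface)
  wc <- surface$cold_lag_weights
  wh <- surface$heat_lag_weights
  expo <- numeric(n)
  for (t in seq_len(n)) {
    lags <- 0:min(21L, t - 1L)
    idx <- t - lags
    wc_t <- wc[lags + 1L] / sum(wc[lags + 1L])
    wh_t <- wh[lags + 1L] / sum(wh[lags + 1L])
    expo[t] <- sum(wc_t * parts$cold[idx]) + sum(wh_t * parts$heat[idx])
  }
  expo
}

#' Simulate daily death counts over a temperature series
#'
#' Draws overdispersed daily counts whose log-mean combines a baseline level,
#' a seasonal cycle, day-of-week effects and the true temperature response
#' distributed over lags 0..21. Counts are Poisson when `overdispersion = 1`,
#' otherwise negative binomial with mean `mu` and variance
#' `overdispersion * mu` (the quasi-Poisson variance form).
#'
#' @param temps A tibble with `date` and `tmean` columns covering a gap-free
#'   daily sequence.
#' @param surface A [true_surface()].
#' @param baseline A [baseline_model()].
#' @param seed Integer seed.
#'
#' @return The input tibble with an added integer `deaths` column.
#' @export
simulate_mortality <- function(temps, surface, baseline, seed = 1L) {
  check_daily_series(temps)
  stopifnot(inherits(surface, "true_surface"),
            inherits(baseline, "baseline_model"))
  n <- nrow(temps)
  t_idx <- seq_len(n)
  expo <- true_exponent_series(temps$tmean, surface)
  dow <- baseline$dow_log_effects[as.integer(format(temps$date, "%u"))]
  seasonal <- baseline$seasonal_log_amplitude *
    cos(2 * pi * (t_idx - baseline$peak_day) / 365.25)
  mu <- exp(log(baseline$baseline_daily_deaths) + seasonal + dow + expo)
  phi <- baseline$overdispersion
  deaths <- with_seed(seed, {
    if (phi == 1) {
      stats::rpois(n, mu)
    } else {
      # NB with variance phi * mu: size = mu / (phi - 1).
      stats::rnbinom(n, mu = mu, size = mu / (phi - 1))
    }
  })
  dplyr::mutate(temps, deaths = as.integer(deaths))
}

#' Per-day true attributable fractions
#'
#' Backward-perspective attributable fraction of each day's deaths computed
#' from the TRUE surface: `1 - exp(-sum_l contribution(x_{t-l}, l))`, where
#' the lag-l contribution is `w_cold(l) f_cold + w_heat(l) f_heat`, optionally
#' restricted to lagged temperatures inside a component range. Days without a
#' complete 21-day history are dropped, matching the estimator.
#'
#' @param series Tibble with `date` and `tmean` (deaths not needed).
#' @param surface A [true_surface()].
#' @param restrict Optional single row of a [component_ranges()] tibble (or a
#'   list with `lower`, `upper`), restricting contributions to lagged
#'   temperatures inside the range; `NULL` means no restriction.
#' @param mmt_ref Reference temperature used to classify range membership
#'   sides; defaults to the surface's true MMT.
#'
#' @return Tibble with `date` and `af` for days with complete lag history.
#' @export
oracle_af_series <- function(series, surface, restrict = NULL,
                             mmt_ref = surface$true_mmt) {
  check_daily_series(series)
  n <- nrow(series)
  if (n <= 21L) stop("series shorter than the lag window.", call. = FALSE)
  parts <- true_response_parts(series$tmean, surface)
  wc <- surface$cold_lag_weights
  wh <- surface$heat_lag_weights
  contrib <- function(lag) {
    wc[lag + 1L] * parts$cold + wh[lag + 1L] * parts$heat
  }
  member <- if (is.null(restrict)) {
    rep(TRUE, n)
  } else {
    in_component(series$tmean, restrict$lower, restrict$upper, mmt_ref)
  }
  keep <- 22:n
  expo <- numeric(length(keep))
  for (l in 0:21) {
    src <- keep - l
    expo <- expo + contrib(l)[src] * member[src]
  }
  tibble::tibble(date = series$date[keep], af = 1 - exp(-expo))
}

#' Ground-truth attributable numbers and fractions by component
#'
#' Aggregates [oracle_af_series()] over the four temperature components using
#' the true exposure-lag-response surface, for parameter-recovery testing.
#'
#' @param series Tibble with `date`, `tmean` and `deaths`.
#' @param surface A [true_surface()].
#' @param ranges A [component_ranges()] tibble (pairwise-disjoint ranges).
#' @param mmt_ref Reference temperature splitting cold- and heat-side ranges;
#'   defaults to the surface's true MMT.
#'
#' @return Tibble with one row per component: `component`, `an` (attributable
#'   deaths) and `af` (percent of total deaths over included days).
#' @export
oracle_attributable_fraction <- function(series, surface, ranges,
                                         mmt_ref = surface$true_mmt) {
  check_daily_series(series, need_deaths = TRUE)
  check_component_ranges(ranges)
  keep <- 22:nrow(series)
  deaths <- series$deaths[keep]
  total <- sum(deaths)
  res <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    af_t <- oracle_af_series(series, surface, restrict = ranges[i, ],
                             mmt_ref = mmt_ref)$af
    an <- sum(deaths * af_t)
    tibble::tibble(component = ranges$component[i], an = an,
                   af = 100 * an / total)
  })
  attr(res, "total_deaths") <- total
  res
}

#' Madrid-like simulation fixture
#'
#' A named parameter set whose marginal temperature distribution and
#' mortality magnitudes echo a large southern-European city across the
#' 20th century: mean 14 deg C, seasonal amplitude 9 deg C, AR(1) noise with
#' sd 2.5 deg C and coefficient 0.7; baseline 45 deaths/day; true MMT
#' 17 deg C with cumulative RR 1.30 at the 1st percentile and 1.15 at the
#' 99th; geometric cold lag decay over lags 0..21 and heat effects
#' concentrated on lags 0..3. The surface's anchor percentiles are the
#' theoretical marginal P1/P99 of the temperature process, computed by
#' numerical integration over the seasonal phase (no simulation involved).
#'
#' @return A list with elements `temperature` ([temperature_model()]),
#'   `surface` ([true_surface()]) and `baseline` ([baseline_model()]).
#' @export
#' @examples
#' fx <- madrid_like()
#' fx$surface$true_mmt
madrid_like <- function() {
  tm <- temperature_model(mean_level = 14, seasonal_amplitude = 9,
                          phase_day = 105, ar_coefficient = 0.7,
                          noise_sd = 2.5, trend_per_year = 0)
  q <- theoretical_temperature_quantiles(tm, c(0.01, 0.99))
  cold_w <- 0.85^(0:21); cold_w <- cold_w / sum(cold_w)
  heat_w <- c(0.4, 0.3, 0.2, 0.1, rep(0, 18))
  surface <- true_surface(
    true_mmt = 17,
    cold_log_rr_at_p1 = log(1.30),
    heat_log_rr_at_p99 = log(1.15),
    cold_lag_weights = cold_w,
    heat_lag_weights = heat_w,
    p1 = q[1L], p99 = q[2L]
  )
  baseline <- baseline_model(baseline_daily_deaths = 45,
                             seasonal_log_amplitude = 0.1,
                             peak_day = 15,
                             dow_log_effects = c(0.01, 0, -0.01, 0, 0.01,
                                                 -0.02, 0.01),
                             overdispersion = 1.5)
  list(temperature = tm, surface = surface, baseline = baseline)
}

# Quantiles of the theoretical marginal distribution of the temperature
# process (uniform seasonal phase, Gaussian stationary noise), by averaging
# the normal CDF over a fine phase grid and inverting with uniroot.
theoretical_temperature_quantiles <- function(model, probs) {
  theta <- 2 * pi * (seq_len(4096L) - 0.5) / 4096L
  seas <- model$mean_level + model$seasonal_amplitude * sin(theta)
  cdf <- function(v) mean(stats::pnorm((v - seas) / model$noise_sd))
  lo <- model$mean_level - model$seasonal_amplitude - 6 * model$noise_sd
  hi <- model$mean_level + model$seasonal_amplitude + 6 * model$noise_sd
  vapply(probs, function(p) {
    stats::uniroot(function(v) cdf(v) - p, c(lo, hi), tol = 1e-8)$root
  }, numeric(1))
}
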