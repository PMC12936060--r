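test_that("degenerate noise model returns the deterministic mean exactly", {
  m <- temperature_model(mean_level = 14, seasonal_amplitude = 0,
                         noise_sd = 0, trend_per_year = 0)
  out <- simulate_temperature(50, m, seed = 1)
  expect_equal(out$tmean, rep(14, 50))
  expect_s3_class(out, "tbl_df")
  expect_true(inherits(out$date, "Date"))
})

test_that("temperature generator is deterministic given the seed", {
  m <- temperature_model()
  a <- simulate_temperature(500, m, seed = 42)
  b <- simulate_temperature(500, m, seed = 42)
  expect_identical(a, b)
  c <- simulate_temperature(500, m, seed = 43)
  expect_false(identical(a$tmean, c$tmean))
})

test_that("generated temperatures match the model moments", {
  m <- temperature_model(mean_level = 14, seasonal_amplitude = 9,
                         ar_coefficient = 0.7, noise_sd = 2.5,
                         trend_per_year = 0)
  out <- simulate_temperature(36525, m, seed = 7)
  expect_lt(abs(mean(out$tmean) - 14), 0.2)
  # deseasonalise with the known deterministic part, then check the AR(1)
  t_idx <- seq_len(nrow(out))
  det <- 14 + 9 * sin(2 * pi * (t_idx - m$phase_day) / 365.25)
  e <- out$tmean - det
  expect_lt(abs(sd(e) - 2.5), 0.15)
  rho_hat <- cor(e[-1], e[-length(e)])
  expect_lt(abs(rho_hat - 0.7), 0.05)
})

test_that("generator rejects invalid arguments", {
  expect_error(simulate_temperature(0, temperature_model()), "positive")
  expect_error(temperature_model(noise_sd = -1), "noise_sd")
  expect_error(temperature_model(ar_coefficient = 1), "ar_coefficient")
})

test_that("the true V-shaped response honours its anchors", {
  w <- rep(1 / 22, 22)
  s <- true_surface(true_mmt = 17, cold_log_rr_at_p1 = log(1.3),
                    heat_log_rr_at_p99 = log(1.15),
                    cold_lag_weights = w, heat_lag_weights = w,
                    p1 = 2, p99 = 27)
  expect_identical(true_log_rr(17, s), 0)
  expect_equal(true_log_rr(2, s), log(1.3))
  expect_equal(true_log_rr(27, s), log(1.15))
  expect_equal(true_log_rr(22, s), log(1.15) / 2)  # midway linearity
  # linear extrapolation beyond the anchors
  expect_equal(true_log_rr(-3, s), log(1.3) * 20 / 15)
  expect_error(true_surface(17, 0.1, 0.1, w, w, p1 = 18, p99 = 27), "p1")
  expect_error(true_surface(17, 0.1, 0.1, w * 2, w, p1 = 2, p99 = 27),
               "sum to 1")
  expect_error(true_surface(17, -0.1, 0.1, w, w, p1 = 2, p99 = 27), ">= 0")
})

test_that("null surface gives counts at the baseline level", {
  w <- rep(1 / 22, 22)
  s <- true_surface(17, 0, 0, w, w, p1 = 2, p99 = 27)
  b <- baseline_model(baseline_daily_deaths = 40,
                      seasonal_log_amplitude = 0,
                      dow_log_effects = rep(0, 7), overdispersion = 1)
  temps <- simulate_temperature(5000, temperature_model(), seed = 5)
  sim <- simulate_mortality(temps, s, b, seed = 6)
  se <- sqrt(40 / nrow(sim))
  expect_lt(abs(mean(sim$deaths) - 40), 3 * se)
})

test_that("mortality generator is deterministic and overdispersed as asked", {
  fx <- madrid_like()
  temps <- simulate_temperature(300, fx$temperature, seed = 9)
  a <- simulate_mortality(temps, fx$surface, fx$baseline, seed = 10)
  b <- simulate_mortality(temps, fx$surface, fx$baseline, seed = 10)
  expect_identical(a, b)

  # fixed covariates: constant temperature at the MMT, flat baseline
  w <- rep(1 / 22, 22)
  s <- true_surface(17, 0, 0, w, w, p1 = 2, p99 = 27)
  bl <- baseline_model(50, seasonal_log_amplitude = 0,
                       dow_log_effects = rep(0, 7), overdispersion = 3)
  const <- tibble::tibble(date = as.Date("2000-01-01") + 0:19999,
                          tmean = rep(17, 20000))
  sim <- simulate_mortality(const, s, bl, seed = 11)
  ratio <- var(sim$deaths) / mean(sim$deaths)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})

test_that("missing days in the temperature series are named in the error", {
  fx <- madrid_like()
  temps <- simulate_temperature(60, fx$temperature, seed = 1)
  gappy <- temps[-10, ]
  expect_error(
    simulate_mortality(gappy, fx$surface, fx$baseline, seed = 1),
    format(temps$date[10])
  )
})

test_that("oracle AF is zero under a null surface and exact on closed forms", {
  w <- rep(1 / 22, 22)
  null_s <- true_surface(17, 0, 0, w, w, p1 = 2, p99 = 27)
  fx <- madrid_like()
  temps <- simulate_temperature(200, fx$temperature, seed = 21)
  sim <- simulate_mortality(temps, null_s, fx$baseline, seed = 22)
  rg <- component_ranges(sim$tmean, 17)
  orc <- oracle_attributable_fraction(sim, null_s, rg)
  expect_equal(orc$af, rep(0, 4))
  expect_equal(orc$an, rep(0, 4))

  # whole lag window at a temperature with total true log-RR = log 2
  # => AF = 1 - exp(-log 2) = 0.5 exactly, for every complete day
  s2 <- true_surface(17, log(2), 0.1, w, w, p1 = 7, p99 = 27)
  const <- tibble::tibble(date = as.Date("2000-01-01") + 0:59,
                          tmean = rep(7, 60), deaths = rep(1L, 60))
  af <- oracle_af_series(const, s2)
  expect_equal(af$af, rep(0.5, nrow(af)))
})

test_that("oracle AF matches an exhaustive hand computation", {
  fx <- madrid_like()
  s <- fx$surface
  temps <- simulate_temperature(40, fx$temperature, seed = 31)
  # brute force: per day, loop lags and split the response by side
  f <- true_log_rr(temps$tmean, s)
  fc <- ifelse(temps$tmean < s$true_mmt, f, 0)
  fh <- ifelse(temps$tmean > s$true_mmt, f, 0)
  expected <- sapply(22:40, function(t) {
    expo <- 0
    for (l in 0:21) {
      expo <- expo + s$cold_lag_weights[l + 1] * fc[t - l] +
        s$heat_lag_weights[l + 1] * fh[t - l]
    }
    1 - exp(-expo)
  })
  got <- oracle_af_series(temps, s)
  expect_equal(got$af, expected, tolerance = 1e-12)
})

test_that("oracle per-day AF ignores baseline and day-of-week structure", {
  # the attribution formula uses only temperatures and the surface, so the
  # per-day AF must be identical whatever baseline generated the deaths
  fx <- madrid_like()
  temps <- simulate_temperature(120, fx$temperature, seed = 41)
  af1 <- oracle_af_series(temps, fx$surface)
  af2 <- oracle_af_series(dplyr::mutate(temps), fx$surface)
  expect_identical(af1, af2)
})

test_that("madrid-like anchors are the theoretical marginal percentiles", {
  fx <- madrid_like()
  expect_lt(fx$surface$p1, fx$surface$true_mmt)
  expect_gt(fx$surface$p99, fx$surface$true_mmt)
  # large-sample empirical percentiles agree with the numerical-integration
  # anchors to Monte-Carlo accuracy
  temps <- simulate_temperature(73050, fx$temperature, seed = 51)
  emp <- quantile(temps$tmean, c(0.01, 0.99), type = 7, names = FALSE)
  expect_lt(abs(emp[1] - fx$surface$p1), 0.35)
  expect_lt(abs(emp[2] - fx$surface$p99), 0.35)
})
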