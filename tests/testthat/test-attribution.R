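test_that("component ranges follow the percentile/MMT vocabulary", {
  temps <- 0:1000 / 25  # 0..40
  rg <- component_ranges(temps, mmt = 17)
  expect_identical(rg$component, c("extreme_cold", "moderate_cold",
                                   "moderate_heat", "extreme_heat"))
  p <- quantile(temps, c(0.01, 0.05, 0.95, 0.99), type = 7, names = FALSE)
  expect_equal(rg$lower, c(-Inf, p[2], 17, p[3]))
  expect_equal(rg$upper, c(p[2], 17, p[3], Inf))
  # literal tail reading cuts at P1/P99
  rg2 <- component_ranges(temps, 17, tail_inclusive = FALSE)
  expect_equal(rg2$lower[1], p[1])
  expect_equal(rg2$upper[4], p[4])
  # every temperature except the MMT belongs to exactly one component
  x <- c(0.5, 3, 10, 16.99, 17.01, 30, 39.9)
  counts <- rowSums(sapply(seq_len(4), function(i) {
    tempmort:::in_component(x, rg$lower[i], rg$upper[i], 17)
  }))
  expect_equal(counts, rep(1, length(x)))
  expect_equal(sum(sapply(seq_len(4), function(i) {
    tempmort:::in_component(17, rg$lower[i], rg$upper[i], 17)
  })), 0)
  expect_warning(rg3 <- component_ranges(temps, mmt = 0.5), "P5")
  # degenerate MMT empties the moderate cold component
  expect_identical(rg3$lower[2], rg3$upper[2])
  expect_false(any(tempmort:::in_component(seq(0, 40, 0.5),
                                           rg3$lower[2], rg3$upper[2], 0.5)))
})

test_that("null coefficients and reference-only exposure give zero AF", {
  fit <- with_beta_cb(toy_fit(), rep(0, 20))
  af <- backward_af_series(fit, reference = 15)
  expect_equal(af$af, rep(0, nrow(af)))
  # non-null fit, but the whole window at the reference temperature
  fit2 <- toy_fit()
  const <- tibble::tibble(
    date = as.Date("2001-01-01") + 0:59,
    tmean = rep(15, 60), deaths = rep(2L, 60)
  )
  af2 <- backward_af_series(fit2, const, reference = 15)
  expect_equal(af2$af, rep(0, nrow(af2)), tolerance = 1e-12)
})

test_that("backward AF matches the brute-force lag-by-lag oracle", {
  fit <- toy_fit()
  sub <- fit$data[60:150, ]  # spans spring temperatures around the reference
  ref <- round(median(sub$tmean), 1)
  got <- backward_af_series(fit, sub, reference = ref)
  brute <- brute_backward_af(fit, sub$tmean, reference = ref)
  expect_equal(got$af, brute, tolerance = 1e-10)
  # restricted version
  rg <- component_ranges(fit$temps_used, ref)
  member <- tempmort:::in_component(sub$tmean, rg$lower[2], rg$upper[2], ref)
  got_r <- backward_af_series(fit, sub, reference = ref,
                              restrict = rg[2, ], mmt = ref)
  brute_r <- brute_backward_af(fit, sub$tmean, reference = ref,
                               member = member)
  expect_equal(got_r$af, brute_r, tolerance = 1e-10)
})

test_that("restricted exponents add exactly over a partition", {
  fit <- toy_fit()
  mmt <- find_mmt(overall_cumulative(fit))
  rg <- component_ranges(fit$temps_used, mmt)
  total <- backward_af_series(fit, reference = mmt)
  parts <- lapply(seq_len(4), function(i) {
    backward_af_series(fit, reference = mmt, restrict = rg[i, ], mmt = mmt)
  })
  # exponents: -log(1 - af); the MMT itself is in no component, but a
  # continuous temperature never sits exactly on it
  expo_sum <- Reduce(`+`, lapply(parts, function(p) -log(1 - p$af)))
  expect_equal(expo_sum, -log(1 - total$af), tolerance = 1e-12)
})

test_that("small effects make component AFs first-order additive", {
  fit <- with_beta_cb(toy_fit(), rep(0.0005, 20))
  mmt <- find_mmt(overall_cumulative(fit))
  rg <- component_ranges(fit$temps_used, mmt)
  af <- component_af(fit, mmt = mmt, ranges = rg)
  total <- backward_af_series(fit, reference = mmt)
  deaths <- fit$data$deaths[match(total$date, fit$data$date)]
  total_af <- 100 * sum(deaths * total$af) / sum(deaths)
  expect_lt(abs(sum(af$af) - total_af) / abs(total_af), 0.01)
})

test_that("a range never visited attributes exactly zero", {
  fit <- toy_fit()
  far <- tibble::tibble(component = "extreme_heat", lower = 100,
                        upper = Inf)
  af <- component_af(fit, mmt = 15, ranges = far)
  expect_identical(af$af, 0)
  expect_identical(af$an, 0)
})

test_that("cold-monotone coefficients give cold AFs and no heat AFs", {
  fit <- toy_fit()
  spec <- fit$cb_spec
  # build a monotone-cold surface in the basis: project log-RR decreasing
  # in temperature onto the exposure basis, constant over lags
  grid <- seq(spec$var_spec$boundary_knots[1],
              spec$var_spec$boundary_knots[2], by = 0.1)
  B <- ns_basis(grid, spec$var_spec)
  target <- 0.02 * (20 - grid)  # monotone decreasing in temperature
  theta <- qr.solve(cbind(1, B), target)[-1]
  M <- cumulative_lag_weights(spec)
  # constant over lag so that sum_k beta_jk M_k = theta_j
  beta <- as.vector(t(outer(theta / sum(M), rep(1, length(M)))))
  fit2 <- with_beta_cb(fit, beta)
  mmt <- find_mmt(overall_cumulative(fit2))
  rg <- component_ranges(fit$temps_used, mmt)
  af <- component_af(fit2, mmt = mmt, ranges = rg)
  cold <- af$af[af$component %in% c("extreme_cold", "moderate_cold")]
  heat <- af$af[af$component %in% c("moderate_heat", "extreme_heat")]
  expect_true(all(cold >= 0))
  expect_true(all(abs(heat) < 0.5))
})

test_that("overlapping ranges are rejected", {
  fit <- toy_fit()
  bad <- tibble::tibble(component = c("a", "b"),
                        lower = c(0, 5), upper = c(10, 15))
  expect_error(component_af(fit, mmt = 15, ranges = bad), "overlap")
  expect_error(
    oracle_attributable_fraction(fit$data, madrid_like()$surface, bad),
    "overlap"
  )
  rev_rg <- tibble::tibble(component = "x", lower = 10, upper = 5)
  expect_error(component_af(fit, mmt = 15, ranges = rev_rg), "lower")
})

test_that("empirical intervals are seeded and collapse with zero variance", {
  fit <- toy_fit()
  mmt <- find_mmt(overall_cumulative(fit))
  rg <- component_ranges(fit$temps_used, mmt)
  a <- attrib_eci(fit, mmt = mmt, ranges = rg, n_sim = 100, seed = 3)
  b <- attrib_eci(fit, mmt = mmt, ranges = rg, n_sim = 100, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$af_low <= a$af_high))
  fit0 <- fit
  fit0$vcov_cb <- matrix(0, 20, 20)
  z <- attrib_eci(fit0, mmt = mmt, ranges = rg, n_sim = 50, seed = 4)
  expect_equal(z$af_low, z$af, tolerance = 1e-12)
  expect_equal(z$af_high, z$af, tolerance = 1e-12)
})
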