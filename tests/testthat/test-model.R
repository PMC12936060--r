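sim_fixture <- function(n_days, seed, baseline = NULL, surface = NULL) {
  fx <- madrid_like()
  temps <- simulate_temperature(n_days, fx$temperature, seed = seed)
  simulate_mortality(temps, surface %||% fx$surface,
                     baseline %||% fx$baseline, seed = seed + 1L)
}

test_that("design matrix has the documented block structure", {
  sim <- sim_fixture(365, seed = 401)
  spec <- cross_basis_spec(temperature_spline_spec(sim$tmean))
  cb <- build_cross_basis(sim, spec)
  d <- assemble_design(sim, cb, model_spec())
  expect_identical(d$time_df, 10L)  # one year at 10 df per year
  J <- 4L; K <- 5L
  expect_identical(ncol(d$X), 1L + J * K + 10L + 6L)
  expect_identical(nrow(d$X), sum(cb$complete))
  # weekday indicators: one-hot with zeros only on reference days
  dow_block <- d$X[, grep("^dow_", colnames(d$X)), drop = FALSE]
  sums <- rowSums(dow_block)
  expect_true(all(sums %in% c(0, 1)))
  ref_days <- weekday_name(d$dates) == "Sunday"
  expect_identical(unname(sums == 0), unname(ref_days))
})

test_that("misaligned series and cross-basis are reported by date", {
  sim <- sim_fixture(100, seed = 402)
  spec <- cross_basis_spec(temperature_spline_spec(sim$tmean))
  cb <- build_cross_basis(sim, spec)
  shifted <- dplyr::mutate(sim, date = date + 1)
  expect_error(assemble_design(shifted, cb), format(sim$date[1] + 1))
})

test_that("intercept-only fit recovers log of the mean count exactly", {
  y <- c(3L, 5L, 8L, 2L, 7L, 4L)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_quasipoisson(X, y)
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-9)
})

test_that("IRLS coefficients match the Newton-Raphson oracle", {
  withr::with_seed(403, {
    for (rep in 1:3) {
      n <- 200; p <- 8
      X <- cbind(1, matrix(rnorm(n * (p - 1), sd = 0.5), n))
      colnames(X) <- paste0("x", 0:(p - 1))
      beta_true <- rnorm(p, sd = 0.3)
      y <- rpois(n, exp(X %*% beta_true))
      fit <- fit_quasipoisson(X, y)
      oracle <- newton_poisson(X, y)
      expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-8)
    }
  })
})

test_that("Pearson dispersion recovers the generating overdispersion", {
  withr::with_seed(404, {
    n <- 20000
    X <- cbind(1, rnorm(n, sd = 0.3), runif(n))
    colnames(X) <- c("a", "b", "c")
    mu <- exp(X %*% c(3, 0.2, -0.1))
    # variance phi * mu with phi = 3
    y <- rnbinom(n, mu = mu, size = mu / 2)
    fit <- fit_quasipoisson(X, y)
    expect_gt(fit$dispersion, 2.5)
    expect_lt(fit$dispersion, 3.5)
    # pure Poisson: dispersion near 1
    y2 <- rpois(n, mu)
    fit2 <- fit_quasipoisson(X, y2)
    expect_lt(abs(fit2$dispersion - 1), 0.1)
  })
})

test_that("quasi-Poisson point estimates equal Poisson maximum likelihood", {
  sim <- sim_fixture(400, seed = 405)
  spec <- cross_basis_spec(temperature_spline_spec(sim$tmean))
  cb <- build_cross_basis(sim, spec)
  d <- assemble_design(sim, cb)
  fit <- fit_quasipoisson(d$X, d$y)
  ref <- stats::glm.fit(d$X, d$y, family = stats::poisson())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-10)
})

test_that("rank deficiency is reported with the dependent columns", {
  y <- rpois(50, 10)
  X <- cbind(a = rep(1, 50), b = rnorm(50), c = rnorm(50))
  X <- cbind(X, dup = X[, "b"])
  expect_error(fit_quasipoisson(X, y), "dup")
})

test_that("weekday reference choice leaves all risk estimates unchanged", {
  sim <- sim_fixture(731, seed = 406)
  f1 <- fit_dlnm(sim, spec = model_spec(dow_reference = "Sunday"))
  f2 <- fit_dlnm(sim, spec = model_spec(dow_reference = "Wednesday"))
  expect_equal(f1$qp$fitted, f2$qp$fitted, tolerance = 1e-8)
  expect_equal(f1$dispersion, f2$dispersion, tolerance = 1e-8)
  c1 <- overall_cumulative(f1, reference = 17)
  c2 <- overall_cumulative(f2, reference = 17)
  expect_equal(c1$log_rr, c2$log_rr, tolerance = 1e-8)
  mmt1 <- find_mmt(c1); mmt2 <- find_mmt(c2)
  expect_equal(mmt1, mmt2, tolerance = 1e-8)
  rg <- component_ranges(f1$temps_used, mmt1)
  a1 <- component_af(f1, mmt = mmt1, ranges = rg)
  a2 <- component_af(f2, mmt = mmt2, ranges = rg)
  expect_equal(a1$af, a2$af, tolerance = 1e-8)
})

test_that("fit summaries expose coefficients and diagnostics tidily", {
  sim <- sim_fixture(365, seed = 407)
  fit <- fit_dlnm(sim)
  td <- tidy(fit)
  expect_identical(sum(td$block == "crossbasis"), 20L)
  expect_true(all(is.finite(td$std_error[td$block == "crossbasis"])))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gt(gl$dispersion, 0)
  expect_identical(gl$n_used, fit$n_used)
})
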