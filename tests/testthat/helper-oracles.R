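# Independent oracles used across the test suite. These deliberately use
# naive constructions (truncated powers, explicit loops, Newton-Raphson on
# the analytic score) so they share no code path with the package.

# Natural cubic spline via the textbook truncated-power construction:
# basis {1, x, d_k(x) - d_{K-1}(x)} with
# d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k),
# over all knots xi = (boundary_min, internal..., boundary_max).
tp_natural_basis <- function(x, internal_knots, boundary_knots) {
  xi <- c(boundary_knots[1], internal_knots, boundary_knots[2])
  K <- length(xi)
  d <- function(k) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  cols <- cbind(1, x)
  for (k in seq_len(K - 2)) {
    cols <- cbind(cols, d(k) - d(K - 1))
  }
  cols
}

# Least-squares fitted values of y on the column space of M (plus an
# explicit intercept, so spans with/without the constant are comparable).
ls_fitted <- function(M, y) {
  M1 <- cbind(1, M)
  qr.fitted(qr(M1), y)
}

# Cross-basis by explicit quadruple loop over (t, l, j, k).
brute_crossbasis <- function(x, spec) {
  B <- ns_basis(x, spec$var_spec)
  C <- ns_basis(0:spec$max_lag, spec$lag_spec)
  n <- length(x); J <- ncol(B); K <- ncol(C); L <- spec$max_lag
  Q <- matrix(NA_real_, n, J * K)
  for (t in seq_len(n)) {
    if (t <= L) next
    for (j in seq_len(J)) {
      for (k in seq_len(K)) {
        s <- 0
        for (l in 0:L) s <- s + B[t - l, j] * C[l + 1, k]
        Q[t, (j - 1) * K + k] <- s
      }
    }
  }
  Q
}

# Poisson maximum likelihood by Newton-Raphson on the analytic score,
# with step halving; independent of the IRLS path under test.
newton_poisson <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- qr.solve(X, log(y + 0.5))
  loglik <- function(b) {
    eta <- X %*% b
    sum(y * eta - exp(eta))
  }
  ll <- loglik(beta)
  for (it in seq_len(maxit)) {
    mu <- as.numeric(exp(X %*% beta))
    score <- crossprod(X, y - mu)
    info <- crossprod(X * sqrt(mu))
    step <- solve(info, score)
    new_beta <- beta + step
    halved <- 0
    while (loglik(new_beta) < ll && halved < 30) {
      step <- step / 2
      new_beta <- beta + step
      halved <- halved + 1
    }
    if (max(abs(new_beta - beta)) < tol) return(as.numeric(new_beta))
    beta <- new_beta
    ll <- loglik(beta)
  }
  as.numeric(beta)
}

# Lag-by-lag backward attributable fraction by explicit loops.
brute_backward_af <- function(fit, tmean, reference, member = NULL) {
  L <- fit$cb_spec$max_lag
  n <- length(tmean)
  if (is.null(member)) member <- rep(TRUE, n)
  eta <- function(x, l) {
    dB <- ns_basis(x, fit$cb_spec$var_spec) -
      ns_basis(reference, fit$cb_spec$var_spec)
    C <- ns_basis(0:L, fit$cb_spec$lag_spec)
    J <- ncol(dB); K <- ncol(C)
    s <- 0
    for (j in seq_len(J)) {
      for (k in seq_len(K)) {
        s <- s + fit$beta_cb[(j - 1) * K + k] * dB[1, j] * C[l + 1, k]
      }
    }
    s
  }
  af <- rep(NA_real_, n)
  for (t in (L + 1):n) {
    expo <- 0
    for (l in 0:L) {
      if (member[t - l]) expo <- expo + eta(tmean[t - l], l)
    }
    af[t] <- 1 - exp(-expo)
  }
  af[(L + 1):n]
}

# Small fitted model reused by prediction/attribution tests (deterministic).
toy_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # strongly identified: high baseline, doubled effects, no
      # overdispersion, so the fitted MMT sits well inside the range
      fx <- madrid_like()
      surface <- true_surface(
        17, 2 * log(1.3), 2 * log(1.15),
        fx$surface$cold_lag_weights, fx$surface$heat_lag_weights,
        fx$surface$p1, fx$surface$p99
      )
      baseline <- baseline_model(300, seasonal_log_amplitude = 0.05,
                                 dow_log_effects = rep(0, 7),
                                 overdispersion = 1)
      temps <- simulate_temperature(3 * 365, fx$temperature, seed = 301)
      sim <- simulate_mortality(temps, surface, baseline, seed = 302)
      cache <<- fit_dlnm(sim)
    }
    cache
  }
})

# Same fit with the cross-basis coefficient block replaced.
with_beta_cb <- function(fit, beta_cb) {
  fit$beta_cb <- beta_cb
  fit
}
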