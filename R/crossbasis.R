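#' Cross-basis specification
#'
#' Pairs an exposure-dimension spline with a lag-dimension spline evaluated
#' at integer lags `0..max_lag`.
#'
#' @param var_spec A [spline_spec()] for the temperature dimension.
#' @param lag_spec A [spline_spec()] for the lag dimension; its boundary
#'   knots must cover `[0, max_lag]`.
#' @param max_lag Maximum lag in days (>= 1).
#'
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(var_spec, lag_spec = lag_spline_spec(max_lag),
                             max_lag = 21L) {
  stopifnot(inherits(var_spec, "spline_spec"),
            inherits(lag_spec, "spline_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("`max_lag` must be >= 1.", call. = FALSE)
  structure(
    list(var_spec = var_spec, lag_spec = lag_spec, max_lag = max_lag),
    class = "cross_basis_spec"
  )
}

# Lag-basis matrix evaluated at integer lags 0..max_lag: (L+1) x df_lag.
lag_basis_matrix <- function(spec) {
  ns_basis(0:spec$max_lag, spec$lag_spec)
}

#' Cumulative lag weights
#'
#' Column sums of the lag basis over integer lags `0..max_lag`; reducing the
#' fitted coefficients with these weights yields the overall cumulative
#' (net-across-lags) exposure-response.
#'
#' @param spec A [cross_basis_spec()].
#' @return Numeric vector of length `df_lag`.
#' @export
cumulative_lag_weights <- function(spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  colSums(lag_basis_matrix(spec))
}

#' Build the exposure-lag cross-basis matrix
#'
#' Entry for day `t` and column `(j, k)` is
#' `sum_{l=0..L} B_j(x_{t-l}) * C_k(l)` with `B` the exposure basis and `C`
#' the lag basis at integer lags. Columns are ordered exposure-major
#' (`j` varies slowest). Days without a complete `L`-day history within
#' their period carry `NA` entries and are flagged incomplete; the lag
#' window never crosses a period boundary.
#'
#' @param data Tibble with `date` and `tmean`, ordered, no duplicate dates.
#'   Calendar gaps are an error unless `periods` declares them.
#' @param spec A [cross_basis_spec()].
#' @param periods Optional vector (length `nrow(data)`) of period labels;
#'   dates must be gap-free within each period, and lag windows are
#'   truncated at period boundaries.
#'
#' @return An object of class `cross_basis`: a list with the `values`
#'   matrix, logical `complete` flags, the dates, and the spec.
#' @export
build_cross_basis <- function(data, spec, periods = NULL) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  check_daily_series(data, allow_gaps = !is.null(periods))
  n <- nrow(data)
  if (is.null(periods)) {
    periods <- rep(1L, n)
  } else if (length(periods) != n) {
    stop("`periods` must have one label per row of `data`.", call. = FALSE)
  }
  # within-period gap check
  for (p in unique(periods)) {
    d <- data$date[periods == p]
    full <- seq(d[1L], d[length(d)], by = "day")
    if (length(full) != length(d)) {
      absent <- full[!full %in% d]
      stop("date sequence has gaps within period ", p,
           "; first missing date: ", format(absent[1L]), ".", call. = FALSE)
    }
  }
  B <- ns_basis(data$tmean, spec$var_spec)
  C <- lag_basis_matrix(spec)
  J <- ncol(B); K <- ncol(C); L <- spec$max_lag
  jj <- rep(seq_len(J), each = K)
  kk <- rep(seq_len(K), times = J)
  Q <- matrix(0, n, J * K)
  run_id <- cumsum(c(1L, as.integer(periods[-1L] != periods[-n])))
  # position of each row within its period run
  pos <- stats::ave(seq_len(n), run_id, FUN = seq_along)
  for (l in 0:L) {
    Blag <- matrix(NA_real_, n, J)
    ok <- pos > l
    Blag[ok, ] <- B[which(ok) - l, , drop = FALSE]
    Q <- Q + Blag[, jj, drop = FALSE] *
      matrix(C[l + 1L, kk], n, J * K, byrow = TRUE)
  }
  colnames(Q) <- paste0("cb", jj, ".", kk)
  complete <- !is.na(Q[, 1L]) & stats::complete.cases(Q)
  structure(
    list(values = Q, complete = complete, dates = data$date, spec = spec,
         periods = periods),
    class = "cross_basis"
  )
}

#' @export
print.cross_basis <- function(x, ...) {
  cat("<cross_basis> ", nrow(x$values), " days x ", ncol(x$values),
      " columns (", sum(x$complete), " complete rows, max lag ",
      x$spec$max_lag, ")\n", sep = "")
  invisible(x)
}
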