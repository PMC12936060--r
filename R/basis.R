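#' Natural cubic spline specification
#'
#' Holds internal and boundary knots for one dimension of the cross-basis
#' (temperature in deg C, or lag in days). The basis has
#' `length(internal_knots) + 1` columns, plus one if `intercept = TRUE`.
#'
#' @param internal_knots Strictly increasing knots inside the boundary
#'   interval.
#' @param boundary_knots Length-2 vector (min, max).
#' @param intercept Whether the basis spans the constant function.
#'
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(internal_knots, boundary_knots, intercept = FALSE) {
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || !(boundary_knots[1] < boundary_knots[2])) {
    stop("`boundary_knots` must be an increasing pair (min, max).",
         call. = FALSE)
  }
  if (length(internal_knots) == 0L) {
    stop("at least one internal knot is required.", call. = FALSE)
  }
  if (is.unsorted(internal_knots, strictly = TRUE)) {
    stop("`internal_knots` must be strictly increasing.", call. = FALSE)
  }
  if (min(internal_knots) <= boundary_knots[1] ||
      max(internal_knots) >= boundary_knots[2]) {
    stop("internal knots must lie strictly inside the boundary interval.",
         call. = FALSE)
  }
  structure(
    list(internal_knots = internal_knots, boundary_knots = boundary_knots,
         intercept = isTRUE(intercept)),
    class = "spline_spec"
  )
}

spline_df <- function(spec) {
  length(spec$internal_knots) + 1L + as.integer(spec$intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Constructs the basis through B-splines with the natural (linear-beyond-
#' boundary) constraint applied by a linear map. Each column is cubic
#' between knots with continuous second derivative and linear outside the
#' boundary knots.
#'
#' @param x Numeric vector of evaluation points (finite).
#' @param spec A [spline_spec()].
#'
#' @return A plain matrix, `length(x)` rows by `df` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x))
    stop("non-finite values in `x` at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "), ".", call. = FALSE)
  }
  b <- splines::ns(x, knots = spec$internal_knots,
                   Boundary.knots = spec$boundary_knots,
                   intercept = spec$intercept)
  m <- unclass(b)
  attributes(m) <- list(dim = dim(m))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Temperature knots at the 10th, 75th and 90th percentiles
#'
#' Empirical quantiles (linear interpolation of order statistics) of the
#' observed temperature distribution, the internal-knot rule used for the
#' exposure dimension of the cross-basis.
#'
#' @param temps Numeric vector of observed temperatures (>= 30 values).
#' @param probs Quantile probabilities for the internal knots.
#'
#' @return Numeric vector of internal knots.
#' @export
temperature_knots <- function(temps, probs = c(0.10, 0.75, 0.90)) {
  temps <- temps[is.finite(temps)]
  if (length(temps) < 30L) {
    stop("at least 30 temperature observations are required.", call. = FALSE)
  }
  k <- quantile7(temps, probs)
  if (any(diff(k) <= 0) || min(k) <= min(temps) || max(k) >= max(temps)) {
    stop("degenerate temperature distribution: knots coincide with each ",
         "other or with the observed range.", call. = FALSE)
  }
  k
}

#' Exposure-dimension spline specification from observed temperatures
#'
#' Internal knots per [temperature_knots()], boundary knots at the observed
#' minimum and maximum, no intercept (absorbed by the model intercept).
#'
#' @inheritParams temperature_knots
#' @return A [spline_spec()].
#' @export
temperature_spline_spec <- function(temps, probs = c(0.10, 0.75, 0.90)) {
  spline_spec(temperature_knots(temps, probs), range(temps),
              intercept = FALSE)
}

#' Lag knots equally spaced on the log scale
#'
#' `knot_i = max_lag^(i / (n_knots + 1))`, i.e. geometric spacing between
#' lag 1 and `max_lag`.
#'
#' @param max_lag Maximum lag in days (>= 2).
#' @param n_knots Number of internal knots (>= 1).
#'
#' @return Numeric vector of internal knots on the lag axis.
#' @export
#' @examples
#' log_lag_knots(21, 3)  # 21^(1/4), 21^(1/2), 21^(3/4)
log_lag_knots <- function(max_lag = 21, n_knots = 3) {
  if (max_lag < 2) stop("`max_lag` must be >= 2.", call. = FALSE)
  if (n_knots < 1) stop("`n_knots` must be >= 1.", call. = FALSE)
  i <- seq_len(n_knots)
  exp(i / (n_knots + 1) * log(max_lag))
}

#' Lag-dimension spline specification
#'
#' Internal knots per [log_lag_knots()], boundary knots at lags 0 and
#' `max_lag`, with an intercept column (constant over lag) so the cumulative
#' effect across lags is estimable.
#'
#' @inheritParams log_lag_knots
#' @return A [spline_spec()].
#' @export
lag_spline_spec <- function(max_lag = 21, n_knots = 3) {
  spline_spec(log_lag_knots(max_lag, n_knots), c(0, max_lag),
              intercept = TRUE)
}
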