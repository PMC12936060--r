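# Internal helpers shared across modules.

# Empirical quantiles, type-7 (linear interpolation of order statistics).
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

# Locale-independent weekday names from Date objects (ISO: Monday = 1).
WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

weekday_name <- function(dates) {
  WEEKDAYS[as.integer(format(dates, "%u"))]
}

# Validate a daily series data frame: date/tmean (and optionally deaths) columns,
# ordered unique dates with no calendar gaps. Errors name the first missing date.
check_daily_series <- function(data, need_deaths = FALSE, allow_gaps = FALSE) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns `date` and `tmean`.",
         call. = FALSE)
  }
  required <- c("date", "tmean", if (need_deaths) "deaths")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("`data` is missing required column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  if (!inherits(data$date, "Date")) {
    stop("`date` must be a Date column (ISO-8601).", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` has no rows.", call. = FALSE)
  if (anyDuplicated(data$date)) {
    stop("duplicate dates in `data` (first: ",
         format(data$date[duplicated(data$date)][1L]), ").", call. = FALSE)
  }
  if (is.unsorted(data$date)) {
    stop("`data` must be ordered by date.", call. = FALSE)
  }
  if (!allow_gaps) {
    full <- seq(data$date[1L], data$date[nrow(data)], by = "day")
    if (length(full) != nrow(data)) {
      absent <- full[!full %in% data$date]
      stop("date sequence has gaps; first missing date: ",
           format(absent[1L]), ".", call. = FALSE)
    }
  }
  if (anyNA(data$tmean) || any(!is.finite(data$tmean))) {
    bad <- which(!is.finite(data$tmean))
    stop("non-finite temperatures at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), ".", call. = FALSE)
  }
  invisible(data)
}

# One RNG stream per seeded operation, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
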