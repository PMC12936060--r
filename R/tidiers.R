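#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted temperature-mortality model
#'
#' One row per coefficient with its name and estimate; cross-basis
#' coefficients additionally carry standard errors from the quasi-Poisson
#' covariance.
#'
#' @param x A [fit_dlnm()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error` (cross-basis terms
#'   only) and `block` (`"intercept"`, `"crossbasis"`, `"time"`, `"dow"`).
#' @method tidy dlnm_fit
#' @export
tidy.dlnm_fit <- function(x, ...) {
  beta <- x$qp$coefficients
  term <- names(beta)
  block <- dplyr::case_when(
    term == "(Intercept)" ~ "intercept",
    startsWith(term, "cb") ~ "crossbasis",
    startsWith(term, "time") ~ "time",
    TRUE ~ "dow"
  )
  se <- rep(NA_real_, length(beta))
  se[block == "crossbasis"] <- sqrt(diag(x$vcov_cb))
  tibble::tibble(term = term, estimate = unname(beta), std_error = se,
                 block = block)
}

#' Model-level summary of a fitted temperature-mortality model
#'
#' @param x A [fit_dlnm()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_used`, `n_coef`, `dispersion`, `deviance`,
#'   `time_df`, `converged`.
#' @method glance dlnm_fit
#' @export
glance.dlnm_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used,
    n_coef = length(x$qp$coefficients),
    dispersion = x$dispersion,
    deviance = x$qp$deviance,
    time_df = x$time_df,
    converged = x$converged
  )
}

#' Flatten a period result into a one-row summary
#'
#' The row mirrors a decade row of a study summary table: period label,
#' stratum, descriptives, MMT/MMTP with bounds, fit diagnostics, and the
#' four component attributable fractions with interval bounds.
#'
#' @param x A [run_period()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy period_result
#' @export
tidy.period_result <- function(x, ...) {
  wide_af <- x$attribution |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::any_of(c("component", "af", "af_low", "af_high"))) |>
    tidyr::pivot_wider(names_from = "component",
                       values_from = dplyr::any_of(c("af", "af_low",
                                                     "af_high")),
                       names_glue = "{.value}_{component}")
  dplyr::bind_cols(
    tibble::tibble(period = x$label, stratum = x$stratum %||% "all"),
    x$descriptive,
    dplyr::select(tibble::as_tibble(x$mmt), -dplyr::any_of(c("n_sim",
                                                             "seed"))),
    tibble::tibble(dispersion = x$fit$dispersion,
                   converged = x$fit$converged,
                   n_fit = x$fit$n_used),
    wide_af
  )
}
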