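#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an exchange fit
#'
#' One row per estimated parameter with its standard error and the method
#' that produced it (Gauss-Newton covariance, or jackknife after
#' [jackknife_errors()]).
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `se_method`.
#' @export
tidy.exchange_fit <- function(x, ...) x$estimates

#' One-row summary of an exchange fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A tibble with the rates, amplitude factors, objective value and
#'   convergence/degeneracy flags.
#' @export
glance.exchange_fit <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    k_f = e$estimate[e$term == "k_f"],
    k_s = e$estimate[e$term == "k_s"],
    a = x$a, b = x$b,
    objective = x$objective,
    n_points = unname(x$n_points[1]),
    converged = x$converged,
    degenerate = x$degenerate,
    se_method = e$se_method[1])
}

#' Per-observation fitted values and residuals of an exchange fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A tibble with `t`, `channel`, `observed`, `fitted`, `residual`.
#' @export
augment.exchange_fit <- function(x, ...) x$residuals

#' Tidy a fluorescence decay fit
#'
#' @param x A `fluor_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` for
#'   `A0..A3` and `tau1..tau3`; component-level half-times and amplitude
#'   percentages live in `components(x)` / `x$components`.
#' @export
tidy.fluor_fit <- function(x, ...) x$estimates

#' One-row summary of a fluorescence decay fit
#'
#' @param x A `fluor_fit`.
#' @param ... Unused.
#' @return A tibble with the three time constants, amplitude percentages,
#'   offset, objective and flags.
#' @export
glance.fluor_fit <- function(x, ...) {
  cmp <- x$components
  tibble::tibble(
    tau1 = cmp$tau[1], tau2 = cmp$tau[2], tau3 = cmp$tau[3],
    amp1_pct = cmp$amplitude_percent[1],
    amp2_pct = cmp$amplitude_percent[2],
    amp3_pct = cmp$amplitude_percent[3],
    A0 = x$estimates$estimate[x$estimates$term == "A0"],
    objective = x$objective, n_points = x$n_points,
    converged = x$converged, degenerate = x$degenerate)
}

#' Per-observation fitted values and residuals of a fluorescence fit
#'
#' @param x A `fluor_fit`.
#' @param ... Unused.
#' @return A tibble with `t`, `observed`, `fitted`, `residual`.
#' @export
augment.fluor_fit <- function(x, ...) x$residuals
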