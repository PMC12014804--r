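#' Normalize variable fluorescence
#'
#' Converts a raw fluorescence-yield vector to normalized variable
#' fluorescence, \eqn{(F(t) - F_0) / (F_{max} - F_0)}: 0 at the dark level
#' and 1 at the maximal (flash-saturated) level.
#'
#' @param F Raw fluorescence yield vector.
#' @param F0 Dark-level fluorescence.
#' @param Fmax Maximal fluorescence; must exceed `F0`.
#'
#' @return Numeric vector of normalized variable fluorescence.
#' @examples
#' normalize_fv(c(0.7, 1.2), F0 = 0.2, Fmax = 1.2)
#' @export
normalize_fv <- function(F, F0, Fmax) {
  stopifnot(is.numeric(F), is.numeric(F0), is.numeric(Fmax),
            length(F0) == 1L, length(Fmax) == 1L)
  if (!is.finite(F0) || !is.finite(Fmax) || Fmax <= F0)
    stop("`Fmax` must be strictly greater than `F0`", call. = FALSE)
  (F - F0) / (Fmax - F0)
}

#' Deconvolve a variable-fluorescence decay into three exponentials
#'
#' Least-squares fit of the three-component decay model
#' \eqn{A_0 + \sum_{i=1}^{3} A_i e^{-t/\tau_i}} to a normalized
#' variable-fluorescence trace on its (typically logarithmic) measuring
#' grid, with the time-constant ordering \eqn{\tau_1 < \tau_2 < \tau_3}
#' enforced by parameterization. Residuals are computed on the natural
#' signal with uniform weight per point. Parameter uncertainties are the
#' square roots of the diagonal of the Gauss-Newton parameter covariance
#' matrix at the optimum. Amplitudes are additionally reported as
#' percentages of the decaying total ([amplitude_percentages()]), and each
#' time constant as a half-time \eqn{t_{1/2} = \tau \ln 2}.
#'
#' Initialization: candidate time constants are spread over the sampled
#' decades and the amplitudes solved by linear least squares (the model is
#' linear in the amplitudes given the time constants); the best candidate
#' set seeds the Levenberg-Marquardt refinement.
#'
#' If adjacent fitted time constants differ by less than a factor of 3 the
#' result carries a degeneracy warning and a single-exponential comparison
#' fit is stored in `$monoexp` (the three-component result is still
#' returned, never silently swapped).
#'
#' @param trace A `fluor_trace` (from [simulate_fluorescence()] or
#'   [read_fluor_trace()]), or any data frame with columns `t` and
#'   `fv_norm`.
#'
#' @return A `fluor_fit` object; see [tidy.fluor_fit()],
#'   [glance.fluor_fit()], [autoplot.fluor_fit()].
#' @examples
#' p <- fluor_decay_params(0.02, 0.07, 0.37, 0.54, 3.5e-3, 0.289, 1.5)
#' tr <- simulate_fluorescence(p, noise_sigma = 0.01, seed = 5)
#' fit <- fit_fluor_decay(tr)
#' generics::tidy(fit)
#' @export
fit_fluor_decay <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("t", "fv_norm") %in% names(trace)))
  t <- trace$t; y <- trace$fv_norm
  if (any(diff(t) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  span_decades <- log10(max(t) / min(t))
  dens <- (length(t) - 1) / span_decades
  if (span_decades < 4 || dens < 8 - 1e-9)
    warning(sprintf(
      "grid has %.1f points/decade over %.1f decades; >= 8/decade over >= 4 decades recommended",
      dens, span_decades))

  start <- init_fluor(t, y)
  par0 <- fluor_to_par(start)
  res_fn <- function(par) {
    names(par) <- names(par0)
    y - fluor_model_par(t, fluor_from_par(par))
  }
  ans <- minpack.lm::nls.lm(par = par0, fn = res_fn,
                            lower = c(-5, 0, 0, 0, log(min(t) / 10), -15, -15),
                            upper = c(rep(5, 4), log(max(t) * 10), 15, 15),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-13))
  par <- stats::coef(ans); names(par) <- names(par0)
  nat <- fluor_from_par(par)

  cov <- fluor_cov(nat, t, y)
  unc <- sqrt(pmax(diag(cov), 0))
  names(unc) <- names(nat)

  taus <- nat[c("tau1", "tau2", "tau3")]
  amps <- nat[c("A1", "A2", "A3")]
  pct <- amplitude_percentages(pmax(amps, 0))
  degenerate <- any(taus[-1] / taus[-3] < 3) || any(pct < 0.5)
  monoexp <- if (degenerate) fit_monoexp(t, y) else NULL
  if (degenerate)
    warning(paste("components poorly resolved (time constants within 3x or a",
                  "vanishing amplitude); see $monoexp"))
  # delta-method SE of the percentages from the amplitude covariance block
  pct_se <- tryCatch({
    Ai <- unname(amps); S <- sum(Ai)
    Jp <- 100 * (diag(3) / S - outer(Ai, rep(1, 3)) / S^2)
    sqrt(pmax(diag(Jp %*% cov[2:4, 2:4] %*% t(Jp)), 0))
  }, error = function(e) rep(NA_real_, 3))

  estimates <- tibble::tibble(
    term = names(nat),
    estimate = unname(nat),
    std.error = unname(unc))
  components <- tibble::tibble(
    component = c("fast", "middle", "slow"),
    tau = unname(taus),
    tau_se = unname(unc[c("tau1", "tau2", "tau3")]),
    half_time = unname(taus) * log(2),
    amplitude = unname(amps),
    amplitude_percent = pct,
    amplitude_percent_se = pct_se)

  fitted_vals <- fluor_model_par(t, nat)
  structure(list(
    estimates = estimates, components = components,
    covariance = cov,
    params = fluor_decay_params(nat[["A0"]], nat[["A1"]], nat[["A2"]], nat[["A3"]],
                                nat[["tau1"]], nat[["tau2"]], nat[["tau3"]]),
    residuals = tibble::tibble(t = t, observed = y, fitted = fitted_vals,
                               residual = y - fitted_vals),
    objective = ans$deviance, converged = ans$info %in% c(1:4, 6:8), message = ans$message,
    n_points = length(t), degenerate = degenerate, monoexp = monoexp),
    class = "fluor_fit")
}

#' Amplitude percentages of the decaying components
#'
#' Expresses each decaying amplitude as a percentage of the decaying total
#' `A1 + A2 + A3`; the non-decaying offset `A0` is excluded from the base
#' and reported separately by [fit_fluor_decay()].
#'
#' @param A Numeric vector of the three decaying amplitudes (or a
#'   [fluor_decay_params()]).
#' @return Numeric vector of three percentages summing to 100.
#' @examples
#' amplitude_percentages(c(0.07, 0.37, 0.54))
#' @export
amplitude_percentages <- function(A) {
  if (inherits(A, "fluor_decay_params")) A <- c(A$A1, A$A2, A$A3)
  stopifnot(is.numeric(A), length(A) == 3L)
  if (any(A < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  s <- sum(A)
  if (s <= 0) stop("all decaying amplitudes are zero: percentages undefined", call. = FALSE)
  100 * A / s
}

# ---- internals --------------------------------------------------------------

fluor_model_par <- function(t, nat) {
  nat[["A0"]] +
    nat[["A1"]] * exp(-t / nat[["tau1"]]) +
    nat[["A2"]] * exp(-t / nat[["tau2"]]) +
    nat[["A3"]] * exp(-t / nat[["tau3"]])
}

# ordering enforced: tau1 = exp(l1), tau_{i+1} = tau_i * (1 + exp(g_i))
fluor_to_par <- function(nat) {
  c(A0 = nat[["A0"]], A1 = nat[["A1"]], A2 = nat[["A2"]], A3 = nat[["A3"]],
    l1 = log(nat[["tau1"]]),
    g2 = log(max(nat[["tau2"]] / nat[["tau1"]] - 1, 1e-6)),
    g3 = log(max(nat[["tau3"]] / nat[["tau2"]] - 1, 1e-6)))
}

fluor_from_par <- function(par) {
  tau1 <- exp(par[["l1"]])
  tau2 <- tau1 * (1 + exp(par[["g2"]]))
  tau3 <- tau2 * (1 + exp(par[["g3"]]))
  c(A0 = par[["A0"]], A1 = par[["A1"]], A2 = par[["A2"]], A3 = par[["A3"]],
    tau1 = tau1, tau2 = tau2, tau3 = tau3)
}

fluor_cov <- function(nat, t, y) {
  f <- function(v) {
    nv <- nat; nv[] <- v
    y - fluor_model_par(t, nv)
  }
  J <- num_jacobian(f, nat)
  r <- f(nat)
  sigma2 <- sum(r^2) / max(length(r) - length(nat), 1)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, length(nat), length(nat))
  })
  dimnames(cov) <- list(names(nat), names(nat))
  cov
}

# spread candidate taus over the sampled decades; amplitudes are linear
init_fluor <- function(t, y) {
  lo <- log10(min(t)); hi <- log10(max(t))
  centers <- 10^seq(lo + 0.4 * (hi - lo) / 4, hi - 0.4 * (hi - lo) / 4, length.out = 6)
  best <- NULL; best_ssr <- Inf
  combos <- utils::combn(seq_along(centers), 3)
  for (j in seq_len(ncol(combos))) {
    taus <- centers[combos[, j]]
    X <- cbind(1, exp(-outer(t, taus, "/")))
    beta <- tryCatch(stats::coef(stats::lm.fit(X, y)), error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) next
    ssr <- sum((y - X %*% beta)^2)
    if (ssr < best_ssr) {
      best_ssr <- ssr
      best <- c(A0 = unname(beta[1]),
                A1 = max(unname(beta[2]), 1e-4),
                A2 = max(unname(beta[3]), 1e-4),
                A3 = max(unname(beta[4]), 1e-4),
                tau1 = taus[1], tau2 = taus[2], tau3 = taus[3])
    }
  }
  if (is.null(best))
    best <- c(A0 = min(y), A1 = 0.2, A2 = 0.3, A3 = 0.4,
              tau1 = 10^(lo + (hi - lo) / 4), tau2 = 10^((lo + hi) / 2),
              tau3 = 10^(hi - (hi - lo) / 4))
  best
}

fit_monoexp <- function(t, y) {
  res_fn <- function(par) y - (par[1] + par[2] * exp(-t / exp(par[3])))
  tau0 <- 10^mean(log10(range(t)))
  ans <- minpack.lm::nls.lm(par = c(A0 = min(y), A1 = max(y) - min(y), lt = log(tau0)),
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(ans)
  list(A0 = unname(p[1]), A1 = unname(p[2]), tau = exp(unname(p[3])),
       objective = ans$deviance, converged = ans$info %in% c(1:4, 6:8))
}

#' @export
print.fluor_fit <- function(x, ...) {
  cat("Three-exponential variable-fluorescence decay fit\n")
  cmp <- x$components
  for (i in 1:3) {
    tau <- cmp$tau[i]
    unit <- if (tau < 1) c(1e3, "ms") else c(1, "s")
    cat(sprintf("  %-6s tau = %.3g %s +/- %.2g (%.1f%%)\n", cmp$component[i],
                tau * as.numeric(unit[1]), unit[2],
                cmp$tau_se[i] * as.numeric(unit[1]), cmp$amplitude_percent[i]))
  }
  cat(sprintf("  A0 = %.3g, n = %d, SSR = %.3g, converged: %s\n",
              x$estimates$estimate[1], x$n_points, x$objective, x$converged))
  if (x$degenerate) cat("  warning: poorly resolved components; see $monoexp\n")
  invisible(x)
}
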