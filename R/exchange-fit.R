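#' Global fit of the two-channel isotope-labeling kinetics
#'
#' Estimates the fast and slow substrate-water exchange rate constants by
#' simultaneous weighted least squares on both isotopologue channels: the
#' m/z 34 signal against `scale_34` times the biphasic model
#' ([mz34_model()]) and the m/z 36 signal against `scale_36` times the
#' monophasic model ([mz36_model()]), with the slow rate `k_s` shared
#' between the two channels. The fast-phase amplitude factor is fixed from
#' the enrichment ([fast_fraction_a()]) and the inter-flash correction from
#' the flash protocol ([interflash_b()]) unless overridden. Rates are fit
#' on a log scale with the ordering `k_f > k_s` enforced by
#' parameterization (`k_f = k_s + exp(u)`), and per-channel positive scale
#' factors absorb the raw signal units.
#'
#' Optimization uses Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]), initialized by a two-segment log-linear
#' heuristic (late-time slope of the m/z 36 channel for `k_s`, early-time
#' residual decay of the m/z 34 channel for `k_f`) with a coarse
#' log-spaced grid search as fallback. Parameter standard errors come from
#' the Gauss-Newton covariance at the optimum; [jackknife_errors()]
#' replaces them with resampling-based ones.
#'
#' @param trace A `mims_trace`, preprocessed ([preprocess_mims()]) or
#'   artifact-free; only samples after the injection time are fit.
#' @param enrichment An [enrichment_spec()].
#' @param protocol A [flash_protocol()].
#' @param fix_a Keep the fast-phase amplitude factor fixed at its
#'   enrichment-derived value (default). If `FALSE`, it is a bounded free
#'   parameter in (0, 1).
#' @param b_override Numeric override for the inter-flash correction
#'   factor (e.g. `1` to disable the correction); `NULL` (default) derives
#'   it from `protocol`.
#' @param weighting `"uniform"` (default) or `"inverse_variance"`, the
#'   latter weighting each channel by the reciprocal noise SD estimated
#'   from its pre-injection baseline samples.
#' @param init `"loglinear"` (default) or `"grid"`.
#' @param k_bounds Allowed range for both rate constants, s^-1.
#' @param mixing_tau Non-instant mixing time constant, s, applied to the
#'   model as a first-order convolution; 0 (default) fits the pure
#'   step-enrichment model.
#' @param jackknife Also run [jackknife_errors()] on the result.
#'
#' @return An `exchange_fit` object; see [tidy.exchange_fit()],
#'   [glance.exchange_fit()], [autoplot.exchange_fit()].
#' @examples
#' tr <- simulate_mims(exchange_params(111, 0.93), enrichment_spec(0.13),
#'                     flash_protocol("S2", k_f_s3 = 29),
#'                     noise_sigma = 0.01, seed = 11)
#' fit <- fit_exchange(tr, enrichment_spec(0.13), flash_protocol("S2", k_f_s3 = 29))
#' generics::tidy(fit)
#' @export
fit_exchange <- function(trace, enrichment, protocol,
                         fix_a = TRUE, b_override = NULL,
                         weighting = c("uniform", "inverse_variance"),
                         init = c("loglinear", "grid"),
                         k_bounds = c(1e-6, 1e6),
                         mixing_tau = 0,
                         jackknife = FALSE) {
  stopifnot(inherits(trace, "mims_trace"),
            inherits(enrichment, "enrichment_spec"),
            inherits(protocol, "flash_protocol"))
  weighting <- match.arg(weighting)
  init <- match.arg(init)
  stopifnot(length(k_bounds) == 2L, all(k_bounds > 0), k_bounds[1] < k_bounds[2])

  t0 <- injection_time(trace) %||% 0
  post <- trace$t > t0
  td <- trace$t[post] - t0
  y34 <- trace$mz34[post]
  y36 <- trace$mz36[post]
  n <- length(td)
  if (n < 8) stop("need >= 8 post-injection points per channel to fit", call. = FALSE)

  w <- c(mz34 = 1, mz36 = 1)
  if (weighting == "inverse_variance") {
    pre <- trace$t < t0
    if (sum(pre) >= 3) {
      sds <- c(stats::sd(trace$mz34[pre]), stats::sd(trace$mz36[pre]))
      if (all(is.finite(sds)) && all(sds > 0)) w <- 1 / sds
    } else {
      warning("inverse-variance weighting requested but no baseline samples; using uniform")
    }
  }

  a_fixed <- fast_fraction_a(enrichment)
  b <- if (is.null(b_override)) interflash_b(protocol) else b_override
  if (!is.finite(b) || b <= 0 || b > 1) stop("`b_override` must lie in (0, 1]", call. = FALSE)

  # common internal rescaling: exact invariance of the rates under joint
  # channel scaling (the per-channel scale estimates are mapped back)
  yscale <- mean(abs(c(y34, y36)))
  if (!is.finite(yscale) || yscale <= 0) yscale <- 1
  y34 <- y34 / yscale
  y36 <- y36 / yscale

  start_nat <- init_exchange(td, y34, y36, a = a_fixed, b = b,
                             strategy = init, mixing_tau = mixing_tau)
  config <- list(fix_a = fix_a, b = b, b_overridden = !is.null(b_override),
                 weighting = weighting, init = init, k_bounds = k_bounds,
                 mixing_tau = mixing_tau, a_fixed = a_fixed,
                 enrichment = enrichment, protocol = protocol)
  data <- list(t = td, y34 = y34, y36 = y36, w = w)

  fit <- exchange_lm(data, start_nat, config)

  est_terms <- c("k_f", "k_s", "scale_34", "scale_36", if (!fix_a) "a")
  se <- exchange_cov_se(fit$estimate, data, config)
  est_nat <- fit$estimate
  est_nat[c("scale_34", "scale_36")] <- est_nat[c("scale_34", "scale_36")] * yscale
  se[c("scale_34", "scale_36")] <- se[c("scale_34", "scale_36")] * yscale
  estimates <- tibble::tibble(term = est_terms,
                              estimate = unname(est_nat[est_terms]),
                              std.error = unname(se[est_terms]),
                              se_method = "covariance")

  kf <- fit$estimate[["k_f"]]; ks <- fit$estimate[["k_s"]]
  at_bounds <- kf <= k_bounds[1] * 1.01 || kf >= k_bounds[2] * 0.99 ||
    ks <= k_bounds[1] * 1.01 || ks >= k_bounds[2] * 0.99
  if (at_bounds) warning("a rate estimate is at its bound; result may be unreliable")

  degenerate <- kf / ks < 2
  monophasic <- if (degenerate) fit_monophasic(data) else NULL
  if (!is.null(monophasic)) {
    monophasic$scale_34 <- monophasic$scale_34 * yscale
    monophasic$scale_36 <- monophasic$scale_36 * yscale
  }
  if (degenerate)
    warning(sprintf("k_f/k_s = %.2f < 2: phases poorly separated; see $monophasic", kf / ks))

  mdl <- exchange_model_values(fit$estimate, td, config)
  resids <- tibble::tibble(
    t = rep(td, 2L),
    channel = rep(c("mz34", "mz36"), each = n),
    observed = c(y34, y36) * yscale,
    fitted = c(mdl$m34, mdl$m36) * yscale,
    residual = (c(y34, y36) - c(mdl$m34, mdl$m36)) * yscale)

  out <- structure(list(
    estimates = estimates,
    a = fit$estimate[["a"]], b = b,
    residuals = resids,
    objective = fit$deviance * yscale^2,
    converged = fit$converged, message = fit$message,
    n_points = c(mz34 = n, mz36 = n),
    at_bounds = at_bounds, degenerate = degenerate, monophasic = monophasic,
    data = data, yscale = yscale, config = config, start = fit$par_transformed,
    jackknife = NULL), class = "exchange_fit")
  if (jackknife) out <- jackknife_errors(out)
  out
}

# ---- internal machinery -----------------------------------------------------

# transform natural parameters <-> optimizer parameterization
exch_to_par <- function(nat, fix_a) {
  p <- c(lks = log(nat[["k_s"]]),
         ldk = log(max(nat[["k_f"]] - nat[["k_s"]], 1e-12)),
         ls34 = log(nat[["scale_34"]]), ls36 = log(nat[["scale_36"]]))
  if (!fix_a) p <- c(p, la = stats::qlogis(min(max(nat[["a"]], 1e-6), 1 - 1e-6)))
  p
}

exch_from_par <- function(par, config) {
  ks <- exp(par[["lks"]])
  kf <- ks + exp(par[["ldk"]])
  a <- if (config$fix_a) config$a_fixed else stats::plogis(par[["la"]])
  c(k_f = kf, k_s = ks, scale_34 = exp(par[["ls34"]]), scale_36 = exp(par[["ls36"]]),
    a = a)
}

exchange_model_values <- function(nat, t, config) {
  prm <- exchange_params(nat[["k_f"]], nat[["k_s"]])
  ker <- mims_kernel(t, prm, a = nat[["a"]], b = config$b,
                     mixing_tau = config$mixing_tau)
  list(m34 = nat[["scale_34"]] * ker$y34, m36 = nat[["scale_36"]] * ker$y36)
}

exchange_residuals_nat <- function(nat, data, config) {
  mdl <- exchange_model_values(nat, data$t, config)
  c(data$w[1] * (data$y34 - mdl$m34), data$w[2] * (data$y36 - mdl$m36))
}

exchange_lm <- function(data, start_nat, config) {
  fix_a <- config$fix_a
  kb <- log(config$k_bounds)
  par0 <- exch_to_par(start_nat, fix_a)
  lower <- c(lks = kb[1], ldk = log(1e-9), ls34 = -30, ls36 = -30)
  upper <- c(lks = kb[2], ldk = kb[2] + log(2), ls34 = 30, ls36 = 30)
  if (!fix_a) { lower <- c(lower, la = -15); upper <- c(upper, la = 15) }
  res_fn <- function(par) {
    names(par) <- names(par0)
    exchange_residuals_nat(exch_from_par(par, config), data, config)
  }
  # analytic Jacobian (step-enrichment model only): locates the optimum to
  # near machine precision, which a forward-difference Jacobian cannot
  jac_fn <- if (config$mixing_tau == 0) function(par) {
    names(par) <- names(par0)
    exchange_jacobian_par(par, data, config)
  } else NULL
  ans <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = res_fn,
                            jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-16, ptol = 1e-15))
  par <- stats::coef(ans); names(par) <- names(par0)
  if (!is.null(jac_fn)) par <- gn_polish(par, res_fn, jac_fn)
  list(estimate = exch_from_par(par, config),
       par_transformed = par,
       deviance = sum(res_fn(par)^2),
       converged = ans$info %in% c(1:4, 6:8),
       message = ans$message)
}

# Gauss-Newton polish: a few fixed-point steps on the analytic gradient
# locate the optimum beyond the SSR rounding floor that limits LM stopping
gn_polish <- function(par, res_fn, jac_fn, steps = 4, max_step = 1e-3) {
  for (i in seq_len(steps)) {
    r <- res_fn(par)
    J <- jac_fn(par)
    delta <- tryCatch(solve(crossprod(J), crossprod(J, r)), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    if (max(abs(delta)) > max_step) break  # not in the quadratic basin
    par <- par - drop(delta)
    if (max(abs(delta)) < 1e-14) break
  }
  par
}

# Jacobian of the stacked weighted residuals w.r.t. the transformed
# parameters (lks, ldk, ls34, ls36[, la]); valid for mixing_tau = 0
exchange_jacobian_par <- function(par, data, config) {
  nat <- exch_from_par(par, config)
  kf <- nat[["k_f"]]; ks <- nat[["k_s"]]
  s34 <- nat[["scale_34"]]; s36 <- nat[["scale_36"]]
  a <- nat[["a"]]; b <- config$b
  t <- data$t
  ef <- exp(-kf * t); es <- exp(-ks * t)
  m34 <- a * (1 - b * ef) + (1 - a) * (1 - es)
  m36 <- 1 - es
  dm34_dkf <- a * b * t * ef
  dm34_dks <- (1 - a) * t * es
  dm36_dks <- t * es
  # chain rule through kf = ks + exp(ldk), ks = exp(lks)
  d34 <- cbind(lks = -(dm34_dkf + dm34_dks) * ks,
               ldk = -dm34_dkf * (kf - ks),
               ls34 = -m34, ls36 = 0)
  d36 <- cbind(lks = -dm36_dks * ks, ldk = 0, ls34 = 0, ls36 = -m36)
  # residual = w (y - s m), s = exp(ls): every column carries the factor -w s
  J <- rbind(data$w[1] * s34 * d34, data$w[2] * s36 * d36)
  if (!config$fix_a) {
    dm34_da <- (1 - b * ef) - (1 - es)
    J <- cbind(J, la = c(data$w[1] * s34 * -dm34_da * a * (1 - a),
                         rep(0, length(t))))
  }
  J
}

# Gauss-Newton covariance standard errors on the natural scale
exchange_cov_se <- function(nat, data, config) {
  terms <- c("k_f", "k_s", "scale_34", "scale_36", if (!config$fix_a) "a")
  x <- nat[terms]
  f <- function(v) {
    nv <- nat; nv[terms] <- v
    exchange_residuals_nat(nv, data, config)
  }
  J <- num_jacobian(f, x)
  r <- f(x)
  dof <- length(r) - length(x)
  sigma2 <- sum(r^2) / max(dof, 1)
  se <- rep(NA_real_, length(x)); names(se) <- terms
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  se
}

num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# two-segment log-linear initialization with coarse-grid fallback
init_exchange <- function(t, y34, y36, a, b, strategy = "loglinear", mixing_tau = 0) {
  plateau <- function(y) {
    k <- max(5L, ceiling(length(y) * 0.1))
    mean(utils::tail(y, k))
  }
  s36 <- plateau(y36); s34 <- plateau(y34)
  if (!is.finite(s36) || s36 <= 0) s36 <- max(y36, 1e-6)
  if (!is.finite(s34) || s34 <= 0) s34 <- max(y34, 1e-6)

  guess <- NULL
  if (strategy == "loglinear") {
    guess <- tryCatch({
      frac <- y36 / s36
      sel <- frac > 0.15 & frac < 0.85
      if (sum(sel) < 3) stop("too few slow-window points")
      ks <- -unname(stats::coef(stats::lm(log(1 - frac[sel]) ~ t[sel]))[2])
      if (!is.finite(ks) || ks <= 0) stop("bad slow slope")
      u <- y34 / s34
      z <- (1 - (u - (1 - a) * (1 - exp(-ks * t))) / a) / b
      sel <- z > 0.05 & z < 0.9 & t < stats::quantile(t, 0.5)
      if (sum(sel) < 3) stop("too few fast-window points")
      kf <- -unname(stats::coef(stats::lm(log(z[sel]) ~ t[sel]))[2])
      if (!is.finite(kf) || kf <= ks) stop("bad fast slope")
      c(k_f = kf, k_s = ks)
    }, error = function(e) NULL)
  }
  if (is.null(guess)) guess <- grid_init_exchange(t, y34, y36, a, b, mixing_tau)

  c(guess, scale_34 = s34, scale_36 = s36, a = a)
}

grid_init_exchange <- function(t, y34, y36, a, b, mixing_tau = 0) {
  ks_grid <- 10^seq(-3, 2, length.out = 16)
  ratio_grid <- 10^seq(0.5, 3.5, length.out = 13)
  best <- NULL; best_ssr <- Inf
  for (ks in ks_grid) for (r in ratio_grid) {
    kf <- ks * r
    ker <- mims_kernel(t, exchange_params(kf, ks), a = a, b = b, mixing_tau = mixing_tau)
    s34 <- sum(y34 * ker$y34) / sum(ker$y34^2)
    s36 <- sum(y36 * ker$y36) / sum(ker$y36^2)
    if (!is.finite(s34) || s34 <= 0) s34 <- 1e-6
    if (!is.finite(s36) || s36 <= 0) s36 <- 1e-6
    ssr <- sum((y34 - s34 * ker$y34)^2) + sum((y36 - s36 * ker$y36)^2)
    if (ssr < best_ssr) { best_ssr <- ssr; best <- c(k_f = kf, k_s = ks) }
  }
  best
}

# monophasic comparison model: one shared rate, per-channel scales
fit_monophasic <- function(data) {
  res_fn <- function(par) {
    k <- exp(par[1]); m <- 1 - exp(-k * data$t)
    c(data$w[1] * (data$y34 - exp(par[2]) * m),
      data$w[2] * (data$y36 - exp(par[3]) * m))
  }
  s34 <- max(mean(utils::tail(data$y34, 5)), 1e-6)
  s36 <- max(mean(utils::tail(data$y36, 5)), 1e-6)
  ans <- minpack.lm::nls.lm(par = c(lk = log(1), ls34 = log(s34), ls36 = log(s36)),
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(k = exp(stats::coef(ans)[1]),
       scale_34 = exp(stats::coef(ans)[2]), scale_36 = exp(stats::coef(ans)[3]),
       objective = ans$deviance, converged = ans$info %in% c(1:4, 6:8))
}

# refit from a warm start on a row subset (used by the jackknife)
refit_exchange_subset <- function(fit, keep) {
  data <- fit$data
  data$t <- data$t[keep]; data$y34 <- data$y34[keep]; data$y36 <- data$y36[keep]
  config <- fit$config
  res_fn <- function(par) {
    names(par) <- names(fit$start)
    exchange_residuals_nat(exch_from_par(par, config), data, config)
  }
  jac_fn <- if (config$mixing_tau == 0) function(par) {
    names(par) <- names(fit$start)
    exchange_jacobian_par(par, data, config)
  } else NULL
  ans <- minpack.lm::nls.lm(par = fit$start, fn = res_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-10))
  par <- stats::coef(ans); names(par) <- names(fit$start)
  if (!is.null(jac_fn)) par <- gn_polish(par, res_fn, jac_fn, steps = 2)
  est <- exch_from_par(par, config)
  est[c("scale_34", "scale_36")] <- est[c("scale_34", "scale_36")] * (fit$yscale %||% 1)
  list(estimate = est, converged = ans$info %in% c(1:4, 6:8))
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Global two-channel isotope-exchange fit\n")
  cat(sprintf("  k_f = %.4g s^-1, k_s = %.4g s^-1 (a = %.4g, b = %.4g)\n",
              x$estimates$estimate[1], x$estimates$estimate[2], x$a, x$b))
  se <- x$estimates$std.error[1:2]
  cat(sprintf("  SE(k_f) = %s, SE(k_s) = %s [%s]\n",
              fmt_se(se[1]), fmt_se(se[2]), x$estimates$se_method[1]))
  cat(sprintf("  n = %d points/channel, SSR = %.4g, converged: %s\n",
              x$n_points[1], x$objective, x$converged))
  if (x$degenerate)
    cat("  warning: k_f/k_s < 2 (poorly separated phases); monophasic refit stored\n")
  invisible(x)
}
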