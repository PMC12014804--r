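#' Default TR-MIMS sampling grid
#'
#' Logarithmically spaced sampling times after injection — dense where the
#' fast phase (rates of order 100 s^-1) lives, sparse over the slow tail —
#' plus a handful of evenly spaced pre-injection baseline points used for
#' baseline and residual-O2 estimation.
#'
#' @param n_post Number of post-injection samples. Default 120.
#' @param t_min,t_max First and last post-injection times, s.
#' @param n_pre Number of pre-injection baseline samples. Default 10.
#' @param pre_span Length of the baseline window before injection, s.
#' @param injection_time Absolute time of the injection trigger, s.
#'
#' @return Numeric vector of strictly increasing sample times, s.
#' @examples
#' head(mims_time_grid())
#' @export
mims_time_grid <- function(n_post = 120, t_min = 0.002, t_max = 20,
                           n_pre = 10, pre_span = 0.2, injection_time = 0) {
  stopifnot(n_post >= 2, t_min > 0, t_max > t_min, n_pre >= 0, pre_span > 0)
  post <- exp(seq(log(t_min), log(t_max), length.out = n_post))
  pre <- if (n_pre > 0) seq(-pre_span, -pre_span / n_pre, length.out = n_pre) else numeric()
  injection_time + c(pre, post)
}

#' Simulate a TR-MIMS isotope-labeling trace
#'
#' Forward-simulates the m/z 34 and m/z 36 O2 isotopologue signals after a
#' rapid H2-18O injection, with known ground truth. The noiseless kernel is
#' the closed-form labeling model ([mz34_model()], [mz36_model()]) evaluated
#' at `t - injection_time`, zero before injection; optionally convolved with
#' a first-order mixing response (time constant `mixing_tau`) to emulate
#' non-instant enrichment rise. A residual-O2 step (dissolved O2 carried by
#' the injected water) is added on both channels at injection, then i.i.d.
#' Gaussian detector noise.
#'
#' @param truth An [exchange_params()]: the generating rate constants.
#' @param enrichment An [enrichment_spec()]; sets the fast-phase amplitude
#'   factor via [fast_fraction_a()].
#' @param protocol A [flash_protocol()]; sets the inter-flash correction via
#'   [interflash_b()].
#' @param time_grid Sampling times, s (absolute; must be strictly
#'   increasing and cover `injection_time` when pre-injection baseline
#'   points are expected). Default [mims_time_grid()].
#' @param injection_time Injection trigger time, s. Default 0.
#' @param mixing_tau First-order enrichment-rise time constant, s;
#'   0 = instantaneous step (default). The injection itself takes about
#'   6 ms, so 0.006 is a realistic non-zero choice.
#' @param residual_o2_step Additive step at injection on each channel,
#'   signal units. Single value (both channels) or length-2
#'   `c(mz34, mz36)`.
#' @param noise_sigma Gaussian noise SD per channel, signal units.
#' @param scale_34,scale_36 Channel gain factors (plateau amplitude of each
#'   channel in signal units).
#' @param seed Integer seed; identical seeds give bit-identical traces.
#'   `NULL` draws from the ambient RNG stream.
#'
#' @return A `mims_trace`: a tibble with columns `t`, `mz34`, `mz36` and
#'   attributes `injection_time`, `truth`, `enrichment`, `protocol`, `a`,
#'   `b`, `seed`, `sim` (the generator settings).
#' @examples
#' tr <- simulate_mims(exchange_params(111, 0.93),
#'                     enrichment_spec(0.13, 0.0007),
#'                     flash_protocol("S2", k_f_s3 = 29),
#'                     noise_sigma = 0.01, seed = 1)
#' head(tr)
#' @export
simulate_mims <- function(truth, enrichment, protocol,
                          time_grid = mims_time_grid(injection_time = injection_time),
                          injection_time = 0,
                          mixing_tau = 0, residual_o2_step = 0, noise_sigma = 0,
                          scale_34 = 1, scale_36 = 1, seed = NULL) {
  stopifnot(inherits(truth, "exchange_params"),
            inherits(enrichment, "enrichment_spec"),
            inherits(protocol, "flash_protocol"))
  if (any(diff(time_grid) <= 0)) stop("`time_grid` must be strictly increasing", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (mixing_tau < 0) stop("`mixing_tau` must be >= 0", call. = FALSE)
  if (max(time_grid) < injection_time)
    stop("`time_grid` does not cover `injection_time`: no post-injection samples", call. = FALSE)
  step <- rep_len(residual_o2_step, 2L)

  a <- fast_fraction_a(enrichment)
  b <- interflash_b(protocol)
  ker <- mims_kernel(time_grid - injection_time, truth, a, b, mixing_tau)

  y34 <- scale_34 * ker$y34 + step[1] * ker$post
  y36 <- scale_36 * ker$y36 + step[2] * ker$post
  if (noise_sigma > 0) {
    n <- length(time_grid)
    noise <- with_local_seed(seed, matrix(stats::rnorm(2 * n, sd = noise_sigma), ncol = 2))
    y34 <- y34 + noise[, 1]
    y36 <- y36 + noise[, 2]
  }

  out <- tibble::tibble(t = time_grid, mz34 = y34, mz36 = y36)
  new_mims_trace(out, injection_time = injection_time,
                 meta = list(truth = truth, enrichment = enrichment,
                             protocol = protocol, a = a, b = b, seed = seed,
                             sim = list(mixing_tau = mixing_tau,
                                        residual_o2_step = step,
                                        noise_sigma = noise_sigma,
                                        scale_34 = scale_34, scale_36 = scale_36)))
}

# Noiseless labeling kernel on times relative to injection (0 before
# injection); returns both channels plus the post-injection indicator.
mims_kernel <- function(dt, params, a, b, mixing_tau = 0) {
  post <- as.numeric(dt >= 0)
  dtp <- pmax(dt, 0)
  if (mixing_tau > 0) {
    c1 <- conv_exp_mixing(dtp, 0, mixing_tau)           # step response
    cf <- conv_exp_mixing(dtp, params$k_f, mixing_tau)  # fast exponential
    cs <- conv_exp_mixing(dtp, params$k_s, mixing_tau)  # slow exponential
    y34 <- a * (c1 - b * cf) + (1 - a) * (c1 - cs)
    y36 <- c1 - cs
  } else {
    y34 <- mz34_model(dtp, params, a = a, b = b)
    y36 <- mz36_model(dtp, params)
  }
  list(y34 = y34 * post, y36 = y36 * post, post = post)
}

new_mims_trace <- function(data, injection_time, meta = list()) {
  stopifnot(all(c("t", "mz34", "mz36") %in% names(data)))
  structure(tibble::as_tibble(data),
            injection_time = injection_time, meta = meta,
            class = c("mims_trace", class(tibble::tibble())))
}

#' Injection time of a MIMS trace
#' @param trace A `mims_trace`.
#' @return The injection trigger time, s.
#' @export
injection_time <- function(trace) attr(trace, "injection_time")

#' Logarithmic measuring-flash grid for fluorescence decays
#'
#' Measuring flashes spaced evenly in log time, the standard acquisition
#' scheme for flash-induced fluorescence relaxation spanning sub-ms to
#' many seconds.
#'
#' @param points_per_decade Measuring flashes per decade. Default 8.
#' @param t_min,t_max Span, s. Default 150 microseconds to 100 s.
#'
#' @return Strictly increasing numeric vector of times, s.
#' @examples
#' length(fluor_time_grid())
#' @export
fluor_time_grid <- function(points_per_decade = 8, t_min = 150e-6, t_max = 100) {
  stopifnot(points_per_decade > 0, t_min > 0, t_max > t_min)
  n <- ceiling(log10(t_max / t_min) * points_per_decade) + 1
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

#' Evaluate the three-exponential fluorescence decay model
#'
#' \deqn{F_V^{norm}(t) = A_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} +
#'   A_3 e^{-t/\tau_3}}
#'
#' @param t Time vector, s.
#' @param params A [fluor_decay_params()].
#' @return Numeric vector of normalized variable fluorescence values.
#' @examples
#' p <- fluor_decay_params(0.02, 0.07, 0.37, 0.54, 3.5e-3, 0.289, 1.5)
#' fluor_decay_model(c(1e-4, 0.1, 10), p)
#' @export
fluor_decay_model <- function(t, params) {
  stopifnot(inherits(params, "fluor_decay_params"))
  params$A0 +
    params$A1 * exp(-t / params$tau1) +
    params$A2 * exp(-t / params$tau2) +
    params$A3 * exp(-t / params$tau3)
}

#' Simulate a variable-fluorescence decay trace
#'
#' Evaluates the three-exponential decay model on a (typically logarithmic)
#' time grid and adds i.i.d. Gaussian noise.
#'
#' @param params A [fluor_decay_params()]: the generating truth.
#' @param time_grid Sampling times, s. Default [fluor_time_grid()].
#' @param noise_sigma Gaussian noise SD (normalized fluorescence units).
#' @param seed Integer seed for reproducibility; `NULL` uses the ambient
#'   RNG stream.
#'
#' @return A `fluor_trace`: tibble with columns `t`, `fv_norm` and
#'   attributes `truth`, `seed`, `noise_sigma`, `f0`, `fmax`.
#' @examples
#' p <- fluor_decay_params(0.02, 0.07, 0.37, 0.54, 3.5e-3, 0.289, 1.5)
#' simulate_fluorescence(p, noise_sigma = 0.01, seed = 7)
#' @export
simulate_fluorescence <- function(params, time_grid = fluor_time_grid(),
                                  noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(params, "fluor_decay_params"))
  if (any(diff(time_grid) <= 0)) stop("`time_grid` must be strictly increasing", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  y <- fluor_decay_model(time_grid, params)
  if (noise_sigma > 0)
    y <- y + with_local_seed(seed, stats::rnorm(length(time_grid), sd = noise_sigma))
  new_fluor_trace(tibble::tibble(t = time_grid, fv_norm = y),
                  meta = list(truth = params, seed = seed, noise_sigma = noise_sigma,
                              f0 = 0, fmax = 1))
}

new_fluor_trace <- function(data, meta = list()) {
  stopifnot(all(c("t", "fv_norm") %in% names(data)))
  structure(tibble::as_tibble(data), meta = meta,
            class = c("fluor_trace", class(tibble::tibble())))
}
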