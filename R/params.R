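#' Substrate-water exchange rate constants
#'
#' Bundle the two first-order rate constants of the biphasic \eqn{^{18}}O
#' labeling kinetics: `k_f` for the fast-exchanging substrate water (W_f)
#' and `k_s` for the slow-exchanging one (W_s).
#'
#' @param k_f Fast-exchange rate constant, s^-1. Must be positive.
#' @param k_s Slow-exchange rate constant, s^-1. Must be positive.
#'
#' @return An object of class `exchange_params` (a named list).
#' @examples
#' exchange_params(k_f = 111, k_s = 0.93)
#' @export
exchange_params <- function(k_f, k_s) {
  stopifnot(is.numeric(k_f), length(k_f) == 1L, is.numeric(k_s), length(k_s) == 1L)
  if (!is.finite(k_f) || k_f <= 0) stop("`k_f` must be a positive finite rate (s^-1)", call. = FALSE)
  if (!is.finite(k_s) || k_s <= 0) stop("`k_s` must be a positive finite rate (s^-1)", call. = FALSE)
  structure(list(k_f = k_f, k_s = k_s), class = "exchange_params")
}

#' Isotope enrichment specification
#'
#' Initial and final \eqn{^{18}}O enrichment of the water pool. The initial
#' enrichment `alpha_i` is the fraction of \eqn{^{18}}O before H2-18O
#' injection (near natural abundance) and `alpha_f` the fraction after
#' injection and mixing. Both are fractions, not percentages.
#'
#' @param alpha_f Final enrichment, in (0, 1).
#' @param alpha_i Initial enrichment, in \[0, 1), strictly below `alpha_f`.
#'
#' @return An object of class `enrichment_spec`.
#' @examples
#' enrichment_spec(alpha_f = 0.13, alpha_i = 0.0007)
#' @export
enrichment_spec <- function(alpha_f, alpha_i = 0.0007) {
  stopifnot(is.numeric(alpha_f), length(alpha_f) == 1L,
            is.numeric(alpha_i), length(alpha_i) == 1L)
  if (!is.finite(alpha_f) || alpha_f <= 0 || alpha_f >= 1)
    stop("`alpha_f` must be a fraction strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(alpha_i) || alpha_i < 0 || alpha_i >= 1)
    stop("`alpha_i` must be a fraction in [0, 1)", call. = FALSE)
  if (alpha_i >= alpha_f)
    stop("`alpha_i` must be strictly smaller than `alpha_f`", call. = FALSE)
  structure(list(alpha_f = alpha_f, alpha_i = alpha_i), class = "enrichment_spec")
}

#' Flash protocol metadata
#'
#' Describes which S state of the Kok cycle the measurement probes and the
#' turnover-flash timing that determines the inter-flash fast-exchange
#' correction. When probing S2, centres dwell in S3 for `t_s3` seconds per
#' turnover cycle (one inter-flash interval, 10 ms at 100 Hz), during which
#' the fast substrate water exchanges at the S3-state rate `k_f_s3`; that
#' partial pre-labeling is absorbed into the amplitude factor returned by
#' [interflash_b()]. For S3 measurements no correction applies.
#'
#' @param probed_state `"S2"` or `"S3"`.
#' @param flash_frequency Turnover flash frequency, Hz. Default 100.
#' @param t_s3 Dwell time in S3 per cycle, s. Defaults to one inter-flash
#'   interval, `1 / flash_frequency`.
#' @param k_f_s3 Fast-exchange rate constant in the S3 state, s^-1. Required
#'   when `probed_state = "S2"` (usually taken from the companion S3
#'   measurement of the same sample).
#'
#' @return An object of class `flash_protocol`.
#' @examples
#' flash_protocol("S2", k_f_s3 = 29)
#' flash_protocol("S3")
#' @export
flash_protocol <- function(probed_state = c("S3", "S2"), flash_frequency = 100,
                           t_s3 = 1 / flash_frequency, k_f_s3 = NULL) {
  probed_state <- match.arg(probed_state)
  stopifnot(is.numeric(flash_frequency), length(flash_frequency) == 1L,
            is.numeric(t_s3), length(t_s3) == 1L)
  if (!is.finite(flash_frequency) || flash_frequency <= 0)
    stop("`flash_frequency` must be positive (Hz)", call. = FALSE)
  if (!is.finite(t_s3) || t_s3 < 0)
    stop("`t_s3` must be a non-negative dwell time (s)", call. = FALSE)
  if (!is.null(k_f_s3)) {
    stopifnot(is.numeric(k_f_s3), length(k_f_s3) == 1L)
    if (!is.finite(k_f_s3) || k_f_s3 <= 0)
      stop("`k_f_s3` must be a positive rate (s^-1)", call. = FALSE)
  }
  structure(list(probed_state = probed_state, flash_frequency = flash_frequency,
                 t_s3 = t_s3, k_f_s3 = k_f_s3),
            class = "flash_protocol")
}

#' Variable-fluorescence decay parameters
#'
#' Parameters of the three-exponential decay of normalized variable
#' fluorescence: a non-decaying offset `A0` and three components with
#' amplitudes `A1..A3` and time constants `tau1 < tau2 < tau3`.
#'
#' @param A0 Non-decaying offset (fraction of normalized F_v).
#' @param A1,A2,A3 Component amplitudes, each >= 0.
#' @param tau1,tau2,tau3 Time constants, s, strictly increasing.
#'
#' @return An object of class `fluor_decay_params`.
#' @examples
#' fluor_decay_params(A0 = 0.02, A1 = 0.07, A2 = 0.37, A3 = 0.54,
#'                    tau1 = 3.5e-3, tau2 = 0.289, tau3 = 1.5)
#' @export
fluor_decay_params <- function(A0, A1, A2, A3, tau1, tau2, tau3) {
  vals <- c(A0 = A0, A1 = A1, A2 = A2, A3 = A3,
            tau1 = tau1, tau2 = tau2, tau3 = tau3)
  if (!all(is.finite(vals))) stop("all decay parameters must be finite", call. = FALSE)
  if (any(c(A1, A2, A3) < 0)) stop("amplitudes `A1..A3` must be >= 0", call. = FALSE)
  if (any(c(tau1, tau2, tau3) <= 0)) stop("time constants must be positive (s)", call. = FALSE)
  if (!(tau1 < tau2 && tau2 < tau3))
    stop("time constants must be strictly ordered: tau1 < tau2 < tau3", call. = FALSE)
  structure(as.list(vals), class = "fluor_decay_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("<exchange_params> k_f = %.4g s^-1, k_s = %.4g s^-1\n", x$k_f, x$k_s))
  invisible(x)
}

#' @export
print.enrichment_spec <- function(x, ...) {
  cat(sprintf("<enrichment_spec> alpha_f = %.4g, alpha_i = %.4g\n", x$alpha_f, x$alpha_i))
  invisible(x)
}

#' @export
print.flash_protocol <- function(x, ...) {
  cat(sprintf("<flash_protocol> probing %s, %g Hz flashes, t_S3 = %g s%s\n",
              x$probed_state, x$flash_frequency, x$t_s3,
              if (is.null(x$k_f_s3)) "" else sprintf(", k_f(S3) = %g s^-1", x$k_f_s3)))
  invisible(x)
}

#' @export
print.fluor_decay_params <- function(x, ...) {
  cat(sprintf(
    "<fluor_decay_params> A0 = %.3g; A = (%.3g, %.3g, %.3g); tau = (%.3g, %.3g, %.3g) s\n",
    x$A0, x$A1, x$A2, x$A3, x$tau1, x$tau2, x$tau3))
  invisible(x)
}
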