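#' O2 isotopologue fractions for two independently labeled oxygen sites
#'
#' Each evolved O2 draws one oxygen atom from each of the two substrate
#' sites. If the sites carry \eqn{^{18}}O fractions `alpha1` and `alpha2`,
#' the isotopologue distribution of the product is the outer product of the
#' two single-site label probabilities. This enumeration is the brute-force
#' basis of the fast-phase amplitude factor computed by [fast_fraction_a()].
#'
#' @param alpha1,alpha2 Label fraction at each site, in \[0, 1\]. Vectorized.
#'
#' @return A tibble with columns `f32`, `f34`, `f36` (fractions of
#'   unlabeled, single-labeled and double-labeled O2), summing to 1 rowwise.
#' @examples
#' isotopologue_fractions(0.13, 0.13)
#' @export
isotopologue_fractions <- function(alpha1, alpha2) {
  stopifnot(is.numeric(alpha1), is.numeric(alpha2))
  if (any(alpha1 < 0 | alpha1 > 1, na.rm = TRUE) ||
      any(alpha2 < 0 | alpha2 > 1, na.rm = TRUE))
    stop("enrichments must lie in [0, 1]", call. = FALSE)
  f36 <- alpha1 * alpha2
  f34 <- alpha1 * (1 - alpha2) + (1 - alpha1) * alpha2
  f32 <- (1 - alpha1) * (1 - alpha2)
  tibble::tibble(f32 = f32, f34 = f34, f36 = f36)
}

#' Fast-phase amplitude factor of the m/z 34 labeling kinetics
#'
#' Fraction of the single-labeled (m/z 34) signal rise carried by the fast
#' phase. Exchange of the fast substrate water alone puts the product in a
#' mixed state: one oxygen at the final enrichment `alpha_f`, the other
#' still at the initial enrichment `alpha_i`. The factor is the
#' single-labeled fraction of that mixed state relative to the fully
#' exchanged state (both sites at `alpha_f`):
#' \deqn{a = \frac{\alpha_f (1-\alpha_i) + (1-\alpha_f)\,\alpha_i}
#'              {2\,\alpha_f (1-\alpha_f)}.}
#'
#' For typical experiments (`alpha_i` near natural abundance, `alpha_f`
#' around 13 percent) this gives a around 0.58: barely more than half of
#' the m/z 34 amplitude reports fast exchange, the remainder rises with the
#' slow component.
#'
#' @param enrichment An [enrichment_spec()], or the final enrichment
#'   `alpha_f` as a bare number (then `alpha_i` is taken from the second
#'   argument).
#' @param alpha_i Initial enrichment, used only when `enrichment` is numeric.
#'
#' @return The dimensionless amplitude factor, in (0, 1\] for
#'   `alpha_i < alpha_f <= 0.5`.
#' @examples
#' fast_fraction_a(enrichment_spec(alpha_f = 0.13, alpha_i = 0.0007))
#' @export
fast_fraction_a <- function(enrichment, alpha_i = 0.0007) {
  if (is.numeric(enrichment)) enrichment <- enrichment_spec(enrichment, alpha_i)
  if (!inherits(enrichment, "enrichment_spec"))
    stop("`enrichment` must be an enrichment_spec or a numeric alpha_f", call. = FALSE)
  af <- enrichment$alpha_f
  ai <- enrichment$alpha_i
  (af * (1 - ai) + (1 - af) * ai) / (2 * af * (1 - af))
}

#' Inter-flash fast-exchange correction factor
#'
#' When probing the S2 state, each turnover cycle leaves the centres in S3
#' for the inter-flash dwell `t_s3` (10 ms at 100 Hz), during which the
#' fast substrate water already exchanges at the S3-state rate. The
#' unexchanged fraction remaining at the moment S2 is probed is
#' \deqn{b = e^{-k_f^{S3}\, t^{S3}},}
#' which scales down the fast-phase amplitude at time zero. For S3
#' measurements no dwell correction applies and b is exactly 1.
#'
#' @param protocol A [flash_protocol()].
#' @param convention Exponent sign convention; `"decay"` (the default)
#'   treats b as the surviving unexchanged fraction, `exp(-k t)`.
#'
#' @return The dimensionless correction factor, in (0, 1\].
#' @examples
#' interflash_b(flash_protocol("S2", k_f_s3 = 29))  # exp(-0.29)
#' interflash_b(flash_protocol("S3"))               # exactly 1
#' @export
interflash_b <- function(protocol, convention = c("decay", "growth")) {
  if (!inherits(protocol, "flash_protocol"))
    stop("`protocol` must be a flash_protocol", call. = FALSE)
  convention <- match.arg(convention)
  if (protocol$probed_state == "S3") return(1)
  if (is.null(protocol$k_f_s3))
    stop("probing S2 requires `k_f_s3` (fast exchange rate in S3) in the flash protocol",
         call. = FALSE)
  x <- protocol$k_f_s3 * protocol$t_s3
  if (convention == "decay") exp(-x) else exp(x)
}

#' Normalized m/z 34 labeling kinetics (biphasic rise)
#'
#' Closed-form model of the single-labeled O2 signal after a step rise in
#' enrichment at t = 0, normalized to unit plateau:
#' \deqn{y_{34}(t) = a\,(1 - b\,e^{-k_f t}) + (1-a)\,(1 - e^{-k_s t})}
#' with fast-phase amplitude `a` (see [fast_fraction_a()]) and inter-flash
#' correction `b` (see [interflash_b()]). At t = 0 the value is `a (1 - b)`
#' (the fast phase partially pre-exchanged during the S3 dwell); as t grows
#' the signal rises monotonically to 1.
#'
#' @param t Time vector, s, non-negative.
#' @param params An [exchange_params()].
#' @param a Fast-phase amplitude factor in (0, 1\].
#' @param b Inter-flash correction factor in (0, 1\].
#'
#' @return Numeric vector of normalized signal values.
#' @examples
#' mz34_model(c(0, 0.01, 1, 10), exchange_params(111, 0.93), a = 0.577, b = 0.748)
#' @export
mz34_model <- function(t, params, a, b = 1) {
  stopifnot(inherits(params, "exchange_params"))
  if (any(t < 0)) stop("`t` must be non-negative (seconds after enrichment rise)", call. = FALSE)
  if (!is.finite(a) || a <= 0 || a > 1) stop("`a` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(b) || b <= 0 || b > 1) stop("`b` must lie in (0, 1]", call. = FALSE)
  a * (1 - b * exp(-params$k_f * t)) + (1 - a) * (1 - exp(-params$k_s * t))
}

#' Normalized m/z 36 labeling kinetics (monophasic rise)
#'
#' Double labeling requires exchange of the slow substrate water, so the
#' m/z 36 signal rises monophasically with the slow rate alone:
#' \deqn{y_{36}(t) = 1 - e^{-k_s t}.}
#'
#' An alternative convention treats double labeling as requiring both
#' exchanges, giving the product \eqn{(1-e^{-k_f t})(1-e^{-k_s t})}; it is
#' available for sensitivity analysis via `form = "product"` but the
#' monophasic form is the default used in fitting.
#'
#' @param t Time vector, s, non-negative.
#' @param params An [exchange_params()].
#' @param form `"monophasic"` (default) or `"product"`.
#'
#' @return Numeric vector of normalized signal values.
#' @examples
#' mz36_model(c(0, 1, 5), exchange_params(111, 0.85))
#' @export
mz36_model <- function(t, params, form = c("monophasic", "product")) {
  stopifnot(inherits(params, "exchange_params"))
  form <- match.arg(form)
  if (any(t < 0)) stop("`t` must be non-negative (seconds after enrichment rise)", call. = FALSE)
  slow <- 1 - exp(-params$k_s * t)
  if (form == "monophasic") slow else (1 - exp(-params$k_f * t)) * slow
}
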