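# internal helpers

# Run code with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws advance it).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Convolution of a unit-rate first-order mixing response h(s) = e^(-s/tau)/tau
# with e^(-k u) on [0, t]; k = 0 gives the response to a unit step.
conv_exp_mixing <- function(t, k, tau) {
  if (tau <= 0) return(exp(-k * t))
  if (k == 0) return(1 - exp(-t / tau))
  d <- k * tau - 1
  if (abs(d) < 1e-10) {
    # k ~ 1/tau: limit form t e^(-kt)/tau
    t * exp(-k * t) / tau
  } else {
    (exp(-t / tau) - exp(-k * t)) / d
  }
}

# abbreviation used in result tables when a standard error is unavailable
fmt_se <- function(se, digits = 3) {
  ifelse(is.na(se), "not estimated", formatC(signif(se, digits), format = "g"))
}
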