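#' Assemble a results bundle
#'
#' Collects exchange-kinetics and/or fluorescence-decay fit results into a
#' reportable bundle: one row per sample/state (exchange) or per
#' sample/component (fluorescence), plus a provenance block (seed, config
#' echo, package version) that [write_results()] emits verbatim.
#'
#' @param exchange A tibble with columns `sample`, `state`, `k_f`,
#'   `k_f_se`, `k_s`, `k_s_se` (see [exchange_result_row()]), or `NULL`.
#' @param fluorescence A tibble with columns `sample`, `component`,
#'   `half_time_s`, `half_time_se`, `amplitude_percent`,
#'   `amplitude_percent_se` (see [fluor_result_rows()]), or `NULL`.
#' @param seed Integer seed used by the run, recorded in provenance.
#' @param config Named list echoed into the provenance block.
#'
#' @return A `results_bundle`.
#' @export
results_bundle <- function(exchange = NULL, fluorescence = NULL,
                           seed = NULL, config = list()) {
  if (!is.null(exchange))
    stopifnot(all(c("sample", "state", "k_f", "k_f_se", "k_s", "k_s_se")
                  %in% names(exchange)))
  if (!is.null(fluorescence))
    stopifnot(all(c("sample", "component", "half_time_s", "half_time_se",
                    "amplitude_percent", "amplitude_percent_se")
                  %in% names(fluorescence)))
  structure(list(exchange = exchange, fluorescence = fluorescence,
                 seed = seed, config = config),
            class = "results_bundle")
}

#' One exchange-table row from a fit
#'
#' @param fit An `exchange_fit`.
#' @param sample Sample label (e.g. `"WT"`).
#' @param state Probed S state label (taken from the fit's protocol when
#'   omitted).
#' @return A one-row tibble suitable for [results_bundle()].
#' @export
exchange_result_row <- function(fit, sample = "sample",
                                state = fit$config$protocol$probed_state) {
  e <- fit$estimates
  pick <- function(term, col) {
    v <- e[[col]][e$term == term]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(sample = sample, state = state,
                 k_f = pick("k_f", "estimate"), k_f_se = pick("k_f", "std.error"),
                 k_s = pick("k_s", "estimate"), k_s_se = pick("k_s", "std.error"),
                 converged = fit$converged)
}

#' Fluorescence-table rows from a fit
#'
#' @param fit A `fluor_fit`.
#' @param sample Sample label.
#' @return A three-row tibble (fast/middle/slow) for [results_bundle()].
#' @export
fluor_result_rows <- function(fit, sample = "sample") {
  cmp <- fit$components
  tibble::tibble(sample = sample, component = cmp$component,
                 half_time_s = cmp$half_time,
                 half_time_se = cmp$tau_se * log(2),
                 amplitude_percent = cmp$amplitude_percent,
                 amplitude_percent_se = cmp$amplitude_percent_se)
}

#' Write a results bundle to deterministic text
#'
#' Fixed section and column order, rates and half-times to 3 significant
#' figures, missing standard errors marked `not estimated`. The same
#' bundle always produces byte-identical output (no timestamps).
#'
#' @param bundle A [results_bundle()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "results_bundle"))
  g3 <- function(x) ifelse(is.na(x), "not estimated",
                           trimws(formatC(signif(x, 3), format = "g")))
  lines <- c("# trmims results v1",
             sprintf("# package_version: %s",
                     as.character(utils::packageVersion("trmims"))))
  if (!is.null(bundle$seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(bundle$seed)))
  for (k in names(bundle$config))
    lines <- c(lines, sprintf("# config.%s: %s", k,
                              paste(format(bundle$config[[k]]), collapse = " ")))
  if (!is.null(bundle$exchange)) {
    ex <- bundle$exchange
    lines <- c(lines, "", "[exchange]",
               "sample,state,k_f_per_s,k_f_se,k_s_per_s,k_s_se",
               paste(ex$sample, ex$state, g3(ex$k_f), g3(ex$k_f_se),
                     g3(ex$k_s), g3(ex$k_s_se), sep = ","))
  }
  if (!is.null(bundle$fluorescence)) {
    fl <- bundle$fluorescence
    lines <- c(lines, "", "[fluorescence]",
               "sample,component,half_time_s,half_time_se,amplitude_percent,amplitude_percent_se",
               paste(fl$sample, fl$component, g3(fl$half_time_s), g3(fl$half_time_se),
                     g3(fl$amplitude_percent), g3(fl$amplitude_percent_se), sep = ","))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, path)
  invisible(path)
}
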