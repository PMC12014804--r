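#' Delete-one jackknife standard errors for an exchange fit
#'
#' Re-estimates the global fit once per time point, deleting the i-th
#' sample from both channels simultaneously (preserving the shared-`k_s`
#' structure), each replicate warm-started from the base estimates. The
#' standard error of each parameter is the usual jackknife formula
#' \deqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\hat\theta_{(i)} -
#'   \bar\theta_{(\cdot)})^2}}
#' over the n leave-one-out estimates. The full replicate distribution is
#' kept for diagnostics (see [autoplot.exchange_fit()]).
#'
#' @param fit A converged `exchange_fit` with at least 10 points per
#'   channel.
#' @param block Delete contiguous blocks of this many time points instead
#'   of single points (block jackknife). Default 1.
#'
#' @return The fit with `std.error` replaced by jackknife values
#'   (`se_method = "jackknife"`) and a `jackknife` element holding the
#'   replicate estimates, the replicate count and the non-convergence
#'   fraction (`unreliable = TRUE` if more than 20 percent of replicates
#'   failed to converge).
#' @examples
#' tr <- simulate_mims(exchange_params(29, 0.85), enrichment_spec(0.13),
#'                     flash_protocol("S3"),
#'                     time_grid = mims_time_grid(n_post = 40),
#'                     noise_sigma = 0.01, seed = 3)
#' fit <- fit_exchange(tr, enrichment_spec(0.13), flash_protocol("S3"))
#' fit <- jackknife_errors(fit)
#' generics::tidy(fit)
#' @export
jackknife_errors <- function(fit, block = 1) {
  stopifnot(inherits(fit, "exchange_fit"), block >= 1)
  if (!fit$converged)
    stop("base fit did not converge; jackknife errors would be meaningless", call. = FALSE)
  n <- length(fit$data$t)
  if (n < 10) stop("jackknife needs >= 10 time points", call. = FALSE)

  groups <- if (block == 1) as.list(seq_len(n)) else
    split(seq_len(n), ceiling(seq_len(n) / block))
  terms <- fit$estimates$term

  reps <- purrr::map(groups, function(drop) {
    r <- refit_exchange_subset(fit, keep = setdiff(seq_len(n), drop))
    tibble::tibble(term = terms, estimate = unname(r$estimate[terms]),
                   converged = r$converged)
  })
  replicates <- dplyr::bind_rows(reps, .id = "replicate")

  ok <- replicates |>
    dplyr::distinct(.data$replicate, .data$converged) |>
    dplyr::summarise(frac_fail = mean(!.data$converged)) |>
    dplyr::pull(.data$frac_fail)

  g <- length(groups)
  se_tbl <- replicates |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(std.error = sqrt((g - 1) / g *
                                        sum((.data$estimate - mean(.data$estimate))^2)),
                     .groups = "drop")

  fit$estimates <- fit$estimates |>
    dplyr::select(-"std.error") |>
    dplyr::left_join(se_tbl, by = "term") |>
    dplyr::mutate(se_method = "jackknife") |>
    dplyr::select("term", "estimate", "std.error", "se_method")
  fit$jackknife <- list(replicates = replicates, n_replicates = g,
                        block = block, frac_nonconverged = ok,
                        unreliable = ok > 0.2)
  if (ok > 0.2)
    warning(sprintf("%.0f%% of jackknife replicates failed to converge; SEs flagged unreliable",
                    100 * ok))
  fit
}
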