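#' Plot a MIMS trace
#'
#' Both isotopologue channels against time; log time axis by default since
#' the kinetics span fast (~10 ms) and slow (~1 s) phases.
#'
#' @param object A `mims_trace`.
#' @param log_time Use a log10 time axis (post-injection samples only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mims_trace <- function(object, log_time = TRUE, ...) {
  t0 <- injection_time(object) %||% 0
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mz34", "mz36"), names_to = "channel", values_to = "signal")
  if (log_time) df <- dplyr::filter(df, .data$t > t0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t - t0, .data$signal,
                                        colour = .data$channel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time after injection (s)", y = "signal (a.u.)",
                  colour = NULL) +
    ggplot2::scale_colour_manual(values = c(mz34 = "#1b6ca8", mz36 = "#c0392b"),
                                 labels = c(mz34 = "m/z 34", mz36 = "m/z 36")) +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot an exchange fit
#'
#' Data and fitted curves per channel (`type = "fit"`), residuals
#' (`type = "residuals"`), or the jackknife replicate distributions
#' (`type = "jackknife"`, requires [jackknife_errors()]).
#'
#' @param object An `exchange_fit`.
#' @param type One of `"fit"`, `"residuals"`, `"jackknife"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exchange_fit <- function(object, type = c("fit", "residuals", "jackknife"),
                                  ...) {
  type <- match.arg(type)
  if (type == "jackknife") {
    if (is.null(object$jackknife))
      stop("no jackknife replicates stored; run jackknife_errors() first", call. = FALSE)
    df <- dplyr::filter(object$jackknife$replicates,
                        .data$term %in% c("k_f", "k_s"), .data$converged)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$estimate)) +
             ggplot2::geom_histogram(bins = 30, fill = "#1b6ca8") +
             ggplot2::facet_wrap(~term, scales = "free_x") +
             ggplot2::labs(x = "leave-one-out estimate (s^-1)", y = "replicates") +
             ggplot2::theme_minimal())
  }
  df <- object$residuals
  if (type == "residuals")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$residual,
                                            colour = .data$channel)) +
             ggplot2::geom_point(size = 0.8) +
             ggplot2::geom_hline(yintercept = 0, linetype = 2) +
             ggplot2::scale_x_log10() +
             ggplot2::labs(x = "time after injection (s)", y = "residual") +
             ggplot2::theme_minimal())
  ggplot2::ggplot(df, ggplot2::aes(.data$t, colour = .data$channel)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time after injection (s)", y = "signal (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence trace
#'
#' @param object A `fluor_trace`.
#' @param ... Unused.
#' @return A ggplot object with a log10 time axis.
#' @export
autoplot.fluor_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$t, .data$fv_norm)) +
    ggplot2::geom_point(size = 0.8, colour = "#1b6ca8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time after flash (s)", y = "normalized variable fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence decay fit
#'
#' @param object A `fluor_fit`.
#' @param type `"fit"` (data plus fitted curve) or `"residuals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluor_fit <- function(object, type = c("fit", "residuals"), ...) {
  type <- match.arg(type)
  df <- object$residuals
  if (type == "residuals")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$residual)) +
             ggplot2::geom_point(size = 0.8) +
             ggplot2::geom_hline(yintercept = 0, linetype = 2) +
             ggplot2::scale_x_log10() +
             ggplot2::labs(x = "time after flash (s)", y = "residual") +
             ggplot2::theme_minimal())
  ggplot2::ggplot(df, ggplot2::aes(.data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8,
                        colour = "#1b6ca8", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c0392b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time after flash (s)",
                  y = "normalized variable fluorescence") +
    ggplot2::theme_minimal()
}
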