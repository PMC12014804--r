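#' Read a MIMS isotopologue trace from delimited text
#'
#' Expects comma-delimited text with a header row `time_s,mz34,mz36`
#' (optionally `mz32`), '.' decimal marks, and optional metadata lines
#' prefixed `#` of the form `# key: value` (recognized keys:
#' `injection_time`, `seed`, and `truth_*` / `alpha_*` provenance written
#' by [write_mims_trace()]).
#'
#' @param path File path.
#' @param injection_time Injection trigger time, s; overrides any value in
#'   the file metadata. Required (here or in the file) for preprocessing
#'   and fitting.
#'
#' @return A `mims_trace`.
#' @export
read_mims_trace <- function(path, injection_time = NULL) {
  meta <- read_hash_meta(path)
  df <- read_numeric_csv(path, required = c("time_s", "mz34", "mz36"))
  check_time_column(df$time_s, path)
  t0 <- injection_time %||% as_num(meta[["injection_time"]])
  out <- tibble::tibble(t = df$time_s, mz34 = df$mz34, mz36 = df$mz36)
  if ("mz32" %in% names(df)) out$mz32 <- df$mz32
  new_mims_trace(out, injection_time = t0, meta = list(file = path, header = meta))
}

#' Write a MIMS trace to delimited text
#'
#' Deterministic comma-delimited output with `# key: value` metadata lines
#' carrying the injection time and, for simulated traces, the generator
#' seed and ground-truth parameters, so parameter-recovery runs are fully
#' reproducible from the file alone.
#'
#' @param trace A `mims_trace`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mims_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mims_trace"))
  meta <- attr(trace, "meta") %||% list()
  hdr <- c("# trmims mims trace v1",
           sprintf("# injection_time: %s", num_str(injection_time(trace) %||% NA)))
  if (!is.null(meta$seed)) hdr <- c(hdr, sprintf("# seed: %d", as.integer(meta$seed)))
  if (!is.null(meta$truth))
    hdr <- c(hdr,
             sprintf("# truth_k_f: %s", num_str(meta$truth$k_f)),
             sprintf("# truth_k_s: %s", num_str(meta$truth$k_s)))
  if (!is.null(meta$enrichment))
    hdr <- c(hdr,
             sprintf("# alpha_f: %s", num_str(meta$enrichment$alpha_f)),
             sprintf("# alpha_i: %s", num_str(meta$enrichment$alpha_i)))
  cols <- intersect(c("t", "mz34", "mz36", "mz32"), names(trace))
  body <- c(paste(sub("^t$", "time_s", cols), collapse = ","),
            do.call(paste, c(lapply(cols, function(cl) num_str(trace[[cl]])),
                             sep = ",")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variable-fluorescence trace from delimited text
#'
#' Expects columns `time_s,fv` with optional metadata lines `# f0: ...`
#' and `# fmax: ...`. When both are present the signal is normalized via
#' [normalize_fv()]; otherwise `fv` is taken as already-normalized
#' variable fluorescence.
#'
#' @param path File path.
#' @return A `fluor_trace`.
#' @export
read_fluor_trace <- function(path) {
  meta <- read_hash_meta(path)
  df <- read_numeric_csv(path, required = c("time_s", "fv"))
  check_time_column(df$time_s, path)
  f0 <- as_num(meta[["f0"]]); fmax <- as_num(meta[["fmax"]])
  y <- if (!is.null(f0) && !is.null(fmax)) normalize_fv(df$fv, f0, fmax) else df$fv
  new_fluor_trace(tibble::tibble(t = df$time_s, fv_norm = y),
                  meta = list(file = path, header = meta,
                              f0 = f0 %||% 0, fmax = fmax %||% 1))
}

#' Write a fluorescence trace to delimited text
#'
#' @param trace A `fluor_trace`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fluor_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  meta <- attr(trace, "meta") %||% list()
  hdr <- "# trmims fluorescence trace v1"
  if (!is.null(meta$seed)) hdr <- c(hdr, sprintf("# seed: %d", as.integer(meta$seed)))
  if (!is.null(meta$truth)) {
    tr <- meta$truth
    hdr <- c(hdr, sprintf("# truth: A0=%s A=(%s,%s,%s) tau=(%s,%s,%s)",
                          num_str(tr$A0), num_str(tr$A1), num_str(tr$A2), num_str(tr$A3),
                          num_str(tr$tau1), num_str(tr$tau2), num_str(tr$tau3)))
  }
  hdr <- c(hdr, sprintf("# f0: %s", num_str(meta$f0 %||% 0)),
           sprintf("# fmax: %s", num_str(meta$fmax %||% 1)))
  body <- c("time_s,fv",
            paste(num_str(trace$t), num_str(trace$fv_norm), sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- shared readers ---------------------------------------------------------

read_hash_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, n = 100L)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^#\\s*([^:]+):\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, function(x) trimws(x[2]), ""))
}

read_numeric_csv <- function(path, required) {
  # parsing issues are re-raised below as errors with a line number
  df <- suppressWarnings(readr::read_csv(path, comment = "#",
                                         col_types = readr::cols(
                                           .default = readr::col_double()),
                                         progress = FALSE))
  pb <- readr::problems(df)
  if (nrow(pb) > 0)
    stop(sprintf("malformed numeric value in %s at line %d: expected %s, got '%s'",
                 path, pb$row[1], pb$expected[1], pb$actual[1]), call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) stop(sprintf("%s contains no data rows", path), call. = FALSE)
  if (anyNA(df[required]))
    stop(sprintf("%s contains missing values in required columns", path), call. = FALSE)
  df
}

check_time_column <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0)
    stop(sprintf("time is not strictly increasing in %s at data row %d (t = %g)",
                 path, bad[1] + 1L, t[bad[1] + 1L]), call. = FALSE)
  invisible(TRUE)
}

as_num <- function(x) if (is.null(x)) NULL else suppressWarnings(as.numeric(x))

# full-precision, locale-independent number formatting for round-trip I/O
num_str <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  trimws(out)
}
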