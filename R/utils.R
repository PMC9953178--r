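#' @keywords internal
"_PACKAGE"

# shared helpers and condition constructors

`%||%` <- function(x, y) if (is.null(x)) y else x

trim_lower <- function(x) tolower(trimws(x))

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slanglex_format_error", "error", "condition")))
}

stop_precondition <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slanglex_precondition_error", "error", "condition")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slanglex_config_error", "error", "condition")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slanglex_data_error", "error", "condition")))
}

#' Signal that a backend has exhausted its query quota
#'
#' Live completion and search services impose daily or per-minute limits.
#' Backends raise this condition so callers can checkpoint partial results and
#' exit with a resumable status instead of losing work.
#'
#' @param message Human-readable description.
#' @return Does not return; signals a condition of class `slanglex_quota_error`.
#' @export
quota_error <- function(message = "backend quota exhausted") {
  stop(errorCondition(message,
                      class = c("slanglex_quota_error", "error", "condition")))
}

#' Signal a transient backend failure
#'
#' Transient failures (timeouts, 5xx responses) are retried a bounded number of
#' times by [run_iterations()]; persistent ones cause the iteration to be
#' skipped with a warning.
#'
#' @param message Human-readable description.
#' @return Does not return; signals a condition of class
#'   `slanglex_transient_error`.
#' @export
transient_error <- function(message = "transient backend failure") {
  stop(errorCondition(message,
                      class = c("slanglex_transient_error", "error", "condition")))
}

is_quota_error <- function(e) inherits(e, "slanglex_quota_error")

# deterministic TSV writer: fixed separator, no quoting, "\n" line endings,
# so repeated runs with identical data produce byte-identical files
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", ...)
}
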