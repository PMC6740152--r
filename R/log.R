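#' Pipeline logging
#'
#' Messages go to standard error with a level tag. The threshold is the
#' option `sidekit.log_level` (one of `"debug"`, `"info"`, `"warning"`;
#' default `"info"`). Every pipeline stage logs its input/output counts so
#' filtering decisions stay auditable.
#'
#' @param ... passed to [sprintf()] (a format string plus arguments).
#' @param level message level.
#' @return invisibly, the formatted message.
#' @export
side_log <- function(..., level = c("info", "debug", "warning")) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warning = 3L)
  threshold <- getOption("sidekit.log_level", "info")
  if (!threshold %in% names(ranks)) threshold <- "info"
  msg <- sprintf(...)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), msg))
  }
  invisible(msg)
}
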