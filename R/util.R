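# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
pan_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("panbgc.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[panbgc %s] %s", level, paste0(...)))
}

pan_warn <- function(...) pan_log(..., level = "WARN")

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("panbgc_format_error", "error")))
}

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("panbgc_argument_error", "error")))
}

assert_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1)
    stop_arg(name, " must be a fraction in ", if (allow_zero) "[0, 1]" else "(0, 1]",
             ", got ", format(x))
  invisible(x)
}

# Deterministic lexicographic sort independent of locale collation.
lex_sort <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(x, method = "radix")]
}

lex_order <- function(...) order(..., method = "radix")
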