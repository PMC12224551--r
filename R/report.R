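# Tabular report writing: deterministic TSV / JSON artifacts.

#' Write a tabular report
#'
#' Writes a data.frame as TSV or JSON with deterministic column order
#' and formatting, so identical records always yield byte-identical
#' files and a write/read round trip preserves content.
#'
#' @param records A data.frame (possibly zero rows).
#' @param path Output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  chr <- as.data.frame(lapply(records, function(col) {
    if (is.numeric(col)) vapply(col, function(v) format(v, scientific = FALSE, trim = TRUE), "")
    else if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
    else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  names(chr) <- names(records)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    lines <- paste(names(chr), collapse = "\t")
    if (nrow(chr) > 0L)
      lines <- c(lines, do.call(paste, c(unname(chr), sep = "\t")))
    writeLines(lines, con)
  } else {
    writeLines(jsonlite::toJSON(chr, dataframe = "rows", pretty = TRUE,
                                na = "null"), con)
  }
  invisible(path)
}

#' Read a report written by \code{\link{write_report}}
#'
#' All columns are returned as character, matching the written text.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return A data.frame with character columns.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (format == "tsv") {
    utils::read.delim(path, colClasses = "character", check.names = FALSE)
  } else {
    df <- jsonlite::fromJSON(path)
    as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE,
                  check.names = FALSE, optional = TRUE)
  }
}
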