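# Packaged reference tables of conserved-BGC presence/absence.

#' Load a packaged presence/absence reference table
#'
#' Two small reference tables ship with the package, both concerning the
#' five biosynthetic gene clusters broadly conserved in Myxococcota
#' (geosmin, carotenoid, VEPE/AEPE/TG-1, alkylpyrone, myxochelin):
#' \describe{
#'   \item{\code{"table2"}}{Genus-level presence/absence of the five
#'     BGCs across the eleven genera with enough sequenced genomes for
#'     pan-genome analysis (5 rows x 11 columns).}
#'   \item{\code{"table3"}}{Presence/absence of the five BGCs in eleven
#'     validation strains from genera outside the pan-genome set
#'     (11 rows x 5 columns).}
#' }
#' Only the cells are stored; row/column totals are always recomputed by
#' the tabulators, never read from the table.
#'
#' @param name \code{"table2"} or \code{"table3"}.
#' @return A list of class \code{table_fixture} with elements
#'   \code{row_labels}, \code{col_labels} and \code{values} (a character
#'   matrix of \code{"present"}/\code{"absent"}).
#' @examples
#' fix <- load_fixture("table3")
#' dim(fix$values)
#' @export
load_fixture <- function(name = c("table2", "table3")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("table2", "table3"))
    stop_arg("unknown fixture name: ", paste(name, collapse = ", "))
  file <- switch(name,
                 table2 = "genus_bgc_presence.tsv",
                 table3 = "validation_strain_presence.tsv")
  path <- system.file("extdata", file, package = "panbgc", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  if (!all(vals %in% c("+", "-")))
    stop_format("fixture ", name, " contains symbols other than +/-")
  out <- matrix(ifelse(vals == "+", "present", "absent"), nrow = nrow(vals),
                dimnames = dimnames(vals))
  structure(list(row_labels = rownames(out), col_labels = colnames(out),
                 values = out, name = name), class = "table_fixture")
}

#' @export
print.table_fixture <- function(x, ...) {
  cat(sprintf("<table_fixture '%s'> %d x %d\n", x$name,
              length(x$row_labels), length(x$col_labels)))
  invisible(x)
}

#' Convert the genus-level presence table into phylum groups
#'
#' Encodes each BGC row of the \code{"table2"} fixture as a
#' \code{phylum_group} whose \code{genera_present} are the genera marked
#' present, ready for \code{\link{call_phylum_conservation}}.
#'
#' @param fix A \code{table_fixture} with BGC rows and genus columns.
#' @return A list of \code{phylum_group} objects.
#' @export
phylum_groups_from_fixture <- function(fix) {
  stopifnot(inherits(fix, "table_fixture"))
  lapply(fix$row_labels, function(bgc) {
    genera <- fix$col_labels[fix$values[bgc, ] == "present"]
    structure(list(group_id = bgc,
                   members = data.frame(genus = genera,
                                        family_id = paste0(bgc, "@", genera),
                                        stringsAsFactors = FALSE),
                   genera_present = genera, label = bgc),
              class = "phylum_group")
  })
}

#' Convert the validation presence table into screen results
#'
#' Replays each strain row of the \code{"table3"} fixture as a
#' \code{screen_result} (with empty alignment evidence), so the
#' presence/absence grid can be fed through \code{\link{screen_table}}
#' and its totals recomputed.
#'
#' @param fix A \code{table_fixture} with strain rows and BGC columns.
#' @return A list of \code{screen_result} objects.
#' @export
screen_results_from_fixture <- function(fix) {
  stopifnot(inherits(fix, "table_fixture"))
  lapply(fix$row_labels, function(strain) {
    calls <- setNames(fix$values[strain, ], fix$col_labels)
    structure(list(genome_id = strain, calls = calls,
                   per_genome_total = sum(calls == "present"),
                   evidence = setNames(vector("list", length(calls)),
                                       names(calls))),
              class = "screen_result")
  })
}
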