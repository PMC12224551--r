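# Gene presence/absence matrix: the pan-genome substrate.

#' Construct a gene presence/absence matrix
#'
#' The central pan-genome container: one row per gene family, one column
#' per genome, each cell holding the locus tags of that family's members
#' in that genome (an empty cell means the family is absent from the
#' genome). Mirrors the content of a Roary \code{gene_presence_absence.csv}.
#'
#' @param cells A list-matrix (\code{matrix} with list cells) of character
#'   vectors of locus tags, with family ids as row names and genome ids as
#'   column names. Alternatively a plain character matrix whose cells are
#'   single tags or empty strings.
#' @param annotation Optional named character vector of free-text
#'   annotations, named by family id.
#' @return An object of class \code{pa_matrix}.
#' @examples
#' cells <- matrix(list("t1", character(), "t2", "t3"), nrow = 2,
#'                 dimnames = list(c("famA", "famB"), c("g1", "g2")))
#' m <- pa_matrix(cells)
#' presence_counts(m)
#' @export
pa_matrix <- function(cells, annotation = NULL) {
  if (!is.matrix(cells)) stop_arg("cells must be a matrix")
  if (!is.list(cells)) {
    chr <- cells
    cells <- matrix(vector("list", length(chr)), nrow = nrow(chr),
                    dimnames = dimnames(chr))
    for (i in seq_along(chr))
      cells[[i]] <- if (is.na(chr[[i]]) || !nzchar(chr[[i]])) character() else chr[[i]]
  }
  if (is.null(rownames(cells)) || is.null(colnames(cells)))
    stop_arg("cells must have family ids as rownames and genome ids as colnames")
  if (anyDuplicated(rownames(cells)))
    stop_format("duplicate family id: ",
                rownames(cells)[duplicated(rownames(cells))][1L])
  if (anyDuplicated(colnames(cells)))
    stop_format("duplicate genome id: ",
                colnames(cells)[duplicated(colnames(cells))][1L])
  # a locus tag may belong to at most one family within a genome
  for (g in colnames(cells)) {
    tags <- unlist(cells[, g], use.names = FALSE)
    if (anyDuplicated(tags))
      stop_format("locus tag assigned to more than one family in genome ", g,
                  ": ", tags[duplicated(tags)][1L])
  }
  structure(list(cells = cells, annotation = annotation), class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d gene families x %d genomes\n",
              length(family_ids(x)), length(genome_ids(x))))
  invisible(x)
}

#' Accessors for a presence/absence matrix
#'
#' @param m A \code{pa_matrix}.
#' @return \code{family_ids} and \code{genome_ids} return character
#'   vectors; \code{presence} a logical family-by-genome matrix;
#'   \code{presence_counts} a named integer vector (number of genomes per
#'   family with at least one member, paralogs counted once);
#'   \code{matrix_cells} the underlying list-matrix.
#' @export
family_ids <- function(m) rownames(m$cells)

#' @rdname family_ids
#' @export
genome_ids <- function(m) colnames(m$cells)

#' @rdname family_ids
#' @export
presence <- function(m) {
  p <- lengths(m$cells) > 0L
  dim(p) <- dim(m$cells)
  dimnames(p) <- dimnames(m$cells)
  p
}

#' @rdname family_ids
#' @export
presence_counts <- function(m) {
  p <- presence(m)
  setNames(as.integer(rowSums(p)), rownames(p))
}

#' @rdname family_ids
#' @export
matrix_cells <- function(m) m$cells

# Roary's fixed leading metadata columns, identified by name not position.
.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Read a Roary-style gene presence/absence CSV
#'
#' Parses a \code{gene_presence_absence.csv} as produced by Roary: the
#' fixed metadata columns are recognized by name (extra unknown metadata
#' columns are ignored with a log line) and every remaining column is
#' treated as a genome. Cells holding several locus tags (paralogs) are
#' split on tab, semicolon, or runs of spaces; the detected separator is
#' logged. When a \code{"No. isolates"} column is present its values are
#' cross-checked against the presence counts computed from cell content;
#' discrepancies are logged and the cell content wins.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{pa_matrix}}.
#' @export
read_roary_csv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (!"Gene" %in% names(df))
    stop_format("not a Roary presence/absence CSV (no 'Gene' column): ", path)
  meta_present <- intersect(names(df), .roary_meta_cols)
  if (length(meta_present) < length(.roary_meta_cols))
    pan_log("metadata columns present: ", length(meta_present), " of ",
            length(.roary_meta_cols), " known Roary columns")
  # every column not named like Roary metadata is a genome column
  genome_cols <- setdiff(names(df), .roary_meta_cols)
  if (length(genome_cols) == 0L)
    stop_format("no genome columns found in ", path)
  fams <- df[["Gene"]]
  if (anyDuplicated(fams))
    stop_format("duplicate family id in ", path, ": ",
                fams[duplicated(fams)][1L])

  cell_chr <- as.matrix(df[genome_cols])
  sep <- if (any(grepl("\t", cell_chr, fixed = TRUE))) "tab"
         else if (any(grepl(";", cell_chr, fixed = TRUE))) "semicolon"
         else "space"
  pan_log("read ", length(fams), " families x ", length(genome_cols),
          " genomes from ", basename(path), " (cell separator: ", sep, ")")

  cells <- matrix(vector("list", length(cell_chr)), nrow = length(fams),
                  dimnames = list(fams, genome_cols))
  split_rx <- "[\t;]+|[ ]+"
  for (i in seq_along(cell_chr)) {
    v <- cell_chr[[i]]
    cells[[i]] <- if (is.na(v) || !nzchar(v)) character()
                  else strsplit(trimws(v), split_rx)[[1L]]
  }

  ann <- if ("Annotation" %in% names(df))
    setNames(df[["Annotation"]], fams) else NULL
  m <- pa_matrix(cells, annotation = ann)

  if ("No. isolates" %in% names(df)) {
    declared <- suppressWarnings(as.integer(df[["No. isolates"]]))
    got <- unname(presence_counts(m))
    bad <- which(!is.na(declared) & declared != got)
    if (length(bad))
      pan_warn("'No. isolates' disagrees with cell content for ",
               length(bad), " families (e.g. ", fams[bad[1L]],
               ": declared ", declared[bad[1L]], ", observed ",
               got[bad[1L]], "); cell content wins")
  }
  m
}

.csv_quote <- function(x) paste0('"', gsub('"', '""', x), '"')

#' Write a presence/absence matrix as a Roary-style CSV
#'
#' Emits the three metadata columns the reader requires ("Gene",
#' "Annotation", "No. isolates") followed by one column per genome, with
#' multi-tag cells joined by tabs inside RFC-4180 quoted fields. Output
#' is deterministic: the same matrix always produces byte-identical
#' files.
#'
#' @param m A \code{\link{pa_matrix}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_roary_csv <- function(m, path) {
  fams <- family_ids(m)
  gens <- genome_ids(m)
  ann <- if (is.null(m$annotation)) setNames(rep("", length(fams)), fams)
         else m$annotation[fams]
  ann[is.na(ann)] <- ""
  counts <- presence_counts(m)
  header <- paste(.csv_quote(c("Gene", "Annotation", "No. isolates", gens)),
                  collapse = ",")
  rows <- vapply(fams, function(f) {
    cells <- vapply(gens, function(g)
      paste(m$cells[[f, g]], collapse = "\t"), "")
    paste(.csv_quote(c(f, ann[[f]], as.character(counts[[f]]), cells)),
          collapse = ",")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
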