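# Genome metadata: which genome belongs to which genus.

#' Construct a genome metadata table
#'
#' @param genome_id Character vector of unique genome identifiers.
#' @param genus Character vector of genus names (recycled if length 1).
#' @param species_label,accession Optional character vectors.
#' @return A data.frame of class \code{genome_metadata}.
#' @export
genome_metadata <- function(genome_id, genus, species_label = NA_character_,
                            accession = NA_character_) {
  if (any(!nzchar(genome_id)) || anyDuplicated(genome_id))
    stop_arg("genome_id values must be non-empty and unique")
  if (any(!nzchar(genus))) stop_arg("genus values must be non-empty")
  df <- data.frame(genome_id = genome_id, genus = genus,
                   species_label = species_label, accession = accession,
                   stringsAsFactors = FALSE)
  class(df) <- c("genome_metadata", "data.frame")
  df
}

#' Read a genome metadata TSV
#'
#' Expects a header line \code{genome_id<TAB>genus} with optional extra
#' columns \code{species_label} and \code{accession}.
#'
#' @param path Path to the TSV file.
#' @return A \code{\link{genome_metadata}} data.frame.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("genome_id", "genus") %in% names(df)))
    stop_format("metadata TSV must have 'genome_id' and 'genus' columns: ", path)
  genome_metadata(df$genome_id, df$genus,
                  species_label = df$species_label %||% NA_character_,
                  accession = df$accession %||% NA_character_)
}

#' Write a genome metadata TSV
#'
#' @param metadata A \code{\link{genome_metadata}} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  keep <- c("genome_id", "genus")
  for (opt in c("species_label", "accession"))
    if (!all(is.na(metadata[[opt]]))) keep <- c(keep, opt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(keep, collapse = "\t"),
               do.call(paste, c(unname(metadata[keep]), sep = "\t"))), con)
  invisible(path)
}

#' @importFrom utils read.delim
NULL

# genomes of one genus, in deterministic order
genus_genomes <- function(metadata, genus) {
  g <- metadata$genome_id[metadata$genus == genus]
  lex_sort(g)
}
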