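# Per-genus prevalence, pan-genome bins, conserved-gene extraction, and
# a self-contained greedy protein clusterer for synthetic end-to-end runs.

#' Per-genus gene-family prevalence
#'
#' Computes, for one genus, the fraction of that genus' genomes carrying
#' each gene family (paralogs count once). Families absent from every
#' genome of the genus are omitted.
#'
#' @param m A \code{\link{pa_matrix}}.
#' @param metadata A \code{\link{genome_metadata}} covering every genome
#'   in the matrix.
#' @param genus Genus to tabulate.
#' @return A list of class \code{prevalence_table} with elements
#'   \code{genus}, \code{n_genomes}, and \code{prevalence} (named numeric
#'   in (0, 1]).
#' @export
compute_prevalence <- function(m, metadata, genus) {
  missing_md <- setdiff(genome_ids(m), metadata$genome_id)
  if (length(missing_md))
    stop_arg("genomes missing from metadata: ",
             paste(head(missing_md, 3L), collapse = ", "))
  gg <- intersect(genus_genomes(metadata, genus), genome_ids(m))
  if (length(gg) == 0L) stop_arg("genus has no genomes in the matrix: ", genus)
  p <- presence(m)[, gg, drop = FALSE]
  counts <- rowSums(p)
  prev <- counts[counts > 0] / length(gg)
  structure(list(genus = genus, n_genomes = length(gg),
                 prevalence = prev), class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("<prevalence_table> genus %s: %d genomes, %d families present\n",
              x$genus, x$n_genomes, length(x$prevalence)))
  invisible(x)
}

#' Conserved gene families of a genus
#'
#' A family is conserved when it is present in at least
#' \code{min_prevalence} of the genus' genomes; the comparison is
#' \code{>=} on exact fractions, so a family in exactly half the genomes
#' qualifies at the default threshold.
#'
#' @param prev A \code{prevalence_table}.
#' @param min_prevalence Minimum fraction of genomes (default 0.5).
#' @return Character vector of family ids, lexicographically sorted.
#' @export
conserved_families <- function(prev, min_prevalence = 0.5) {
  assert_fraction(min_prevalence, "min_prevalence")
  lex_sort(names(prev$prevalence)[prev$prevalence >= min_prevalence])
}

#' Classify families into pan-genome bins
#'
#' Partitions the families present in a genus into the conventional
#' core / soft-core / shell / cloud bins by prevalence. Boundaries
#' follow Roary's reporting convention: core >= 0.99, soft core
#' [0.95, 0.99), shell [0.15, 0.95), cloud (0, 0.15).
#'
#' @param prev A \code{prevalence_table}.
#' @param bounds Named numeric of strictly decreasing lower bounds for
#'   \code{core}, \code{soft_core}, and \code{shell}.
#' @return A list of class \code{pangenome_bins}: per-bin family id
#'   vectors, per-bin counts, and the bounds used.
#' @export
classify_bins <- function(prev,
                          bounds = c(core = 0.99, soft_core = 0.95, shell = 0.15)) {
  if (!(bounds[["core"]] > bounds[["soft_core"]] &&
        bounds[["soft_core"]] > bounds[["shell"]] && bounds[["shell"]] > 0))
    stop_arg("bin bounds must be strictly decreasing positive fractions")
  p <- prev$prevalence
  bin <- ifelse(p >= bounds[["core"]], "core",
         ifelse(p >= bounds[["soft_core"]], "soft_core",
         ifelse(p >= bounds[["shell"]], "shell", "cloud")))
  fams <- lapply(c(core = "core", soft_core = "soft_core",
                   shell = "shell", cloud = "cloud"),
                 function(b) lex_sort(names(p)[bin == b]))
  structure(list(families = fams, counts = lengths(fams), bounds = bounds,
                 genus = prev$genus), class = "pangenome_bins")
}

#' @export
print.pangenome_bins <- function(x, ...) {
  cat(sprintf("<pangenome_bins> %s: core %d, soft_core %d, shell %d, cloud %d\n",
              x$genus, x$counts[["core"]], x$counts[["soft_core"]],
              x$counts[["shell"]], x$counts[["cloud"]]))
  invisible(x)
}

#' Clustering parameters for \code{\link{cluster_proteins}}
#'
#' @param min_identity Minimum global-alignment identity for a protein
#'   to join a centroid's family (default 0.7).
#' @param min_coverage Minimum bidirectional coverage (default 0.8).
#' @param params Alignment scoring, see \code{\link{alignment_params}}.
#' @return A list of class \code{clustering_params}.
#' @export
clustering_params <- function(min_identity = 0.7, min_coverage = 0.8,
                              params = alignment_params()) {
  assert_fraction(min_identity, "min_identity")
  assert_fraction(min_coverage, "min_coverage")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 params = params), class = "clustering_params")
}

#' Greedy incremental protein clustering
#'
#' A CD-HIT-style stand-in for an external pan-genome tool, used by
#' synthetic end-to-end runs: proteins are sorted by length descending
#' (ties by genome id then locus tag), and each protein joins the first
#' existing centroid whose global-alignment identity and bidirectional
#' coverage meet the thresholds, else founds a new family. Family ids
#' are assigned in founding order ("fam00001", ...), so output is fully
#' deterministic.
#'
#' @param proteins A data.frame with columns \code{genome_id},
#'   \code{locus_tag}, \code{translation} (all non-empty).
#' @param cparams A \code{\link{clustering_params}}.
#' @return A \code{\link{pa_matrix}} over the input genomes.
#' @export
cluster_proteins <- function(proteins, cparams = clustering_params()) {
  stopifnot(is.data.frame(proteins))
  genomes <- lex_sort(unique(proteins$genome_id))
  if (nrow(proteins) == 0L) {
    cells <- matrix(vector("list", 0L), nrow = 0L,
                    dimnames = list(character(), genomes))
    return(pa_matrix(cells))
  }
  if (any(!nzchar(proteins$translation)))
    stop_arg("all translations must be non-empty")
  ord <- lex_order(-nchar(proteins$translation), proteins$genome_id,
                   proteins$locus_tag)
  proteins <- proteins[ord, , drop = FALSE]

  centroid_seq <- character()
  assign <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$translation[i]
    hit <- 0L
    for (k in seq_along(centroid_seq)) {
      idc <- protein_identity(s, centroid_seq[k], cparams$params)
      if (idc[["identity"]] >= cparams$min_identity &&
          idc[["coverage"]] >= cparams$min_coverage) { hit <- k; break }
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, s)
      hit <- length(centroid_seq)
    }
    assign[i] <- hit
  }
  fam_ids <- sprintf("fam%05d", seq_along(centroid_seq))
  cells <- matrix(rep(list(character()), length(fam_ids) * length(genomes)),
                  nrow = length(fam_ids), dimnames = list(fam_ids, genomes))
  for (i in seq_len(nrow(proteins))) {
    f <- fam_ids[assign[i]]; g <- proteins$genome_id[i]
    cells[[f, g]] <- c(cells[[f, g]], proteins$locus_tag[i])
  }
  pa_matrix(cells)
}
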