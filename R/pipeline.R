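# End-to-end drivers wiring the module operations together.

#' Run the genus-level conservation pipeline
#'
#' For every genus in the metadata (or a chosen subset): computes gene
#' family prevalence, extracts the conserved gene set, maps families
#' into that genus' BGC regions, groups regions into BGC families, and
#' calls genus-level conservation.
#'
#' @param m A \code{\link{pa_matrix}}.
#' @param metadata A \code{\link{genome_metadata}}.
#' @param regions Named list of \code{\link{bgc_region}}.
#' @param genera Genera to analyze; default all in the metadata.
#' @param min_prevalence Conserved-gene prevalence threshold
#'   (default 0.5).
#' @param min_genome_frac,min_conserved_genes Conservation-call
#'   thresholds (defaults 0.5 and 2).
#' @param min_shared Shared conserved families needed to group two
#'   regions (default 2).
#' @param coords Optional coordinate sidecar for tag-less mapping, see
#'   \code{\link{map_families_to_regions}}.
#' @return A list of class \code{conservation_result}: \code{per_genus}
#'   (each with \code{prevalence}, \code{conserved}, \code{contents},
#'   \code{families}, \code{calls}) and \code{calls}, the combined
#'   genus-call table.
#' @export
run_conservation <- function(m, metadata, regions, genera = NULL,
                             min_prevalence = 0.5, min_genome_frac = 0.5,
                             min_conserved_genes = 2L, min_shared = 2L,
                             coords = NULL) {
  genera <- genera %||% lex_sort(unique(metadata$genus))
  region_genome <- vapply(regions, `[[`, "", "genome_id")
  per_genus <- list()
  for (ge in genera) {
    prev <- compute_prevalence(m, metadata, ge)
    cons <- conserved_families(prev, min_prevalence)
    gg <- genus_genomes(metadata, ge)
    regs <- regions[region_genome %in% gg]
    contents <- map_families_to_regions(m, regs, conserved = cons,
                                        coords = coords)
    fams <- build_bgc_families(contents, cons, genus = ge,
                               min_shared = min_shared)
    calls <- call_genus_conservation(fams, prev$n_genomes,
                                     min_genome_frac, min_conserved_genes)
    per_genus[[ge]] <- list(genus = ge, prevalence = prev, conserved = cons,
                            contents = contents, families = fams,
                            calls = calls)
  }
  combined <- do.call(rbind, c(lapply(per_genus, `[[`, "calls"),
                               make.row.names = FALSE))
  structure(list(per_genus = per_genus, calls = combined,
                 params = list(min_prevalence = min_prevalence,
                               min_genome_frac = min_genome_frac,
                               min_conserved_genes = min_conserved_genes,
                               min_shared = min_shared)),
            class = "conservation_result")
}

#' Aggregate conserved genus families into phylum groups
#'
#' Links the genus-level conserved BGC families across genera (see
#' \code{\link{link_across_genera}}) and calls phylum-level
#' conservation, attaching the result to the pipeline object.
#'
#' @param result A \code{conservation_result} from
#'   \code{\link{run_conservation}}.
#' @param regions Named list of \code{\link{bgc_region}} supplying
#'   representative regions.
#' @param min_genera Phylum-conservation threshold (default 7).
#' @param min_shared_genes,min_identity,min_coverage Linkage
#'   thresholds, see \code{\link{link_across_genera}}.
#' @param params Alignment scoring.
#' @return The input \code{result} with an added \code{phylum} element
#'   (\code{groups} and \code{calls}).
#' @export
aggregate_phylum <- function(result, regions, min_genera = 7L,
                             min_shared_genes = 2L, min_identity = 0.4,
                             min_coverage = 0.6,
                             params = alignment_params()) {
  stopifnot(inherits(result, "conservation_result"))
  conserved_fams <- list()
  for (ge in names(result$per_genus)) {
    gr <- result$per_genus[[ge]]
    ids <- gr$calls$family_id[gr$calls$is_conserved]
    conserved_fams <- c(conserved_fams, gr$families[ids])
  }
  groups <- link_across_genera(conserved_fams, regions, min_shared_genes,
                               min_identity, min_coverage, params)
  calls <- call_phylum_conservation(groups,
                                    length(result$per_genus), min_genera)
  result$phylum <- list(groups = groups, calls = calls,
                        min_genera = min_genera)
  result
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("<conservation_result> %d genera, %d BGC families, %d conserved\n",
              length(x$per_genus), nrow(x$calls), sum(x$calls$is_conserved)))
  if (!is.null(x$phylum))
    cat(sprintf("  phylum: %d groups, %d conserved at >= %d genera\n",
                nrow(x$phylum$calls),
                sum(x$phylum$calls$is_phylum_conserved),
                x$phylum$min_genera))
  invisible(x)
}

#' Phylum-group report mirroring a genus presence/absence table
#'
#' One row per phylum group with per-genus "+"/"-" presence and the
#' number of genera present.
#'
#' @param groups List of \code{phylum_group}.
#' @param genera Character vector of all analyzed genera (columns).
#' @return A data.frame report.
#' @export
phylum_table <- function(groups, genera) {
  rows <- lapply(groups, function(gr) {
    row <- data.frame(group = gr$label %||% gr$group_id,
                      stringsAsFactors = FALSE)
    for (ge in genera)
      row[[ge]] <- if (ge %in% gr$members$genus) "+" else "-"
    row$n_genera <- length(unique(gr$members$genus))
    row
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(group = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
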