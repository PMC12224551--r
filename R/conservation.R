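# Core inference: map conserved gene families into BGC regions, group
# regions into genus-level BGC families, call conservation, and link
# families across genera.

#' Map gene families into BGC regions
#'
#' For each region, resolves its CDS locus tags to the gene families of
#' the presence/absence matrix. Primary mapping is exact locus-tag
#' equality within the same genome. When tag universes are disjoint
#' (e.g. the cluster annotation was run on raw FASTA rather than the
#' annotation used for the pan-genome), an optional coordinate fallback
#' maps a CDS to the family of any matrix locus tag whose recorded
#' coordinates overlap it reciprocally by at least
#' \code{min_reciprocal_overlap}; this requires a coordinate sidecar.
#'
#' @param m A \code{\link{pa_matrix}}.
#' @param regions List of \code{\link{bgc_region}} objects whose
#'   genomes all appear in the matrix.
#' @param conserved Optional character vector of conserved family ids;
#'   when supplied, each result also reports the conserved subset.
#' @param coords Optional coordinate sidecar: data.frame with columns
#'   \code{genome_id}, \code{locus_tag}, \code{contig_id}, \code{start},
#'   \code{end}. Enables the coordinate fallback.
#' @param min_reciprocal_overlap Reciprocal overlap fraction for the
#'   fallback (default 0.5).
#' @return A list of \code{region_family_content} objects: each has
#'   \code{region_id}, \code{families_all}, \code{families_conserved},
#'   \code{unmapped_tags}, and \code{tag_family} (named mapping of
#'   resolved tags).
#' @export
map_families_to_regions <- function(m, regions, conserved = character(),
                                    coords = NULL,
                                    min_reciprocal_overlap = 0.5) {
  unknown <- setdiff(vapply(regions, `[[`, "", "genome_id"), genome_ids(m))
  if (length(unknown))
    stop_arg("regions reference genomes absent from the matrix: ",
             paste(head(unknown, 3L), collapse = ", "))

  # per-genome tag -> family lookup
  lookup <- list()
  for (g in genome_ids(m)) {
    col <- m$cells[, g]
    tags <- unlist(col, use.names = FALSE)
    fams <- rep(names(col), lengths(col))
    lookup[[g]] <- setNames(fams, tags)
  }

  lapply(regions, function(r) {
    lk <- lookup[[r$genome_id]]
    fam <- unname(lk[r$cds$locus_tag])
    unmapped <- r$cds$locus_tag[is.na(fam)]
    if (length(unmapped) && !is.null(coords)) {
      csub <- coords[coords$genome_id == r$genome_id &
                     coords$contig_id == r$contig_id, , drop = FALSE]
      for (k in which(is.na(fam))) {
        s1 <- r$cds$start[k]; e1 <- r$cds$end[k]; len1 <- e1 - s1 + 1L
        ov <- pmax(0L, pmin(e1, csub$end) - pmax(s1, csub$start) + 1L)
        len2 <- csub$end - csub$start + 1L
        hit <- which(ov / len1 >= min_reciprocal_overlap &
                     ov / len2 >= min_reciprocal_overlap)
        if (length(hit)) {
          # best reciprocal overlap, ties by lexicographic tag
          sc <- pmin(ov[hit] / len1, ov[hit] / len2[hit])
          hit <- hit[lex_order(-sc, csub$locus_tag[hit])][1L]
          fam[k] <- lk[[csub$locus_tag[hit]]] %||% NA_character_
        }
      }
      unmapped <- r$cds$locus_tag[is.na(fam)]
    }
    if (all(is.na(fam)) && nrow(r$cds) > 0L)
      pan_warn("no CDS of region ", r$region_id,
               " could be mapped to a gene family")
    tag_family <- setNames(fam[!is.na(fam)], r$cds$locus_tag[!is.na(fam)])
    families_all <- lex_sort(unique(unname(tag_family)))
    structure(list(region_id = r$region_id, genome_id = r$genome_id,
                   families_all = families_all,
                   families_conserved = intersect(families_all, conserved),
                   unmapped_tags = unmapped, tag_family = tag_family),
              class = "region_family_content")
  })
}

#' Group regions into genus-level BGC families
#'
#' Builds a graph whose nodes are regions, with an edge whenever two
#' regions share at least \code{min_shared} conserved gene families;
#' connected components become BGC families (single linkage). Regions
#' carrying fewer than \code{min_shared} conserved families in total
#' form no family. Family ids are deterministic: components are sorted
#' by their smallest member region id.
#'
#' @param contents List of \code{region_family_content} from
#'   \code{\link{map_families_to_regions}}.
#' @param conserved Character vector of conserved family ids for the
#'   genus.
#' @param genus Genus label attached to the resulting families.
#' @param min_shared Minimum number of shared conserved families for an
#'   edge (default 2).
#' @return A list of \code{bgc_family} objects with fields
#'   \code{family_id}, \code{genus}, \code{member_regions} (genome ->
#'   region ids), \code{defining_families}, \code{n_genomes_with}, and
#'   \code{region_conserved_n} (per-region conserved-family counts).
#' @export
build_bgc_families <- function(contents, conserved, genus = "",
                               min_shared = 2L) {
  if (min_shared < 1L) stop_arg("min_shared must be >= 1")
  cons_sets <- lapply(contents, function(ct)
    intersect(ct$families_all, conserved))
  names(cons_sets) <- vapply(contents, `[[`, "", "region_id")
  eligible <- which(lengths(cons_sets) >= min_shared)
  if (length(eligible) == 0L) return(list())

  ids <- names(cons_sets)[eligible]
  sets <- cons_sets[eligible]
  edges <- character()
  n <- length(ids)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(intersect(sets[[i]], sets[[j]])) >= min_shared)
      edges <- c(edges, ids[i], ids[j])
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  genome_of <- setNames(vapply(contents, `[[`, "", "genome_id"),
                        vapply(contents, `[[`, "", "region_id"))
  fams <- lapply(split(names(comp), comp), function(members) {
    members <- lex_sort(members)
    member_regions <- split(members, genome_of[members])
    defining <- lex_sort(unique(unlist(cons_sets[members], use.names = FALSE)))
    structure(list(family_id = NA_character_, genus = genus,
                   member_regions = member_regions,
                   defining_families = defining,
                   n_genomes_with = length(member_regions),
                   region_conserved_n = lengths(cons_sets[members])),
              class = "bgc_family")
  })
  # deterministic ids: sort components by smallest member region id
  first_member <- vapply(fams, function(f)
    lex_sort(unlist(f$member_regions, use.names = FALSE))[1L], "")
  fams <- fams[lex_order(first_member)]
  for (k in seq_along(fams))
    fams[[k]]$family_id <- sprintf("%s_bgcfam%03d",
                                   if (nzchar(genus)) genus else "x", k)
  names(fams) <- vapply(fams, `[[`, "", "family_id")
  fams
}

#' @export
print.bgc_family <- function(x, ...) {
  cat(sprintf("<bgc_family> %s (%s): %d genomes, %d defining families\n",
              x$family_id, x$genus, x$n_genomes_with,
              length(x$defining_families)))
  invisible(x)
}

#' Genus-level conservation calls
#'
#' A BGC family is conserved in its genus when it is present in at
#' least \code{min_genome_frac} of the genus' genomes AND carries at
#' least \code{min_conserved_genes} distinct conserved gene families.
#' Both comparisons are \code{>=} on exact fractions/counts.
#'
#' @param families List of \code{bgc_family}.
#' @param n_genomes_total Number of genomes analyzed for the genus.
#' @param min_genome_frac Minimum genome fraction (default 0.5).
#' @param min_conserved_genes Minimum distinct conserved families
#'   (default 2).
#' @return A data.frame with one row per family: \code{genus},
#'   \code{family_id}, \code{n_genomes_with}, \code{n_genomes_total},
#'   \code{genome_fraction}, \code{n_conserved_genes},
#'   \code{is_conserved}.
#' @export
call_genus_conservation <- function(families, n_genomes_total,
                                    min_genome_frac = 0.5,
                                    min_conserved_genes = 2L) {
  if (n_genomes_total < 1L) stop_arg("n_genomes_total must be >= 1")
  rows <- lapply(families, function(f) {
    frac <- f$n_genomes_with / n_genomes_total
    ncg <- length(f$defining_families)
    data.frame(genus = f$genus, family_id = f$family_id,
               n_genomes_with = f$n_genomes_with,
               n_genomes_total = n_genomes_total,
               genome_fraction = frac, n_conserved_genes = ncg,
               is_conserved = frac >= min_genome_frac &&
                              ncg >= min_conserved_genes,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(genus = character(), family_id = character(),
                         n_genomes_with = integer(),
                         n_genomes_total = integer(),
                         genome_fraction = numeric(),
                         n_conserved_genes = integer(),
                         is_conserved = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# representative region of a genus family: the member with the most
# conserved families mapped; ties by lexicographic genome id, then
# region id.
representative_region_id <- function(family) {
  regs <- unlist(family$member_regions, use.names = FALSE)
  genome_of <- rep(names(family$member_regions),
                   lengths(family$member_regions))
  ncons <- family$region_conserved_n[regs]
  regs[lex_order(-ncons, genome_of, regs)][1L]
}

#' Link genus-level BGC families across genera
#'
#' Each conserved genus family is represented by one member region (the
#' region with the most conserved families mapped; ties broken by
#' lexicographic genome id). Two genus families are linked when their
#' representative regions share at least \code{min_shared_genes}
#' best-bidirectional-hit protein pairs at the given identity and
#' coverage thresholds; connected components become phylum groups.
#'
#' @param families List of conserved \code{bgc_family} objects (across
#'   genera).
#' @param regions Named list of \code{\link{bgc_region}} keyed by
#'   region id, supplying the representative regions.
#' @param min_shared_genes Minimum mutual-best pairs to link (default 2).
#' @param min_identity,min_coverage Protein match thresholds (defaults
#'   0.4 and 0.6).
#' @param params Alignment scoring.
#' @return A list of \code{phylum_group} objects with deterministic ids
#'   ("group001", ...), each carrying \code{members} (genus, family_id),
#'   \code{genera_present}, and \code{representatives}.
#' @export
link_across_genera <- function(families, regions, min_shared_genes = 2L,
                               min_identity = 0.4, min_coverage = 0.6,
                               params = alignment_params()) {
  if (length(families) == 0L) return(list())
  fam_ids <- vapply(families, `[[`, "", "family_id")
  names(families) <- fam_ids
  reps <- vapply(families, representative_region_id, "")
  missing_reg <- setdiff(reps, names(regions))
  if (length(missing_reg))
    stop_arg("representative regions not supplied: ",
             paste(head(missing_reg, 3L), collapse = ", "))

  edges <- character()
  n <- length(fam_ids)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mm <- best_bidirectional_hits(regions[[reps[i]]], regions[[reps[j]]],
                                  min_identity, min_coverage, params)
    if (nrow(mm) >= min_shared_genes)
      edges <- c(edges, fam_ids[i], fam_ids[j])
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(fam_ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  groups <- lapply(split(names(comp), comp), function(members) {
    members <- lex_sort(members)
    genera <- lex_sort(unique(vapply(families[members], `[[`, "", "genus")))
    structure(list(group_id = NA_character_,
                   members = data.frame(
                     genus = vapply(families[members], `[[`, "", "genus"),
                     family_id = members, stringsAsFactors = FALSE),
                   genera_present = genera,
                   representatives = unname(reps[members]), label = NULL),
              class = "phylum_group")
  })
  first_member <- vapply(groups, function(gr) gr$members$family_id[1L], "")
  groups <- groups[lex_order(first_member)]
  for (k in seq_along(groups)) groups[[k]]$group_id <- sprintf("group%03d", k)
  names(groups) <- vapply(groups, `[[`, "", "group_id")
  groups
}

#' @export
print.phylum_group <- function(x, ...) {
  cat(sprintf("<phylum_group> %s: %d members across %d genera%s\n",
              x$group_id, nrow(x$members), length(x$genera_present),
              if (!is.null(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Phylum-level conservation calls
#'
#' A phylum group is conserved when its member families span at least
#' \code{min_genera} genera.
#'
#' @param groups List of \code{phylum_group}.
#' @param n_genera_total Number of genera analyzed.
#' @param min_genera Minimum genera for a phylum-conserved call
#'   (default 7).
#' @return A data.frame: \code{group_id}, \code{label},
#'   \code{n_genera_present}, \code{n_genera_total},
#'   \code{is_phylum_conserved}.
#' @export
call_phylum_conservation <- function(groups, n_genera_total,
                                     min_genera = 7L) {
  if (min_genera < 1L) stop_arg("min_genera must be >= 1")
  rows <- lapply(groups, function(gr) {
    genera <- lex_sort(unique(gr$members$genus))  # recomputed, not cached
    data.frame(group_id = gr$group_id,
               label = gr$label %||% NA_character_,
               n_genera_present = length(genera),
               n_genera_total = n_genera_total,
               is_phylum_conserved = length(genera) >= min_genera,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(group_id = character(), label = character(),
                         n_genera_present = integer(),
                         n_genera_total = integer(),
                         is_phylum_conserved = logical(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
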