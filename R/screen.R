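# Presence/absence screening of genomes outside the pan-genome set.

#' Construct a BGC screening profile
#'
#' A profile is the reference gene content of one conserved cluster:
#' at least two labelled protein sequences used to probe query genomes.
#'
#' @param profile_id Profile identifier (e.g. the cluster label).
#' @param reference_genes A data.frame with columns \code{gene_label}
#'   and \code{translation} (>= 2 rows, non-empty translations).
#' @param source Free-text provenance label (e.g. a phylum group id).
#' @return A list of class \code{bgc_profile}.
#' @export
bgc_profile <- function(profile_id, reference_genes, source = "") {
  stopifnot(is.data.frame(reference_genes))
  if (nrow(reference_genes) < 2L)
    stop_arg("a profile needs at least 2 reference genes")
  if (any(!nzchar(reference_genes$translation)))
    stop_arg("reference gene translations must be non-empty")
  structure(list(profile_id = profile_id,
                 reference_genes = reference_genes[, c("gene_label", "translation")],
                 source = source), class = "bgc_profile")
}

#' Build a screening profile from a representative region
#'
#' @param region A \code{\link{bgc_region}} with translated CDS.
#' @param profile_id Profile id; defaults to the region id.
#' @return A \code{\link{bgc_profile}} using the region's CDS as
#'   reference genes.
#' @export
profile_from_region <- function(region, profile_id = region$region_id) {
  cds <- region$cds[nzchar(region$cds$translation), , drop = FALSE]
  bgc_profile(profile_id,
              data.frame(gene_label = cds$locus_tag,
                         translation = cds$translation,
                         stringsAsFactors = FALSE),
              source = region$region_id)
}

#' Screen one genome's BGC regions against cluster profiles
#'
#' A profile is called present when some single region contains at
#' least \code{min_matched_genes} distinct CDS that are best
#' bidirectional hits of distinct profile reference genes at the given
#' identity and coverage thresholds. Matches split across different
#' regions do not count: colocation is required.
#'
#' @param profiles List of \code{\link{bgc_profile}} (non-empty).
#' @param regions List of the genome's \code{\link{bgc_region}}
#'   objects (may be empty: every profile is then absent).
#' @param genome_id Genome identifier for the result; inferred from the
#'   first region when omitted.
#' @param min_matched_genes Minimum mutual-best pairs within one region
#'   (default 2).
#' @param min_identity,min_coverage Protein match thresholds (defaults
#'   0.4 and 0.6).
#' @param params Alignment scoring.
#' @return A \code{screen_result}: \code{genome_id}, \code{calls}
#'   (named "present"/"absent"), \code{per_genome_total}, and
#'   \code{evidence} (per profile, the matched gene pairs).
#' @export
screen_genome <- function(profiles, regions, genome_id = NULL,
                          min_matched_genes = 2L, min_identity = 0.4,
                          min_coverage = 0.6, params = alignment_params()) {
  if (length(profiles) == 0L) stop_arg("profiles must be non-empty")
  pids <- vapply(profiles, `[[`, "", "profile_id")
  if (anyDuplicated(pids)) stop_arg("duplicate profile ids")
  if (is.null(genome_id))
    genome_id <- if (length(regions)) regions[[1L]]$genome_id else "unknown"

  calls <- setNames(rep("absent", length(pids)), pids)
  evidence <- setNames(vector("list", length(pids)), pids)
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    pseudo <- bgc_region(region_id = paste0("profile:", prof$profile_id),
                         genome_id = "profile", contig_id = "profile",
                         start = 1L, end = 1L + 100L * nrow(prof$reference_genes),
                         cds = data.frame(
                           locus_tag = prof$reference_genes$gene_label,
                           start = 1L + 100L * (seq_len(nrow(prof$reference_genes)) - 1L),
                           end = 100L * seq_len(nrow(prof$reference_genes)),
                           strand = "+", product = "",
                           translation = prof$reference_genes$translation,
                           stringsAsFactors = FALSE))
    best <- NULL
    for (r in regions) {
      if (!any(nzchar(r$cds$translation))) next
      mm <- best_bidirectional_hits(pseudo, r, min_identity, min_coverage,
                                    params)
      if (nrow(mm) >= min_matched_genes &&
          (is.null(best) || nrow(mm) > nrow(best$mm))) {
        best <- list(region_id = r$region_id, mm = mm)
      }
    }
    if (!is.null(best)) {
      calls[[p]] <- "present"
      ev <- best$mm
      names(ev)[names(ev) == "query_tag"] <- "reference_gene"
      names(ev)[names(ev) == "target_tag"] <- "matched_locus_tag"
      ev$region_id <- best$region_id
      evidence[[p]] <- ev
    }
  }
  structure(list(genome_id = genome_id, calls = calls,
                 per_genome_total = sum(calls == "present"),
                 evidence = evidence), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %d/%d profiles present\n", x$genome_id,
              x$per_genome_total, length(x$calls)))
  invisible(x)
}

#' Tabulate screen results into a presence/absence report
#'
#' One row per genome with per-profile "+"/"-" cells and a per-genome
#' total "k/P"; a final row labelled "total" carries per-profile counts
#' "m/N". All totals are recomputed from the grid, never copied from
#' inputs.
#'
#' @param results List of \code{screen_result} sharing one profile set.
#' @return A data.frame report (character columns).
#' @export
screen_table <- function(results, label_col = "genome") {
  if (length(results) == 0L) stop_arg("no screen results to tabulate")
  pids <- names(results[[1L]]$calls)
  for (r in results)
    if (!identical(names(r$calls), pids))
      stop_arg("screen results have inconsistent profile sets")
  n_prof <- length(pids)
  n_gen <- length(results)
  grid <- t(vapply(results, function(r)
    ifelse(r$calls == "present", "+", "-"), character(n_prof)))
  rows <- data.frame(
    genome = vapply(results, `[[`, "", "genome_id"),
    stringsAsFactors = FALSE)
  names(rows) <- label_col
  for (p in pids) rows[[p]] <- grid[, p]
  rows$total <- sprintf("%d/%d", rowSums(grid == "+"), n_prof)
  total_row <- c("total", sprintf("%d/%d", colSums(grid == "+"), n_gen), "")
  out <- rbind(rows, setNames(as.list(total_row), names(rows)))
  rownames(out) <- NULL
  out
}

#' @rdname screen_table
#' @param label_col Name of the first (genome label) column.
#' @export
screen_totals <- function(results) {
  tab <- screen_table(results)
  totals <- tab[nrow(tab), -c(1L, ncol(tab))]
  setNames(as.integer(sub("/.*", "", unlist(totals))), names(totals))
}
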