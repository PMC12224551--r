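# Pairwise cluster comparison: mutual-best-hit gene matching, gene-order
# synteny, and fragment-based cluster nucleotide identity.

#' Best bidirectional protein hits between two BGC regions
#'
#' All-vs-all global protein alignment between the CDS of two regions;
#' a pair is retained when each gene is the other's best-scoring partner
#' (identity, ties broken by lexicographic partner tag) and the pair
#' meets the identity and coverage thresholds. Every CDS appears in at
#' most one match. This is the gene-matching layer behind clinker-style
#' cluster comparison figures.
#'
#' @param region_a,region_b \code{\link{bgc_region}} objects whose CDS
#'   carry translations.
#' @param min_identity,min_coverage Acceptance thresholds.
#' @param params Alignment scoring, see \code{\link{alignment_params}}.
#' @return A data.frame with columns \code{query_tag}, \code{target_tag},
#'   \code{identity}, \code{coverage}, sorted by \code{query_tag}.
#' @export
best_bidirectional_hits <- function(region_a, region_b, min_identity = 0.4,
                                    min_coverage = 0.6,
                                    params = alignment_params()) {
  ca <- region_a$cds[nzchar(region_a$cds$translation), , drop = FALSE]
  cb <- region_b$cds[nzchar(region_b$cds$translation), , drop = FALSE]
  if (nrow(ca) == 0L || nrow(cb) == 0L)
    stop_arg("both regions need at least one CDS with a translation")
  idm <- matrix(0, nrow(ca), nrow(cb), dimnames = list(ca$locus_tag, cb$locus_tag))
  cvm <- idm
  for (j in seq_len(nrow(cb))) {
    r <- .protein_identity_many(ca$translation, cb$translation[j], params)
    idm[, j] <- r$identity
    cvm[, j] <- r$coverage
  }
  .mutual_best_from_matrix(idm, cvm, min_identity, min_coverage)
}

# mutual-best filtering given identity/coverage matrices with dimnames
.mutual_best_from_matrix <- function(idm, cvm, min_identity, min_coverage) {
  a_tags <- rownames(idm); b_tags <- colnames(idm)
  # best partner with lexicographic tie-break (columns/rows already sorted
  # lexicographically is not guaranteed, so order explicitly)
  best_of_a <- vapply(seq_along(a_tags), function(i) {
    v <- idm[i, ]
    cand <- b_tags[v == max(v)]
    lex_sort(cand)[1L]
  }, "")
  best_of_b <- vapply(seq_along(b_tags), function(j) {
    v <- idm[, j]
    cand <- a_tags[v == max(v)]
    lex_sort(cand)[1L]
  }, "")
  names(best_of_a) <- a_tags
  names(best_of_b) <- b_tags
  keep <- lapply(a_tags, function(qa) {
    tb <- best_of_a[[qa]]
    if (best_of_b[[tb]] != qa) return(NULL)
    if (idm[qa, tb] < min_identity || cvm[qa, tb] < min_coverage) return(NULL)
    data.frame(query_tag = qa, target_tag = tb,
               identity = idm[qa, tb], coverage = cvm[qa, tb],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep)
  if (is.null(out))
    out <- data.frame(query_tag = character(), target_tag = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[lex_order(out$query_tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-order synteny score between two matched regions
#'
#' Projects the matched genes onto their positional order in each
#' region and scores the fraction of adjacent matched pairs in region A
#' that are also adjacent in region B, orientation-insensitively: a full
#' inversion of B preserves every adjacency and scores 1. With m
#' matches the denominator is m - 1; a single match scores 1 only when
#' both regions are single-gene, else 0.
#'
#' @param matches A data.frame as returned by
#'   \code{\link{best_bidirectional_hits}}.
#' @param order_a,order_b Character vectors giving the gene order
#'   (locus tags) of regions A and B.
#' @return A synteny score in [0, 1].
#' @export
synteny_score <- function(matches, order_a, order_b) {
  m <- nrow(matches)
  if (m == 0L) return(0)
  if (!all(matches$query_tag %in% order_a) ||
      !all(matches$target_tag %in% order_b))
    stop_arg("match references a gene absent from the given orders")
  if (m == 1L)
    return(if (length(order_a) == 1L && length(order_b) == 1L) 1 else 0)
  pos_a <- match(matches$query_tag, order_a)
  pos_b <- match(matches$target_tag, order_b)
  # rank matched genes within each region, then count shared adjacencies
  ra <- rank(pos_a)
  rb <- rank(pos_b)
  ord <- order(ra)
  rb_in_a_order <- rb[ord]
  adjacent <- abs(diff(rb_in_a_order)) == 1
  sum(adjacent) / (m - 1L)
}

#' Fragment-based average nucleotide identity of two sequences
#'
#' OrthoANI-style ANI at cluster scale: both sequences are chopped into
#' consecutive non-overlapping fragments of \code{fragment_length}
#' (trailing remainder dropped), all fragments of one sequence are
#' globally aligned against all fragments of the other, reciprocal best
#' fragment pairs passing the identity and coverage cutoffs are kept,
#' and the ANI is 100 times the mean identity over kept pairs. With no
#' qualifying pair the ANI is undefined (\code{NA}).
#'
#' @param a,b Nucleotide sequences, each at least
#'   \code{fragment_length} long.
#' @param fragment_length Fragment size in bp (default 1020, the
#'   OrthoANI convention).
#' @param min_frag_identity,min_frag_coverage Per-fragment acceptance
#'   cutoffs.
#' @param params Alignment scoring, see \code{\link{alignment_params}}.
#' @return A list of class \code{ani_result}: \code{ani_percent}
#'   (\code{NA} when undefined), \code{n_fragments_used},
#'   \code{fragment_length}.
#' @export
fragment_ani <- function(a, b, fragment_length = 1020,
                         min_frag_identity = 0.3, min_frag_coverage = 0.7,
                         params = alignment_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < fragment_length || nchar(b) < fragment_length)
    stop_arg("sequences must be at least fragment_length (", fragment_length,
             ") bp; got ", nchar(a), " and ", nchar(b))
  chop <- function(s) {
    n <- nchar(s) %/% fragment_length
    substring(s, (seq_len(n) - 1L) * fragment_length + 1L,
              seq_len(n) * fragment_length)
  }
  fa <- chop(a); fb <- chop(b)
  idm <- matrix(0, length(fa), length(fb),
                dimnames = list(sprintf("a%04d", seq_along(fa)),
                                sprintf("b%04d", seq_along(fb))))
  cvm <- idm
  for (j in seq_along(fb)) {
    r <- .nt_identity_many(fa, fb[j], params)
    idm[, j] <- r$identity
    cvm[, j] <- r$coverage
  }
  pairs <- .mutual_best_from_matrix(idm, cvm, min_frag_identity,
                                    min_frag_coverage)
  if (nrow(pairs) == 0L)
    return(structure(list(ani_percent = NA_real_, n_fragments_used = 0L,
                          fragment_length = fragment_length),
                     class = "ani_result"))
  structure(list(ani_percent = 100 * mean(pairs$identity),
                 n_fragments_used = nrow(pairs),
                 fragment_length = fragment_length),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI %s%% over %d fragments of %d bp\n",
              if (is.na(x$ani_percent)) "undefined"
              else formatC(x$ani_percent, digits = 2, format = "f"),
              x$n_fragments_used, x$fragment_length))
  invisible(x)
}

#' Pairwise comparison table for a set of regions
#'
#' The numeric analogue of a cluster-comparison figure panel: for every
#' unordered pair of regions, the number of best-bidirectional-hit gene
#' matches, the synteny score, and (when both regions carry nucleotide
#' sequences long enough) the fragment ANI.
#'
#' @param regions Named list of \code{\link{bgc_region}} objects.
#' @param min_identity,min_coverage Thresholds for gene matching.
#' @param fragment_length Fragment size for ANI (default 1020 bp).
#' @param params Alignment scoring.
#' @return A data.frame with one row per region pair.
#' @export
compare_regions <- function(regions, min_identity = 0.4, min_coverage = 0.6,
                            fragment_length = 1020,
                            params = alignment_params()) {
  ids <- lex_sort(vapply(regions, `[[`, "", "region_id"))
  regions <- regions[match(ids, vapply(regions, `[[`, "", "region_id"))]
  rows <- list()
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (j <= i) next
    ra <- regions[[i]]; rb <- regions[[j]]
    mm <- best_bidirectional_hits(ra, rb, min_identity, min_coverage, params)
    syn <- synteny_score(mm, ra$cds$locus_tag, rb$cds$locus_tag)
    ani <- NA_real_
    if (!is.null(ra$seq) && !is.null(rb$seq) &&
        nchar(ra$seq) >= fragment_length && nchar(rb$seq) >= fragment_length)
      ani <- fragment_ani(ra$seq, rb$seq, fragment_length,
                          params = params)$ani_percent
    rows[[length(rows) + 1L]] <- data.frame(
      region_a = ra$region_id, region_b = rb$region_id,
      n_matches = nrow(mm), synteny = syn, ani_percent = ani,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(region_a = character(), region_b = character(),
                         n_matches = integer(), synteny = numeric(),
                         ani_percent = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
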