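# Ground-truthed synthetic datasets: multi-genus genome sets with an
# open pan-genome structure, planted colocated BGCs of controlled
# prevalence, and controlled sequence divergence, emitted in the exact
# input formats the pipeline consumes.

.NT <- c("A", "C", "G", "T")
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# fixed arbitrary codon per amino acid (no stop codons), used for
# back-translation of generated proteins
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
            S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Specification of one planted gene cluster
#'
#' @param label Cluster label (unique within a simulation).
#' @param n_genes Number of colocated genes (>= 2).
#' @param prevalence Fraction of each genus' genomes carrying the
#'   cluster; either a single number applied to all \code{genera} or a
#'   named vector keyed by genus.
#' @param genera Genera carrying the cluster; \code{NULL} means every
#'   simulated genus.
#' @param hgt When \code{TRUE} the cluster's ancestral sequences are
#'   drawn from an independent out-group root and are not diverged
#'   between genera, emulating a horizontally transferred cluster.
#' @return A list of class \code{cluster_spec}.
#' @export
cluster_spec <- function(label, n_genes = 4L, prevalence = 0.75,
                         genera = NULL, hgt = FALSE) {
  if (n_genes < 2L) stop_arg("a cluster needs at least 2 genes")
  if (any(prevalence < 0 | prevalence > 1))
    stop_arg("prevalence must be in [0, 1]")
  structure(list(label = label, n_genes = as.integer(n_genes),
                 prevalence = prevalence, genera = genera, hgt = hgt),
            class = "cluster_spec")
}

#' Simulation parameters
#'
#' Defaults describe the standard recovery-test conditions: three
#' genera of eight genomes with an open pan-genome (200 core, 300
#' shell, 300 cloud families), two conserved clusters planted per genus
#' at prevalence 0.75 with four genes each, three decoy clusters below
#' the conservation threshold, and 2\% within-genus sequence
#' divergence.
#'
#' @param seed Integer seed; the same parameters always produce
#'   byte-identical outputs.
#' @param n_genera,genomes_per_genus Dataset shape.
#' @param n_core,n_shell,n_cloud Gene family counts per bin.
#' @param shell_presence_prob,cloud_presence_prob Per-genome presence
#'   probabilities for shell and cloud families.
#' @param planted_clusters List of \code{\link{cluster_spec}}.
#' @param divergence_within_genus,divergence_between_genera Per-site
#'   substitution probabilities applied on a two-level star phylogeny.
#' @param protein_length_range Length range (aa) for generated
#'   proteins.
#' @param n_decoy_regions Unused decoy knob retained for reports.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(seed = 1L, n_genera = 3L, genomes_per_genus = 8L,
                       n_core = 200L, n_shell = 300L, n_cloud = 300L,
                       shell_presence_prob = 0.5,
                       cloud_presence_prob = 0.1,
                       planted_clusters = NULL,
                       divergence_within_genus = 0.02,
                       divergence_between_genera = 0.1,
                       protein_length_range = c(80L, 150L)) {
  assert_fraction(shell_presence_prob, "shell_presence_prob")
  assert_fraction(cloud_presence_prob, "cloud_presence_prob", allow_zero = TRUE)
  if (divergence_within_genus < 0 || divergence_within_genus > 1 ||
      divergence_between_genera < 0 || divergence_between_genera > 1)
    stop_arg("divergence parameters must be in [0, 1]")
  if (is.null(planted_clusters))
    planted_clusters <- c(
      lapply(1:2, function(i)
        cluster_spec(sprintf("cons%d", i), n_genes = 4L, prevalence = 0.75)),
      lapply(1:3, function(i)
        cluster_spec(sprintf("decoy%d", i), n_genes = 4L, prevalence = 0.25)))
  labels <- vapply(planted_clusters, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_arg("duplicate cluster labels")
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 genomes_per_genus = as.integer(genomes_per_genus),
                 n_core = as.integer(n_core), n_shell = as.integer(n_shell),
                 n_cloud = as.integer(n_cloud),
                 shell_presence_prob = shell_presence_prob,
                 cloud_presence_prob = cloud_presence_prob,
                 planted_clusters = planted_clusters,
                 divergence_within_genus = divergence_within_genus,
                 divergence_between_genera = divergence_between_genera,
                 protein_length_range = as.integer(protein_length_range)),
            class = "sim_params")
}

#' Per-site sequence mutation
#'
#' Substitutes each site independently with probability \code{d} to a
#' uniformly chosen different symbol of the alphabet; length is
#' preserved. Uses the current RNG state.
#'
#' @param seq A character string over \code{alphabet}.
#' @param d Per-site substitution probability in [0, 1].
#' @param alphabet \code{"nt"}, \code{"aa"}, or an explicit character
#'   vector of symbols (>= 2).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, d, alphabet = "nt") {
  if (d < 0 || d > 1) stop_arg("d must be in [0, 1]")
  if (identical(alphabet, "nt")) alphabet <- .NT
  else if (identical(alphabet, "aa")) alphabet <- .AA
  if (length(alphabet) < 2L)
    stop_arg("alphabet must have at least 2 symbols")
  if (d == 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- runif(length(chars)) < d
  if (any(hit)) {
    k <- length(alphabet)
    # index shift by 1..k-1 guarantees a different symbol
    cur <- match(chars[hit], alphabet)
    shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
    chars[hit] <- alphabet[((cur - 1L + shift) %% k) + 1L]
  }
  paste(chars, collapse = "")
}

.rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.back_translate <- function(protein) {
  paste(.CODON[strsplit(protein, "")[[1L]]], collapse = "")
}

#' Generate a complete synthetic dataset
#'
#' Produces, under \code{out_dir}: a genome metadata TSV, a Roary-style
#' gene presence/absence CSV, one GenBank file per planted cluster
#' occurrence (the analogue of one region file per antiSMASH region),
#' a locus-tag coordinate sidecar TSV, and a ground-truth JSON. The
#' generator is fully deterministic given \code{params$seed}.
#'
#' Cluster genes are planted as colocated CDS runs; their gene families
#' enter the presence/absence matrix exactly in the genomes carrying
#' the cluster, so a cluster's gene-family prevalence equals the
#' cluster's prevalence by construction. Decoy clusters (prevalence
#' below the conservation threshold) exercise false-positive behavior.
#'
#' @param params A \code{\link{sim_params}}.
#' @param out_dir Output directory (created if needed).
#' @return A list: \code{dir}, \code{files} (named paths),
#'   \code{matrix} (the internal \code{\link{pa_matrix}}),
#'   \code{metadata}, \code{region_files}, and \code{truth}.
#' @export
simulate_dataset <- function(params, out_dir) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  regions_dir <- file.path(out_dir, "regions")
  dir.create(regions_dir, showWarnings = FALSE)
  set.seed(params$seed)

  genera <- sprintf("Genus%02d", seq_len(params$n_genera))
  genomes <- lapply(genera, function(ge)
    sprintf("%s_g%02d", ge, seq_len(params$genomes_per_genus)))
  names(genomes) <- genera
  all_genomes <- unlist(genomes, use.names = FALSE)

  # validate cluster specs against the genus set
  for (cs in params$planted_clusters) {
    tg <- cs$genera %||% genera
    bad <- setdiff(tg, genera)
    if (length(bad))
      stop_arg("cluster ", cs$label, " targets unknown genus: ", bad[1L])
    if (length(tg) == 0L && any(cs$prevalence > 0))
      stop_arg("cluster ", cs$label, " has prevalence > 0 but no genera")
  }

  fam_core <- sprintf("core%04d", seq_len(params$n_core))
  fam_shell <- sprintf("shell%04d", seq_len(params$n_shell))
  fam_cloud <- sprintf("cloud%04d", seq_len(params$n_cloud))
  cluster_fams <- lapply(params$planted_clusters, function(cs)
    sprintf("%s_gene%d", cs$label, seq_len(cs$n_genes)))
  names(cluster_fams) <- vapply(params$planted_clusters, `[[`, "", "label")
  fam_all <- c(fam_core, fam_shell, fam_cloud,
               unlist(cluster_fams, use.names = FALSE))

  # ancestral proteins for cluster genes (background families carry no
  # emitted sequence: only region genes appear in GenBank output)
  lens <- params$protein_length_range
  root_prot <- lapply(cluster_fams, function(fams)
    setNames(vapply(fams, function(f)
      .rand_seq(sample(seq(lens[1L], lens[2L]), 1L), .AA), ""), fams))

  # per-genus ancestral sequences (two-level star phylogeny); HGT
  # clusters share one out-group root across genera
  genus_prot <- list()
  for (ci in seq_along(params$planted_clusters)) {
    cs <- params$planted_clusters[[ci]]
    for (ge in genera) {
      d <- if (cs$hgt) 0 else params$divergence_between_genera
      genus_prot[[cs$label]][[ge]] <-
        vapply(root_prot[[cs$label]], mutate_sequence, "", d = d,
               alphabet = "aa")
    }
  }

  # presence sampling
  pres <- matrix(FALSE, nrow = length(fam_all), ncol = length(all_genomes),
                 dimnames = list(fam_all, all_genomes))
  pres[fam_core, ] <- TRUE
  for (g in all_genomes) {
    pres[fam_shell, g] <- runif(params$n_shell) < params$shell_presence_prob
    pres[fam_cloud, g] <- runif(params$n_cloud) < params$cloud_presence_prob
  }
  planted <- list()
  for (cs in params$planted_clusters) {
    tg <- cs$genera %||% genera
    prev <- cs$prevalence
    if (is.null(names(prev))) prev <- setNames(rep(prev[1L], length(tg)), tg)
    carriers <- list()
    for (ge in tg) {
      k <- round(prev[[ge]] * length(genomes[[ge]]))
      chosen <- if (k > 0L) lex_sort(sample(genomes[[ge]], k)) else character()
      carriers[[ge]] <- chosen
      pres[cluster_fams[[cs$label]], chosen] <- TRUE
    }
    planted[[cs$label]] <- list(genera = tg, genomes = carriers,
                                families = cluster_fams[[cs$label]])
  }

  # locus tags: per genome, present families in fixed family order
  cells <- matrix(rep(list(character()),
                      length(fam_all) * length(all_genomes)),
                  nrow = length(fam_all),
                  dimnames = list(fam_all, all_genomes))
  tag_of <- list()
  for (g in all_genomes) {
    fams_here <- fam_all[pres[, g]]
    tags <- sprintf("%s_%05d", g, seq_along(fams_here))
    tag_of[[g]] <- setNames(tags, fams_here)
    for (i in seq_along(fams_here)) cells[[fams_here[i], g]] <- tags[i]
  }

  # drop families absent everywhere (an external pan-genome tool would
  # never report them)
  keep <- rowSums(pres) > 0L
  cells <- cells[keep, , drop = FALSE]
  m <- pa_matrix(cells)

  # emit region files: one GenBank per cluster occurrence
  region_files <- character()
  coords_rows <- list()
  spacer <- 50L
  for (g in all_genomes) {
    ge <- sub("_g[0-9]+$", "", g)
    labels_here <- names(planted)[vapply(planted, function(pl)
      g %in% unlist(pl$genomes, use.names = FALSE), NA)]
    ordinal <- 0L
    for (lab in labels_here) {
      ordinal <- ordinal + 1L
      fams <- cluster_fams[[lab]]
      prots <- vapply(genus_prot[[lab]][[ge]], mutate_sequence, "",
                      d = params$divergence_within_genus, alphabet = "aa")
      nts <- vapply(unname(prots), .back_translate, "")
      # region record: spacer + gene + spacer + gene ... + spacer
      seqs <- character(); cds <- list(); pos <- 1L
      for (k in seq_along(fams)) {
        sp <- .rand_seq(spacer, .NT)
        seqs <- c(seqs, sp, nts[k])
        gstart <- pos + spacer
        gend <- gstart + nchar(nts[k]) - 1L
        cds[[k]] <- data.frame(
          locus_tag = tag_of[[g]][[fams[k]]], start = gstart, end = gend,
          strand = "+", product = paste0("synthetic ", lab, " protein"),
          translation = unname(prots[k]), stringsAsFactors = FALSE)
        pos <- gend + 1L
      }
      seqs <- c(seqs, .rand_seq(spacer, .NT))
      region_seq <- paste(seqs, collapse = "")
      rid <- sprintf("%s_region%03d", g, ordinal)
      reg <- bgc_region(region_id = rid, genome_id = g, contig_id = rid,
                        start = 1L, end = nchar(region_seq),
                        product_classes = "synthetic",
                        cds = do.call(rbind, cds), seq = region_seq)
      f <- file.path(regions_dir, paste0(rid, ".gbk"))
      write_region_genbank(reg, f)
      region_files <- c(region_files, f)
      coords_rows[[length(coords_rows) + 1L]] <- data.frame(
        genome_id = g, locus_tag = reg$cds$locus_tag, contig_id = rid,
        start = reg$cds$start, end = reg$cds$end, stringsAsFactors = FALSE)
    }
  }

  metadata <- genome_metadata(all_genomes,
                              sub("_g[0-9]+$", "", all_genomes))
  md_path <- file.path(out_dir, "metadata.tsv")
  write_metadata_tsv(metadata, md_path)
  csv_path <- file.path(out_dir, "gene_presence_absence.csv")
  write_roary_csv(m, csv_path)
  coords_path <- file.path(out_dir, "gene_coords.tsv")
  coords <- if (length(coords_rows)) do.call(rbind, coords_rows)
            else data.frame(genome_id = character(), locus_tag = character(),
                            contig_id = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  write_report(coords, coords_path, "tsv")

  # ground truth, derivable from the construction alone
  fam_bin <- c(setNames(rep("core", length(fam_core)), fam_core),
               setNames(rep("shell", length(fam_shell)), fam_shell),
               setNames(rep("cloud", length(fam_cloud)), fam_cloud),
               setNames(rep("cluster",
                            length(unlist(cluster_fams, use.names = FALSE))),
                        unlist(cluster_fams, use.names = FALSE)))
  expected_conserved <- lapply(setNames(genera, genera), function(ge) {
    labs <- character()
    for (cs in params$planted_clusters) {
      pl <- planted[[cs$label]]
      if (!ge %in% pl$genera) next
      frac <- length(pl$genomes[[ge]]) / length(genomes[[ge]])
      if (frac >= 0.5 && cs$n_genes >= 2L) labs <- c(labs, cs$label)
    }
    labs
  })
  truth <- structure(list(family_bin = fam_bin, planted = planted,
                          expected_conserved = expected_conserved,
                          genera = genera, genomes = genomes,
                          seed = params$seed), class = "sim_truth")
  truth_path <- file.path(out_dir, "truth.json")
  con <- file(truth_path, open = "wb")
  writeLines(jsonlite::toJSON(unclass(truth), auto_unbox = FALSE,
                              pretty = TRUE), con)
  close(con)

  list(dir = out_dir,
       files = list(metadata = md_path, matrix = csv_path,
                    regions_dir = regions_dir, coords = coords_path,
                    truth = truth_path),
       matrix = m, metadata = metadata, region_files = region_files,
       truth = truth)
}

#' Precision/recall of conservation calls against planted truth
#'
#' Matches each predicted conserved BGC family to a planted cluster via
#' its defining gene families, and scores genus-level (and, when a
#' phylum aggregation is supplied, phylum-level) precision and recall
#' of the conservation calls against the clusters expected to be
#' conserved by construction.
#'
#' @param result A pipeline result from \code{\link{run_conservation}}
#'   (optionally with a \code{phylum} element from
#'   \code{\link{aggregate_phylum}}).
#' @param truth A \code{sim_truth} from \code{\link{simulate_dataset}}.
#' @param min_genera Threshold used for the expected phylum-level label
#'   set (default 2 at simulation scale).
#' @return A list with elements \code{genus} and (when applicable)
#'   \code{phylum}, each \code{c(precision=, recall=)}. Precision is 1
#'   when there are no predictions.
#' @export
truth_eval <- function(result, truth, min_genera = 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  label_of_family <- function(defining) {
    hits <- names(truth$planted)[vapply(truth$planted, function(pl)
      length(intersect(pl$families, defining)) > 0L, NA)]
    if (length(hits) == 1L) hits else NA_character_
  }
  bad_genus <- setdiff(names(result$per_genus), truth$genera)
  if (length(bad_genus))
    stop_arg("calls reference genera absent from the truth: ", bad_genus[1L])

  tp <- 0L; fp <- 0L
  recovered <- list()
  for (ge in names(result$per_genus)) {
    gr <- result$per_genus[[ge]]
    conserved_ids <- gr$calls$family_id[gr$calls$is_conserved]
    for (fid in conserved_ids) {
      lab <- label_of_family(gr$families[[fid]]$defining_families)
      if (!is.na(lab) && lab %in% truth$expected_conserved[[ge]]) {
        tp <- tp + 1L
        recovered[[ge]] <- unique(c(recovered[[ge]], lab))
      } else fp <- fp + 1L
    }
  }
  n_expected <- sum(lengths(truth$expected_conserved))
  n_recovered <- sum(lengths(recovered[truth$genera]))
  genus_pr <- c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
                recall = if (n_expected == 0L) 1 else n_recovered / n_expected)

  out <- list(genus = genus_pr)
  if (!is.null(result$phylum)) {
    exp_counts <- table(unlist(truth$expected_conserved, use.names = FALSE))
    expected_phylum <- names(exp_counts)[exp_counts >= min_genera]
    fam_lookup <- list()
    for (ge in names(result$per_genus))
      fam_lookup <- c(fam_lookup, result$per_genus[[ge]]$families)
    ptp <- 0L; pfp <- 0L; precovered <- character()
    calls <- result$phylum$calls
    groups <- result$phylum$groups
    for (i in seq_len(nrow(calls))) {
      if (!calls$is_phylum_conserved[i]) next
      gr <- groups[[calls$group_id[i]]]
      defs <- unique(unlist(lapply(fam_lookup[gr$members$family_id],
                                   `[[`, "defining_families")))
      lab <- label_of_family(defs)
      if (!is.na(lab) && lab %in% expected_phylum) {
        ptp <- ptp + 1L
        precovered <- unique(c(precovered, lab))
      } else pfp <- pfp + 1L
    }
    out$phylum <- c(
      precision = if (ptp + pfp == 0L) 1 else ptp / (ptp + pfp),
      recall = if (length(expected_phylum) == 0L) 1
               else length(precovered) / length(expected_phylum))
  }
  out
}
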