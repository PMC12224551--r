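map_matrix <- function() {
  cells <- make_cells(c("f1", "f2", "f3"), c("g1", "g2"),
                      "f1|g1" = "A", "f2|g1" = "B", "f3|g2" = "Z")
  pa_matrix(cells)
}

test_that("families map into regions by locus tag, with unmapped tags reported", {
  reg <- make_region("g1_r1", "g1", c("MKL", "MAA", "MWW"),
                     tags = c("A", "B", "C"))
  ct <- map_families_to_regions(map_matrix(), list(reg))[[1]]
  expect_setequal(ct$families_all, c("f1", "f2"))
  expect_equal(ct$unmapped_tags, "C")

  # disjoint tag universe, fallback off: everything unmapped
  reg2 <- make_region("g1_r2", "g1", c("MKL", "MAA"),
                      tags = c("X1", "X2"))
  ct2 <- suppressMessages(
    map_families_to_regions(map_matrix(), list(reg2)))[[1]]
  expect_equal(length(ct2$families_all), 0L)
  expect_setequal(ct2$unmapped_tags, c("X1", "X2"))

  expect_error(map_families_to_regions(map_matrix(),
                                       list(make_region("r", "gZ", "MKL"))),
               class = "panbgc_argument_error")
})

test_that("coordinate fallback recovers families and matches an interval-overlap oracle", {
  reg <- make_region("g1_r3", "g1", c("MKL", "MAA"), tags = c("Y1", "Y2"),
                     gene_len = 300L, spacer = 50L)
  # sidecar places matrix tags A and B at (near-)identical coordinates
  coords <- data.frame(genome_id = "g1",
                       locus_tag = c("A", "B"),
                       contig_id = "g1_r3",
                       start = reg$cds$start + c(0L, 30L),
                       end = reg$cds$end + c(0L, 30L),
                       stringsAsFactors = FALSE)
  ct <- map_families_to_regions(map_matrix(), list(reg), coords = coords)[[1]]
  expect_setequal(ct$families_all, c("f1", "f2"))
  expect_equal(length(ct$unmapped_tags), 0L)

  # brute-force oracle over all CDS x sidecar pairs
  for (k in seq_len(nrow(reg$cds))) {
    s1 <- reg$cds$start[k]; e1 <- reg$cds$end[k]
    ok <- vapply(seq_len(nrow(coords)), function(i) {
      ov <- min(e1, coords$end[i]) - max(s1, coords$start[i]) + 1
      ov >= 0.5 * (e1 - s1 + 1) &&
        ov >= 0.5 * (coords$end[i] - coords$start[i] + 1)
    }, NA)
    expect_true(any(ok))  # every CDS has a qualifying partner here
  }

  # an overlap below the reciprocal threshold does not map (shift of 160
  # leaves every CDS/tag pair under 50% overlap, including neighbors)
  coords_far <- transform(coords, start = start + 160L, end = end + 160L)
  ct_far <- suppressMessages(map_families_to_regions(
    map_matrix(), list(reg), coords = coords_far))[[1]]
  expect_equal(length(ct_far$families_all), 0L)
})

make_content <- function(region_id, genome_id, fams) {
  structure(list(region_id = region_id, genome_id = genome_id,
                 families_all = fams, families_conserved = fams,
                 unmapped_tags = character(),
                 tag_family = setNames(fams, fams)),
            class = "region_family_content")
}

test_that("region grouping follows the shared-conserved-family graph", {
  cons <- c("f1", "f2", "f3")
  # two regions sharing two conserved families form one family
  fams <- build_bgc_families(list(make_content("r1", "g1", c("f1", "f2")),
                                  make_content("r2", "g2", c("f1", "f2"))),
                             cons, genus = "Alpha")
  expect_equal(length(fams), 1L)
  expect_true(all(c("f1", "f2") %in% fams[[1]]$defining_families))
  expect_equal(fams[[1]]$n_genomes_with, 2L)

  # sharing a single family is below min_shared; regions with only one
  # conserved family in total form no family at all
  fams2 <- build_bgc_families(list(make_content("r1", "g1", "f1"),
                                   make_content("r2", "g2", "f1")),
                              cons, genus = "Alpha")
  expect_equal(length(fams2), 0L)

  # chain r1-r2 (f1,f2), r2-r3 (f2,f3): one component of three regions
  chain <- list(make_content("r1", "g1", c("f1", "f2")),
                make_content("r2", "g2", c("f1", "f2", "f3")),
                make_content("r3", "g3", c("f2", "f3")))
  fams3 <- build_bgc_families(chain, cons, genus = "Alpha")
  expect_equal(length(fams3), 1L)
  expect_equal(sort(unlist(fams3[[1]]$member_regions, use.names = FALSE)),
               c("r1", "r2", "r3"))

  # random instances against a BFS components oracle
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    pool <- sprintf("f%d", 1:6)
    sets <- lapply(1:n, function(i) sort(sample(pool, sample(0:4, 1))))
    names(sets) <- sprintf("r%02d", 1:n)
    contents <- lapply(names(sets), function(r)
      make_content(r, paste0("g_", r), sets[[r]]))
    got <- build_bgc_families(contents, pool, genus = "X", min_shared = 2L)
    eligible <- names(sets)[lengths(sets) >= 2]
    want <- oracle_components(eligible, function(v, w)
      v != w && length(intersect(sets[[v]], sets[[w]])) >= 2)
    got_parts <- lapply(got, function(f)
      sort(unlist(f$member_regions, use.names = FALSE)))
    want_parts <- unname(lapply(split(names(want), want), sort))
    expect_setequal(got_parts, want_parts)
  }
})

test_that("the genus conservation call applies both >= rules", {
  fam <- function(n_genomes, n_fams) {
    structure(list(family_id = "x", genus = "Alpha",
                   member_regions = setNames(
                     as.list(sprintf("r%d", seq_len(n_genomes))),
                     sprintf("g%d", seq_len(n_genomes))),
                   defining_families = sprintf("f%d", seq_len(n_fams)),
                   n_genomes_with = n_genomes,
                   region_conserved_n = setNames(rep(n_fams, n_genomes),
                                                 sprintf("r%d", seq_len(n_genomes)))),
              class = "bgc_family")
  }
  calls <- call_genus_conservation(list(fam(2, 2), fam(1, 5), fam(3, 1)), 4)
  expect_equal(calls$is_conserved, c(TRUE, FALSE, FALSE))

  # monotonicity: adding a genome or a defining family never turns a
  # conserved call unconserved
  base <- call_genus_conservation(list(fam(2, 2)), 4)$is_conserved
  expect_true(base)
  expect_true(call_genus_conservation(list(fam(3, 2)), 4)$is_conserved)
  expect_true(call_genus_conservation(list(fam(2, 3)), 4)$is_conserved)

  # 5 of 11 genomes does not reach the exact-fraction threshold
  expect_false(call_genus_conservation(list(fam(5, 2)), 11)$is_conserved)
})

test_that("cross-genus linkage groups representative regions by mutual-best content", {
  tr <- c("MKLVTTACDEFG", "MWWYYHACDEFG", "MHHHHHCCCCCC")
  mk_family <- function(genus, region_id) {
    structure(list(family_id = paste0(genus, "_bgcfam001"), genus = genus,
                   member_regions = setNames(list(region_id),
                                             paste0(genus, "_g1")),
                   defining_families = c("f1", "f2"),
                   n_genomes_with = 1L,
                   region_conserved_n = setNames(2L, region_id)),
              class = "bgc_family")
  }
  regions <- list(
    rA = make_region("rA", "GenA_g1", tr),
    rB = make_region("rB", "GenB_g1", tr),
    rC = make_region("rC", "GenC_g1", vapply(rep(20, 3), rand_protein, "")))
  fams <- list(mk_family("GenA", "rA"), mk_family("GenB", "rB"),
               mk_family("GenC", "rC"))
  groups <- link_across_genera(fams, regions)
  expect_equal(length(groups), 2L)
  sizes <- sort(unname(vapply(groups, function(g)
    length(g$genera_present), 0L)))
  expect_equal(sizes, c(1L, 2L))

  # chain linkage: A~B and B~C link all three genera into one group
  trA <- vapply(rep(30, 4), rand_protein, "")
  trB <- c(vapply(unname(trA[1:2]), function(s)
    mutate_sequence(s, 0.1, "aa"), ""), rand_protein(30), rand_protein(30))
  trC <- c(rand_protein(30), rand_protein(30),
           vapply(unname(trB[3:4]), function(s)
             mutate_sequence(s, 0.1, "aa"), ""))
  regions2 <- list(rA = make_region("rA", "GenA_g1", unname(trA)),
                   rB = make_region("rB", "GenB_g1", trB),
                   rC = make_region("rC", "GenC_g1", trC))
  fams2 <- list(mk_family("GenA", "rA"), mk_family("GenB", "rB"),
                mk_family("GenC", "rC"))
  groups2 <- link_across_genera(fams2, regions2)
  expect_equal(length(groups2), 1L)
  expect_setequal(groups2[[1]]$genera_present, c("GenA", "GenB", "GenC"))

  # brute-force component check on the same instance
  linked <- function(v, w) {
    if (v == w) return(FALSE)
    mm <- best_bidirectional_hits(regions2[[v]], regions2[[w]], 0.4, 0.6)
    nrow(mm) >= 2
  }
  want <- oracle_components(c("rA", "rB", "rC"), linked)
  expect_equal(length(unique(want)), 1L)
})

test_that("phylum conservation counts genera with >= and replays the genus table", {
  groups <- phylum_groups_from_fixture(load_fixture("table2"))
  calls <- call_phylum_conservation(groups, 11, 7)
  expect_equal(sum(calls$is_phylum_conserved), 5L)
  expect_equal(sum(call_phylum_conservation(groups, 11, 11)$is_phylum_conserved),
               0L)

  single <- groups[1]
  single[[1]]$members <- single[[1]]$members[1, , drop = FALSE]
  expect_true(call_phylum_conservation(single, 1, 1)$is_phylum_conserved)
})

test_that("screening requires colocated mutual-best matches in one region", {
  set.seed(123)
  ref <- vapply(rep(25, 3), rand_protein, "")
  prof <- bgc_profile("clusterX",
                      data.frame(gene_label = sprintf("ref%d", 1:3),
                                 translation = ref, stringsAsFactors = FALSE))
  other <- bgc_profile("clusterY",
                       data.frame(gene_label = c("o1", "o2"),
                                  translation = vapply(rep(25, 2),
                                                       rand_protein, ""),
                                  stringsAsFactors = FALSE))

  # genome with no regions: all absent
  r0 <- screen_genome(list(prof, other), list(), genome_id = "empty")
  expect_equal(unname(r0$calls), c("absent", "absent"))
  expect_equal(r0$per_genome_total, 0L)

  # one region carrying exact copies of two reference genes: present
  hit_region <- make_region("q_r1", "q", c(ref[1], ref[2], rand_protein(25)))
  r1 <- screen_genome(list(prof, other), list(hit_region), genome_id = "q")
  expect_equal(unname(r1$calls), c("present", "absent"))
  expect_equal(r1$per_genome_total, 1L)
  expect_equal(nrow(r1$evidence$clusterX), 2L)

  # the same two matches split across two regions: absent
  split_regions <- list(make_region("q_r2", "q", c(ref[1], rand_protein(25))),
                        make_region("q_r3", "q", c(ref[2], rand_protein(25))))
  r2 <- screen_genome(list(prof, other), split_regions, genome_id = "q")
  expect_equal(unname(r2$calls), c("absent", "absent"))
})

test_that("screen tables recompute totals from the grid", {
  fix <- load_fixture("table3")
  results <- screen_results_from_fixture(fix)
  tab <- screen_table(results, label_col = "strain")
  expect_equal(nrow(tab), 12L)

  grid <- as.matrix(tab[1:11, fix$col_labels])
  col_tot <- colSums(grid == "+")
  expect_equal(unname(unlist(tab[12, fix$col_labels])),
               sprintf("%d/11", col_tot))
  row_tot <- rowSums(grid == "+")
  expect_equal(tab$total[1:11], sprintf("%d/5", row_tot))

  # inconsistent profile sets are rejected
  bad <- results
  bad[[2]]$calls <- bad[[2]]$calls[c(2, 1, 3, 4, 5)]
  expect_error(screen_table(bad), class = "panbgc_argument_error")
})
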