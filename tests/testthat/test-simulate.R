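tiny_params <- function(seed = 42, ...) {
  sim_params(seed = seed, n_genera = 2, genomes_per_genus = 4,
             n_core = 15, n_shell = 20, n_cloud = 20, ...)
}

test_that("per-site mutation hits the binomial expectation and its edge cases", {
  set.seed(1)
  s <- rand_dna(500)
  expect_identical(mutate_sequence(s, 0), s)

  m1 <- mutate_sequence(s, 1, "nt")
  expect_equal(nchar(m1), nchar(s))
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))

  long <- rand_dna(10000)
  mut <- mutate_sequence(long, 0.05, "nt")
  frac <- mean(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)

  expect_error(mutate_sequence(s, 1.5), class = "panbgc_argument_error")
  expect_error(mutate_sequence(s, 0.5, alphabet = "A"),
               class = "panbgc_argument_error")
})

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(tiny_params(), d1)
  simulate_dataset(tiny_params(), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 3L)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
})

test_that("emitted files re-read into exactly the internal state", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(tiny_params(seed = 7), d)
  m <- read_roary_csv(sim$files$matrix)
  expect_identical(family_ids(m), family_ids(sim$matrix))
  expect_identical(genome_ids(m), genome_ids(sim$matrix))
  expect_identical(m$cells, sim$matrix$cells)

  md <- read_metadata_tsv(sim$files$metadata)
  expect_equal(md$genome_id, sim$metadata$genome_id)
  expect_equal(md$genus, sim$metadata$genus)

  regs <- read_regions_dir(sim$files$regions_dir)
  expect_equal(length(regs), length(sim$region_files))
  # locus tags inside region files are the matrix's tags for that genome
  r1 <- regs[[1]]
  lk <- unlist(m$cells[, r1$genome_id], use.names = FALSE)
  expect_true(all(r1$cds$locus_tag %in% lk))
})

test_that("realized shell prevalence tracks its probability on a large genus", {
  d <- withr::local_tempdir()
  p <- sim_params(seed = 3, n_genera = 1, genomes_per_genus = 60,
                  n_core = 10, n_shell = 150, n_cloud = 10,
                  shell_presence_prob = 0.5,
                  planted_clusters = list(cluster_spec("c1", prevalence = 1)))
  sim <- simulate_dataset(p, d)
  counts <- presence_counts(sim$matrix)
  shell <- counts[grep("^shell", names(counts))]
  n <- 60; prob <- 0.5
  sd3 <- 3 * sqrt(prob * (1 - prob) / n)
  within <- abs(shell / n - prob) <= sd3
  expect_gt(mean(within), 0.98)
})

test_that("noiseless planted clusters are recovered perfectly; decoys are not called", {
  d <- withr::local_tempdir()
  p <- sim_params(seed = 11, n_genera = 2, genomes_per_genus = 4,
                  n_core = 15, n_shell = 20, n_cloud = 20,
                  divergence_within_genus = 0,
                  divergence_between_genera = 0)
  sim <- simulate_dataset(p, d)
  m <- read_roary_csv(sim$files$matrix)
  md <- read_metadata_tsv(sim$files$metadata)
  regs <- read_regions_dir(sim$files$regions_dir)
  res <- aggregate_phylum(run_conservation(m, md, regs), regs,
                          min_genera = 2)
  pr <- truth_eval(res, sim$truth, min_genera = 2)
  expect_equal(unname(pr$genus), c(1, 1))
  expect_equal(unname(pr$phylum), c(1, 1))
  # decoys (prevalence 0.25 of 4 genomes) are never among conserved calls
  expect_equal(sum(res$calls$is_conserved), 4L)  # 2 clusters x 2 genera

  # with zero divergence every family present everywhere is core
  prev <- compute_prevalence(m, md, "Genus01")
  core_only <- prev$prevalence[grep("^core", names(prev$prevalence))]
  expect_true(all(core_only == 1))
})

test_that("prevalence at and below the genome-fraction threshold flips the call", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  base <- list(n_genera = 1, genomes_per_genus = 4, n_core = 10,
               n_shell = 10, n_cloud = 10, divergence_within_genus = 0,
               divergence_between_genera = 0)
  p_hi <- do.call(sim_params, c(base, list(
    seed = 5, planted_clusters = list(cluster_spec("full", prevalence = 1)))))
  sim_hi <- simulate_dataset(p_hi, d1)
  res_hi <- run_conservation(read_roary_csv(sim_hi$files$matrix),
                             read_metadata_tsv(sim_hi$files$metadata),
                             read_regions_dir(sim_hi$files$regions_dir))
  expect_equal(sum(res_hi$calls$is_conserved), 1L)

  p_lo <- do.call(sim_params, c(base, list(
    seed = 5, planted_clusters = list(cluster_spec("rare", prevalence = 0.25)))))
  sim_lo <- simulate_dataset(p_lo, d2)
  res_lo <- run_conservation(read_roary_csv(sim_lo$files$matrix),
                             read_metadata_tsv(sim_lo$files$metadata),
                             read_regions_dir(sim_lo$files$regions_dir))
  expect_equal(sum(res_lo$calls$is_conserved), 0L)
  expect_equal(length(sim_lo$truth$expected_conserved$Genus01), 0L)
})

test_that("truth_eval reports zero recall when thresholds exclude all planted clusters", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(tiny_params(seed = 19), d)
  m <- read_roary_csv(sim$files$matrix)
  md <- read_metadata_tsv(sim$files$metadata)
  regs <- read_regions_dir(sim$files$regions_dir)
  res <- run_conservation(m, md, regs, min_conserved_genes = 10L)
  pr <- truth_eval(res, sim$truth)
  expect_equal(pr$genus[["recall"]], 0)
  expect_equal(pr$genus[["precision"]], 1)  # no predictions made
})

test_that("infeasible cluster specifications are rejected", {
  expect_error(cluster_spec("bad", n_genes = 1),
               class = "panbgc_argument_error")
  p <- tiny_params(planted_clusters = list(
    cluster_spec("c1", genera = "GenusXX", prevalence = 0.5)))
  expect_error(simulate_dataset(p, withr::local_tempdir()),
               class = "panbgc_argument_error")
})

test_that("an HGT cluster is more self-similar across genera than vertical clusters", {
  d <- withr::local_tempdir()
  p <- sim_params(seed = 23, n_genera = 2, genomes_per_genus = 2,
                  n_core = 5, n_shell = 5, n_cloud = 5,
                  divergence_within_genus = 0.01,
                  divergence_between_genera = 0.15,
                  planted_clusters = list(
                    cluster_spec("vert", prevalence = 1),
                    cluster_spec("hgt1", prevalence = 1, hgt = TRUE)))
  sim <- simulate_dataset(p, d)
  regs <- read_regions_dir(sim$files$regions_dir)
  pick <- function(lab, genus) {
    # first region of that cluster in that genus
    for (r in regs)
      if (startsWith(r$genome_id, genus) &&
          grepl(lab, r$cds$product[1])) return(r)
    NULL
  }
  id_between <- function(lab) {
    ra <- pick(lab, "Genus01"); rb <- pick(lab, "Genus02")
    mm <- best_bidirectional_hits(ra, rb, 0.1, 0.3)
    mean(mm$identity)
  }
  expect_gt(id_between("hgt1"), id_between("vert"))
})
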