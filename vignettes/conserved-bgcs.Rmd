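---
title: "Detecting conserved biosynthetic gene clusters from pan-genome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved biosynthetic gene clusters from pan-genome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panbgc)
options(panbgc.quiet = TRUE)
```

## The problem

Myxobacteria (phylum Myxococcota) are prolific producers of specialized
metabolites, and most of their biosynthetic gene clusters (BGCs) are
accessory: they sit outside the core pan-genome of any genus. Asking
which clusters the phylum actually *keeps* — maintained across most
genomes of most genera — therefore needs a procedure that is
deliberately BGC-agnostic. `panbgc` implements such a procedure as a
reusable pipeline:

1. **Conserved genes per genus.** From a gene presence/absence matrix
   (the shape of Roary's `gene_presence_absence.csv`), every gene
   family present in at least half of a genus' genomes is marked
   conserved. The comparison is `>=` on exact fractions: a family in
   exactly 2 of 4 genomes qualifies; one in 5 of 11 does not reach
   0.5.
2. **Mapping into clusters.** Conserved families are mapped into
   antiSMASH-style region files by locus tag (with an optional
   reciprocal-overlap coordinate fallback for annotation runs with
   disjoint tag universes).
3. **Genus-level calls.** Regions are grouped into BGC families by
   shared conserved gene content; a family present in at least half of
   the genus' genomes that carries at least two *distinct* conserved
   gene families is called conserved at the genus level.
4. **Phylum-level aggregation.** Genus-level conserved families are
   linked across genera through mutual-best protein hits between
   representative regions; a linked group spanning at least seven of
   eleven genera is called phylum-conserved. Both thresholds are
   parameters.
5. **Screening.** Genomes from genera too sparsely sequenced for
   pan-genome analysis are screened for each conserved cluster:
   a cluster is present when a *single* region carries at least two
   mutual-best matches to the cluster's reference genes — colocation
   is required, matches scattered over different regions do not count.

The package also ships the comparison machinery used to characterize
conserved clusters (mutual-best-hit gene matching, adjacency-based
synteny scores, fragment-based cluster ANI) and a ground-truthed
synthetic data generator, so the whole pipeline is testable end to end
without external tools or downloads.

## Thresholds and what they mean

| Parameter | Default | Meaning |
|---|---|---|
| `min_prevalence` | 0.5 | fraction of genus genomes a gene family needs to be conserved |
| `min_genome_frac` | 0.5 | fraction of genus genomes a BGC family needs |
| `min_conserved_genes` | 2 | distinct conserved families a BGC family must carry |
| `min_genera` | 7 | genera (of 11) a group needs to be phylum-conserved |
| `min_shared` | 2 | conserved families two regions must share to be grouped |
| `min_identity` / `min_coverage` | 0.4 / 0.6 | protein-match acceptance for linkage and screening |
| `fragment_length` | 1020 bp | ANI fragment size (the OrthoANI convention) |

Two interpretation choices deserve comment. First, "at least two
conserved genes" counts distinct conserved gene *families*, not gene
copies: paralogous copies of one family carry no additional evidence of
conservation. Second, thresholds compare exact fractions with `>=`
rather than rounded percentages, which pins down the boundary cases
(2/4 qualifies, 5/11 does not).

## The grouping procedures are explicit stand-ins

How to decide that two regions in different genomes are "the same
cluster" is genuinely open: published analyses typically combine
database similarity scores with manual inspection. `panbgc` makes the
rule explicit and parameterized in both places it is needed:

* within a genus, regions are nodes of a graph with an edge when they
  share at least `min_shared = 2` conserved families; BGC families are
  the connected components (single linkage);
* across genera, one representative region per genus family (the
  member with the most conserved families mapped; ties broken by
  lexicographic genome id) is compared by mutual-best protein hits,
  and groups are again connected components.

Single linkage was chosen because cluster boundaries drawn by
annotation tools wobble: two halves of one biological cluster can
appear as separate regions, and transitive linkage tolerates that.
The price is potential chaining through promiscuous families; the
`min_shared` parameter is the lever against it. Hybrid regions are
kept whole by default — a flag to split a region's mapped families by
product class before grouping was considered and left out of the
default path, because splitting creates artificial family pairs that
never co-occur as annotated.

## Alignment and comparison conventions

All pairwise alignment is global (end gaps charged) under a flat
scoring scheme: match +1, mismatch −1, gap open 2, gap extend 1, so a
gap of length L costs 2 + L. Identity is identical columns divided by
*all* alignment columns; coverage is the aligned (non-gap-vs-gap)
columns of the shorter sequence divided by its length. Identity is
made exactly symmetric by aligning sequence pairs in a canonical
orientation. No substitution matrix is used — at cluster scale and the
identity ranges that matter here (40–100%), a flat scheme ranks
partners the same way, and a hook for substitution matrices remains
open in `alignment_params()`.

The synteny score projects matched genes onto their positional order
in each region and reports the fraction of adjacent matched pairs in
one region that are adjacent (in either direction) in the other. It is
orientation-insensitive on purpose: a fully inverted but colinear
cluster scores 1, matching the field's reading of inverted clusters as
organizationally conserved.

Fragment ANI chops both sequences into consecutive 1020 bp fragments,
drops the trailing remainder, aligns all fragments of one sequence
against all of the other, keeps reciprocal best pairs at >=30%
identity and >=70% coverage, and averages the kept identities. With no
qualifying pair the result is undefined (`NA`), not 0 — an undefined
ANI and a measured low ANI are different findings. Expected behavior
is easy to state analytically: under independent per-site substitution
at rate *d* with no indels, the optimal alignment is gap-free and ANI
concentrates at 100(1 − *d*); the test suite checks 95 ± 1 at
*d* = 0.05 on 50 kb.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a two-level star phylogeny: one ancestral
sequence per planted gene, a per-genus copy mutated at
`divergence_between_genera`, and a per-genome copy mutated at
`divergence_within_genus`. Gene content follows an open pan-genome:
core families are universal, shell families are present per genome
with probability 0.5, cloud families with probability 0.1. Planted
clusters are colocated CDS runs emitted as one GenBank region file per
occurrence — mirroring the one-region-per-file layout of antiSMASH
output — plus decoy clusters below the conservation threshold so
false-positive behavior is exercised. An `hgt = TRUE` cluster draws
its root independently and skips between-genus divergence, emulating
a recently transferred cluster that is more self-similar across genera
than vertically inherited ones.

Defaults describe the standard recovery conditions used throughout the
tests: 3 genera × 8 genomes, 200 core / 300 shell / 300 cloud
families, two conserved clusters per genus at prevalence 0.75 with
four genes each, three decoys at prevalence 0.25, and 2% within-genus
divergence. Sample-size choices keep a full end-to-end run under a
minute on one core while leaving every rule with genuine headroom to
fail (prevalence 0.75 is comfortably above 0.5; decoys at 0.25 are
comfortably below).

The simulator deliberately omits: gene gain/loss along a real
phylogeny, recombination, indels, assembly artifacts, paralog
expansion beyond single-copy families, and genuine intergenic
structure. Passing recovery tests therefore show the *rules* are
implemented correctly and are recoverable under controlled noise —
they do not show robustness to annotation noise or fragmented
assemblies in real data.

Because background (core/shell/cloud) families never appear in any
emitted region file, the generator materializes mutated sequences only
for genes that reach an output file; background families exist as
locus tags in the matrix alone.

## Numerical and determinism choices

* All tie-breaks are lexicographic (radix order, locale-independent):
  best-hit partners, representative regions, family and group ids.
* Family ids are assigned in a canonical order (components sorted by
  smallest member region id), so identical inputs give byte-identical
  reports; the generator is byte-identical under a fixed seed.
* Empty inputs are legal where the science allows: a genome with no
  regions screens as all-absent; an empty match list scores synteny 0;
  a single-gene pair scores 1 only when both regions are single-gene.
* Report totals (the "total" row/column of screen tables) are always
  recomputed from the +/− grid, never copied from input.

## Known limitations

* The greedy protein clusterer is a convenience for synthetic
  end-to-end runs, not a replacement for a real pan-genome tool; its
  centroid rule is order-dependent by design (canonical length-then-tag
  order makes it deterministic) and it makes no attempt at paralog
  splitting.
* The GenBank reader covers the subset of the format that antiSMASH
  region files and this package's writer use (simple and
  `complement()` locations, `region`/CDS features); it is not a
  general GenBank parser.
* Screening quality depends on the chosen reference genes; profiles
  built from a single representative region inherit that region's
  idiosyncrasies.

## A worked example

```{r example, eval = FALSE}
library(panbgc)

sim <- simulate_dataset(sim_params(seed = 101), "sim_out")
m    <- read_roary_csv(sim$files$matrix)
md   <- read_metadata_tsv(sim$files$metadata)
regs <- read_regions_dir(sim$files$regions_dir)

res <- run_conservation(m, md, regs)
res <- aggregate_phylum(res, regs, min_genera = 2)
truth_eval(res, sim$truth, min_genera = 2)
```

The same steps behind a shell interface:

```sh
panbgc simulate --seed 101 --out sim_out
panbgc genus-conserve --matrix sim_out/gene_presence_absence.csv \
  --metadata sim_out/metadata.tsv --regions-dir sim_out/regions --out calls
panbgc fixtures --table 3
```
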