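# In-code fixture builders.

make_cells <- function(fams, genomes, ...) {
  cells <- matrix(rep(list(character()), length(fams) * length(genomes)),
                  nrow = length(fams), dimnames = list(fams, genomes))
  entries <- list(...)  # named "fam|genome" = tags
  for (key in names(entries)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cells[[parts[1], parts[2]]] <- entries[[key]]
  }
  cells
}

make_region <- function(region_id, genome_id, translations,
                        tags = sprintf("%s_%02d", region_id,
                                       seq_along(translations)),
                        gene_len = 300L, spacer = 50L, seq = NULL,
                        product_classes = "test") {
  n <- length(translations)
  starts <- spacer + (seq_len(n) - 1L) * (gene_len + spacer) + 1L
  cds <- data.frame(locus_tag = tags, start = starts,
                    end = starts + gene_len - 1L, strand = "+",
                    product = "", translation = translations,
                    stringsAsFactors = FALSE)
  bgc_region(region_id = region_id, genome_id = genome_id,
             contig_id = region_id, start = 1L,
             end = max(cds$end) + spacer, product_classes = product_classes,
             cds = cds, seq = seq)
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

roary_csv_text <- function() {
  # f1 in g1 (paralogs) and g2; f2 in g1 only; f3 empty everywhere
  c(paste('"Gene","Non-unique Gene name","Annotation","No. isolates"',
          '"g1","g2"', sep = ","),
    '"f1","","hypothetical","2","tagA\ttagB","tagC"',
    '"f2","","thing","1","tagD",""',
    '"f3","","","0","",""')
}
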