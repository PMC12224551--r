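# Minimal GenBank flat-file reader/writer for antiSMASH-style BGC region
# files (one region per file, CDS features with locus_tag/translation).
# No installed R package parses local GenBank flat files, so the subset
# of the format these files use is handled here directly.

#' Construct a BGC region
#'
#' One annotated biosynthetic gene cluster region: a contiguous genomic
#' span plus the CDS features it contains, the shape emitted by
#' antiSMASH as one GenBank file per region.
#'
#' @param region_id Unique region identifier.
#' @param genome_id Genome the region belongs to.
#' @param contig_id Contig/record identifier.
#' @param start,end 1-based inclusive region boundaries (bp).
#' @param product_classes Character vector of product class labels
#'   (length > 1 for hybrid regions).
#' @param cds A data.frame with columns \code{locus_tag}, \code{start},
#'   \code{end}, \code{strand} ("+" or "-"), \code{product},
#'   \code{translation} and optionally \code{nt_seq}. Rows are sorted by
#'   \code{start}.
#' @param seq Optional nucleotide sequence of the whole region record.
#' @param known_cluster Optional list \code{(id, similarity)} carrying a
#'   pass-through database annotation.
#' @return An object of class \code{bgc_region}.
#' @export
bgc_region <- function(region_id, genome_id, contig_id, start, end,
                       product_classes = "unknown", cds, seq = NULL,
                       known_cluster = NULL) {
  if (start < 1L || end < start) stop_arg("invalid region span [", start, ", ", end, "]")
  if (length(product_classes) == 0L) stop_arg("product_classes must be non-empty")
  stopifnot(is.data.frame(cds))
  needed <- c("locus_tag", "start", "end", "strand", "product", "translation")
  missing_cols <- setdiff(needed, names(cds))
  if (length(missing_cols))
    stop_arg("cds missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"nt_seq" %in% names(cds)) cds$nt_seq <- NA_character_
  if (nrow(cds)) {
    if (any(cds$start < 1L | cds$end < cds$start))
      stop_arg("invalid CDS coordinates in region ", region_id)
    if (!all(cds$strand %in% c("+", "-")))
      stop_arg("CDS strand must be '+' or '-'")
    cds <- cds[lex_order(cds$start, cds$locus_tag), , drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(region_id = region_id, genome_id = genome_id,
                 contig_id = contig_id, start = as.integer(start),
                 end = as.integer(end),
                 product_classes = as.character(product_classes),
                 cds = cds, seq = seq, known_cluster = known_cluster),
            class = "bgc_region")
}

#' @export
print.bgc_region <- function(x, ...) {
  cat(sprintf("<bgc_region> %s [%s %s:%d-%d] %s, %d CDS\n", x$region_id,
              x$genome_id, x$contig_id, x$start, x$end,
              paste(x$product_classes, collapse = "/"), nrow(x$cds)))
  invisible(x)
}

.parse_location <- function(loc) {
  strand <- if (grepl("^complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (length(nums) < 2L) stop_format("unparseable feature location: ", loc)
  list(start = min(nums), end = max(nums), strand = strand)
}

#' Read an antiSMASH-style region GenBank file
#'
#' Parses one GenBank flat file containing a single BGC region. Region
#' boundaries are taken from the \code{region} feature when present,
#' else the full record span; product classes come from the region
#' feature's \code{/product} qualifiers (\code{"unknown"} when absent).
#' CDS features lacking a \code{/locus_tag} receive a synthetic tag
#' \code{<record_id>_cds<ordinal>} with a logged warning. Feature types
#' other than \code{region} and \code{CDS} are ignored.
#'
#' @param path Path to the GenBank file.
#' @param genome_id Genome identifier to attach; defaults to the file
#'   name stripped of its extension and of any trailing
#'   \code{_regionNNN} suffix.
#' @param region_id Region identifier; defaults to the file name without
#'   extension.
#' @return A \code{\link{bgc_region}}.
#' @export
read_region_genbank <- function(path, genome_id = NULL, region_id = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop_format("not a GenBank file (no LOCUS line): ", path)
  locus_fields <- strsplit(trimws(lines[locus_i[1L]]), "[ ]+")[[1L]]
  record_id <- locus_fields[2L]
  rec_len <- suppressWarnings(as.integer(locus_fields[3L]))

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (!length(feat_i)) stop_format("no FEATURES table in ", path)
  feat_end <- min(c(origin_i, end_i, length(lines) + 1L)) - 1L
  flines <- lines[(feat_i[1L] + 1L):feat_end]

  # split the feature table into (key, location+qualifier block) chunks
  is_new <- grepl("^ {5}\\S", flines)
  if (!any(is_new)) stop_format("no features in ", path)
  idx <- cumsum(is_new)
  feats <- split(flines[idx > 0], idx[idx > 0])

  region_span <- NULL
  product_classes <- character()
  cds_list <- list()
  ordinal <- 0L
  n_synth <- 0L
  for (chunk in feats) {
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
    loc <- sub("^ {5}\\S+\\s+", "", chunk[1L])
    qual_lines <- if (length(chunk) > 1L) trimws(chunk[-1L]) else character()
    # continuation lines of a multi-line location precede the first qualifier
    q_start <- which(startsWith(qual_lines, "/"))
    if (length(q_start) && q_start[1L] > 1L)
      loc <- paste0(loc, paste(qual_lines[seq_len(q_start[1L] - 1L)], collapse = ""))
    # fold continued qualifier values back onto their qualifier line
    quals <- character()
    for (ql in qual_lines[seq_along(qual_lines) >= (if (length(q_start)) q_start[1L] else Inf)]) {
      if (startsWith(ql, "/")) quals <- c(quals, ql)
      else if (length(quals)) quals[length(quals)] <- paste0(quals[length(quals)],
        if (grepl("^/translation=", quals[length(quals)])) "" else " ", ql)
    }
    qval <- function(name) {
      hits <- grep(paste0("^/", name, "="), quals, value = TRUE)
      v <- sub(paste0("^/", name, "="), "", hits)
      gsub('^"|"$', "", v)
    }
    if (key == "region") {
      region_span <- .parse_location(loc)
      pc <- qval("product")
      if (length(pc)) product_classes <- pc
    } else if (key == "CDS") {
      ordinal <- ordinal + 1L
      lc <- .parse_location(loc)
      tag <- qval("locus_tag")
      if (!length(tag) || !nzchar(tag[1L])) {
        tag <- sprintf("%s_cds%d", record_id, ordinal)
        n_synth <- n_synth + 1L
      }
      tr <- qval("translation")
      tr <- if (length(tr)) gsub("[ ]", "", tr[1L]) else ""
      pr <- qval("product")
      cds_list[[length(cds_list) + 1L]] <- data.frame(
        locus_tag = tag[1L], start = lc$start, end = lc$end,
        strand = lc$strand, product = if (length(pr)) pr[1L] else "",
        translation = tr, stringsAsFactors = FALSE)
    }
  }
  if (!length(cds_list)) stop_format("no CDS features in ", path)
  if (n_synth > 0L)
    pan_warn(n_synth, " CDS without locus_tag in ", basename(path),
             "; synthetic tags assigned")
  cds <- do.call(rbind, cds_list)

  seq <- NULL
  if (length(origin_i)) {
    stop_line <- if (length(end_i)) min(end_i[end_i > origin_i[1L]]) else length(lines) + 1L
    sl <- lines[(origin_i[1L] + 1L):(stop_line - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }

  span_start <- if (!is.null(region_span)) region_span$start else 1L
  span_end <- if (!is.null(region_span)) region_span$end
              else if (!is.na(rec_len)) rec_len
              else if (!is.null(seq)) nchar(seq)
              else max(cds$end)
  if (length(product_classes) == 0L) product_classes <- "unknown"

  # extract per-CDS nucleotide sequence when the record carries one
  if (!is.null(seq)) {
    nt <- substring(seq, cds$start, cds$end)
    rev_i <- cds$strand == "-"
    if (any(rev_i))
      nt[rev_i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(nt[rev_i])))
    cds$nt_seq <- nt
  }

  # the writer records genome and region ids on the DEFINITION line;
  # fall back to the file name for foreign files
  def_i <- grep("^DEFINITION  \\S+ region \\S+\\.$", lines)
  def_gid <- def_rid <- NULL
  if (length(def_i)) {
    parts <- strsplit(trimws(sub("^DEFINITION", "", lines[def_i[1L]])),
                      " region ")[[1L]]
    def_gid <- parts[1L]
    def_rid <- sub("\\.$", "", parts[2L])
  }
  rid <- region_id %||% def_rid %||%
    tools::file_path_sans_ext(basename(path))
  gid <- genome_id %||% def_gid %||%
    sub("_region[0-9]+$", "", tools::file_path_sans_ext(basename(path)))
  bgc_region(region_id = rid, genome_id = gid, contig_id = record_id,
             start = span_start, end = span_end,
             product_classes = product_classes, cds = cds, seq = seq)
}

.wrap_qualifier <- function(text, width = 58L) {
  if (!nzchar(text)) return(character())
  substring(text, seq(1L, nchar(text), width),
            pmin(seq(1L, nchar(text), width) + width - 1L, nchar(text)))
}

#' Write a BGC region as a GenBank flat file
#'
#' Emits the subset of the GenBank format that
#' \code{\link{read_region_genbank}} consumes: a LOCUS line, a
#' \code{region} feature with product qualifiers, the CDS features with
#' locus tags and translations, and the nucleotide sequence in an ORIGIN
#' block. Output is deterministic (fixed date string, fixed wrapping).
#'
#' @param region A \code{\link{bgc_region}}; \code{region$seq} must be a
#'   nucleotide sequence covering the record.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_region_genbank <- function(region, path) {
  if (is.null(region$seq)) stop_arg("region has no sequence to write")
  seq <- region$seq
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-1970",
                   region$contig_id, nchar(seq)),
           sprintf("DEFINITION  %s region %s.", region$genome_id, region$region_id),
           sprintf("ACCESSION   %s", region$contig_id),
           "FEATURES             Location/Qualifiers")
  pad <- strrep(" ", 21L)
  feat_line <- function(key, loc) sprintf("     %-16s%s", key, loc)
  out <- c(out, feat_line("region", sprintf("%d..%d", region$start, region$end)))
  for (pc in region$product_classes)
    out <- c(out, paste0(pad, sprintf('/product="%s"', pc)))
  for (i in seq_len(nrow(region$cds))) {
    r <- region$cds[i, ]
    loc <- if (r$strand == "+") sprintf("%d..%d", r$start, r$end)
           else sprintf("complement(%d..%d)", r$start, r$end)
    out <- c(out, feat_line("CDS", loc),
             paste0(pad, sprintf('/locus_tag="%s"', r$locus_tag)))
    if (nzchar(r$product %||% ""))
      out <- c(out, paste0(pad, sprintf('/product="%s"', r$product)))
    if (nzchar(r$translation)) {
      tr <- .wrap_qualifier(paste0('"', r$translation, '"'))
      tr[1L] <- paste0("/translation=", tr[1L])
      out <- c(out, paste0(pad, tr))
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, nchar(seq), 60L)
  for (s in starts) {
    block <- substring(seq, seq(s, min(s + 59L, nchar(seq)), 10L),
                       pmin(seq(s, min(s + 59L, nchar(seq)), 10L) + 9L, nchar(seq)))
    out <- c(out, sprintf("%9d %s", s, paste(tolower(block), collapse = " ")))
  }
  out <- c(out, "//")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read every region GenBank file in a directory
#'
#' @param dir Directory containing \code{.gbk}/\code{.gb} files.
#' @param metadata Optional metadata data.frame used only for validation.
#' @return Named list of \code{\link{bgc_region}} objects keyed by
#'   region id, in lexicographic file order.
#' @export
read_regions_dir <- function(dir, metadata = NULL) {
  files <- lex_sort(list.files(dir, pattern = "\\.(gbk|gb|gbff)$",
                               full.names = TRUE))
  regions <- lapply(files, read_region_genbank)
  names(regions) <- vapply(regions, `[[`, "", "region_id")
  if (anyDuplicated(names(regions)))
    stop_format("duplicate region id across files in ", dir)
  regions
}
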