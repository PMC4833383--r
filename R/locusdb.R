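# Local locus database: annotation parsing, strand-aware window extraction
# from a genome FASTA, genomic-context classification, and coordinate mapping
# between genomic, window and anchor-relative frames.
#
# Conventions: genomic coordinates are 1-based inclusive (UCSC-style
# annotation); window offsets are 0-based; minus-strand windows are stored
# reverse-complemented so that "upstream/downstream" always reads in
# transcript orientation.

.loci_required_cols <- c("name", "accession", "chrom", "strand",
                         "pre_start", "pre_end")

#' Read a locus annotation table
#'
#' Loads a miRBase/miRStart-style TSV with one row per annotated miRNA gene.
#' Mandatory columns: `name`, `accession`, `chrom`, `strand`, `pre_start`,
#' `pre_end`; optional: `tss`, `cluster`, `host_gene`. An empty TSS cell means
#' the locus has no annotated transcription start site.
#'
#' @param path Path to the TSV file.
#' @return A tibble of loci in file order, with a `context` column initialised
#'   to `"unknown"` (see [classify_context()]).
#' @export
read_loci <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.loci_required_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("annotation is missing mandatory column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "lociscan_format_error")
  }
  df$strand <- gsub("−", "-", df$strand)  # tolerate typographic minus
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("row %d: strand must be '+' or '-', got '%s'",
                         bad[1], df$strand[bad[1]]),
                 class = "lociscan_format_error")
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate accession: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "lociscan_format_error")
  }
  loci <- tibble::tibble(
    name = df$name,
    accession = df$accession,
    chrom = df$chrom,
    strand = df$strand,
    pre_start = as.numeric(df$pre_start),
    pre_end = as.numeric(df$pre_end),
    tss = if ("tss" %in% names(df)) suppressWarnings(as.numeric(df$tss)) else NA_real_,
    cluster = if ("cluster" %in% names(df)) df$cluster else NA_character_,
    host_gene = if ("host_gene" %in% names(df)) df$host_gene else NA_character_,
    context = if ("context" %in% names(df)) df$context else "unknown"
  )
  if (any(is.na(loci$pre_start)) || any(is.na(loci$pre_end))) {
    rlang::abort("pre_start/pre_end must be numeric",
                 class = "lociscan_format_error")
  }
  if (any(loci$pre_start < 1) || any(loci$pre_end < loci$pre_start)) {
    rlang::abort("require 1 <= pre_start <= pre_end",
                 class = "lociscan_format_error")
  }
  loci
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive coordinates on load (via `rtracklayer`).
#'
#' @param path Path to a BED3+name file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, in file
#'   order.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
  )
}

#' Load a genome as a named vector of uppercase contig sequences
#'
#' @param x A FASTA file path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of contig sequences. FASTA record ids are truncated at
#'   the first whitespace.
#' @return Named character vector, sequences uppercased.
#' @export
read_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x) && !is.null(names(x))) {
    out <- x
  } else {
    rlang::abort("genome must be a FASTA path, DNAStringSet or named character vector",
                 class = "lociscan_format_error")
  }
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out)
}

#' Classify loci as intragenic or intergenic
#'
#' A locus is intragenic when its pre-miRNA interval overlaps any gene
#' interval by at least one base; its host gene is the first overlapping
#' interval in input order. With an empty gene table every locus is
#' intergenic.
#'
#' @param loci Tibble of loci (see [read_loci()]).
#' @param genes Tibble of gene intervals, 1-based inclusive, with columns
#'   `chrom`, `start`, `end`, `name` (see [read_gene_bed()]).
#' @return `loci` with `context` and `host_gene` filled in.
#' @export
classify_context <- function(loci, genes) {
  loci$context <- "intergenic"
  loci$host_gene <- NA_character_
  if (nrow(genes) == 0) {
    return(loci)
  }
  q <- GenomicRanges::GRanges(loci$chrom,
                              IRanges::IRanges(loci$pre_start, loci$pre_end))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  fo <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  if (length(fo) > 0) {
    first <- tapply(S4Vectors::subjectHits(fo), S4Vectors::queryHits(fo), min)
    idx <- as.integer(names(first))
    loci$context[idx] <- "intragenic"
    loci$host_gene[idx] <- genes$name[as.integer(first)]
  }
  loci
}

# Window extraction for one locus; genome is a named uppercase character
# vector. Returns a one-row tibble.
.extract_one_window <- function(genome, name, accession, chrom, strand,
                                pre_start, pre_end, tss, up, down, ...) {
  if (!chrom %in% names(genome)) {
    rlang::abort(sprintf("unknown chromosome '%s' for %s", chrom, accession),
                 class = "lociscan_window_error")
  }
  contig_len <- nchar(genome[[chrom]])
  if (pre_start > contig_len || pre_end > contig_len) {
    rlang::abort(sprintf("%s: pre-miRNA [%d,%d] lies beyond contig '%s' (length %d)",
                         accession, pre_start, pre_end, chrom, contig_len),
                 class = "lociscan_window_error")
  }
  if (strand == "+") {
    want_start <- pre_start - up
    want_end <- pre_end + down
    win_start <- max(1, want_start)
    win_end <- min(contig_len, want_end)
    clipped_up <- win_start - want_start
    clipped_down <- want_end - win_end
    seq <- substr(genome[[chrom]], win_start, win_end)
  } else {
    want_start <- pre_start - down
    want_end <- pre_end + up
    win_start <- max(1, want_start)
    win_end <- min(contig_len, want_end)
    clipped_up <- want_end - win_end
    clipped_down <- win_start - want_start
    seq <- reverse_complement(substr(genome[[chrom]], win_start, win_end))
  }
  len <- nchar(seq)
  pre5_offset <- up - clipped_up
  pre3_offset <- pre5_offset + (pre_end - pre_start)
  tss_offset <- NA_real_
  if (!is.na(tss)) {
    tss_offset <- if (strand == "+") tss - win_start else win_end - tss
    if (tss_offset < 0 || tss_offset >= len) {
      rlang::warn(sprintf("%s: TSS falls outside the extracted window; treated as absent",
                          accession))
      tss_offset <- NA_real_
    }
  }
  tibble::tibble(
    name = name, accession = accession, chrom = chrom, strand = strand,
    pre_start = pre_start, pre_end = pre_end, tss = tss,
    win_start = win_start, win_end = win_end,
    pre5_offset = pre5_offset, pre3_offset = pre3_offset,
    tss_offset = tss_offset,
    clipped_up = clipped_up, clipped_down = clipped_down,
    seq = seq
  )
}

#' Extract strand-aware scan windows around each pre-miRNA
#'
#' For a plus-strand locus the window spans `[pre_start - up, pre_end + down]`
#' on the contig (clipped to contig bounds); for a minus-strand locus the
#' genomic span is `[pre_start - down, pre_end + up]` and the stored sequence
#' is its reverse complement. In both cases the sequence reads 5'->3' along
#' transcription and `pre5_offset` is the 0-based offset of the pre-miRNA 5'
#' base. Bases lost to contig edges are recorded in `clipped_up` /
#' `clipped_down`.
#'
#' @param loci Tibble of loci ([read_loci()]).
#' @param genome Genome accepted by [read_genome()].
#' @param up,down Window extent in bp upstream of the pre-miRNA 5' end and
#'   downstream of its 3' end (defaults 60000 and 5000).
#' @return A tibble of windows, one row per locus, in input order.
#' @export
extract_windows <- function(loci, genome, up = 60000, down = 5000) {
  stopifnot(up >= 0, down >= 0)
  genome <- read_genome(genome)
  purrr::pmap(loci, .extract_one_window, genome = genome,
              up = up, down = down) |>
    dplyr::bind_rows()
}

#' Map a window offset to an anchor-relative signed position
#'
#' Returns `offset - anchor_offset` in transcript orientation: negative means
#' upstream of the anchor, 0 is the anchor base itself.
#'
#' @param window A one-row window tibble (a row of [extract_windows()]).
#' @param offset 0-based window offset(s).
#' @param anchor `"pre5"`, `"pre3"` or `"tss"`.
#' @return Signed bp distance(s).
#' @export
rel_position <- function(window, offset, anchor = c("pre5", "pre3", "tss")) {
  anchor <- match.arg(anchor)
  len <- nchar(window$seq[1])
  if (any(offset < 0 | offset >= len)) {
    rlang::abort("offset outside window", class = "lociscan_window_error")
  }
  a <- switch(anchor,
              pre5 = window$pre5_offset[1],
              pre3 = window$pre3_offset[1],
              tss = window$tss_offset[1])
  if (is.na(a)) {
    rlang::abort(sprintf("locus %s has no %s anchor",
                         window$accession[1], toupper(anchor)),
                 class = "lociscan_anchor_error")
  }
  offset - a
}

#' Map window offsets to genomic coordinates (and back)
#'
#' On the plus strand `genomic = win_start + offset`; on the minus strand the
#' stored window is reverse-complemented, so `genomic = win_end - offset`.
#'
#' @param window A one-row window tibble.
#' @param offset 0-based window offset(s).
#' @return 1-based genomic coordinate(s).
#' @export
window_offset_to_genomic <- function(window, offset) {
  if (window$strand[1] == "+") window$win_start[1] + offset
  else window$win_end[1] - offset
}

#' @rdname window_offset_to_genomic
#' @param genomic 1-based genomic coordinate(s).
#' @export
genomic_to_window_offset <- function(window, genomic) {
  if (window$strand[1] == "+") genomic - window$win_start[1]
  else window$win_end[1] - genomic
}

# Atomic file write helpers: write to a sibling temp file, then rename.
.atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    rlang::abort(sprintf("cannot write '%s'", path), class = "lociscan_io_error")
  }
  invisible(path)
}

.db_meta_cols <- function() {
  c("name", "accession", "chrom", "strand", "pre_start", "pre_end", "tss",
    "cluster", "host_gene", "context", "win_start", "win_end", "pre5_offset",
    "pre3_offset", "tss_offset", "clipped_up", "clipped_down")
}

#' Build the flat-file locus database
#'
#' Writes `loci.tsv` (locus annotation plus window index) and `windows.fa`
#' (one FASTA record per locus, id = accession, sequence in transcript
#' orientation) into `dir`.
#'
#' @inheritParams extract_windows
#' @param dir Output directory (created if needed).
#' @param genes Optional gene-interval tibble for [classify_context()].
#' @return Invisibly, the windows tibble.
#' @export
build_locus_db <- function(loci, genome, dir, up = 60000, down = 5000,
                           genes = NULL) {
  if (!is.null(genes)) {
    loci <- classify_context(loci, genes)
  }
  win <- extract_windows(loci, genome, up = up, down = down)
  meta <- dplyr::left_join(
    win[setdiff(names(win), "seq")],
    loci[c("accession", "cluster", "host_gene", "context")],
    by = "accession"
  )[.db_meta_cols()]
  .atomic_write(function(p) readr::write_tsv(meta, p), file.path(dir, "loci.tsv"))
  .atomic_write(function(p) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(win$seq, win$accession)), p
    )
  }, file.path(dir, "windows.fa"))
  invisible(win)
}

#' Read a locus database built by [build_locus_db()]
#'
#' @param dir Database directory containing `loci.tsv` and `windows.fa`.
#' @return The windows tibble (metadata plus `seq`).
#' @export
read_locus_db <- function(dir) {
  meta_path <- file.path(dir, "loci.tsv")
  fa_path <- file.path(dir, "windows.fa")
  if (!file.exists(meta_path) || !file.exists(fa_path)) {
    rlang::abort(sprintf("'%s' is not a locus database (need loci.tsv + windows.fa)",
                         dir), class = "lociscan_io_error")
  }
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    name = "c", accession = "c", chrom = "c", strand = "c",
    cluster = "c", host_gene = "c", context = "c",
    .default = readr::col_double()
  ))
  seqs <- read_genome(fa_path)
  if (!all(meta$accession %in% names(seqs))) {
    rlang::abort("windows.fa is missing records for some accessions",
                 class = "lociscan_io_error")
  }
  meta$seq <- unname(seqs[meta$accession])
  meta
}
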