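# Annotation parsing, window extraction, context classification and
# coordinate mapping.

make_loci <- function(...) {
  tibble::tibble(...)
}

test_that("annotation TSV loads with optional fields and preserves order", {
  path <- write_loci_tsv(tibble::tibble(
    name = c("mir-T1", "mir-T2"), accession = c("MI000T1", "MI000T2"),
    chrom = c("chr1", "chr1"), strand = c("+", "-"),
    pre_start = c(61, 30), pre_end = c(65, 40),
    tss = c(55, NA), cluster = c(NA, "clusterA"), host_gene = c(NA, NA)
  ))
  loci <- read_loci(path)
  expect_equal(loci$accession, c("MI000T1", "MI000T2"))
  expect_equal(loci$tss, c(55, NA))
  expect_equal(loci$context, c("unknown", "unknown"))
})

test_that("annotation validation names the offending column or row", {
  base <- tibble::tibble(
    name = "a", accession = "MI1", chrom = "chr1", strand = "+",
    pre_start = 10, pre_end = 20
  )
  expect_error(read_loci(write_loci_tsv(base[setdiff(names(base), "accession")])),
               "accession")
  bad_strand <- dplyr::bind_rows(base, dplyr::mutate(base, accession = "MI2",
                                                     strand = "x"))
  expect_error(read_loci(write_loci_tsv(bad_strand)), "row 2")
  dup <- dplyr::bind_rows(base, base)
  expect_error(read_loci(write_loci_tsv(dup)), "duplicate accession")
})

test_that("window extraction matches slice-and-count arithmetic on both strands", {
  set.seed(21)
  contig <- random_dna(100)
  genome <- c(chr1 = contig)
  plus <- make_loci(name = "p", accession = "MIP", chrom = "chr1",
                    strand = "+", pre_start = 61, pre_end = 65, tss = 55)
  w <- extract_windows(plus, genome, up = 10, down = 5)
  expect_equal(c(w$win_start, w$win_end), c(51, 70))
  expect_equal(nchar(w$seq), 20)
  expect_equal(w$pre5_offset, 10)
  expect_equal(w$pre3_offset, 14)
  expect_equal(w$seq, substr(contig, 51, 70))
  expect_equal(w$tss_offset, 4)

  minus <- dplyr::mutate(plus, strand = "-", tss = NA)
  wm <- extract_windows(minus, genome, up = 10, down = 5)
  expect_equal(c(wm$win_start, wm$win_end), c(56, 75))
  expect_equal(wm$pre5_offset, 10)
  expect_equal(wm$seq, oracle_revcomp(substr(contig, 56, 75)))
  expect_true(is.na(wm$tss_offset))
})

test_that("windows are truncated at contig edges with recorded clipping", {
  set.seed(22)
  genome <- c(chr1 = random_dna(50))
  edge <- make_loci(name = "e", accession = "MIE", chrom = "chr1",
                    strand = "+", pre_start = 5, pre_end = 9, tss = NA)
  w <- extract_windows(edge, genome, up = 10, down = 3)
  expect_equal(w$clipped_up, 6)
  expect_equal(w$clipped_down, 0)
  expect_equal(w$pre5_offset, 4)
  # invariant: length = (up - clipped_up) + pre_len + (down - clipped_down)
  expect_equal(nchar(w$seq), (10 - 6) + 5 + 3)

  minus_edge <- dplyr::mutate(edge, strand = "-", pre_start = 44, pre_end = 48)
  wm <- extract_windows(minus_edge, genome, up = 10, down = 3)
  expect_equal(wm$clipped_up, 8)  # upstream on minus strand is the right edge
  expect_equal(wm$pre5_offset, 2)
})

test_that("unknown chromosomes and off-contig loci are errors", {
  genome <- c(chr1 = "ACGTACGTAC")
  loci <- make_loci(name = "x", accession = "MIX", chrom = "chr9",
                    strand = "+", pre_start = 2, pre_end = 4, tss = NA)
  expect_error(extract_windows(loci, genome, 2, 2), "unknown chromosome")
  off <- dplyr::mutate(loci, chrom = "chr1", pre_start = 20, pre_end = 24)
  expect_error(extract_windows(off, genome, 2, 2), "beyond contig")
})

test_that("pre-miRNA-only extraction returns the precursor (or its reverse complement)", {
  set.seed(23)
  contig <- random_dna(80)
  genome <- c(c1 = contig)
  for (strand in c("+", "-")) {
    loci <- make_loci(name = "m", accession = "MI0", chrom = "c1",
                      strand = strand, pre_start = 31, pre_end = 45, tss = NA)
    w <- extract_windows(loci, genome, up = 0, down = 0)
    want <- substr(contig, 31, 45)
    if (strand == "-") want <- oracle_revcomp(want)
    expect_equal(w$seq, want)
    expect_equal(w$pre5_offset, 0)
  }
})

test_that("offset <-> genomic round trip is the identity on both strands", {
  set.seed(24)
  genome <- c(c1 = random_dna(500))
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    ps <- sample(100:300, 1)
    loci <- make_loci(name = "r", accession = "MIR", chrom = "c1",
                      strand = strand, pre_start = ps, pre_end = ps + 30,
                      tss = NA)
    w <- extract_windows(loci, genome, up = sample(0:80, 1), down = sample(0:40, 1))
    offs <- sample(0:(nchar(w$seq) - 1), 10)
    g <- window_offset_to_genomic(w, offs)
    expect_true(all(g >= w$win_start & g <= w$win_end))
    expect_equal(genomic_to_window_offset(w, g), offs)
  }
})

test_that("anchor-relative positions are signed transcript-orientation distances", {
  set.seed(25)
  genome <- c(c1 = random_dna(1200))
  loci <- make_loci(name = "t", accession = "MIT", chrom = "c1",
                    strand = "+", pre_start = 601, pre_end = 680, tss = 201)
  w <- extract_windows(loci, genome, up = 500, down = 20)
  expect_equal(w$tss_offset, 500 - 400)  # tss 400 bp upstream of pre5
  expect_equal(rel_position(w, w$tss_offset, "tss"), 0)
  expect_equal(rel_position(w, w$pre5_offset, "pre5"), 0)
  # signed table convention: upstream negative, downstream positive
  tssw <- dplyr::mutate(w, tss_offset = 500)
  expect_equal(rel_position(tssw, 99, "tss"), -401)
  tssw2 <- dplyr::mutate(w, tss_offset = 100)
  expect_equal(rel_position(tssw2, 318, "tss"), 218)
  no_tss <- dplyr::mutate(w, tss_offset = NA_real_)
  expect_error(rel_position(no_tss, 10, "tss"), "no TSS")
  expect_error(rel_position(w, nchar(w$seq), "pre5"), "outside")
})

test_that("context classification uses 1-bp overlap and first-gene tie rule", {
  loci <- make_loci(name = c("a", "b", "c"),
                    accession = c("M1", "M2", "M3"),
                    chrom = "chr1", strand = "+",
                    pre_start = c(61, 61, 61), pre_end = c(65, 65, 65),
                    tss = NA)
  genes1 <- tibble::tibble(chrom = "chr1", start = 1, end = 100, name = "G1")
  out <- classify_context(loci[1, ], genes1)
  expect_equal(out$context, "intragenic")
  expect_equal(out$host_gene, "G1")
  # adjacency is not overlap
  out2 <- classify_context(loci[1, ], tibble::tibble(
    chrom = "chr1", start = 66, end = 100, name = "G2"))
  expect_equal(out2$context, "intergenic")
  # 1-bp overlaps on both sides; first gene in input order wins
  out3 <- classify_context(loci[1, ], tibble::tibble(
    chrom = "chr1", start = c(1, 65), end = c(61, 99), name = c("GA", "GB")))
  expect_equal(out3$host_gene, "GA")
  expect_equal(classify_context(loci, genes1[0, ])$context,
               rep("intergenic", 3))
})

test_that("gene BED intervals convert from 0-based half-open on load", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tG1", "chr2\t59\t65\tG2"), bed)
  genes <- read_gene_bed(bed)
  expect_equal(genes$start, c(1, 60))
  expect_equal(genes$end, c(100, 65))
  expect_equal(genes$name, c("G1", "G2"))
})

test_that("locus database round-trips through loci.tsv + windows.fa", {
  set.seed(26)
  genome <- c(c1 = random_dna(400), c2 = random_dna(300))
  loci <- make_loci(
    name = c("a", "b"), accession = c("MI1", "MI2"),
    chrom = c("c1", "c2"), strand = c("+", "-"),
    pre_start = c(201, 101), pre_end = c(260, 180),
    tss = c(151, NA), cluster = NA_character_, host_gene = NA_character_,
    context = "unknown"
  )
  dir <- tempfile()
  win <- build_locus_db(loci, genome, dir, up = 100, down = 30)
  expect_true(file.exists(file.path(dir, "loci.tsv")))
  expect_true(file.exists(file.path(dir, "windows.fa")))
  back <- read_locus_db(dir)
  expect_equal(back$accession, win$accession)
  expect_equal(back$seq, win$seq)
  expect_equal(back$pre5_offset, win$pre5_offset)
  expect_equal(back$tss_offset, win$tss_offset)
})
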