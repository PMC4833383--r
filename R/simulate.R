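# Synthetic locus sets with planted matrix occurrences and exact ground
# truth. The background is kept free of the matrix core (in both
# orientations) by rejection resampling, so the complete hit set of a
# scan is exactly the planted set.

#' Generate core-free random background sequence
#'
#' I.i.d. bases at the requested GC content; any occurrence of a forbidden
#' core (or its reverse complement) is resampled until none remains.
#' Deterministic for a given `seed`.
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction in `[0, 1]` (default 0.41, the human genome
#'   average).
#' @param forbidden_cores Character vector of substrings that must not occur
#'   in either orientation (default the CCAAT core).
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @param max_tries Resampling rounds before giving up.
#' @return A nucleotide string.
#' @export
generate_background <- function(length, gc = 0.41,
                                forbidden_cores = "CCAAT", seed = NULL,
                                max_tries = 1000L) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  draw <- function() {
    bases <- c("A", "C", "G", "T")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    pats <- unique(c(toupper(forbidden_cores),
                     reverse_complement(toupper(forbidden_cores))))
    chars <- sample(bases, length, replace = TRUE, prob = prob)
    s <- paste(chars, collapse = "")
    for (try in seq_len(max_tries)) {
      cover <- integer(0)
      for (p in pats) {
        occ <- gregexpr(p, s, fixed = TRUE)[[1]]
        if (occ[1] != -1) {
          cover <- c(cover, unlist(lapply(occ, function(o) o:(o + nchar(p) - 1))))
        }
      }
      if (length(cover) == 0) {
        return(s)
      }
      cover <- unique(cover)
      chars <- strsplit(s, "")[[1]]
      chars[cover] <- sample(bases, length(cover), replace = TRUE, prob = prob)
      s <- paste(chars, collapse = "")
    }
    rlang::abort(sprintf(
      "could not produce a background free of {%s} in %d rounds (gc = %g)",
      paste(forbidden_cores, collapse = ","), max_tries, gc
    ), class = "lociscan_simulate_error")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Plant concrete sites into a background sequence
#'
#' Writes each site at its 0-based offset; for strand `"-"` the reverse
#' complement of the site is written, so a both-strand scan reports it as a
#' reverse-strand hit whose `matched` string is the window-orientation
#' sequence. Items must be within bounds and non-overlapping.
#'
#' @param background Nucleotide string.
#' @param items Tibble with columns `offset` (0-based), `strand`, `site`.
#' @return List with `seq` (the planted sequence) and `truth` (the items,
#'   with the window-orientation `written` string added).
#' @export
plant_sites <- function(background, items) {
  n <- nchar(background)
  if (nrow(items) == 0) {
    return(list(seq = background,
                truth = dplyr::mutate(items, written = character(0))))
  }
  stopifnot(all(c("offset", "strand", "site") %in% names(items)))
  L <- nchar(items$site)
  if (any(items$offset < 0 | items$offset + L > n)) {
    rlang::abort("planted site out of bounds", class = "lociscan_simulate_error")
  }
  ord <- order(items$offset)
  starts <- items$offset[ord]
  ends <- starts + L[ord] - 1
  if (any(starts[-1] <= ends[-length(ends)])) {
    rlang::abort("planted sites overlap", class = "lociscan_simulate_error")
  }
  items$written <- ifelse(items$strand == "-",
                          reverse_complement(toupper(items$site)),
                          toupper(items$site))
  seq <- background
  for (i in seq_len(nrow(items))) {
    substr(seq, items$offset[i] + 1, items$offset[i] + L[i]) <- items$written[i]
  }
  list(seq = seq, truth = items)
}

# Site strings usable for exact-truth planting: accepted by the policy and
# containing exactly one core occurrence over both orientations.
.plantable_sites <- function(m, policy, cap = 100000L) {
  run <- .core_run(m)
  sites <- expand_matrix(m, match_policy(
    mode = policy$mode, min_identity = policy$min_identity,
    max_mismatches = policy$max_mismatches,
    allowed_positions = policy$allowed_positions, strands = "forward",
    text_n = policy$text_n
  ), cap = cap)
  if (is.null(run)) {
    return(sites)
  }
  count_core <- function(s) {
    sum(vapply(unique(c(run$str, reverse_complement(run$str))), function(p) {
      occ <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (occ[1] == -1) 0L else length(occ)
    }, integer(1)))
  }
  sites[vapply(sites, count_core, integer(1)) == 1L]
}

#' Simulate a locus set with planted matrix occurrences
#'
#' Builds a desk-scale stand-in for a genome-wide locus database: one contig
#' per locus, loci on both strands, a fraction of loci without an annotated
#' TSS, core-free background, and a known number of planted matrix sites per
#' locus at recorded anchor-relative offsets. Because the background contains
#' no core in either orientation, the ground truth is exact: a scan recovers
#' the planted set and nothing else.
#'
#' Defaults emulate the genome-wide survey conditions at reduced scale:
#' windows of 600 bp upstream / 50 bp downstream (in place of 60 kb / 5 kb),
#' GC 0.41, a TSS annotated for 740/939 of loci, 80 bp pre-miRNAs.
#'
#' @param n_loci Number of loci.
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @param up,down Window extent in bp (scaled-down defaults 600/50; pass
#'   60000/5000 for full-size windows).
#' @param pre_len Pre-miRNA length in bp.
#' @param gc Background GC fraction.
#' @param tss_prob Probability that a locus has an annotated TSS.
#' @param hits_per_locus Integer vector sampled for the number of planted
#'   sites per locus.
#' @param m,policy Matrix and policy the planted sites must satisfy.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `loci.tsv` and `truth.tsv`.
#' @return List with `genome` (named character vector), `loci` (annotation
#'   tibble loadable by the locus db), `truth` (accession, offset, strand,
#'   site, rel_pre5, rel_tss), and the `up`/`down` used.
#' @export
simulate_locus_set <- function(n_loci = 10, seed = 1, up = 600, down = 50,
                               pre_len = 80, gc = 0.41,
                               tss_prob = 740 / 939, hits_per_locus = 0:3,
                               m = ccaat_matrix(), policy = match_policy(),
                               dir = NULL) {
  stopifnot(n_loci >= 1)
  run <- .core_run(m)
  forbidden <- if (is.null(run)) character(0) else run$str
  pool <- .plantable_sites(m, policy)
  L <- matrix_length(m)
  sim <- withr::with_seed(seed, {
    loci <- list()
    truth <- list()
    genome <- character(0)
    for (i in seq_len(n_loci)) {
      len <- up + pre_len + down
      strand <- sample(c("+", "-"), 1)
      has_tss <- stats::runif(1) < tss_prob
      tss_offset <- if (has_tss) {
        up - round(stats::runif(1, min(50, up * 0.5), up * 0.7))
      } else {
        NA_real_
      }
      k <- sample(hits_per_locus, 1)
      # non-overlapping planted offsets, redrawn if a junction creates a
      # spurious core occurrence
      for (attempt in 1:50) {
        bg <- if (length(forbidden) > 0) {
          generate_background(len, gc, forbidden)
        } else {
          generate_background(len, gc, character(0))
        }
        offs <- integer(0)
        while (length(offs) < k) {
          cand <- sample(0:(len - L), 1)
          if (all(abs(cand - offs) >= L)) offs <- c(offs, cand)
        }
        items <- tibble::tibble(
          offset = sort(offs),
          strand = sample(c("+", "-"), k, replace = TRUE),
          site = if (k > 0) sample(pool, k, replace = TRUE) else character(0)
        )
        planted <- plant_sites(bg, items)
        n_core <- if (is.null(run)) k else {
          sum(vapply(unique(c(run$str, reverse_complement(run$str))),
                     function(p) {
                       occ <- gregexpr(p, planted$seq, fixed = TRUE)[[1]]
                       if (occ[1] == -1) 0L else length(occ)
                     }, integer(1)))
        }
        if (n_core == k) break
        if (attempt == 50) {
          rlang::abort("could not plant sites without junction artifacts",
                       class = "lociscan_simulate_error")
        }
      }
      chrom <- sprintf("chrS%02d", i)
      accession <- sprintf("SIM%04d", i)
      window_seq <- planted$seq
      genome[chrom] <- if (strand == "+") window_seq else
        reverse_complement(window_seq)
      if (strand == "+") {
        pre_start <- up + 1
        pre_end <- up + pre_len
        tss <- if (has_tss) 1 + tss_offset else NA_real_
      } else {
        pre_start <- down + 1
        pre_end <- len - up
        tss <- if (has_tss) len - tss_offset else NA_real_
      }
      loci[[i]] <- tibble::tibble(
        name = sprintf("sim-mir-%d", i), accession = accession,
        chrom = chrom, strand = strand,
        pre_start = pre_start, pre_end = pre_end, tss = tss,
        cluster = NA_character_, host_gene = NA_character_,
        context = "unknown"
      )
      truth[[i]] <- tibble::tibble(
        accession = accession,
        offset = items$offset, strand = items$strand, site = items$site,
        rel_pre5 = items$offset - up,
        rel_tss = items$offset - tss_offset
      )
    }
    list(genome = genome, loci = dplyr::bind_rows(loci),
         truth = dplyr::bind_rows(truth))
  })
  sim$up <- up
  sim$down <- down
  if (!is.null(dir)) {
    write_locus_set(sim, dir)
  }
  sim
}

#' Write a simulated locus set to disk
#'
#' @param sim Result of [simulate_locus_set()].
#' @param dir Output directory; writes `genome.fa`, `loci.tsv`, `truth.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_locus_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .atomic_write(function(p) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome), p
    )
  }, file.path(dir, "genome.fa"))
  .atomic_write(function(p) readr::write_tsv(sim$loci, p),
                file.path(dir, "loci.tsv"))
  .atomic_write(function(p) readr::write_tsv(sim$truth, p),
                file.path(dir, "truth.tsv"))
  invisible(dir)
}
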