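# Matrix scanning: brute-force position-by-position matcher, core-anchored
# Boyer-Moore matcher (bad-character rule), containment prescreen, automatic
# algorithm selection, and region-restricted scans over locus windows.

.hit_schema <- function() {
  tibble::tibble(
    offset = integer(0), strand = character(0),
    matched = character(0), flank_identity = double(0)
  )
}

# Longest maximal run of singleton core positions; NULL when there is none.
# Returns list(str = core string, start = 1-based matrix position).
.core_run <- function(m) {
  singleton_core <- m$core_mask & lengths(m$positions) == 1L
  if (!any(singleton_core)) {
    return(NULL)
  }
  r <- rle(singleton_core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- seq(starts[best], ends[best])
  list(
    str = paste(vapply(m$positions[idx], `[`, character(1), 1), collapse = ""),
    start = starts[best]
  )
}

#' Core-containment prescreen
#'
#' Cheap necessary condition for a sequence to contain any hit: the longest
#' invariant core substring of the matrix (e.g. `CCAAT`), or its reverse
#' complement (`ATTGG`), must occur somewhere in the text. A `FALSE` result
#' guarantees zero hits, so the sequence can be skipped. Matrices without a
#' singleton core run prescreen as `TRUE` unconditionally.
#'
#' @param text Nucleotide string.
#' @param m A [consensus_matrix()].
#' @return Logical scalar.
#' @export
prescreen <- function(text, m) {
  run <- .core_run(m)
  if (is.null(run)) {
    return(TRUE)
  }
  text <- toupper(text)
  grepl(run$str, text, fixed = TRUE) ||
    grepl(reverse_complement(run$str), text, fixed = TRUE)
}

#' Choose the scanning algorithm from the text length
#'
#' Brute force for short texts, Boyer-Moore above the threshold. The default
#' switch point of 32768 bp sits inside the 30-40 kb band where the two
#' approaches trade places.
#'
#' @param text_length Length of the text to scan, in bp.
#' @param threshold Switch point; brute force is used iff
#'   `text_length <= threshold`.
#' @return `"brute"` or `"boyer_moore"`.
#' @export
choose_algorithm <- function(text_length, threshold = 32768L) {
  stopifnot(threshold > 0)
  if (text_length <= threshold) "brute" else "boyer_moore"
}

# Boyer-Moore (bad-character rule) exact search; returns 1-based start
# positions of every occurrence of pattern in text.
.bm_find <- function(text, pattern) {
  n <- nchar(text)
  L <- nchar(pattern)
  if (L == 0 || L > n) {
    return(integer(0))
  }
  t <- utf8ToInt(text)
  p <- utf8ToInt(pattern)
  last <- integer(256L)  # rightmost position of each character in pattern
  last[p] <- seq_len(L)
  out <- integer(0)
  s <- 0L
  while (s <= n - L) {
    j <- L
    while (j >= 1L && p[j] == t[s + j]) {
      j <- j - 1L
    }
    if (j == 0L) {
      out <- c(out, s + 1L)
      s <- s + 1L
    } else {
      s <- s + max(1L, j - last[t[s + j]])
    }
  }
  out
}

# Accepted hits for one matrix orientation given candidate 1-based site
# starts. Shared validation for both matchers.
.validated_hits <- function(text, starts, mm, policy, strand) {
  if (length(starts) == 0) {
    return(.hit_schema())
  }
  L <- matrix_length(mm)
  sites <- substring(text, starts, starts + L - 1L)
  acc <- .accept_oriented(sites, mm, policy)
  keep <- which(acc$accept)
  tibble::tibble(
    offset = as.integer(starts[keep] - 1L),
    strand = rep(strand, length(keep)),
    matched = sites[keep],
    flank_identity = acc$flank_identity[keep]
  )
}

.oriented_matrices <- function(m, policy) {
  out <- list()
  if (policy$strands %in% c("both", "forward")) {
    out[["+"]] <- m
  }
  if (policy$strands %in% c("both", "reverse")) {
    out[["-"]] <- reverse_complement(m)
  }
  out
}

#' Brute-force scan
#'
#' Tests every offset of the text against the matrix on the selected strands.
#' Overlapping hits are all reported; a forward and a reverse hit at the same
#' offset are reported separately. Hits are sorted by `(offset, strand)`.
#'
#' @param text Nucleotide string (uppercased internally).
#' @param m A [consensus_matrix()].
#' @param policy A [match_policy()].
#' @return Tibble with columns `offset` (0-based, first base of the hit),
#'   `strand` (relative to the text), `matched` (text-orientation substring)
#'   and `flank_identity`.
#' @export
scan_brute <- function(text, m, policy = match_policy()) {
  text <- toupper(text)
  n <- nchar(text)
  L <- matrix_length(m)
  if (L > n) {
    return(.hit_schema())
  }
  starts <- seq_len(n - L + 1L)
  hits <- lapply(names(.oriented_matrices(m, policy)), function(strand) {
    .validated_hits(text, starts, .oriented_matrices(m, policy)[[strand]],
                    policy, strand)
  })
  dplyr::arrange(dplyr::bind_rows(hits), .data$offset, .data$strand)
}

#' Core-anchored Boyer-Moore scan
#'
#' Locates occurrences of the matrix's longest invariant core run with a
#' Boyer-Moore bad-character search, extends each candidate to the full
#' matrix window, and validates it under the policy; the reverse strand is
#' scanned with the reverse-complemented matrix. Produces exactly the same
#' hit list as [scan_brute()]. Matrices whose longest singleton core run is
#' shorter than 3 fall back to brute force (with a notice), since the anchor
#' would not prune the search.
#'
#' @inheritParams scan_brute
#' @return As [scan_brute()].
#' @export
scan_bm <- function(text, m, policy = match_policy()) {
  run <- .core_run(m)
  if (is.null(run) || nchar(run$str) < 3) {
    rlang::inform("matrix has no singleton core run >= 3; falling back to brute force",
                  .frequency = "once", .frequency_id = "lociscan_bm_fallback")
    return(scan_brute(text, m, policy))
  }
  text <- toupper(text)
  n <- nchar(text)
  L <- matrix_length(m)
  if (L > n) {
    return(.hit_schema())
  }
  oriented <- .oriented_matrices(m, policy)
  hits <- lapply(names(oriented), function(strand) {
    mm <- oriented[[strand]]
    rr <- .core_run(mm)
    cand <- .bm_find(text, rr$str)
    starts <- cand - (rr$start - 1L)
    starts <- starts[starts >= 1L & starts <= n - L + 1L]
    .validated_hits(text, starts, mm, policy, strand)
  })
  dplyr::arrange(dplyr::bind_rows(hits), .data$offset, .data$strand)
}

#' Scan a single sequence
#'
#' Applies the containment [prescreen()] (unless disabled), chooses the
#' matcher via [choose_algorithm()] when `algorithm = "auto"`, and returns
#' the hit table.
#'
#' @inheritParams scan_brute
#' @param algorithm `"auto"`, `"brute"` or `"bm"`.
#' @param bm_threshold Switch point passed to [choose_algorithm()].
#' @param use_prescreen Apply the core-containment prescreen first.
#' @return As [scan_brute()].
#' @export
scan_sequence <- function(text, m, policy = match_policy(),
                          algorithm = c("auto", "brute", "bm"),
                          bm_threshold = 32768L, use_prescreen = TRUE) {
  algorithm <- match.arg(algorithm)
  if (use_prescreen && !prescreen(text, m)) {
    return(.hit_schema())
  }
  if (algorithm == "auto") {
    algorithm <- if (choose_algorithm(nchar(text), bm_threshold) == "brute") {
      "brute"
    } else {
      "bm"
    }
  }
  switch(algorithm,
         brute = scan_brute(text, m, policy),
         bm = scan_bm(text, m, policy))
}

#' Anchor-relative region of interest
#'
#' A region is a signed interval around an anchor in transcript orientation:
#' negative offsets are upstream of the anchor, 0 is the anchor base. Regions
#' are clipped to window bounds before use; a hit belongs to the region iff
#' its first base lies inside.
#'
#' @param anchor `"tss"`, `"pre5"` or `"pre3"`.
#' @param from,to Signed bp bounds, `from <= to`.
#' @return An object of class `region_spec`.
#' @examples
#' region_spec("tss", -500, 500)
#' parse_region("pre5:-3000:+5000")
#' @export
region_spec <- function(anchor = c("tss", "pre5", "pre3"), from, to) {
  anchor <- match.arg(anchor)
  stopifnot(is.numeric(from), is.numeric(to), from <= to)
  structure(list(anchor = anchor, from = from, to = to), class = "region_spec")
}

#' @rdname region_spec
#' @param x Region string `"anchor:from:to"` (e.g. `"tss:-500:+500"`), or
#'   `"all"` for the whole window.
#' @export
parse_region <- function(x) {
  if (is.null(x) || identical(tolower(x), "all")) {
    return(NULL)
  }
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    rlang::abort(sprintf("cannot parse region '%s' (expected anchor:from:to)", x),
                 class = "lociscan_region_error")
  }
  region_spec(tolower(parts[1]), as.numeric(parts[2]), as.numeric(parts[3]))
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s%+d..%+d\n", x$anchor, x$from, x$to))
  invisible(x)
}

# Scan one window row within an optional region; returns the annotated hit
# tibble or NULL when the required anchor is absent.
.scan_window_row <- function(w, m, policy, region, algorithm, bm_threshold) {
  len <- nchar(w$seq)
  L <- matrix_length(m)
  anchor_off <- c(pre5 = w$pre5_offset, pre3 = w$pre3_offset,
                  tss = w$tss_offset)
  if (!is.null(region)) {
    a <- anchor_off[[region$anchor]]
    if (is.na(a)) {
      return(NULL)
    }
    lo <- max(0, a + region$from)
    hi <- min(len - 1, a + region$to)
  } else {
    lo <- 0
    hi <- len - 1
  }
  hits <- if (lo > hi) {
    .hit_schema()
  } else {
    # extend the slice so hits starting near `hi` are still validated in full
    text <- substr(w$seq, lo + 1, min(hi + L, len))
    alg <- if (algorithm == "auto") {
      if (choose_algorithm(hi - lo + 1, bm_threshold) == "brute") "brute" else "bm"
    } else {
      algorithm
    }
    h <- scan_sequence(text, m, policy, algorithm = alg,
                       bm_threshold = bm_threshold)
    h$offset <- h$offset + as.integer(lo)
    dplyr::filter(h, .data$offset <= hi)
  }
  tibble::tibble(
    accession = w$accession, name = w$name,
    hits[c("offset", "strand", "matched")],
    rel_pre5 = hits$offset - w$pre5_offset,
    rel_tss = hits$offset - w$tss_offset,
    rel_pre3 = hits$offset - w$pre3_offset,
    flank_identity = hits$flank_identity
  )
}

#' Scan every locus window in a database
#'
#' Runs the matrix scan over each window (optionally restricted to an
#' anchor-relative region), in stable input order. Loci lacking the requested
#' anchor (for instance a TSS-anchored scan on a TSS-less locus) are skipped
#' and recorded in the skip report.
#'
#' @param windows Windows tibble ([extract_windows()] or [read_locus_db()]).
#' @param m A [consensus_matrix()].
#' @param policy A [match_policy()].
#' @param region A [region_spec()], or `NULL` for the whole window.
#' @param algorithm `"auto"`, `"brute"` or `"bm"`; auto selection uses the
#'   region length.
#' @param bm_threshold Switch point for auto selection.
#' @return An object of class `scan_result`: a list with `hits` (one row per
#'   hit), `summary` (one row per scanned locus: `accession`, `name`,
#'   `n_hits`, `matrix_length`, `elapsed_ms`), `skipped` (accession +
#'   reason), and the scan settings. `tidy()`, `glance()` and `autoplot()`
#'   methods are provided.
#' @export
scan_windows <- function(windows, m, policy = match_policy(), region = NULL,
                         algorithm = c("auto", "brute", "bm"),
                         bm_threshold = 32768L) {
  algorithm <- match.arg(algorithm)
  if (is.character(region)) {
    region <- parse_region(region)
  }
  hits <- list()
  summary <- list()
  skipped <- list()
  for (i in seq_len(nrow(windows))) {
    w <- as.list(windows[i, ])
    t0 <- proc.time()[["elapsed"]]
    h <- .scan_window_row(w, m, policy, region, algorithm, bm_threshold)
    if (is.null(h)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        accession = w$accession, name = w$name,
        reason = sprintf("no %s anchor", toupper(region$anchor))
      )
      next
    }
    hits[[length(hits) + 1]] <- h
    summary[[length(summary) + 1]] <- tibble::tibble(
      accession = w$accession, name = w$name, n_hits = nrow(h),
      matrix_length = matrix_length(m),
      elapsed_ms = as.integer(round((proc.time()[["elapsed"]] - t0) * 1000))
    )
  }
  structure(
    list(
      hits = dplyr::bind_rows(c(list(.scan_hit_schema()), hits)),
      summary = dplyr::bind_rows(c(list(.scan_summary_schema()), summary)),
      skipped = dplyr::bind_rows(c(list(.skip_schema()), skipped)),
      matrix = m, policy = policy, region = region
    ),
    class = "scan_result"
  )
}

.scan_hit_schema <- function() {
  tibble::tibble(
    accession = character(0), name = character(0), offset = integer(0),
    strand = character(0), matched = character(0), rel_pre5 = double(0),
    rel_tss = double(0), rel_pre3 = double(0), flank_identity = double(0)
  )
}

.scan_summary_schema <- function() {
  tibble::tibble(accession = character(0), name = character(0),
                 n_hits = integer(0), matrix_length = integer(0),
                 elapsed_ms = integer(0))
}

.skip_schema <- function() {
  tibble::tibble(accession = character(0), name = character(0),
                 reason = character(0))
}

#' @export
print.scan_result <- function(x, ...) {
  reg <- if (is.null(x$region)) "whole window" else {
    sprintf("%s%+d..%+d", x$region$anchor, x$region$from, x$region$to)
  }
  cat(sprintf(
    "<scan_result> %s over %d loci (%s): %d hits, %d skipped\n",
    x$matrix$label, nrow(x$summary), reg, nrow(x$hits), nrow(x$skipped)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Hit table of a scan result
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return The hits tibble, one row per hit.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) x$hits

#' One-row overview of a scan result
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return Tibble with locus/hit totals and per-locus hit-count extremes.
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$summary),
    n_skipped = nrow(x$skipped),
    total_hits = sum(x$summary$n_hits),
    min_hits = if (nrow(x$summary) > 0) min(x$summary$n_hits) else NA_integer_,
    max_hits = if (nrow(x$summary) > 0) max(x$summary$n_hits) else NA_integer_,
    matrix_length = matrix_length(x$matrix)
  )
}
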