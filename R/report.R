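# Aggregation of scan results: per-locus summaries, hit-count frequency and
# positional distributions, and round-trip-safe TSV/CSV export.

#' Per-locus summary table
#'
#' One row per scanned locus (input order) with the anchor-relative positions
#' of its hits.
#'
#' @param result A `scan_result` from [scan_windows()].
#' @param anchor Anchor used to render hit positions: `"pre5"`, `"tss"` or
#'   `"pre3"`.
#' @return Tibble with columns `name`, `accession`, `n_hits`, `positions`
#'   (list column of signed bp), `matrix_length`, `elapsed_ms`.
#' @export
summarize_scan <- function(result, anchor = c("pre5", "tss", "pre3")) {
  anchor <- match.arg(anchor)
  rel_col <- paste0("rel_", anchor)
  pos <- split(result$hits[[rel_col]], factor(result$hits$accession,
                                              levels = result$summary$accession))
  tibble::tibble(
    name = result$summary$name,
    accession = result$summary$accession,
    n_hits = result$summary$n_hits,
    positions = unname(pos[result$summary$accession]),
    matrix_length = result$summary$matrix_length,
    elapsed_ms = result$summary$elapsed_ms
  )
}

# Half-open [lo, hi) histogram over numeric values, bins aligned to
# multiples of bin_width.
.make_hist <- function(values, bin_width, what) {
  stopifnot(bin_width >= 1)
  if (length(values) == 0) {
    h <- tibble::tibble(bin_lo = double(0), bin_hi = double(0),
                        count = integer(0))
  } else {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- floor(max(values) / bin_width) * bin_width + bin_width
    edges <- seq(lo, hi, by = bin_width)
    idx <- findInterval(values, edges, rightmost.closed = FALSE)
    h <- tibble::tibble(
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      count = as.integer(tabulate(idx, nbins = length(edges) - 1))
    )
  }
  structure(h, class = c("scan_histogram", class(h)),
            what = what, bin_width = bin_width)
}

#' Frequency distribution of per-locus hit counts
#'
#' Histogram of `n_hits` across loci, in half-open bins of `bin_width`; the
#' counts sum to the number of scanned loci, and the minimum/maximum loci are
#' recoverable from the same summary.
#'
#' @param x A `scan_result` or a summary tibble with an `n_hits` column.
#' @param bin_width Bin width in hits (default 10).
#' @return A `scan_histogram` tibble (`bin_lo`, `bin_hi`, `count`).
#' @export
hit_count_frequency <- function(x, bin_width = 10) {
  counts <- if (inherits(x, "scan_result")) x$summary$n_hits else x$n_hits
  .make_hist(counts, bin_width, "per_locus_hit_count")
}

#' Positional distribution of hits around an anchor
#'
#' Histogram of anchor-relative hit positions in half-open `[lo, hi)` bins.
#'
#' @param x A `scan_result` or a hits tibble with `rel_*` columns.
#' @param anchor `"pre5"`, `"tss"` or `"pre3"`.
#' @param bin_width Bin width in bp (default 100).
#' @return A `scan_histogram` tibble.
#' @export
position_distribution <- function(x, anchor = c("pre5", "tss", "pre3"),
                                  bin_width = 100) {
  anchor <- match.arg(anchor)
  hits <- if (inherits(x, "scan_result")) x$hits else x
  pos <- hits[[paste0("rel_", anchor)]]
  if (anyNA(pos)) {
    rlang::warn(sprintf("%d hit(s) without a %s anchor dropped from the distribution",
                        sum(is.na(pos)), toupper(anchor)))
    pos <- pos[!is.na(pos)]
  }
  .make_hist(pos, bin_width, "hit_position")
}

#' Export a table to TSV or CSV
#'
#' The write is atomic (temp file + rename) and round-trip safe: reading the
#' file back reproduces the table. CSV fields containing commas are quoted;
#' TSV uses no quoting, so tab or newline characters inside fields are
#' rejected. List columns (e.g. `positions`) are collapsed with commas.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
export_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ","), character(1))
  ))
  if (format == "tsv") {
    chr <- vapply(x, is.character, logical(1))
    bad <- vapply(x[chr], function(col) any(grepl("[\t\n]", col)), logical(1))
    if (any(bad)) {
      rlang::abort(sprintf("tsv export forbids tabs/newlines inside fields (column %s)",
                           names(bad)[bad][1]), class = "lociscan_io_error")
    }
    .atomic_write(function(p) readr::write_tsv(x, p), path)
  } else {
    .atomic_write(function(p) readr::write_csv(x, p), path)
  }
  invisible(path)
}

#' Read back an exported hit table
#'
#' @param path Path written by the scan CLI or [export_table()].
#' @param format `"tsv"` or `"csv"`.
#' @return A tibble.
#' @export
read_hits <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  reader(path, col_types = readr::cols(
    accession = "c", name = "c", strand = "c", matched = "c",
    offset = "i", .default = readr::col_double()
  ))
}

#' @export
print.scan_histogram <- function(x, ...) {
  cat(sprintf("<scan_histogram> %s, bin width %g, %d bins, %d items\n",
              attr(x, "what"), attr(x, "bin_width"), nrow(x), sum(x$count)))
  NextMethod()
}

#' Plot a scan histogram
#'
#' @param object A `scan_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_histogram
#' @export
autoplot.scan_histogram <- function(object, ...) {
  lab <- if (attr(object, "what") == "per_locus_hit_count") {
    c(x = "hits per locus", y = "loci")
  } else {
    c(x = "position relative to anchor (bp)", y = "hits")
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::labs(x = lab[["x"]], y = lab[["y"]]) +
    ggplot2::theme_minimal()
}

#' Plot the positional distribution of a scan result
#'
#' @param object A `scan_result`.
#' @param anchor,bin_width Passed to [position_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, anchor = "pre5", bin_width = 100,
                                 ...) {
  autoplot(position_distribution(object, anchor, bin_width))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
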