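# Curated worked-example tables shipped with the package: CCAAT matrices
# found at experimentally validated miRNA loci, and a literature compilation
# of mature miRNAs up-regulated in colorectal cancer. Entries are transcribed
# verbatim from the published tables (including the capitalised sites of the
# downstream table and one 10-mer printed short of full matrix length).

#' Packaged worked-example tables
#'
#' Returns three curated tables used for worked examples and cross-checks:
#'
#' * `colon_upregulated`: mature miRNAs reported up-regulated in colorectal
#'   cancer, one row per (miRNA, reference-set) with citation keys.
#' * `promoter_matrices`: CCAAT matrix strings found within the minimal
#'   promoter (-500..+500 bp of the TSS) of four in-vivo-validated miRNA
#'   clusters, with their signed distance from the TSS.
#' * `downstream_matrices`: CCAAT matrix strings found within 5 kb downstream
#'   of the 3' end of six validated pre-miRNAs, with their distance from the
#'   pre-miRNA 3' end.
#'
#' @return Named list of three tibbles.
#' @examples
#' tabs <- example_tables()
#' dplyr::n_distinct(tabs$colon_upregulated$mirna)
#' @export
example_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "lociscan",
                                 mustWork = TRUE)
  list(
    colon_upregulated = readr::read_tsv(
      ext("colon_upregulated_mirnas.tsv"),
      col_types = readr::cols(.default = "c")
    ),
    promoter_matrices = readr::read_tsv(
      ext("promoter_matrices.tsv"),
      col_types = readr::cols(pri_mirna = "c", n_printed = "i",
                              site = "c", distance_tss = "d")
    ),
    downstream_matrices = readr::read_tsv(
      ext("downstream_matrices.tsv"),
      col_types = readr::cols(pre_mirna = "c", n_printed = "i",
                              site = "c", distance_pre3 = "d")
    )
  )
}
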