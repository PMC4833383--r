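# Independent oracles used to validate the implementation. These are kept
# deliberately naive and separate from the package's own code paths.

# Reverse complement by explicit per-base table (independent of the
# package's chartr-based implementation; cross-checked against Biostrings
# in tests).
oracle_revcomp <- function(s) {
  tab <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- rev(strsplit(toupper(s), "")[[1]])
  paste(tab[ch], collapse = "")
}

# Per-position set-membership oracle: identity detail of a site against a
# list of allowed sets with a core mask.
oracle_site_detail <- function(site, sets, core_mask) {
  ch <- strsplit(toupper(site), "")[[1]]
  ok <- mapply(function(c, s) c %in% s, ch, sets)
  nf <- sum(!core_mask)
  list(
    core_ok = all(ok[core_mask]),
    flank_identity = if (nf > 0) sum(ok[!core_mask]) / nf else 1
  )
}

# Set-containment scan oracle: given the exact accepted k-mer sets per
# strand, test every offset by plain substring equality.
oracle_set_scan <- function(text, fwd_set, rev_set, L) {
  text <- toupper(text)
  n <- nchar(text)
  if (L > n) {
    return(data.frame(offset = integer(0), strand = character(0)))
  }
  out <- list()
  for (o in 0:(n - L)) {
    s <- substr(text, o + 1, o + L)
    if (s %in% fwd_set) out[[length(out) + 1]] <- data.frame(offset = o, strand = "+")
    if (s %in% rev_set) out[[length(out) + 1]] <- data.frame(offset = o, strand = "-")
  }
  do.call(rbind, c(list(data.frame(offset = integer(0), strand = character(0))), out))
}

# Forward/reverse accepted k-mer sets for a matrix + identity policy,
# enumerated by brute force over all 4^L strings (tiny L only).
oracle_accept_sets <- function(sets, core_mask, min_identity) {
  L <- length(sets)
  grid <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), L),
                                 list(stringsAsFactors = FALSE)))
  all_kmers <- apply(grid, 1, paste, collapse = "")
  acc <- vapply(all_kmers, function(s) {
    d <- oracle_site_detail(s, sets, core_mask)
    d$core_ok && d$flank_identity > min_identity
  }, logical(1))
  fwd <- all_kmers[acc]
  rev <- vapply(fwd, oracle_revcomp, character(1))
  list(fwd = fwd, rev = unname(rev))
}

# Random degenerate matrix of length L as a list(sets, core_mask, iupac),
# guaranteed to contain a singleton run of length >= 3 so the anchored
# matcher is exercised.
random_matrix_spec <- function(L = 6, run_len = 3) {
  codes <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", V = "ACG", D = "AGT",
             H = "ACT", B = "CGT", N = "ACGT")
  sym <- sample(names(codes), L, replace = TRUE,
                prob = c(rep(3, 4), rep(1, 11)))
  start <- sample(1:(L - run_len + 1), 1)
  sym[start:(start + run_len - 1)] <- sample(c("A", "C", "G", "T"),
                                             run_len, replace = TRUE)
  sets <- lapply(sym, function(x) strsplit(codes[[x]], "")[[1]])
  list(iupac = paste(sym, collapse = ""), sets = sets,
       core_mask = lengths(sets) == 1L)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Write a small annotation TSV and return its path.
write_loci_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, na = "")
  path
}

default_ccaat <- function() consensus_matrix("DVVCCAATSNV")
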