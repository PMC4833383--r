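# Degenerate consensus matrices: ordered per-position allowed-nucleotide sets
# with an invariant core, plus the match policies used to accept or reject a
# candidate site.

# Inverse of Biostrings::IUPAC_CODE_MAP, keyed by the sorted base set.
.iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(x) sort(strsplit(x, "")[[1]]))
}

.code_of_set <- function(set) {
  sets <- .iupac_sets()
  keys <- vapply(sets, paste, character(1), collapse = "")
  names(sets)[match(paste(sort(set), collapse = ""), keys)]
}

#' Build a degenerate consensus matrix from an IUPAC string
#'
#' A consensus matrix is an ordered list of allowed-nucleotide sets over
#' \{A,C,G,T\}, one per position, together with a core mask marking the
#' invariant positions at which no mismatch is ever tolerated. The NF-Y
#' CCAAT-box matrix, for example, is `"DVVCCAATSNV"` with the CCAAT
#' pentanucleotide (positions 4-8) as core.
#'
#' @param iupac Consensus as an IUPAC string (case-insensitive), 4-30
#'   characters from `A C G T R Y S W K M B D H V N`.
#' @param core Optional integer vector of 1-based core positions (e.g. `4:8`).
#'   When absent, every singleton (non-degenerate) position is core. Forcing a
#'   degenerate position into the core is allowed; it then requires set
#'   membership but never counts as a flank.
#' @param label Human-readable label; defaults to the consensus string.
#' @return An object of class `consensus_matrix`.
#' @examples
#' ccaat <- consensus_matrix("DVVCCAATSNV")
#' ccaat
#' reverse_complement(ccaat)
#' @export
consensus_matrix <- function(iupac, core = NULL, label = NULL) {
  stopifnot(is.character(iupac), length(iupac) == 1)
  chars <- strsplit(toupper(trimws(iupac)), "")[[1]]
  n <- length(chars)
  if (n < 4 || n > 30) {
    rlang::abort(sprintf(
      "consensus length must be between 4 and 30 nucleotides, got %d", n
    ), class = "lociscan_matrix_error")
  }
  sets <- .iupac_sets()
  bad <- which(!chars %in% names(sets))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid IUPAC symbol '%s' at position %d",
      chars[bad[1]], bad[1]
    ), class = "lociscan_matrix_error")
  }
  positions <- sets[chars]
  names(positions) <- NULL
  if (is.null(core)) {
    core_mask <- lengths(positions) == 1L
  } else {
    core <- as.integer(core)
    if (any(core < 1 | core > n)) {
      rlang::abort("core positions out of range", class = "lociscan_matrix_error")
    }
    core_mask <- seq_len(n) %in% core
  }
  structure(
    list(
      label = label %||% paste(chars, collapse = ""),
      consensus = paste(chars, collapse = ""),
      positions = positions,
      core_mask = core_mask
    ),
    class = "consensus_matrix"
  )
}

#' The NF-Y CCAAT-box consensus matrix
#'
#' Convenience constructor for the canonical CCAAT matrix
#' `D/V/V/C/C/A/A/T/S/N/V` (D = A/G/T, V = A/C/G, S = C/G, N = any) with the
#' invariant CCAAT pentanucleotide as core.
#'
#' @return A `consensus_matrix` of length 11.
#' @export
ccaat_matrix <- function() {
  consensus_matrix("DVVCCAATSNV", label = "NF-Y CCAAT")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  marked <- strsplit(x$consensus, "")[[1]]
  marked[x$core_mask] <- tolower(marked[x$core_mask])
  cat(sprintf(
    "<consensus_matrix> %s (%d nt, core positions marked lowercase)\n  %s\n",
    x$label, matrix_length(x), paste(marked, collapse = "")
  ))
  invisible(x)
}

#' Length of a consensus matrix
#' @param m A `consensus_matrix`.
#' @return Integer number of positions.
#' @export
matrix_length <- function(m) length(m$positions)

#' Reverse complement
#'
#' Generic over plain nucleotide strings and consensus matrices. For a matrix
#' the position order is reversed and every allowed set is complemented
#' set-wise, so `reverse_complement(consensus_matrix("CCAAT..."))` describes
#' the same motif read on the opposite strand (CCAAT becomes ATTGG).
#'
#' @param x A character vector of nucleotide strings or a `consensus_matrix`.
#' @param ... Unused.
#' @return Same type as `x`.
#' @export
reverse_complement <- function(x, ...) UseMethod("reverse_complement")

#' @rdname reverse_complement
#' @export
reverse_complement.character <- function(x, ...) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' @rdname reverse_complement
#' @export
reverse_complement.consensus_matrix <- function(x, ...) {
  comp_tab <- c(A = "T", C = "G", G = "C", T = "A")
  positions <- rev(lapply(x$positions, function(s) sort(unname(comp_tab[s]))))
  consensus <- paste(
    vapply(positions, .code_of_set, character(1)),
    collapse = ""
  )
  structure(
    list(
      label = paste0("revcomp(", x$label, ")"),
      consensus = consensus,
      positions = positions,
      core_mask = rev(x$core_mask)
    ),
    class = "consensus_matrix"
  )
}

#' Match policy for degenerate positions
#'
#' Controls how a candidate site may deviate from the matrix. Core positions
#' always require exact set membership. In `"identity"` mode the fraction of
#' matching non-core (flank) positions must be strictly greater than
#' `min_identity` (the default 0.82 reproduces the ">82% in the flanking
#' sequences" rule: with 6 flanks at least 5 must match). In `"mismatch"` mode
#' at most `max_mismatches` flank positions may deviate, and only at
#' `allowed_positions`.
#'
#' @param mode `"identity"` or `"mismatch"`.
#' @param min_identity Strict lower bound on the flank identity fraction.
#' @param max_mismatches Maximum number of flank mismatches (`"mismatch"` mode).
#' @param allowed_positions 1-based positions where mismatches are permitted;
#'   `NULL` means every non-core position.
#' @param strands `"both"`, `"forward"` or `"reverse"`.
#' @param text_n How an `N` in the scanned text behaves: `"never"` (default;
#'   matches no position, conservative for assembly gaps) or `"iupac"`
#'   (matches positions whose allowed set is all four bases).
#' @return An object of class `match_policy`.
#' @export
match_policy <- function(mode = c("identity", "mismatch"),
                         min_identity = 0.82,
                         max_mismatches = 0L,
                         allowed_positions = NULL,
                         strands = c("both", "forward", "reverse"),
                         text_n = c("never", "iupac")) {
  mode <- match.arg(mode)
  strands <- match.arg(strands)
  text_n <- match.arg(text_n)
  stopifnot(min_identity >= 0, min_identity <= 1, max_mismatches >= 0)
  structure(
    list(
      mode = mode,
      min_identity = min_identity,
      max_mismatches = as.integer(max_mismatches),
      allowed_positions = if (!is.null(allowed_positions)) {
        as.integer(allowed_positions)
      },
      strands = strands,
      text_n = text_n
    ),
    class = "match_policy"
  )
}

#' @export
print.match_policy <- function(x, ...) {
  detail <- if (x$mode == "identity") {
    sprintf("flank identity > %.3g", x$min_identity)
  } else {
    sprintf("<= %d mismatches at {%s}", x$max_mismatches,
            paste(x$allowed_positions %||% "any flank", collapse = ","))
  }
  cat(sprintf("<match_policy> %s, strands = %s\n", detail, x$strands))
  invisible(x)
}

# Character matrix (n sites x L) from equal-length site strings.
.site_char_matrix <- function(sites, L) {
  lens <- nchar(sites)
  if (any(lens != L)) {
    rlang::abort(sprintf(
      "site length %d does not match matrix length %d",
      lens[which(lens != L)[1]], L
    ), class = "lociscan_matrix_error")
  }
  matrix(unlist(strsplit(toupper(sites), "")), ncol = L, byrow = TRUE)
}

# n x L logical membership matrix for sites against matrix positions.
.membership <- function(chmat, m, text_n = "never") {
  L <- matrix_length(m)
  ok <- matrix(FALSE, nrow = nrow(chmat), ncol = L)
  for (j in seq_len(L)) {
    set <- m$positions[[j]]
    ok[, j] <- chmat[, j] %in% set
    if (text_n == "iupac" && length(set) == 4L) {
      ok[, j] <- ok[, j] | chmat[, j] == "N"
    }
  }
  ok
}

#' Core check and flank identity of candidate sites
#'
#' For each site (a string of exactly matrix length) reports whether every
#' core position's character belongs to its allowed set, and the fraction of
#' matching non-core positions (1 when the matrix has no non-core positions).
#' The orientation is not switched here; compare against
#' `reverse_complement(m)` for the opposite strand.
#'
#' @param sites Character vector of candidate sites.
#' @param m A `consensus_matrix`.
#' @param text_n See [match_policy()].
#' @return A tibble with columns `site`, `core_ok`, `flank_identity`,
#'   `n_flank_mismatch`.
#' @examples
#' site_identity(c("agcccaatcag", "tatccaatccc"), ccaat_matrix())
#' @export
site_identity <- function(sites, m, text_n = "never") {
  L <- matrix_length(m)
  chmat <- .site_char_matrix(sites, L)
  ok <- .membership(chmat, m, text_n)
  core <- m$core_mask
  core_ok <- if (any(core)) {
    rowSums(!ok[, core, drop = FALSE]) == 0L
  } else {
    rep(TRUE, length(sites))
  }
  nf <- sum(!core)
  fmatch <- if (nf > 0) rowSums(ok[, !core, drop = FALSE]) else rep(0L, length(sites))
  tibble::tibble(
    site = sites,
    core_ok = core_ok,
    flank_identity = if (nf > 0) fmatch / nf else 1,
    n_flank_mismatch = if (nf > 0) as.integer(nf - fmatch) else 0L
  )
}

# Acceptance of sites against a single matrix orientation.
.accept_oriented <- function(sites, m, policy) {
  L <- matrix_length(m)
  chmat <- .site_char_matrix(sites, L)
  ok <- .membership(chmat, m, policy$text_n)
  core <- m$core_mask
  core_ok <- if (any(core)) rowSums(!ok[, core, drop = FALSE]) == 0L else TRUE
  flank_idx <- which(!core)
  nf <- length(flank_idx)
  if (nf == 0) {
    acc <- core_ok
    fid <- rep(1, length(sites))
  } else {
    fmatch <- rowSums(ok[, flank_idx, drop = FALSE])
    fid <- fmatch / nf
    if (policy$mode == "identity") {
      acc <- core_ok & fid > policy$min_identity
    } else {
      allowed <- policy$allowed_positions %||% flank_idx
      if (any(allowed %in% which(core))) {
        rlang::abort("allowed_positions may not include core positions",
                     class = "lociscan_matrix_error")
      }
      n_mis <- nf - fmatch
      forbidden <- setdiff(flank_idx, allowed)
      ok_forbidden <- if (length(forbidden) > 0) {
        rowSums(!ok[, forbidden, drop = FALSE]) == 0L
      } else {
        TRUE
      }
      acc <- core_ok & n_mis <= policy$max_mismatches & ok_forbidden
    }
  }
  list(accept = acc & core_ok, flank_identity = fid, core_ok = core_ok)
}

#' Classify candidate sites under a match policy
#'
#' A site matches when it satisfies the policy against the matrix in the
#' forward orientation, or (with `strands = "both"` or `"reverse"`) against
#' the reverse-complemented matrix.
#'
#' @inheritParams site_identity
#' @param policy A [match_policy()].
#' @param detail Return a tibble of per-orientation detail instead of a
#'   logical vector.
#' @return Logical vector, or with `detail = TRUE` a tibble with columns
#'   `site`, `forward`, `reverse`, `match`, `strand`, `flank_identity`.
#' @examples
#' classify_sites(c("agcccaatcag", "ataattggttt"), ccaat_matrix(), match_policy())
#' @export
classify_sites <- function(sites, m, policy = match_policy(), detail = FALSE) {
  use_fwd <- policy$strands %in% c("both", "forward")
  use_rev <- policy$strands %in% c("both", "reverse")
  n <- length(sites)
  fwd <- if (use_fwd) {
    .accept_oriented(sites, m, policy)
  } else {
    list(accept = rep(FALSE, n), flank_identity = rep(NA_real_, n))
  }
  rev <- if (use_rev) {
    .accept_oriented(sites, reverse_complement(m), policy)
  } else {
    list(accept = rep(FALSE, n), flank_identity = rep(NA_real_, n))
  }
  match <- fwd$accept | rev$accept
  if (!detail) {
    return(match)
  }
  tibble::tibble(
    site = sites,
    forward = fwd$accept,
    reverse = rev$accept,
    match = match,
    strand = dplyr::case_when(fwd$accept ~ "+", rev$accept ~ "-",
                              TRUE ~ NA_character_),
    flank_identity = dplyr::case_when(
      fwd$accept ~ fwd$flank_identity,
      rev$accept ~ rev$flank_identity,
      TRUE ~ NA_real_
    )
  )
}

#' Enumerate every concrete k-mer accepted by a matrix and policy
#'
#' Expands the matrix into the exact set of strings for which
#' [classify_sites()] is true, by enumerating mismatch patterns over the flank
#' positions. Intended as an exhaustive oracle and for set-scan cross-checks;
#' refuse expansions larger than `cap`.
#'
#' @inheritParams classify_sites
#' @param cap Maximum number of strings to enumerate.
#' @return Character vector of accepted k-mers (both orientations when
#'   `policy$strands == "both"`).
#' @export
expand_matrix <- function(m, policy = match_policy(), cap = 100000L) {
  core <- m$core_mask
  flank_idx <- which(!core)
  nf <- length(flank_idx)
  k_max <- if (policy$mode == "identity") {
    if (nf == 0) 0L else max(0L, sum(((nf - seq(0, nf)) / nf) > policy$min_identity) - 1L)
  } else {
    min(policy$max_mismatches, nf)
  }
  allowed <- if (policy$mode == "mismatch") {
    policy$allowed_positions %||% flank_idx
  } else {
    flank_idx
  }
  bases <- c("A", "C", "G", "T")
  subsets <- list(integer(0))
  if (k_max > 0 && length(allowed) > 0) {
    for (k in seq_len(min(k_max, length(allowed)))) {
      cmb <- utils::combn(allowed, k, simplify = FALSE)
      subsets <- c(subsets, cmb)
    }
  }
  total <- 0
  choice_sets <- list()
  for (s in subsets) {
    per_pos <- lapply(seq_along(m$positions), function(j) {
      if (j %in% s) setdiff(bases, m$positions[[j]]) else m$positions[[j]]
    })
    sz <- prod(lengths(per_pos))
    if (sz == 0) next
    total <- total + sz
    choice_sets[[length(choice_sets) + 1]] <- per_pos
  }
  if (policy$strands == "both") total <- total * 2
  if (total > cap) {
    rlang::abort(sprintf("expansion would produce %d strings (cap %d)",
                         total, cap), class = "lociscan_matrix_error")
  }
  out <- unlist(lapply(choice_sets, function(per_pos) {
    grid <- do.call(expand.grid, c(rev(per_pos),
                                   list(stringsAsFactors = FALSE)))
    apply(grid[, rev(seq_along(per_pos)), drop = FALSE], 1, paste,
          collapse = "")
  }))
  out <- unique(out)
  if (policy$strands == "both") {
    out <- unique(c(out, reverse_complement(out)))
  } else if (policy$strands == "reverse") {
    out <- unique(reverse_complement(out))
  }
  out
}

`%||%` <- rlang::`%||%`
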