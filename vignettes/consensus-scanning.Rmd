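---
title: "Scanning degenerate consensus matrices across miRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning degenerate consensus matrices across miRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lociscan)
library(dplyr)
```

## The problem

Transcription factors bind short, partially degenerate DNA motifs. NF-Y, a
ubiquitous heterotrimeric factor, recognises the CCAAT pentanucleotide — in
either orientation, CCAAT or ATTGG — with binding further modulated by the
flanking bases. To ask whether a factor like NF-Y could regulate microRNA
genes, one scans large windows around every annotated pre-miRNA (the hairpin
precursor) for occurrences of a *consensus matrix*: an ordered list of
allowed-nucleotide sets, written as an IUPAC string, with an invariant core
at which no mismatch is tolerated. `lociscan` implements this scan
end-to-end: a flat-file locus database built from a genome FASTA and
miRBase/miRStart-style annotation, strand-aware window extraction, exhaustive
matching on both strands under configurable mismatch policies, and reporting
of every hit as a signed distance from the pre-miRNA or its transcription
start site (TSS).

## The matching model

A matrix of length $L$ (allowed range 4–30) assigns each position $j$ a set
$S_j \subseteq \{A,C,G,T\}$ and a core flag. A candidate site $x_{1..L}$ is
evaluated in two parts:

* **core**: every core position must satisfy $x_j \in S_j$ — no exceptions;
* **flanks**: the flank identity is the fraction of non-core positions with
  $x_j \in S_j$.

Under the default *identity* policy a site matches when the core holds and
the flank identity is **strictly greater than** 0.82. For the canonical NF-Y
matrix `D/V/V/C/C/A/A/T/S/N/V` (D = A/G/T, V = A/C/G, S = C/G, N = any;
CCAAT core at positions 4–8) there are six flank positions, so a match
requires at least 5 of 6 flanks — 5/6 ≈ 0.833 is the only attainable value
strictly above 0.82 short of a perfect flank. The alternative *mismatch*
policy instead allows at most $k$ flank mismatches, optionally restricted to
a user-chosen set of positions. With `strands = "both"` a site also matches
when the reverse-complemented matrix accepts it; such hits are reported on
the `-` strand with the window-orientation substring as `matched`.

Two deliberate numerical choices: the threshold comparison is strict (`>`,
not `>=`), and an `N` in the scanned text matches nothing by default — a
conservative rule that avoids phantom hits inside assembly gaps. Setting
`text_n = "iupac"` in `match_policy()` lets text `N` match positions whose
allowed set is all four bases. Matching is case-insensitive throughout, so
soft-masked genomes scan identically to uppercase ones.

This is a set-membership model, not a position weight matrix: there is no
log-odds scoring, by design, because the matrix definition itself is the
object of interest and its acceptance set must be exactly enumerable
(`expand_matrix()` does precisely that, and doubles as an exhaustive test
oracle).

## Windows, coordinates, anchors

Each locus contributes one window: `up` bp upstream of the pre-miRNA 5' end
and `down` bp downstream of its 3' end (defaults 60 kb and 5 kb — large
enough to cover the TSS of polycistronic primary transcripts, which can sit
tens of kb away). Genomic coordinates are 1-based inclusive; window offsets
are 0-based. Minus-strand windows are stored reverse-complemented, so
"upstream" always means smaller offsets and all downstream code is
strand-free. Windows that would run off a contig are truncated with the
clipped lengths recorded (`clipped_up`/`clipped_down`) rather than the locus
dropped, so no annotated locus silently disappears.

A hit is anchored at the **first base** of the matched $L$-mer in window
orientation, for both strands, and reported as `offset - anchor_offset`
relative to the pre-miRNA 5' end (`rel_pre5`), 3' end (`rel_pre3`) and TSS
(`rel_tss`, `NA` when the locus has no annotated TSS). Negative is upstream.
Region-restricted scans (`region_spec("tss", -500, 500)` for a minimal
promoter, `region_spec("pre5", -3000, 5000)` for the precursor
neighbourhood) clip the region to the window and keep a hit iff its first
base lies inside — a boundary convention that makes region counts partition
exactly: summing hits over a partition of the window reproduces the
whole-window count, which the test suite checks as an invariant.

## Matchers and the algorithm switch

Two matchers produce bit-for-bit identical hit lists:

* `scan_brute()` tests every offset, vectorised position-wise over the text;
* `scan_bm()` runs a Boyer–Moore search (bad-character rule) for the
  matrix's longest invariant core run (CCAAT for the NF-Y matrix), extends
  each candidate to the full matrix window and validates it under the
  policy; the reverse strand is scanned with the reverse-complemented
  matrix, whose core run is ATTGG.

Brute force wins on short texts, the anchored search on long ones;
`choose_algorithm()` switches at 32768 bp (a power of two inside the
30–40 kb band where the two approaches trade places; overridable via
`--bm-threshold`). A matrix whose longest singleton core run is shorter
than 3 gains nothing from anchoring and falls back to brute force with a
notice. Before any scan, a containment prescreen checks that the core (or
its reverse complement) occurs at all in the sequence — a necessary
condition, so a `FALSE` skips the sequence outright.

Scan timings (`elapsed_ms`) are recorded per locus because they are part of
the output contract, but they are the only nondeterministic field and are
excluded from every equality test.

## The synthetic locus generator

`simulate_locus_set()` builds a desk-scale stand-in for a genome-wide locus
database with exact ground truth. Per locus: one contig, strand drawn at
random, an 80 bp pre-miRNA, background bases i.i.d. at GC 0.41 (the human
genome average), a TSS annotated with probability 740/939 (the fraction of
loci with a miRStart-style TSS in the genome-wide annotation this emulates)
at a uniform distance upstream of the precursor, and 0–3 planted sites drawn
from the matrix's accepted set. Default windows are scaled to 600 bp
upstream / 50 bp downstream so the whole fixture pipeline runs in seconds;
pass `up = 60000, down = 5000` for full-size windows. These values were
fixed once as the study conditions of the simulator and are not tuned.

Exactness of the truth rests on two constraints: the background is kept free
of the core in both orientations by rejection resampling, and planted site
strings are restricted to those containing exactly one core occurrence
across both orientations (junction-created cores are detected and
re-drawn). Every hit then corresponds to exactly one planted site, so
recovered set = planted set, and the suite asserts precision = recall = 1.

What the generator does *not* emulate: real genomes are not i.i.d. — they
carry repeats, CpG islands, and core occurrences that fail the flank rule;
real windows overlap when miRNAs cluster; real TSS annotation is noisy.
Passing the planted-recovery tests therefore demonstrates correctness of
the matcher and the coordinate algebra, not biological performance on hg19.

## Worked-example tables and two data notes

The package ships three curated tables (`example_tables()`): CCAAT matrices
found in the minimal promoters (−500..+500 bp of the TSS) of four
in-vivo-validated miRNA clusters, CCAAT matrices within 5 kb downstream of
six validated pre-miRNAs, and a literature compilation of mature miRNAs
up-regulated in colorectal cancer. They are transcribed verbatim from their
published source, which implies two documented quirks:

1. Two promoter-table entries (`ataattggttt` at mir-181a2/181b2 and
   `atcccaatcat` at mir-21) have flank identity 4/6 in both orientations and
   are therefore *not* accepted by the stated >82% rule; the classifier
   honestly counts 2 of 3 for the mir-21 row where the printed per-row count
   is 3. The package keeps the stated rule rather than bending it to the
   printed rows.
2. The compilation table as printed contains 114 distinct mature-miRNA
   names although its caption says 118; the transcription preserves the
   printed rows. One downstream-table entry (`gggccaatga`) is printed one
   base short of the matrix length; it is kept verbatim and is usable with
   the core-containment check though not with the fixed-length classifier.

## A short worked example

```{r example}
sim <- simulate_locus_set(n_loci = 6, seed = 7)
win <- extract_windows(sim$loci, sim$genome, up = sim$up, down = sim$down)
res <- scan_windows(win, ccaat_matrix(), match_policy())
glance(res)
tidy(res) |> select(accession, offset, strand, matched, rel_pre5, rel_tss)
```

Every reported hit is a planted one:

```{r truth}
all.equal(
  tidy(res)[c("accession", "offset", "strand")] |> arrange(accession, offset),
  sim$truth[c("accession", "offset", "strand")] |> arrange(accession, offset),
  check.attributes = FALSE
)
```

## Known limitations

* Set-membership only; no PWM scores, no TRANSFAC/JASPAR import.
* Single-pattern scanning (brute force or anchored Boyer–Moore); no
  multi-pattern automata or genome indexes — deliberately, since the
  matcher pair *is* the method.
* Annotation and genome are user-supplied files; there are no download
  clients, and genome-wide results depend entirely on the assembly and TSS
  annotation chosen.
* Whether a published minus-strand window was reverse-complemented is not
  resolvable from printed tables; this package fixes the convention
  (transcript orientation everywhere) and documents it.
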