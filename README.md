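# lociscan

Genome-wide scanning of degenerate DNA consensus matrices across
miRNA-anchored genomic windows.

## What it is for

Transcription factors such as NF-Y recognise short, partially degenerate
motifs — for NF-Y the CCAAT pentanucleotide in either orientation (CCAAT /
ATTGG), with preferences in the flanking bases. `lociscan` is for asking, at
locus scale, *where* such a motif occurs around microRNA genes: it builds a
local database of ~65 kb windows (60 kb upstream of each pre-miRNA 5' end,
5 kb downstream of its 3' end) from a genome FASTA and miRBase/miRStart-style
annotation, scans a user-defined consensus matrix over every window on both
strands, and reports each hit as a signed distance from the pre-miRNA or its
transcription start site (TSS). It is aimed at regulatory-genomics users who
want exhaustive, reproducible motif maps over miRNA loci — including motifs
not represented in TRANSFAC/JASPAR — rather than PWM scores.

## The model

A consensus matrix of length `L` (4–30) assigns each position an allowed
set over {A,C,G,T}, written as an IUPAC string, with an invariant **core**.
The canonical NF-Y matrix is `D/V/V/C/C/A/A/T/S/N/V` (D = A/G/T,
V = A/C/G, S = C/G, N = any), core CCAAT at positions 4–8. A site `x`
matches when

* every core position has `x_j ∈ S_j` (no mismatch ever), and
* the flank identity — matching non-core positions / total non-core
  positions — is **strictly > 0.82** (for this matrix: ≥ 5 of 6 flanks),

or, alternatively, under a max-mismatch policy (`≤ k` mismatches at chosen
positions). With `strands = "both"` the reverse-complemented matrix
(`B/N/S/A/T/T/G/G/B/B/H`) is scanned too and such hits are reported on the
`-` strand. Two matchers produce bit-for-bit identical results: a
brute-force scan of every offset, and a Boyer–Moore (bad-character)
search anchored on the invariant core with full-window validation;
selection is automatic at 32768 bp. A core-containment prescreen skips
sequences that cannot contain a hit.

## Worked example

Simulate a small locus set with planted CCAAT matrices and exact ground
truth, extract windows, and scan:

```r
library(lociscan)
library(dplyr)

sim <- simulate_locus_set(n_loci = 6, seed = 7)
win <- extract_windows(sim$loci, sim$genome, up = sim$up, down = sim$down)
res <- scan_windows(win, ccaat_matrix(), match_policy())
res
#> <scan_result> NF-Y CCAAT over 6 loci (whole window): 12 hits, 0 skipped

glance(res)
#> # A tibble: 1 × 6
#>   n_loci n_skipped total_hits min_hits max_hits matrix_length
#>    <int>     <int>      <int>    <int>    <int>         <int>
#> 1      6         0         12        0        3            11

tidy(res) |> select(accession, offset, strand, matched, rel_pre5, rel_tss)
#> # A tibble: 12 × 6
#>    accession offset strand matched     rel_pre5 rel_tss
#>    <chr>      <int> <chr>  <chr>          <dbl>   <dbl>
#>  1 SIM0001       28 -      GCGATTGGTGT     -572    -479
#>  2 SIM0001      272 +      TCACCAATCTA     -328    -235
#>  3 SIM0001      550 +      GCACCAATAGG      -50      43
#>  4 SIM0003      292 +      TGACCAATAGA     -308      71
#>  ...
```

Each row is one matrix occurrence: `offset` is the 0-based position of the
hit's first base in the window, `strand` its orientation relative to the
window, `matched` the window-orientation sequence, and `rel_pre5`/`rel_tss`
the signed distance from the pre-miRNA 5' end and the TSS (negative =
upstream; `NA` when the locus has no annotated TSS, as for SIM0006 above).
Because the simulated background is core-free, these 12 hits are exactly
the planted sites — the test suite asserts precision = recall = 1.

Classifying individual sites shows the policy at work:

```r
classify_sites(c("tatccaatccc", "ataattggttt"), ccaat_matrix(),
               match_policy(), detail = TRUE)
#> # A tibble: 2 × 6
#>   site        forward reverse match strand flank_identity
#>   <chr>       <lgl>   <lgl>   <lgl> <chr>           <dbl>
#> 1 tatccaatccc TRUE    FALSE   TRUE  +               0.833
#> 2 ataattggttt FALSE   FALSE   FALSE <NA>           NA
```

`tatccaatccc` passes with 5/6 flanks (0.833 > 0.82); `ataattggttt` has only
4/6 in either orientation and is rejected.

The same pipeline is available from a shell via `exec/lociscan`:

```sh
lociscan simulate --n 8 --seed 7 --out sim/
lociscan build-db --genome sim/genome.fa --loci sim/loci.tsv --up 600 --down 50 --out db/
lociscan scan --db db/ --matrix DVVCCAATSNV --min-identity 0.82 \
  --region tss:-500:+500 --out hits.tsv --skips skips.tsv
lociscan report --hits hits.tsv --summary summary.tsv --anchor tss --bin 100
```

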