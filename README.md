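# wavealign

Batched one-to-one pairwise **local alignment** of DNA and protein
sequences for R, built for pipelines that need the optimal score and the
start/end coordinates of millions of alignments — but not the residue-level
traceback. Typical users: metagenome assembly validation (reads vs the
contigs assembled from them) and protein-similarity network construction
(candidate pairs filtered upstream), where sequence `i` of one set is
aligned only to sequence `i` of the other.

## The algorithm

The core is Smith–Waterman with Gotoh affine gap scoring. For query
*Q* (length *n*) and reference *R* (length *m*):

```
E[i,j] = max(E[i,j-1] - g_ext,  H[i,j-1] - g_open)
F[i,j] = max(F[i-1,j] - g_ext,  H[i-1,j] - g_open)
H[i,j] = max(E[i,j], F[i,j], H[i-1,j-1] + S(q_j, r_i), 0)
```

with zero first row/column; the optimal local score is max H. Three design
elements distinguish the implementation:

* **Anti-diagonal wavefronts, two-diagonal storage.** The table is swept
  diagonal by diagonal; only the two most recent H diagonals, the E/F
  carries and per-column running maxima are kept — six integers per query
  column, so working memory is O(|Q|) regardless of reference length.
* **Traceback-free start recovery.** After the forward sweep finds the
  best cell, the prefixes ending there are reversed and re-scored with the
  same kernel; by the symmetry of the optimal alignment the reverse best
  cell yields the start coordinates. No traceback matrices are ever stored.
* **A scheduling-invisible batch driver.** One call validates the batch,
  splits it evenly across abstract workers, chunks each share
  (default 20,000 pairs), and reassembles results in input order — worker
  count and batch size never change a single output bit.

DNA mode takes match/mismatch/gap scalars (defaults 6/4, gaps 4/1);
protein mode takes an NCBI-format substitution matrix (BLOSUM62 shipped,
gaps 6/1). A length-1 gap costs `gap_open` alone. Coordinates are 0-based
inclusive; unaligned pairs carry −1 sentinels.

An independent full-matrix oracle (`full_matrix_align()`), a synthetic
mutated-substring pair generator (`simulate_pairs()`), and a Binary
Masking Array model of the wavefront's active-column window
(`bma_init()`/`bma_step()`) ship in the package and back the test suite.

## Worked example

```r
library(wavealign)

# one pair: where does the query land in the reference?
align_pair("CGT", "AACGTAA", dna_scheme())
#> <pairwise_alignment> score 18, query [0, 2], ref [2, 4]
```

Score 18 is three matches at +6; the query aligns in full (query 0–2)
starting at reference position 2, all 0-based inclusive.

```r
# a batch: generated read-vs-contig pairs, aligned one-to-one
pairs <- simulate_pairs(5, query_len = c(20, 30), ref_len = c(60, 90),
                        identity = 0.9, indel_rate = 0.02, seed = 42)
res <- align_pairs(pairs, dna_scheme())
res
#> # A tibble: 5 × 9
#>   pair_index query_id ref_id score query_start query_end ref_start ref_end
#>        <int> <chr>    <chr>  <int>       <int>     <int>     <int>   <int>
#> 1          0 q0       r0        96           0        19        48      67
#> 2          1 q1       r1       160           0        29         9      38
#> 3          2 q2       r2       134           0        28         9      36
#> 4          3 q3       r3       137           0        24        29      57
#> 5          4 q4       r4       144           0        23        38      61
#> # ℹ 1 more variable: aligned <lgl>

glance(res)[, 1:6]
#> # A tibble: 1 × 6
#>   n_pairs n_aligned n_failed mean_score max_score total_cells
#>     <int>     <int>    <int>      <dbl>     <int>       <dbl>
#> 1       5         5        0       134.       160        9653
```

Each row is one pair: `q1`'s 30-residue query scores 160 — below the
perfect-substring score of 180 because of the mutations the generator
applied — and every query locates its source interval in its reference. `write_results(res, path)`
serialises the table as TSV; `read_sequences()` +
`pair_sequences()` build batches from FASTA/FASTQ files. A command-line
front end with `dna`, `protein` and `simulate` subcommands is installed at
`system.file("cli", "wavealign", package = "wavealign")`.

## Scope

No CIGAR/traceback output (by design), no SAM/BAM writing, no banded or
heuristic variants, no quality-aware scoring. See the methods vignette
(`vignettes/wavefront-alignment.Rmd`) for the model, tie-break and
degenerate-input choices, and known limitations.
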