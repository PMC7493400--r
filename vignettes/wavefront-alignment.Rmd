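---
title: "Wavefront local alignment: model, contracts and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefront local alignment: model, contracts and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavealign)
```

## The problem

Large genomics and proteomics pipelines — read-to-contig validation in
metagenome assembly, candidate-pair scoring in protein family detection —
need millions of *one-to-one* pairwise local alignments: sequence `i` of a
query set against sequence `i` of a reference set, never all-against-all.
For these uses the optimal score and the start/end coordinates of the
alignment are needed, but the residue-level alignment (the CIGAR) usually is
not. wavealign implements a batched Smith–Waterman aligner specialised for
exactly that contract: affine-gap local alignment of DNA or protein pairs,
computed by anti-diagonal wavefronts in linear working memory, with start
coordinates recovered by a second scoring pass instead of a traceback.

## Scoring model

For query $Q = q_1 \ldots q_n$ and reference $R = r_1 \ldots r_m$, the
Gotoh formulation tracks three tables:

$$E_{ij} = \max(E_{i,j-1} - g_{ext},\; H_{i,j-1} - g_{open})$$
$$F_{ij} = \max(F_{i-1,j} - g_{ext},\; H_{i-1,j} - g_{open})$$
$$H_{ij} = \max(E_{ij},\; F_{ij},\; H_{i-1,j-1} + S(q_j, r_i),\; 0)$$

with the first row and column of all three tables zero. $E$ and $F$ carry
gaps in the reference and query respectively and are *not* floored at zero;
only $H$ is. The optimal local score is $\max_{ij} H_{ij}$.

Conventions that matter, fixed once and used everywhere:

* **Penalties are magnitudes.** `gap_open` and `gap_extend` are non-negative
  and subtracted. A length-1 gap costs `gap_open` alone; a length-$k$ gap
  costs `gap_open` + $(k-1)$ `gap_extend`. Some libraries charge
  open + extend for the first gap residue; to reproduce their scores here,
  lower their opening penalty by one extension (the Biostrings
  cross-check test in this package does exactly that).
* **Coordinates** are 0-based inclusive; query residues index columns,
  reference residues index rows. A zero score is reported as
  `aligned = FALSE` with −1 sentinels rather than a degenerate alignment at
  the origin.
* **Ties** are broken deterministically: within a column the running
  maximum keeps the smallest row (strict-greater updates); across columns
  the smallest column wins.
* **Defaults** are the conventional benchmark settings: DNA match 6,
  mismatch 4, gap open 4, gap extend 1; protein BLOSUM62 with gap open 6,
  gap extend 1. The packaged BLOSUM62 is the canonical NCBI file (24
  residues).
* **Ambiguity codes.** DNA IUPAC codes (N, R, Y, …) are accepted and score
  as a mismatch against everything, including themselves — a conservative
  choice, since there is no standard for scoring ambiguous bases with
  scalar match/mismatch scoring. Protein ambiguity codes (B, Z, X, \*) use
  the matrix's own rows.
* **Scores are 32-bit integers.** Narrower cell storage is a memory
  optimisation for accelerator hardware, not part of the scoring semantics;
  wide integers remove overflow hazards for long references.

## The wavefront sweep and the activity model

All cells on an anti-diagonal $I = i + j$ are mutually independent, so the
table can be computed diagonal by diagonal. Each cell needs only the two
previous diagonals, so the engine stores per query column: two H diagonals
(the freshly written diagonal overwrites the one two steps back), the E and
F carries, and the running column maximum with the row that first attained
it — six integers per column, verified by instrumentation
(`attr(forward_score(...), "work_ints")`). The reported result is the
reduction of the column maxima under the tie-break above, which is provably
identical to scanning a full table.

The set of *active* columns on diagonal $I$ is
$\{\max(0, I-m+1), \ldots, \min(I, n-1)\}$: it grows by one column per
iteration while $I < n$, stays at full width $n$ while $n \le I < m$, and
shrinks while $I \ge m$. `active_range()` states this analytically. The
Binary Masking Array (`bma_init()` / `bma_step()` / `bma_active()`) models
the same window the way a lock-step parallel implementation tracks it: a
bit array of length $3n$, initialised with ones at positions $n \ldots 2n$,
column $j$ reading bit $2n + j$, shifted right by one exactly when
$C = (I < n) \lor (I \ge m)$ holds. The literal shift rule clears the
leftmost column's bit one iteration late in the shrinking region; a
lock-step lane also masks itself after computing the last cell of its
column, and `bma_step()` models that completion masking too. With both
rules the bit-set equals `active_range()` for every iteration — the package
asserts this exhaustively for all $1 \le n \le m \le 40$. The BMA is a
tested *model* of the schedule, not the runtime mechanism: the kernel may
compute each diagonal in any order, and all results are bit-identical to
the contract regardless.

The engine maps the shorter sequence to the columns (`forward_score()`
errors if `|Q| > |R|`; the user-facing `align_pair()`/`align_pairs()` swap
roles internally and transpose the coordinates back, so the public contract
is symmetric).

## Start recovery by reverse scoring

An optimal alignment is symmetric: scoring the two sequences reversed
yields the same optimal alignment. After the forward phase finds the best
cell $(q_e, r_e)$, the prefixes ending there are reversed and re-scored
with the same kernel. The reverse maximum must equal the forward maximum —
the engine treats any deviation as an internal error, so every successful
run is itself a proof of the symmetry property — and the reverse best cell
$(a, b)$ gives the start: $q_s = q_e - a$, $r_s = r_e - b$. Only the
prefixes are re-scored, never the whole sequences (re-scoring whole
reversed sequences could surface a different local optimum elsewhere), so
the reverse pass never does more work than the forward pass.

Two subtleties were settled during design:

* **Orientation of the reverse pass.** The reversed query prefix can be
  longer than the reversed reference prefix. The kernel sweep is valid for
  any $(n, m)$, so the reverse pass keeps the query on the columns rather
  than swapping roles: swapping would flip which coordinate the tie-break
  minimises first, making the reported start depend on prefix lengths.
* **Which start, under ties.** When several optimal paths share the best
  end cell, the reverse phase's reduction (smallest reverse column, then
  smallest reverse row) selects the start that is lexicographically
  *latest* in (query, reference). The independent full-table oracle
  implements exactly that definition — a memoised walk of the optimal-move
  graph maximising `(query_start, ref_start)` — rather than an arbitrary
  greedy traceback, so starts are comparable on every unique-optimum
  instance. When the maximum is attained at several cells, different
  optimal alignments genuinely exist and the reported start refers to the
  engine's tie-break; comparisons are therefore filtered to instances whose
  maximum is attained at exactly one cell (`n_optimal_cells == 1`).

## The batch driver

`align_pairs()` is the single driver call: it validates the one-to-one
batch up front, splits the index range evenly across `workers` abstract
lanes (sizes differing by at most one, larger shares to lower lanes —
`partition_work()`), processes each share in sub-batches of `batch_size`
pairs (default 20,000, the batch size used in the accelerator experiments
this design derives from), and reassembles results in input order. Workers
and batch size are *scheduling parameters only*: the output is a pure
function of the pairs, the scheme and `with_start`, asserted by
byte-comparing TSV output across schedules. Physical accelerator
management — device discovery, per-device memory-based batch sizing, stream
overlap — is deliberately abstracted away; the contract is that completion
implies all results are final and ordered.

Per-pair failures (empty sequence, residue outside the alphabet) abort with
the pair index by default; `on_error = "permissive"` records an NA sentinel
row and continues, which pipelines aligning heterogeneous dumps need.
Throughput is reported as GCUPS = total cells / forward time / $10^9$,
where total cells is $\sum_i |Q_i| \cdot |R_i|$; it is informational, and
only the forward-only mode (`with_start = FALSE`) matches the metric's
definition.

## The synthetic generator

`simulate_pairs()` emulates the structure of the evaluation data this
design targets: each query is a mutated substring of its reference, pairs
binned by query length. Defaults are a short-read bin — queries 150–200
drawn from references 99–779 — at identity 0.95 and indel rate 0.01,
a typical error profile for reads aligned back to contigs assembled from
them. Substitutions are uniform over the alphabet minus the original
residue; indels are length 1, insertions and deletions equally likely —
the simplest model that exercises the E and F tables. The generator is
deterministic given a seed.

What it does **not** emulate: read-quality profiles, position-dependent
error rates, repeats and low-complexity tracts, or realistic residue
composition. Passing the oracle-equivalence suite on generated pairs
demonstrates *algorithmic correctness* on sequences of this shape; it says
nothing about biological sensitivity, which is a property of the scoring
model, not of this implementation.

## Numerical and degenerate-input choices

* Scores, coordinates and penalties are integers throughout; there is no
  floating point in the scoring path, so results are exactly reproducible
  across platforms.
* Empty sequences are rejected (there is no meaningful local alignment),
  distinct from the empty *batch*, which returns an empty result table.
* An all-negative substitution matrix legitimately yields score 0 /
  unaligned for every pair; the stress suite covers this.
* `gap_extend > gap_open` is unusual but admissible (the recurrence simply
  re-opens rather than extends); the constructor warns and proceeds, and
  the stress grid covers it.
* No hard cap is placed on query length; `warn_query_len` (default 1024,
  a common lock-step lane-count limit) flags inputs outside the design
  envelope without refusing them.

## Problem sizes used in the shipped checks

The validation corpus aligns 1,000 generated pairs (queries 20–300,
references up to 1,200; identities 0.6–1.0; indel rates 0–0.1) across the
default DNA and protein schemes and both stress grids, each checked
exactly against the full-matrix oracle; the scheduling check aligns a
10,000-pair batch under two worker/batch configurations and compares TSV
bytes; the BMA model is checked exhaustively to $40 \times 40$; the
throughput measurement uses a 20,000-pair forward-only run. These sizes
were chosen as the smallest that exercise every regime (growing/constant/
shrinking windows, swapped roles, tied optima, zero scores) with margin.

## Known limitations

* No residue-level traceback, by design: the result is score plus
  coordinates. Pipelines needing a CIGAR must re-align the reported span
  with a traceback aligner.
* One worker semantics only: the abstract lanes define *how work is
  split*, not a parallel runtime. The R implementation processes lanes
  sequentially; the contract makes any future concurrent execution
  observationally invisible.
* Scoring is quality-unaware (FASTQ qualities are read and discarded) and
  position-independent (no profiles, no context-dependent scoring).
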