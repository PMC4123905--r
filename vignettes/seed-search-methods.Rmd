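---
title: "Score-adaptive seed search with paired suffix arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-adaptive seed search with paired suffix arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsearch)
```

## The problem and the model

Metagenomic analyses translate DNA reads into protein space and assign them
to families by homology search. BLASTX-style tools dominate this step, and
its cost is dominated by seeding and ungapped extension. `saxsearch`
implements a seed-and-extend engine whose seeding stage differs from
BLAST's in one essential way: seeds have no fixed length. A seed is a pair
of equal-length substrings, one from a query and one from the database,
extended one residue at a time until the substitution score of the pair
reaches a threshold `t_seed`. A low-information 3-mer such as `AAA`
(self-score 12 under BLOSUM62) can never seed on its own, while `WWW`
(self-score 33) seeds immediately; intermediate pairs earn their way in by
growing. This lets the engine run a much higher effective seed threshold
than fixed-length seeding at the same sensitivity, so far fewer extensions
are attempted.

The search for all such pairs runs as one simultaneous depth-first descent
of two suffix arrays: one over the concatenated query frames
(`S_q = Q_0#Q_1#...`), one over the concatenated database chunk
(`S_db = P_0#P_1#...`). A search state is a pair of SA intervals — the set
of query suffixes and the set of database suffixes sharing the two matched
substrings — plus the accumulated pair score and the accumulated
exact-match (self) score of the query substring. Descending one level
extends both substrings by one symbol each, giving at most `|Σ|²` children;
each child's intervals come from binary-search narrowing (or, database-side
for the first five characters, a precomputed lookup table). The state space
is cut down by three rules, applied in this order after each extension:

1. **Emission.** If the pair score has reached `t_seed`, the cross product
   of the two intervals is emitted as coordinate seeds and the state is not
   extended further. Seeds are therefore *minimal-length* attainments of
   the threshold; anything longer is recovered by the extension stages.
2. **Dead pair.** If the score is ≤ 0 the state is dropped: any
   high-scoring longer pair through it would also be found from a later
   start position with a higher-scoring suffix.
3. **Score gap.** If the score lags the query substring's exact-match score
   by `d` or more (`score ≤ score_max − d`), the state is dropped. This is
   the sensitivity/speed dial: small `d` prunes aggressively.

A depth cap `length_max` bounds the recursion. With the BLOSUM62 diagonal
at ≥ 4 and `d = 4`, any state surviving rule 3 to depth 13 has score
≥ 4·13 − 4 + 1 = 49 and would have been emitted long before at the default
`t_seed = 30`, so the cap of 13 is non-binding at defaults; it is exposed
because other matrices or parameters could bind it.

Seeds then pass through X-drop **ungapped extension** (both directions
independently; a direction stops at a sequence boundary or when the running
score falls below `best − x_drop_ungapped`), a **chain filter** that merges
redundant same-diagonal extents (overlap, or a cheap intervening segment
scoring ≥ `−x_drop_ungapped`), and X-drop **gapped extension**: affine-gap
dynamic programming outward from an anchor cell, discarding cells that fall
more than `x_drop_gapped` below the running best. With an infinite dropoff
the gapped stage provably returns the optimal local alignment through its
anchor, which is how it is validated.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `t_seed` | 30 | raw score | balance of sensitivity and speed; the engine's central threshold |
| `d` | 4 | raw score | score-gap pruning bound |
| `length_max` | 13 | residues | non-binding at defaults (see above) |
| `x_drop_ungapped` | 20 | raw score | ≈ BLAST's 7-bit ungapped dropoff under gapped BLOSUM62 λ |
| `x_drop_gapped` | 38 | raw score | ≈ BLAST's 15-bit gapped dropoff |
| `gap_open`, `gap_extend` | 11, 1 | raw score | BLAST protein defaults; a gap of length L costs 11 + L |
| `l_db` | 2³¹−1 | residues | chunk budget; positions are 32-bit |
| `max_targets` | 10 | subjects | short-read workloads rarely need more |
| `evalue_max` | 10 | — | conventional report threshold |
| `block_size` | 2000 | frames | query batching; output-neutral (asserted by test) |
| `max_interval_product` | ∞ | seeds/state | guard against low-complexity blowup, off by default |

Raising `t_seed` can only shrink the seed set; raising `d` can only grow
it. Both monotonicities are asserted as tests, since they are the mechanism
by which the parameter grid trades sensitivity for time.

## Statistics

E-values are computed as `E = K·m·n·exp(−λS)` with `m` the query frame
length in residues, `n` the **total** database residue count (summed over
chunks, which keeps results invariant under chunking), and the standard
published gapped constants for BLOSUM62/11/1 (λ = 0.267, K = 0.041),
configurable through `karlin_altschul_params()`. No BLAST-style
effective-length correction is applied: the correction needs the entropy
`H` of the scoring system and buys little at the short query lengths this
engine targets; the plain closed form keeps the statistic transparent and
exactly testable. Bit scores are `(λS − ln K)/ln 2`.

## Numerical and representational choices

* **Collation.** `#` (delimiter) < `*` (stop) < residues alphabetically.
  Any total order works — matching never crosses `#` — but a fixed order is
  required for reproducible arrays. The order chosen coincides with ASCII
  byte order, so reference implementations can sort raw bytes.
* **Delimiters are walls.** `#` scores one below the smallest matrix entry
  against everything, and in addition neither the seed walk nor any
  extension stage ever steps onto one. The penalty alone would not
  guarantee truncation (a state at score 33 would survive one −5 step), so
  the wall is structural, which is the only behaviour consistent with
  seeds never spanning two sequences. Stops (`*`) are kept in-frame and
  score like the delimiter but are *not* walls; rules 2 and 3 eliminate
  them organically.
* **Emission comparison.** "Score reaches the threshold" is implemented as
  `score ≥ t_seed`, centralized in a single predicate; the strict variant
  is a one-line change.
* **Intervals.** Half-open `[sp, ep)`, 1-based ranks; the empty interval
  is `sp == ep` and narrowing maps it to itself, which is also the fixed
  point the prefix table stores for absent keys.
* **Prefix table.** Keys are all residue strings of length 1–5 (20^k keys
  per depth); keys containing `X`, `*` or `#` fall back to binary-search
  narrowing. Table entries are defined as — and tested to be — exactly the
  result of iterated narrowing.
* **Chain filter geometry.** Only same-diagonal, same-query,
  same-subject extents are ever merged; cross-diagonal chaining is out of
  scope, and the intervening segment is scored as the plain ungapped pair
  score of the diagonal gap.
* **Gapped anchor.** The midpoint of the HSP's maximal-scoring sub-segment
  (max-subarray over per-position scores). The anchor pair is forced into
  the alignment; both half-extensions are corner-anchored DPs.
* **Tie-breaks.** Child states are generated in lexicographic
  (query symbol, database symbol) order; interval cross products expand in
  ascending rank order; result rows sort by bit score, then E-value, then
  subject id, then coordinates. Output is thereby deterministic, and
  asserted invariant under chunking, block size and thread count.
* **Degenerate inputs.** Empty query files yield empty results; empty
  intervals propagate silently; a sequence longer than `l_db` or a
  malformed FASTA/matrix file fails with the offending identifier.

## The synthetic-data generator

`make_protein_db()` draws i.i.d. residues from Robinson–Robinson background
frequencies — the standard protein null model — and `plant_queries()`
samples database segments, applies an exact count of point substitutions to
hit the requested identity, applies single-residue indels at a given rate,
and reverse-translates through uniformly chosen synonymous codons onto a
random strand. The truth table records source, interval, strand, and the
mutated protein, and tests assert the emitted reads are byte-reproducible
from it.

This emulates the *structure* of a metagenomic short-read search — reads
of ~150 nt at moderate divergence against a protein database — and supports
exact ground-truth checks (top-hit recovery, chunk invariance,
frame-consistency). It deliberately does not model sequencing error
profiles, quality scores, homopolymer artifacts, real domain architecture,
low-complexity regions, or compositional bias. Passing the planted-homolog
suites therefore demonstrates algorithmic correctness and sensitivity under
idealized divergence, not field performance on real metagenomes.

Validation problem sizes were chosen to keep the full suite fast while
leaving no stage untested at realistic shape: seed-oracle equivalence runs
on 100 random concatenated texts of up to ~500 residues per side across the
`t_seed ∈ {22, 26, 30} × d ∈ {1, 4, 7}` grid plus low-complexity
adversaria; the end-to-end recovery fixture uses 500 proteins of 300
residues and 50 reads of 150 nt at 80% identity, cross-checked against a
full Smith–Waterman scan of every query frame against every subject.

## Known limitations

* No composition-based statistics, and no effective-length correction;
  E-values on real databases will differ from BLASTX's.
* Chaining is same-diagonal only; BLAST's two-hit policy and its final
  larger-dropoff re-alignment pass are not implemented.
* Chunks are capped at 2³¹−1 symbols by the 32-bit position encoding.
* The suffix array is plain (no compression or sampling); memory is
  ~5 bytes per database symbol plus the prefix table.
* One alignment is reported per non-overlapping region per
  query-frame/subject pair; containment-redundant sub-alignments are
  culled.
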