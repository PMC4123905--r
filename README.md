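# saxsearch

Translated protein homology search with paired suffix arrays — a
BLASTX-family seed-and-extend engine for R.

Metagenomic pipelines translate DNA reads in six frames and search them
against protein databases; the seeding and ungapped-extension steps
dominate the cost. `saxsearch` attacks the seeding step with
**score-adaptive variable-length seeds**: instead of fixed-length word
hits, a seed is a pair of substrings {database, query} grown one residue at
a time until its substitution score reaches a threshold *T*<sub>seed</sub>.
All such pairs are enumerated by a simultaneous depth-first descent of two
suffix arrays (query-side and database-side), with two pruning rules
bounding the walk:

* a pair whose score *s* satisfies *s* ≤ 0 is dropped;
* a pair whose score lags the exact-match (self) score of its query
  substring by at least *D* — *s* ≤ *s*<sub>max</sub> − *D* — is dropped.

Under BLOSUM62 an exact `AAA` match scores only 12 and can never seed at
the default *T*<sub>seed</sub> = 30, while `WWW` scores 33 and seeds
immediately — low-information hits are filtered out before any extension
work is spent on them. Emitted seeds are refined by X-drop ungapped
extension, merged by a same-diagonal chain filter, and finished with
X-drop gapped (affine) extension, producing standard 12-column BLAST
tabular rows with Karlin–Altschul E-values. Databases are split into
bounded-memory chunks whose union provably reproduces the unchunked
result, and a planted-homolog fixture generator provides exact ground
truth for end-to-end validation.

## Worked example

```r
library(saxsearch)

m <- load_score_matrix("BLOSUM62")
pair_score("AAA", "AAA", m)   # 12  -- can never seed at T_seed = 30
pair_score("WWW", "WWW", m)   # 33  -- seeds immediately
pair_score("A",   "R",   m)   # -1  -- dead on arrival (score <= 0 rule)

# a synthetic database with planted homologous reads
db_seqs <- make_protein_db(20, 200, seed = 5)
planted <- plant_queries(db_seqs, 3, identity = 0.9, read_len_nt = 150,
                         seed = 6)
db  <- build_index(db_seqs)
hits <- sax_search(planted$queries, db, m, search_params(),
                   query_type = "dna")
write_tabular(hits, "")
```

which prints (query, subject, %identity, length, mismatches, gap opens,
query start/end on the read, subject start/end, E-value, bit score):

```
read0001  dbseq0010  90.00  50  5  0    1  150  78  127  4.6e-24  95.1
read0002  dbseq0002  90.00  50  5  0    1  150  50   99  1.5e-22  90.1
read0003  dbseq0019  90.00  50  5  0  150    1  45   94  8.7e-23  90.9
```

Each read's true source is the top hit; `read0003` aligned through a
reverse-strand frame, so its read coordinates run 150 → 1. A command-line
front end wrapping the same functions ships at
`inst/scripts/saxsearch` (`saxsearch index …`, `saxsearch aln …`).

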