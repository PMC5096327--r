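# dbblastp

Database-indexed protein sequence search in R.

Classical protein BLAST builds a lookup table over the *query* and scans
every database sequence against it. `dbblastp` inverts that layout: it
builds a compressed inverted index over the *database* — the structure
that makes large-scale protein search cache-friendly — and searches it
with the standard seed-and-extend pipeline, producing BLAST-style local
alignments with Karlin–Altschul statistics. It is aimed at people working
on sequence-search methods: every stage is exposed as a testable function,
and brute-force reference implementations (full Smith–Waterman, the
classical query-indexed two-hit scan) ship alongside the engine so that
its heuristics can be checked against ground truth.

## What it implements

**Index.** The database is sorted by sequence length and partitioned into
blocks of at most `block_cap` letters (default 128 K), so block-local
sequence ids need only `ceil(log2(n_block))` bits and a block's index fits
in cache. Per block, all overlapping 3-mers are indexed; per word,
positions are sorted by subject offset, runs sharing an offset are merged
(offset and count stored once, then the sequence ids), and offsets are
delta-encoded into 8-bit increments. Entries that overflow the 8-bit
fields are split: increment 300 with 25 positions becomes `(255, 0)` +
`(45, 25)`; 300 positions at increment 2 become `(2, 255)` + `(0, 45)`.
Neighboring words (word pairs scoring ≥ T under BLOSUM62) are not
materialized; the lookup table stores per-word offsets into a shared
neighbor pool instead.

**Search.** For a query of length m, hits (subject offset s, query offset
p) are binned by diagonal d = s − p; a second binning pass regroups them
by sequence id with a last-hit array applying the two-hit rule (two hits
on one diagonal at distance `overlap ≤ d < window`, defaults 3 and 40).
Triggered seeds get ungapped X-drop extension along the diagonal; HSPs at
or above the gap trigger get affine-gap X-drop extension with traceback.
Scores are reported as bit scores `S' = (λS − ln K)/ln 2` and E-values
`E = K m′ n′ e^(−λS)` with the standard length adjustment. Results are
invariant to the block size and worker count, and the database-indexed
pipeline returns exactly the hits of the classical query-indexed scan —
these invariances are part of the test suite.

## Worked example

```r
library(dbblastp)

# a synthetic database of 200 proteins with 5 planted homolog pairs at 70 %
# identity; the generator returns the ground truth alongside the FASTA-able db
gen <- generate_database(synthetic_spec(n_sequences = 200, n_planted = 5,
                                        identity = 0.7, seed = 42))
db  <- sort_database(gen$db)
dbx <- index_database(db, block_cap = 131072)
#> <db_index> 200 sequences, 49902 letters, 1 blocks (cap 131072)

gen$truth[1, c("donor", "receiver", "target_identity")]
#>   donor    receiver target_identity
#> 1 SYN00096 SYN00086             0.7

query <- setNames(decode_residues(db$seqs[[match("SYN00096", db$meta$accession)]]),
                  "SYN00096")
res <- run_batch(query, dbx, search_params(), workers = 2)
res$hits[, c("query","subject","raw_score","bit_score","evalue",
             "identities","length","gaps")]
#>    query    subject  raw_score bit_score   evalue identities length  gaps
#>  1 SYN00096 SYN00086       329     131.  7.20e-34         81    122     5
#>  2 SYN00096 SYN00053        39      19.6 3.05e+ 0          8     23     0
#>  3 SYN00096 SYN00020        38      19.2 3.99e+ 0          6     16     0
#>  ...
```

The planted partner SYN00086 is reported first: raw score 329 (131.3
bits), E = 7.2e-34, 81 identities over a 122-column alignment with 5 gap
columns — i.e. 66 % identity, matching the planted 70 % target up to the
indels and local alignment trimming. Everything else is background noise
near the E = 10 reporting cutoff. `format_tabular(res)` prints the
familiar 12-column report:

```
SYN00096  SYN00086  66.393  122  36  5  31  151  170  287  7e-34  131.3
```

A command-line front end wrapping these functions (subcommands `gendb`,
`formatdb`, `sortdb`, `indexdb`, `search`) is installed at
`system.file("cli/dbblastp.R", package = "dbblastp")`.

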