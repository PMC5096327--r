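---
title: "Database-indexed protein search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Database-indexed protein search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dbblastp` searches a protein database with a *database index* rather than
the query index classical protein BLAST uses. This vignette describes the
data structures and the algorithm as implemented, the tunable parameters
and their defaults, what the synthetic data generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The index

**Blocking.** The database is sorted by sequence length (ascending, stable
in input order) and partitioned greedily into blocks capped at `block_cap`
letters (default 131072, i.e. 128 K). A sequence that would overflow the
cap starts the next block; an oversized sequence sits alone in its own
block, so no sequence ever spans two blocks. Blocking serves three
purposes: block-local sequence ids need only `ceil(log2(n_block))` bits
instead of `ceil(log2(n_database))`; length sorting keeps subject offsets
narrow in the blocks that hold short sequences; and one block's index is
small enough to stay cache-resident while every query is aligned against
it.

**Basic index and sorting.** Per block, every overlapping 3-mer over the
20-letter alphabet contributes one position `(sequence id, subject
offset)`. Windows touching a masked residue are skipped. Positions of each
word are then sorted by `(subject offset, sequence id)`. Sorting is what
makes the two compression steps possible and makes posting-list traversal
emit hits in subject-offset order, so first-level bin writes are
sequential.

**Compression.** Runs of positions sharing a subject offset merge into one
entry that stores the offset once, the run length, and the run's sequence
ids. Offsets are then stored as 8-bit increments from the previous entry's
absolute offset; the count field is also 8 bits. Entries that do not fit
are split: an increment above 255 is preceded by padding entries `(255,
0)` carrying offset only, and a count above 255 is emitted as maximal
255-count entries first, the increment on the first. Decoding is stateless
per word because the first increment is measured from absolute offset 0.
Losslessness — `decode(compress(x)) == x` for every word — is enforced by
fuzz tests, and the engine's C++ decoder is property-tested against the
R-level reference codec.

**Neighbor indirection.** Protein seeding matches *neighboring words*
(word pairs whose substitution score reaches the threshold `T`), which
would inflate a materialized index by an order of magnitude. Instead, the
lookup table stores, per word, offsets into a shared pool of neighbor word
ids; hit detection walks the posting runs of the word itself and of each
neighbor. A test asserts that the hit multiset equals a brute-force scan
of all query-word x subject-word matches, which is exactly what a
materialized-neighbor index would produce.

## The search

**Hit detection and two-level binning.** For each query position `p`, the
decoded positions `(id, s)` of the query word and its neighbors become
hits on diagonal `s - p`. First-level bins are indexed densely by
`diagonal + query_len - 1`. Second-level binning scans first-level bins in
ascending diagonal order and regroups surviving hits by sequence id, so
each second-level bin arrives naturally sorted by diagonal.

**Two-hit filter.** While scanning, a last-hit array keyed by sequence id
records the most recent hit (diagonal, offset). A hit on the same diagonal
whose distance `d` to the last hit satisfies `overlap <= d < window`
(defaults `3 <= d < 40`) is emitted as the *triggering* hit of a two-hit
pair; the record is always updated. Two consequences of the always-update
rule are worth knowing. First, it makes the filter exactly equivalent to
the classical query-indexed last-hit scan, which is verified
property-style on synthetic batches. Second, a *dense* same-diagonal hit
run — an exact repeat, where every word matches at spacing 1 — never
reaches the distance threshold and emits no trigger, a sensitivity trade
the two-hit heuristic makes by construction. The spec-level alternative
(skipping the update for overlapping hits) would restore those seeds but
is not what the two-level binning contract prescribes; sequences similar
at realistic identity levels (the synthetic default is 60 %) seed
normally, because substitutions break up the hit runs.

**Ungapped extension.** Each emitted pair seeds an X-drop extension along
its diagonal from the triggering word, left then right (default X-drop 7
bits, converted to a raw score with the ungapped Karlin–Altschul lambda).
Per (sequence, diagonal), a seed that does not pass the right end of the
previous extension on that diagonal is skipped; because same-diagonal
seeds are processed in ascending offset order in both the indexed engine
and the query-indexed oracle, this gating is order-independent and the two
pipelines remain comparable hit for hit. HSPs scoring below
`ungapped_cutoff` (default: the gapped trigger, 22) are dropped.

**Gapped extension.** HSPs at or above `gap_trigger` are extended with an
affine-gap X-drop dynamic program (default 15 bits; `Inf` disables
pruning) seeded at the midpoint of the HSP's best-scoring 11-column
window. The DP runs in two halves (left of the seed on reversed prefixes,
right of it including the seed cell) and concatenates the tracebacks. A
gap of length L costs `gap_open + gap_extend * L` (defaults 11 + L). With
an unbounded X-drop the result equals the optimal local alignment
constrained through the seed cell, which is how the engine is tested
against the full Smith–Waterman oracle: reported scores may never exceed
the optimum, and must equal it on planted homologies whose optimum
traverses the seeded segment.

**Deduplication and ranking.** HSPs are deduplicated exactly, then
processed strongest-first (ties broken on coordinates); an HSP whose query
and subject spans both lie inside an already-kept alignment of the same
subject is skipped. Alignments are ranked by (E-value ascending, raw score
descending, accession ascending), truncated to `max_reported` (500). All
orderings are fully keyed, so output is deterministic.

**Statistics.** Bit scores are `(lambda * S - ln K) / ln 2`; E-values are
`K m' n' exp(-lambda S)` with the standard fixed-point length adjustment
`l = ln(K m' n') / H`. Only published constants are embedded (BLOSUM62:
ungapped and gapped 11/1); any other matrix/gap combination is rejected
with an error rather than extrapolated. Composition-based score
adjustment is deliberately out of scope, so E-values follow plain
Karlin–Altschul statistics.

**Batch orchestration.** `run_batch()` walks blocks in the outer loop and
queries in the inner loop, so all workers (forked processes) share one
index block at a time; hit detection and ungapped extension produce
per-(query, block) HSP partials. Partials are merged across blocks, and
gapped extension with traceback runs once per query on the merged
survivors against the whole-database search space. Because all
per-sequence state is block-local, sequences never span blocks, and every
ordering is deterministic, the final report is invariant to the block cap
and the worker count — both properties are asserted byte-for-byte in the
tests. Traceback after the cross-block merge (rather than per block) was
chosen because the per-block alternative computes identical alignments
redundantly before deduplication; either order yields the same output.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `W` | 3 | residues | protein word length |
| `T` | 11 | raw score | neighbor threshold; the conventional BLASTP value |
| `window` | 40 | residues | max two-hit distance on a diagonal |
| `overlap` | `W` | residues | min two-hit distance (non-overlap rule) |
| `xdrop_ungapped_bits` | 7 | bits | converted via ungapped lambda |
| `gap_trigger` | 22 | raw score | HSP score that triggers gapped extension |
| `ungapped_cutoff` | `gap_trigger` | raw score | HSP reporting floor |
| `xdrop_gapped_bits` | 15 | bits | `Inf` = exact DP through the seed |
| `gap_open`, `gap_extend` | 11, 1 | raw score | gap of length L costs 11 + L |
| `evalue_cutoff` | 10 | — | reporting threshold |
| `max_reported` | 500 | alignments | per query |
| `block_cap` | 131072 | letters | 128 K; raise for single-threaded runs |

`window`, `overlap`, `T`, and the X-drops are seeding/extension
conventions rather than fitted quantities; they are exposed because
sensitivity/speed trade-offs differ between use cases.

## The synthetic generator

`generate_database()` draws i.i.d. sequences from the Robinson–Robinson
background composition with log-normal lengths (default `meanlog =
log(230)`, `sdlog = 0.45`) truncated to 60–1000 residues, the range where
real protein databases concentrate. Homology is planted pairwise: a donor
segment (default 120 residues) is copied into a receiver after exactly
`round((1 - identity) * L)` point substitutions (background-weighted,
never silent) and a small number of single-residue indels (rate 0.02 per
position). Indel sites keep a 4-residue margin from every substitution and
from each other, so the measuring alignment cannot trade a gap for
mismatch runs; a gap sliding inside identical context leaves the match
count unchanged. The post-hoc measured identity of planted segments (by
global alignment of the two segments, matches over aligned pairs) is
asserted to stay within ±2 % of the target.

What the generator does *not* emulate: domain architecture, low-complexity
and repeat regions, compositional bias, realistic indel length
distributions, and families larger than two. Passing tests therefore
demonstrate algorithmic correctness (equivalences, losslessness,
invariances, optimality bounds) on homologies of controlled identity —
not retrieval performance on real databases.

## Numerical and degenerate-input choices

- Residues outside the 20-letter alphabet map to a mask code scoring -1
  against everything; masked windows are never indexed or seeded. The
  ambiguity letters X/B/Z/U/* mask silently; anything else masks with a
  warning. Only the 20 canonical residues are indexable; the lookup table
  has 20^3 entries.
- All offsets are 0-based; spans are half-open internally and printed
  1-based inclusive in reports.
- The first compressed increment of every word is measured from absolute
  offset 0, making per-word decoding stateless.
- Ties: sorting is stable everywhere; the best DP cell is the earliest in
  row-major order; diagonal moves win score ties in tracebacks; gap
  openings win ties against extensions.
- Queries shorter than `W` warn and return no hits. Blocks whose
  sequences are all shorter than `W` produce an empty (but valid) index.
- X-drop bit values of `Inf` are mapped to effectively unbounded raw
  drops, turning both extensions into exact DP.

## Test scale

The property suites run at sizes chosen to exercise every code path while
keeping a full check fast on one core: 200 fuzzed blocks for
losslessness, 50 synthetic query/database pairs for the seeding
equivalences, a 2000-sequence database (about 0.5 M letters) for block
invariance at caps 1 K/8 K/128 K, and a 50-sequence database for the
Smith–Waterman bound, where the oracle's O(mn) R implementation is the
limiting cost.

## Known limitations

- Exact repeats and near-identical duplicates may produce no two-hit
  trigger on their main diagonal (see the filter discussion above).
- E-values use plain Karlin–Altschul statistics with length adjustment;
  no composition-based rescaling is applied, so E-values differ from
  tools that apply it even when the alignments coincide.
- Karlin–Altschul constants are embedded only for BLOSUM62 (ungapped and
  11/1 gapped); other combinations error out by design.
- The index is memory-resident; databases whose index exceeds memory are
  out of scope, as are nucleotide searches, PSSMs, and iterative search.
- SEG-style low-complexity filtering is not applied; the masking hook is
  the residue-level mask code only.
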