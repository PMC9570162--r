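---
title: "Methods: k-mer dot-plot alignment and contig ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer dot-plot alignment and contig ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigdot)
```

## The problem

After a de novo assembly, a set of contigs has no defined order or
orientation. When a genetically close reference genome exists, placing each
contig against that reference answers the practical questions quickly: where
does each contig belong, which strand is it on, how much of it actually
matches, and in what order should the contigs be read? `contigdot` does this
placement with exact k-mer matching only — no mismatches, no gaps — and
renders the classical dot-plot view: reference position on x, stacked query
position on y, forward matches as ascending blue diagonals, reverse matches
as descending red diagonals.

The pipeline has three stages, each of which refines the previous one:

1. **Basic alignment** — find every maximal exact match between each query
   and the reference, on both strands.
2. **Optimal tiling** — resolve overlapping matches so each reference
   region is explained by a single best segment per query.
3. **Rearrangement** — rank the queries by percent similarity and reorder
   them for stacked display and FASTA output.

## Basic alignment: k-mer anchors and diagonal merging

The reference is indexed once: every substring of length $k$ that contains
no `N` is stored with all of its 0-based start positions. Each query is
then scanned twice — as given ($5'\!\to\!3'$) and reverse complemented
($3'\!\to\!5'$) — and every query k-mer found in the index produces an
*anchor*, one per reference occurrence. A repeated k-mer therefore
contributes all of its reference positions; this is deliberate, because
repeat structure is one of the things a dot plot is for, and capping
occurrences would hide it.

Anchors that lie on the same diagonal (constant
$\text{ref\_pos} - \text{query\_pos}$ on the scanned orientation) and whose
query positions step by one merge into a single segment: a run of $r$
consecutive anchors is one exact match of $r + k - 1$ bases. Because every
k-mer window inside an exact match is itself an anchor (the alphabet is
`A/C/G/T` after sanitization and `N` never matches), a merged segment is
exactly a *maximal* exact match of length $\ge k$: it cannot be extended by
a single base on either side. The test suite checks this equivalence
against a brute-force per-diagonal scan on hundreds of random sequence
pairs.

Reverse-strand segments are stored in forward-query coordinates plus a
strand flag. If the scanned (reverse-complemented) orientation matched at
$[s, e)$ of a query of length $L$, the reported interval is $[L-e,\,L-s)$,
and the invariant is
$\text{ref}[rs, re) = \mathrm{revcomp}(\text{query}[L-e, L-s))$.

Two user parameters control this stage:

* `k` (default **15**, accepted range 10–50 with a warning outside it) —
  the anchor size in bp. Small $k$ is more sensitive but quadratically
  noisier and slower; large $k$ misses diverged regions. At $k = 15$ a
  random 50 kb sequence contains almost no chance 15-mer collisions
  ($4^{15} \approx 10^9$), which is why it is the default working point.
* `threshold` (default `k`, must be $\ge k$) — minimum merged-segment
  length, in bp, kept for output. Raising it prunes short spurious
  segments; it can only remove segments, never add them (tested as a
  monotonicity property).

A related monotonicity property connects the two: the reference coverage of
the pre-tiling segment set is non-increasing in $k$, because any exact
match at $k+1$ is also one at $k$.

## Optimal tiling: greedy conflict resolution on the reference axis

Basic alignment typically explains one reference region several times.
The tiling stage walks the reference left to right: the unresolved segment
with the smallest `ref_start` opens a conflict; among it and every
remaining segment overlapping it on the reference, the *longest* is kept —
with exact matching, segment length is the alignment score, so "best" and
"longest" coincide. Losers overlapping the kept segment are removed whole,
never trimmed. Ties are broken deterministically: smallest `ref_start`,
then forward strand, then smallest `query_start`. The kept set is pairwise
disjoint on the reference and the procedure is idempotent.

Query-side overlap between kept segments is allowed: a genuine repeat can
place one query interval at two reference copies, and removing the second
placement would erase the repeat from the optimal plot. The consequence is
a definitional subtlety for the *mapped bases* count. Summing kept segment
lengths would count repeat-shared query bases twice and could push a
query's "mapped" total past its own length. `mapped_bases` is therefore
defined as the number of **distinct query bases covered by kept segments**
(the union of their query intervals). Whenever kept segments do not share
query bases — every non-repeat case, including the whole validation design
below — this equals the plain sum of lengths; in repeat cases it is the
smaller, meaningful number, and percent similarity stays bounded by 100.

The dynamic-programming weighted-interval-scheduling optimum is *not*
computed; the greedy sweep is the method. The test oracle for this stage is
an independently coded naive version of the same rule (quadratic pairwise
overlap checks, recomputed from scratch every round), not a DP neighbour.

## Similarity and rearrangement

A query's similarity is

$$\mathrm{sim} = \left\lfloor \frac{100 \cdot \text{mapped}}{\text{length}} \cdot 10^3 \right\rfloor / 10^3 \; \%$$

— truncated, not rounded, to three decimals, computed in exact integer
arithmetic. Truncation is the convention that keeps a printed figure from
ever overstating the exact ratio, and it is the only rule consistent with
pooling: a set of eight fragments individually printing 99.997/99.995 can
pool to 99.996 even though rounding the pooled exact ratio (99.99671…)
would print 99.997. The per-query denominator is the query's own length;
the overall figure pools mapped and total bases before truncating.

`rank_queries()` sorts by similarity (descending), then mapped bases
(descending), then input order — a stable sort, so equally similar queries
keep their input order. The ranked order is used bottom-to-top in the
stacked plot and first-to-last in the rearranged FASTA.

## Plotting and text outputs

Segments are drawn as line segments, not scatter points, since merged
matches are intervals; `point_size` controls optional endpoint markers and
`line_width` the segments. Queries stack along y in bands whose origins are
prefix sums of query lengths; thin dotted separators mark band boundaries,
without which multi-query plots are unreadable. Modes: `basic` plots every
merged segment, `optimal` the tiled segments, `rearranged` the tiled
segments in ranked stacking order (optionally coloured per query instead of
per strand, so the ordering is visible). Output formats are `pdf`
(default), `png`, `ps`, `svg`; rendering is deterministic — identical
inputs give byte-identical SVG.

Two text artifacts accompany the plots. The *optimal segment listing* has
one record per tiled segment: a header `>` *query id* `TAB` *initial
position* (1-based start on the original query) `TAB` *aligned position*
(1-based start on the reference), then the subsequence, reverse
complemented when the segment is on the reverse strand so that every
record reads in reference orientation. Tab-separated header fields keep the
file FASTA-adjacent and machine-parseable. The *rearranged FASTA* holds the
original full-length query sequences in ranked order with a
`similarity=` annotation in each header. All coordinates in text outputs
are 1-based inclusive (the internal convention is 0-based half-open).

## The synthetic validation design

The generator reproduces the split-and-shuffle experiment used to validate
the pipeline: draw a uniform-random `A/C/G/T` reference (no `N`), cut it
into $n$ consecutive fragments — first $n-1$ of size `chunk_size` (default
$\lfloor L/n \rfloor$), remainder in the last — and shuffle the fragment
order with a seeded permutation. Fragment ids are `<ref>_T0 … _T<n-1>` in
reference order. Because every fragment is an exact substring of the
reference, a correct aligner must recover each one as (essentially) a
single full-length segment, and overall similarity must come out at or
above 99.99 %.

What this emulates — and what it does not. The design tests coordinate
bookkeeping, strand handling, merging, tiling and the similarity
arithmetic on clean data. It does not emulate sequencing error,
inter-species divergence, `N` runs, or biased base composition; passing it
says nothing about sensitivity to mismatches (the method is exact by
construction, so diverged regions simply drop out of coverage as $k$
grows). Real chunking conventions can also differ: a fixed published chunk
size (e.g. 72,100 bp for an eight-way split of a 576,874 bp sequence) is
not $\lfloor L/n \rfloor$, which is why `chunk_size` is an explicit
parameter rather than a guess.

Problem sizes used by the shipped checks, chosen to exercise the documented
conditions while keeping a full run comfortably interactive: a 50 kb
reference, split 8 ways, for the headline experiment (repeated over a
20-seed panel with seeds 1–20 fixed in advance; boundary-spanning k-mer
coincidences can in rare seeds shave a few bases, so the panel requires
19/20 at $\ge 99.99$ %); one run at the full 576,874 bp / 72,100 bp-chunk
scale on a synthetic reference; oracle comparisons on 100 random pairs up
to 2 kb; and a 20 kb fixture with one substitution per ~150 bp for the
$k$-sweep monotonicity check over $k \in \{10, 15, 20, 30, 50\}$.

## Numerical and degenerate-input choices

* Similarity is computed as `(mapped * 1e5) %/% total / 1000`; both
  operands are exact integers well below $2^{53}$, so the floor is exact.
* A query shorter than `k` aligns to nothing (empty result, not an error);
  `threshold < k` is a parameter error, as is `k` outside
  `[1, reference length]`.
* Sanitization uppercases, maps `U` to `T`, strips whitespace, strips `-`
  with a warning, and maps every other letter (IUPAC ambiguity codes
  included) to `N`; non-alphabetic characters are a format error. `N`
  participates in no match on either side, so sanitized-in-place ambiguity
  never creates false anchors but preserves coordinates.
* Record identity is the first whitespace-delimited header token; the
  remainder is carried as a description and round-trips through the FASTA
  writer.
* Empty segment sets tile to an empty tiling with `mapped_bases = 0` and
  similarity `0.000`; a single query ranks as itself.
* The seeded generators restore the caller's RNG state, so library use
  never perturbs a user's simulation stream.

## Known limitations

* Exact matching only: a single mismatch splits a segment, so sensitivity
  to diverged references is governed entirely by `k`.
* Tiling is greedy, per query, and resolves conflicts only on the
  reference axis; it is not a global optimum over all queries jointly.
* One reference sequence per job (the first record of the reference FASTA
  is used, with a warning if more are present).
* Memory scales with the number of indexed k-mers (one entry per
  reference position); references in the tens-of-megabases range are the
  practical ceiling for the pure-R index.
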