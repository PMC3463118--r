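---
title: "splitmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splitmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

splitmap is a seed-and-extend DNA aligner for long reads and assembled
contigs whose distinguishing feature is *optimal split-alignment
selection*: instead of reporting one alignment per query, or all of them,
it selects the set of alignments that best covers the query under an
objective tuned to structural-variant (SV) breakpoint detection. This
vignette explains the model at each stage, the tunable parameters and their
defaults, the numerical conventions, what the bundled simulator does and
does not emulate, and the design choices made where the design was
genuinely open.

## The pipeline

A query passes through six stages.

**1. Seed lookup.** The reference is indexed once per parameter combination
`(k, skip, maxHits)`: every k-mer starting at positions `0, skip, 2*skip,
...` of each sequence is 2-bit encoded (A=0, C=1, G=2, T=3, first base most
significant) and its start offset recorded in a Reference Offset Array
(ROA), ascending per key. K-mers containing ambiguous bases are never
indexed or looked up. `k` ranges over 8–15 (keys must fit 30 bits); the
default is a "15/1" index. K-mers with more than `maxHits` reference hits
are dropped entirely, or — with sampling enabled — uniformly down-sampled
without replacement to exactly `maxHits`, reproducibly from the index's
RNG seed. The default `maxHits = 650` retains the overwhelming majority of
distinct 15-mers of a mammalian-scale genome while bounding the work spent
on high-copy repeats.

The conceptual hash array has one slot per possible key (`4^k`). At
`k = 15` a literal table of that size costs gigabytes, so the index stores
the occupied keys sorted, with CSR-style offsets into the ROA, and lookup
binary-searches the key array. Hit lists, their order and their content are
identical to the direct-address layout; only the lookup cost changes, from
O(1) to O(log #keys). The index persists to a self-describing little-endian
binary file (magic `SSIX`, versioned, parameters embedded) so an index can
never be silently reused with mismatched parameters. Only the forward
strand is indexed; minus-strand alignment re-runs the query's reverse
complement through the same machinery, which halves the index.

**2. Seed collation.** For a query of length QL, the hit lists of all its
k-mers are merged into a single stream sorted by (diagonal, query offset),
where `diagonal = referenceOffset - queryOffset`. Because each per-position
ROA slice is pre-sorted, the merge is a QL-way heap merge with at most one
live heap entry per query position — N log QL work for N seeds rather than
N log N — and the peak heap size is asserted in the tests. Seeds on one
diagonal whose query spans overlap or abut (`next.qo <= prev.qo + k`)
coalesce into *fragments*, maximal runs of exactly matching bases. Merged
spans are contiguous unions of exact k-mer matches, so fragments are exact
by construction and are never re-verified downstream.

**3. Chaining.** Fragments of one strand are grouped into reference
regions: sorted by reference start, a new region begins when the gap to
the previous fragment exceeds `maxRegionGap` (default `min(10 * QL, 50 kb)`
— wide enough that a deletion up to ten query lengths stays in one region,
capped so distant loci are not conflated) or a sequence boundary is
crossed. Within a region, the best *potential alignment* is the maximum
estimated-score path in a DAG whose nodes are fragments sorted by query
start. A fragment's reward is `match * length`; an edge from `f1` to `f2`
charges:

* a single indel for the diagonal difference `d`: `gapOpen + gapExtend*d`
  (0 when collinear);
* the overlap between the fragments on query or reference, trimmed from
  `f2`'s reward so each base is counted once;
* the unmatched middle, `min(qGap, rGap)` bases when both gaps are
  positive, at the mismatch rate.

The last term deserves a note. The classical estimate scores fragments as
matches and the diagonal difference as one indel — implicitly assuming the
inter-fragment gap *is* that indel. That assumption fails when two
fragments are far apart on both axes yet lie on similar diagonals, a
configuration that is rare in ordinary reads but ubiquitous among the
shuffled blocks of complex rearrangements; without the middle term such
pairs chain for free and swallow every block between them. Charging the
middle at the mismatch rate is exactly the lower bound of what the
banded fill between the fragments can score on non-homologous sequence, and
it vanishes for pure-indel joins, so the classical estimate is preserved
precisely where its assumption holds.

Edges also require the later fragment to contribute novel bases on *both*
query and reference (so overlap trimming can never consume a fragment
whole) and to not precede its predecessor on the reference. The relaxation
visits each ordered pair once — O(n²) time, O(n) space, no edge
materialization — and breaks score ties toward the predecessor with the
smaller reference gap, then the smaller query start, making output
deterministic. An exhaustive enumeration oracle checks equality for groups
of up to 12 fragments.

After the best chain is removed, remaining fragments that still cover at
least one uncovered query base seed another run, until none do. A fragment
straddling a covered-region boundary stays available: junctions frequently
carry a base or two of coincidental micro-homology, and discarding a
fragment for sharing a few query bases with an earlier chain silently
drops one side of a split alignment (in simulation this costs roughly half
of all SV junctions). Each surviving potential alignment must then cover at
least `minMatch` *non-overlapping* query bases with seeds — a measure of
the union of fragment query intervals, boundary inclusive, so one k-base
seed survives `minMatch = k`.

**4. Completion.** The alignment is assembled as: backward X-drop extension
+ fragment 1 + banded global fill + ... + forward X-drop extension.
Inter-fragment fills are *global* (both endpoints pinned by exact-match
fragments) banded affine-gap DP within `bandWidth` (default 15) of the
segment diagonal; when the two segments' length difference exceeds the
band, the corridor is widened once to cover the endpoint diagonal and the
result flagged. Extensions are *local* (free end): anchored at the outer
fragment ends, banded at twice `bandWidth`, and terminated by the X-dropoff
rule — extension stops when the current row's best score falls more than
`X` (default 25) below the best score seen, and the best-scoring extension
is returned. Pruning is per DP row of the extension (the query axis);
per-cell and per-antidiagonal variants differ only in how eagerly they
stop, and the row rule composes naturally with the row-major band
implementation. A gap of length L costs `gapOpen + gapExtend * L`
throughout — chaining estimates, fills, extensions and rescoring all share
this one convention, so scores are comparable across stages. Traceback ties
prefer M over D over I, giving deterministic CIGARs. Defaults
`bandWidth = 15`, `X = 25` are conventional values for this heuristic
family; both are exposed on the function and CLI surface.

Every completed alignment satisfies, by construction and by test: CIGAR
query-consuming ops sum to the query span, reference-consuming ops to the
reference span, and rescoring the CIGAR against the sequences reproduces
the reported score exactly. An unbanded, un-heuristic local
Smith–Waterman (`full_sw_oracle()`) lives alongside the pipeline as the
accuracy benchmark; the pipeline can only ever match or undershoot it, and
the accuracy experiment measures how often it matches.

**5. Optimal Query Coverage (OQC).** Completed alignments from both strands
enter a second max-path DAG, sorted by query start. Appending alignment
`next` after `prev` gains `next`'s score minus an overlap credit, and pays
a split penalty `BP * GDP`:

* Overlap credit: when the two alignments overlap on the query (as at
  homology-flanked breakpoints), the overlapping bases are credited once at
  the per-base score of the *weaker* alignment
  (`overlap * min(score/len)`). This prorates rather than recomputes the
  overlap sub-alignment — an approximation chosen because it is cheap,
  monotone, and exact when scores are uniform along the alignment.
* GDP (genomic distance penalty): `min(maxGDP, log10(max(1, refGap)))`,
  where `refGap` is the distance between the nearest reference endpoints
  (0 when touching or overlapping; the floor at 1 bp avoids `log10(0)`).
  Alignments on different sequences always incur `maxGDP`.

Defaults `BP = 5`, `maxGDP = 5`. Strand does not restrict chaining — an
inversion junction joins opposite-strand alignments — and cross-sequence
pairs are chainable at `maxGDP`, which is what lets translocations and
distant insertions form a coverage set. The winning set (the Optimal
Coverage Set) members are the primary alignments; a brute-force subset
enumeration oracle checks the objective on instances of up to 10
alignments. With OQC disabled the aligner reports everything, flagging the
single best-scoring alignment (ties broken by reference name, then
position) as the one primary.

**6. Filter By Similarity (FBS).** A non-primary alignment is reported as a
secondary iff, for some primary, its query interval overlaps the primary's
reciprocally by at least `minOverlapFrac` and its score is at least
`minScoreFrac` of the primary's. Both default to 0.9 — tight enough that
secondaries are genuine alternative placements of a primary's query
segment (repeat copies), loose enough to survive a few percent of read
error. Each secondary is tagged with its best-matching primary.

**SAM output.** Records carry FLAG 16 for minus strand (SEQ
reverse-complemented), 256 for every non-primary, 4 for unmapped queries;
POS is 1-based; internal coordinates are 0-based half-open everywhere and
converted exactly once, at the writer. Soft clips (never hard clips) cover
uncovered query ends so downstream split-read tools keep the full
sequence; secondaries carry full SEQ for the same reason. The affine-gap
score is in `AS:i`. MAPQ is emitted as 255 (unavailable): no
mapping-quality model is defined here, deliberately — the accuracy
experiment benchmarks against externally verified alignment scores rather
than a mapping-quality heuristic.

## The simulator

The simulator exists to make the SV-detection experiments reproducible
from nothing but a seed.

* `make_synthetic_reference()` draws i.i.d. bases at a configurable GC
  fraction, optionally planting a repeat family: copies of one consensus
  overwriting random non-overlapping host positions, older copies carrying
  substitutions at a configurable divergence and `nIdentical` copies kept
  exact, emulating a young, recently expanded subfamily whose members are
  indistinguishable.
* `simulate_sv_events()` places non-overlapping deletions, tandem
  duplications, inversions and distant-locus insertions with log-uniform
  lengths (SV sizes span orders of magnitude; log-uniform spreads events
  across the whole range instead of piling onto the largest decade).
  Insertion donors are at least 100 kb away or on another sequence, or are
  drawn from a supplied pool such as planted repeat copies.
* `apply_sv_events()` builds one contig per event: the whole rearranged
  sequence with 500 bp flanks when the rearranged length is at most the
  flank, otherwise a left-breakpoint-only contig. Each junction between
  reference-non-adjacent blocks is recorded as truth: the two sides carry
  the junction-adjacent reference coordinate and an orientation (`+` if
  the joined segment lies left of the coordinate, `-` if right), which
  makes verification symmetric for reads sampled from either strand.
* `apply_cgr()` shatters one or two ~30 kb regions into fragments with
  approximately exponential lengths (mean 300, floored at 50 — the law is
  a modelling choice; only the mean and floor are fixed by design),
  deletes 30%, duplicates 10%, inverts 50% (categorical fates), shuffles
  and ligates.
* `sample_reads()` draws reads uniformly from both strands to a target
  coverage; each base errs independently at `errorRate`, an error being a
  1 bp indel with probability `indelFrac` (insertion/deletion
  equiprobable; longer indel length models are out of scope) else a random
  substitution. The canonical profiles are 2%/10% (simulated reads),
  1%/10% (assembled contigs) and 4%/90% (nanopore-like long reads).
* `verify_breakpoints()` declares a junction verified when some query has
  two reported alignments, adjacent on the query within a small slack,
  whose junction-facing reference breakends both fall within the tolerance
  (5 bp, inclusive) of the truth sides with matching orientations.

What the generator does *not* emulate — and hence what passing experiments
do and do not show: real genomes are not i.i.d. (repeat density, GC
structure, segmental duplications), error processes are not i.i.d. per
base (homopolymer and quality-dependent errors), genomes are haploid here,
and the planted repeat family is a caricature of a real transposon
phylogeny. The experiments demonstrate that the *algorithms* recover
breakpoints under the stated error and repeat models; they do not predict
absolute performance on a particular instrument or genome.

## Experiment problem sizes

The packaged experiments run on a 1 Mb synthetic genome: 1000 100-mers at
2% error for the accuracy benchmark (minMatch 20); 100 simple SVs (25 per
type, 100–10 000 bp) with 500-mer reads at 5x and 2% error (minMatch 25);
30 repeat insertions against a 30-copy family with 6 identical members;
and ten 30 kb chromothripsis contigs aligned whole. These sizes keep each
experiment in the tens-of-seconds range on one CPU while leaving the
verification denominators (hundreds of junctions, about a thousand reads)
large enough for stable percentages.

## Degenerate inputs and numerical notes

Queries shorter than k produce an empty seed stream; all-ambiguous queries
are emitted unmapped. Empty DP segments never reach the DP (pure gaps are
scored in closed form). Scores are integers throughout the DP (R doubles
only aggregate them), so no floating-point comparison tolerances are
needed anywhere in the aligner itself; the coverage objective mixes in
`log10` distances and is compared with `expect_equal` tolerances in tests.
Extension windows are clamped to sequence boundaries, so an alignment can
never leak across concatenated sequences. Duplicate completed alignments
(same strand, spans, reference and CIGAR) are collapsed before OQC.

## Known limitations

Chaining is O(n²) per region by design (matching the estimated-score DAG
formulation); pathological repeat structures that produce thousands of
fragments in one region will feel it. The overlap credit prorates rather
than recomputes overlap sub-scores. No mapping quality is computed. BAM,
paired-end fields and read groups are out of scope for the writer, as are
spaced seeds and minimizer schemes for the index.
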