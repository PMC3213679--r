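---
title: "Radius-bounded greedy clustering of near-duplicate DNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radius-bounded greedy clustering of near-duplicate DNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amplicon surveys of microbial communities (16S rRNA and similar phylogenetic
markers) produce millions of reads, most of which are exact or near-exact
duplicates of a much smaller number of template molecules: sequencing error
surrounds each true sequence with a "cloud" of imperfect copies. Before any
expensive downstream analysis it pays to collapse these clouds. `otuclust`
does this by greedy, radius-bounded clustering: given a similarity threshold
$s \in (0, 1]$, it partitions the input so that every member of a cluster is
within a guaranteed edit-distance radius of the cluster representative. The
clusters can stand in for operational taxonomic units (OTUs) at high
stringency, or simply shrink a dataset so that one representative per
cluster feeds slower phylogenetic pipelines.

## Distance model

The distance between two sequences is the unit-cost edit distance of their
best pairwise alignment: matches cost 0; every mismatch and every *charged*
gap costs 1. When the sequences have different lengths, gaps at the ends of
the **shorter** sequence may be left uncharged. The `alignment_policy()`
controls which ends:

* default (`anchor_start = TRUE, anchor_end = FALSE`): sequences are
  anchored at their 5' end and gaps at the 3' end of the shorter sequence
  are free — the natural choice for amplicons that begin at a shared primer
  but are truncated at varying positions;
* `TRUE, TRUE` is a plain global alignment (this, and only this, variant is
  a metric);
* `FALSE, FALSE` frees both ends.

An `N` mismatches everything, including another `N`; ambiguity is never
allowed to create a spurious match.

Similarity converts to an integer radius via the length of the shorter
sequence, counted before alignment:

$$\mathrm{sim}(a, b) = 1 - \frac{\mathrm{cost}(a, b)}{\min(|a|, |b|)},
\qquad
r(s, L) = \lfloor (1 - s)\, L \rfloor .$$

`radius_for()` floors because the radius must be the largest integer cost
that still satisfies $\mathrm{sim} \ge s$; a $10^{-9}$ additive guard
compensates for the binary representation of decimal thresholds (e.g.
$(1 - 0.9) \times 10$ evaluates below 1 in double precision).

## The greedy loop and its guarantees

Sequences are sorted by non-increasing length (ties broken
lexicographically by residues, then by id, so the pipeline is fully
deterministic). The longest unclustered sequence becomes the next
representative and recruits, in one search, *every* unclustered sequence
whose cost against it is within that sequence's own radius
$r(s, \text{its length})$. Taking the longest remaining sequence as the
center matters: it makes every member the shorter sequence of its pair, so
the radius denominators are well defined and members can never be longer
than their representative.

Because the search is exact, the output satisfies:

1. **validity** — every member cost is at most its radius;
2. **exactness** — any two representatives are farther apart than the
   threshold (a representative within the threshold of an earlier one
   would have been recruited by it).

With `separation = "well_separated"` each center searches out to twice each
candidate's radius; hits inside the radius are recruited, hits between once
and twice the radius are *flagged*. Flagged sequences may still be
recruited later but can never become centers, which forces centers to be
more than twice the radius apart. Flagged sequences that are never
recruited cannot be attached to any cluster without breaking the
guarantee; they are emitted as singleton clusters marked `leftover = TRUE`
in the R object (the flat cluster file stays a plain partition). For all
non-leftover clusters, the closest center to any member is the center of
its own cluster.

**On the diameter.** For a metric distance, the triangle inequality bounds
the cluster diameter by twice the radius. The global policy is a metric and
the bound holds for it verbatim (the test suite checks it by direct
pairwise computation). The semi-global policies are *not* metrics: two
members that cover different-length stretches of the representative can be
farther apart than twice the radius when aligned directly, because the
surplus of the longer coverage is charged. What is guaranteed for every
policy is the star-alignment form of the bound described below.

## The search: banded rows over an implicit trie

The expensive step is finding all unclustered sequences within radius $d$
of a query. `otuclust` never materialises a trie. The input is sorted
lexicographically once (a C-locale radix sort; any comparison sort yields
the same, binding, order), and adjacent longest-common-prefix lengths are
recorded. The sorted list is then scanned left to right while a stack of
dynamic-programming rows mirrors the current prefix path:

* a row holds, per query prefix length, the best cost of aligning the
  current candidate prefix against it, with every cell that provably
  exceeds $d$ saturated at the sentinel $d + 1$;
* pushing one character advances the row with the classic three-way
  recurrence, touching only cells whose predecessors are within the
  threshold (row minima never decrease with depth, which is what makes
  the saturation sound);
* between consecutive candidates only the non-shared suffix of the path is
  popped and re-pushed, so common prefixes are aligned exactly once;
* when a row's band empties after $\alpha$ characters, every following
  candidate sharing more than $\alpha$ prefix characters is skipped
  without touching it.

The DFS band is pruned at `band_radius`, the loosest radius any candidate
in scope could need (a subtree's candidate lengths are unknown
mid-descent); each surviving leaf is then re-checked against its own
length-dependent radius, restoring tightness without losing completeness.
The row stack is never deeper than the query length, and the number of row
advances is bounded by the total length of the candidates scanned.

## The k-mer screen and its completeness

A sequence of length $n$ has $n - k + 1$ overlapping k-mers, and a single
edit touches at most $k$ of them. If a candidate $c$ aligns within $d$
edits to a substring of the query $q$, then
$$\mathrm{pos}\big(\mathrm{spectrum}_k(c) - \mathrm{spectrum}_k(q)\big)
  \le k\, d,$$
where $\mathrm{pos}$ sums the positive entries of the element-wise
difference: candidate k-mers not covered by the query must all stem from
the at most $d$ edits. `may_match()` rejects a candidate only when this
bound is violated, so the screen passes false positives (the alignment
search removes them) but never produces a false negative. Note the
direction: it is the candidate's surplus over the query that is bounded —
the query is longer and its surplus over a short candidate is arbitrarily
large even for exact substrings.

k-mers containing `N` are dropped from both spectra. This is the
completeness-preserving convention: the bound above holds over the
five-letter alphabet, and projecting both spectra onto the A/C/G/T
subspace can only shrink the positive part of the difference.

To discard whole sub-lists at once, a balanced binary tree is built over
contiguous intervals of the lexicographic order. Each node stores the
element-wise **minimum** and maximum of the covered spectra and the
interval's length extremes. Since the minimum spectrum is dominated by
every covered spectrum, applying the bound to it — at the radius of the
node's longest member — can never discard a true hit; exact-mode
clustering with the tree is bit-identical to clustering without it (tested
end to end).

The **approximate** mode trades completeness for pruning power: it
evaluates each node at the radius of its *shortest* member and
additionally requires an optimistic shared-k-mer count,
$\sum_i \min(\mathrm{maxspec}_i, q_i)$, to reach what a shortest member
needs, $(\mathrm{minlen} - k + 1) - k\, d_{\min}$. At a leaf this
coincides with the exact pair test; in subtrees that mix lengths across a
radius step it can discard true hits, splitting (never corrupting)
clusters. On the bundled read-cloud conditions at $s = 0.99$ the inflation
in cluster count is well under the 10% envelope the tests assert; an
earlier design that tied the shared-count requirement to the node's
*maximum* length was rejected during development because it pruned the
root for any query shorter than the longest input.

The default word size is $k = 3$: the tree stores dense $4^k$ count
vectors per node, so small $k$ keeps it compact, and the screen's power at
high stringency comes from the $k\,d$ bound, not from long words.

## Star multiple alignments

Each member's pairwise alignment against the representative is a byproduct
of the search (recomputed by full-matrix traceback with deterministic tie
breaking: diagonal over subject-gap over query-gap, leftmost end point).
`build_star_msa()` reconciles them: for every representative position, a
column block is allocated before it, as wide as the longest insertion run
any member places there; members write insertions left-justified and pad
with gaps ("once a gap, always a gap"). Left-justification is a
convention — nothing in the reconciliation fixes it — chosen for
determinism.

`msa_column_dist()` scores rows column by column: mismatch or charged gap
1, double gap 0, and terminal gap runs of a row are free exactly when the
policy frees that end. Under this scoring the triangle inequality holds
column-wise through the representative row, so the distance between any
two rows is at most twice the cluster radius — for every policy. This is
the operational form of the diameter guarantee, and the form in which the
test suite asserts it for semi-global clusterings. (Scoring every one-sided
gap column as charged would break the bound trivially: a 3'-truncated
member has pairwise cost 0 but many trailing gap columns.)

## The synthetic generator

`generate_clouds()` emulates the study conditions the package is built
for: `n_centers` random templates (default 20) of 220–240 bp — the scale
of a pyrosequenced 16S variable region, where reads average roughly 230
bp — each with `cloud_size` reads (default 50), a 0.5% per-base error
rate, and clustering stringency 0.99. Its design choices:

* centers are accepted by rejection sampling only if every pair is farther
  apart than twice the maximum radius, so the planted structure is
  recoverable by an exact clusterer;
* a read with zero drawn errors is an exact full-length copy; an erroneous
  read is first truncated at the 3' end by 1–`max_trunc` bp (error and
  truncation co-occur in practice, and the truncation exercises the free
  3' end gaps) and then edited, with the edit budget capped so the read
  stays within its own radius of the center even after deletions shrink
  it;
* erroneous reads are kept strictly shorter than their center, so the
  center (or an identical copy) is always the first pick of its cloud in
  the length order — without this, a same-length mutant picked first could
  legitimately split its cloud and planted recovery would not be a fair
  test of the search's exactness.

What the generator does **not** emulate: chimeras, homopolymer-biased
error, abundance skew between clouds, and cross-cloud similarity gradients
(centers are independent random sequences, so distinct clouds are far
apart with overwhelming probability at these lengths; the rejection check
bounds full-length distances only). Passing the planted-recovery tests
therefore demonstrates the algorithmic guarantees — exact search, validity,
exactness — not biological fidelity on real communities.

## Numerical and degenerate-input choices

* INF sentinel is `threshold + 1` with saturating comparisons — no
  overflow, and banded rows are bit-comparable to the full matrix wherever
  the full value is within threshold.
* The band is kept as one covering `[lo, hi]` interval of the finite
  cells. Under free-start policies the finite set itself can be
  non-contiguous (e.g. query `AXA`, subject `A`, threshold 0), so interior
  cells are stored saturated; the interval only bounds where finite cells
  can live.
* Empty input yields an empty (valid) clustering; a dead row is absorbing
  under advance; duplicate ids, empty records and non-`A/C/G/T/N` residues
  are hard errors naming the offender — silent coercion would corrupt the
  spectra.
* Equal-length ties everywhere (center picking, lexicographic order,
  co-optimal tracebacks, leftmost free-end endpoint) are resolved by fixed
  documented rules; the clustering is a pure function of the input set.

## Problem sizes used by the test suite

The suite validates search exactness on 50 random instances of 200–500
sequences (lengths 30–60 bp, thresholds 0.90–1.0, both policies) against
an independently implemented full-matrix oracle; filter completeness on
10,000 mutated pairs per combination of $k \in \{3..6\}$ and
$d \in \{0..5\}$; banded-row equivalence on 1,000 random pairs per policy;
planted-structure recovery across 20 seeded configurations; and the
qualitative exact-versus-approximate comparison on a 10,000-read cloud set
(200 clouds of 50 reads) at 0.99 similarity. These sizes keep a full run
in the order of minutes on one core while exercising every guarantee at
non-toy scale.

## Known limitations

* The search assumes the query is at least as long as every eligible
  candidate (the greedy loop guarantees it); longer candidates are skipped
  defensively, not aligned in the reverse orientation.
* Runtime grows with the radius: the method is designed for high
  stringency (dereplication and tight OTUs, $s \ge 0.95$); at loose
  thresholds the band widens and the k-mer bound loses power.
* Abundance-aware center ordering, database-search mode and
  parallelisation are out of scope.
* The filter tree stores dense `4^k` vectors per node; `k` is capped at 6
  and the default of 3 is recommended.
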