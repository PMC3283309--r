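---
title: "The consistency model behind condel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The consistency model behind condel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condel)
```

# The data model

`condel` works on paired-end mappings: for each sequenced fragment, the
two reads are placed on the reference with an orientation and a distance.
Where donor and reference agree, the mapping is *concordant* — proper
orientation (leftmost read on `+`, mate on `-`) and a span length (outer
distance, reads included) inside the fragment-length cutoffs
`[min_len, max_len]`. A pair spanning a deletion breakpoint maps with
proper orientation but a span stretched by the deleted bases. From such a
mapping `m` we know:

* the deleted segment lies in the *breakpoint region* `br(m)`, the
  interval between the inner read ends;
* its size is between `del_min(m) = |span(m)| - max_len` and
  `del_max(m) = |span(m)| - min_len`.

A set of deletion mappings is a **valid cluster** when a single deletion
length is compatible with all of them: the intersected breakpoint region
is non-empty, `max del_min <= min del_max`, and `max del_min` fits inside
the intersected region. Validity is *hereditary* (every subset of a valid
cluster is valid) but **not pairwise**: the third condition compares the
largest member demand against the multi-way intersection, so three
mappings can be pairwise compatible and jointly invalid. This drives two
implementation choices described below.

Assumptions inherited from the model: reads have a unique mapping
location; every deletion is covered by exactly one cluster (no deletion
splitting); all deletions are heterozygous; very small deletions
(≈10 bases) are out of scope, as are insertions, inversions and
translocations — mappings with wrong orientation, overlapping reads, or
spans below `min_len` are classified `other` and excluded.

# Consistency and conflicts

On a single chromosome copy, any mapped read blocks the positions it
covers. A set of clusters (plus concordant mappings, treated as clusters
with minimal deletion length zero) is **haploid-consistent** if every
cluster still finds a free interval of length `del_min(c)` inside
`br(c)` after subtracting the blocked regions of all other elements. The
blocked region of a cluster is its span hull (leftmost read start to
rightmost read end); for a concordant mapping, its span.

Conflicts are monotone (supersets of conflicting sets stay conflicting),
so all conflicts are summarized by the *minimal* conflicting sets. Among
clusters these always have exactly two or three members — a squeezed
pair, or a chain whose middle element loses both flanks — so the search
tests only pairs and overlap-connected triples. With concordant
(demand-zero) nodes we keep the same pair/triple search and skip sets
with two or more concordant members: a demand-zero node only ever blocks,
so two of them cannot both be essential without a smaller conflict
existing. The acceptance suite verifies the cardinality bound
empirically on randomly generated configurations.

For a diploid chromosome, conflicting clusters may still be separable
onto the two copies. Build a hypergraph with one node per cluster (and
per involved concordant mapping) and one hyperedge per minimal
conflicting set: assignments to two copies with no per-copy conflict are
exactly the proper two-colorings (no monochromatic hyperedge). With
edges of sizes two and three the problem is still NP-hard, so `two_color()`
is an exact backtracking search guarded by `max_nodes` (default 20 — far
above the component sizes seen in practice, small enough that the search
is instant), while `diploid_conflict_triplets()` provides the polynomial
heuristic: any three nodes that are *pairwise* in conflict cannot be
placed on two copies. The heuristic misses exotic non-pairwise diploid
structures, which require at least six clusters overlapping in a very
specific pattern; its hits are guaranteed lower bounds, which the test
suite confirms by showing each reported triple induces an unsatisfiable
sub-hypergraph.

# The matched normal/tumor analysis

The tumor sample is modelled as a mixture of tumor and normal cells —
four chromosome copies: two normal (one of which carries any germline
deletion), and two tumor copies that inherit the germline deletions and
may add tumor-specific ones. For each germline deletion cluster `c`, the
tumor deletion mappings overlapping `br(c)` directly or transitively
(span overlap) form an *overlapping component*; components that share
mappings, or whose germline clusters overlap, cannot be solved
independently and are dropped with a diagnostic.

Each component is solved in three steps:

1. **Concordant mappings** are explained by the non-deleted normal copy.
   They then constrain nothing else; the `concordant_constrain` option
   instead keeps them as blockers on the tumor copies for a stricter
   analysis.
2. **Support**: a maximum subset `S` of the discordant mappings with
   `c ∪ S` still valid joins the germline deletion, refining its
   breakpoint region and size range (`c' = c ∪ S`). Assigning supporters
   to the normal side (rather than a tumor copy) leaves the most room
   for tumor-specific deletions. `S` is found by branch-and-bound over
   the individually compatible candidates with the trivial
   remaining-count bound; ties go to the lexicographically smallest id
   set. Mappings absorbed into `S` are never reconsidered for tumor
   clusters — re-assignment is an explicit non-goal.
3. **Assignment**: the remaining mappings are partitioned into valid
   clusters on the two tumor copies (copy 1 also carries `c'`), plus a
   minimal set `D` of discarded mappings. The branch-and-bound processes
   mappings in `(br_start, id)` order; each either joins an open cluster
   (kept valid at every step), opens a new cluster on copy 1 or copy 2,
   or is discarded. Partial arrangements are pruned when a copy becomes
   inconsistent — sound because adding members or clusters only ever
   shrinks free space and raises demands — and when the discard count
   reaches the incumbent. The first optimum found under this fixed order
   makes the result deterministic; a wall-clock budget (`time_limit`,
   default 600 s per component) returns the best solution found so far
   flagged `time_limited`.

Because only `|D|` is minimized, the first optimum may split one
deletion's mappings across the two copies. A deterministic post-pass
therefore merges tumor clusters whenever the union is still valid and
both copies stay consistent; this never changes `|D|` and restores the
one-cluster-per-deletion reading of the calls. This merge is a design
choice of this implementation: without it the partition is equally
optimal but cosmetically fragmented.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` | estimated | insert-size cutoffs (bases, span including reads) |
| `q_low`, `q_high` | 0.001, 0.999 | quantile levels for cutoff estimation |
| `min_quality` | 20 | mapping-quality threshold for input pairs |
| `max_clusters` | 1e6 | per-chromosome cap on maximal clusters |
| `max_nodes` | 20 | exact two-coloring size guard |
| `time_limit` | 600 s | per-component branch-and-bound budget |
| `overlap_on` | `"span"` | component seeding test (`span` or `br` vs `br(c)`) |
| `support_threshold` | 20 | support cutoff in summary tables |

Cutoffs are estimated per sample as *nearest-rank* quantiles of the
proper-orientation insert lengths: the q-quantile of n sorted values is
the value at rank `ceiling(q n)`. The nearest-rank estimator returns an
observed integer length and is monotone in q; interpolating estimators
would manufacture non-observed lengths. Quantiles are computed on
proper-orientation pairs only (including discordant ones): orientation is
known before cutoffs exist, distance is not.

# Numerical and representation choices

* **Coordinates** are 0-based half-open everywhere; SAM input (1-based
  closed) is converted at the reader. Interval arithmetic then needs no
  ±1 bookkeeping; a breakpoint region is empty exactly when
  `end <= start`, and pairs with overlapping reads (empty region) are
  classified `other`.
* **Distance** means span length *including* the reads. SAM `TLEN`
  conventions vary, so the readers recompute the span from the two read
  placements and never trust `TLEN`.
* **Maximal cluster enumeration** cannot rely on cliques of the pairwise
  compatibility graph (validity is not pairwise). It is a
  Bron–Kerbosch-style branch enumeration in which a candidate survives
  only if the full current set plus that candidate is valid, over
  span-overlap connected components. A domination shortcut makes densely
  compatible components linear: when the current set plus all remaining
  candidates is jointly valid, that union is the only possible maximal
  set in the branch. Correctness is tested against exhaustive subset
  enumeration, including instances with pairwise-compatible but jointly
  invalid triples.
* **Tie-breaks and ordering**: clusters are reported sorted by
  (chromosome, breakpoint start/end, support); the supporting set prefers
  the lexicographically smallest ids; the assignment search order is
  fixed. Identical inputs in any row order produce identical results.
* **Degenerate inputs**: empty mapping files yield empty results with a
  warning; a chromosome whose cluster count would exceed `max_clusters`
  is abandoned with a per-chromosome diagnostic while the rest proceed;
  `min_len = max_len` collapses each mapping's size range to a point and
  everything downstream still holds.

# The simulator

`simulate_dataset()` generates the data the analysis model assumes: one
reference chromosome; heterozygous germline deletions on one normal
copy; tumor copies derived from the normal copies plus heterozygous
tumor-specific deletions; fragments drawn per copy with Normal insert
lengths (truncated at twice the read length) at the requested physical
coverages; and a tumor sample mixing tumor- and normal-cell fragments by
the contamination fraction. Mapping is simulated — coordinates are
computed from the truth; fragments whose *reads* straddle a breakpoint
are dropped as unmappable, while fragments whose inner gap spans
deletions become deletion-indicating mappings with correspondingly
stretched spans.

Defaults describe a desk-scale study: 1 Mb reference; ten germline and
five tumor-specific deletions of 200–1000 bases (a few hundred bases is
the size regime the method targets); fragment length 200 ± 20 bases with
50-base reads, echoing a short-insert Illumina library whose 0.1%/99.9%
cutoffs land near 126/263; 15-fold physical coverage per sample and 30%
contamination. Two generator choices deserve justification:

* `proximity_bias = 1`: tumor-specific deletions are planted next to a
  germline deletion, because deletions near germline events are exactly
  the case the method exists for; isolated tumor deletions never enter
  an overlapping component and are invisible to this analysis by design.
* Proximal tumor deletions are planted on the tumor copy derived from
  the deletion-free normal copy (in *trans*). In *cis*, fragments
  spanning both deletions would arise and the local configuration could
  become genuinely inconsistent; the trans layout keeps noise-free
  recovery attainable by construction, which is what the recovery tests
  measure. The planter also spaces unrelated deletions at least
  `min_separation` (4 kb) apart so components stay disjoint.

What the simulator does **not** model: sequencing errors, chimeric
fragments, repeat-induced mismapping, multi-mapping reads, copy-number
changes, homozygous deletions. Passing tests therefore demonstrate the
combinatorial machinery — classification, clustering, consistency,
assignment — under the model's own assumptions, not robustness to the
noise sources of real libraries. A "noise-free" analysis additionally
uses the true fragment-length extremes of the simulated library as
cutoffs (recorded in the truth object), so no mapping is misclassified;
with quantile-estimated cutoffs a ~0.1% tail of fragments is
misclassified by construction, which produces occasional spurious
singleton calls but leaves the pipeline's behavior otherwise intact.

# Verification strategy and problem sizes

Every non-trivial operation is checked against an independent oracle:
exhaustive subset enumeration for maximal clusters (≤12 mappings),
position-by-position placement for haploid consistency, exhaustive
bipartition for diploid two-coloring (≤12 nodes), exhaustive labelled
partitioning for the minimal-discard assignment (≤8 mappings), and
full-size-range enumeration of minimal conflicting sets (4–8 clusters,
1000 random configurations) for the cardinality bound. End-to-end, a
simulate→pipeline run at 60× coverage with 30% contamination must
recover all planted tumor-specific deletions with nothing discarded.
These sizes keep each suite section within tens of seconds while the
exhaustive oracles remain tractable; the combinatorial properties they
check are size-independent.

# Known limitations

* Homozygous deletions and loss of heterozygosity are not modelled; a
  homozygous germline deletion misread as heterozygous can inflate the
  discard count.
* Diploid conflict detection at scale is heuristic (pairwise triples);
  the exact search is reserved for small node sets.
* The supporting step is greedy in spirit: a tumor-specific deletion
  adjacent to a germline one may lose supporters to `c'`, understating
  its support. Re-assignment post-processing is deliberately out of
  scope.
* The assignment minimizes discarded mappings only; among equally
  optimal partitions the merge post-pass, not the objective, decides the
  cluster count.
* Components sharing mappings are dropped rather than solved jointly.
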