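---
title: "Constraint-based classification of kinase families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based classification of kinase families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinclust)
```

This vignette is the package's account of its science: the model behind
constraint-based classification, the design decisions inside the
sampler, the numerical choices, what the synthetic generator does and
does not emulate, and the known limitations.

## The constraint model

A *constraint* is a triple (alignment column, allowed residue set,
weight). It asserts that members of a cluster conserve one of the
allowed residues at that column, while sequences outside the cluster do
not. The weight quantifies, in nats, how much evidence the column
carries for the foreground/background split. We use a pseudocounted
binomial log-likelihood-ratio contrast: with foreground total $n_F$,
foreground count in the set $n_{FR}$, and set frequencies
$q_F = (n_{FR}+\alpha)/(n_F+2\alpha)$ (background analogous),

$$w \;=\; n_{FR}\,\ln\frac{q_F}{q_B} \;+\;
  (n_F-n_{FR})\,\ln\frac{1-q_F}{1-q_B}.$$

This is the foreground's log-likelihood ratio between the foreground
and background binomial models of "residue in set". It is linear in
counts (so evidence accumulates with sequences), may be negative, and
reduces to zero for proportional profiles. The default pseudocount is
$\alpha = 1$. Full Bayesian pattern-partition samplers integrate over
priors on patterns and partitions; this contrast deliberately trades
that machinery for an interpretable, testable statistic with the same
units, and compensates for the lost Occam penalty with an explicit
empirical null (below).

A *hierarchy* is a single-rooted tree of clusters. Constraints attach to
the node where they arise; the **effective** constraint set of a node is
the union of its own and all ancestors' constraints. Child constraint
columns are disjoint from ancestor columns, matching the picture of
family-specific motifs layered on top of subgroup-specific motifs.

## Pattern selection

For a fixed foreground, every column is searched greedily: residue sets
grow one residue at a time (sizes 1–4), keeping the best-weight set.
Two filters make the search behave like "conserved within, divergent
outside" rather than raw contrast maximisation:

* **Enrichment** (`min_enrichment`, default 1.5): a residue may join a
  set only when its pseudocounted foreground frequency is at least 1.5×
  its background frequency. Without this, the greedy pads sets with
  background-typical residues to manufacture coverage. The value is
  deliberately permissive: during search the membership is impure, and a
  genuinely cluster-specific residue seen through a 60–70%-pure
  foreground sits near ratio 2, while background residues sit near 1.
* **Foreground conservation**: the set must cover at least
  `min_fg_conservation` (0.6) of the non-gap foreground during the
  search, and `final_fg_conservation` (0.75) in the final reported
  constraint set of a converged cluster. The permissive search threshold
  lets weak signal bootstrap from an impure initial membership; the
  strict final threshold stops half-conserved *child* columns from being
  absorbed into a parent node (which would destroy child recovery, since
  descendants must avoid ancestor columns).

Columns are kept when the best set has positive weight, sorted by
weight, and truncated at `max_constraints_per_node` (20). Ties are
broken by column index; candidate residues in alphabet order. Gaps and
the unknown residue `X` are excluded from all counts and never satisfy a
constraint.

## The partition sampler

One sampler run (`sample_partition()`) is a seeded coordinate ascent:

1. **Initialisation.** A random seed sequence is drawn; its nearest
   neighbours by pairwise match-column identity (half the pool) form the
   initial foreground, refined by two k-means-style rounds that re-rank
   the pool by log-likelihood under the foreground residue profile
   relative to the pool profile. A balanced coin-flip split would have
   *no expected contrast at any true constraint column* (foreground
   frequency equals background frequency), leaving only noise for the
   ascent to amplify; the neighbour-based init starts inside a basin of
   real structure, and its half-pool size biases the first split toward
   the coarsest (subgroup-level) distinction.
2. **Sweeps.** Alternate pattern reselection with membership
   reassignment: a sequence joins the foreground when its matched-weight
   fraction exceeds 0.5 (ties stay where they are). Sweeps stop on
   convergence or after `n_sweeps` (50); `n_sweeps = 0` scores the
   initial split once.
3. **Acceptance.** The summed constraint weight of the converged split
   is compared against an empirical null: the same ascent run on a
   column-wise shuffled copy of the submatrix (column compositions
   preserved, co-occurrence destroyed), with failed null ascents redrawn
   because the observed statistic is only ever tested when the real
   ascent survived. The split is accepted iff
   $W_{\mathrm{obs}} \ge \max(\overline{W}_0 + 2\,\mathrm{sd}(W_0),\;
   1.5 \max W_0) + \texttt{minnat}$.
   The margin absorbs the selection variance of an ascent-optimised
   statistic — on homogeneous data the ascent reaches 40–80 nats of pure
   noise, so a raw `sum(weight) >= minnat` test (or a fixed-membership
   permutation null) would accept junk clusters freely; against this
   calibrated null, homogeneous alignments are rejected in essentially
   every seed while true planted splits pass with hundreds of nats to
   spare. Accepted clusters must also have at least `min_cluster_size`
   (8) members.

`infer_hierarchy()` recurses: at each node, accepted foregrounds are
extracted repeatedly from the pool of unassigned members (each candidate
contrasted against *all* other node members, including already-extracted
siblings). Before each sampler run the remaining pool as a whole is
tested as a candidate child — without this, the complement of the first
subgroup would be discovered via its own substructure and attach at the
wrong level. Rejected extractions are retried up to `n_restarts` (3)
times with fresh seeds at the same init granularity; restarting at
smaller granularities was evaluated and rejected (small inits have
heavier-tailed noise optima, and selection across many restarts
over-fragments the leaves). Recursion stops at `max_depth` or when no
split passes.

The sampler is deterministic given `seed`. Multiple runs with different
seeds can be merged by `consensus_hierarchy()`: clusters are matched
across runs by membership Jaccard (≥ 0.5), kept at `min_support`,
re-nested by containment, and their constraints re-estimated on the
union membership.

## Scoring, cut-offs, classification

The fit score of a sequence against a cluster is the summed weight of
satisfied *effective* constraints over the total effective weight — in
[0, 1] by construction, exactly 1 when all constraints are satisfied
and exactly 0 when none are. Scoring uses the nested (own ∪ ancestors)
set: this is what makes subcluster members score highly against their
supercluster while the converse mean is lower, the asymmetry visible in
the all-versus-all similarity matrix.

The classification cut-off defaults to 0.7, with a relaxed 0.6 preset
for conservation analysis. `select_cutoff()` operationalises "the global
minimum of the bimodal score distribution": histogram at `bin_width`
(0.01), light moving-average smoothing (window 5) so bin raggedness does
not spawn modes, candidate modes at ≥ 20% of the tallest, and a scan
over all separated mode pairs for the deepest relative valley (raw-count
minimum below half the smaller mode; plateaus resolved to their middle
bin). If no qualifying pair exists the distribution is declared
unimodal and the conventional 0.7 is returned with a `fallback` flag.

`classify()` assigns each sequence to the deepest node on a
root-to-leaf path whose every scoreable node clears the cut-off
(unconstrained nodes, typically the root, qualify automatically but are
not assignment targets); ties prefer the higher score, then the
lexicographically smaller id; sequences qualifying nowhere go to the
`"unclassified"` sink.

## Downstream analyses

**Similarity.** Entry (A, B) is the mean fit of A's classified members
(path membership: a member of a family is a member of its subgroup)
against B's effective constraints. Diagonals are ≥ the cut-off by
construction of the assignment rule.

**Comparative logos.** Pseudocounted foreground/background frequencies
per column with a relative-entropy divergence in nats. The divergence is
zero iff the pseudocounted distributions coincide and approaches
$\ln 20$ for a fully conserved foreground against a uniform background.
All-gap foreground columns are flagged and set to zero.

**Taxonomic conservation.** Organisms come from `OX=` header tags;
lineages are traced through taxdump-dialect nodes/names files (root
self-parenting normalised to a null parent, only `scientific name` rows
used). A cluster is detected in a taxon when any sequence scoring at or
above the cut-off descends from it; detections are monotone in the
cut-off. Sequences without an organism id are counted and excluded.

**Introns.** Phase = cumulative coding length before the intron, mod 3;
`codon_position` (the floor over 3) is also the 0-based index of the
interrupted (phase 1/2) or next (phase 0) residue — the package maps
that residue through the record's interleaved insert/match structure to
an alignment column. Introns landing in inserts or beyond the domain are
reported with a null column and excluded from shared-intron grouping
(their counts remain visible in the mapped table). Exon tables are taken
as ORF-ordered; the GFF3 convenience reader reverses minus-strand CDS
segments.

**DE loops.** Loop length = non-gap match residues strictly between the
αD-end and αE-start anchors plus all insert residues attached between
them. Anchors are profile configuration, not inferred. The
longDE/shortDE dichotomy is phylogeny-derived in principle; the
threshold labelling (`median > 10` residues → longDE) is a convenience
heuristic and is reported as such.

## The synthetic study conditions

`simulate_kinome()` fixes the default conditions used across the test
suite: 2 superclusters × 2 subclusters, 50 sequences per leaf, 200
match columns, 5 constraints per non-root node (residue sets of size
1–2, weights uniform in [1, 4] nats, columns disjoint across the tree),
constraint fidelity 0.95, uniform background composition, taxon
emergence points cycling through Holozoa, Metazoa, Eumetazoa and
Chordata over a built-in 33-node toy taxonomy, DE-insert lengths
Poisson(70) for longDE and Poisson(4) for shortDE leaves (the first
supercluster's leaves are shortDE), a planted shared phase-2 intron at
the αH anchor for longDE sequences, and Poisson(0.5) random extra
introns per gene. The root carries no constraints: universally conserved
positions have no contrast and cannot be recovered from within the
family. Anchors sit at fixed fractions of the alignment width. Weights
in [1, 4] keep single constraints individually unremarkable while each
node's summed weight (≥ 5 nats) clears the minnat floor, and fidelity
0.95 mirrors the "highly conserved within" regime the method assumes.

What the generator deliberately does **not** emulate: phylogenetic
autocorrelation along a tree (sequences are conditionally independent
given their cluster), realistic amino-acid composition (uniform
background by default; a 20-vector can be supplied), alignment error,
gap structure in match columns, or fragmentary sequences. Passing tests
therefore show that the algorithms recover planted structure under the
model's own assumptions — they do not certify performance on real
kinome alignments, where misalignment and lineage effects add
correlated noise.

Test and pipeline runs use these sizes (200 × 200 for recovery checks,
60–80 × 120 for pipeline smoke and determinism checks, 1,000 random
exon structures for the intron oracle), chosen as the smallest problems
that still separate signal from the sampler's noise floor.

## Numerical and degenerate-input choices

* Columns are 1-based everywhere, R-style, including the JSON model file.
* `X` and non-standard residue letters are recoded to `X` on input,
  never satisfy constraints, never count as identical in the identity
  purge, and are excluded from counts.
* Identity purging is greedy in input order (first seen kept); a pair
  with no mutually non-gap columns has identity 0.
* Score bounds are snapped exactly: all-satisfied is exactly 1,
  none-satisfied exactly 0, independent of float summation order.
* Alignments of identical sequences, `max_depth = 0`, or fewer than 4
  records yield a single-node hierarchy or an argument error as
  documented; empty node memberships contribute 0 to the total LPR, as
  does the root (its background is empty).
* All generators and the sampler consume a single integer seed;
  `run_pipeline()` reruns are byte-identical apart from the timestamped
  log.

## Limitations

* The sampler is a conservative point estimator, not a posterior: weak
  but real clusters near the minnat floor are sometimes missed
  (preferring a shallower tree), and occasionally a small spurious leaf
  child survives the null margin. Consensus across seeds is the intended
  remedy for both.
* The headline LPR is comparable only between hierarchies on the same
  alignment; it is not calibrated across data sets.
* Conservation analysis treats detection as boolean and is silent about
  copy number; the representative sampler picks one sequence per
  cluster-taxon pair without regard to within-pair diversity.
* Tree building itself is out of scope: the package writes representative
  sets and consumes clade maps, but never infers phylogenies.
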