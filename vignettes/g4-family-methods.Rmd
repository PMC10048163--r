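---
title: "Models and methods behind quadfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfam)
```

quadfam groups putative G-quadruplex (G4) DNA sequences into *families*:
sets of sequences similar enough in tract/loop architecture that one profile
hidden Markov model describes them all, statistically distinct from every
other family's profile. This vignette explains each model in the pipeline,
the parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Detection

Canonical intramolecular G4s follow the pattern
G~x~N~1–7~G~x~N~1–7~G~x~N~1–7~G~x~ with x ≥ 3: four runs of guanine (the
*tracts*, each contributing one column of the stacked tetrads) separated by
loops of 1–7 nt. `detect_g4()` implements this by *tract chaining* rather
than a literal regular expression: all maximal G runs are found first, then
maximal chains of at least four tracts whose consecutive gaps lie within the
loop bounds are reported. Chaining makes the two counts a greedy regex
cannot define cleanly — the total number of 4-tract placements
(`n_tracts - 3`) and the maximum number of disjoint placements
(`floor(n_tracts / 4)`) — exact by construction.

Defaults: `min_tract_len = 3` (two-tetrad structures form in vitro but are
excluded by default because their computational false-positive rate is
high; `min_tract_len = 2` re-enables them), loops 1–7 nt, both strands.
Coordinates are 0-based half-open (BED convention) on the plus strand
everywhere; 1-based browser-style labels are converted only at I/O
(`parse_region_label()`). For minus-strand hits the interval refers to the
C-rich plus strand while the stored sequence is the G-rich scanned strand,
because the G-rich sequence is what clustering and modelling consume.
`N` and IUPAC ambiguity codes never count as G.

## Initial clustering

Two stages mirror how short, highly repetitive genomic motifs behave:

1. **Sphere clustering** (`cluster_spheres()`): centers are chosen
   longest-first (ties broken lexicographically, so the procedure is
   deterministic) and every unassigned sequence within a fixed Levenshtein
   radius (default 2) joins the center's cluster, subject to a group filter
   (same tract count, length within the radius). This captures the large
   mass of identical and near-identical G4 copies cheaply. Singleton
   spheres are returned as unassigned.
2. **Alignment similarity** (`pairwise_similarity()`): the remainder is
   scored all-vs-all with Smith–Waterman local alignment (match +2,
   mismatch −3, gap open −5, extend −2) and converted to an E-value with
   the Karlin–Altschul formula E = K·m·n·e^(−λS) (λ = 0.625, K = 0.41,
   m·n the pairwise length product). Similarity is max(0, −log E);
   distance is the matrix maximum minus similarity. This keeps the
   −log(E)-similarity semantics of an all-vs-all BLAST without shelling
   out to an external binary.

The number of clusters for the similarity stage is chosen by the
*inertia-ratio rule* (`select_k_inertia()`): for each cut of the tree the
within-cluster inertia I~m~ is the sum of squared distances to cluster
medoids (medoids, not centroids, because only a distance matrix exists),
and the chosen k maximizes the successive ratio I~k−1~/I~k~ — the cut whose
creation collapses the most inertia. Read literally as "report the m where
I~m~/I~m+1~ peaks" the rule would systematically under-cluster by one: for
three planted groups the peak ratio occurs moving from 2 to 3 clusters.
Applied across the four linkages (Ward, complete, average, and DIANA-style
divisive) the mode of the per-linkage choices is reported. A consensus
alternative (`select_k_consensus()`) votes across silhouette, Dunn,
C-index, McClain–Rao and the Frey–van Groenewoud ratio; note that on noisy
continuous data McClain–Rao is biased toward high k (splitting a noisy blob
leaves tiny within-pairs), which is why the consensus, not any single
index, is used.

## Alignment and gap score

Each cluster is aligned with guide-tree progressive alignment
(`align_sequences()`): UPGMA tree on edit distances, then profile–profile
Needleman–Wunsch with affine gaps (match +1, mismatch −1, open −2, extend
−0.5 — chosen for sequences ≤ 40 nt where a single gap should cost more
than a mismatch but not forbid length variation). Progressive alignment is
a heuristic: it attains the exhaustive sum-of-pairs optimum pairwise (the
DP is exact) but can miss it for three or more sequences; the test suite
asserts exactness pairwise and the upper bound beyond. `adjust_gaps()`
then makes score-neutral gap moves that concentrate guanines into purer
columns (greedy passes to a fixed point, hence idempotent).

The **gap score** of an alignment is its overall gap fraction: total gap
characters over rows × columns. The phrase "average number of gaps per
column divided by the length" admits a per-column and a per-alignment
reading; the per-alignment fraction is used because it is bounded in
[0, 1], which is the scale on which the refinement thresholds (0.10, 0.6,
0.07) operate as fractions. The IUPAC consensus takes, per column, the
minimal degeneracy code covering every base whose count reaches half the
modal base's count (plurality 0.5, reproducing the mixed literal/ambiguity
style of published family consensus strings); gap-majority columns emit
`-`.

## Profile HMMs

`build_phmm()` trains a plan7 profile HMM: one node per match column
(columns with gap fraction ≤ 0.5), each with match, insert and delete
states and the seven transition types (M→M, M→I, M→D, I→I, I→M, D→M,
D→D). Counts of emissions and transitions along each row's state path are
Laplace-smoothed (pseudocount 1 — keeps every transition finite for
four-member clusters) and normalized. Plan7 has no D→I transition; an
insert encountered while in a delete state is counted against the node's
M→I so the model stays proper (a rare event in G4-scale alignments).

`forward_log_odds()` sums over all state paths in log space and reports
the natural-log odds against a background null (uniform 0.25 by default —
the choice of null only shifts all scores jointly, and natural log fixes
the unit in which the merge threshold "log odds 5" is read).
`viterbi()` gives the best single path with deterministic M > D > I
tie-breaking. Both are verified against exhaustive path enumeration for
every model with ≤ 3 match states and sequences of length ≤ 4. Scoring is
global (the training sequences are full-length minimal G4s); a uniform
local entry/exit mode is intentionally not offered until a use case needs
it, keeping the scoring contract single-valued.

## Family refinement

`refine_families()` iterates:

1. align each cluster, train its profile;
2. score every cluster's sequences against every profile
   (`score_matrix()`);
3. test distinctness (`divergence_test()`): profile i is distinct iff for
   every j ≠ i the one-sided Wilcoxon rank-sum test of (own scores of
   S~i~ on P~i~) vs (cross scores of S~i~ on P~j~) gives p < 0.05. P-values
   are raw by design; a Benjamini–Hochberg switch exists but is off, so the
   test errs toward declaring profiles non-distinct, i.e. toward merging;
4. accept profiles that are distinct, have no non-distinctness edge toward
   any other profile, claim their own sequences with mean Akaike weight
   ≥ 0.99 (the "membership probability"; a `min` aggregation is available
   via `prob_rule`), and have gap score < 0.10;
5. pool each connected component of the non-distinctness relation and
   re-cluster it (average linkage on edit distance, k by the inertia-ratio
   rule with k = 1 allowed so duplicated clusters can collapse into one);
   pooled alignments with gap score ≥ 0.6 are dropped, and undersized
   split-offs are reassigned to the nearest sizeable part rather than
   silently lost;
6. repeat to convergence or 100 iterations.

Two asymmetries matter and are worth stating. First, the rank-sum test is
directional: a small fragment of a family often cannot be told apart from
its larger sibling while the sibling looks "distinct" against everything
(its profile fits its own training data better). Acceptance therefore
requires having *no* non-distinctness edge, pooling both endpoints —
otherwise the large fragment would be accepted and removed, stranding the
small one as a spurious family. Second, "membership probability 0.99"
could mean forward probability, posterior membership, or Akaike weight;
it is operationalized as the mean Akaike weight of a profile's own test
sequences because that quantity is normalized across the competing
profiles, making 0.99 a meaningful dominance requirement.

`merge_family_sets()` deduplicates families found by different routes with
the same machinery plus stricter thresholds: direction i→j passes when i's
members average ≥ 5 nats log odds on j's profile, the rank-sum test cannot
distinguish own from cross scores (p ≥ 0.05), and j receives mean
cross-family Akaike weight ≥ 0.7 computed with i excluded from the
candidate set (two duplicates would otherwise split the weight 0.5/0.5 and
the 0.7 threshold could never fire). Both directions must pass — a broad
profile absorbing a narrow one is one-way attraction, not identity — and
the merged alignment must keep gap score ≤ 0.07 or the merge is rejected.
Thresholds alone (without the rank-sum gate) demonstrably merge the
closest pair of genuinely distinct families: 5 nats of cross log odds is a
low bar among G-rich profiles.

`classify_g4()` scores a query against every family and converts log odds
to normalized Akaike weights, AIC~i~ = 2k~i~ − 2ℓ~i~ with k = 0 for all
families (family models have similar complexity, so the weights reduce to
likelihood weights; a free-parameter-count mode is the natural extension
if model lengths ever diverge). Ties break to the lowest family id.

## The quadruplex energy model

`g4_thermo()` annotates sequences with a thermodynamic model *restricted
to quadruplex states*: the structure space is the open chain (energy 0)
plus every placement of four ordered, equal-length G sub-tracts (layers
L ≥ 2, linkers 1–7 nt). A placement's energy is

E = α·(L − 1) + trunc(β·ln(l~tot~ − 2))

with α = −18.00 kcal/mol per stacked-tetrad step, β = 12.0 kcal/mol, and
l~tot~ the total linker length; for l~tot~ = 3 the linker term is exactly
zero. The linker term is **truncated toward zero** at the 0.01 kcal/mol
resolution: 12·ln 2 = 8.3178 contributes 8.31, which is what makes the
worked examples −27.69 and −9.64 exact — plain rounding would give −27.68
and −9.63 and is rejected by the tests. Ensemble quantities use the
restricted partition function Z = 1 + Σ e^(−E/RT) at 37 °C
(RT = 0.61633 kcal/mol): ensemble free energy −RT·ln Z, MFE frequency
100·e^(−E~MFE~/RT)/Z (reported for the single tie-broken MFE structure, as
folding programs do when minima are degenerate), and ensemble diversity as
the expected pairwise symmetric difference of quadruplex-involved position
sets. Because canonical base-pair competition is out of scope, these
quantities are faithful only where quadruplex states dominate the
ensemble — true for the four worked examples, not guaranteed for G4s
embedded in self-complementary context.

## Synthetic data and what the benchmark shows

`simulate_g4_genome()` plants K mutated families in an i.i.d. background
(GC 0.4). Mutations follow the biological prior the clustering relies on:
tracts conserved, loops accumulating substitutions (redrawn from A/C/T so
the tract structure is stable) and single-base indels bounded by the loop
limits; tract erosion is opt-in. Two generator invariants keep the planted
truth well defined: plants receive A/T flanks so a chance background
guanine can never extend a planted tract (which would silently change the
region the detector sees), and random templates are kept ≥ 6 edits apart —
two templates a couple of edits apart would be one family planted under
two labels, making any recovery score ill-defined.

The end-to-end benchmark (5 families × 20 members, loop substitution rate
0.05, loop indel rate 0.02, 20 kb background) runs detect → cluster →
refine → merge and checks adjusted Rand index ≥ 0.8 with K ± 1 families
recovered; it completes in well under a minute on one CPU, and the test
suite uses these sizes throughout as its standard working scale. Passing
it shows the pipeline's statistical machinery is sound under the stated
mutation model. It does *not* show performance on real genomes: the
background has no repeats or isochores, loop mutations are independent,
and family sizes are balanced — none of which holds genomically. The
genome-scale family counts reported for the human genome depend on
external clustering binaries and unstated seeds and are out of scope here.

## Degenerate inputs and edge cases

Empty sequence sets, clusters below the minimum size (4), constant
distance matrices (k-selection reports `defined = FALSE`), all-gap
alignment columns (training errors out), sequences with no placement
(`g4_thermo()` reports the open chain: MFE 0, frequency 100%), and empty
FASTA files are all handled explicitly and covered by tests. All
randomness (sampling from models, simulation, sphere-free stages have
none) flows through explicit integer seeds, and identical configuration
plus seed gives byte-identical outputs.
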