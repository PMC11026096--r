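---
title: "Somatotopic connectome analysis with somamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatotopic connectome analysis with somamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bristle mechanosensory neurons (BMNs) innervate the bristles that cover an
insect head; each neuron sends one axon through a head nerve into the
subesophageal zone of the brain. A long-standing organizational hypothesis
is somatotopy: neurons from neighboring bristle populations should project
to overlapping zones and talk to overlapping downstream circuitry, while
neurons from distant bristles should not. Testing that hypothesis on an
EM-reconstructed brain requires a chain of analyses — morphological
similarity of skeletons, filtering of machine-predicted synapses,
connectivity profiles and their clustering, partner-group graphs, and
midline-crossing classification — each with thresholds and normalizations
that matter. `somamap` packages that chain as reusable, tested components,
and pairs it with a seeded generator of synthetic somatotopic connectomes
with known ground truth, so every stage can be validated end to end.

## Morphological similarity

Skeletons (SWC trees) are first **pruned** to their synapse-rich territory,
dropping the smooth nerve axon. The original analysis pruned against a 3-d
mesh built from the neuron's synapses; the mesh construction is not
specified anywhere reproducible, so `somamap` prunes to the axis-aligned
bounding box of the neuron's own cleft-filtered presynaptic positions
(`bounding_box()` + `prune_to_region()`), which preserves the operation's
intent (remove the arborization-free cable) while staying exactly testable.
Membership is closed (boundary nodes kept) for deterministic ties; by
default only the largest surviving fragment is retained (`keep =
"largest"`), since whether the original analysis kept minor fragments is
unknowable — `keep = "all"` is available.

Pruned skeletons are **resampled** to a maximum inter-node spacing (default
1 µm) so that point density reflects cable, not tracing habits, and
converted to **dotprops**: each node becomes a point with a unit tangent
from a PCA over its k = 5 nearest nodes and a colinearity weight
α = λ₁/(λ₁+λ₂+λ₃). Tangent signs are canonicalized (first nonzero component
positive) for determinism.

NBLAST-style scoring sums, over query points, a contribution from the
single nearest target point. The published algorithm uses a score matrix
trained on matched and random neuron pairs; that matrix is data-derived and
not reproducible here, so the default scoring function is the parametric
form

  s(d, |u·v|) = exp(−d/σ) · |u·v|,  σ = 3 µm,

which preserves the algorithm's structure (distance decay times tangent
alignment) and makes closed-form checks possible: identical clouds score
exactly N, parallel offset lines score N·exp(−d₀/σ). Any other scoring
function, including a tabulated one, can be passed in. Raw scores are
normalized as the mean of forward and reverse self-score-normalized scores
(the standard "mean" mode; the original report does not state its mode),
giving a symmetric similarity matrix with unit diagonal.

Clustering is Ward on the distance 1 − S (the `ward.D2` criterion, i.e.
Lance–Williams on squared distances). **Cut heights do not transfer**: the
original dendrogram cut heights (5 for morphology, 4.5 for connectivity)
live on the score scale of the natverse pipeline with its trained score
matrix. The transferable quantity is the cluster count, so `somamap` cuts
are specified as k (or as a height on its own scale, with the documented
strictly-below-h semantics, under which duplicates merged at height 0 never
separate).

## Connectivity

The synapse table carries a per-synapse cleft confidence score;
`filter_synapses()` removes scores *below* 50, so a score of exactly 50 is
kept — the boundary semantics follow the stated rule that sub-50 scores are
the unreliable ones. Type-level connectivity sums synaptic weights of
BMN-to-BMN edges by type pair and normalizes by the number of *possible*
edges between the groups. The possible-edge count is taken as directed with
autapses excluded — n_a·n_b off-diagonal, n_a·(n_a−1) on the diagonal —
because the underlying synapse data are directed; the original text does
not define the count, and this choice is recorded in the matrix attributes.
A single-neuron type has no possible within-type edge and its diagonal is
reported missing rather than zero. The un-normalized sums exactly conserve
the within-scope synapse count, which the tests assert.

**Cosine clustering** works on postsynaptic profiles: rows are focal BMNs,
columns non-BMN partners, cells the synapse count of the edge. BMN-to-BMN
edges are excluded before thresholding. Three per-edge synapse thresholds
appear in the source analyses — 3 (the low preset, used for the sparsely
connected eye-bristle neurons), 7 (the main preset) and 6 (a figure
caption) — and they are internally inconsistent, so all three are
first-class presets rather than one "correct" value. The threshold is
applied per edge; the alternative reading (per partner-column total) is a
config switch (`per_column_total`), and the choice is recorded in the
profile object. Rows with no surviving weight are excluded from clustering
and logged, not imputed — this mirrors what actually happens when a high
threshold meets weakly connected neurons.

The pipeline runs cosine clustering in **two passes**: all non-InOm-like
types at the main threshold and the InOm-like type alone at the low
threshold, because joint clustering of a numerous, weakly connected type
with everything else is known to obscure structure. A `--joint` flag runs
the combined pass for comparison.

## Partner graph and laterality

Each non-BMN partner is assigned to the BMN type providing its largest
summed input (ties: lexicographically smallest label, flagged). The
type→partner-group graph keeps an edge only when its weight exceeds 5 % of
the type's total output *onto assigned partners* — the strict inequality
follows the stated ">5 %" rule, and the denominator choice (assigned-partner
universe rather than all presynaptic entries) matches the plotted graph; it
is flagged in the output metadata.

Laterality uses a constant-x midline plane (the mediolateral axis of a
symmetric brain space): a neuron is midline-crossing when *any* node lies
strictly contralateral to its side of origin. A node exactly on the plane
does not cross. The maximum excursion past the midline is reported as a
diagnostic but plays no role in classification.

## The synthetic world

The generator states a world once and the tests live in it:

* **Roster** — 15 types named for head bristle populations, 14 small types
  (4–26 neurons) plus one large "InOm-like" type of 60 neurons. The real
  head has ~555 eye-bristle neurons versus ~150 others; 60 keeps that
  imbalance at desk scale. Exact per-type bristle counts from the source
  imaging tables are not available in extracted form, so counts are
  proportioned to the reconstructed per-type numbers the text does give.
* **Geometry** — type centroids on the unit hemisphere (deterministic
  spiral), per-neuron bristle jitter 0.08 rad, zone centers at
  offset + 40 µm · u so inter-zone distance is monotone in head-surface
  distance; every zone sits ≥ 10 µm right of the midline. Arbor points are
  Gaussian with σ = 2 µm around the zone center (so ipsilateral arbors stay
  ≥ 5σ from the midline and laterality ground truth is unambiguous), plus a
  smooth synapse-free entry axon and, for designated types, a contralateral
  branch reaching 5 µm past the midline.
* **Connectivity** — each type owns 26 partners; connection probabilities
  0.9 / 0.4 / 0.0 for same / neighbor (2 nearest centroids) / distant
  types; edge weights 1 + Poisson(4); sparse BMN-to-BMN edges among same
  and neighboring types; cleft scores from a clipped Normal(70, 25), which
  puts ≈ 21 % of synapses below the 50 filter so the filter genuinely
  bites.

What a green test establishes: that the implementation recovers a known
partition under the stated noise model, that its filters and normalizations
are exact, and that the whole pipeline is deterministic under a seed. What
it does not establish: anything about real EM data — real arbors are not
Gaussian blobs, real partner pools are not type-exclusive, and real synapse
false-positive structure is not i.i.d. Normal. The quantities printed in
the source study (705 BMNs, five clusters, specific percentages) depend on
an external reconstruction snapshot and are out of reach by design.

One interaction worth knowing: with the generator's default mean edge
weight of 5 and ~21 % cleft attrition, the *main* preset (≥ 7 synapses)
censors most true edges — exactly the situation that forced the low
threshold for the weakly connected eye-bristle neurons in the real data.
Recovery benchmarks on the default world therefore use the low preset; the
main preset is meaningful when edges are heavier than the default.

## Numerical choices and edge cases

* Degenerate tangent PCA (coincident points, single node) returns the
  canonical tangent (1,0,0) with α = 1.
* Ward input must be symmetric within 1e−9; the matrix is symmetrized
  exactly before linkage.
* Flat cuts at height h count merges with height < h (strict), then label
  via the merge tree; k-cuts delegate to the tree directly.
* Zero-norm profile rows never reach the cosine kernel (excluded upstream;
  reaching it is an internal error).
* Empty prune results are an error naming the neuron, distinguishing "no
  arbor in region" from silent data loss.
* All neuron ids are opaque strings end to end; 64-bit numeric ids survive
  CSV round-trips untouched.

## Known limitations

Mesh-based pruning, score-matrix training, hemisphere mirroring before
NBLAST, registration to a standard brain, and typing of the postsynaptic
partners are out of scope. The acceptance metrics in
`scripts/acceptance.R` are property-based for the reasons above; every
number it emits is computed at run time from the seeded synthetic world.
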