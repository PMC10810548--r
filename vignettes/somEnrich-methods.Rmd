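---
title: "somEnrich: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somEnrich: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somEnrich)
```

# The problem

Quantitative high-throughput screening (qHTS) scores compound libraries
against panels of in-vitro assays; per assay, a compound's
concentration-response is summarized by a *curve rank*, an activity score
in [−9, 9] combining potency, efficacy and curve quality (positive values
= activation, negative = inhibition). The working hypothesis of this
package is pharmacological: compounds with similar activity profiles
plausibly share targets or modes of action. Grouping compounds by profile
and testing each group for overrepresented gene targets and pathways
yields candidate target associations for compounds that have none — the
raw material of drug-repurposing hypotheses.

`somEnrich` implements the complete chain: self-organizing-map (SOM)
clustering, hierarchical consolidation of undersized clusters, structure
key-based annotation joining, Fisher-exact enrichment under
beta-uniform-mixture FDR control, pathway analysis with a randomized
null, and Tanimoto structural validation.

# Clustering

## SOM model and training

The SOM is a `gridRows × gridCols` lattice of units, each with a codebook
vector in assay space. Training is online: the codebook is initialized
from randomly sampled data rows; at each step the presented profile's
best-matching unit (BMU; minimal Euclidean distance) and its neighbors
move toward the profile, neighbor strength following a Gaussian kernel
over grid distance. Learning rate and radius decay linearly over all
`epochs × n` steps; presentation order is reshuffled every epoch. The
whole procedure is a pure function of `(data, parameters, seed)` — two
runs with the same seed agree bit for bit, which the test suite asserts.

Parameter defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `topology` | rectangular | simplest unit indexing; merging uses centroids and is topology-agnostic; hexagonal is available |
| `epochs` | 100 | online SOMs on library-scale data converge well within 100 passes; doubling changes assignments marginally |
| `lrInitial → lrFinal` | 0.05 → 0.01 | conventional small online rates; updates stay convex so codebooks remain inside the data's value range |
| `radiusInitial` | half the larger grid dimension | standard "cover the map, then localize" schedule |
| `radiusFinal` | 0.1 | at radius 0.1 the Gaussian kernel is effectively BMU-only, so late training converges each unit to the mean of its own basin; larger final radii leave cross-unit pull that biases codebooks toward the grand mean and can *worsen* quantization error relative to the row-sampled initialization |
| grid size | 12 × 12 | a conventional square map for ~10⁴-compound libraries; for the synthetic studies in the tests (≤ 500 compounds, ≤ 5 latent clusters) we use 1×2 to 3×3 grids — the grid should give latent structure a few units of headroom, not dwarf the data (a warning fires when units outnumber compounds) |

No feature scaling is applied: curve ranks share one bounded scale by
construction.

A *cluster* is a non-empty unit after BMU assignment; empty units produce
no cluster. Exact distance ties break to the lowest unit index, making
assignment deterministic.

## Merging undersized clusters

Very small clusters starve the enrichment stage of statistical power, so
clusters with fewer than `minSize = 15` compounds are merged into their
most similar neighbors. Similarity is Pearson distance (1 − r) between
cluster centroids (member means), agglomerated with *complete* linkage:
the distance between two merged groups is the maximum pairwise distance
between their constituent original centroids.

Three choices here were genuinely open and are fixed as follows:

* **Iterative, not single-pass.** Merging repeats — always taking the
  currently smallest undersized cluster and its nearest partner under
  complete linkage — until every cluster meets the floor or one cluster
  remains. A single pass can leave newly formed clusters still under the
  floor; iteration is the only policy that guarantees the floor, and it
  makes the operation idempotent (asserted on 100 random fixtures).
* **Label retention.** The merged cluster keeps the label of the larger
  constituent (ties: lower label), so surviving labels are stable,
  meaningful SOM unit indices throughout.
* **Merged centroid = size-weighted mean** of constituent centroids,
  which equals the centroid of the pooled members — keeping
  `computeCentroids()` and the merge loop mutually consistent.

Pearson distance is undefined for a constant profile; `pearsonDistance()`
errors rather than guessing. Constant centroids do not arise under the
synthetic generator (archetype levels vary across assays almost surely).

# Compound identity and annotation joining

Annotation sources key compounds by structure. To make the join salt- and
stereo-insensitive, each compound's SMILES is reduced to its *main
component* — the longest dot-separated component, ties broken
lexicographically (a literal, deterministic reading of "longest") — and
hashed to InChIKey *block 1*: the first 14 characters of the standard
InChIKey, which encode the skeleton without stereochemistry or
protonation. Stereoisomers and salt forms of one parent therefore
collide, which is exactly the intended behavior. Charges on the retained
component are *not* neutralized: block 1 already ignores protonation in
the common cases, and aggressive standardization is out of scope.
Unparseable structures are recorded as failures and excluded, never
fatal — real libraries always lose a few structures at this step.

`joinAnnotations()` unions (key, gene) pairs across sources, collapsing
duplicates with concatenated source labels, and reports matched/unmatched
counts per source.

# Enrichment statistics

## Contingency semantics

For cluster *C* and gene *g*, over the *annotated universe* (compounds
with ≥ 1 gene annotation):

|  | annotated to *g* | not annotated to *g* |
|---|---|---|
| in *C* | a | b |
| not in *C* | c | d |

The four cells partition the universe — the form Fisher's exact test
requires. "Not annotated to *g*" means exactly that; a compound may
target several genes. The one-tailed p-value is the upper hypergeometric
tail P(X ≥ a) at the table's margins, validated in the tests against an
explicit binomial-coefficient enumeration over every table with N ≤ 30.

## Beta-uniform mixture FDR

P-values pooled over all (cluster, gene) tests are modeled as

$$f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}, \qquad 0 < a < 1,$$

a Uniform(0,1) null component plus a Beta(a, 1) alternative spiking at
zero. The fit maximizes the log-likelihood by L-BFGS-B on
logit-transformed parameters from 10 seeded starts (the likelihood can be
multi-modal at small n). π̂ = λ + (1−λ)a = f(1) bounds the null
proportion from above, and the FDR at threshold τ is estimated as
π̂τ / F(τ) with F(τ) = λτ + (1−λ)τᵃ; inverting FDR(τ) = α gives the
closed-form cutoff

$$\tau = \left[\frac{\hat\pi - \alpha\lambda}{\alpha(1-\lambda)}\right]^{1/(a-1)}.$$

One *global* cutoff is applied across all clusters — a single pooled fit,
not per-cluster fits. Numerical guards: p-values are clamped to a floor
of 1e−12 before the likelihood (p^(a−1) diverges at 0); a pure-null fit
(λ = 1) or a bracket outside (0, 1) yields "no cutoff", i.e. nothing is
declared significant.

The mixture needs sample size: below 50 pooled tests `fitBum()` refuses,
and `clusterGeneEnrichment(adjust = "auto")` falls back to Holm
adjustment at the same α, with a message. This matters for small planted
studies (5 clusters × 1 gene ≈ 25 tests) where the BUM route is not
identifiable; the planted signals are many orders of magnitude below any
reasonable cutoff, so the two routes agree on the calls.

## Pathways and the randomized null

Each cluster's *enriched* genes (not all its genes — following the
package's reading that pathway analysis should characterize the enriched
targets) are tested against GMT gene sets over the annotation-wide gene
background: Fisher one-tailed per set, Holm-adjusted within the cluster,
significant at adjusted p ≤ 0.05. Holm (family-wise) rather than BUM is
used here because the per-cluster pathway families are small.

The randomized null permutes each compound's *entire annotation set* as a
block across compounds. This preserves every cluster's size and the
global multiset of annotation sets — including per-compound annotation
multiplicities — while destroying any cluster–target association. A real
signal shows as the actual significant-pathway count exceeding the null
distribution's median.

# Structural validation

Cluster coherence is checked chemically: Tanimoto similarity
|A∩B| / |A∪B| over fingerprint bit sets, averaged over intra-cluster
versus inter-cluster compound pairs. Real structures get circular
(radius-2) hashed fingerprints via OpenBabel's ECFP4 at its native 4096
bits — the community-standard fingerprint family for Tanimoto screening
comparisons. Two empty bit sets score 0 (featureless molecules carry no
similarity evidence). Strata larger than 10⁶ pairs are subsampled with a
seeded uniform draw; the subsample size is reported, and a test checks
that capped means track exhaustive means.

# The synthetic-data generator

The generator plants known structure at every level the pipeline
consumes:

* **Activity**: cluster archetypes with per-assay levels drawn uniformly
  from {−9, −6, −3, 0, 3, 6, 9} (mimicking curve-rank discreteness
  without modeling concentration-response fitting); member rows are
  archetype + iid Gaussian noise (default sd 1), hard-clipped to [−9, 9]
  — the simplest noise model consistent with the bounded scale.
* **Annotations**: each cluster's planted genes annotate members with
  probability 0.6 and non-members with 0.05 — a strong but not
  deterministic signal, comparable to a well-annotated target class
  against sparse background annotation.
* **Fingerprints**: per-cluster random bit patterns (density 0.1) with
  5% per-bit flips per compound, giving intra > inter Tanimoto without
  simulating chemistry.
* **Pathways**: gene sets wrapping each cluster's planted genes plus
  random decoys. For pathway-level studies we plant 8 genes per cluster —
  the scale of per-cluster enriched-target counts seen in real
  annotation data — because a 1-gene cluster cannot reach Holm-level
  pathway significance no matter how clean the signal.
* Compound identifiers are synthetic 14-uppercase-letter strings in the
  shape of InChIKey block 1, so the annotation join runs unchanged with
  no structure generation.

What the generator does **not** emulate: concentration-response curves
and curve-class artifacts, assay cross-talk and correlated noise,
real chemical scaffolds, unbalanced cluster sizes, and incomplete/biased
annotation databases. Passing tests therefore demonstrate that the
machinery is correct and well-calibrated on clean planted structure, not
that real screening data will yield clusters this crisp.

# Study sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run fully synthetic studies
sized for desk-scale reproduction: 150–500 compounds, 8–16 assays, 2–5
latent clusters, grids from 1×2 to 3×3, 20-seed replication for
stochastic claims, BUM calibration at n = 5,000–10,000 p-values, and an
exhaustive Fisher sweep over all ~37,000 tables with N ≤ 30. These sizes
exercise every code path; scaling to library-sized inputs is a matter of
configuration (grid 12×12, pair-subsampling for the >10⁷ Tanimoto pairs),
not code.

# Known limitations

* The SOM gives no uncertainty on cluster membership; borderline
  compounds sit on unit boundaries silently.
* The BUM cutoff is a plug-in estimate; its FDR control is approximate
  for dependent tests (gene annotations overlap across compounds).
* InChIKey block-1 matching can, rarely, merge distinct skeletons
  (hash collisions) and treats charge variants as identical only insofar
  as block 1 does.
* Pathway enrichment inherits the annotation background: genes never
  annotated to any compound are invisible to both actual and null runs.
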