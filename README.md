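# somEnrich

Activity-profile clustering of compound libraries with gene-target
enrichment, for hypothesis generation in drug repurposing.

Large quantitative high-throughput screening (qHTS) programs score
thousands of compounds against dozens of in-vitro assays. Each compound's
activity is summarized per assay by a *curve rank* in [−9, 9] (positive =
activation, negative = inhibition). Compounds with similar activity
profiles plausibly share targets or modes of action, so clustering the
profile matrix and asking which gene targets are overrepresented in each
cluster surfaces candidate new target–compound links — including for
compounds with no annotated target at all.

`somEnrich` implements that pipeline end to end:

1. **SOM clustering** — a self-organizing map is trained online on the
   compound × assay matrix (Euclidean matching, Gaussian grid
   neighborhood, linear learning-rate/radius decay); each compound maps to
   its best-matching unit, and non-empty units are the clusters.
2. **Small-cluster merging** — clusters with fewer than 15 compounds are
   merged into their most similar neighbors by complete-linkage
   agglomeration under Pearson distance (1 − r) between cluster centroids;
   the merged cluster keeps the label of its larger constituent.
3. **Annotation join** — compounds are keyed by InChIKey block 1 (first 14
   characters, computed on the longest dot-separated SMILES component), a
   salt- and stereo-insensitive identity, and joined to one or more
   compound→gene annotation tables.
4. **Gene-target enrichment** — for every (cluster, gene) pair, a
   one-tailed Fisher exact test on the 2×2 table partitioning the
   annotated universe by cluster membership and gene annotation. All
   p-values are pooled into a beta-uniform mixture (BUM) fit
   f(p) = λ + (1−λ)·a·p^(a−1), whose closed-form threshold τ controls the
   FDR at a chosen level (default 1%).
5. **Pathway enrichment** — each cluster's enriched genes are tested
   against GMT gene sets (Fisher + Holm within cluster), with a
   size-matched randomized-cluster null for comparison.
6. **Structural validation** — Tanimoto similarity of chemical
   fingerprints, contrasting intra- vs inter-cluster means.

A seeded synthetic-data generator plants latent clusters, enriched genes,
pathways and fingerprints with known ground truth, so the whole pipeline
is testable without external screening data.

## Worked example

```r
library(somEnrich)

cfg <- defaultPipelineConfig()
cfg$synthetic$n_compounds <- 300L; cfg$synthetic$n_assays <- 12L
cfg$synthetic$n_clusters <- 5L
cfg$som$grid_rows <- 3L; cfg$som$grid_cols <- 3L; cfg$som$epochs <- 50L
cfg$seed <- 7L

p <- simulateInputs(cfg, "inputs")          # writes TSV/GMT/JSON inputs
cfg$paths$activity    <- p$activity
cfg$paths$annotations <- list(p$annotations)
cfg$paths$gene_sets   <- p$gene_sets

res <- runPipeline(cfg, "run", fingerprintsPath = p$fingerprints)
res$merged$assignment
#> ClusterAssignment: 300 compounds in 5 clusters (sizes 60-60)
head(res$geneEnrichment[res$geneEnrichment$significant,
                        c("cluster_label", "gene", "a", "b", "c", "d", "p_value")])
#>    cluster_label  gene  a b  c   d      p_value
#> 1              0 PG0_1 34 6 10 167 1.123883e-24
#> 6              2 PG1_1 43 3 14 157 1.628690e-29
#> 10             6 PG3_1 41 3  5 168 5.077659e-35
#> 15             7 PG2_1 38 6 10 163 8.817178e-27
#> 19             8 PG4_1 36 7 15 159 3.513231e-22
res$similarity[c("intra_mean", "inter_mean")]
#> $intra_mean
#> [1] 0.4851059
#> $inter_mean
#> [1] 0.07598713
```

The five latent clusters are recovered exactly (labels are SOM unit
indices), each planted gene is the top enriched target of its own cluster
— e.g. gene `PG0_1` annotates 34 of cluster 0's 40 annotated compounds
(`a`) versus 10 of the 177 outside (`c`), p ≈ 1e−24 — and clusters are
about six times more structurally self-similar (0.485) than the
between-cluster background (0.076).

`inst/scripts/som-enrich` wraps the same two entry points for shell use:

```sh
Rscript inst/scripts/som-enrich simulate --out inputs --seed 7
Rscript inst/scripts/som-enrich run-all --config cfg.yaml --out run
```

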