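#' Synthetic qHTS data with planted cluster structure
#'
#' Generates a compound-by-assay activity matrix whose rows fall into
#' `nClusters` latent clusters. Each cluster has an archetype profile with
#' per-assay levels drawn from the discrete curve-rank grid
#' \{-9, -6, -3, 0, 3, 6, 9\}; member rows are archetype plus iid Gaussian
#' noise, hard-clipped to the curve-rank range \[-9, 9\]. Compound
#' identifiers are synthetic 14-uppercase-letter strings shaped like
#' InChIKey block 1, so annotation joins can be exercised without real
#' structures.
#'
#' @param nCompounds,nAssays,nClusters positive integers;
#'   `nClusters <= nCompounds`.
#' @param noiseSd non-negative Gaussian noise standard deviation
#'   (curve-rank units).
#' @param seed integer seed; identical arguments and seed reproduce
#'   identical output.
#' @return list with components `matrix` (an [ActivityMatrix-class]) and
#'   `truth` (a [SyntheticTruth-class]; `plantedGenes` is filled later by
#'   [generateAnnotations()] / [plantedGeneSets()]).
#' @examples
#' sim <- generateActivityMatrix(100, 10, 4, noiseSd = 1, seed = 1)
#' sim$matrix
#' table(sim$truth@labels)
#' @export
generateActivityMatrix <- function(nCompounds, nAssays, nClusters,
                                   noiseSd = 1, seed = 1) {
    nCompounds <- assertCount(nCompounds, "nCompounds")
    nAssays <- assertCount(nAssays, "nAssays")
    nClusters <- assertCount(nClusters, "nClusters")
    if (nClusters > nCompounds)
        stop("nClusters must not exceed nCompounds", call. = FALSE)
    if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
        stop("noiseSd must be a non-negative number", call. = FALSE)

    withSeed(seed, {
        ids <- syntheticKeys(nCompounds)
        levels <- c(-9, -6, -3, 0, 3, 6, 9)
        arch <- matrix(sample(levels, nClusters * nAssays, replace = TRUE),
                       nrow = nClusters, ncol = nAssays)
        colnames(arch) <- sprintf("assay%03d", seq_len(nAssays))
        labels <- sample(rep_len(0:(nClusters - 1L), nCompounds))
        vals <- arch[labels + 1L, , drop = FALSE] +
            matrix(stats::rnorm(nCompounds * nAssays, sd = noiseSd),
                   nCompounds, nAssays)
        vals <- pmin(pmax(vals, -9), 9)
        dimnames(vals) <- list(ids, colnames(arch))
        truth <- new("SyntheticTruth",
                     labels = stats::setNames(as.integer(labels), ids),
                     archetypes = arch,
                     plantedGenes = list(),
                     params = list(nCompounds = nCompounds, nAssays = nAssays,
                                   nClusters = nClusters, noiseSd = noiseSd,
                                   seed = as.integer(seed)))
        list(matrix = ActivityMatrix(vals), truth = truth)
    })
}

## unique random 14-uppercase-letter compound keys (InChIKey block-1 shape)
syntheticKeys <- function(n) {
    keys <- character(0)
    while (length(keys) < n) {
        need <- n - length(keys)
        fresh <- vapply(seq_len(need), function(i)
            paste(sample(LETTERS, 14, replace = TRUE), collapse = ""),
            character(1))
        keys <- unique(c(keys, fresh))
    }
    keys[seq_len(n)]
}

#' Deterministic planted gene symbols per latent cluster
#'
#' Gene symbols planted by the synthetic generator are a pure function of
#' the cluster index, so truth can be reconstructed without side channels.
#' Lists are disjoint across clusters by construction.
#'
#' @param nClusters,genesPerCluster positive integers.
#' @return list of `nClusters` character vectors of length `genesPerCluster`.
#' @examples
#' plantedGeneSets(3, 2)
#' @export
plantedGeneSets <- function(nClusters, genesPerCluster) {
    nClusters <- assertCount(nClusters, "nClusters")
    genesPerCluster <- assertCount(genesPerCluster, "genesPerCluster")
    lapply(0:(nClusters - 1L), function(c)
        sprintf("PG%d_%d", c, seq_len(genesPerCluster)))
}

#' Synthetic compound-to-gene annotations with planted enrichment
#'
#' Annotates each latent cluster's planted genes (see [plantedGeneSets()])
#' to cluster members with probability `enrichmentProb` and to non-members
#' with probability `backgroundProb`, emulating the exported shape of a
#' target-annotation database: one (compound key, gene, source) row per
#' association.
#'
#' @param truth a [SyntheticTruth-class] from [generateActivityMatrix()].
#' @param genesPerCluster planted genes per latent cluster.
#' @param enrichmentProb,backgroundProb annotation probabilities inside and
#'   outside the gene's home cluster; `backgroundProb <= enrichmentProb`.
#' @param seed integer seed.
#' @return an [AnnotationTable-class] with `source = "synthetic"`.
#' @examples
#' sim <- generateActivityMatrix(60, 8, 3, seed = 2)
#' ann <- generateAnnotations(sim$truth, genesPerCluster = 1,
#'                            enrichmentProb = 0.6, backgroundProb = 0.05,
#'                            seed = 2)
#' ann
#' @export
generateAnnotations <- function(truth, genesPerCluster = 1,
                                enrichmentProb = 0.6, backgroundProb = 0.05,
                                seed = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    genesPerCluster <- assertCount(genesPerCluster, "genesPerCluster")
    enrichmentProb <- assertProb(enrichmentProb, "enrichmentProb")
    backgroundProb <- assertProb(backgroundProb, "backgroundProb")
    if (backgroundProb > enrichmentProb)
        stop("backgroundProb must not exceed enrichmentProb", call. = FALSE)

    k <- nrow(truth@archetypes)
    genes <- plantedGeneSets(k, genesPerCluster)
    ids <- names(truth@labels)
    lab <- truth@labels
    withSeed(seed, {
        rows <- vector("list", k * genesPerCluster)
        i <- 0L
        for (c in 0:(k - 1L)) {
            inside <- lab == c
            for (g in genes[[c + 1L]]) {
                p <- ifelse(inside, enrichmentProb, backgroundProb)
                hit <- stats::runif(length(ids)) < p
                i <- i + 1L
                rows[[i]] <- data.frame(compound_key = ids[hit], gene = g,
                                        source = "synthetic",
                                        stringsAsFactors = FALSE)
            }
        }
        AnnotationTable(do.call(rbind, rows))
    })
}

#' Synthetic binary fingerprints, more similar within than between clusters
#'
#' Each latent cluster receives a random seed bit-pattern (each bit set with
#' probability `interSeedDensity`); each compound's fingerprint is its
#' cluster's pattern with independent per-bit flips at probability
#' `intraFlipProb`. With a small flip probability, intra-cluster Tanimoto
#' similarity exceeds inter-cluster similarity, emulating the structural
#' coherence expected of activity-based clusters.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nBits fingerprint width.
#' @param intraFlipProb per-bit flip probability within a cluster.
#' @param interSeedDensity probability a bit is set in a cluster's pattern.
#' @param seed integer seed.
#' @return a [FingerprintSet-class].
#' @examples
#' sim <- generateActivityMatrix(30, 6, 3, seed = 4)
#' fps <- generateFingerprints(sim$truth, nBits = 256, seed = 4)
#' fps
#' @export
generateFingerprints <- function(truth, nBits = 1024, intraFlipProb = 0.05,
                                 interSeedDensity = 0.1, seed = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    nBits <- assertCount(nBits, "nBits")
    intraFlipProb <- assertProb(intraFlipProb, "intraFlipProb")
    interSeedDensity <- assertProb(interSeedDensity, "interSeedDensity")

    k <- nrow(truth@archetypes)
    lab <- truth@labels
    withSeed(seed, {
        patterns <- matrix(stats::runif(k * nBits) < interSeedDensity,
                           nrow = k)
        bits <- lapply(seq_along(lab), function(i) {
            fp <- patterns[lab[[i]] + 1L, ]
            flip <- stats::runif(nBits) < intraFlipProb
            which(xor(fp, flip)) - 1L
        })
        names(bits) <- names(lab)
        new("FingerprintSet", nBits = nBits, bits = bits)
    })
}

#' Synthetic gene sets grouping planted genes into pathways
#'
#' Builds a GMT-writable gene-set collection in which each set contains one
#' latent cluster's planted genes plus `extraGenesPerSet` random decoy genes,
#' so pathway overrepresentation has a recoverable signal.
#'
#' @param truth a [SyntheticTruth-class] whose `plantedGenes` slot is filled
#'   (see [plantedGeneSets()]); alternatively pass `genesPerCluster` to
#'   reconstruct them.
#' @param setsPerCluster gene sets per latent cluster.
#' @param extraGenesPerSet decoy genes added to each set.
#' @param seed integer seed.
#' @param genesPerCluster used to reconstruct planted genes when
#'   `truth@plantedGenes` is empty.
#' @return named list of character gene vectors (a gene-set collection);
#'   names are unique.
#' @examples
#' sim <- generateActivityMatrix(30, 6, 3, seed = 5)
#' generatePathways(sim$truth, setsPerCluster = 1, extraGenesPerSet = 2,
#'                  seed = 5, genesPerCluster = 2)
#' @export
generatePathways <- function(truth, setsPerCluster = 1, extraGenesPerSet = 5,
                             seed = 1, genesPerCluster = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    setsPerCluster <- assertCount(setsPerCluster, "setsPerCluster")
    extraGenesPerSet <- assertCount(extraGenesPerSet, "extraGenesPerSet",
                                    positive = FALSE)
    k <- nrow(truth@archetypes)
    planted <- truth@plantedGenes
    if (!length(planted)) planted <- plantedGeneSets(k, genesPerCluster)

    withSeed(seed, {
        sets <- list()
        for (c in 0:(k - 1L)) {
            for (s in seq_len(setsPerCluster)) {
                decoys <- if (extraGenesPerSet > 0)
                    sprintf("DY%05d", sample.int(99999, extraGenesPerSet))
                else character(0)
                sets[[sprintf("PATH_c%d_%d", c, s)]] <-
                    c(planted[[c + 1L]], decoys)
            }
        }
        sets
    })
}
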