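test_that("activity generator honors shape, labels, clipping and seeds", {
    sim <- generateActivityMatrix(100, 10, 4, noiseSd = 1, seed = 1)
    expect_identical(dim(actValues(sim$matrix)), c(100L, 10L))
    expect_true(all(sim$truth@labels %in% 0:3))
    expect_length(sim$truth@labels, 100)

    ## heavy noise still clipped to the curve-rank range
    big <- generateActivityMatrix(200, 20, 5, noiseSd = 2, seed = 3)
    expect_gte(min(actValues(big$matrix)), -9)
    expect_lte(max(actValues(big$matrix)), 9)

    ## determinism: identical args + seed give identical bits
    again <- generateActivityMatrix(100, 10, 4, noiseSd = 1, seed = 1)
    expect_identical(actValues(sim$matrix), actValues(again$matrix))
    other <- generateActivityMatrix(100, 10, 4, noiseSd = 1, seed = 2)
    expect_false(identical(actValues(sim$matrix), actValues(other$matrix)))

    expect_error(generateActivityMatrix(0, 10, 2), "positive")
    expect_error(generateActivityMatrix(5, 10, 6), "exceed")
})

test_that("zero noise reproduces cluster archetypes exactly", {
    sim <- generateActivityMatrix(50, 8, 2, noiseSd = 0, seed = 7)
    v <- actValues(sim$matrix)
    arch <- sim$truth@archetypes
    for (i in seq_len(nrow(v)))
        expect_identical(unname(v[i, ]),
                         unname(arch[sim$truth@labels[[i]] + 1L, ]))
})

test_that("annotation generator plants disjoint genes at the right rates", {
    sim <- generateActivityMatrix(60, 6, 5, seed = 2)

    ## degenerate probabilities: members all annotated, non-members never
    ann <- generateAnnotations(sim$truth, 2, enrichmentProb = 1,
                               backgroundProb = 0, seed = 1)
    rec <- annotationRecords(ann)
    expect_identical(sort(unique(rec$gene)),
                     sort(unlist(plantedGeneSets(5, 2))))  # 10 distinct genes
    for (cl in 0:4) {
        members <- names(sim$truth@labels)[sim$truth@labels == cl]
        for (g in plantedGeneSets(5, 2)[[cl + 1]]) {
            got <- rec$compound_key[rec$gene == g]
            expect_setequal(got, members)
        }
    }
    expect_error(generateAnnotations(sim$truth, 1, 0.2, 0.5), "exceed")
})

test_that("equal enrichment and background rates are indistinguishable", {
    ## binomial sampling oracle: with p_in = p_out the observed in/out rate
    ## difference stays within 3 binomial standard errors almost always
    sim <- generateActivityMatrix(200, 6, 4, seed = 5)
    g <- plantedGeneSets(4, 1)[[1]]
    members <- names(sim$truth@labels)[sim$truth@labels == 0L]
    nIn <- length(members); nOut <- 200 - nIn
    okCount <- 0
    for (s in 1:100) {
        rec <- annotationRecords(
            generateAnnotations(sim$truth, 1, 0.1, 0.1, seed = s))
        keys <- rec$compound_key[rec$gene == g]
        pIn <- sum(keys %in% members) / nIn
        pOut <- sum(!keys %in% members) / nOut
        pool <- length(keys) / 200
        se <- sqrt(pool * (1 - pool) * (1 / nIn + 1 / nOut))
        if (se == 0 || abs(pIn - pOut) < 3 * se) okCount <- okCount + 1
    }
    expect_gte(okCount, 95)
})

test_that("expected within-cluster annotation count is monotone in the enrichment rate", {
    sim <- generateActivityMatrix(100, 6, 4, seed = 11)
    members <- names(sim$truth@labels)[sim$truth@labels == 0L]
    g <- plantedGeneSets(4, 1)[[1]]
    countIn <- function(prob) {
        mean(vapply(1:50, function(s) {
            rec <- annotationRecords(
                generateAnnotations(sim$truth, 1, prob, 0.05, seed = s))
            sum(rec$compound_key[rec$gene == g] %in% members)
        }, numeric(1)))
    }
    expect_lte(countIn(0.2), countIn(0.5))
    expect_lte(countIn(0.5), countIn(0.9))
})

test_that("fingerprint generator separates clusters and is deterministic", {
    sim <- generateActivityMatrix(40, 6, 4, seed = 3)

    ## no flips: identical fingerprints within a cluster
    fps0 <- generateFingerprints(sim$truth, 128, intraFlipProb = 0,
                                 interSeedDensity = 0.2, seed = 1)
    lab <- sim$truth@labels
    for (cl in 0:3) {
        ids <- names(lab)[lab == cl]
        base <- fingerprintBits(fps0)[[ids[1]]]
        for (id in ids[-1])
            expect_identical(fingerprintBits(fps0)[[id]], base)
    }

    ## determinism at fixed seed
    a <- generateFingerprints(sim$truth, 64, 0.05, 0.1, seed = 9)
    b <- generateFingerprints(sim$truth, 64, 0.05, 0.1, seed = 9)
    expect_identical(fingerprintBits(a), fingerprintBits(b))

    ## planted structure: intra-cluster Tanimoto above inter, 10 seeds
    wins <- 0
    for (s in 1:10) {
        fps <- generateFingerprints(sim$truth, 1024, 0.05, 0.1, seed = s)
        sm <- suppressMessages(
            intraInterSummary(fps, ClusterAssignment(lab), seed = s))
        if (sm$intra_mean > sm$inter_mean) wins <- wins + 1
    }
    expect_identical(wins, 10)
})

test_that("pathway generator wraps planted genes with unique set names", {
    sim <- generateActivityMatrix(30, 6, 5, seed = 4)
    sim$truth@plantedGenes <- plantedGeneSets(5, 2)

    ## no decoys: sets equal the planted lists exactly
    sets0 <- generatePathways(sim$truth, 1, extraGenesPerSet = 0, seed = 1)
    expect_length(sets0, 5)
    for (cl in 0:4)
        expect_setequal(sets0[[sprintf("PATH_c%d_1", cl)]],
                        plantedGeneSets(5, 2)[[cl + 1]])

    sets <- generatePathways(sim$truth, 2, extraGenesPerSet = 3, seed = 1)
    expect_length(sets, 10)
    expect_false(anyDuplicated(names(sets)) > 0)

    ## GMT round trip preserves the collection
    path <- withr::local_tempfile(fileext = ".gmt")
    writeGeneSets(sets, path)
    back <- readGeneSets(path)
    expect_identical(names(back), names(sets))
    for (nm in names(sets)) expect_identical(back[[nm]], sets[[nm]])
})
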