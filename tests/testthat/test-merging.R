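test_that("pearsonDistance matches hand computations and guards input", {
    expect_identical(pearsonDistance(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_identical(pearsonDistance(c(1, 2, 3), c(-1, -2, -3)), 2)
    ## r = 1.5 / sqrt(7/3) = 0.98198...
    expect_equal(pearsonDistance(c(1, 2, 3), c(1, 2, 4)),
                 1 - 1.5 / sqrt(7 / 3), tolerance = 1e-12)
    expect_error(pearsonDistance(c(1, 1, 1), c(1, 2, 3)), "constant")
    expect_error(pearsonDistance(1:3, 1:4), "length")
    expect_error(pearsonDistance(1, 2), "length >= 2")
})

test_that("centroids are member means; zero-noise centroids equal archetypes", {
    x <- ActivityMatrix(matrix(c(2, 4, 4, 6, -1, 0), 3, 2, byrow = TRUE,
                               dimnames = list(c("C1", "C2", "C3"),
                                               c("a1", "a2"))))
    asg <- ClusterAssignment(c(C1 = 0L, C2 = 0L, C3 = 5L))
    cent <- computeCentroids(x, asg)
    expect_equal(unname(cent["0", ]), c(3, 5))
    expect_equal(unname(cent["5", ]), c(-1, 0))  # singleton = its own row

    sim <- generateActivityMatrix(60, 8, 3, noiseSd = 0, seed = 5)
    truthAsg <- ClusterAssignment(sim$truth@labels)
    cent2 <- computeCentroids(sim$matrix, truthAsg)
    for (cl in 0:2)
        expect_equal(unname(cent2[as.character(cl), ]),
                     unname(sim$truth@archetypes[cl + 1, ]),
                     tolerance = 1e-12)
})

test_that("a small cluster is absorbed by its most correlated partner", {
    base <- c(1, 2, 3, 4, 2, 1)
    cent <- rbind(`0` = base + c(0.01, -0.01, 0, 0.01, 0, -0.01),  # A
                  `1` = base,                                      # B
                  `2` = -base)                                     # C
    labels <- rep(c(0L, 1L, 2L), c(5, 30, 40))
    asg <- asgOf(labels)
    res <- mergeSmallClusters(asg, cent, minSize = 15)
    sizes <- clusterSizes(res$assignment)
    expect_identical(sizes, c(`1` = 35L, `2` = 40L))   # A kept B's label
    expect_identical(res$log$absorbed_label, 0L)
    expect_identical(res$log$surviving_label, 1L)
    ## merged centroid is the size-weighted constituent mean
    expect_equal(unname(res$centroids["1", ]),
                 unname((5 * cent["0", ] + 30 * cent["1", ]) / 35),
                 tolerance = 1e-12)
})

test_that("undersized merges iterate until the floor holds or one cluster remains", {
    base <- c(5, 1, 4, 2, 3, 0)
    cent <- rbind(`0` = base + 0.01 * c(1, -1, 0, 1, 0, -1),
                  `1` = base,
                  `2` = -base)
    labels <- rep(c(0L, 1L, 2L), c(5, 6, 40))
    res <- mergeSmallClusters(asgOf(labels), cent, minSize = 15)
    ## small pair merges first (5+6=11 < 15), then onward into the large one
    expect_identical(nrow(res$log), 2L)
    expect_identical(res$log$surviving_label, c(1L, 2L))
    expect_identical(clusterSizes(res$assignment), c(`2` = 51L))
})

test_that("merging is a no-op when every cluster meets the floor", {
    cent <- rbind(`0` = c(1, 2, 3), `1` = c(3, 1, 2))
    labels <- rep(c(0L, 1L), c(20, 16))
    asg <- asgOf(labels)
    res <- mergeSmallClusters(asg, cent, minSize = 15)
    expect_identical(clusterLabels(res$assignment), clusterLabels(asg))
    expect_identical(nrow(res$log), 0L)

    single <- asgOf(rep(0L, 4))
    res1 <- mergeSmallClusters(single, cent["0", , drop = FALSE], 15)
    expect_identical(clusterLabels(res1$assignment), clusterLabels(single))
})

test_that("merge invariants hold on random fixtures", {
    for (s in 1:20) {
        fix <- withr::with_seed(s, {
            k <- sample(5:40, 1)
            sizes <- sample(1:60, k, replace = TRUE)
            labels <- rep(seq_len(k) - 1L, sizes)
            cent <- matrix(stats::rnorm(k * 10), k, 10,
                           dimnames = list(seq_len(k) - 1L, NULL))
            list(asg = asgOf(labels), cent = cent)
        })
        res <- mergeSmallClusters(fix$asg, fix$cent, minSize = 15)
        sizes <- clusterSizes(res$assignment)
        ## size floor or single cluster
        expect_true(min(sizes) >= 15 || length(sizes) == 1L)
        ## compound count conserved, cluster count non-increasing
        expect_identical(sum(sizes), length(clusterLabels(fix$asg)))
        expect_lte(length(sizes), length(clusterSizes(fix$asg)))
        ## idempotent on its own output
        again <- mergeSmallClusters(res$assignment, res$centroids, 15)
        expect_identical(clusterLabels(again$assignment),
                         clusterLabels(res$assignment))
        expect_identical(nrow(again$log), 0L)
    }
})
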