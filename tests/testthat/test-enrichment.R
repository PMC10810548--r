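test_that("contingency cells partition the annotated universe", {
    ## universe of 10, cluster holds 4, gene annotates 3 compounds inside
    keys <- vapply(1:10, function(i)
        paste(rep(LETTERS[i], 14), collapse = ""), character(1))
    asg <- ClusterAssignment(stats::setNames(rep(c(0L, 1L), c(4, 6)), keys))
    rec <- rbind(
        data.frame(compound_key = keys[1:3], gene = "G1", source = "s"),
        data.frame(compound_key = keys, gene = "G0", source = "s"))
    ann <- AnnotationTable(rec)
    tab <- buildContingency(asg, ann, 0L, "G1")
    expect_identical(tab, c(a = 3L, b = 1L, c = 0L, d = 6L))
    expect_identical(sum(tab), 10L)

    ## absent gene gives a = c = 0 but still partitions the universe
    tab0 <- buildContingency(asg, ann, 0L, "NOPE")
    expect_identical(tab0[["a"]], 0L)
    expect_identical(tab0[["c"]], 0L)
    expect_identical(sum(tab0), 10L)
})

test_that("one-tailed Fisher equals the explicit hypergeometric tail", {
    expect_identical(fisherOneTailed(c(0, 3, 2, 5)), 1.0)  # a = 0
    expect_identical(fisherOneTailed(c(0, 0, 0, 0)), 1.0)  # empty table
    expect_equal(fisherOneTailed(c(2, 0, 0, 2)), 1 / 6, tolerance = 1e-12)

    ## brute-force sweep over all tables with N <= 12
    for (N in 2:12) for (k in 1:(N - 1)) for (m in 1:(N - 1)) {
        for (a in max(0, k + m - N):min(k, m)) {
            tab <- c(a, k - a, m - a, N - k - m + a)
            expect_equal(fisherOneTailed(tab),
                         bruteFisher(tab[1], tab[2], tab[3], tab[4]),
                         tolerance = 1e-10)
        }
    }

    ## agreement with the standard one-sided test implementation
    tab <- matrix(c(8, 2, 3, 12), 2, byrow = TRUE)
    expect_equal(fisherOneTailed(c(8, 2, 3, 12)),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
})

test_that("the BUM fit recovers mixture parameters and flags uniformity", {
    ## uniform p-values: the null-proportion upper bound is essentially 1
    p <- withr::with_seed(1, stats::runif(10000))
    fit <- fitBum(p)
    expect_gte(fit@piUb, 0.95)

    ## a = 1 reduces the density to uniform for any lambda
    fitA <- new("BumFit", aHat = 0.999999, lambdaHat = 0.3, piUb = 1,
                loglik = 0, n = 100L)
    expect_equal(bumDensity(fitA, c(0.1, 0.5, 0.9)), rep(1, 3),
                 tolerance = 1e-4)

    ## parameter recovery on two seeded mixture draws
    for (s in 1:2) {
        p <- rbum(10000, a = 0.3, lam = 0.6, seed = s)
        fit <- fitBum(p, seed = s)
        expect_lt(abs(fit@aHat - 0.3), 0.05)
        expect_lt(abs(fit@lambdaHat - 0.6), 0.08)
    }

    ## density integrates to one for fitted parameters
    fit <- fitBum(rbum(5000, 0.4, 0.5, seed = 3))
    expect_equal(stats::integrate(function(x) bumDensity(fit, x), 0, 1,
                                  rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)

    expect_error(fitBum(stats::runif(10)), "Holm")
})

test_that("the closed-form FDR cutoff solves FDR(tau) = alpha", {
    ## pure-null fit: no cutoff exists
    pure <- new("BumFit", aHat = 0.5, lambdaHat = 1, piUb = 1,
                loglik = 0, n = 100L)
    expect_true(is.na(bumFdrCutoff(pure, 0.01)))

    ## closed form vs bisection root, over random valid fits
    withr::with_seed(7, {
        for (i in 1:100) {
            a <- stats::runif(1, 0.05, 0.95)
            lam <- stats::runif(1, 0, 0.9)
            fit <- new("BumFit", aHat = a, lambdaHat = lam,
                       piUb = lam + (1 - lam) * a, loglik = 0, n = 1000L)
            alpha <- stats::runif(1, 0.001, min(0.2, fit@piUb * 0.9))
            tau <- bumFdrCutoff(fit, alpha)
            if (is.na(tau)) next
            expect_equal(bumFdr(fit, tau), alpha, tolerance = 1e-9)
            root <- stats::uniroot(function(t) bumFdr(fit, t) - alpha,
                                   c(1e-300, 1 - 1e-12), tol = 1e-15)$root
            expect_equal(tau, root, tolerance = 1e-6)
        }
    })

    ## monotonicity: a larger alpha never shrinks the cutoff
    withr::with_seed(8, {
        for (i in 1:100) {
            a <- stats::runif(1, 0.05, 0.95)
            lam <- stats::runif(1, 0, 0.9)
            fit <- new("BumFit", aHat = a, lambdaHat = lam,
                       piUb = lam + (1 - lam) * a, loglik = 0, n = 1000L)
            t1 <- bumFdrCutoff(fit, 0.01)
            t2 <- bumFdrCutoff(fit, 0.05)
            if (!is.na(t1) && !is.na(t2)) expect_lte(t1, t2)
        }
    })
})

test_that("Holm adjustment reproduces the hand step-down", {
    expect_identical(holmAdjust(0.2), 0.2)
    expect_equal(holmAdjust(c(0.01, 0.04)), c(0.02, 0.04))
    expect_equal(holmAdjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
    ## monotone non-decreasing in rank, capped at one
    p <- c(0.9, 0.001, 0.5, 0.04)
    adj <- holmAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= 0))
    expect_true(all(adj <= 1))
})

test_that("planted genes are recovered by per-cluster gene enrichment", {
    w <- plantedWorld(n = 300, nClusters = 5, seed = 1)
    res <- suppressMessages(clusterGeneEnrichment(w$assignment,
                                                  w$annotations))
    ## the pooled-test count equals the (cluster, gene) pairs with a >= 1
    rec <- annotationRecords(w$annotations)
    lab <- clusterLabels(w$assignment)
    manual <- sum(table(lab[rec$compound_key], rec$gene) >= 1)
    expect_identical(nrow(res), manual)
    expect_true(all(res$a >= 1))

    ## every planted gene significant in its own latent cluster
    for (cl in 0:4) {
        g <- plantedGeneSets(5, 1)[[cl + 1]]
        hit <- res[res$cluster_label == cl & res$gene == g, ]
        expect_identical(nrow(hit), 1L)
        expect_true(hit$significant)
    }

    ## empty annotations give an empty result
    none <- AnnotationTable(data.frame(compound_key = character(),
                                       gene = character(),
                                       source = character()))
    expect_identical(nrow(clusterGeneEnrichment(w$assignment, none)), 0L)
    single <- ClusterAssignment(stats::setNames(
        rep(0L, 10), names(w$truth@labels)[1:10]))
    expect_error(clusterGeneEnrichment(single, w$annotations), "2 clusters")
})

test_that("permuted annotations produce few significant calls", {
    w <- plantedWorld(n = 300, nClusters = 5, genesPerCluster = 4, seed = 2)
    rec <- annotationRecords(w$annotations)
    ok <- 0
    for (s in 1:5) {
        prec <- withr::with_seed(s, {
            ids <- compoundIds(w$assignment)
            perm <- stats::setNames(sample(ids), ids)
            data.frame(compound_key = perm[rec$compound_key],
                       gene = rec$gene, source = rec$source)
        })
        res <- suppressMessages(clusterGeneEnrichment(
            w$assignment, AnnotationTable(prec), seed = s))
        if (sum(res$significant) <= max(1, 0.01 * nrow(res))) ok <- ok + 1
    }
    expect_gte(ok, 4)
})

test_that("pathway overrepresentation hits an exactly matching set", {
    ## cluster's enriched genes equal one pathway of 5 in a background of 100
    background <- sprintf("BG%03d", 1:100)
    pw <- background[1:5]
    sets <- list(hit = pw, miss = background[50:60])
    res <- pathwayEnrichment(list(`0` = pw), sets, background)
    hit <- res[res$pathway == "hit", ]
    expect_equal(hit$p_value, 1 / choose(100, 5), tolerance = 1e-12)
    expect_true(hit$significant)

    ## no overlap anywhere: nothing significant
    res2 <- pathwayEnrichment(list(`0` = background[90:95]),
                              list(s = background[1:5]), background)
    expect_false(any(res2$significant))

    ## Holm ordering within each cluster
    expect_true(all(tapply(seq_len(nrow(res)), res$cluster_label, function(i)
        all(diff(res$adjusted_p[i][order(res$p_value[i])]) >= 0))))

    expect_error(pathwayEnrichment(list(`0` = "X"), sets, character()),
                 "background")
    expect_error(pathwayEnrichment(list(`0` = "X"), sets, background),
                 "missing from the background")
})

test_that("the randomized null preserves structure and loses signal", {
    w <- plantedWorld(n = 250, nClusters = 5, genesPerCluster = 6,
                      enrichmentProb = 0.7, backgroundProb = 0.05, seed = 3)
    w$truth@plantedGenes <- plantedGeneSets(5, 6)
    sets <- generatePathways(w$truth, 1, extraGenesPerSet = 0, seed = 3)

    cmp <- randomizedNullComparison(w$assignment, w$annotations, sets,
                                    nReps = 3, seed = 1)
    ## cluster sizes unchanged by construction (assignment never touched);
    ## the annotation multiset is preserved per replicate
    expect_identical(nrow(cmp$null), 3L)
    expect_gte(cmp$actual$nSignificant, 1)
    expect_gt(cmp$actual$nSignificant, cmp$summary$nullMedianSignificant)

    ## block permutation keeps each compound's annotation set together:
    ## total rows and per-gene counts are invariant
    rec <- annotationRecords(w$annotations)
    perm <- withr::with_seed(1, {
        ids <- compoundIds(w$assignment)
        s <- split(rec$gene, factor(rec$compound_key, levels = ids))
        p <- sample(ids)
        data.frame(compound_key = rep(p, lengths(s[ids])),
                   gene = unlist(s[ids], use.names = FALSE))
    })
    expect_identical(sort(table(perm$gene)), sort(table(rec$gene)))
    expect_identical(nrow(perm), nrow(rec))
})
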