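## fixtures shared across test files; all built in code, seeded

## small activity matrix with two well-separated blobs
blobMatrix <- function(n = 100, nAssays = 8, sep = 5, noiseSd = 1,
                       seed = 1) {
    withr::with_seed(seed, {
        labels <- sample(rep(0:1, length.out = n))
        arch <- rbind(rep(-sep, nAssays), rep(sep, nAssays))
        v <- arch[labels + 1L, ] +
            matrix(stats::rnorm(n * nAssays, sd = noiseSd), n, nAssays)
        v <- pmin(pmax(v, -9), 9)
        dimnames(v) <- list(sprintf("CPD%04d", seq_len(n)),
                            sprintf("a%02d", seq_len(nAssays)))
        list(matrix = ActivityMatrix(v), labels = labels)
    })
}

## hand-built assignment: named labels
asgOf <- function(labels, ids = sprintf("CPD%04d", seq_along(labels))) {
    ClusterAssignment(stats::setNames(as.integer(labels), ids))
}

## brute-force one-tailed Fisher via explicit binomial coefficients:
## P(X >= a) for X hypergeometric with margins of (a, b, c, d)
bruteFisher <- function(a, b, c, d) {
    m <- a + c            # compounds annotated to the gene
    n <- b + d            # compounds not annotated
    k <- a + b            # cluster size
    aMax <- min(m, k)
    tot <- choose(m + n, k)
    sum(vapply(a:aMax, function(x) choose(m, x) * choose(n, k - x),
               numeric(1))) / tot
}

## draw p-values from the beta-uniform mixture f(p)=lam+(1-lam)*a*p^(a-1)
rbum <- function(n, a, lam, seed) {
    withr::with_seed(seed, {
        isNull <- stats::runif(n) < lam
        p <- stats::runif(n)
        p[!isNull] <- p[!isNull]^(1 / a)   # Beta(a,1) via inverse cdf
        p
    })
}

## annotated synthetic world with true-label clusters, for enrichment tests
plantedWorld <- function(n = 300, nClusters = 5, genesPerCluster = 1,
                         enrichmentProb = 0.6, backgroundProb = 0.05,
                         seed = 1) {
    sim <- generateActivityMatrix(n, 12, nClusters, noiseSd = 1, seed = seed)
    ann <- generateAnnotations(sim$truth, genesPerCluster, enrichmentProb,
                               backgroundProb, seed = seed)
    list(matrix = sim$matrix, truth = sim$truth,
         assignment = ClusterAssignment(sim$truth@labels), annotations = ann)
}
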