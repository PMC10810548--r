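#' Contingency table for gene-target overrepresentation in a cluster
#'
#' Over the annotated universe (compounds carrying at least one gene
#' annotation and present in the assignment), counts
#' \describe{
#'   \item{a}{compounds annotated to the gene, inside the cluster}
#'   \item{b}{compounds not annotated to the gene, inside the cluster}
#'   \item{c}{compounds annotated to the gene, outside the cluster}
#'   \item{d}{compounds not annotated to the gene, outside the cluster}
#' }
#' The four cells partition the universe: `a + b` is the cluster's annotated
#' size and `a + c` the gene's total annotated compounds. A compound may
#' target several genes; "not annotated to the gene" means exactly that,
#' regardless of its other targets.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param annotations an [AnnotationTable-class] keyed by the assignment's
#'   compound identifiers.
#' @param clusterLabel cluster to test.
#' @param gene gene symbol to test (absent genes give `a = c = 0`).
#' @return named integer vector `c(a, b, c, d)`.
#' @seealso [fisherOneTailed()], [clusterGeneEnrichment()]
#' @export
buildContingency <- function(assignment, annotations, clusterLabel, gene) {
    stopifnot(is(assignment, "ClusterAssignment"),
              is(annotations, "AnnotationTable"))
    rec <- annotationRecords(annotations)
    lab <- clusterLabels(assignment)
    universe <- intersect(names(lab), unique(rec$compound_key))
    inCl <- lab[universe] == clusterLabel
    hasGene <- universe %in% rec$compound_key[rec$gene == gene]
    c(a = sum(inCl & hasGene), b = sum(inCl & !hasGene),
      c = sum(!inCl & hasGene), d = sum(!inCl & !hasGene))
}

#' One-tailed Fisher exact test for overrepresentation
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge a)} with the table's
#' margins fixed -- the overrepresentation direction of Fisher's exact
#' test. An all-zero table returns 1 by convention.
#'
#' @param tab numeric vector `c(a, b, c, d)` of non-negative counts (see
#'   [buildContingency()]).
#' @return p-value in (0, 1\].
#' @examples
#' fisherOneTailed(c(a = 2, b = 0, c = 0, d = 2))  # 1/6
#' @export
fisherOneTailed <- function(tab) {
    stopifnot(length(tab) == 4L, all(tab >= 0))
    a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
    if (a + b + cc + d == 0) return(1.0)
    stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Fit a beta-uniform mixture to pooled p-values
#'
#' Maximum-likelihood fit of the BUM density
#' \eqn{f(p) = \lambda + (1-\lambda)\, a\, p^{a-1}} on (0, 1\], with
#' \eqn{0 < a < 1} and \eqn{0 \le \lambda \le 1}, by seeded multi-start
#' bounded quasi-Newton optimization on logit-transformed parameters. The
#' fit is the basis for the FDR-controlling p-value cutoff (see
#' [bumFdrCutoff()]).
#'
#' The likelihood can be multi-modal for small samples, hence the
#' multi-start; with fewer than `minN` p-values the fit is refused --
#' use Holm adjustment instead at that scale.
#'
#' @param pValues numeric vector of p-values; values below `pFloor` are
#'   clamped to it (the density diverges at 0 for `a < 1`).
#' @param nStarts number of optimization starts (default 10).
#' @param pFloor lower clamp for p-values (default 1e-12).
#' @param minN minimum number of p-values (default 50).
#' @param seed integer seed for the start points.
#' @return a [BumFit-class].
#' @export
fitBum <- function(pValues, nStarts = 10, pFloor = 1e-12, minN = 50,
                   seed = 1) {
    p <- as.numeric(pValues)
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    if (length(p) < minN)
        stop("fewer than ", minN, " p-values; the beta-uniform mixture is ",
             "unreliable at this scale -- use Holm adjustment instead",
             call. = FALSE)
    p <- pmax(p, pFloor)
    lp <- log(p)

    negll <- function(theta) {
        a <- stats::plogis(theta[1])
        lam <- stats::plogis(theta[2])
        dens <- lam + (1 - lam) * a * exp((a - 1) * lp)
        -sum(log(pmax(dens, 1e-300)))
    }
    starts <- withSeed(seed, {
        s <- matrix(stats::runif(2 * nStarts, -3, 3), ncol = 2)
        s[1, ] <- c(0, 0)                  # always include a central start
        s
    })
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                         lower = c(-15, -15), upper = c(15, 15)),
            error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best)) stop("beta-uniform mixture fit failed", call. = FALSE)
    aHat <- stats::plogis(best$par[1])
    lamHat <- stats::plogis(best$par[2])
    new("BumFit", aHat = aHat, lambdaHat = lamHat,
        piUb = lamHat + (1 - lamHat) * aHat,
        loglik = -best$value, n = length(p))
}

#' BUM density, distribution function, and estimated FDR
#'
#' Utility functions of a fitted beta-uniform mixture: the density
#' \eqn{f(p)}, the cdf \eqn{F(\tau) = \lambda\tau + (1-\lambda)\tau^a}, and
#' the estimated FDR at threshold \eqn{\tau},
#' \eqn{\mathrm{FDR}(\tau) = \hat\pi\,\tau / F(\tau)} with
#' \eqn{\hat\pi = \lambda + (1-\lambda)a}.
#'
#' @param fit a [BumFit-class].
#' @param p,tau evaluation points in (0, 1\].
#' @return numeric vector.
#' @export
bumDensity <- function(fit, p) {
    fit@lambdaHat + (1 - fit@lambdaHat) * fit@aHat * p^(fit@aHat - 1)
}

#' @rdname bumDensity
#' @export
bumCdf <- function(fit, tau) {
    fit@lambdaHat * tau + (1 - fit@lambdaHat) * tau^fit@aHat
}

#' @rdname bumDensity
#' @export
bumFdr <- function(fit, tau) {
    fit@piUb * tau / bumCdf(fit, tau)
}

#' FDR-controlling p-value cutoff from a BUM fit
#'
#' Closed-form threshold \eqn{\tau} at which the estimated FDR equals
#' `alpha`:
#' \deqn{\tau = \left[\frac{\hat\pi - \alpha\lambda}{\alpha(1-\lambda)}
#'   \right]^{1/(a - 1)}.}
#' Returns `NA` when no threshold in (0, 1) achieves `alpha` -- in
#' particular for a pure-null fit (\eqn{\lambda = 1}), where the estimated
#' FDR is 1 at every threshold.
#'
#' @param fit a [BumFit-class].
#' @param alpha target FDR level in (0, 1) (default 0.01).
#' @return p-value threshold in (0, 1), or `NA_real_`.
#' @export
bumFdrCutoff <- function(fit, alpha = 0.01) {
    stopifnot(is(fit, "BumFit"), alpha > 0, alpha < 1)
    lam <- fit@lambdaHat
    if (lam >= 1) return(NA_real_)
    bracket <- (fit@piUb - alpha * lam) / (alpha * (1 - lam))
    if (!is.finite(bracket) || bracket <= 0) return(NA_real_)
    tau <- bracket^(1 / (fit@aHat - 1))
    if (!is.finite(tau) || tau <= 0 || tau >= 1) return(NA_real_)
    tau
}

#' Holm step-down adjustment
#'
#' Classical Holm family-wise-error correction: the i-th smallest p-value
#' is multiplied by (n - i + 1), the sequence made monotone non-decreasing,
#' and capped at 1; values return in the original order.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
holmAdjust <- function(pValues) {
    stopifnot(all(pValues >= 0 & pValues <= 1))
    stats::p.adjust(pValues, method = "holm")
}

#' Per-cluster gene-target enrichment with pooled FDR control
#'
#' For every (cluster, gene) pair in which the gene annotates at least one
#' compound of the cluster, builds the overrepresentation contingency table
#' over the annotated universe and computes the one-tailed Fisher p-value.
#' All p-values across clusters and genes are pooled into a single
#' beta-uniform mixture fit, and pairs at or below the FDR-controlling
#' cutoff (see [bumFdrCutoff()]) are flagged significant -- one global
#' cutoff, not per-cluster fits.
#'
#' When the pooled test count is below `minBumTests` the mixture fit is not
#' identifiable in practice; with `adjust = "auto"` (default) the function
#' then falls back to Holm adjustment at the same `alpha`, with a message.
#'
#' @param assignment a [ClusterAssignment-class] with >= 2 clusters.
#' @param annotations an [AnnotationTable-class]; an empty table yields an
#'   empty result.
#' @param alpha FDR level (default 0.01).
#' @param adjust `"auto"`, `"bum"`, or `"holm"`.
#' @param minBumTests minimum pooled tests for the BUM route (default 50).
#' @param pFloor p-value clamp used inside the BUM fit.
#' @param seed seed for the BUM multi-start.
#' @return data.frame with columns `cluster_label`, `gene`, `a`, `b`, `c`,
#'   `d`, `p_value`, `adjusted_p` (Holm route; `NA` otherwise),
#'   `cutoff_used`, `significant`, `adjustment`; the fitted [BumFit-class]
#'   (BUM route) is attached as attribute `"bumFit"`.
#' @examples
#' sim <- generateActivityMatrix(200, 10, 4, seed = 11)
#' ann <- generateAnnotations(sim$truth, 1, 0.6, 0.05, seed = 11)
#' asg <- ClusterAssignment(sim$truth@labels)  # true clusters
#' res <- clusterGeneEnrichment(asg, ann)
#' head(res[order(res$p_value), ])
#' @export
clusterGeneEnrichment <- function(assignment, annotations, alpha = 0.01,
                                  adjust = c("auto", "bum", "holm"),
                                  minBumTests = 50, pFloor = 1e-12,
                                  seed = 1) {
    stopifnot(is(assignment, "ClusterAssignment"),
              is(annotations, "AnnotationTable"))
    adjust <- match.arg(adjust)
    lab <- clusterLabels(assignment)
    if (length(unique(lab)) < 2L)
        stop("need at least 2 clusters for enrichment", call. = FALSE)
    rec <- annotationRecords(annotations)
    rec <- rec[rec$compound_key %in% names(lab), , drop = FALSE]
    empty <- data.frame(cluster_label = integer(), gene = character(),
                        a = integer(), b = integer(), c = integer(),
                        d = integer(), p_value = numeric(),
                        adjusted_p = numeric(), cutoff_used = numeric(),
                        significant = logical(), adjustment = character())
    if (!nrow(rec)) return(empty)

    universe <- unique(rec$compound_key)
    N <- length(universe)
    clOf <- lab[universe]
    ## cluster x gene incidence counts over the universe
    cnt <- table(cluster = clOf[rec$compound_key], gene = rec$gene)
    clSize <- table(factor(clOf, levels = rownames(cnt)))
    geneTotal <- colSums(cnt)

    idx <- which(cnt >= 1, arr.ind = TRUE)
    a <- as.integer(cnt[idx])
    cl <- as.integer(rownames(cnt)[idx[, 1]])
    gene <- colnames(cnt)[idx[, 2]]
    nIn <- as.integer(clSize[idx[, 1]])
    nGene <- as.integer(geneTotal[idx[, 2]])
    b <- nIn - a
    cc <- nGene - a
    d <- N - a - b - cc
    p <- stats::phyper(a - 1, nGene, N - nGene, nIn, lower.tail = FALSE)

    res <- data.frame(cluster_label = cl, gene = gene, a = a, b = b, c = cc,
                      d = d, p_value = p, adjusted_p = NA_real_,
                      cutoff_used = NA_real_, significant = FALSE,
                      adjustment = NA_character_,
                      stringsAsFactors = FALSE)
    res <- res[order(res$cluster_label, res$p_value, res$gene), ]
    rownames(res) <- NULL

    route <- adjust
    if (route == "auto")
        route <- if (nrow(res) >= minBumTests) "bum" else "holm"
    if (route == "bum") {
        fit <- fitBum(res$p_value, pFloor = pFloor, seed = seed)
        tau <- bumFdrCutoff(fit, alpha)
        res$cutoff_used <- if (is.na(tau)) NA_real_ else tau
        res$significant <- !is.na(tau) & res$p_value <= tau
        res$adjustment <- "bum_fdr"
        attr(res, "bumFit") <- fit
    } else {
        if (adjust == "auto")
            message("pooled test count ", nrow(res), " < ", minBumTests,
                    "; using Holm adjustment instead of the BUM fit")
        res$adjusted_p <- holmAdjust(res$p_value)
        res$significant <- res$adjusted_p <= alpha
        res$adjustment <- "holm"
    }
    attr(res, "enrichedPerCluster") <-
        vapply(split(res$significant, res$cluster_label), sum, integer(1))
    res
}

#' Extract each cluster's significantly enriched genes
#'
#' @param results data.frame from [clusterGeneEnrichment()].
#' @return named list, cluster label -> character vector of enriched genes
#'   (clusters with none are omitted).
#' @export
enrichedGeneSets <- function(results) {
    sig <- results[results$significant, , drop = FALSE]
    if (!nrow(sig)) return(list())
    lapply(split(sig$gene, sig$cluster_label), unique)
}

#' Pathway overrepresentation of each cluster's enriched genes
#'
#' Per cluster and per gene set: a 2x2 table of (enriched vs not) x (in
#' pathway vs not) over the background gene universe, one-tailed Fisher
#' p-value, Holm adjustment within the cluster, significance at adjusted
#' p <= `alpha`.
#'
#' @param enrichedGenes named list, cluster -> enriched gene vector (see
#'   [enrichedGeneSets()]).
#' @param geneSets named list of character vectors (see [readGeneSets()]).
#' @param background character vector of the gene universe; must contain
#'   every enriched gene.
#' @param alpha significance level on the Holm-adjusted p (default 0.05).
#' @return data.frame with columns `cluster_label`, `pathway`, `a`, `b`,
#'   `c`, `d`, `p_value`, `adjusted_p`, `significant`, `adjustment`.
#' @export
pathwayEnrichment <- function(enrichedGenes, geneSets, background,
                              alpha = 0.05) {
    background <- unique(background)
    if (!length(background)) stop("empty background", call. = FALSE)
    stray <- setdiff(unique(unlist(enrichedGenes)), background)
    if (length(stray))
        stop("enriched gene(s) missing from the background: ",
             paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
    N <- length(background)
    out <- list()
    for (cl in names(enrichedGenes)) {
        eg <- intersect(enrichedGenes[[cl]], background)
        if (!length(eg)) next
        rows <- lapply(names(geneSets), function(ps) {
            pw <- intersect(geneSets[[ps]], background)
            a <- length(intersect(eg, pw))
            b <- length(eg) - a
            cc <- length(pw) - a
            d <- N - a - b - cc
            data.frame(cluster_label = cl, pathway = ps, a = a, b = b,
                       c = cc, d = d,
                       p_value = fisherOneTailed(c(a, b, cc, d)),
                       stringsAsFactors = FALSE)
        })
        df <- do.call(rbind, rows)
        df$adjusted_p <- holmAdjust(df$p_value)
        df$significant <- df$adjusted_p <= alpha
        df$adjustment <- "holm"
        out[[cl]] <- df
    }
    if (!length(out))
        return(data.frame(cluster_label = character(), pathway = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p_value = numeric(),
                          adjusted_p = numeric(), significant = logical(),
                          adjustment = character()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Compare pathway enrichment against a randomized-cluster null
#'
#' Repeatedly permutes each compound's whole annotation set across
#' compounds (cluster sizes and the global multiset of annotation sets are
#' both preserved), reruns gene-target enrichment followed by pathway
#' enrichment, and collects the null pathway p-values. The contrast between
#' the actual significant-pathway count and the null distribution shows
#' whether compounds targeting similar pathways really are co-clustered.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param annotations an [AnnotationTable-class].
#' @param geneSets named list of gene sets.
#' @param nReps number of randomized replicates (default 20).
#' @param seed integer seed.
#' @param alphaFdr FDR level for the gene-target stage (default 0.01).
#' @param alphaPathway level for the pathway stage (default 0.05).
#' @param ... further arguments to [clusterGeneEnrichment()].
#' @return list with `actual` (list: `pValues`, `nSignificant`), `null`
#'   (data.frame: `rep`, `nSignificant`), `nullPValues` (list per rep), and
#'   `summary` (actual count, null median).
#' @export
randomizedNullComparison <- function(assignment, annotations, geneSets,
                                     nReps = 20, seed = 1, alphaFdr = 0.01,
                                     alphaPathway = 0.05, ...) {
    stopifnot(is(assignment, "ClusterAssignment"),
              is(annotations, "AnnotationTable"))
    nReps <- assertCount(nReps, "nReps")
    background <- unique(annotationRecords(annotations)$gene)

    runOnce <- function(ann, repSeed) {
        ge <- suppressMessages(
            clusterGeneEnrichment(assignment, ann, alpha = alphaFdr,
                                  seed = repSeed, ...))
        pe <- pathwayEnrichment(enrichedGeneSets(ge), geneSets, background,
                                alpha = alphaPathway)
        list(pValues = pe$p_value, nSignificant = sum(pe$significant))
    }

    actual <- runOnce(annotations, stableSeed("actual", seed))
    ids <- compoundIds(assignment)
    rec <- annotationRecords(annotations)
    sets <- split(rec$gene, factor(rec$compound_key, levels = ids))
    nullRows <- vector("list", nReps)
    nullP <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        permAnn <- withSeed(stableSeed(sprintf("null_rep_%d", r), seed), {
            perm <- sample(ids)
            genes <- sets[ids]         # annotation set of each compound
            newKey <- rep(perm, lengths(genes))
            AnnotationTable(data.frame(compound_key = newKey,
                                       gene = unlist(genes, use.names = FALSE),
                                       source = "permuted",
                                       stringsAsFactors = FALSE))
        })
        res <- runOnce(permAnn, stableSeed(sprintf("null_fit_%d", r), seed))
        nullRows[[r]] <- data.frame(rep = r,
                                    nSignificant = res$nSignificant)
        nullP[[r]] <- res$pValues
    }
    null <- do.call(rbind, nullRows)
    list(actual = actual, null = null, nullPValues = nullP,
         summary = list(actualSignificant = actual$nSignificant,
                        nullMedianSignificant = stats::median(null$nSignificant)))
}
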