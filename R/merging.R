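#' Pearson correlation distance
#'
#' `1 - r` where `r` is the Pearson correlation coefficient; ranges over
#' \[0, 2\] (0 = perfectly correlated, 2 = perfectly anti-correlated). Used
#' as the dissimilarity between cluster centroids during merging.
#'
#' @param x,y numeric vectors of equal length >= 2; neither constant.
#' @return number in \[0, 2\].
#' @examples
#' pearsonDistance(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonDistance <- function(x, y) {
    if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
    if (length(x) < 2L) stop("need length >= 2", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for a constant vector", call. = FALSE)
    1 - stats::cor(x, y)
}

#' Per-cluster centroid activity profiles
#'
#' Arithmetic mean of the member rows, per assay. Clusters whose members are
#' absent from the matrix are excluded with a warning.
#'
#' @param x an [ActivityMatrix-class].
#' @param assignment a [ClusterAssignment-class] over the same compounds.
#' @return numeric matrix, one row per cluster (rownames = cluster labels),
#'   one column per assay.
#' @export
computeCentroids <- function(x, assignment) {
    stopifnot(is(x, "ActivityMatrix"), is(assignment, "ClusterAssignment"))
    lab <- clusterLabels(assignment)
    v <- actValues(x)
    present <- names(lab) %in% rownames(v)
    if (!all(present)) {
        lost <- unique(lab[!present])
        lab <- lab[present]
        gone <- setdiff(lost, lab)
        if (length(gone))
            warning("cluster(s) with no compounds in the matrix excluded: ",
                    paste(sort(gone), collapse = ", "))
    }
    labs <- sort(unique(lab))
    cent <- t(vapply(labs, function(l)
        colMeans(v[names(lab)[lab == l], , drop = FALSE]),
        numeric(ncol(v))))
    rownames(cent) <- labs
    colnames(cent) <- colnames(v)
    cent
}

#' Merge undersized clusters into their most similar neighbors
#'
#' Consolidates clusters with fewer than `minSize` compounds by
#' complete-linkage agglomeration under Pearson distance over the original
#' cluster centroids: iteratively, the smallest undersized cluster is merged
#' with its nearest partner -- the cluster minimizing the maximum Pearson
#' distance between any pair of constituent centroids (complete linkage).
#' The merged cluster keeps the label of the larger constituent (ties: the
#' lower label), and its centroid is the size-weighted mean of the
#' constituents, which equals the centroid of the pooled members. Iteration
#' continues until no cluster is below `minSize` or a single cluster
#' remains. Ties in partner choice also resolve to the lower label.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param centroids centroid matrix from [computeCentroids()] covering every
#'   cluster label in `assignment`.
#' @param minSize minimum acceptable cluster size (default 15).
#' @return list with components `assignment` (relabeled
#'   [ClusterAssignment-class]), `centroids` (merged centroid matrix), and
#'   `log` (data.frame: `step`, `absorbed_label`, `surviving_label`,
#'   `linkage_distance`).
#' @examples
#' sim <- generateActivityMatrix(60, 8, 3, seed = 9)
#' model <- trainSom(sim$matrix, 2, 2, epochs = 20, seed = 9)
#' asg <- assignBmu(model, sim$matrix)
#' merged <- mergeSmallClusters(asg, computeCentroids(sim$matrix, asg))
#' merged$assignment
#' @export
mergeSmallClusters <- function(assignment, centroids, minSize = 15) {
    stopifnot(is(assignment, "ClusterAssignment"))
    minSize <- assertCount(minSize, "minSize")
    lab <- clusterLabels(assignment)
    labs <- sort(unique(lab))
    if (!all(as.character(labs) %in% rownames(centroids)))
        stop("centroids must cover every cluster in the assignment",
             call. = FALSE)
    emptyLog <- data.frame(step = integer(), absorbed_label = integer(),
                           surviving_label = integer(),
                           linkage_distance = numeric())
    if (length(labs) < 2L)
        return(list(assignment = assignment, centroids = centroids,
                    log = emptyLog))

    ## pairwise Pearson distances between the original centroids
    orig <- centroids[as.character(labs), , drop = FALSE]
    D0 <- 1 - stats::cor(t(orig))
    dimnames(D0) <- list(labs, labs)

    sizes <- clusterSizes(assignment)[as.character(labs)]
    groups <- stats::setNames(as.list(labs), labs)   # label -> orig members
    log <- list()
    step <- 0L
    repeat {
        cur <- as.integer(names(sizes))
        if (length(cur) < 2L || min(sizes) >= minSize) break
        small <- cur[sizes == min(sizes)]
        s <- min(small)                       # smallest cluster, lowest label
        others <- setdiff(cur, s)
        link <- vapply(as.character(others), function(o)
            max(D0[as.character(groups[[as.character(s)]]),
                   as.character(groups[[o]]), drop = FALSE]),
            numeric(1))
        partner <- others[link == min(link)]
        p <- min(partner)                     # nearest partner, lowest label
        dval <- min(link)
        ## label retention: larger constituent wins, ties to the lower label
        keep <- if (sizes[as.character(s)] > sizes[as.character(p)]) s
                else if (sizes[as.character(p)] > sizes[as.character(s)]) p
                else min(s, p)
        drop <- if (keep == s) p else s
        groups[[as.character(keep)]] <- c(groups[[as.character(keep)]],
                                          groups[[as.character(drop)]])
        groups[[as.character(drop)]] <- NULL
        sizes[as.character(keep)] <- sizes[as.character(keep)] +
            sizes[as.character(drop)]
        sizes <- sizes[names(sizes) != as.character(drop)]
        step <- step + 1L
        log[[step]] <- data.frame(step = step, absorbed_label = drop,
                                  surviving_label = keep,
                                  linkage_distance = dval)
    }

    ## relabel compounds: original label -> surviving group label
    relabel <- integer(0)
    for (k in names(groups))
        relabel[as.character(groups[[k]])] <- as.integer(k)
    newLab <- unname(relabel[as.character(lab)])
    newAssignment <- ClusterAssignment(stats::setNames(newLab, names(lab)))

    ## merged centroids: size-weighted mean of original constituent centroids
    origSizes <- clusterSizes(assignment)
    mergedCent <- t(vapply(names(groups), function(k) {
        mem <- as.character(groups[[k]])
        w <- origSizes[mem]
        colSums(orig[mem, , drop = FALSE] * w) / sum(w)
    }, numeric(ncol(orig))))
    o <- order(as.integer(rownames(mergedCent)))
    mergedCent <- mergedCent[o, , drop = FALSE]

    list(assignment = newAssignment, centroids = mergedCent,
         log = if (length(log)) do.call(rbind, log) else emptyLog)
}
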