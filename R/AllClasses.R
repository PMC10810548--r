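#' @import methods
NULL

#' Compound-by-assay activity matrix
#'
#' Holds quantitative high-throughput screening (qHTS) activity scores on the
#' curve-rank scale: integers (or real-valued summaries) in \[-9, 9\] where
#' large positive values indicate strong activation of the assay readout and
#' large negative values strong inhibition. Rows are compounds, columns are
#' assays; both carry unique identifiers. Missing values are not permitted --
#' compounds with incomplete assay coverage are dropped at load time (see
#' [readActivityMatrix()]).
#'
#' @slot values numeric matrix with compound identifiers as rownames and
#'   assay identifiers as colnames; all entries in \[-9, 9\], no `NA`.
#' @seealso [ActivityMatrix()], [readActivityMatrix()], [trainSom()]
#' @export
setClass("ActivityMatrix", representation(values = "matrix"))

setValidity("ActivityMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if ((nrow(v) && is.null(rownames(v))) ||
        (ncol(v) && is.null(colnames(v))))
        msg <- c(msg, "values must have compound rownames and assay colnames")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "compound identifiers must be unique")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "assay identifiers must be unique")
    }
    if (anyNA(v))
        msg <- c(msg, "missing values are not allowed")
    else if (is.numeric(v) && length(v) && (min(v) < -9 || max(v) > 9))
        msg <- c(msg, "activity values must lie in [-9, 9] (curve-rank scale)")
    if (length(msg)) msg else TRUE
})

#' Construct an ActivityMatrix
#'
#' @param values numeric matrix, compounds in rows, assays in columns, with
#'   rownames and colnames set. Values must lie in \[-9, 9\].
#' @return an [ActivityMatrix-class] object.
#' @examples
#' m <- matrix(c(1, -3, 0, 9), 2, 2,
#'             dimnames = list(c("C1", "C2"), c("A1", "A2")))
#' ActivityMatrix(m)
#' @export
ActivityMatrix <- function(values) {
    new("ActivityMatrix", values = values)
}

#' Self-organizing map model
#'
#' A rectangular or hexagonal grid of units, each carrying a codebook vector
#' in assay space. Compounds are mapped to their best-matching unit (BMU),
#' the unit whose codebook vector has minimal Euclidean distance to the
#' compound's activity profile. Unit indices are 0-based, row-major over the
#' grid.
#'
#' @slot gridRows,gridCols integer grid dimensions.
#' @slot topology `"rectangular"` or `"hexagonal"`.
#' @slot codebook numeric matrix, one row per unit (gridRows * gridCols rows),
#'   one column per assay.
#' @slot trainingParams list recording epochs, learning-rate schedule, radius
#'   schedule and the training seed.
#' @seealso [trainSom()], [assignBmu()], [quantizationError()]
#' @export
setClass("SomModel", representation(
    gridRows = "integer", gridCols = "integer", topology = "character",
    codebook = "matrix", trainingParams = "list"))

setValidity("SomModel", function(object) {
    msg <- character()
    if (object@gridRows < 1L || object@gridCols < 1L)
        msg <- c(msg, "grid must have at least one unit")
    if (!object@topology %in% c("rectangular", "hexagonal"))
        msg <- c(msg, "topology must be 'rectangular' or 'hexagonal'")
    if (nrow(object@codebook) != object@gridRows * object@gridCols)
        msg <- c(msg, "codebook must have one row per grid unit")
    if (anyNA(object@codebook))
        msg <- c(msg, "codebook must not contain NA")
    if (length(msg)) msg else TRUE
})

#' Compound-to-cluster assignment
#'
#' Maps every compound to exactly one cluster label. Labels are the retained
#' SOM unit indices and remain stable across merging: when two clusters merge
#' the label of the larger constituent survives.
#'
#' @slot labels named integer vector; names are compound identifiers, values
#'   cluster labels.
#' @seealso [assignBmu()], [mergeSmallClusters()], [clusterSizes()]
#' @export
setClass("ClusterAssignment", representation(labels = "integer"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (is.null(names(object@labels)) || any(!nzchar(names(object@labels))))
        msg <- c(msg, "labels must be named by compound identifier")
    else if (anyDuplicated(names(object@labels)))
        msg <- c(msg, "compound identifiers must be unique")
    if (anyNA(object@labels))
        msg <- c(msg, "every compound needs a cluster label")
    if (length(msg)) msg else TRUE
})

#' Construct a ClusterAssignment
#'
#' @param labels named integer vector of cluster labels (names = compound ids).
#' @return a [ClusterAssignment-class] object.
#' @export
ClusterAssignment <- function(labels) {
    storage.mode(labels) <- "integer"
    new("ClusterAssignment", labels = labels)
}

#' Compound-to-gene annotation table
#'
#' Records (compound key, gene, source) triples. The compound key is InChIKey
#' block 1: the first 14 characters of the InChIKey, which encode the
#' molecular skeleton without stereochemistry or protonation -- a salt- and
#' stereo-insensitive identity. After merging sources, (key, gene) pairs are
#' unique and `source` concatenates the contributing source labels with
#' `";"`.
#'
#' @slot records data.frame with character columns `compound_key`, `gene`,
#'   `source`.
#' @seealso [joinAnnotations()], [readAnnotations()], [generateAnnotations()]
#' @export
setClass("AnnotationTable", representation(records = "data.frame"))

setValidity("AnnotationTable", function(object) {
    r <- object@records
    msg <- character()
    need <- c("compound_key", "gene", "source")
    if (!all(need %in% names(r)))
        return("records needs columns compound_key, gene, source")
    if (nrow(r)) {
        if (!all(grepl("^[A-Z]{14}$", r$compound_key)))
            msg <- c(msg, "compound_key must be exactly 14 uppercase letters")
        if (anyDuplicated(r[, c("compound_key", "gene")]))
            msg <- c(msg, "(compound_key, gene) pairs must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTable
#'
#' @param records data.frame with columns `compound_key`, `gene`, `source`.
#' @return an [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(records) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    rownames(records) <- NULL
    new("AnnotationTable", records = records)
}

#' Fitted beta-uniform mixture (BUM) model of a p-value distribution
#'
#' The BUM model writes the density of a collection of p-values as
#' \deqn{f(p) = \lambda + (1 - \lambda)\, a\, p^{a - 1}, \quad 0 < a < 1,}
#' a mixture of a Uniform(0,1) null component (weight \eqn{\lambda}) and a
#' Beta(a, 1) alternative component concentrated near zero. The quantity
#' \eqn{\hat\pi = \lambda + (1-\lambda)a = f(1)} is a conservative upper
#' bound on the proportion of true nulls and drives the FDR-controlling
#' p-value cutoff (see [bumFdrCutoff()]).
#'
#' @slot aHat beta shape estimate in (0, 1).
#' @slot lambdaHat mixing weight estimate in \[0, 1\].
#' @slot piUb null-proportion upper bound `lambdaHat + (1 - lambdaHat) * aHat`.
#' @slot loglik maximized log-likelihood.
#' @slot n number of p-values used in the fit.
#' @seealso [fitBum()], [bumFdrCutoff()]
#' @export
setClass("BumFit", representation(
    aHat = "numeric", lambdaHat = "numeric", piUb = "numeric",
    loglik = "numeric", n = "integer"))

setValidity("BumFit", function(object) {
    msg <- character()
    if (object@aHat <= 0 || object@aHat >= 1)
        msg <- c(msg, "aHat must lie in (0, 1)")
    if (object@lambdaHat < 0 || object@lambdaHat > 1)
        msg <- c(msg, "lambdaHat must lie in [0, 1]")
    if (object@piUb < 0 || object@piUb > 1 + 1e-12)
        msg <- c(msg, "piUb must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Binary chemical fingerprints as bit sets
#'
#' Stores, per compound, the 0-based indices of set bits in an `nBits`-wide
#' binary fingerprint. Used for Tanimoto similarity: |intersection| / |union|
#' of the two bit sets.
#'
#' @slot nBits fingerprint width.
#' @slot bits named list; each element an increasing integer vector of set-bit
#'   indices in \[0, nBits).
#' @seealso [tanimoto()], [structureFingerprints()], [generateFingerprints()],
#'   [intraInterSummary()]
#' @export
setClass("FingerprintSet", representation(nBits = "integer", bits = "list"))

setValidity("FingerprintSet", function(object) {
    msg <- character()
    if (object@nBits < 1L)
        msg <- c(msg, "nBits must be positive")
    if (is.null(names(object@bits)) && length(object@bits))
        msg <- c(msg, "bits must be named by compound identifier")
    bad <- vapply(object@bits, function(b)
        length(b) && (min(b) < 0L || max(b) >= object@nBits || is.unsorted(b, strictly = TRUE)),
        logical(1))
    if (any(bad))
        msg <- c(msg, "bit indices must be strictly increasing and in [0, nBits)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Records everything the synthetic-data generator planted: the latent
#' cluster label of every compound, the cluster archetype activity profiles,
#' and the genes planted per cluster, together with the generator parameters.
#' Downstream tests compare recovered structure against this object.
#'
#' @slot labels named integer vector, compound -> latent cluster index in
#'   \[0, nClusters).
#' @slot archetypes numeric matrix, one row per latent cluster, one column per
#'   assay, entries in \[-9, 9\].
#' @slot plantedGenes list of character vectors, one per cluster; disjoint
#'   across clusters.
#' @slot params list of generator parameters (sample sizes, probabilities,
#'   noise level, seed).
#' @seealso [generateActivityMatrix()], [generateAnnotations()],
#'   [generateFingerprints()], [generatePathways()]
#' @export
setClass("SyntheticTruth", representation(
    labels = "integer", archetypes = "matrix", plantedGenes = "list",
    params = "list"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    k <- nrow(object@archetypes)
    if (length(object@labels) && (min(object@labels) < 0L ||
                                  max(object@labels) >= k))
        msg <- c(msg, "labels must lie in [0, nClusters)")
    if (length(object@archetypes) &&
        (min(object@archetypes) < -9 || max(object@archetypes) > 9))
        msg <- c(msg, "archetype entries must lie in [-9, 9]")
    pg <- unlist(object@plantedGenes)
    if (anyDuplicated(pg))
        msg <- c(msg, "planted gene lists must be disjoint across clusters")
    if (length(msg)) msg else TRUE
})
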