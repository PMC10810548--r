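#' @name accessors
#' @title Accessors for somEnrich classes
#' @description Small accessor generics: prefer these over direct slot
#'   access.
#' @param x an object of the documented class.
NULL

#' @describeIn accessors compound identifiers of an [ActivityMatrix-class],
#'   [ClusterAssignment-class] or [FingerprintSet-class].
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @describeIn accessors assay identifiers of an [ActivityMatrix-class] or
#'   [SomModel-class].
#' @export
setGeneric("assayIds", function(x) standardGeneric("assayIds"))

#' @describeIn accessors the numeric activity matrix.
#' @export
setGeneric("actValues", function(x) standardGeneric("actValues"))

#' @describeIn accessors named integer vector compound -> cluster label.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn accessors table of cluster sizes, named by cluster label.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @describeIn accessors codebook matrix of a [SomModel-class] (one row per
#'   unit).
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @describeIn accessors annotation records data.frame of an
#'   [AnnotationTable-class].
#' @export
setGeneric("annotationRecords", function(x) standardGeneric("annotationRecords"))

#' @describeIn accessors named list of set-bit index vectors.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' @describeIn accessors fingerprint width in bits.
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' @rdname accessors
#' @export
setMethod("compoundIds", "ActivityMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("compoundIds", "ClusterAssignment", function(x) names(x@labels))
#' @rdname accessors
#' @export
setMethod("compoundIds", "FingerprintSet", function(x) names(x@bits))

#' @rdname accessors
#' @export
setMethod("assayIds", "ActivityMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("assayIds", "SomModel", function(x) colnames(x@codebook))

#' @rdname accessors
#' @export
setMethod("actValues", "ActivityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterAssignment", function(x) {
    s <- table(x@labels)
    stats::setNames(as.integer(s), names(s))
})

#' @rdname accessors
#' @export
setMethod("codebook", "SomModel", function(x) x@codebook)

#' @rdname accessors
#' @export
setMethod("annotationRecords", "AnnotationTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("fingerprintBits", "FingerprintSet", function(x) x@bits)

#' @rdname accessors
#' @export
setMethod("nBits", "FingerprintSet", function(x) x@nBits)

setMethod("show", "ActivityMatrix", function(object) {
    v <- object@values
    cat(sprintf("ActivityMatrix: %d compounds x %d assays\n", nrow(v), ncol(v)))
    cat(sprintf("  curve-rank range: [%.2f, %.2f]\n",
                if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "SomModel", function(object) {
    cat(sprintf("SomModel: %d x %d %s grid, %d assays\n",
                object@gridRows, object@gridCols, object@topology,
                ncol(object@codebook)))
    tp <- object@trainingParams
    if (length(tp))
        cat(sprintf("  trained: epochs=%s, lr=%s->%s, seed=%s\n",
                    tp$epochs, tp$lrInitial, tp$lrFinal, tp$seed))
})

setMethod("show", "ClusterAssignment", function(object) {
    s <- clusterSizes(object)
    cat(sprintf("ClusterAssignment: %d compounds in %d clusters (sizes %d-%d)\n",
                length(object@labels), length(s),
                if (length(s)) min(s) else 0L, if (length(s)) max(s) else 0L))
})

setMethod("show", "AnnotationTable", function(object) {
    r <- object@records
    cat(sprintf("AnnotationTable: %d (compound, gene) pairs, %d compounds, %d genes\n",
                nrow(r), length(unique(r$compound_key)), length(unique(r$gene))))
})

setMethod("show", "BumFit", function(object) {
    cat(sprintf("BumFit (n = %d p-values):\n", object@n))
    cat(sprintf("  a = %.4f, lambda = %.4f, pi_ub = %.4f, loglik = %.2f\n",
                object@aHat, object@lambdaHat, object@piUb, object@loglik))
})

setMethod("show", "FingerprintSet", function(object) {
    cat(sprintf("FingerprintSet: %d compounds, %d bits\n",
                length(object@bits), object@nBits))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d compounds, %d latent clusters, %d assays\n",
                length(object@labels), nrow(object@archetypes),
                ncol(object@archetypes)))
    cat(sprintf("  planted genes: %d\n", length(unlist(object@plantedGenes))))
})
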