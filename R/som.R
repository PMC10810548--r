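## grid coordinates of the units, 0-based row-major indexing.
## hexagonal: odd rows offset by 0.5, row spacing sqrt(3)/2.
somGridCoords <- function(gridRows, gridCols, topology) {
    r <- rep(seq_len(gridRows) - 1L, each = gridCols)
    c <- rep(seq_len(gridCols) - 1L, times = gridRows)
    if (topology == "hexagonal") {
        cbind(x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
    } else {
        cbind(x = as.numeric(c), y = as.numeric(r))
    }
}

#' Train a self-organizing map on activity profiles
#'
#' Online (per-sample) SOM training with Euclidean matching. The codebook is
#' initialized from randomly sampled data rows. At every step the presented
#' row's best-matching unit (BMU, minimal Euclidean distance) and its grid
#' neighborhood -- a Gaussian kernel over grid distance -- move toward the
#' row. Learning rate and neighborhood radius decay linearly from their
#' initial to final values over all `epochs * nrow` steps; presentation
#' order is reshuffled each epoch. Fully deterministic given `seed`.
#'
#' Curve ranks share the single bounded scale \[-9, 9\], so no feature
#' scaling is applied before training.
#'
#' @param x an [ActivityMatrix-class].
#' @param gridRows,gridCols grid dimensions (default 12 x 12; a
#'   conventional square grid for library-scale inputs).
#' @param topology `"rectangular"` (default) or `"hexagonal"`.
#' @param epochs passes over the data (default 100). `epochs = 0` returns
#'   the untouched initialization.
#' @param lrInitial,lrFinal learning-rate schedule, decayed linearly
#'   (defaults 0.05 to 0.01); requires `lrInitial >= lrFinal > 0`.
#' @param radiusInitial,radiusFinal neighborhood radius schedule in
#'   grid-distance units; default from half the larger grid dimension down
#'   to 0.1, at which the Gaussian kernel is effectively BMU-only, so late
#'   training converges each unit to the mean of its own basin.
#' @param seed integer seed controlling initialization and epoch shuffling.
#' @param unitExcessWarn warn when the grid has more than this multiple of
#'   the number of data rows in units (default 1).
#' @return a [SomModel-class].
#' @examples
#' sim <- generateActivityMatrix(80, 8, 2, noiseSd = 1, seed = 1)
#' model <- trainSom(sim$matrix, gridRows = 1, gridCols = 2, epochs = 20,
#'                   seed = 1)
#' model
#' @export
trainSom <- function(x, gridRows = 12, gridCols = 12,
                     topology = c("rectangular", "hexagonal"),
                     epochs = 100, lrInitial = 0.05, lrFinal = 0.01,
                     radiusInitial = NULL, radiusFinal = 0.1, seed = 1,
                     unitExcessWarn = 1) {
    stopifnot(is(x, "ActivityMatrix"))
    gridRows <- assertCount(gridRows, "gridRows")
    gridCols <- assertCount(gridCols, "gridCols")
    topology <- match.arg(topology)
    epochs <- assertCount(epochs, "epochs", positive = FALSE)
    if (!(lrInitial >= lrFinal && lrFinal > 0))
        stop("need lrInitial >= lrFinal > 0", call. = FALSE)
    v <- actValues(x)
    if (!nrow(v)) stop("empty activity matrix", call. = FALSE)
    nUnits <- gridRows * gridCols
    if (nUnits > unitExcessWarn * nrow(v))
        warning(sprintf("grid has %d units for %d compounds", nUnits,
                        nrow(v)))
    if (is.null(radiusInitial)) radiusInitial <- max(gridRows, gridCols) / 2
    if (radiusInitial < radiusFinal) radiusInitial <- radiusFinal

    coords <- somGridCoords(gridRows, gridCols, topology)
    ## squared grid distances between all unit pairs
    gd2 <- as.matrix(stats::dist(coords))^2

    withSeed(seed, {
        init <- v[sample.int(nrow(v), nUnits,
                             replace = nUnits > nrow(v)), , drop = FALSE]
        cb <- unname(init)
        steps <- epochs * nrow(v)
        t0 <- 0L
        if (epochs > 0) for (e in seq_len(epochs)) {
            order <- sample.int(nrow(v))
            for (i in order) {
                frac <- if (steps > 1) t0 / (steps - 1) else 0
                lr <- lrInitial + (lrFinal - lrInitial) * frac
                radius <- radiusInitial + (radiusFinal - radiusInitial) * frac
                xi <- v[i, ]
                d2 <- rowSums(cb * cb) - 2 * drop(cb %*% xi) + sum(xi * xi)
                bmu <- which.min(d2)
                h <- exp(-gd2[, bmu] / (2 * radius * radius))
                cb <- cb + (lr * h) * (rep(1, nUnits) %o% xi - cb)
                t0 <- t0 + 1L
            }
        }
        colnames(cb) <- assayIds(x)
        new("SomModel", gridRows = gridRows, gridCols = gridCols,
            topology = topology, codebook = cb,
            trainingParams = list(epochs = epochs, lrInitial = lrInitial,
                                  lrFinal = lrFinal,
                                  radiusInitial = radiusInitial,
                                  radiusFinal = radiusFinal,
                                  seed = as.integer(seed)))
    })
}

#' Assign compounds to their best-matching SOM unit
#'
#' Maps every compound to the unit with minimal Euclidean distance between
#' its activity profile and the unit's codebook vector. Exact distance ties
#' break to the lowest unit index. A "cluster" is a non-empty unit after
#' assignment; empty units produce no cluster label.
#'
#' @param model a [SomModel-class].
#' @param x an [ActivityMatrix-class] with the same assays as the codebook.
#' @return a [ClusterAssignment-class]; labels are 0-based unit indices.
#' @examples
#' sim <- generateActivityMatrix(40, 6, 2, seed = 3)
#' model <- trainSom(sim$matrix, 1, 2, epochs = 10, seed = 3)
#' assignBmu(model, sim$matrix)
#' @export
assignBmu <- function(model, x) {
    stopifnot(is(model, "SomModel"), is(x, "ActivityMatrix"))
    v <- actValues(x)
    cb <- codebook(model)
    if (ncol(v) != ncol(cb) || !identical(colnames(v), colnames(cb)))
        stop("assay list of the matrix does not match the codebook",
             call. = FALSE)
    d2 <- matrix(rowSums(cb * cb), nrow(v), nrow(cb), byrow = TRUE) -
        2 * v %*% t(cb) + rowSums(v * v)
    bmu <- max.col(-d2, ties.method = "first") - 1L
    ClusterAssignment(stats::setNames(bmu, rownames(v)))
}

#' Mean quantization error of a SOM on a dataset
#'
#' Mean over compounds of the Euclidean distance to the assigned
#' best-matching unit; a standard SOM training diagnostic (lower is a
#' tighter fit).
#'
#' @param model a [SomModel-class].
#' @param x an [ActivityMatrix-class].
#' @return non-negative number.
#' @export
quantizationError <- function(model, x) {
    stopifnot(is(model, "SomModel"), is(x, "ActivityMatrix"))
    v <- actValues(x)
    if (!nrow(v)) stop("empty activity matrix", call. = FALSE)
    cb <- codebook(model)
    if (ncol(v) != ncol(cb))
        stop("assay list of the matrix does not match the codebook",
             call. = FALSE)
    d2 <- matrix(rowSums(cb * cb), nrow(v), nrow(cb), byrow = TRUE) -
        2 * v %*% t(cb) + rowSums(v * v)
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
}
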