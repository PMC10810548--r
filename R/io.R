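#' Read a compound-by-assay activity matrix from TSV
#'
#' Expects a tab-separated file with a header row of assay identifiers and a
#' first column of compound identifiers. Missing cells (empty strings)
#' either cause the whole compound row to be dropped (`dropIncomplete =
#' TRUE`, mirroring the preprocessing rule that only compounds with activity
#' data across all assays are kept) or raise an error. Values outside the
#' curve-rank range \[-9, 9\] are rejected.
#'
#' @param path TSV file path.
#' @param dropIncomplete drop rows with any missing cell (default `TRUE`);
#'   the number of dropped rows is reported with a message.
#' @return an [ActivityMatrix-class].
#' @seealso [writeActivityMatrix()]
#' @export
readActivityMatrix <- function(path, dropIncomplete = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate compound identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    body <- df[, -1, drop = FALSE]
    suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(body))))
    if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body),
                                       dimnames = list(NULL, names(body)))
    bad <- which(is.na(num) & !(body == "" | is.na(as.matrix(body))),
                 arr.ind = TRUE)
    if (nrow(bad <- as.matrix(bad)))
        stop(sprintf("non-numeric cell at compound '%s', assay '%s'",
                     ids[bad[1, 1]], colnames(num)[bad[1, 2]]), call. = FALSE)
    missing <- rowSums(is.na(num)) > 0
    if (any(missing)) {
        if (!dropIncomplete)
            stop(sum(missing), " compound row(s) have missing cells",
                 call. = FALSE)
        message(sum(missing), " compound row(s) with incomplete assay ",
                "coverage dropped")
        num <- num[!missing, , drop = FALSE]
        ids <- ids[!missing]
    }
    if (length(num) && (min(num) < -9 || max(num) > 9))
        stop("activity values outside the curve-rank range [-9, 9]",
             call. = FALSE)
    rownames(num) <- ids
    ActivityMatrix(num)
}

#' Write an activity matrix as TSV
#'
#' @param x an [ActivityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readActivityMatrix()]
#' @export
writeActivityMatrix <- function(x, path) {
    stopifnot(is(x, "ActivityMatrix"))
    df <- data.frame(compound_id = compoundIds(x), actValues(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write compound-to-gene annotation tables (3-column TSV)
#'
#' The on-disk shape is `compound_key`, `gene`, `source`, tab-separated with
#' a header. Duplicate (key, gene) pairs are collapsed on read with their
#' source labels concatenated by `";"`.
#'
#' @param path TSV file path.
#' @return [readAnnotations()] returns an [AnnotationTable-class];
#'   [writeAnnotations()] returns `path` invisibly.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "",
                            quote = "")
    need <- c("compound_key", "gene", "source")
    if (!all(need %in% names(df)))
        stop("annotation TSV needs columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    AnnotationTable(collapseAnnotationRows(df[need]))
}

#' @rdname readAnnotations
#' @param x an [AnnotationTable-class].
#' @export
writeAnnotations <- function(x, path) {
    stopifnot(is(x, "AnnotationTable"))
    utils::write.table(annotationRecords(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

## collapse duplicate (key, gene) rows; sources joined with ";" in first-seen
## order, deduplicated
collapseAnnotationRows <- function(df) {
    key <- paste(df$compound_key, df$gene, sep = "\r")
    if (!anyDuplicated(key)) return(df)
    src <- vapply(split(df$source, factor(key, levels = unique(key))),
                  function(s) paste(unique(s), collapse = ";"), character(1))
    out <- df[!duplicated(key), , drop = FALSE]
    out$source <- unname(src)
    rownames(out) <- NULL
    out
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene members.
#' Empty member lists and duplicate set names are rejected on read.
#'
#' @param path GMT file path.
#' @return [readGeneSets()] returns a named list of character vectors, with
#'   the description column in attribute `"description"`;
#'   [writeGeneSets()] returns `path` invisibly.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d: gene set '%s' has no members", i,
                         if (length(f)) f[1] else ""), call. = FALSE)
        if (f[1] %in% names(sets))
            stop(sprintf("GMT line %d: duplicate set name '%s'", i, f[1]),
                 call. = FALSE)
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members))
            stop(sprintf("GMT line %d: gene set '%s' has no members", i, f[1]),
                 call. = FALSE)
        sets[[f[1]]] <- members
        desc[[f[1]]] <- f[2]
    }
    attr(sets, "description") <- desc
    sets
}

#' @rdname readGeneSets
#' @param sets named list of character vectors; optional `"description"`
#'   attribute (defaults to the set names).
#' @export
writeGeneSets <- function(sets, path) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    desc <- attr(sets, "description")
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

#' Read / write cluster assignments (2-column TSV)
#'
#' On-disk shape: `compound_id`, `cluster_id`, tab-separated with header.
#'
#' @param path TSV file path.
#' @return [readClusterAssignment()] returns a [ClusterAssignment-class];
#'   [writeClusterAssignment()] returns `path` invisibly.
#' @export
readClusterAssignment <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer"))
    if (!all(c("compound_id", "cluster_id") %in% names(df)))
        stop("cluster TSV needs columns compound_id, cluster_id",
             call. = FALSE)
    ClusterAssignment(stats::setNames(df$cluster_id, df$compound_id))
}

#' @rdname readClusterAssignment
#' @param x a [ClusterAssignment-class].
#' @export
writeClusterAssignment <- function(x, path) {
    stopifnot(is(x, "ClusterAssignment"))
    df <- data.frame(compound_id = compoundIds(x),
                     cluster_id = unname(clusterLabels(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a JSON run manifest
#'
#' Records, for each completed stage, its output paths with MD5 content
#' checksums, plus a snapshot of the configuration and the global seed, so a
#' run can be compared bit-for-bit against a repeat.
#'
#' @param stageOutputs named list: stage name -> character vector of output
#'   paths (all must exist).
#' @param configSnapshot list of configuration key-values to freeze.
#' @param seed integer global seed of the run.
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @seealso [compareManifests()]
#' @export
writeRunManifest <- function(stageOutputs, configSnapshot, seed, path) {
    stopifnot(is.list(stageOutputs), !is.null(names(stageOutputs)))
    stages <- lapply(names(stageOutputs), function(nm) {
        paths <- stageOutputs[[nm]]
        if (!all(file.exists(paths)))
            stop("manifest: missing output path(s) for stage '", nm, "': ",
                 paste(paths[!file.exists(paths)], collapse = ", "),
                 call. = FALSE)
        list(stage = nm, outputs = basename(paths),
             checksums = unname(tools::md5sum(paths)))
    })
    manifest <- list(stages = stages, config = configSnapshot,
                     seed = as.integer(seed))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(manifest)
}

#' Compare two run manifests
#'
#' @param pathA,pathB manifest JSON paths.
#' @return list with logical `identicalChecksums`, `identicalConfig`, and
#'   character `differingStages`.
#' @export
compareManifests <- function(pathA, pathB) {
    a <- jsonlite::read_json(pathA); b <- jsonlite::read_json(pathB)
    ck <- function(m) unlist(lapply(m$stages, function(s)
        stats::setNames(unlist(s$checksums), unlist(s$outputs))))
    ca <- ck(a); cb <- ck(b)
    shared <- intersect(names(ca), names(cb))
    diff <- shared[unlist(ca[shared]) != unlist(cb[shared])]
    list(identicalChecksums = setequal(names(ca), names(cb)) &&
             length(diff) == 0L,
         identicalConfig = identical(a$config, b$config),
         differingStages = diff)
}
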