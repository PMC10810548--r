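#' Main component of a multi-component SMILES
#'
#' Splits a SMILES string on the `.` separator and returns the component
#' with the greatest character length; ties break to the lexicographically
#' smallest component. Multi-component SMILES usually encode salts or
#' mixtures; the longest component is taken as the parent structure.
#'
#' @param smiles a single SMILES string.
#' @return the retained component (contains no `.`).
#' @examples
#' primaryComponent("CCO.Cl")
#' primaryComponent("[Na+].CC(=O)[O-]")
#' @export
primaryComponent <- function(smiles) {
    if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
        stop("smiles must be a non-empty string", call. = FALSE)
    parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (!length(parts)) stop("no components in SMILES", call. = FALSE)
    longest <- parts[nchar(parts) == max(nchar(parts))]
    sort(longest)[1]
}

#' Salt- and stereo-insensitive 14-character compound key
#'
#' Computes the standard InChIKey of the SMILES' main component (see
#' [primaryComponent()]) and returns its first 14 characters -- InChIKey
#' block 1, which hashes the molecular skeleton without stereochemistry or
#' protonation. Two stereoisomers of one skeleton, or a parent and its
#' salt form, therefore share a key. Conversion goes through
#' OpenBabel (via \pkg{ChemmineOB}).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of 14-uppercase-letter keys, `NA` where the
#'   SMILES could not be parsed (a message reports how many failed;
#'   failures never abort the run).
#' @examples
#' \donttest{compoundKey(c("CCO", "CCO.Cl"))}
#' @export
compoundKey <- function(smiles) {
    stopifnot(is.character(smiles))
    keys <- vapply(smiles, function(s) {
        prim <- tryCatch(primaryComponent(s), error = function(e) NA_character_)
        if (is.na(prim)) return(NA_character_)
        full <- tryCatch(
            ChemmineOB::convertFormat("SMI", "INCHIKEY", source = prim),
            error = function(e) "")
        full <- sub("\n$", "", full)
        if (!grepl("^[A-Z]{14}-", full)) return(NA_character_)
        substr(full, 1, 14)
    }, character(1), USE.NAMES = FALSE)
    nFail <- sum(is.na(keys))
    if (nFail) message(nFail, " SMILES could not be converted to a key")
    keys
}

#' Build compound records with structure keys
#'
#' Reads (or accepts) `compound_id` / `smiles` pairs and derives, for each
#' compound, the main component and the 14-character structure key.
#' Compounds whose SMILES cannot be parsed get `status = "failed"` and are
#' retained in the table (excluded from downstream joins), mirroring how a
#' mapping step loses a few structures but continues.
#'
#' @param x either a 2-column TSV path (`compound_id`, `smiles`) or a
#'   data.frame with those columns.
#' @return data.frame with columns `compound_id`, `smiles_raw`,
#'   `smiles_primary`, `key14`, `status` (`"ok"` or `"failed"`).
#' @export
compoundRecords <- function(x) {
    df <- if (is.character(x) && length(x) == 1L) {
        if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
        utils::read.table(x, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "",
                          quote = "")
    } else as.data.frame(x, stringsAsFactors = FALSE)
    if (!all(c("compound_id", "smiles") %in% names(df)))
        stop("need columns compound_id, smiles", call. = FALSE)
    prim <- vapply(df$smiles, function(s)
        tryCatch(primaryComponent(s), error = function(e) NA_character_),
        character(1), USE.NAMES = FALSE)
    key <- suppressMessages(compoundKey(df$smiles))
    data.frame(compound_id = df$compound_id, smiles_raw = df$smiles,
               smiles_primary = prim, key14 = key,
               status = ifelse(is.na(key), "failed", "ok"),
               stringsAsFactors = FALSE)
}

#' Join compounds to gene annotations from multiple sources
#'
#' Takes the union over sources of (compound key, gene) pairs, restricted
#' to the supplied compounds' keys; duplicate pairs collapse with their
#' source labels concatenated by `";"`. Reports counts of matched
#' compounds and distinct genes, overall and per source, in attribute
#' `"joinStats"`; unmatched annotation rows are counted there too.
#'
#' @param compounds data.frame from [compoundRecords()], or any data.frame
#'   with a `key14` column (rows with `NA` keys are ignored). For synthetic
#'   pipelines whose compound identifiers already are 14-letter keys, a
#'   character vector of keys is also accepted.
#' @param tables list of [AnnotationTable-class] objects, optionally named
#'   by source.
#' @return an [AnnotationTable-class] restricted to the supplied compounds.
#' @export
joinAnnotations <- function(compounds, tables) {
    keys <- if (is.character(compounds)) compounds
            else compounds$key14[!is.na(compounds$key14)]
    keys <- unique(keys)
    stopifnot(is.list(tables), length(tables) >= 1L)
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        names(tables) <- sprintf("source%d", seq_along(tables))

    perSource <- lapply(names(tables), function(nm) {
        r <- annotationRecords(tables[[nm]])
        r$source <- nm
        r
    })
    all <- do.call(rbind, perSource)
    matched <- all[all$compound_key %in% keys, , drop = FALSE]
    out <- collapseAnnotationRows(matched)
    stats <- list(
        matchedCompounds = length(unique(matched$compound_key)),
        distinctGenes = length(unique(matched$gene)),
        unmatchedRows = nrow(all) - nrow(matched),
        perSource = lapply(perSource, function(r) {
            m <- r[r$compound_key %in% keys, , drop = FALSE]
            list(matchedCompounds = length(unique(m$compound_key)),
                 distinctGenes = length(unique(m$gene)))
        }))
    names(stats$perSource) <- names(tables)
    res <- AnnotationTable(out)
    attr(res, "joinStats") <- stats
    res
}
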