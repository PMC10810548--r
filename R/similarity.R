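#' Tanimoto coefficient of two bit sets
#'
#' |intersection| / |union| of the set-bit indices of two binary
#' fingerprints. Two empty sets give 0 by convention: featureless
#' molecules carry no similarity evidence.
#'
#' @param fp1,fp2 integer vectors of set-bit indices.
#' @return number in \[0, 1\].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto <- function(fp1, fp2) {
    ni <- length(intersect(fp1, fp2))
    nu <- length(fp1) + length(fp2) - ni
    if (nu == 0L) return(0.0)
    ni / nu
}

#' Circular structure fingerprints for compound records
#'
#' Computes hashed extended-connectivity (circular, radius 2) fingerprints
#' of each compound's primary structure component through OpenBabel's ECFP4
#' implementation (via \pkg{ChemmineR}/\pkg{ChemmineOB}). Deterministic per
#' molecule: two SMILES spellings of one structure give identical bit sets.
#' Compounds whose SMILES cannot be parsed are skipped with a message.
#'
#' @param compounds data.frame from [compoundRecords()], or any data.frame
#'   with columns `compound_id` and `smiles_primary` (or `smiles`).
#' @return a [FingerprintSet-class] (4096 bits, the ECFP4 width of the
#'   backend).
#' @export
structureFingerprints <- function(compounds) {
    df <- as.data.frame(compounds, stringsAsFactors = FALSE)
    smi <- if ("smiles_primary" %in% names(df)) df$smiles_primary
           else df$smiles
    if (is.null(smi) || !"compound_id" %in% names(df))
        stop("need columns compound_id and smiles_primary (or smiles)",
             call. = FALSE)
    ok <- !is.na(smi) & nzchar(smi)
    sdf <- NULL
    keepIds <- character(0)
    if (any(ok)) {
        parsed <- tryCatch(
            ChemmineR::smiles2sdf(stats::setNames(smi[ok],
                                                  df$compound_id[ok])),
            error = function(e) NULL)
        if (!is.null(parsed)) {
            valid <- ChemmineR::validSDF(parsed)
            sdf <- parsed[valid]
            keepIds <- ChemmineR::sdfid(sdf)
        }
    }
    nSkip <- nrow(df) - length(keepIds)
    if (nSkip > 0) message(nSkip, " compound(s) skipped (unparseable SMILES)")
    if (!length(keepIds))
        return(new("FingerprintSet", nBits = 4096L,
                   bits = stats::setNames(list(), character(0))))
    fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
    m <- fp@fpma
    bits <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1) - 1L)
    names(bits) <- df$compound_id[ok][match(keepIds, df$compound_id[ok])]
    names(bits) <- keepIds
    new("FingerprintSet", nBits = ncol(m), bits = bits)
}

#' Intra- versus inter-cluster Tanimoto similarity
#'
#' Mean Tanimoto coefficient over all same-cluster compound pairs
#' (intra) and all different-cluster pairs (inter). Structurally coherent
#' clusterings show `intra_mean > inter_mean`. When a stratum holds more
#' than `maxPairsPerStratum` pairs, a seeded uniform subsample is used and
#' its size reported.
#'
#' @param fps a [FingerprintSet-class].
#' @param assignment a [ClusterAssignment-class]; compounds without a
#'   fingerprint are excluded (their count is reported with a message).
#' @param maxPairsPerStratum pair cap per stratum (default 1e6).
#' @param seed integer seed for the subsample.
#' @return list: `intra_mean`, `inter_mean`, `n_intra_pairs`,
#'   `n_inter_pairs`, `subsampled` (logical).
#' @export
intraInterSummary <- function(fps, assignment, maxPairsPerStratum = 1e6,
                              seed = 1) {
    stopifnot(is(fps, "FingerprintSet"), is(assignment, "ClusterAssignment"))
    lab <- clusterLabels(assignment)
    ids <- intersect(names(lab), compoundIds(fps))
    missing <- length(lab) - length(ids)
    if (missing > 0)
        message(missing, " assigned compound(s) without a fingerprint ",
                "excluded")
    if (length(ids) < 2L) stop("need at least 2 compounds", call. = FALSE)
    lab <- lab[ids]
    bits <- fingerprintBits(fps)[ids]

    n <- length(ids)
    pairI <- utils::combn(n, 2)
    same <- lab[pairI[1, ]] == lab[pairI[2, ]]
    intraIdx <- which(same)
    interIdx <- which(!same)

    sampleStratum <- function(idx, tag) {
        if (length(idx) <= maxPairsPerStratum) return(list(idx = idx,
                                                           sub = FALSE))
        sub <- withSeed(stableSeed(tag, seed),
                        sample(idx, maxPairsPerStratum))
        list(idx = sub, sub = TRUE)
    }
    si <- sampleStratum(intraIdx, "intra")
    se <- sampleStratum(interIdx, "inter")
    meanTan <- function(idx) {
        if (!length(idx)) return(NA_real_)
        mean(vapply(idx, function(k)
            tanimoto(bits[[pairI[1, k]]], bits[[pairI[2, k]]]), numeric(1)))
    }
    list(intra_mean = meanTan(si$idx), inter_mean = meanTan(se$idx),
         n_intra_pairs = length(si$idx), n_inter_pairs = length(se$idx),
         subsampled = si$sub || se$sub)
}
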