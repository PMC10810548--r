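#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; user-supplied
#' configuration files (YAML key-value sections, see
#' [readPipelineConfig()]) override these values. Unknown keys are
#' rejected.
#'
#' @return nested named list of configuration defaults.
#' @export
defaultPipelineConfig <- function() {
    list(
        paths = list(activity = NULL, structures = NULL,
                     annotations = NULL, gene_sets = NULL, out = NULL),
        som = list(grid_rows = 12L, grid_cols = 12L,
                   topology = "rectangular", epochs = 100L,
                   lr_initial = 0.05, lr_final = 0.01,
                   radius_initial = NULL, radius_final = 0.1),
        merge = list(min_size = 15L),
        enrichment = list(alpha_fdr = 0.01, alpha_pathway = 0.05,
                          p_floor = 1e-12, adjust = "auto",
                          min_bum_tests = 50L),
        similarity = list(fingerprint_bits = 1024L, pair_cap = 1e6),
        synthetic = list(n_compounds = 500L, n_assays = 16L,
                         n_clusters = 5L, noise_sd = 1,
                         genes_per_cluster = 1L, enrichment_prob = 0.6,
                         background_prob = 0.05, intra_flip_prob = 0.05,
                         inter_seed_density = 0.1, sets_per_cluster = 1L,
                         extra_genes_per_set = 5L),
        seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML with the sections of [defaultPipelineConfig()] (`paths`, `som`,
#' `merge`, `enrichment`, `similarity`, `synthetic`, `seed`). Values given
#' in the file override the defaults; keys not present in the defaults are
#' rejected so typos fail loudly. Numeric parameters are checked against
#' their documented bounds.
#'
#' @param path YAML file path; `NULL` returns the defaults unchanged.
#' @return validated nested configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
    cfg <- defaultPipelineConfig()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config not found: ", path,
                                     call. = FALSE)
        user <- yaml::read_yaml(path)
        for (sec in names(user)) {
            if (!sec %in% names(cfg))
                stop("unknown config section: ", sec, call. = FALSE)
            if (sec == "seed") { cfg$seed <- user$seed; next }
            for (k in names(user[[sec]])) {
                if (!k %in% names(cfg[[sec]]))
                    stop("unknown config key: ", sec, ".", k, call. = FALSE)
                cfg[[sec]][[k]] <- user[[sec]][[k]]
            }
        }
    }
    validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
    with(cfg, {
        assertCount(som$grid_rows, "som.grid_rows")
        assertCount(som$grid_cols, "som.grid_cols")
        assertCount(som$epochs, "som.epochs", positive = FALSE)
        if (!som$topology %in% c("rectangular", "hexagonal"))
            stop("som.topology must be rectangular or hexagonal",
                 call. = FALSE)
        if (!(som$lr_initial >= som$lr_final && som$lr_final > 0))
            stop("need som.lr_initial >= som.lr_final > 0", call. = FALSE)
        assertCount(merge$min_size, "merge.min_size")
        for (a in c("alpha_fdr", "alpha_pathway"))
            if (enrichment[[a]] <= 0 || enrichment[[a]] >= 1)
                stop("enrichment.", a, " must lie in (0, 1)", call. = FALSE)
        assertProb(synthetic$enrichment_prob, "synthetic.enrichment_prob")
        assertProb(synthetic$background_prob, "synthetic.background_prob")
    })
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

#' Write a synthetic input bundle for the pipeline
#'
#' Generates a full, seeded input set with planted ground truth -- activity
#' matrix TSV, annotation TSV, gene-set GMT, fingerprint sidecar and truth
#' JSON -- parseable by the package's readers, so the whole pipeline can
#' run without external screening data.
#'
#' @param config configuration list (see [readPipelineConfig()]); the
#'   `synthetic` section and `seed` drive generation.
#' @param dir output directory (created if needed).
#' @return named list of the written file paths, invisibly; component
#'   `truth` holds the [SyntheticTruth-class] object.
#' @export
simulateInputs <- function(config = defaultPipelineConfig(), dir) {
    cfg <- validatePipelineConfig(config)
    sc <- cfg$synthetic
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    seed <- cfg$seed

    sim <- generateActivityMatrix(sc$n_compounds, sc$n_assays,
                                  sc$n_clusters, sc$noise_sd,
                                  seed = stableSeed("activity", seed))
    truth <- sim$truth
    truth@plantedGenes <- plantedGeneSets(sc$n_clusters,
                                          sc$genes_per_cluster)
    ann <- generateAnnotations(truth, sc$genes_per_cluster,
                               sc$enrichment_prob, sc$background_prob,
                               seed = stableSeed("annotations", seed))
    fps <- generateFingerprints(truth, cfg$similarity$fingerprint_bits,
                                sc$intra_flip_prob, sc$inter_seed_density,
                                seed = stableSeed("fingerprints", seed))
    sets <- generatePathways(truth, sc$sets_per_cluster,
                             sc$extra_genes_per_set,
                             seed = stableSeed("pathways", seed),
                             genesPerCluster = sc$genes_per_cluster)

    paths <- list(activity = file.path(dir, "activity.tsv"),
                  annotations = file.path(dir, "annotations.tsv"),
                  gene_sets = file.path(dir, "gene_sets.gmt"),
                  fingerprints = file.path(dir, "fingerprints.json"),
                  truth = file.path(dir, "truth.json"))
    writeActivityMatrix(sim$matrix, paths$activity)
    writeAnnotations(ann, paths$annotations)
    writeGeneSets(sets, paths$gene_sets)
    jsonlite::write_json(list(n_bits = nBits(fps),
                              bits = fingerprintBits(fps)),
                         paths$fingerprints, digits = NA)
    jsonlite::write_json(list(labels = as.list(truth@labels),
                              archetypes = truth@archetypes,
                              planted_genes = truth@plantedGenes,
                              params = truth@params),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    out <- paths
    out$truth <- truth
    invisible(out)
}

#' Read a fingerprint sidecar written by [simulateInputs()]
#'
#' @param path JSON path.
#' @return a [FingerprintSet-class].
#' @export
readFingerprints <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    bits <- lapply(x$bits, as.integer)
    new("FingerprintSet", nBits = as.integer(x$n_bits), bits = bits)
}

#' Run the full candidate-discovery pipeline
#'
#' Executes the stages in order -- load activity data, SOM clustering,
#' small-cluster merging, annotation join, per-cluster gene-target
#' enrichment, pathway enrichment, structural-similarity validation -- and
#' writes each stage's outputs to `outDir` before the next stage starts,
#' ending with a JSON run manifest of content checksums. Identical
#' configuration and seed reproduce a byte-identical run directory. Any
#' stage failure aborts with the stage name; the manifest of completed
#' stages is still written.
#'
#' The per-stage random seeds are derived from the global seed by a stable
#' hash of the stage name, so adding a stage never perturbs earlier
#' stages' randomness.
#'
#' @param config configuration list (see [readPipelineConfig()]); the
#'   `paths` section must point at the inputs. `paths$structures` is
#'   optional -- with real structures, fingerprints are computed with
#'   [structureFingerprints()]; otherwise a fingerprint sidecar
#'   (`paths$annotations` directory convention of [simulateInputs()]) may
#'   be passed as `fingerprintsPath`.
#' @param outDir run directory (created if needed).
#' @param fingerprintsPath optional fingerprint JSON for synthetic runs.
#' @return named list of result objects (`assignment`, `merged`,
#'   `geneEnrichment`, `pathwayEnrichment`, `similarity`, `manifest`),
#'   invisibly.
#' @export
runPipeline <- function(config, outDir, fingerprintsPath = NULL) {
    cfg <- validatePipelineConfig(config)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    seed <- cfg$seed
    stageOutputs <- list()
    finish <- function(stage, paths) stageOutputs[[stage]] <<- paths
    fail <- function(stage, msg) {
        ## partial manifest of the stages that did complete
        try(writeRunManifest(stageOutputs, cfg[names(cfg) != "paths"], seed,
                             file.path(outDir, "manifest.json")),
            silent = TRUE)
        stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) fail(name, conditionMessage(e)))
    }

    ## load
    act <- stage("load", {
        if (is.null(cfg$paths$activity))
            stop("paths.activity is not set", call. = FALSE)
        readActivityMatrix(cfg$paths$activity)
    })

    ## SOM
    som <- cfg$som
    asg <- stage("som", {
        model <- suppressWarnings(trainSom(
            act, som$grid_rows, som$grid_cols, som$topology, som$epochs,
            som$lr_initial, som$lr_final, som$radius_initial,
            som$radius_final, seed = stableSeed("som", seed)))
        a <- assignBmu(model, act)
        utils::write.table(
            data.frame(unit_id = seq_len(nrow(codebook(model))) - 1L,
                       codebook(model), check.names = FALSE),
            file.path(outDir, "codebook.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        writeClusterAssignment(a, file.path(outDir, "clusters_som.tsv"))
        finish("som", file.path(outDir, c("codebook.tsv",
                                          "clusters_som.tsv")))
        a
    })

    ## merge
    merged <- stage("merge", {
        cent <- computeCentroids(act, asg)
        m <- mergeSmallClusters(asg, cent, cfg$merge$min_size)
        writeClusterAssignment(m$assignment,
                               file.path(outDir, "clusters_merged.tsv"))
        utils::write.table(m$log, file.path(outDir, "merge_log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        finish("merge", file.path(outDir, c("clusters_merged.tsv",
                                            "merge_log.tsv")))
        m
    })

    ## annotate (map compounds to annotation keys and join sources)
    ann <- stage("annotate", {
        if (is.null(cfg$paths$annotations))
            stop("paths.annotations is not set", call. = FALSE)
        tables <- lapply(cfg$paths$annotations, readAnnotations)
        names(tables) <- sprintf("table%d", seq_along(tables))
        keys <- if (!is.null(cfg$paths$structures)) {
            recs <- compoundRecords(cfg$paths$structures)
            utils::write.table(recs,
                               file.path(outDir, "compound_records.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            recs
        } else compoundIds(act)          # synthetic ids are already keys
        j <- joinAnnotations(keys, tables)
        writeAnnotations(j, file.path(outDir, "annotations_joined.tsv"))
        finish("annotate", file.path(outDir, "annotations_joined.tsv"))
        j
    })

    ## gene-target enrichment
    ge <- stage("enrich", {
        en <- cfg$enrichment
        res <- suppressMessages(clusterGeneEnrichment(
            merged$assignment, ann, alpha = en$alpha_fdr,
            adjust = en$adjust, minBumTests = en$min_bum_tests,
            pFloor = en$p_floor, seed = stableSeed("enrich", seed)))
        utils::write.table(res, file.path(outDir, "gene_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        fit <- attr(res, "bumFit")
        if (!is.null(fit))
            jsonlite::write_json(
                list(a_hat = fit@aHat, lambda_hat = fit@lambdaHat,
                     pi_ub = fit@piUb, loglik = fit@loglik, n = fit@n,
                     alpha = en$alpha_fdr,
                     tau = bumFdrCutoff(fit, en$alpha_fdr)),
                file.path(outDir, "bum_fit.json"), auto_unbox = TRUE,
                digits = NA)
        finish("enrich", file.path(outDir,
                                   c("gene_enrichment.tsv",
                                     if (!is.null(fit)) "bum_fit.json")))
        res
    })

    ## pathway enrichment
    pe <- stage("pathways", {
        if (is.null(cfg$paths$gene_sets))
            stop("paths.gene_sets is not set", call. = FALSE)
        sets <- readGeneSets(cfg$paths$gene_sets)
        background <- unique(annotationRecords(ann)$gene)
        res <- pathwayEnrichment(enrichedGeneSets(ge), sets, background,
                                 alpha = cfg$enrichment$alpha_pathway)
        utils::write.table(res, file.path(outDir, "pathway_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        finish("pathways", file.path(outDir, "pathway_enrichment.tsv"))
        res
    })

    ## structural-similarity validation
    sim <- stage("similarity", {
        fps <- if (!is.null(fingerprintsPath)) readFingerprints(fingerprintsPath)
               else if (!is.null(cfg$paths$structures))
                   suppressMessages(structureFingerprints(
                       compoundRecords(cfg$paths$structures)))
               else NULL
        if (is.null(fps)) {
            NULL
        } else {
            s <- suppressMessages(intraInterSummary(
                fps, merged$assignment, cfg$similarity$pair_cap,
                seed = stableSeed("similarity", seed)))
            jsonlite::write_json(s, file.path(outDir, "similarity.json"),
                                 auto_unbox = TRUE, digits = NA)
            finish("similarity", file.path(outDir, "similarity.json"))
            s
        }
    })

    manifest <- writeRunManifest(stageOutputs, cfg[names(cfg) != "paths"],
                                 seed, file.path(outDir, "manifest.json"))
    invisible(list(assignment = asg, merged = merged, geneEnrichment = ge,
                   pathwayEnrichment = pe, similarity = sim,
                   manifest = manifest))
}
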