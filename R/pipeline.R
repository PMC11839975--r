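## End-to-end orchestration: normalize -> phylostratigraphy -> indices ->
## flat-line significance -> enrichment, from one validated configuration,
## with every artifact written as TSV/JSON under a single run directory.

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list; unknown keys are rejected so typos
#' fail before any stage runs. Required: \code{outDir} and \code{seed}, plus
#' either \code{simulate = TRUE} (inputs generated with
#' \code{\link{writeSimulatedData}}) or the input paths \code{countsPath},
#' \code{designPath}, \code{hitsPath}, \code{lineagePath}.
#'
#' @param config named list; recognised keys: outDir, seed, simulate,
#'   simConfig, countsPath, designPath, lengthsPath, hitsPath, lineagePath,
#'   cdsPath, divergencePath, annotationsPath, eCutoff, sweepCutoffs,
#'   indices, nPerm, enrichThreshold, useLengths, stageOrder
#' @return the validated config with defaults filled in
#' @export
validateRunConfig <- function(config) {
    known <- c("outDir", "seed", "simulate", "simConfig", "countsPath",
               "designPath", "lengthsPath", "hitsPath", "lineagePath",
               "cdsPath", "divergencePath", "annotationsPath", "eCutoff",
               "sweepCutoffs", "indices", "nPerm", "enrichThreshold",
               "useLengths", "stageOrder")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (is.null(config$outDir)) stop("config$outDir is required")
    if (is.null(config$seed)) stop("config$seed is required")
    defaults <- list(simulate = FALSE, eCutoff = 1e-3,
                     indices = c("tai", "tdni", "tdsi", "tcbi"),
                     nPerm = 1000L, enrichThreshold = 0.5,
                     useLengths = FALSE)
    for (k in names(defaults))
        if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    if (isTRUE(config$simulate)) {
        if (is.null(config$simConfig))
            config$simConfig <- simulationConfig(seed = config$seed)
    } else {
        need <- c("countsPath", "designPath", "hitsPath", "lineagePath")
        miss <- need[vapply(need, function(k) is.null(config[[k]]), TRUE)]
        if (length(miss))
            stop("config missing required input path(s): ",
                 paste(miss, collapse = ", "))
        if (is.null(config$stageOrder))
            stop("config$stageOrder is required when reading external counts")
    }
    config
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, fraction-of-transcripts normalization
#' with replicate-median collapse, standardization, phylostratigraphic
#' assignment (with an optional e-value sweep), the selected
#' expression-weighted indices with flat-line permutation tests, and the
#' stage-wise enrichment scan. All artifacts are written under
#' \code{config$outDir} and a JSON manifest records the seed, package
#' version and md5 digests of every input and output, so two runs with the
#' same config and seed are byte-identical.
#'
#' @param config a run configuration list (see
#'   \code{\link{validateRunConfig}})
#' @return (invisibly) the manifest as a list
#' @export
runPipeline <- function(config) {
    config <- validateRunConfig(config)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    stageName <- "setup"
    manifest <- list(package = "devoTAI",
                     version = as.character(utils::packageVersion("devoTAI")),
                     seed = config$seed, inputs = list(), outputs = list())
    fail <- function(e) stop("pipeline failed at stage '", stageName, "': ",
                             conditionMessage(e), call. = FALSE)
    tryCatch({
        stageName <- "inputs"
        if (isTRUE(config$simulate)) {
            catalog <- simulateGeneCatalog(config$simConfig)
            inDir <- file.path(config$outDir, "inputs")
            paths <- writeSimulatedData(catalog, config$simConfig, inDir)
            config$countsPath <- paths[["counts"]]
            config$designPath <- paths[["design"]]
            config$hitsPath <- paths[["hits"]]
            config$lineagePath <- paths[["lineage"]]
            config$cdsPath <- paths[["cds"]]
            config$divergencePath <- paths[["divergence"]]
            config$annotationsPath <- paths[["annotations"]]
            config$stageOrder <- config$simConfig@stages
        }
        for (k in c("countsPath", "designPath", "hitsPath", "lineagePath",
                    "cdsPath", "divergencePath", "annotationsPath")) {
            p <- config[[k]]
            if (!is.null(p)) {
                if (!file.exists(p)) stop("input not found: ", p)
                manifest$inputs[[k]] <- unname(tools::md5sum(p))
            }
        }

        stageName <- "normalize"
        counts <- readStageCounts(config$countsPath, config$designPath,
                                  stageOrder = config$stageOrder,
                                  lengthsPath = config$lengthsPath)
        frac <- normalizeFractions(counts, useLengths = config$useLengths)
        expr <- collapseReplicates(frac, SummarizedExperiment::colData(counts))
        writeStageExpression(expr, file.path(config$outDir, "stage_expression.tsv"))
        std <- standardizeExpression(expr)
        writeStandardizedExpression(std,
            file.path(config$outDir, "standardized_expression.tsv"))

        stageName <- "phylostratigraphy"
        hits <- utils::read.delim(config$hitsPath, stringsAsFactors = FALSE)
        lin <- utils::read.delim(config$lineagePath, stringsAsFactors = FALSE)
        lineage <- LineageMap(stats::setNames(lin$ps, lin$taxon))
        psMap <- assignPhylostrata(hits, lineage, config$eCutoff)
        writePhylostratumMap(psMap, file.path(config$outDir, "phylostrata.tsv"))
        if (!is.null(config$sweepCutoffs)) {
            sw <- evalueSweep(hits, lineage, config$sweepCutoffs)
            sweepDf <- do.call(rbind, lapply(names(sw$maps), function(nm) {
                m <- sw$maps[[nm]]
                data.frame(cutoff = nm, gene = names(m@ps),
                           ps = unname(m@ps))
            }))
            writeTsv(sweepDf, file.path(config$outDir, "evalue_sweep.tsv"))
        }

        stageName <- "evolutionary stats"
        div <- if (!is.null(config$divergencePath))
            readDivergenceTable(config$divergencePath) else NULL
        enc <- NULL
        if (!is.null(config$cdsPath)) {
            cds <- Biostrings::readDNAStringSet(config$cdsPath)
            enc <- pmin(pmax(encProfile(cds), 20), 61)
        }
        genes <- rownames(exprValues(expr))
        evol <- GeneEvolStats(
            genes,
            ps = psAssignments(psMap)[genes],
            dN = if (!is.null(div)) div$dN[genes],
            dS = if (!is.null(div)) div$dS[genes],
            enc = if (!is.null(enc)) enc[genes])

        stageName <- "indices"
        indexFuns <- list(tai = tai, tdni = tdni, tdsi = tdsi, tcbi = tcbi)
        flat <- list()
        for (ix in config$indices) {
            prof <- indexFuns[[ix]](expr, evol)
            writeIndexProfile(prof,
                file.path(config$outDir, paste0(ix, "_profile.tsv")))
            writeIndexProfile(minMaxNormalizeProfile(prof),
                file.path(config$outDir, paste0(ix, "_profile_norm.tsv")))
            stageName <- "flat-line test"
            w <- stats::setNames(
                as.numeric(evolStats(evol)[[weightName(prof)]]),
                rownames(evolStats(evol)))
            fl <- flatLineTest(expr, w, nPerm = config$nPerm,
                               seed = config$seed, gammaFit = TRUE,
                               weightName = weightName(prof))
            flat[[ix]] <- list(observed_variance = fl@observedVariance,
                               p_value = fl@pValue, p_gamma = fl@pGamma,
                               n_permutations = fl@nPermutations)
            writeTsv(fl@nullBand,
                     file.path(config$outDir, paste0(ix, "_null_band.tsv")))
            stageName <- "indices"
        }
        jsonlite::write_json(flat, file.path(config$outDir, "flatline.json"),
                             auto_unbox = TRUE, digits = NA)

        stageName <- "relative expression"
        re <- relativeExpression(expr, evol)
        writeTsv(data.frame(ps = rownames(re), re, check.names = FALSE),
                 file.path(config$outDir, "relative_expression.tsv"))

        stageName <- "enrichment"
        if (!is.null(config$annotationsPath)) {
            ann <- readAnnotations(config$annotationsPath)
            scan <- enrichmentScan(std, ann,
                                   threshold = config$enrichThreshold)
            writeTsv(scan, file.path(config$outDir, "enrichment.tsv"))
        }

        stageName <- "manifest"
        outFiles <- setdiff(list.files(config$outDir, recursive = TRUE,
                                       full.names = TRUE),
                            file.path(config$outDir, "manifest.json"))
        digests <- tools::md5sum(outFiles)
        manifest$outputs <- as.list(stats::setNames(
            unname(digests),
            sub(paste0("^", config$outDir, "/?"), "", outFiles)))
        jsonlite::write_json(manifest,
                             file.path(config$outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }, error = fail)
    invisible(manifest)
}
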