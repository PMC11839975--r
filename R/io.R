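## Plain-text readers and writers: every intermediate of the pipeline is a
## TSV (or JSON sidecar) so multi-stage runs stay inspectable.

#' Read a count matrix and sample design from TSV
#'
#' @param countsPath TSV, genes x samples, first column gene ids, header row
#'   sample ids
#' @param designPath TSV with columns \code{sample}, \code{stage},
#'   \code{replicate}; stage order is the order of first appearance unless
#'   \code{stageOrder} is given
#' @param stageOrder optional ordered stage labels
#' @param lengthsPath optional TSV with columns \code{gene}, \code{length}
#' @return a \linkS4class{StageCounts}
#' @export
readStageCounts <- function(countsPath, designPath, stageOrder = NULL,
                            lengthsPath = NULL) {
    cts <- utils::read.delim(countsPath, row.names = 1, check.names = FALSE)
    design <- utils::read.delim(designPath, stringsAsFactors = FALSE)
    need <- c("sample", "stage", "replicate")
    if (!all(need %in% colnames(design)))
        stop("design needs columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(cts), design$sample)
    if (length(missing))
        stop("samples without design rows: ", paste(missing, collapse = ", "))
    design <- design[match(colnames(cts), design$sample), ]
    lengths <- NULL
    if (!is.null(lengthsPath)) {
        lt <- utils::read.delim(lengthsPath, stringsAsFactors = FALSE)
        lengths <- stats::setNames(lt$length, lt$gene)
    }
    StageCounts(as.matrix(cts), stage = design$stage,
                replicate = design$replicate, stageOrder = stageOrder,
                geneLengths = lengths)
}

#' Write a StageCounts object as counts + design TSV
#' @param counts a \linkS4class{StageCounts}
#' @param countsPath,designPath output paths
#' @export
writeStageCounts <- function(counts, countsPath, designPath) {
    cts <- SummarizedExperiment::assay(counts, "counts")
    writeTsv(data.frame(gene = rownames(cts), cts, check.names = FALSE),
             countsPath)
    cd <- SummarizedExperiment::colData(counts)
    writeTsv(data.frame(sample = rownames(cd),
                        stage = as.character(cd$stage),
                        replicate = cd$replicate), designPath)
}

#' Write / read stage-level expression
#' @param expr a \linkS4class{StageExpression}
#' @param path TSV path
#' @export
writeStageExpression <- function(expr, path) {
    v <- expr@values
    writeTsv(data.frame(gene = rownames(v), v, check.names = FALSE), path)
}

#' @rdname writeStageExpression
#' @export
readStageExpression <- function(path) {
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    new("StageExpression", values = m, stageOrder = colnames(m))
}

#' Write standardized expression with its audit sidecar
#' @param std a \linkS4class{StandardizedExpression}
#' @param path TSV path; the audit is written next to it as
#'   \code{<path>.audit.json}
#' @export
writeStandardizedExpression <- function(std, path) {
    v <- std@values
    writeTsv(data.frame(gene = rownames(v), v, check.names = FALSE), path)
    jsonlite::write_json(std@audit, paste0(path, ".audit.json"),
                         auto_unbox = TRUE)
}

#' Write a phylostratum map as TSV (gene, ps; unassigned genes ps = NA)
#' @param map a \linkS4class{PhylostratumMap}
#' @param path output path
#' @export
writePhylostratumMap <- function(map, path) {
    df <- rbind(
        data.frame(gene = names(map@ps), ps = unname(map@ps)),
        if (length(map@unassigned))
            data.frame(gene = map@unassigned, ps = NA_integer_))
    writeTsv(df[order(df$gene), ], path)
}

#' Write an index profile as TSV (stage, value)
#' @param profile an \linkS4class{IndexProfile}
#' @param path output path
#' @export
writeIndexProfile <- function(profile, path) {
    writeTsv(data.frame(stage = names(profile@values),
                        value = unname(profile@values)), path)
}

#' Read a gene-term annotation TSV (columns gene, term)
#' @param path input path
#' @param termSubset,universe passed to \code{\link{AnnotationSet}}
#' @export
readAnnotations <- function(path, termSubset = NULL, universe = NULL) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    AnnotationSet(tab, termSubset = termSubset, universe = universe)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write all simulated inputs of a run to a directory
#'
#' Materializes the synthetic study as the plain-text files a real analysis
#' would start from: counts + design TSV, homology hit table TSV, lineage
#' TSV, CDS FASTA, dN/dS TSV, GO annotation TSV, and a ground-truth TSV with
#' the true phylostrata.
#'
#' @param catalog a \linkS4class{GeneCatalog}
#' @param config its \linkS4class{SimulationConfig}
#' @param dir output directory (created if needed)
#' @param taxaPerPs,noise passed to \code{\link{simulateHitTable}}
#' @return named character vector of the written paths
#' @export
writeSimulatedData <- function(catalog, config, dir, taxaPerPs = 2L,
                               noise = 0) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    g <- catalog@genes
    sim <- simulateCounts(catalog, config)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               design = file.path(dir, "design.tsv"),
               hits = file.path(dir, "hits.tsv"),
               lineage = file.path(dir, "lineage.tsv"),
               cds = file.path(dir, "cds.fasta"),
               divergence = file.path(dir, "divergence.tsv"),
               annotations = file.path(dir, "annotations.tsv"),
               truth = file.path(dir, "ground_truth.tsv"))
    writeStageCounts(sim$counts, paths["counts"], paths["design"])
    ht <- simulateHitTable(catalog, taxaPerPs = taxaPerPs, noise = noise,
                           seed = config@seed + 2L)
    writeTsv(ht$hits, paths["hits"])
    writeTsv(data.frame(taxon = names(ht$lineage@taxonToPs),
                        ps = unname(ht$lineage@taxonToPs)), paths["lineage"])
    cds <- simulateCds(catalog, seed = config@seed + 3L)
    Biostrings::writeXStringSet(cds, paths["cds"])
    writeTsv(data.frame(gene = rownames(g), dN = g$dN, dS = g$dS),
             paths["divergence"])
    ann <- data.frame(
        gene = rep(rownames(g), lengths(g$go_terms)),
        term = unlist(g$go_terms, use.names = FALSE))
    writeTsv(ann, paths["annotations"])
    writeTsv(data.frame(gene = rownames(g), true_ps = g$true_ps,
                        cds_length = g$cds_length,
                        target_enc = g$target_enc), paths["truth"])
    paths
}
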