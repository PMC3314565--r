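## End-to-end analysis driver and per-gene report assembly.

#' Run the full analysis pipeline
#'
#' Executes normalization, exon-level statistics, DABG filtering,
#' gene-level statistics and meta statistics in order and writes
#' `exon_stats.tsv`, `gene_stats.tsv`, `meta_stats.tsv` and a JSON run
#' manifest (configuration, seed, package version, row counts) to
#' `outDir`. Re-running with identical inputs reproduces byte-identical
#' tables.
#'
#' @param x an `ExonArrayExperiment`.
#' @param outDir output directory (created if needed).
#' @param paired paired t-tests (requires `patient_id`).
#' @param summaryMethod cluster summarization for normalization.
#' @param geneMethod gene-level summarizer ([geneStats()]).
#' @param adjust `"none"` or `"BH"`.
#' @param dabgThreshold,dabgMinFraction,dabgMode DABG filter parameters.
#' @param siThreshold,pThreshold flagging thresholds ([exonStats()]).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return invisibly, a list with `exon`, `gene`, `meta` tables, the
#'   `scaled` meta object and the output `paths`.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(nGenes = 10, nPairs = 5))
#' res <- runAnalyze(sim$dataset, tempfile("run"))
#' names(res)
#' @export
runAnalyze <- function(x, outDir, paired = FALSE,
                       summaryMethod = "medianpolish",
                       geneMethod = "medianpolish",
                       adjust = "none",
                       dabgThreshold = 0.05, dabgMinFraction = 0.5,
                       dabgMode = "either",
                       siThreshold = 0.5, pThreshold = 0.05,
                       seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(what, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", what, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    exon <- stage("exon_stats", exonStats(
        x, paired = paired, summaryMethod = summaryMethod,
        adjust = adjust, dabgThreshold = dabgThreshold,
        dabgMinFraction = dabgMinFraction, dabgMode = dabgMode,
        siThreshold = siThreshold, pThreshold = pThreshold))
    gene <- stage("gene_stats", suppressWarnings(
        geneStats(x, method = geneMethod, paired = paired)))
    meta <- stage("meta_stats", suppressWarnings(computeMeta(exon)))
    scaled <- if (nrow(meta) >= 2L) scaleMeta(meta) else NULL

    paths <- c(exon = file.path(outDir, "exon_stats.tsv"),
               gene = file.path(outDir, "gene_stats.tsv"),
               meta = file.path(outDir, "meta_stats.tsv"),
               manifest = file.path(outDir, "manifest.json"))
    writeStatsTable(exon, paths[["exon"]])
    writeStatsTable(gene, paths[["gene"]])
    writeStatsTable(meta, paths[["meta"]])
    manifest <- list(
        package = "exonsplice",
        version = as.character(packageVersion("exonsplice")),
        seed = seed,
        parameters = list(paired = paired, summaryMethod = summaryMethod,
                          geneMethod = geneMethod, adjust = adjust,
                          dabgThreshold = dabgThreshold,
                          dabgMinFraction = dabgMinFraction,
                          dabgMode = dabgMode, siThreshold = siThreshold,
                          pThreshold = pThreshold),
        n_probesets = nrow(exon), n_genes = nrow(gene),
        n_samples = ncol(x), n_filtered = sum(exon$filtered))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), paths[["manifest"]])
    invisible(list(exon = exon, gene = gene, meta = meta, scaled = scaled,
                   paths = paths))
}

#' Assemble a per-gene report
#'
#' Collects everything known about one gene into a three-section report:
#' annotation (position, pathway and GO membership); exon level (the
#' per-probeset statistics ordered along the gene in transcription order,
#' the Splicing Index profile with traffic-light support colors, flagged
#' probesets, and the isoform x probeset membership matrix); and gene
#' level (fold change and t p-value, meta statistics, pathway/GO neighbor
#' rankings and, when supplied, per-probeset tree summaries). Every number
#' is taken from the analysis tables unchanged.
#'
#' Traffic-light color on the MiDAS p-value: `"green"` for p >= 0.05,
#' `"amber"` for 0.01 <= p < 0.05, `"red"` for p < 0.01.
#'
#' @param geneId the gene to report.
#' @param x the analyzed `ExonArrayExperiment`.
#' @param analysis result of [runAnalyze()] (list with `exon`, `gene`,
#'   `meta`, `scaled`).
#' @param trees optional result of [probesetTrees()] covering this gene's
#'   probesets.
#' @return a nested list (JSON-serializable via [writeGeneReport()]).
#' @export
buildGeneReport <- function(geneId, x, analysis, trees = NULL) {
    ga <- geneAnno(x)
    if (!(geneId %in% ga$gene_id))
        stop("unknown gene '", geneId, "'")
    anno <- probesetAnno(x)
    ps <- anno[anno$gene_id == geneId, , drop = FALSE]
    ## transcription order: genomic start ascending, reversed on minus
    ## strand so exon_index increases left to right
    ord <- order(ps$start)
    if (ps$strand[1L] == "-") ord <- rev(ord)
    ps <- ps[ord, , drop = FALSE]

    ex <- analysis$exon
    ex <- ex[match(ps$probeset_id, ex$probeset_id), , drop = FALSE]
    lights <- ifelse(ex$midas_p < 0.01, "red",
                     ifelse(ex$midas_p < 0.05, "amber", "green"))
    isoforms <- sort(unique(unlist(strsplit(ps$isoform_ids, ";"))))
    isoMat <- vapply(ps$probeset_id, function(id) {
        members <- strsplit(ps$isoform_ids[ps$probeset_id == id], ";")[[1L]]
        isoforms %in% members
    }, logical(length(isoforms)))
    if (is.null(dim(isoMat)))
        isoMat <- matrix(isoMat, nrow = length(isoforms),
                         dimnames = list(isoforms, ps$probeset_id))
    else rownames(isoMat) <- isoforms

    gs <- geneSets(x)
    myPw <- unique(gs$set_id[gs$gene_id == geneId & gs$kind == "pathway"])
    myGo <- unique(gs$set_id[gs$gene_id == geneId & gs$kind == "go"])
    neighbors <- list()
    if (!is.null(analysis$scaled) &&
        geneId %in% rownames(analysis$scaled$scaled)) {
        for (s in c(myPw, myGo))
            neighbors[[s]] <- rankWithinSet(geneId, s, analysis$scaled, gs)
    }
    gn <- analysis$gene[analysis$gene$gene_id == geneId, , drop = FALSE]
    mt <- analysis$meta[analysis$meta$gene_id == geneId, , drop = FALSE]

    treeSummaries <- NULL
    if (!is.null(trees)) {
        ts <- trees$summary
        treeSummaries <- ts[ts$probeset_id %in% ps$probeset_id, ,
                            drop = FALSE]
    }
    list(
        annotation = list(
            gene_id = geneId,
            symbol = ga$symbol[ga$gene_id == geneId],
            aliases = ga$aliases[ga$gene_id == geneId],
            chrom = ga$chrom[ga$gene_id == geneId],
            start = ga$start[ga$gene_id == geneId],
            stop = ga$stop[ga$gene_id == geneId],
            strand = ga$strand[ga$gene_id == geneId],
            pathways = myPw, go_terms = myGo),
        exon_level = list(
            probesets = cbind(ps[c("probeset_id", "exon_index", "start",
                                   "stop")],
                              ex[setdiff(colnames(ex),
                                         c("probeset_id", "gene_id",
                                           "transcript_cluster_id"))],
                              traffic_light = lights),
            si_profile = setNames(ex$splicing_index, ex$probeset_id),
            flagged = ex$probeset_id[ex$flagged],
            isoform_matrix = isoMat),
        gene_level = list(
            stats = gn,
            meta = mt,
            neighbors = neighbors,
            trees = treeSummaries))
}

#' Write a gene report as JSON
#'
#' @param report result of [buildGeneReport()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGeneReport <- function(report, path) {
    report$exon_level$isoform_matrix <-
        as.data.frame(report$exon_level$isoform_matrix)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, dataframe = "rows"), path)
    invisible(path)
}
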