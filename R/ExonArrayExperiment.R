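#' Construct an ExonArrayExperiment
#'
#' Assembles probeset-level expression (and optionally DABG p-values),
#' sample metadata and probeset annotation into a validated
#' [ExonArrayExperiment][ExonArrayExperiment-class]. Gene-level annotation
#' is derived from the probeset annotation (gene span = range of its
#' probesets; symbol defaults to the gene id) and may be enriched with a
#' `genes` table and a `geneSets` membership table.
#'
#' @param exprs numeric matrix of log2 intensities, probesets x samples,
#'   with dimnames.
#' @param samples `data.frame` of sample metadata; must contain
#'   `sample_id` and `condition` (`"normal"`/`"pathological"`); optional
#'   `patient_id`, `gender`, `age`, `stage` and arbitrary extra covariates.
#' @param annotation `data.frame` of probeset annotation with columns
#'   `probeset_id`, `transcript_cluster_id`, `gene_id`, `chrom`, `start`,
#'   `stop`, `strand`, `exon_index`, `isoform_ids` (semicolon-separated or
#'   a list column).
#' @param dabg optional numeric matrix of DABG p-values, same dimnames as
#'   `exprs`.
#' @param genes optional `data.frame` with `gene_id`, `symbol` and
#'   optionally `aliases` (semicolon-separated) overriding derived gene
#'   annotation.
#' @param geneSets optional `data.frame` with columns `set_id`, `gene_id`,
#'   `kind` (`"pathway"` or `"go"`).
#' @return an `ExonArrayExperiment`.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(nGenes = 5, nPairs = 3))
#' sim$dataset
#' @export
ExonArrayExperiment <- function(exprs, samples, annotation, dabg = NULL,
                                genes = NULL, geneSets = NULL) {
    samples <- as.data.frame(samples)
    annotation <- as.data.frame(annotation)
    .checkSampleTable(samples)
    .checkAnnotationTable(annotation)

    ord <- match(rownames(exprs), annotation$probeset_id)
    if (anyNA(ord)) {
        bad <- rownames(exprs)[which(is.na(ord))[1L]]
        stop("probeset '", bad, "' in expression matrix is absent from ",
             "the annotation table")
    }
    anno <- annotation[ord, , drop = FALSE]
    sord <- match(colnames(exprs), samples$sample_id)
    if (anyNA(sord)) {
        bad <- colnames(exprs)[which(is.na(sord))[1L]]
        stop("sample '", bad, "' in expression matrix is absent from ",
             "the metadata table")
    }
    smp <- samples[sord, , drop = FALSE]

    iso <- anno$isoform_ids
    if (!is.list(iso))
        iso <- .splitSemicolon(as.character(iso))
    rr <- GRanges(seqnames = as.character(anno$chrom),
                  ranges = IRanges(start = as.integer(anno$start),
                                   end = as.integer(anno$stop)),
                  strand = as.character(anno$strand))
    names(rr) <- anno$probeset_id
    mcols(rr) <- DataFrame(
        probeset_id = anno$probeset_id,
        transcript_cluster_id = as.character(anno$transcript_cluster_id),
        gene_id = as.character(anno$gene_id),
        exon_index = as.integer(anno$exon_index),
        isoform_ids = CharacterList(iso))

    cd <- DataFrame(smp, row.names = smp$sample_id)
    cd$condition <- factor(as.character(cd$condition),
                           levels = c("normal", "pathological"))

    assays <- list(exprs = exprs)
    if (!is.null(dabg)) {
        if (!identical(dimnames(dabg), dimnames(exprs)))
            stop("dabg matrix must have identical dimnames to exprs")
        assays$dabg <- dabg
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = rr, colData = cd)
    obj <- new("ExonArrayExperiment", se)
    metadata(obj)$genes <- .deriveGeneAnnotation(rr, genes)
    metadata(obj)$geneSets <- .checkGeneSets(geneSets)
    validObject(obj)
    obj
}

.splitSemicolon <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
}

.checkSampleTable <- function(samples) {
    if (!("sample_id" %in% colnames(samples)))
        stop("sample metadata: 'sample_id' column required")
    if (!("condition" %in% colnames(samples)))
        stop("sample metadata: 'condition' column required")
    dup <- samples$sample_id[duplicated(samples$sample_id)]
    if (length(dup))
        stop("duplicate sample id '", dup[1L], "' in metadata")
    bad <- setdiff(unique(as.character(samples$condition)),
                   c("normal", "pathological"))
    if (length(bad))
        stop("sample metadata: condition value '", bad[1L],
             "' is not 'normal' or 'pathological'")
    invisible(TRUE)
}

.checkAnnotationTable <- function(anno) {
    need <- c("probeset_id", "transcript_cluster_id", "gene_id", "chrom",
              "start", "stop", "strand", "exon_index", "isoform_ids")
    miss <- setdiff(need, colnames(anno))
    if (length(miss))
        stop("annotation table lacks column(s): ",
             paste(miss, collapse = ", "))
    dup <- anno$probeset_id[duplicated(anno$probeset_id)]
    if (length(dup))
        stop("duplicate probeset id '", dup[1L], "' in annotation")
    bad <- which(as.integer(anno$start) > as.integer(anno$stop))
    if (length(bad))
        stop("annotation: start > stop for probeset '",
             anno$probeset_id[bad[1L]], "'")
    bad <- setdiff(unique(as.character(anno$strand)), c("+", "-"))
    if (length(bad))
        stop("annotation: strand must be '+' or '-' (probeset '",
             anno$probeset_id[which(anno$strand == bad[1L])[1L]], "')")
    invisible(TRUE)
}

.checkGeneSets <- function(gs) {
    if (is.null(gs))
        return(data.frame(set_id = character(), gene_id = character(),
                          kind = character()))
    gs <- as.data.frame(gs)
    need <- c("set_id", "gene_id", "kind")
    miss <- setdiff(need, colnames(gs))
    if (length(miss))
        stop("gene-set table lacks column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(gs$kind), c("pathway", "go"))
    if (length(bad))
        stop("gene-set kind '", bad[1L], "' is not 'pathway' or 'go'")
    gs[c("set_id", "gene_id", "kind")]
}

## Gene span = range over the gene's probesets; transcription-order display
## relies on strand kept here.
.deriveGeneAnnotation <- function(rr, genes = NULL) {
    gid <- mcols(rr)$gene_id
    idx <- split(seq_along(rr), gid)
    df <- data.frame(
        gene_id = names(idx),
        symbol = names(idx),
        aliases = "",
        chrom = vapply(idx, function(i)
            as.character(seqnames(rr))[i[1L]], character(1)),
        start = vapply(idx, function(i) min(start(rr)[i]), integer(1)),
        stop = vapply(idx, function(i) max(end(rr)[i]), integer(1)),
        strand = vapply(idx, function(i)
            as.character(strand(rr))[i[1L]], character(1)),
        n_probesets = lengths(idx),
        stringsAsFactors = FALSE)
    rownames(df) <- df$gene_id
    if (!is.null(genes)) {
        genes <- as.data.frame(genes)
        m <- match(df$gene_id, genes$gene_id)
        hit <- !is.na(m)
        if ("symbol" %in% colnames(genes))
            df$symbol[hit] <- as.character(genes$symbol[m[hit]])
        if ("aliases" %in% colnames(genes))
            df$aliases[hit] <- as.character(genes$aliases[m[hit]])
    }
    df
}

#' Accessors for ExonArrayExperiment components
#'
#' `exonExprs()` returns the log2 expression matrix, `dabg()` the DABG
#' p-value matrix (or `NULL`), `probesetAnno()` the probeset annotation as
#' a `data.frame` (coordinates 1-based inclusive), `geneAnno()` the derived
#' gene annotation and `geneSets()` the pathway/GO membership table.
#'
#' @param x an `ExonArrayExperiment`.
#' @return matrix or `data.frame` as described.
#' @name accessors
#' @aliases exonExprs dabg probesetAnno geneAnno geneSets
#' @examples
#' sim <- simulateExonDataset(simulationConfig(nGenes = 4, nPairs = 3))
#' dim(exonExprs(sim$dataset))
#' head(probesetAnno(sim$dataset))
NULL

#' @rdname accessors
#' @export
exonExprs <- function(x) assay(x, "exprs")

#' @rdname accessors
#' @export
dabg <- function(x) {
    if ("dabg" %in% assayNames(x)) assay(x, "dabg") else NULL
}

#' @rdname accessors
#' @export
probesetAnno <- function(x) {
    rr <- rowRanges(x)
    mc <- mcols(rr)
    data.frame(
        probeset_id = mc$probeset_id,
        transcript_cluster_id = mc$transcript_cluster_id,
        gene_id = mc$gene_id,
        chrom = as.character(seqnames(rr)),
        start = start(rr),
        stop = end(rr),
        strand = as.character(strand(rr)),
        exon_index = mc$exon_index,
        isoform_ids = vapply(as.list(mc$isoform_ids), paste,
                             character(1), collapse = ";"),
        row.names = mc$probeset_id,
        stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

#' @rdname accessors
#' @export
geneAnno <- function(x) metadata(x)$genes

#' @rdname accessors
#' @export
geneSets <- function(x) metadata(x)$geneSets

#' Condition factor of an ExonArrayExperiment
#'
#' @param x an `ExonArrayExperiment`.
#' @return factor with levels `normal`, `pathological`, one per sample.
#' @export
condition <- function(x) colData(x)$condition

setMethod("show", "ExonArrayExperiment", function(object) {
    callNextMethod()
    tab <- table(condition(object))
    cat(sprintf("genes(%d) | conditions: normal=%d pathological=%d | dabg: %s\n",
                nrow(geneAnno(object)), tab[["normal"]],
                tab[["pathological"]],
                if ("dabg" %in% assayNames(object)) "yes" else "no"))
})
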