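#' @import methods
#' @importFrom stats median p.adjust pf pt var sd rnorm runif setNames
#'   medpolish model.matrix
#' @importFrom utils read.delim read.csv write.csv write.table
#'   packageVersion head
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData rowRanges
#' @importFrom S4Vectors DataFrame metadata `metadata<-` mcols `mcols<-`
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges start end strand seqnames
NULL

#' Container for probeset-level exon array data
#'
#' `ExonArrayExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are probesets
#' (each interrogating at most one exon), columns are samples. The `"exprs"`
#' assay holds post-summarization log2 intensities; an optional `"dabg"`
#' assay holds detection-above-background p-values. Probeset annotation
#' (transcript cluster, gene, exon ordinal, isoform membership) lives in
#' `rowRanges()`/`rowData()`; sample metadata (condition, patient pairing,
#' clinical covariates) in `colData()`. Gene-level annotation and optional
#' pathway/GO membership tables are carried in `metadata()`.
#'
#' @section Validity:
#' * the `"exprs"` assay exists and is all finite;
#' * a `"dabg"` assay, if present, has the same dimnames and values in
#'   \[0, 1\];
#' * `colData()` has a `condition` column with values in
#'   `{"normal", "pathological"}`;
#' * `rowData()` carries `transcript_cluster_id`, `gene_id`, `exon_index`
#'   and `isoform_ids`.
#'
#' @aliases ExonArrayExperiment-class
#' @seealso [readExonDataset()], [simulateExonDataset()], [exonStats()]
#' @export
setClass("ExonArrayExperiment", contains = "RangedSummarizedExperiment")

.validExonArrayExperiment <- function(object) {
    msg <- character()
    if (!("exprs" %in% assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        e <- assay(object, "exprs")
        if (!is.numeric(e) || any(!is.finite(e)))
            msg <- c(msg, "assay 'exprs' must be finite numeric (log2 scale)")
    }
    if ("dabg" %in% assayNames(object)) {
        d <- assay(object, "dabg")
        if (any(d < 0 | d > 1, na.rm = TRUE))
            msg <- c(msg, "assay 'dabg' must contain p-values in [0, 1]")
    }
    cd <- colData(object)
    if (!("condition" %in% colnames(cd)))
        msg <- c(msg, "colData must contain a 'condition' column")
    else if (!all(as.character(cd$condition) %in% c("normal", "pathological")))
        msg <- c(msg, "condition must be 'normal' or 'pathological'")
    need <- c("transcript_cluster_id", "gene_id", "exon_index", "isoform_ids")
    miss <- setdiff(need, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate probeset ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
}

setValidity("ExonArrayExperiment", .validExonArrayExperiment)

#' Conditional-inference splice tree
#'
#' A fitted decision tree relating a single response (typically one
#' probeset's cluster-normalized expression) to clinical covariates.
#' Internal nodes carry the selected covariate, its Bonferroni-adjusted
#' permutation p-value and an ANOVA-optimal split; leaves carry sample
#' counts and response moments. Create with [growTree()].
#'
#' @slot root recursive `list` of nodes (see [growTree()] for fields)
#' @slot control the [treeControl()] list used for fitting
#' @slot covariates character vector of candidate covariate names
#' @slot nobs number of samples at the root
#' @aliases SpliceTree-class
#' @export
setClass("SpliceTree",
         representation(root = "list", control = "list",
                        covariates = "character", nobs = "integer"))
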