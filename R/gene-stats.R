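## Gene-level summarization from isoform-mapped probesets and
## differential expression statistics.

## Tukey median polish at the fixed settings used throughout (tolerance
## 1e-6, at most 10 row-then-column sweeps); hitting the sweep cap is
## intentional, so the non-convergence warning is muffled.
.medpolishQuiet <- function(m) {
    withCallingHandlers(
        medpolish(m, eps = 1e-6, maxiter = 10L, trace.iter = FALSE),
        warning = function(w) {
            if (grepl("did not converge", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

#' Summarize a gene's expression across samples
#'
#' Collapses a set of probesets to one log2 expression value per sample.
#' `"medianpolish"` fits Tukey's median polish (row-then-column sweeps,
#' convergence tolerance 1e-6, at most 10 sweeps) to the probesets x
#' samples submatrix and returns overall + column effects, the RMA-style
#' summarizer operating on already-summarized probeset values; `"mean"`
#' returns plain column means. A single probeset is returned unchanged by
#' both methods.
#'
#' @param expression log2 expression matrix (probesets x samples).
#' @param probesetIds rows to aggregate; must be non-empty and present.
#' @param method `"medianpolish"` (default) or `"mean"`.
#' @return named numeric vector, one value per sample.
#' @export
summarizeGene <- function(expression, probesetIds,
                          method = c("medianpolish", "mean")) {
    method <- match.arg(method)
    if (length(probesetIds) == 0L)
        stop("probesetIds must be non-empty")
    miss <- setdiff(probesetIds, rownames(expression))
    if (length(miss))
        stop("probeset '", miss[1L], "' not present in the expression matrix")
    sub <- expression[probesetIds, , drop = FALSE]
    if (nrow(sub) == 1L || method == "mean") {
        if (nrow(sub) == 1L) return(sub[1L, ])
        return(colMeans(sub))
    }
    mp <- .medpolishQuiet(sub)
    setNames(mp$overall + mp$col, colnames(sub))
}

#' Gene-level fold change and t-test
#'
#' Group difference of per-sample gene summaries, `mean(normal) -
#' mean(pathological)` in log2 units (the same sign convention as the exon
#' level), with a two-sided Student t p-value from the same machinery as
#' [exonTTest()].
#'
#' @param summary named per-sample gene expression vector from
#'   [summarizeGene()].
#' @param groups condition labels, one per sample.
#' @param paired paired test on `pairs`.
#' @param pairs pairing key, required when `paired = TRUE`.
#' @return list with `log2_fc` and `p`.
#' @export
geneFoldChangeTest <- function(summary, groups, paired = FALSE,
                               pairs = NULL) {
    m <- matrix(summary, nrow = 1L,
                dimnames = list("gene", names(summary)))
    gi <- .twoGroupIdx(groups)
    fc <- rowMeans(m[, gi$normal, drop = FALSE]) -
        rowMeans(m[, gi$pathological, drop = FALSE])
    tt <- exonTTest(m, groups, paired = paired, pairs = pairs)
    list(log2_fc = unname(fc), p = unname(tt$p))
}

#' Gene-level statistics table
#'
#' For every gene, summarizes expression over its isoform-mapped probesets
#' (probesets with non-empty isoform membership; genes without any fall
#' back to all their probesets, with one collective warning) and computes
#' the gene-level log2 fold change and t-test p-value.
#'
#' @param x an `ExonArrayExperiment`.
#' @param method summarizer, `"medianpolish"` (default) or `"mean"`.
#' @param paired paired t-test on patient pairs.
#' @return `data.frame` with `gene_id`, `symbol`, `gene_log2_fc`,
#'   `gene_t_p`, `n_probesets_used`; the genes x samples summary matrix is
#'   attached as `attr(, "summary")`.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(
#'     nGenes = 10, nPairs = 6, geneDeFraction = 0.3, seed = 3))
#' gs <- geneStats(sim$dataset)
#' head(gs)
#' @export
geneStats <- function(x, method = c("medianpolish", "mean"),
                      paired = FALSE) {
    method <- match.arg(method)
    anno <- probesetAnno(x)
    exprs <- exonExprs(x)
    groups <- condition(x)
    pairs <- if (paired) colData(x)$patient_id
    genes <- sort(unique(anno$gene_id))
    hasIso <- nzchar(anno$isoform_ids)
    fellBack <- character()

    summ <- matrix(NA_real_, length(genes), ncol(exprs),
                   dimnames = list(genes, colnames(exprs)))
    fc <- numeric(length(genes)); pv <- numeric(length(genes))
    nUsed <- integer(length(genes))
    for (i in seq_along(genes)) {
        sel <- anno$gene_id == genes[i]
        ids <- anno$probeset_id[sel & hasIso]
        if (!length(ids)) {
            ids <- anno$probeset_id[sel]
            fellBack <- c(fellBack, genes[i])
        }
        s <- summarizeGene(exprs, ids, method = method)
        summ[i, ] <- s
        res <- geneFoldChangeTest(s, groups, paired = paired, pairs = pairs)
        fc[i] <- res$log2_fc; pv[i] <- res$p
        nUsed[i] <- length(ids)
    }
    if (length(fellBack))
        warning(length(fellBack), " gene(s) without isoform-mapped ",
                "probesets; fell back to all probesets (e.g. '",
                fellBack[1L], "')")
    ga <- geneAnno(x)
    out <- data.frame(
        gene_id = genes,
        symbol = ga$symbol[match(genes, ga$gene_id)],
        gene_log2_fc = fc,
        gene_t_p = pv,
        n_probesets_used = nUsed,
        stringsAsFactors = FALSE)
    rownames(out) <- genes
    attr(out, "summary") <- summ
    out
}
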