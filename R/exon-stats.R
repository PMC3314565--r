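## Exon-level alternative-splicing statistics: transcript-cluster
## normalization, Splicing Index, row-wise Student t, MiDAS-style one-way
## ANOVA, DABG detection filtering, BH adjustment.

#' Summarize expression per transcript cluster
#'
#' Collapses the probesets of each transcript cluster to one expression
#' value per sample. The default, Tukey median polish (overall + column
#' effects), mirrors the RMA-style summarization used upstream and is
#' robust to isolated splicing events: probeset affinities are absorbed by
#' the row effects, so a single aberrant exon does not drag the cluster
#' summary with it. `"median"` (plain per-sample median) and `"mean"` are
#' transparent alternatives.
#'
#' @param x an `ExonArrayExperiment`, or a numeric matrix (then `clusters`
#'   is required).
#' @param method summarization method.
#' @param clusters character vector of cluster ids, one per row of the
#'   matrix (ignored when `x` is an `ExonArrayExperiment`).
#' @return numeric matrix, clusters x samples.
#' @export
clusterSummary <- function(x, method = c("medianpolish", "median", "mean"),
                           clusters = NULL) {
    method <- match.arg(method)
    if (is(x, "ExonArrayExperiment")) {
        clusters <- probesetAnno(x)$transcript_cluster_id
        x <- exonExprs(x)
    }
    stopifnot(is.matrix(x), length(clusters) == nrow(x))
    idx <- split(seq_len(nrow(x)), clusters)
    out <- matrix(NA_real_, length(idx), ncol(x),
                  dimnames = list(names(idx), colnames(x)))
    for (i in seq_along(idx)) {
        sub <- x[idx[[i]], , drop = FALSE]
        out[i, ] <- switch(method,
            median = apply(sub, 2L, median),
            mean = colMeans(sub),
            medianpolish = if (nrow(sub) == 1L) sub[1L, ] else {
                mp <- .medpolishQuiet(sub)
                mp$overall + mp$col
            })
    }
    out
}

#' Normalize probeset expression to the transcript-cluster level
#'
#' Computes `e = x - g` in log2 space, where `g` is the transcript-cluster
#' summary of the cluster containing each probeset (equivalently, the
#' ratio of linear intensities). The normalized values isolate
#' exon-specific signal from overall gene expression and feed the Splicing
#' Index, t and ANOVA statistics.
#'
#' @param x an `ExonArrayExperiment`.
#' @param summary optional precomputed cluster-summary matrix (clusters x
#'   samples); computed with [clusterSummary()] if `NULL`.
#' @param method passed to [clusterSummary()] when `summary` is `NULL`.
#' @return numeric matrix of normalized log2 ratios, probesets x samples.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(nGenes = 5, nPairs = 3))
#' e <- normalizeExons(sim$dataset)
#' @export
normalizeExons <- function(x, summary = NULL,
                           method = c("medianpolish", "median", "mean")) {
    cl <- probesetAnno(x)$transcript_cluster_id
    if (is.null(summary))
        summary <- clusterSummary(x, method = match.arg(method))
    m <- match(cl, rownames(summary))
    if (anyNA(m))
        stop("probeset '", rownames(x)[which(is.na(m))[1L]],
             "' belongs to cluster '", cl[which(is.na(m))[1L]],
             "' absent from the cluster summary")
    if (!identical(colnames(summary), colnames(x)))
        stop("cluster summary has different sample columns")
    exonExprs(x) - summary[m, , drop = FALSE]
}

.groupIdx <- function(groups) {
    g <- as.factor(groups)
    lv <- levels(droplevels(g))
    if (length(lv) < 2L) stop("need at least two non-empty groups")
    lapply(lv, function(l) which(g == l))
}

.twoGroupIdx <- function(groups) {
    g <- as.character(groups)
    i1 <- which(g == "normal"); i2 <- which(g == "pathological")
    if (!length(i1) || !length(i2))
        stop("both 'normal' and 'pathological' groups must be non-empty")
    list(normal = i1, pathological = i2)
}

#' Splicing Index
#'
#' Per-probeset difference of group means of cluster-normalized log2
#' expression: `SI = mean(e[, normal]) - mean(e[, pathological])`.
#' Positive values mean the normal normalized signal is higher (the exon
#' is relatively lost in disease).
#'
#' @param normalized matrix from [normalizeExons()].
#' @param groups condition labels (`normal`/`pathological`), one per
#'   column.
#' @return named numeric vector of SI values (log2 units).
#' @export
splicingIndex <- function(normalized, groups) {
    gi <- .twoGroupIdx(groups)
    rowMeans(normalized[, gi$normal, drop = FALSE]) -
        rowMeans(normalized[, gi$pathological, drop = FALSE])
}

#' Exon-level fold change
#'
#' Per-probeset signed log2 fold change on raw (not cluster-normalized)
#' intensities: `FC = mean(x[, normal]) - mean(x[, pathological])`. Unlike
#' the Splicing Index it responds to overall gene-level shifts. The
#' ratio-scale value is `2^FC`.
#'
#' @param expression log2 expression matrix (probesets x samples).
#' @param groups condition labels, one per column.
#' @return named numeric vector of log2 fold changes.
#' @export
exonFoldChange <- function(expression, groups) {
    gi <- .twoGroupIdx(groups)
    rowMeans(expression[, gi$normal, drop = FALSE]) -
        rowMeans(expression[, gi$pathological, drop = FALSE])
}

## Vectorized equal-variance two-sample Student t across rows.
## Zero pooled variance: p = 1 when the mean difference is 0, else p = 0.
.rowStudentT <- function(m, i1, i2) {
    n1 <- length(i1); n2 <- length(i2)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples for the t-test")
    m1 <- rowMeans(m[, i1, drop = FALSE])
    m2 <- rowMeans(m[, i2, drop = FALSE])
    ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    s2 <- (ss1 + ss2) / df
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    d <- m1 - m2
    t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
    p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), 0)
    p[se == 0 & d == 0] <- 1
    list(statistic = t, df = df, p = p)
}

.rowPairedT <- function(m, i1, i2, pairs) {
    p1 <- pairs[i1]; p2 <- pairs[i2]
    common <- intersect(p1, p2)
    if (length(common) < 2L)
        stop("paired t-test needs at least 2 complete pairs")
    d <- m[, i1[match(common, p1)], drop = FALSE] -
         m[, i2[match(common, p2)], drop = FALSE]
    n <- length(common)
    md <- rowMeans(d)
    sdv <- sqrt(rowSums((d - md)^2) / (n - 1L))
    se <- sdv / sqrt(n)
    t <- ifelse(se > 0, md / se, ifelse(md == 0, 0, sign(md) * Inf))
    p <- ifelse(is.finite(t), 2 * pt(-abs(t), n - 1L), 0)
    p[se == 0 & md == 0] <- 1
    list(statistic = t, df = n - 1L, p = p)
}

#' Row-wise Student t-test on normalized exon expression
#'
#' Unpaired mode is the classical equal-variance two-sample Student t on
#' the cluster-normalized values, two-sided. Paired mode is a one-sample t
#' on within-pair (normal minus pathological) differences. Degenerate rows
#' with zero variance and zero mean difference return p = 1 (no
#' evidence), never `NaN`.
#'
#' @param normalized matrix from [normalizeExons()] (any numeric matrix
#'   works; gene-level vectors are handled by [geneStats()]).
#' @param groups condition labels, one per column.
#' @param paired use the paired test.
#' @param pairs pairing key (e.g. patient id), required when
#'   `paired = TRUE`.
#' @return list with `statistic`, `df` and `p` (vectors over rows).
#' @export
exonTTest <- function(normalized, groups, paired = FALSE, pairs = NULL) {
    gi <- .twoGroupIdx(groups)
    if (paired) {
        if (is.null(pairs)) stop("paired = TRUE requires 'pairs'")
        .rowPairedT(normalized, gi$normal, gi$pathological, pairs)
    } else {
        .rowStudentT(normalized, gi$normal, gi$pathological)
    }
}

#' MiDAS-style ANOVA p-value
#'
#' One-way fixed-effects ANOVA of cluster-normalized expression across two
#' or more experimental groups, the in-package realization of the
#' microarray detection-of-alternative-splicing statistic. With exactly
#' two groups the F statistic equals the square of the unpaired Student t
#' and the p-values coincide. Zero between-group sum of squares returns
#' p = 1.
#'
#' @param normalized matrix from [normalizeExons()].
#' @param groups labels defining >= 2 groups, each with >= 2 samples.
#' @return named numeric vector of two-sided F-test p-values.
#' @export
midasPValue <- function(normalized, groups) {
    gi <- .groupIdx(groups)
    if (any(lengths(gi) < 2L))
        stop("each group needs at least 2 samples")
    k <- length(gi)
    n <- sum(lengths(gi))
    grand <- rowMeans(normalized[, unlist(gi), drop = FALSE])
    ssb <- 0; ssw <- 0
    for (ix in gi) {
        sub <- normalized[, ix, drop = FALSE]
        mg <- rowMeans(sub)
        ssb <- ssb + length(ix) * (mg - grand)^2
        ssw <- ssw + rowSums((sub - mg)^2)
    }
    f <- ifelse(ssw > 0, (ssb / (k - 1L)) / (ssw / (n - k)),
                ifelse(ssb == 0, 0, Inf))
    p <- ifelse(is.finite(f), pf(f, k - 1L, n - k, lower.tail = FALSE), 0)
    p[ssb == 0] <- 1
    setNames(p, rownames(normalized))
}

#' DABG detection fractions per group
#'
#' For each probeset, the fraction of samples in each condition whose
#' detection-above-background p-value is at or below `pThreshold`.
#'
#' @param dabg DABG p-value matrix (probesets x samples).
#' @param groups condition labels, one per column.
#' @param pThreshold detection call threshold (default 0.05).
#' @return matrix with columns `dabg_frac_normal`, `dabg_frac_path`.
#' @export
dabgDetection <- function(dabg, groups, pThreshold = 0.05) {
    gi <- .twoGroupIdx(groups)
    det <- dabg <= pThreshold
    cbind(dabg_frac_normal = rowMeans(det[, gi$normal, drop = FALSE]),
          dabg_frac_path = rowMeans(det[, gi$pathological, drop = FALSE]))
}

#' Flag probesets failing DABG detection
#'
#' Marks probesets whose detection fraction falls below `minFraction` in
#' one (`mode = "both"` requires both groups to pass) or both
#' (`mode = "either"` requires at least one group to pass) conditions.
#' Statistics of filtered probesets are kept, never deleted.
#'
#' @param records exon statistics `data.frame` with `dabg_frac_normal` and
#'   `dabg_frac_path` columns (see [exonStats()]).
#' @param minFraction minimum detection fraction (default 0.5).
#' @param mode `"either"` (retain if either group passes, default) or
#'   `"both"`.
#' @return `records` with a logical `filtered` column set; the number
#'   removed is attached as `attr(, "n_filtered")`.
#' @export
filterByDabg <- function(records, minFraction = 0.5,
                         mode = c("either", "both")) {
    mode <- match.arg(mode)
    if (!all(c("dabg_frac_normal", "dabg_frac_path") %in% colnames(records)))
        stop("records lack DABG detection fractions")
    passN <- records$dabg_frac_normal >= minFraction
    passP <- records$dabg_frac_path >= minFraction
    keep <- if (mode == "either") passN | passP else passN & passP
    records$filtered <- !keep
    attr(records, "n_filtered") <- sum(!keep)
    records
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values via [stats::p.adjust()];
#' `method = "none"` returns the input unchanged.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param method `"none"` or `"BH"`.
#' @return q-values, same length and names.
#' @export
adjustPValues <- function(pvalues, method = c("none", "BH")) {
    method <- match.arg(method)
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (method == "none") pvalues else p.adjust(pvalues, method = "BH")
}

#' Exon-level statistics table
#'
#' Runs the full exon-level analysis: transcript-cluster normalization,
#' Splicing Index, fold change on raw intensities, Student t, MiDAS-style
#' ANOVA, DABG detection fractions and filtering (when a DABG assay is
#' present) and optional BH adjustment. Probesets are flagged when they
#' pass all three significance thresholds and survive the DABG filter.
#'
#' @param x an `ExonArrayExperiment`.
#' @param paired paired t-test on patient pairs (requires `patient_id` in
#'   `colData`).
#' @param summaryMethod cluster summarization for normalization
#'   (see [clusterSummary()]).
#' @param adjust multiplicity adjustment, `"none"` (default) or `"BH"`.
#' @param dabgThreshold DABG detection-call threshold.
#' @param dabgMinFraction,dabgMode see [filterByDabg()].
#' @param siThreshold,pThreshold flagging thresholds: `flagged` requires
#'   `midas_p < pThreshold`, `t_p < pThreshold` and
#'   `|SI| >= siThreshold`.
#' @return `data.frame`, one row per probeset, with columns
#'   `probeset_id`, `transcript_cluster_id`, `gene_id`, `splicing_index`,
#'   `log2_fold_change`, `t_p`, `midas_p`, DABG fractions / `filtered`
#'   (when available), `t_q`/`midas_q` (when adjusted) and `flagged`.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(
#'     nGenes = 10, nPairs = 6, asFraction = 0.3, seed = 2))
#' es <- exonStats(sim$dataset)
#' head(es)
#' @export
exonStats <- function(x, paired = FALSE,
                      summaryMethod = c("medianpolish", "median", "mean"),
                      adjust = c("none", "BH"),
                      dabgThreshold = 0.05, dabgMinFraction = 0.5,
                      dabgMode = c("either", "both"),
                      siThreshold = 0.5, pThreshold = 0.05) {
    adjust <- match.arg(adjust)
    groups <- condition(x)
    e <- normalizeExons(x, method = match.arg(summaryMethod))
    anno <- probesetAnno(x)
    tt <- exonTTest(e, groups, paired = paired,
                    pairs = if (paired) colData(x)$patient_id)
    rec <- data.frame(
        probeset_id = anno$probeset_id,
        transcript_cluster_id = anno$transcript_cluster_id,
        gene_id = anno$gene_id,
        splicing_index = splicingIndex(e, groups),
        log2_fold_change = exonFoldChange(exonExprs(x), groups),
        t_p = tt$p,
        midas_p = unname(midasPValue(e, groups)),
        stringsAsFactors = FALSE)
    rownames(rec) <- rec$probeset_id
    if (!is.null(dabg(x))) {
        det <- dabgDetection(dabg(x), groups, pThreshold = dabgThreshold)
        rec$dabg_frac_normal <- det[, "dabg_frac_normal"]
        rec$dabg_frac_path <- det[, "dabg_frac_path"]
        rec <- filterByDabg(rec, minFraction = dabgMinFraction,
                            mode = match.arg(dabgMode))
    } else {
        rec$filtered <- FALSE
    }
    if (adjust == "BH") {
        rec$t_q <- adjustPValues(rec$t_p, "BH")
        rec$midas_q <- adjustPValues(rec$midas_p, "BH")
    }
    rec$flagged <- !rec$filtered &
        rec$midas_p < pThreshold & rec$t_p < pThreshold &
        abs(rec$splicing_index) >= siThreshold
    rec
}
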