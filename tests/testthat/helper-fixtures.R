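## Shared fixture builders. Everything is generated in code; file-based
## fixtures are written to tempdir() on demand.

## A tiny hand-written dataset: 2 genes x 2 probesets, 4 samples.
tinyTables <- function() {
    exprs <- matrix(c(8.0, 7.5, 8.2, 7.9,
                      6.0, 6.1, 5.9, 6.2,
                      9.0, 9.1, 8.8, 9.2,
                      4.0, 4.2, 4.1, 3.9),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(paste0("ps", 1:4), paste0("s", 1:4)))
    dabg <- matrix(0.01, 4, 4, dimnames = dimnames(exprs))
    samples <- data.frame(
        sample_id = paste0("s", 1:4),
        condition = c("normal", "normal", "pathological", "pathological"),
        patient_id = c("p1", "p2", "p1", "p2"),
        gender = c("M", "F", "M", "F"),
        age = c(55, 65, 55, 65),
        stringsAsFactors = FALSE)
    annotation <- data.frame(
        probeset_id = paste0("ps", 1:4),
        transcript_cluster_id = c("tcA", "tcA", "tcB", "tcB"),
        gene_id = c("gA", "gA", "gB", "gB"),
        chrom = c("chr1", "chr1", "chr2", "chr2"),
        start = c(100L, 600L, 100L, 600L),
        stop = c(250L, 750L, 250L, 750L),
        strand = c("+", "+", "-", "-"),
        exon_index = c(1L, 2L, 1L, 2L),
        isoform_ids = c("gA:I1;gA:I2", "gA:I1", "gB:I1", "gB:I1"),
        stringsAsFactors = FALSE)
    geneSets <- data.frame(
        set_id = c("PW1", "PW1", "GO1"),
        gene_id = c("gA", "gB", "gA"),
        kind = c("pathway", "pathway", "go"),
        stringsAsFactors = FALSE)
    list(exprs = exprs, dabg = dabg, samples = samples,
         annotation = annotation, geneSets = geneSets)
}

tinyDataset <- function() {
    tb <- tinyTables()
    ExonArrayExperiment(tb$exprs, tb$samples, tb$annotation,
                        dabg = tb$dabg, geneSets = tb$geneSets)
}

## Write the tiny tables as files; individual pieces can be overridden
## with pre-mangled data.frames/matrices to exercise validation.
writeTinyFiles <- function(dir = tempfile("fixture"), exprs = NULL,
                           dabg = NULL, samples = NULL, annotation = NULL,
                           withDabg = TRUE) {
    tb <- tinyTables()
    if (!is.null(exprs)) tb$exprs <- exprs
    if (!is.null(dabg)) tb$dabg <- dabg
    if (!is.null(samples)) tb$samples <- samples
    if (!is.null(annotation)) tb$annotation <- annotation
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(expression = file.path(dir, "expression.tsv"),
              dabg = if (withDabg) file.path(dir, "dabg.tsv"),
              samples = file.path(dir, "samples.csv"),
              annotation = file.path(dir, "annotation.tsv"),
              geneSets = file.path(dir, "gene_sets.tsv"))
    writeMat <- function(m, path) {
        df <- data.frame(probeset_id = rownames(m), m, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeMat(tb$exprs, p$expression)
    if (withDabg) writeMat(tb$dabg, p$dabg)
    write.csv(tb$samples, p$samples, row.names = FALSE, quote = FALSE)
    write.table(tb$annotation, p$annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(tb$geneSets, p$geneSets, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
}

## Dataset with hand-set expression values on a fixed layout:
## `genes` gives probesets per gene; values supplied as a matrix.
datasetFromMatrix <- function(exprs, clustersPerRow, conditions,
                              isoforms = NULL, dabg = NULL) {
    n <- nrow(exprs)
    anno <- data.frame(
        probeset_id = rownames(exprs),
        transcript_cluster_id = clustersPerRow,
        gene_id = sub("^tc", "g", clustersPerRow),
        chrom = "chr1",
        start = seq_len(n) * 1000L,
        stop = seq_len(n) * 1000L + 100L,
        strand = "+",
        exon_index = as.integer(stats::ave(seq_len(n), clustersPerRow,
                                           FUN = seq_along)),
        isoform_ids = if (is.null(isoforms))
            paste0(sub("^tc", "g", clustersPerRow), ":I1") else isoforms,
        stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = colnames(exprs),
                          condition = conditions,
                          stringsAsFactors = FALSE)
    ExonArrayExperiment(exprs, samples, anno, dabg = dabg)
}

randomMatrix <- function(nr, nc, seed = 1) {
    set.seed(seed)
    matrix(rnorm(nr * nc, 7, 1), nr, nc,
           dimnames = list(sprintf("ps%03d", seq_len(nr)),
                           sprintf("s%02d", seq_len(nc))))
}
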