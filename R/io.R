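#' Read an exon-array dataset from TSV/CSV files
#'
#' Loads a probeset-level log2 expression matrix, sample metadata, probeset
#' annotation and (optionally) a DABG p-value matrix and a gene-set
#' membership table, cross-validates them and returns an
#' [ExonArrayExperiment][ExonArrayExperiment-class].
#'
#' File formats (all UTF-8):
#' * expression / DABG: tab-delimited, first column `probeset_id`,
#'   remaining columns sample ids;
#' * metadata: CSV with header `sample_id,condition,...`; `condition` must
#'   be `normal` or `pathological`; empty strings in optional covariates
#'   load as missing (`NA`), never as zero. Extra covariate columns are
#'   typed numeric when every non-missing value parses as a number, else
#'   categorical;
#' * annotation: tab-delimited with header `probeset_id,
#'   transcript_cluster_id, gene_id, chrom, start, stop, strand,
#'   exon_index, isoform_ids` (isoforms semicolon-separated; coordinates
#'   1-based inclusive);
#' * gene sets: tab-delimited `set_id, gene_id, kind` with kind in
#'   `{pathway, go}`.
#'
#' Validation is total: duplicate ids, non-finite expression values, DABG
#' values outside \[0, 1\], probesets missing from the annotation or
#' samples missing from the metadata all raise an error naming the
#' offending id.
#'
#' @param expressionPath path to the expression TSV.
#' @param metadataPath path to the sample metadata CSV.
#' @param annotationPath path to the probeset annotation TSV.
#' @param dabgPath optional path to a DABG p-value TSV (same shape as the
#'   expression file).
#' @param geneSetsPath optional path to the gene-set membership TSV.
#' @param genesPath optional path to a gene annotation TSV
#'   (`gene_id<TAB>symbol<TAB>aliases`).
#' @return an `ExonArrayExperiment`.
#' @seealso [writeSimulatedDataset()] writes the complementary fixture
#'   files; [writeStatsTable()] writes result tables.
#' @export
readExonDataset <- function(expressionPath, metadataPath, annotationPath,
                            dabgPath = NULL, geneSetsPath = NULL,
                            genesPath = NULL) {
    for (p in c(expressionPath, metadataPath, annotationPath, dabgPath,
                geneSetsPath, genesPath))
        if (!is.null(p) && !file.exists(p))
            stop("input file not found: ", p)

    exprs <- .readMatrixTSV(expressionPath, what = "expression")
    if (any(!is.finite(exprs))) {
        bad <- which(!is.finite(exprs), arr.ind = TRUE)[1L, ]
        stop("non-finite expression value for probeset '",
             rownames(exprs)[bad[1L]], "', sample '",
             colnames(exprs)[bad[2L]], "'")
    }
    samples <- .readMetadataCSV(metadataPath)
    anno <- read.delim(annotationPath, colClasses = "character",
                       check.names = FALSE)
    anno$start <- .parseIntCol(anno$start, "start", anno$probeset_id)
    anno$stop <- .parseIntCol(anno$stop, "stop", anno$probeset_id)
    anno$exon_index <- .parseIntCol(anno$exon_index, "exon_index",
                                    anno$probeset_id)

    dabgM <- NULL
    if (!is.null(dabgPath)) {
        dabgM <- .readMatrixTSV(dabgPath, what = "DABG")
        if (!identical(dimnames(dabgM), dimnames(exprs)))
            stop("DABG matrix row/column ids differ from the expression matrix")
        if (any(dabgM < 0 | dabgM > 1, na.rm = TRUE) || anyNA(dabgM)) {
            bad <- which(is.na(dabgM) | dabgM < 0 | dabgM > 1,
                         arr.ind = TRUE)[1L, ]
            stop("DABG value outside [0, 1] for probeset '",
                 rownames(dabgM)[bad[1L]], "', sample '",
                 colnames(dabgM)[bad[2L]], "'")
        }
    }
    gs <- if (!is.null(geneSetsPath))
        read.delim(geneSetsPath, colClasses = "character",
                   check.names = FALSE)
    genes <- if (!is.null(genesPath))
        read.delim(genesPath, colClasses = "character", check.names = FALSE)

    ExonArrayExperiment(exprs, samples, anno, dabg = dabgM,
                        genes = genes, geneSets = gs)
}

.readMatrixTSV <- function(path, what = "expression") {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (colnames(df)[1L] != "probeset_id")
        stop(what, " file ", path, ": first column must be 'probeset_id'")
    ids <- df[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(what, " file: duplicate probeset id '", dup[1L], "'")
    sid <- colnames(df)[-1L]
    dup <- sid[duplicated(sid)]
    if (length(dup))
        stop(what, " file: duplicate sample id '", dup[1L], "'")
    m <- suppressWarnings(
        vapply(df[-1L], as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, sid))
    rownames(m) <- ids
    m
}

.readMetadataCSV <- function(path) {
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (!("sample_id" %in% colnames(df)))
        stop("metadata: 'sample_id' column required")
    if (!("condition" %in% colnames(df)))
        stop("metadata: 'condition' column required")
    df[df == ""] <- NA
    known <- c("sample_id", "condition", "patient_id", "gender", "stage")
    for (cn in setdiff(colnames(df), known)) {
        v <- df[[cn]]
        parsed <- suppressWarnings(as.numeric(v))
        if (all(is.na(parsed) == is.na(v)))   # every non-missing value numeric
            df[[cn]] <- parsed
    }
    if ("age" %in% colnames(df) && is.numeric(df$age) &&
        any(df$age < 0, na.rm = TRUE))
        stop("metadata: negative age for sample '",
             df$sample_id[which(df$age < 0)[1L]], "'")
    df
}

.parseIntCol <- function(x, col, ids) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v))
        stop("annotation: non-integer '", col, "' for probeset '",
             ids[which(is.na(v))[1L]], "'")
    v
}

#' Write a statistics table as TSV
#'
#' Writes any of the package's result tables (exon, gene or meta
#' statistics, rankings) with a single header row, the id column first and
#' numeric columns rendered with 8 significant digits, so a read-back
#' reproduces values to rendering precision.
#'
#' @param records a `data.frame`; may have zero rows (header-only output).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStatsTable <- function(records, path) {
    stopifnot(is.data.frame(records))
    out <- records
    for (cn in colnames(out)) {
        if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
            out[[cn]] <- sprintf("%.8g", out[[cn]])
        else out[[cn]] <- as.character(out[[cn]])
    }
    ok <- tryCatch({
        suppressWarnings(
            write.table(out, path, sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = TRUE))
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write table to '", path, "': ", conditionMessage(ok))
    invisible(path)
}

#' Read back a statistics table written by writeStatsTable
#'
#' @param path path to a TSV written by [writeStatsTable()].
#' @return a `data.frame` with numeric columns re-parsed.
#' @export
readStatsTable <- function(path) {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    for (cn in colnames(df)) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        if (!anyNA(v) || all(is.na(v) == is.na(df[[cn]])))
            if (!all(is.na(v))) df[[cn]] <- v
        if (all(df[[cn]] %in% c("TRUE", "FALSE")))
            df[[cn]] <- as.logical(df[[cn]])
    }
    df
}
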