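## Per-gene meta statistics over exon-level results and scaled
## Euclidean-distance ranking.

.metaBases <- c("t_p", "midas_p", "splicing_index", "log2_fold_change")
.metaMoments <- c("min", "max", "mean", "var")

.metaComponents <- function()
    as.vector(outer(.metaBases, .metaMoments, paste, sep = "_"))

#' Per-gene meta statistics
#'
#' Summarizes the exon-level statistics of each gene's probesets into a
#' 16-component vector: minimum, maximum, mean and sample variance (n - 1
#' denominator, defined as 0 for a single probeset) of each of the four
#' base statistics (t p-value, MiDAS p-value, Splicing Index, log2 fold
#' change). A gene subject to an isolated AS event shows a minimum p-value
#' near 0 while the remaining probesets keep it high on average — the
#' signature the distance-based search exploits.
#'
#' @param exonStats exon-level table from [exonStats()].
#' @param useFiltered include DABG-filtered probesets (default `FALSE`).
#' @return `data.frame` with `gene_id`, `n_probesets` and the 16
#'   components named `<base>_<moment>`; genes with no eligible probeset
#'   are omitted with a warning.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(nGenes = 8, nPairs = 5))
#' meta <- computeMeta(exonStats(sim$dataset))
#' colnames(meta)
#' @export
computeMeta <- function(exonStats, useFiltered = FALSE) {
    stats <- exonStats
    if (!useFiltered && "filtered" %in% colnames(stats)) {
        dropped <- setdiff(unique(stats$gene_id),
                           unique(stats$gene_id[!stats$filtered]))
        if (length(dropped))
            warning(length(dropped), " gene(s) with no unfiltered ",
                    "probesets omitted (e.g. '", dropped[1L], "')")
        stats <- stats[!stats$filtered, , drop = FALSE]
    }
    idx <- split(seq_len(nrow(stats)), stats$gene_id)
    comp <- .metaComponents()
    out <- matrix(NA_real_, length(idx), length(comp),
                  dimnames = list(names(idx), comp))
    for (i in seq_along(idx)) {
        for (b in .metaBases) {
            v <- stats[[b]][idx[[i]]]
            out[i, paste0(b, "_min")] <- min(v)
            out[i, paste0(b, "_max")] <- max(v)
            out[i, paste0(b, "_mean")] <- mean(v)
            out[i, paste0(b, "_var")] <- if (length(v) > 1L) var(v) else 0
        }
    }
    df <- data.frame(gene_id = names(idx), n_probesets = lengths(idx),
                     out, stringsAsFactors = FALSE)
    rownames(df) <- df$gene_id
    df
}

#' Scale meta statistics for distance computation
#'
#' Standardizes each of the 16 meta-statistic components across genes
#' (z-score: mean 0, standard deviation 1; `"minmax"` maps to \[0, 1\])
#' so Euclidean distances weight the components comparably. Zero-variance
#' components scale to all zeros and contribute nothing to distances. The
#' returned object carries the scaling parameters so query points can be
#' mapped into the same space.
#'
#' @param meta table from [computeMeta()] (>= 2 genes).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return object of class `scaled_meta`: list with `scaled` (genes x 16
#'   matrix), `center`, `scale`, `method`, `components`.
#' @export
scaleMeta <- function(meta, method = c("zscore", "minmax")) {
    method <- match.arg(method)
    comp <- .metaComponents()
    stopifnot(all(comp %in% colnames(meta)), nrow(meta) >= 2L)
    m <- as.matrix(meta[, comp, drop = FALSE])
    rownames(m) <- meta$gene_id
    if (method == "zscore") {
        ctr <- colMeans(m)
        scl <- apply(m, 2L, sd)
    } else {
        ctr <- apply(m, 2L, min)
        scl <- apply(m, 2L, max) - ctr
    }
    degenerate <- scl == 0
    scl[degenerate] <- 1
    scaled <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
    scaled[, degenerate] <- 0
    structure(list(scaled = scaled, center = ctr, scale = scl,
                   degenerate = degenerate, method = method,
                   components = comp),
              class = "scaled_meta")
}

#' Undo meta-statistic scaling
#'
#' @param scaled a `scaled_meta` object from [scaleMeta()].
#' @return the original genes x 16 matrix (degenerate components restored
#'   to their constant value).
#' @export
unscaleMeta <- function(scaled) {
    m <- sweep(sweep(scaled$scaled, 2L, scaled$scale, "*"), 2L,
               scaled$center, "+")
    m
}

## Map a query (named vector, original units) into the scaled space.
.scaleQuery <- function(scaled, query) {
    comp <- names(query)
    bad <- setdiff(comp, scaled$components)
    if (length(bad))
        stop("unknown meta-statistic component '", bad[1L], "'")
    q <- (query - scaled$center[comp]) / scaled$scale[comp]
    q[scaled$degenerate[comp]] <- 0
    q
}

#' Rank genes by scaled Euclidean distance to a query point
#'
#' The query is a named numeric vector over a subset of the 16
#' meta-statistic components (the active components, mirroring search-page
#' checkboxes); values are given in original units and mapped into the
#' scaled space. Distance is the Euclidean distance over the active
#' components only; genes are returned in ascending distance, ties broken
#' by gene id.
#'
#' @param scaled a `scaled_meta` object.
#' @param query named numeric vector with >= 1 active component, e.g.
#'   `c(t_p_min = 0, midas_p_min = 0)`.
#' @return `data.frame` with `gene_id` and `distance`, sorted.
#' @seealso [defaultASQuery()] for a ready-made AS-event query.
#' @export
rankByDistance <- function(scaled, query) {
    if (length(query) == 0L || is.null(names(query)))
        stop("query must have at least one active (named) component")
    q <- .scaleQuery(scaled, query)
    sub <- scaled$scaled[, names(q), drop = FALSE]
    d <- sqrt(rowSums(sweep(sub, 2L, q)^2))
    ord <- order(d, rownames(sub))
    data.frame(gene_id = rownames(sub)[ord], distance = unname(d[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank the members of a pathway or GO set around a focal gene
#'
#' Ranks the other members of a gene set by Euclidean distance (all 16
#' scaled components active) to the focal gene's meta-statistic vector, so
#' genes that statistically behave like the gene under examination come
#' first.
#'
#' @param focalGene gene id; must belong to the set and the scaled table.
#' @param setId pathway or GO set id.
#' @param scaled a `scaled_meta` object.
#' @param geneSets membership table (`set_id`, `gene_id`, `kind`).
#' @return `data.frame` with `gene_id` and `distance`, excluding the focal
#'   gene, sorted ascending (ties by gene id).
#' @export
rankWithinSet <- function(focalGene, setId, scaled, geneSets) {
    members <- geneSets$gene_id[geneSets$set_id == setId]
    if (!length(members))
        stop("unknown gene set '", setId, "'")
    if (!(focalGene %in% members))
        stop("gene '", focalGene, "' is not a member of set '", setId, "'")
    if (!(focalGene %in% rownames(scaled$scaled)))
        stop("gene '", focalGene, "' absent from the meta-statistics table")
    others <- intersect(setdiff(members, focalGene),
                        rownames(scaled$scaled))
    if (!length(others))
        return(data.frame(gene_id = character(), distance = numeric()))
    ref <- scaled$scaled[focalGene, ]
    sub <- scaled$scaled[others, , drop = FALSE]
    d <- sqrt(rowSums(sweep(sub, 2L, ref)^2))
    ord <- order(d, others)
    data.frame(gene_id = others[ord], distance = unname(d[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Default query for isolated AS events
#'
#' A reconstruction of a search preset for alternative-splicing discovery:
#' minimum t and MiDAS p-values at 0 (some probeset strongly significant)
#' and the mean t p-value at 1 (the rest of the gene undisturbed). This
#' preset is the package's own choice of defaults for the search surface.
#'
#' @return named numeric query vector for [rankByDistance()].
#' @export
defaultASQuery <- function() {
    c(t_p_min = 0, midas_p_min = 0, t_p_mean = 1)
}

#' Search genes by annotation with optional meta-statistic ranking
#'
#' Applies a conjunction of annotation filters (symbol/alias substring,
#' gene id, chromosome, genomic interval overlap, pathway or GO
#' membership) to the dataset's genes; survivors are ordered by
#' [rankByDistance()] when a query is given, else by gene id.
#'
#' @param x an `ExonArrayExperiment`.
#' @param symbol substring matched against symbol and aliases.
#' @param geneId exact gene id.
#' @param chrom chromosome name.
#' @param start,stop optional interval (requires `chrom`); genes
#'   overlapping \[start, stop\] are retained; `start <= stop` required.
#' @param pathway,go set ids the gene must belong to.
#' @param scaled a `scaled_meta` object, required when `query` is given.
#' @param query optional named query vector (see [rankByDistance()]).
#' @param top return at most this many rows.
#' @return `data.frame` of gene annotation rows, plus `distance` when
#'   ranked.
#' @export
searchGenes <- function(x, symbol = NULL, geneId = NULL, chrom = NULL,
                        start = NULL, stop = NULL, pathway = NULL,
                        go = NULL, scaled = NULL, query = NULL,
                        top = Inf) {
    genes <- geneAnno(x)
    keep <- rep(TRUE, nrow(genes))
    if (!is.null(symbol))
        keep <- keep & (grepl(symbol, genes$symbol, fixed = TRUE) |
                        grepl(symbol, genes$aliases, fixed = TRUE))
    if (!is.null(geneId)) keep <- keep & genes$gene_id %in% geneId
    if (!is.null(chrom)) keep <- keep & genes$chrom == chrom
    if (!is.null(start) || !is.null(stop)) {
        if (is.null(start) || is.null(stop))
            stop("start and stop must be given together")
        if (start > stop) stop("malformed interval: start > stop")
        keep <- keep & genes$start <= stop & genes$stop >= start
    }
    gs <- geneSets(x)
    if (!is.null(pathway))
        keep <- keep & genes$gene_id %in%
            gs$gene_id[gs$set_id == pathway & gs$kind == "pathway"]
    if (!is.null(go))
        keep <- keep & genes$gene_id %in%
            gs$gene_id[gs$set_id == go & gs$kind == "go"]
    out <- genes[keep, , drop = FALSE]
    if (!is.null(query)) {
        if (is.null(scaled))
            stop("a scaled_meta object is required to rank by query")
        rk <- rankByDistance(scaled, query)
        rk <- rk[rk$gene_id %in% out$gene_id, , drop = FALSE]
        out <- out[match(rk$gene_id, out$gene_id), , drop = FALSE]
        out$distance <- rk$distance
    } else {
        out <- out[order(out$gene_id), , drop = FALSE]
    }
    rownames(out) <- NULL
    utils::head(out, top)
}
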