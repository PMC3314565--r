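#' Configuration for the exon-array simulator
#'
#' Collects and validates the parameters of the generative model used by
#' [simulateExonDataset()]. The model for probeset `ps` of gene `g` in
#' sample `s` is
#' \deqn{x_{ps,s} = \mu_g + a_{ps} + c_g 1(s\ path) + \delta_{ps}
#'   1(s\ path) + \sum covariate\ effects + \varepsilon,\qquad
#'   \varepsilon \sim N(0, \sigma^2)}
#' with gene baselines \eqn{\mu_g \sim N(baselineMean, baselineSd^2)} and
#' probeset affinities \eqn{a_{ps} \sim N(0,1)} shared across samples
#' (emulating probe-affinity structure without re-running RMA).
#'
#' Planted events, applied to pathological samples only:
#' * cassette mode: one probeset of each AS gene gets \eqn{-\delta}
#'   (the exon is skipped in disease, so the normal signal is higher);
#' * mutually-exclusive mode: one probeset gets \eqn{+\delta} and the
#'   probeset of the adjacent exon gets \eqn{-\delta}, the isoform
#'   annotation placing the two exons in disjoint isoforms.
#'
#' Numeric covariate effects apply only to samples whose covariate value
#' exceeds the configured threshold; categorical effects to samples at the
#' configured level. Gender and age (Uniform(40, 80), so a threshold of 60
#' is interior) are always generated per patient, independent of
#' condition; effects are added only for covariates listed in
#' `covariates`.
#'
#' @param nGenes number of genes.
#' @param probesetsPerGene integer range `c(min, max)`; each gene draws its
#'   probeset count (one probeset per exon) uniformly from this range.
#' @param nPairs number of patients; each contributes one normal and one
#'   pathological sample (mirroring paired tumor/normal designs such as a
#'   14-pair colorectal-cancer study).
#' @param geneDeFraction,geneDeEffect fraction of genes with a gene-level
#'   shift and its size (log2 units); direction random per gene, recorded
#'   in the truth table with `+1` meaning normal higher.
#' @param asFraction,asEffect,asMode fraction of genes with a planted AS
#'   event, the effect size delta (log2 units) and the event type
#'   (`"cassette"` or `"mutually_exclusive"`).
#' @param covariates list of covariate effect specs; each element a list
#'   with `name` (`"gender"`, `"age"` or a new covariate name), `kind`
#'   (`"numeric"`/`"categorical"`), `effect` (log2 units), `nProbesets`
#'   (how many probesets are affected), and `threshold` (numeric kind) or
#'   `level` (categorical kind, default `"M"`).
#' @param noiseSd residual standard deviation sigma (log2 units), > 0.
#' @param baselineMean,baselineSd gene baseline distribution (log2 units).
#' @param backgroundFraction fraction of probesets that are unexpressed:
#'   they fall to a low constant intensity and their DABG p-values are
#'   Uniform(0, 1) instead of Uniform(0, 0.01).
#' @param paired if `FALSE`, samples are unrelated (no `patient_id`).
#' @param nPathways,pathwaySize,nGoTerms,goSize optional synthetic
#'   pathway/GO membership sets for ranking and search.
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return a validated `simulation_config` list.
#' @seealso [simulateExonDataset()]
#' @export
simulationConfig <- function(nGenes = 100,
                             probesetsPerGene = c(6L, 10L),
                             nPairs = 14L,
                             geneDeFraction = 0,
                             geneDeEffect = 1,
                             asFraction = 0,
                             asEffect = 1,
                             asMode = c("cassette", "mutually_exclusive"),
                             covariates = list(),
                             noiseSd = 0.25,
                             baselineMean = 7,
                             baselineSd = 1,
                             backgroundFraction = 0,
                             paired = TRUE,
                             nPathways = 0L,
                             pathwaySize = 5L,
                             nGoTerms = 0L,
                             goSize = 5L,
                             seed = 1L) {
    asMode <- match.arg(asMode)
    cfg <- list(nGenes = as.integer(nGenes),
                probesetsPerGene = as.integer(rep(probesetsPerGene,
                                                  length.out = 2L)),
                nPairs = as.integer(nPairs),
                geneDeFraction = geneDeFraction,
                geneDeEffect = geneDeEffect,
                asFraction = asFraction, asEffect = asEffect,
                asMode = asMode, covariates = covariates,
                noiseSd = noiseSd, baselineMean = baselineMean,
                baselineSd = baselineSd,
                backgroundFraction = backgroundFraction,
                paired = isTRUE(paired),
                nPathways = as.integer(nPathways),
                pathwaySize = as.integer(pathwaySize),
                nGoTerms = as.integer(nGoTerms),
                goSize = as.integer(goSize),
                seed = as.integer(seed))
    frac <- c(cfg$geneDeFraction, cfg$asFraction, cfg$backgroundFraction)
    if (any(frac < 0 | frac > 1))
        stop("fractions must lie in [0, 1]")
    if (cfg$nPairs < 2L) stop("nPairs must be >= 2")
    if (cfg$noiseSd <= 0) stop("noiseSd must be > 0")
    if (cfg$probesetsPerGene[1L] < 1L ||
        cfg$probesetsPerGene[2L] < cfg$probesetsPerGene[1L])
        stop("probesetsPerGene must be an increasing range with min >= 1")
    if (cfg$asFraction > 0 && cfg$asMode == "mutually_exclusive" &&
        cfg$probesetsPerGene[2L] < 2L)
        stop("mutually_exclusive mode requires probesetsPerGene max >= 2")
    for (cv in cfg$covariates) {
        if (is.null(cv$name) || is.null(cv$effect) || is.null(cv$nProbesets))
            stop("each covariate spec needs name, effect and nProbesets")
    }
    class(cfg) <- "simulation_config"
    cfg
}

#' Simulate an exon-array dataset with known ground truth
#'
#' Draws a paired normal/pathological probeset-level dataset from the
#' generative model described in [simulationConfig()], together with a
#' truth table marking planted AS probesets (with expected Splicing Index
#' sign), differentially expressed genes and covariate-affected probesets.
#'
#' @param config a [simulationConfig()].
#' @return a list with elements `dataset` (an
#'   [ExonArrayExperiment][ExonArrayExperiment-class] including a DABG
#'   assay), `truth` (list of data.frames `probesets`, `genes`,
#'   `covariates`) and `config`.
#' @examples
#' sim <- simulateExonDataset(simulationConfig(
#'     nGenes = 20, nPairs = 5, asFraction = 0.2, seed = 7))
#' sum(sim$truth$probesets$is_as)
#' @export
simulateExonDataset <- function(config) {
    stopifnot(inherits(config, "simulation_config"))
    set.seed(config$seed)
    nG <- config$nGenes

    K <- if (config$probesetsPerGene[1L] == config$probesetsPerGene[2L])
        rep(config$probesetsPerGene[1L], nG)
    else sample(seq(config$probesetsPerGene[1L], config$probesetsPerGene[2L]),
                nG, replace = TRUE)
    nPs <- sum(K)
    geneIds <- sprintf("g%04d", seq_len(nG))
    geneOf <- rep(seq_len(nG), K)
    psIds <- sprintf("ps%05d", seq_len(nPs))
    exonIdx <- unlist(lapply(K, seq_len), use.names = FALSE)

    ## genomic layout: genes tiled along chr1..chr22; exon width 150,
    ## intron 350; minus-strand genes store exon 1 at the highest coordinate
    chrom <- paste0("chr", 1L + (seq_len(nG) - 1L) %% 22L)
    strandG <- sample(c("+", "-"), nG, replace = TRUE)
    offset <- integer(nG)
    byChr <- split(seq_len(nG), chrom)
    for (ix in byChr)
        offset[ix] <- cumsum(c(1L, head(K[ix], -1L) * 500L + 10000L))
    startPs <- integer(nPs); stopPs <- integer(nPs)
    for (g in seq_len(nG)) {
        ord <- if (strandG[g] == "+") seq_len(K[g]) else rev(seq_len(K[g]))
        st <- offset[g] + (ord - 1L) * 500L
        i <- which(geneOf == g)
        startPs[i] <- st
        stopPs[i] <- st + 149L
    }

    ## samples
    nPairs <- config$nPairs
    if (config$paired) {
        pat <- sprintf("p%03d", seq_len(nPairs))
        sampleId <- as.vector(rbind(paste0(pat, "_normal"),
                                    paste0(pat, "_path")))
        cond <- rep(c("normal", "pathological"), nPairs)
        patientId <- rep(pat, each = 2L)
        gender <- rep(sample(c("M", "F"), nPairs, replace = TRUE), each = 2L)
        age <- rep(round(runif(nPairs, 40, 80), 1L), each = 2L)
    } else {
        nS <- 2L * nPairs
        sampleId <- sprintf("s%03d", seq_len(nS))
        cond <- rep(c("normal", "pathological"), each = nPairs)
        patientId <- NA_character_
        gender <- sample(c("M", "F"), nS, replace = TRUE)
        age <- round(runif(nS, 40, 80), 1L)
    }
    nS <- length(sampleId)
    isPath <- cond == "pathological"

    ## planted gene-level DE
    nDe <- round(config$geneDeFraction * nG)
    deGenes <- if (nDe > 0) sort(sample(seq_len(nG), nDe)) else integer()
    deDir <- integer(nG)
    deDir[deGenes] <- sample(c(-1L, 1L), nDe, replace = TRUE)

    ## planted AS events
    nAs <- round(config$asFraction * nG)
    needK <- if (config$asMode == "mutually_exclusive") 2L else 1L
    elig <- which(K >= needK)
    if (nAs > length(elig))
        stop("not enough genes with sufficient probesets for AS events")
    asGenes <- if (nAs > 0) sort(sample(elig, nAs)) else integer()
    asShift <- numeric(nPs)          # added to pathological samples
    asDir <- integer(nPs)            # expected SI sign (+1: normal higher)
    for (g in asGenes) {
        i <- which(geneOf == g)
        if (config$asMode == "cassette") {
            pick <- i[sample.int(length(i), 1L)]
            asShift[pick] <- -config$asEffect
            asDir[pick] <- 1L
        } else {
            j <- sample.int(length(i) - 1L, 1L)
            up <- i[j]; dn <- i[j + 1L]
            asShift[up] <- config$asEffect;  asDir[up] <- -1L
            asShift[dn] <- -config$asEffect; asDir[dn] <- 1L
        }
    }

    ## isoforms: two per gene; cassette/MEE probesets restricted so that
    ## the event's exons never co-occur in one isoform
    iso <- vector("list", nPs)
    for (g in seq_len(nG)) {
        i <- which(geneOf == g)
        i1 <- paste0(geneIds[g], ":I1"); i2 <- paste0(geneIds[g], ":I2")
        for (p in i) {
            iso[[p]] <- if (asDir[p] == 0L) c(i1, i2)
                        else if (asShift[p] > 0) i1 else i2
        }
    }

    ## background (unexpressed) probesets
    nBg <- round(config$backgroundFraction * nPs)
    bgPs <- if (nBg > 0) sort(sample(seq_len(nPs), nBg)) else integer()
    isBg <- seq_len(nPs) %in% bgPs

    ## covariate effects
    covRows <- list()
    covShift <- matrix(0, nPs, nS)
    covVals <- list(gender = gender, age = age)
    for (cv in config$covariates) {
        nm <- cv$name
        kind <- if (!is.null(cv$kind)) cv$kind
                else if (nm %in% c("age")) "numeric" else "categorical"
        if (!nm %in% names(covVals))
            stop("covariate effect on unknown covariate '", nm,
                 "' (only gender and age are generated)")
        vals <- covVals[[nm]]
        if (kind == "numeric") {
            thr <- if (!is.null(cv$threshold)) cv$threshold else 60
            hit <- !is.na(vals) & vals > thr
            lev <- NA_character_
        } else {
            lev <- if (!is.null(cv$level)) cv$level else "M"
            hit <- !is.na(vals) & vals == lev
            thr <- NA_real_
        }
        okPs <- setdiff(which(!isBg & asDir == 0L), unlist(
            lapply(covRows, function(r) r$idx)))
        pick <- sort(sample(okPs, cv$nProbesets))
        covShift[pick, hit] <- covShift[pick, hit] + cv$effect
        covRows[[length(covRows) + 1L]] <-
            list(name = nm, kind = kind, effect = cv$effect,
                 threshold = thr, level = lev, idx = pick)
    }

    ## assemble expression
    mu <- rnorm(nG, config$baselineMean, config$baselineSd)
    aff <- rnorm(nPs, 0, 1)
    base <- mu[geneOf] + aff
    x <- matrix(base, nPs, nS)
    condShift <- -config$geneDeEffect * deDir[geneOf]   # normal higher if +1
    x[, isPath] <- x[, isPath] + condShift + asShift
    x <- x + covShift
    x[isBg, ] <- 3                                     # background floor
    x <- x + matrix(rnorm(nPs * nS, 0, config$noiseSd), nPs, nS)
    dimnames(x) <- list(psIds, sampleId)

    dbg <- matrix(runif(nPs * nS, 0, 0.01), nPs, nS,
                  dimnames = dimnames(x))
    if (nBg > 0)
        dbg[bgPs, ] <- matrix(runif(nBg * nS), nBg, nS)

    anno <- data.frame(
        probeset_id = psIds,
        transcript_cluster_id = sprintf("tc%04d", geneOf),
        gene_id = geneIds[geneOf],
        chrom = chrom[geneOf],
        start = startPs, stop = stopPs,
        strand = strandG[geneOf],
        exon_index = exonIdx,
        isoform_ids = vapply(iso, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE)
    samples <- data.frame(
        sample_id = sampleId, condition = cond,
        patient_id = patientId, gender = gender, age = age,
        stringsAsFactors = FALSE)

    gsets <- NULL
    if (config$nPathways > 0L || config$nGoTerms > 0L) {
        mk <- function(n, size, prefix, kind) {
            do.call(rbind, lapply(seq_len(n), function(i) data.frame(
                set_id = sprintf("%s%03d", prefix, i),
                gene_id = geneIds[sort(sample.int(nG, min(size, nG)))],
                kind = kind, stringsAsFactors = FALSE)))
        }
        gsets <- rbind(
            if (config$nPathways > 0L)
                mk(config$nPathways, config$pathwaySize, "PW", "pathway"),
            if (config$nGoTerms > 0L)
                mk(config$nGoTerms, config$goSize, "GO", "go"))
    }

    dataset <- ExonArrayExperiment(x, samples, anno, dabg = dbg,
                                   geneSets = gsets)
    truth <- list(
        probesets = data.frame(
            probeset_id = psIds, gene_id = geneIds[geneOf],
            is_as = asDir != 0L, as_direction = asDir,
            is_background = isBg, stringsAsFactors = FALSE),
        genes = data.frame(
            gene_id = geneIds,
            is_de = deDir != 0L, de_direction = deDir,
            is_as = seq_len(nG) %in% asGenes, stringsAsFactors = FALSE),
        covariates = if (length(covRows)) do.call(rbind, lapply(
            covRows, function(r) data.frame(
                name = r$name, kind = r$kind, effect = r$effect,
                threshold = r$threshold, level = r$level,
                probeset_ids = paste(psIds[r$idx], collapse = ";"),
                stringsAsFactors = FALSE)))
        else data.frame(name = character(), kind = character(),
                        effect = numeric(), threshold = numeric(),
                        level = character(), probeset_ids = character()))
    list(dataset = dataset, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the TSV/CSV files consumed by [readExonDataset()] plus
#' `truth.tsv` (probeset-level ground truth joined with gene-level truth)
#' and, when present, `gene_sets.tsv`.
#'
#' @param sim result of [simulateExonDataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the files written.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    x <- sim$dataset
    paths <- c(expression = file.path(dir, "expression.tsv"),
               dabg = file.path(dir, "dabg.tsv"),
               samples = file.path(dir, "samples.csv"),
               annotation = file.path(dir, "annotation.tsv"),
               truth = file.path(dir, "truth.tsv"))
    .writeMatrixTSV(exonExprs(x), paths[["expression"]])
    .writeMatrixTSV(dabg(x), paths[["dabg"]])
    smp <- as.data.frame(colData(x))
    smp$condition <- as.character(smp$condition)
    write.csv(smp, paths[["samples"]], row.names = FALSE, quote = FALSE,
              na = "")
    writeStatsTable(probesetAnno(x), paths[["annotation"]])
    tr <- merge(sim$truth$probesets,
                sim$truth$genes[c("gene_id", "is_de", "de_direction")],
                by = "gene_id", sort = FALSE)
    tr <- tr[order(match(tr$probeset_id, rownames(x))),
             c("probeset_id", "gene_id", "is_as", "as_direction",
               "is_background", "is_de", "de_direction")]
    writeStatsTable(tr, paths[["truth"]])
    gs <- geneSets(x)
    if (nrow(gs)) {
        paths <- c(paths, gene_sets = file.path(dir, "gene_sets.tsv"))
        writeStatsTable(gs, paths[["gene_sets"]])
    }
    invisible(paths)
}

.writeMatrixTSV <- function(m, path) {
    df <- data.frame(probeset_id = rownames(m),
                     apply(m, 2L, function(v) sprintf("%.8g", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("probeset_id", colnames(m))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
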