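## Conditional-inference decision tree for multivariate AS analysis:
## permutation-test variable selection with per-node Bonferroni
## adjustment, ANOVA-F split search, recursive partitioning.

#' Control parameters for splice trees
#'
#' @param alpha significance level for the per-node (Bonferroni-adjusted)
#'   global independence test; growth stops when it cannot be rejected.
#' @param nPermutations Monte-Carlo permutations per association test
#'   (>= 99); the smallest attainable p-value is
#'   `1 / (nPermutations + 1)`.
#' @param minNodeSize do not attempt to split nodes with fewer samples.
#' @param minLeafSize every child of a split must keep at least this many
#'   samples.
#' @param maxDepth maximum number of splits from root to leaf.
#' @param seed integer seed making tree growth deterministic.
#' @return a validated `tree_control` list.
#' @export
treeControl <- function(alpha = 0.05, nPermutations = 9999L,
                        minNodeSize = 10L, minLeafSize = 5L,
                        maxDepth = 4L, seed = 1L) {
    ctl <- list(alpha = alpha, nPermutations = as.integer(nPermutations),
                minNodeSize = as.integer(minNodeSize),
                minLeafSize = as.integer(minLeafSize),
                maxDepth = as.integer(maxDepth), seed = as.integer(seed))
    if (ctl$alpha <= 0 || ctl$alpha >= 1) stop("alpha must lie in (0, 1)")
    if (ctl$nPermutations < 99L) stop("nPermutations must be >= 99")
    if (ctl$minLeafSize < 1L || ctl$minNodeSize < 2L * ctl$minLeafSize)
        stop("minNodeSize must be >= 2 * minLeafSize >= 2")
    class(ctl) <- "tree_control"
    ctl
}

## Association statistic between a numeric response and one covariate.
## Numeric covariate: |Pearson correlation|. Categorical: the largest
## absolute standardized group-mean deviation, max_g sqrt(n_g) *
## |mean_g - grand| / sd(y). Both are computed on the standardized
## response so permutation replicates reduce to indexed sums.
.assocTest <- function(response, covariate, B) {
    ok <- !is.na(response) & !is.na(covariate)
    y <- response[ok]; cv <- covariate[ok]
    n <- length(y)
    if (n < 3L || length(unique(cv)) < 2L || sd(y) == 0)
        return(structure(1, statistic = NA_real_))
    ys <- as.vector(scale(y))               # mean 0, sd 1
    perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    if (is.numeric(cv)) {
        if (sd(cv) == 0) return(structure(1, statistic = NA_real_))
        xs <- as.vector(scale(cv))
        obs <- abs(sum(ys * xs)) / (n - 1L)
        stat <- abs(as.vector(crossprod(matrix(ys[perm], n, B), xs))) /
            (n - 1L)
    } else {
        g <- factor(cv)
        G <- stats::model.matrix(~ g - 1)
        ng <- colSums(G)
        obs <- max(abs(as.vector(crossprod(G, ys))) / sqrt(ng))
        M <- abs(crossprod(G, matrix(ys[perm], n, B))) / sqrt(ng)
        stat <- apply(M, 2L, max)
    }
    p <- (1 + sum(stat >= obs * (1 - 1e-12))) / (B + 1)
    structure(p, statistic = obs)
}

#' Permutation test of association between response and one covariate
#'
#' Tests the partial null hypothesis of independence between a numeric
#' response and a single covariate. The statistic is the absolute Pearson
#' correlation for numeric covariates and the maximum absolute
#' standardized group-mean deviation for categorical ones; its null
#' distribution is obtained by randomly permuting the response, giving
#' `p = (1 + #\{permuted >= observed\}) / (nPermutations + 1)`. A constant
#' covariate (or constant response) is untestable and returns p = 1.
#' Missing values are excluded pairwise.
#'
#' @param response numeric vector.
#' @param covariate numeric or categorical vector, same length.
#' @param control a [treeControl()]; `control$seed` makes the result
#'   deterministic.
#' @return the permutation p-value, with the observed statistic attached
#'   as `attr(, "statistic")`.
#' @export
associationPValue <- function(response, covariate,
                              control = treeControl()) {
    stopifnot(length(response) == length(covariate))
    set.seed(control$seed)
    .assocTest(response, covariate, control$nPermutations)
}

.testableCovariates <- function(covariates, response, control) {
    ok <- vapply(covariates, function(cv) {
        use <- !is.na(cv) & !is.na(response)
        sum(use) >= control$minNodeSize &&
            length(unique(cv[use])) >= 2L
    }, logical(1))
    names(covariates)[ok]
}

.selectVariable <- function(response, covariates, control) {
    testable <- .testableCovariates(covariates, response, control)
    if (!length(testable)) return(NULL)
    pv <- vapply(testable, function(nm)
        as.numeric(.assocTest(response, covariates[[nm]],
                              control$nPermutations)), numeric(1))
    padj <- pmin(1, pv * length(testable))
    if (min(padj) > control$alpha) return(NULL)
    best <- testable[which.min(padj)]       # ties: first in declared order
    list(variable = best, p = pv[[best]], adjusted_p = min(padj))
}

#' Select the covariate most associated with the response
#'
#' Computes a permutation association p-value per testable covariate
#' (>= 2 distinct values among the current samples), Bonferroni-adjusts by
#' the number of testable covariates, and returns the arg-min variable —
#' or `NULL` (the stop signal) when the global null of independence cannot
#' be rejected at `control$alpha`. Ties go to the first covariate in
#' declared order.
#'
#' @param response numeric vector.
#' @param covariates `data.frame` of candidate covariates.
#' @param control a [treeControl()].
#' @return `list(variable, p, adjusted_p)` or `NULL`.
#' @export
selectVariable <- function(response, covariates, control = treeControl()) {
    set.seed(control$seed)
    .selectVariable(response, covariates, control)
}

.anovaF <- function(y, left) {
    n <- length(y); n1 <- sum(left); n2 <- n - n1
    m1 <- mean(y[left]); m2 <- mean(y[!left])
    grand <- mean(y)
    ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
    ssw <- sum((y[left] - m1)^2) + sum((y[!left] - m2)^2)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / 1) / (ssw / (n - 2L))
}

#' Find the ANOVA-optimal split of a selected covariate
#'
#' Numeric covariates are split at the midpoint between consecutive sorted
#' unique values that maximizes the two-group ANOVA F statistic, subject
#' to both sides keeping at least `minLeafSize` samples; ties take the
#' smallest threshold. A binary categorical covariate splits by its two
#' values; with k > 2 levels (k <= 8) all `2^(k-1) - 1` two-group level
#' partitions are enumerated and the F-maximizing one chosen. Missing
#' covariate values are excluded from the search.
#'
#' @param response numeric vector.
#' @param covariate the selected covariate, same length.
#' @param control a [treeControl()].
#' @return `NULL` when no admissible split exists, else a list with
#'   `type` (`"numeric"`/`"categorical"`), `threshold` (numeric type) or
#'   `left`/`right` level sets, and the `statistic` (F).
#' @export
bestSplit <- function(response, covariate, control = treeControl()) {
    ok <- !is.na(response) & !is.na(covariate)
    y <- response[ok]; cv <- covariate[ok]
    minL <- control$minLeafSize
    if (is.numeric(cv)) {
        u <- sort(unique(cv))
        if (length(u) < 2L) return(NULL)
        cand <- (u[-length(u)] + u[-1L]) / 2
        best <- NULL; bestF <- -Inf
        for (thr in cand) {
            left <- cv <= thr
            if (sum(left) < minL || sum(!left) < minL) next
            f <- .anovaF(y, left)
            if (f > bestF) {          # strict: ties keep smaller threshold
                bestF <- f
                best <- list(type = "numeric", threshold = thr,
                             statistic = f)
            }
        }
        best
    } else {
        lev <- sort(unique(as.character(cv)))
        k <- length(lev)
        if (k < 2L) return(NULL)
        if (k > 8L) stop("categorical covariates with more than 8 levels ",
                         "are not supported")
        best <- NULL; bestF <- -Inf
        for (mask in seq_len(2L^(k - 1L) - 1L)) {
            inLeft <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
            leftLev <- lev[inLeft]
            left <- cv %in% leftLev
            if (sum(left) < minL || sum(!left) < minL) next
            f <- .anovaF(y, left)
            if (f > bestF) {
                bestF <- f
                best <- list(type = "categorical", left = leftLev,
                             right = lev[!inLeft], statistic = f)
            }
        }
        best
    }
}

#' Grow a conditional-inference splice tree
#'
#' Recursively partitions the samples: at each node the global null of
#' independence between the response and all covariates is tested
#' (Bonferroni-adjusted permutation tests, [selectVariable()]); if
#' rejected, the strongest covariate is split at its ANOVA-optimal point
#' ([bestSplit()]) and the children are grown, until the null cannot be
#' rejected, the node is smaller than `minNodeSize`, or `maxDepth` is
#' reached. Samples missing the chosen split variable go to the larger
#' child. A single-leaf tree is a valid outcome (and the expected one on
#' null data).
#'
#' @param response numeric vector, typically one probeset's
#'   cluster-normalized expression.
#' @param covariates `data.frame` of clinical covariates (condition,
#'   gender, age, stage, ...), one row per sample.
#' @param control a [treeControl()]; identical inputs and seed give an
#'   identical tree.
#' @return a [SpliceTree][SpliceTree-class]. Node lists carry `node_id`
#'   (preorder), `kind`, `n`; internal nodes add `variable`,
#'   `adjusted_p`, `split` (with `na_child`) and `children`; leaves add
#'   `mean` and `var` of the response.
#' @examples
#' set.seed(1)
#' gender <- rep(c("M", "F"), each = 20)
#' y <- 2 * (gender == "M") + rnorm(40, sd = 0.5)
#' growTree(y, data.frame(gender = gender,
#'                        age = runif(40, 40, 80)),
#'          treeControl(nPermutations = 499))
#' @export
growTree <- function(response, covariates, control = treeControl()) {
    stopifnot(is.numeric(response),
              nrow(covariates) == length(response))
    covariates <- as.data.frame(covariates)
    set.seed(control$seed)
    counter <- new.env(parent = emptyenv())
    counter$id <- 0L
    rootSmall <- length(response) < control$minNodeSize
    if (rootSmall)
        warning("fewer than minNodeSize samples at the root; ",
                "returning a single-leaf tree")
    root <- .growNode(response, covariates, seq_along(response),
                      depth = 0L, control = control, counter = counter)
    new("SpliceTree", root = root, control = unclass(control),
        covariates = names(covariates), nobs = length(response))
}

.leafNode <- function(id, response, idx) {
    y <- response[idx]
    list(node_id = id, kind = "leaf", n = length(idx),
         mean = mean(y), var = if (length(y) > 1L) var(y) else 0)
}

.growNode <- function(response, covariates, idx, depth, control, counter) {
    counter$id <- counter$id + 1L
    id <- counter$id
    y <- response[idx]
    if (length(idx) < control$minNodeSize || depth >= control$maxDepth)
        return(.leafNode(id, response, idx))
    sel <- .selectVariable(y, covariates[idx, , drop = FALSE], control)
    if (is.null(sel))
        return(.leafNode(id, response, idx))
    cv <- covariates[[sel$variable]][idx]
    split <- bestSplit(y, cv, control)
    if (is.null(split))
        return(.leafNode(id, response, idx))
    goLeft <- if (split$type == "numeric") cv <= split$threshold
              else cv %in% split$left
    naIdx <- is.na(goLeft)
    nl <- sum(goLeft, na.rm = TRUE); nr <- sum(!goLeft, na.rm = TRUE)
    split$na_child <- if (nl >= nr) "left" else "right"
    goLeft[naIdx] <- split$na_child == "left"
    kids <- list(
        .growNode(response, covariates, idx[goLeft], depth + 1L,
                  control, counter),
        .growNode(response, covariates, idx[!goLeft], depth + 1L,
                  control, counter))
    list(node_id = id, kind = "internal", n = length(idx),
         variable = sel$variable, adjusted_p = sel$adjusted_p,
         split = split, children = kids)
}

.splitLabel <- function(node, side) {
    s <- node$split
    if (s$type == "numeric") {
        op <- if (side == "left") "<=" else ">"
        sprintf("%s %s %.6g", node$variable, op, s$threshold)
    } else {
        lev <- if (side == "left") s$left else s$right
        sprintf("%s in {%s}", node$variable, paste(lev, collapse = ","))
    }
}

#' Tree depth
#' @param tree a `SpliceTree`.
#' @return number of splits on the longest root-to-leaf path.
#' @export
treeDepth <- function(tree) {
    rec <- function(nd) if (nd$kind == "leaf") 0L
        else 1L + max(vapply(nd$children, rec, integer(1)))
    rec(tree@root)
}

#' Assign samples to tree leaves with human-readable rules
#'
#' Replays the tree's split rules on a covariate table, assigning every
#' sample a leaf id and a rule string such as `"gender in {M} AND age >
#' 60"`. Samples missing a split variable follow the larger child, as
#' during growth. The labels can be reused as experimental groups for
#' re-running exon statistics. A single-leaf tree labels every sample
#' `"all"`.
#'
#' @param tree a `SpliceTree`.
#' @param covariates `data.frame` with the tree's covariate columns.
#' @return list with `leaf` (integer leaf node id per sample), `label`
#'   (rule string per sample) and `rules` (named character, one per leaf).
#' @export
suggestGroups <- function(tree, covariates) {
    covariates <- as.data.frame(covariates)
    n <- nrow(covariates)
    leaf <- integer(n); label <- character(n)
    rules <- character()
    assign_ <- function(node, idx, conds) {
        if (node$kind == "leaf") {
            lab <- if (length(conds)) paste(conds, collapse = " AND ")
                   else "all"
            leaf[idx] <<- node$node_id
            label[idx] <<- lab
            rules[as.character(node$node_id)] <<- lab
            return(invisible())
        }
        cv <- covariates[[node$variable]][idx]
        goLeft <- if (node$split$type == "numeric") cv <= node$split$threshold
                  else cv %in% node$split$left
        goLeft[is.na(goLeft)] <- node$split$na_child == "left"
        assign_(node$children[[1L]], idx[goLeft],
                c(conds, .splitLabel(node, "left")))
        assign_(node$children[[2L]], idx[!goLeft],
                c(conds, .splitLabel(node, "right")))
    }
    assign_(tree@root, seq_len(n), character())
    list(leaf = leaf, label = label, rules = rules)
}

setMethod("show", "SpliceTree", function(object) {
    cat(sprintf("SpliceTree: %d samples, %d covariate(s), depth %d\n",
                object@nobs, length(object@covariates), treeDepth(object)))
    rec <- function(nd, indent, edge) {
        pad <- strrep("  ", indent)
        if (nd$kind == "leaf") {
            cat(sprintf("%s[%d] %sleaf: n=%d mean=%.4g\n", pad, nd$node_id,
                        edge, nd$n, nd$mean))
        } else {
            cat(sprintf("%s[%d] %s%s (adj. p=%.4g)\n", pad, nd$node_id,
                        edge, nd$variable, nd$adjusted_p))
            rec(nd$children[[1L]], indent + 1L,
                paste0(.splitLabel(nd, "left"), ": "))
            rec(nd$children[[2L]], indent + 1L,
                paste0(.splitLabel(nd, "right"), ": "))
        }
    }
    rec(object@root, 0L, "")
})

#' Per-probeset splice trees
#'
#' Grows one conditional-inference tree per requested probeset, using the
#' probeset's cluster-normalized expression as response and the sample
#' metadata as covariates. `condition` is included as a candidate
#' covariate by default so that splicing effects correlated with
#' non-pathological characteristics (gender, age of onset, stage) surface
#' explicitly next to the disease effect.
#'
#' @param x an `ExonArrayExperiment`.
#' @param probesetIds probesets to analyze (default: all).
#' @param control a [treeControl()].
#' @param covariateNames metadata columns to use; defaults to `condition`,
#'   `gender`, `age`, `stage` plus any extra covariate columns present.
#' @param includeCondition drop `condition` from the candidates when
#'   `FALSE` (e.g. when fitting within condition strata).
#' @param summaryMethod normalization summary, see [normalizeExons()].
#' @return list with `trees` (named list of `SpliceTree`) and `summary`
#'   (`data.frame`: `probeset_id`, `root_variable`, `root_adjusted_p`,
#'   `depth`, `n_leaves`).
#' @export
probesetTrees <- function(x, probesetIds = rownames(x),
                          control = treeControl(),
                          covariateNames = NULL,
                          includeCondition = TRUE,
                          summaryMethod = "medianpolish") {
    e <- normalizeExons(x, method = summaryMethod)
    cd <- as.data.frame(colData(x))
    if (is.null(covariateNames)) {
        covariateNames <- intersect(
            c("condition", "gender", "age", "stage"), colnames(cd))
        extra <- setdiff(colnames(cd),
                         c(covariateNames, "sample_id", "patient_id"))
        covariateNames <- c(covariateNames, extra)
    }
    if (!includeCondition)
        covariateNames <- setdiff(covariateNames, "condition")
    cov <- cd[, covariateNames, drop = FALSE]
    cov[] <- lapply(cov, function(v) if (is.factor(v)) as.character(v) else v)
    miss <- setdiff(probesetIds, rownames(e))
    if (length(miss)) stop("unknown probeset '", miss[1L], "'")
    trees <- lapply(probesetIds, function(ps)
        growTree(e[ps, ], cov, control))
    names(trees) <- probesetIds
    summary <- data.frame(
        probeset_id = probesetIds,
        root_variable = vapply(trees, function(tr)
            if (tr@root$kind == "internal") tr@root$variable
            else NA_character_, character(1)),
        root_adjusted_p = vapply(trees, function(tr)
            if (tr@root$kind == "internal") tr@root$adjusted_p
            else NA_real_, numeric(1)),
        depth = vapply(trees, treeDepth, integer(1)),
        n_leaves = vapply(trees, function(tr) {
            rec <- function(nd) if (nd$kind == "leaf") 1L
                else sum(vapply(nd$children, rec, integer(1)))
            rec(tr@root)
        }, integer(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    list(trees = trees, summary = summary)
}

## Plain-list rendering of a tree for JSON serialization.
treeToList <- function(tree) {
    rec <- function(nd) {
        if (nd$kind == "leaf")
            return(list(node_id = nd$node_id, kind = "leaf", n = nd$n,
                        mean = nd$mean, var = nd$var))
        list(node_id = nd$node_id, kind = "internal", n = nd$n,
             variable = nd$variable, adjusted_p = nd$adjusted_p,
             split = nd$split[setdiff(names(nd$split), "statistic")],
             statistic = nd$split$statistic,
             children = lapply(nd$children, rec))
    }
    list(nobs = tree@nobs, covariates = tree@covariates, root = rec(tree@root))
}
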