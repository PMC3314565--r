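ctl <- function(...) treeControl(nPermutations = 999L, ...)

test_that("perfect association attains the permutation floor", {
    y <- seq_len(30) / 10
    p <- associationPValue(y, y, ctl(seed = 2))
    expect_equal(as.numeric(p), 1 / 1000)
})

test_that("constant covariates and responses are untestable (p = 1)", {
    set.seed(1)
    y <- rnorm(30)
    expect_equal(as.numeric(associationPValue(y, rep(1, 30), ctl())), 1)
    expect_equal(as.numeric(associationPValue(y, rep("a", 30), ctl())), 1)
    expect_equal(as.numeric(associationPValue(rep(0, 30),
                                              rnorm(30), ctl())), 1)
})

test_that("a strong binary group effect is detected", {
    set.seed(4)
    g <- rep(c("a", "b"), each = 20)
    y <- ifelse(g == "a", 0, 3) + rnorm(40, sd = 0.5)
    expect_lt(as.numeric(associationPValue(y, g, ctl(seed = 5))), 0.01)
    ## numeric covariate with a linear effect
    z <- runif(40)
    expect_lt(as.numeric(associationPValue(3 * z + rnorm(40, sd = 0.5),
                                           z, ctl(seed = 6))), 0.01)
})

test_that("missing values are excluded pairwise", {
    set.seed(7)
    g <- rep(c("a", "b"), each = 15)
    y <- ifelse(g == "a", 0, 2) + rnorm(30, sd = 0.5)
    g[1:3] <- NA
    p <- associationPValue(y, g, ctl(seed = 8))
    expect_lt(as.numeric(p), 0.01)
})

test_that("variable selection Bonferroni-adjusts and stops on noise", {
    set.seed(9)
    n <- 60
    cov <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                      age = runif(n, 40, 80),
                      stage = sample(c("I", "II", "III"), n, TRUE))
    y <- 2 * (cov$gender == "M") + rnorm(n, sd = 0.5)
    sel <- selectVariable(y, cov, ctl(seed = 10))
    expect_identical(sel$variable, "gender")
    expect_equal(sel$adjusted_p, min(1, sel$p * 3))

    ## single covariate: adjusted equals raw
    sel1 <- selectVariable(y, cov["gender"], ctl(seed = 11))
    expect_equal(sel1$adjusted_p, sel1$p)

    ## pure noise stops most of the time (light Monte-Carlo check)
    stops <- vapply(1:60, function(i) {
        set.seed(100 + i)
        yn <- rnorm(n)
        cv <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                         age = runif(n, 40, 80))
        is.null(selectVariable(yn, cv, ctl(seed = 200 + i)))
    }, logical(1))
    expect_gt(mean(stops), 0.85)
})

test_that("binary categorical split separates the two values", {
    set.seed(12)
    g <- rep(c("M", "F"), each = 10)
    y <- ifelse(g == "M", 1, 0) + rnorm(20, sd = 0.1)
    sp <- bestSplit(y, g, ctl())
    expect_identical(sp$type, "categorical")
    expect_setequal(c(sp$left, sp$right), c("M", "F"))
    expect_length(sp$left, 1L)
})

test_that("numeric split maximizes F over midpoints (brute-force oracle)", {
    y <- c(1, 2, 3, 10, 11, 12)       # strictly increasing response
    v <- c(10, 20, 30, 40, 50, 60)
    sp <- bestSplit(y, v, treeControl(minLeafSize = 1, minNodeSize = 2,
                                      nPermutations = 99))
    ## brute force over all admissible thresholds
    u <- sort(unique(v))
    cand <- (u[-6] + u[-1]) / 2
    f <- vapply(cand, function(thr) {
        l <- v <= thr
        n1 <- sum(l); n2 <- 6 - n1
        m1 <- mean(y[l]); m2 <- mean(y[!l]); gm <- mean(y)
        ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
        ssw <- sum((y[l] - m1)^2) + sum((y[!l] - m2)^2)
        ssb / (ssw / 4)
    }, numeric(1))
    expect_equal(sp$threshold, cand[which.max(f)])
    expect_equal(sp$statistic, max(f), tolerance = 1e-12)
})

test_that("an age step at 60 is recovered near 60", {
    set.seed(13)
    age <- runif(60, 40, 80)
    y <- 2 * (age > 60) + rnorm(60, sd = 0.1)
    sp <- bestSplit(y, age, ctl())
    expect_identical(sp$type, "numeric")
    expect_gt(sp$threshold, 58)
    expect_lt(sp$threshold, 62)
})

test_that("multi-level categorical split enumerates level partitions", {
    set.seed(14)
    g <- rep(c("I", "II", "III", "IV"), each = 10)
    y <- ifelse(g %in% c("I", "III"), 2, 0) + rnorm(40, sd = 0.2)
    sp <- bestSplit(y, g, ctl())
    side <- if ("I" %in% sp$left) sp$left else sp$right
    expect_setequal(side, c("I", "III"))
    expect_error(bestSplit(rnorm(20), sample(letters[1:9], 20, TRUE),
                           treeControl(minLeafSize = 1, minNodeSize = 2)),
                 "more than 8 levels")
})

test_that("split respects the minimum leaf size", {
    y <- c(10, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
    v <- seq_len(20)
    sp <- bestSplit(y, v, treeControl(minLeafSize = 5, minNodeSize = 10))
    expect_gte(sum(v <= sp$threshold), 5)
    expect_gte(sum(v > sp$threshold), 5)
})

test_that("a planted gender effect grows a depth-1 tree on gender", {
    set.seed(15)
    n <- 60
    cov <- data.frame(gender = rep(c("M", "F"), each = n / 2),
                      age = runif(n, 40, 80))
    y <- 2 * (cov$gender == "M") + rnorm(n, sd = 0.5)
    tr <- growTree(y, cov, ctl(seed = 16))
    expect_s4_class(tr, "SpliceTree")
    expect_identical(tr@root$kind, "internal")
    expect_identical(tr@root$variable, "gender")
    expect_lte(tr@root$adjusted_p, 0.05)
    expect_identical(treeDepth(tr), 1L)
})

test_that("trees are deterministic given a seed", {
    set.seed(17)
    n <- 80
    cov <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                      age = runif(n, 40, 80))
    y <- 1.5 * (cov$gender == "M") + 1.5 * (cov$age > 60) +
        rnorm(n, sd = 0.4)
    t1 <- growTree(y, cov, ctl(seed = 18))
    t2 <- growTree(y, cov, ctl(seed = 18))
    expect_identical(exonsplice:::treeToList(t1),
                     exonsplice:::treeToList(t2))
})

test_that("leaves partition the samples exactly", {
    set.seed(19)
    n <- 100
    cov <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                      age = runif(n, 40, 80),
                      stage = sample(c("I", "II"), n, TRUE))
    y <- 2 * (cov$gender == "M") + 2 * (cov$age > 55) + rnorm(n, sd = 0.5)
    tr <- growTree(y, cov, ctl(seed = 20))
    g <- suggestGroups(tr, cov)
    expect_length(g$leaf, n)
    sizes <- table(g$leaf)
    leafN <- function(nd) if (nd$kind == "leaf")
        setNames(nd$n, nd$node_id) else
        c(leafN(nd$children[[1]]), leafN(nd$children[[2]]))
    stored <- leafN(tr@root)
    expect_equal(unname(sizes[as.character(names(stored))]),
                 unname(stored), ignore_attr = TRUE)
    expect_identical(sum(stored), as.integer(n))
})

test_that("nested effects produce a condition-then-age structure", {
    set.seed(21)
    n <- 120
    cov <- data.frame(condition = rep(c("normal", "pathological"),
                                      each = n / 2),
                      age = runif(n, 40, 80))
    y <- 3 * (cov$condition == "pathological") +
        1.8 * (cov$age > 60) + rnorm(n, sd = 0.6)
    tr <- growTree(y, cov, ctl(seed = 22))
    expect_identical(tr@root$variable, "condition")
    kids <- tr@root$children
    ageSplits <- vapply(kids, function(nd)
        nd$kind == "internal" && nd$variable == "age", logical(1))
    expect_true(any(ageSplits))
    thr <- vapply(kids[ageSplits], function(nd) nd$split$threshold,
                  numeric(1))
    expect_true(all(thr > 55 & thr < 65))
})

test_that("suggestGroups replays the rules exactly", {
    set.seed(23)
    n <- 100
    cov <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                      age = runif(n, 40, 80))
    y <- 2.5 * (cov$gender == "M") + 2 * (cov$age > 60) +
        rnorm(n, sd = 0.5)
    tr <- growTree(y, cov, ctl(seed = 24))
    g <- suggestGroups(tr, cov)
    ## manual rule evaluation per sample
    manual <- function(i) {
        nd <- tr@root
        while (nd$kind == "internal") {
            cv <- cov[[nd$variable]][i]
            left <- if (nd$split$type == "numeric") cv <= nd$split$threshold
                    else cv %in% nd$split$left
            if (is.na(left)) left <- nd$split$na_child == "left"
            nd <- nd$children[[if (left) 1 else 2]]
        }
        nd$node_id
    }
    expect_identical(g$leaf, vapply(seq_len(n), manual, integer(1)))
    expect_true(all(nzchar(g$label)))

    ## a single-leaf tree labels everyone "all"
    nullTree <- growTree(rnorm(30), data.frame(age = runif(30, 40, 80)),
                         ctl(seed = 25))
    gn <- suggestGroups(nullTree, data.frame(age = runif(30, 40, 80)))
    expect_identical(unique(gn$label), "all")
})

test_that("small root yields a single-leaf tree with a warning", {
    expect_warning(
        tr <- growTree(rnorm(5), data.frame(age = runif(5)), ctl()),
        "minNodeSize")
    expect_identical(tr@root$kind, "leaf")
    expect_identical(treeDepth(tr), 0L)
})

test_that("per-probeset trees surface the planted covariate", {
    sim <- simulateExonDataset(simulationConfig(
        nGenes = 8, nPairs = 20, noiseSd = 0.25,
        covariates = list(list(name = "gender", kind = "categorical",
                               effect = 2, nProbesets = 3)),
        seed = 26))
    affected <- strsplit(sim$truth$covariates$probeset_ids, ";")[[1]]
    res <- probesetTrees(sim$dataset, affected,
                         control = ctl(seed = 27))
    expect_identical(res$summary$probeset_id, affected)
    expect_true(all(res$summary$root_variable == "gender"))
    expect_true(all(res$summary$root_adjusted_p <= 0.05))
    ## unaffected probesets overwhelmingly yield single leaves
    calm <- setdiff(rownames(sim$dataset), affected)[1:10]
    resC <- probesetTrees(sim$dataset, calm, control = ctl(seed = 28))
    expect_gt(mean(resC$summary$depth == 0), 0.7)
})

test_that("control parameters are validated", {
    expect_error(treeControl(alpha = 0), "alpha")
    expect_error(treeControl(nPermutations = 10), ">= 99")
    expect_error(treeControl(minNodeSize = 4, minLeafSize = 5),
                 "minNodeSize")
})
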