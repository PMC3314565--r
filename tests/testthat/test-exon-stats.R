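twoGroups <- function(n1, n2) rep(c("normal", "pathological"), c(n1, n2))

test_that("exon normalization is log-space subtraction of the cluster summary", {
    x <- matrix(8.0, 1, 3, dimnames = list("ps1", paste0("s", 1:3)))
    xa <- datasetFromMatrix(x, "tcA", twoGroups(2, 1))
    g <- matrix(6.5, 1, 3, dimnames = list("tcA", paste0("s", 1:3)))
    expect_equal(unname(normalizeExons(xa, summary = g)[1, ]), rep(1.5, 3))

    ## single-probeset cluster: its own summary, so e == 0 for any method
    for (m in c("median", "mean", "medianpolish"))
        expect_equal(unname(normalizeExons(xa, method = m)), matrix(0, 1, 3))
})

test_that("e + g reconstructs x exactly on random data", {
    m <- randomMatrix(50, 10, seed = 4)
    cl <- rep(sprintf("tc%02d", 1:10), each = 5)
    x <- datasetFromMatrix(m, cl, twoGroups(5, 5))
    for (method in c("median", "mean")) {
        g <- clusterSummary(x, method = method)
        e <- normalizeExons(x, summary = g)
        rebuilt <- e + g[rep(1:10, each = 5), ]
        dimnames(rebuilt) <- dimnames(m)
        expect_equal(rebuilt, m, tolerance = 1e-12)
    }
})

test_that("Splicing Index sign convention: positive when normal is higher", {
    e <- rbind(ps1 = c(1, 1, 1, 0, 0, 0), ps2 = c(2, 2, 2, 2, 2, 2))
    colnames(e) <- paste0("s", 1:6)
    si <- splicingIndex(e, twoGroups(3, 3))
    expect_equal(unname(si), c(1, 0))
    expect_error(splicingIndex(e, rep("normal", 6)), "non-empty")
})

test_that("fold change works on raw intensities and is not gene-normalized", {
    x <- rbind(ps1 = c(9, 9, 8, 8))
    colnames(x) <- paste0("s", 1:4)
    expect_equal(unname(exonFoldChange(x, twoGroups(2, 2))), 1)

    ## gene-level shift: FC ~ effect for all probesets while SI ~ 0
    sim <- simulateExonDataset(simulationConfig(
        nGenes = 30, nPairs = 15, geneDeFraction = 0.5, geneDeEffect = 1,
        asFraction = 0, noiseSd = 0.25, seed = 21))
    cond <- condition(sim$dataset)
    fc <- exonFoldChange(exonExprs(sim$dataset), cond)
    si <- splicingIndex(normalizeExons(sim$dataset), cond)
    tr <- merge(sim$truth$probesets, sim$truth$genes[c("gene_id", "is_de",
                                                       "de_direction")],
                by = "gene_id")
    tr <- tr[match(names(fc), tr$probeset_id), ]
    de <- tr$is_de
    expect_gt(mean(abs(fc[de]) > 0.5), 0.95)
    expect_lt(mean(abs(si[de])), 0.1)
})

test_that("the hand-worked two-sample t example is reproduced", {
    e <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                dimnames = list("ps1", paste0("s", 1:6)))
    tt <- exonTTest(e, twoGroups(3, 3))
    expect_equal(unname(tt$statistic), -3.6742, tolerance = 1e-4)
    expect_equal(tt$df, 4)
    expect_equal(unname(tt$p), 0.02131, tolerance = 1e-3)
    ## independent oracle
    ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
    expect_equal(unname(tt$p), ref$p.value, tolerance = 1e-12)
})

test_that("row t-tests match stats::t.test on random data, both modes", {
    m <- randomMatrix(10, 12, seed = 6)
    grp <- twoGroups(6, 6)
    tt <- exonTTest(m, grp)
    for (i in 1:10) {
        ref <- t.test(m[i, 1:6], m[i, 7:12], var.equal = TRUE)
        expect_equal(unname(tt$p[i]), ref$p.value, tolerance = 1e-12)
    }
    pairs <- rep(paste0("p", 1:6), 2)
    tp <- exonTTest(m, grp, paired = TRUE, pairs = pairs)
    for (i in 1:10) {
        ref <- t.test(m[i, 1:6], m[i, 7:12], paired = TRUE)
        expect_equal(unname(tp$p[i]), ref$p.value, tolerance = 1e-12)
    }
})

test_that("degenerate zero-variance rows give p = 1, never NaN", {
    e <- rbind(flat = rep(2, 8), shift = rep(c(0, 1), each = 4))
    colnames(e) <- paste0("s", 1:8)
    grp <- twoGroups(4, 4)
    tt <- exonTTest(e, grp)
    expect_equal(unname(tt$p), c(1, 0))
    expect_equal(unname(midasPValue(e, grp)), c(1, 0))
    expect_error(exonTTest(e[, 1:3, drop = FALSE],
                           c("normal", "normal", "pathological")),
                 "at least 2")
})

test_that("two-group MiDAS ANOVA equals the squared-t test", {
    m <- randomMatrix(200, 14, seed = 8)
    grp <- twoGroups(6, 8)
    tt <- exonTTest(m, grp)
    mp <- midasPValue(m, grp)
    expect_lt(max(abs(unname(mp) - tt$p)), 1e-10)
})

test_that("MiDAS matches stats::oneway.test and detects a planted group", {
    set.seed(9)
    m <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(paste0("ps", 1:5), paste0("s", 1:30)))
    grp <- rep(c("a", "b", "c"), each = 10)
    m[3, grp == "b"] <- m[3, grp == "b"] + 2   # 2 sigma shift
    mp <- midasPValue(m, grp)
    for (i in 1:5) {
        ref <- oneway.test(m[i, ] ~ grp, var.equal = TRUE)
        expect_equal(unname(mp[i]), ref$p.value, tolerance = 1e-12)
    }
    expect_lt(mp[["ps3"]], 0.01)
    expect_error(midasPValue(m, rep("a", 30)), "two non-empty groups")
})

test_that("DABG detection fractions count samples at or below threshold", {
    d <- rbind(allOn = rep(0, 10), allOff = rep(1, 10),
               mixed = c(0.01, 0.01, 0.01, 0.5, 0.5, rep(0.5, 5)))
    colnames(d) <- paste0("s", 1:10)
    det <- dabgDetection(d, twoGroups(5, 5), pThreshold = 0.05)
    expect_equal(unname(det[, "dabg_frac_normal"]), c(1, 0, 0.6))
    expect_equal(unname(det[, "dabg_frac_path"]), c(1, 0, 0))
})

test_that("DABG filtering follows the either/both rule table", {
    rec <- data.frame(probeset_id = c("a", "b", "c"),
                      dabg_frac_normal = c(1.0, 0.0, 0.6),
                      dabg_frac_path = c(1.0, 0.0, 0.0))
    either <- filterByDabg(rec, minFraction = 0.5, mode = "either")
    expect_identical(either$filtered, c(FALSE, TRUE, FALSE))
    both <- filterByDabg(rec, minFraction = 0.5, mode = "both")
    expect_identical(both$filtered, c(FALSE, TRUE, TRUE))
    expect_identical(attr(both, "n_filtered"), 2L)
})

test_that("BH adjustment matches the hand computation", {
    expect_equal(adjustPValues(c(0.01, 0.02, 0.03), "BH"),
                 c(0.03, 0.03, 0.03))
    expect_equal(adjustPValues(rep(1, 5), "BH"), rep(1, 5))
    expect_equal(adjustPValues(0.2, "BH"), 0.2)
    p <- runif(50)
    expect_true(all(adjustPValues(p, "BH") >= p))
    expect_identical(adjustPValues(p, "none"), p)
    expect_error(adjustPValues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("swapping group labels negates SI and FC but keeps p-values", {
    m <- randomMatrix(30, 10, seed = 10)
    g1 <- twoGroups(5, 5)
    g2 <- rev(g1)
    expect_equal(splicingIndex(m, g1), -splicingIndex(m, g2))
    expect_equal(exonFoldChange(m, g1), -exonFoldChange(m, g2))
    expect_equal(exonTTest(m, g1)$p, exonTTest(m, g2)$p)
    expect_equal(midasPValue(m, g1), midasPValue(m, g2))
})

test_that("statistics are invariant to per-sample cluster-level shifts", {
    m <- randomMatrix(8, 10, seed = 12)
    cl <- rep(c("tcA", "tcB"), each = 4)
    grp <- twoGroups(5, 5)
    shift <- rnorm(10)
    m2 <- m
    m2[cl == "tcA", ] <- sweep(m2[cl == "tcA", ], 2, shift, "+")
    for (method in c("median", "mean")) {
        e1 <- normalizeExons(datasetFromMatrix(m, cl, grp), method = method)
        e2 <- normalizeExons(datasetFromMatrix(m2, cl, grp), method = method)
        expect_equal(e1, e2, tolerance = 1e-12)
    }
})

test_that("exonStats assembles a coherent table with flagging", {
    sim <- simulateExonDataset(simulationConfig(
        nGenes = 20, nPairs = 10, asFraction = 0.25, asEffect = 1.5,
        noiseSd = 0.2, seed = 30))
    es <- exonStats(sim$dataset, adjust = "BH")
    expect_identical(nrow(es), nrow(sim$dataset))
    expect_true(all(es$t_q >= es$t_p & es$midas_q >= es$midas_p))
    expect_true(all(es$t_p >= 0 & es$t_p <= 1))
    ## planted probesets dominate the flagged set
    tr <- sim$truth$probesets
    planted <- tr$probeset_id[tr$is_as]
    expect_gt(mean(planted %in% es$probeset_id[es$flagged]), 0.8)
    expect_lt(mean(es$flagged[!es$probeset_id %in% planted]), 0.05)
})
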