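
test_that("differential expression has exact null and antisymmetry behaviour", {
    d <- makeGroupedExpr(seed = 3L)
    # identical groups (same patients duplicated): log ratios 0, p 1
    half <- d$expr[, 1:20]
    dup <- cbind(half, half)
    colnames(dup) <- sprintf("q%02d", 1:40)
    de0 <- differentialExpression(dup,
        rep(c("positive", "negative"), each = 20L))
    expect_true(all(de0$log_ratio == 0))
    expect_true(all(de0$p_value == 1))

    de <- differentialExpression(d$expr, d$groups)
    swapped <- differentialExpression(d$expr,
        ifelse(d$groups == "positive", "negative", "positive"))
    expect_identical(de$log_ratio, -swapped$log_ratio)
    expect_equal(de$p_value, swapped$p_value, tolerance = 1e-12)

    # matches t.test gene by gene
    for (g in c(1L, 10L, 50L)) {
        ref <- t.test(log2(d$expr[g, d$groups == "positive"] + 1),
            log2(d$expr[g, d$groups == "negative"] + 1))
        expect_equal(de$p_value[g], ref$p.value, tolerance = 1e-12)
        expect_equal(de$t_statistic[g], unname(ref$statistic),
            tolerance = 1e-12)
    }
    expect_error(differentialExpression(d$expr,
        c("positive", rep("negative", 59L))), "at least 2")
})

test_that("planted four-fold shifts pass the signature thresholds", {
    d <- makeGroupedExpr(nGenes = 80L, nPer = 50L, shiftGenes = 6L,
        log2shift = 2, seed = 5L)
    de <- differentialExpression(d$expr, d$groups)
    sets <- selectSignatureGenes(de, fc_min = 2, p_max = 0.01)
    expect_true(all(sprintf("g%03d", 1:6) %in% sets$up))
    expect_length(intersect(sets$up, sets$down), 0L)

    # tightening the fold-change threshold never adds members
    tighter <- selectSignatureGenes(de, fc_min = 3, p_max = 0.01)
    expect_true(all(tighter$up %in% sets$up))
    expect_true(all(tighter$down %in% sets$down))

    # null genes only: empty signature at these thresholds almost surely
    dNull <- makeGroupedExpr(nGenes = 200L, nPer = 30L, shiftGenes = 0L,
        seed = 7L)
    deN <- differentialExpression(dNull$expr, dNull$groups)
    setsN <- selectSignatureGenes(deN)
    expect_lte(length(setsN$up) + length(setsN$down),
        ceiling(0.01 * 200L) + 2L)
})

test_that("enrichment score equals the step-by-step oracle", {
    set.seed(11)
    for (rep in 1:5) {
        metric <- setNames(rnorm(20L), sprintf("g%02d", 1:20))
        members <- sample(names(metric), 6L)
        res <- gseaEnrichment(metric, members, nPermutations = 0L)
        expect_equal(res$es, oracleGseaES(metric, members),
            tolerance = 1e-12)
        # running sum terminates at zero
        expect_lt(abs(res$running_sum[[20L]]), 1e-9)
        # top-k geneset gives a positive score
        top <- names(sort(metric, decreasing = TRUE))[1:5]
        expect_gt(gseaEnrichment(metric, top, nPermutations = 0L)$es, 0)
    }
})

test_that("weight 0 reduces to the Kolmogorov-Smirnov statistic on ranks", {
    set.seed(13)
    metric <- setNames(sort(rnorm(30L), decreasing = TRUE),
        sprintf("g%02d", 1:30))
    members <- sample(names(metric), 10L)
    res <- gseaEnrichment(metric, members, weight = 0, nPermutations = 0L)
    # direct KS-style computation on the ranked list
    hit <- names(res$running_sum) %in% members
    dev <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
    ks <- if (max(dev) >= -min(dev) - 1e-12) max(dev) else min(dev)
    expect_equal(res$es, ks, tolerance = 1e-12)
})

test_that("ES is invariant to positive scaling and permutation p is seeded", {
    set.seed(17)
    metric <- setNames(rnorm(40L), sprintf("g%02d", 1:40))
    members <- sample(names(metric), 8L)
    a <- gseaEnrichment(metric, members, nPermutations = 200L, seed = 9L)
    b <- gseaEnrichment(metric * 7.5, members, nPermutations = 200L,
        seed = 9L)
    expect_equal(a$es, b$es, tolerance = 1e-12)
    expect_identical(a$p_value, b$p_value)
    c2 <- gseaEnrichment(metric, members, nPermutations = 200L, seed = 9L)
    expect_identical(a$p_value, c2$p_value)

    expect_error(gseaEnrichment(metric, "not_a_gene"), "intersect")
    expect_error(gseaEnrichment(metric, names(metric)), "proper subset")
})

test_that("null gene sets give near-symmetric enrichment scores", {
    set.seed(19)
    metric <- setNames(rnorm(60L), sprintf("g%02d", 1:60))
    es <- vapply(1:300, function(i) {
        members <- sample(names(metric), 12L)
        gseaEnrichment(metric, members, nPermutations = 0L)$es
    }, numeric(1L))
    expect_lt(abs(mean(es)), 3 * sd(es) / sqrt(length(es)) + 0.05)
})

test_that("enrichment agrees with fgsea on a tie-free ranking", {
    skip_if_not_installed("fgsea")
    set.seed(23)
    metric <- setNames(rnorm(100L), sprintf("g%03d", 1:100))
    members <- sample(names(metric), 15L)
    ours <- gseaEnrichment(metric, members, nPermutations = 0L)$es
    ref <- suppressWarnings(fgsea::fgsea(list(s = members), metric,
        minSize = 1, maxSize = 500, nPermSimple = 101))
    expect_equal(ours, ref$ES, tolerance = 1e-6)
})

test_that("signature correlation behaves on identity, negation and shared axes", {
    d <- makeGroupedExpr(nGenes = 60L, shiftGenes = 10L, seed = 29L)
    de <- differentialExpression(d$expr, d$groups)
    expect_equal(signatureCorrelation(de, de)$correlation, 1)
    neg <- de; neg$log_ratio <- -neg$log_ratio
    expect_equal(signatureCorrelation(de, neg)$correlation, -1)
    # an independent cohort sharing the same planted axis correlates
    d2 <- makeGroupedExpr(nGenes = 60L, shiftGenes = 10L, seed = 31L)
    de2 <- differentialExpression(d2$expr, d2$groups)
    expect_gt(signatureCorrelation(de, de2)$correlation, 0.5)
    expect_error(signatureCorrelation(de[1:2, ], de2[1:2, ]), "3 shared")
})
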