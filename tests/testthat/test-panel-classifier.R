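test_that("activation counts and the 0-1/2-3 grouping are exact on all combinations", {
    combos <- expand.grid(g1 = 0:1, g2 = 0:1, g3 = 0:1)
    calls <- t(as.matrix(combos))
    rownames(calls) <- c("g1", "g2", "g3")
    colnames(calls) <- sprintf("p%d", seq_len(ncol(calls)))
    sc <- scorePanel(calls, c("g1", "g2", "g3"))
    expect_identical(sc$activation_count, as.integer(rowSums(combos)))
    expect_identical(as.character(sc$risk_group),
        ifelse(rowSums(combos) <= 1, "good", "poor"))
    expect_error(scorePanel(calls, c("g1", "gX")), "missing")
    bad <- calls; bad[1L, 1L] <- 2L
    expect_error(scorePanel(bad, c("g1", "g2", "g3")), "binary")
})

test_that("stratified survival recovers the per-activation hazard ratio", {
    cfg <- simConfig(n_genes = 6L, n_tissue_specific = 0L,
        n_ectopic_candidates = 3L, n_true_prognostic = 3L,
        n_patients = 1000L, log_hazard_per_activation = log(2),
        covariate_effects = numeric(0), seed = 19L)
    sim <- simulateTumorCohort(cfg)
    cd <- clinicalData(sim$cohort)
    sc <- scorePanel(sim$truth$activation_matrix,
        rownames(sim$truth$activation_matrix))
    rep <- stratifiedSurvival(sc, cd$os_months, cd$event)
    hr <- rep$cox_count$hazard_ratio[[1L]]
    expect_gt(hr, 1.7); expect_lt(hr, 2.4)
    expect_lt(rep$logrank_risk$p_value, 1e-6)
    expect_equal(sum(rep$group_sizes), nrow(cd))
    # KM median survival non-increasing in activation count
    med <- vapply(rep$km_by_count, `[[`, numeric(1L), "median")
    med <- med[!is.na(med)]
    expect_true(all(diff(med) <= 0))
})

test_that("degenerate stratifications skip tests with notices, KM still emitted", {
    calls <- matrix(0L, 3L, 40L,
        dimnames = list(c("a", "b", "c"), sprintf("p%d", 1:40)))
    sc <- scorePanel(calls, c("a", "b", "c"))
    set.seed(3)
    rep <- stratifiedSurvival(sc, rexp(40) + 0.1, rbinom(40, 1, 0.5))
    expect_null(rep$logrank_risk)
    expect_null(rep$cox_count)
    expect_gt(length(rep$notices), 0L)
    expect_length(rep$km_by_count, 1L)
    expect_s3_class(rep$km_by_count[[1L]], "KMCurve")
})

test_that("risk-group relabeling flips the sign of the binary Cox coefficient", {
    sim <- simulateTumorCohort(smallCohortConfig(seed = 37L))
    cd <- clinicalData(sim$cohort)
    sc <- scorePanel(sim$truth$activation_matrix[1:3, ],
        rownames(sim$truth$activation_matrix)[1:3])
    fitA <- coxFit(cd$os_months, cd$event,
        cbind(poor = as.numeric(sc$risk_group == "poor")))
    fitB <- coxFit(cd$os_months, cd$event,
        cbind(good = as.numeric(sc$risk_group == "good")))
    expect_lt(abs(fitA$coefficients[[1L]] + fitB$coefficients[[1L]]), 1e-9)
})

test_that("clinical covariates derive stage, site and HPV classes correctly", {
    clin <- data.frame(
        patient_id = paste0("p", 1:6),
        t_stage = c(2, 1, 4, NA, 1, 2),
        n_stage = c(1, 2, 0, 1, 0, 0),
        m_stage = c(0, 0, 0, 0, 1, 0),
        hpv = c("positive", "negative", "NA", "negative", "positive",
            "negative"),
        site = c("tonsil", "other", "TBOT", "base of tongue", "other",
            "floor of mouth"),
        age = rep(60, 6), gender = rep("male", 6))
    cov <- deriveClinicalCovariates(clin)
    expect_identical(as.character(cov$stage_class),
        c("early", "late", "late", NA, "late", "early"))
    expect_identical(as.character(cov$site_class),
        c("TBOT", "other", "TBOT", "TBOT", "other", "other"))
    expect_identical(as.character(cov$hpv),
        c("positive", "negative", NA, "negative", "positive", "negative"))
    # M1 -> late is configurable
    cov2 <- deriveClinicalCovariates(clin, m1_is_late = FALSE)
    expect_identical(as.character(cov2$stage_class)[5L], "early")
})

test_that("subgroup analyses partition patients and flag degeneracy", {
    cfg <- simConfig(n_genes = 6L, n_tissue_specific = 0L,
        n_ectopic_candidates = 3L, n_true_prognostic = 3L,
        n_patients = 400L, hpv_activation_fraction = 0.97,
        covariate_effects = numeric(0), seed = 47L)
    sim <- simulateTumorCohort(cfg)
    cd <- clinicalData(sim$cohort)
    sc <- scorePanel(sim$truth$activation_matrix,
        rownames(sim$truth$activation_matrix))
    cov <- deriveClinicalCovariates(cd)

    sub <- subgroupAnalysis(sc, cov, cd$os_months, cd$event, "hpv")
    nKnown <- sum(!is.na(cov$hpv))
    expect_equal(sub$negative$n + sub$positive$n, nKnown)
    # HPV-positive tumours are nearly all panel-positive: flagged degenerate
    expect_true(sub$positive$degenerate)
    expect_false(sub$negative$degenerate)

    # identity filter: single-level variable reproduces the global analysis
    cov$all <- factor(rep("all", nrow(cov)))
    subAll <- subgroupAnalysis(sc, cov, cd$os_months, cd$event, "all")
    global <- stratifiedSurvival(sc, cd$os_months, cd$event)
    expect_equal(subAll$all$report$logrank_risk$p_value,
        global$logrank_risk$p_value)
    expect_error(subgroupAnalysis(sc, cov, cd$os_months, cd$event,
        "nope"), "unknown covariate")
})

test_that("multivariate Cox recovers joint panel and stage effects", {
    cfg <- simConfig(n_genes = 6L, n_tissue_specific = 0L,
        n_ectopic_candidates = 3L, n_true_prognostic = 3L,
        n_patients = 1000L, log_hazard_per_activation = log(2.2),
        covariate_effects = c(stage_late = 0.7), seed = 57L)
    sim <- simulateTumorCohort(cfg)
    cd <- clinicalData(sim$cohort)
    sc <- scorePanel(sim$truth$activation_matrix,
        rownames(sim$truth$activation_matrix))
    cov <- deriveClinicalCovariates(cd)
    mv <- multivariateCox(sc, cov, cd$os_months, cd$event,
        terms = c("age", "gender", "stage_class"))
    tab <- mv$table
    expect_lt(tab$p[tab$term == "risk_poor"], 0.05)
    expect_lt(tab$p[tab$term == "stage_class"], 0.05)
    expect_lt(abs(log(tab$hazard_ratio[tab$term == "stage_class"]) - 0.7),
        0.35)
    expect_equal(mv$n_used + mv$n_excluded, nrow(cd))

    # a panel fully determined by stage is collinear: refused, not estimated
    scDup <- sc
    scDup$risk_group <- factor(ifelse(cov$stage_class == "late",
        "poor", "good"), levels = c("good", "poor"))
    cc <- !is.na(cov$stage_class)
    expect_error(multivariateCox(scDup[cc, ], cov[cc, ],
        cd$os_months[cc], cd$event[cc], terms = "stage_class"),
        "rank-deficient")
    expect_error(multivariateCox(sc, cov, cd$os_months, cd$event,
        terms = c("age", "bogus")), "unknown covariate")
})
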