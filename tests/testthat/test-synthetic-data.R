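test_that("generators are deterministic given the seed and independent", {
    cfg <- smallPanelConfig(seed = 42L)
    p1 <- simulateNormalTissuePanel(cfg)
    p2 <- simulateNormalTissuePanel(cfg)
    expect_identical(exprValues(p1$panel), exprValues(p2$panel))

    cfgC <- smallCohortConfig(seed = 42L)
    c1 <- simulateTumorCohort(cfgC)
    c2 <- simulateTumorCohort(cfgC)
    expect_identical(exprValues(c1$cohort), exprValues(c2$cohort))
    expect_identical(clinicalData(c1$cohort), clinicalData(c2$cohort))

    ihc1 <- simulateIHCTable(cfgC, c1$truth$activation_matrix[1:3, ])
    ihc2 <- simulateIHCTable(cfgC, c1$truth$activation_matrix[1:3, ])
    expect_identical(ihc1, ihc2)
})

test_that("panel values are non-negative and planted genes are home-tissue predominant", {
    sim <- simulateNormalTissuePanel(simConfig(seed = 7L))
    x <- exprValues(sim$panel)
    expect_true(all(x >= 0))
    tissue <- tissueLabels(sim$panel)
    # exhaustive per-gene per-tissue mean comparison
    for (g in sim$truth$tissue_specific_genes) {
        home <- sim$truth$home_tissue[[g]]
        means <- tapply(x[g, ], tissue, mean)
        expect_identical(names(which.max(means)), home)
        expect_true(all(means[names(means) != home] < means[home]))
    }
})

test_that("nothing planted means no tissue-specific contrast", {
    cfg <- simConfig(n_tissues = 10L, n_samples_per_tissue = 4L,
        n_genes = 80L, n_tissue_specific = 0L, seed = 3L)
    sim <- simulateNormalTissuePanel(cfg)
    expect_length(sim$truth$tissue_specific_genes, 0L)
    x <- exprValues(sim$panel)
    tissue <- tissueLabels(sim$panel)
    # max/other-tissue contrast stays below the planting contrast
    planting_ratio <- exp(cfg$active_log_mean - cfg$background_log_mean) / 2
    ratios <- apply(x, 1L, function(v) {
        m <- tapply(v, tissue, mean)
        max(m) / max(sort(m, decreasing = TRUE)[2L], 1e-9)
    })
    expect_true(all(ratios < planting_ratio))
})

test_that("survival output is valid and censoring behaves", {
    sim <- simulateTumorCohort(smallCohortConfig(seed = 9L))
    cd <- clinicalData(sim$cohort)
    expect_true(all(cd$os_months > 0))
    expect_true(all(cd$event %in% c(0, 1)))
    # event only when the true event time was not censored away
    expect_true(all(cd$os_months[cd$event == 1] <=
        sim$truth$event_time[cd$event == 1] + 1e-9))

    degenerate <- simulateTumorCohort(smallCohortConfig(seed = 9L,
        censor_time = 0))
    cdd <- clinicalData(degenerate$cohort)
    expect_identical(sum(cdd$event), 0L)
    expect_error(logrankTest(cdd$os_months, cdd$event,
        rep(c("a", "b"), length.out = nrow(cdd))), "no events")
})

test_that("null effect gives hazard ratio near 1 and planted effect is recovered", {
    cfgNull <- simConfig(n_genes = 10L, n_tissue_specific = 0L,
        n_ectopic_candidates = 5L, n_true_prognostic = 3L,
        n_patients = 2000L, log_hazard_per_activation = 0,
        covariate_effects = numeric(0), seed = 21L)
    simN <- simulateTumorCohort(cfgNull)
    cd <- clinicalData(simN$cohort)
    count <- colSums(simN$truth$activation_matrix[
        simN$truth$true_prognostic_genes, ])
    fitN <- coxFit(cd$os_months, cd$event, cbind(count = count))
    expect_lt(abs(fitN$coefficients[[1L]]), 0.15)

    cfgE <- simConfig(n_genes = 10L, n_tissue_specific = 0L,
        n_ectopic_candidates = 5L, n_true_prognostic = 3L,
        n_patients = 2000L, log_hazard_per_activation = log(2.5),
        covariate_effects = numeric(0), seed = 22L)
    simE <- simulateTumorCohort(cfgE)
    cdE <- clinicalData(simE$cohort)
    countE <- colSums(simE$truth$activation_matrix[
        simE$truth$true_prognostic_genes, ])
    fitE <- coxFit(cdE$os_months, cdE$event, cbind(count = countE))
    expect_lt(abs(fitE$coefficients[[1L]] - log(2.5)), 0.1)
})

test_that("stronger per-activation hazard shortens fully-activated survival", {
    medians <- vapply(c(0, log(2), log(4)), function(beta) {
        sim <- simulateTumorCohort(simConfig(n_genes = 10L,
            n_tissue_specific = 0L, n_ectopic_candidates = 3L,
            n_true_prognostic = 3L, n_patients = 2000L,
            log_hazard_per_activation = beta,
            covariate_effects = numeric(0), seed = 33L))
        count <- colSums(sim$truth$activation_matrix)
        median(sim$truth$event_time[count == 3L])
    }, numeric(1L))
    expect_true(all(diff(medians) < 0))
})

test_that("log-rank p-values on a null activation split are uniform", {
    cfg0 <- simConfig(n_genes = 4L, n_tissue_specific = 0L,
        n_ectopic_candidates = 4L, n_true_prognostic = 1L,
        n_patients = 60L, log_hazard_per_activation = 0,
        covariate_effects = numeric(0), dropout_rate = 0, seed = 1L)
    pvals <- vapply(seq_len(500L), function(i) {
        cfg <- cfg0; cfg$seed <- 1000L + i
        sim <- simulateTumorCohort(cfg)
        cd <- clinicalData(sim$cohort)
        a <- sim$truth$activation_matrix[1L, ]
        if (min(table(a)) < 2L) return(NA_real_)
        logrankTest(cd$os_months, cd$event, a)$p_value
    }, numeric(1L))
    pvals <- pvals[!is.na(pvals)]
    expect_gt(length(pvals), 450L)
    expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("invalid configurations name the offending field", {
    expect_error(simConfig(n_patients = 0), "n_patients")
    expect_error(simConfig(activation_fraction = 1.2),
        "activation_fraction")
    expect_error(simConfig(baseline_hazard = -1), "baseline_hazard")
    expect_error(simConfig(n_true_prognostic = 10,
        n_ectopic_candidates = 5), "n_true_prognostic")
})

test_that("IHC generator couples staining to activation truth", {
    cfg <- smallCohortConfig(seed = 5L, ihc_coupling = 0.95)
    sim <- simulateTumorCohort(cfg)
    truth <- sim$truth$activation_matrix[1:3, ]
    rownames(truth) <- c("AREG", "CCNA1", "DDX20")
    tab <- simulateIHCTable(cfg, truth)
    expect_true(all(tab$intensity %in% 0:3))
    expect_true(all(tab$percent_positive >= 0 & tab$percent_positive <= 100))
    sc <- scoreIHCPatients(tab)
    act <- truth[cbind(sc$calls$marker, sc$calls$patient_id)]
    highRate <- tapply(sc$calls$call == "high", act, mean)
    # direct 2x2 comparison: activated markers are scored high far more often
    expect_gt(highRate[["1"]], highRate[["0"]] + 0.3)

    cfg0 <- smallCohortConfig(seed = 5L, ihc_coupling = 0)
    tab0 <- simulateIHCTable(cfg0, truth)
    sc0 <- scoreIHCPatients(tab0)
    act0 <- truth[cbind(sc0$calls$marker, sc0$calls$patient_id)]
    tt <- table(sc0$calls$call, act0)
    expect_gt(suppressWarnings(chisq.test(tt))$p.value, 0.001)

    expect_error(simulateIHCTable(cfg, truth, markers = c("AREG", "XYZ")),
        "missing")
})
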