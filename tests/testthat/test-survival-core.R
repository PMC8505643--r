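test_that("Kaplan-Meier matches the product-limit formula by hand", {
    # times (1,event),(2,censor),(3,event): S = 1 -> 2/3 on [1,3) -> 0
    km <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
    expect_equal(kmSurvival(km, 0.5), 1)
    expect_equal(kmSurvival(km, 1), 2 / 3)
    expect_equal(kmSurvival(km, 2.9), 2 / 3)
    expect_equal(kmSurvival(km, 3), 0)

    # all censored: S identically 1
    km0 <- kaplanMeier(c(2, 5, 9), c(0, 0, 0))
    expect_true(all(kmSurvival(km0, c(0, 4, 100)) == 1))

    # doubling every record leaves the curve unchanged
    t1 <- c(1, 2, 2, 4, 7); e1 <- c(1, 1, 0, 1, 0)
    kmA <- kaplanMeier(t1, e1)
    kmB <- kaplanMeier(rep(t1, 2L), rep(e1, 2L))
    grid <- seq(0, 8, by = 0.5)
    expect_equal(kmSurvival(kmA, grid), kmSurvival(kmB, grid))

    # censored record beyond the last event adds no step: the event times
    # are unchanged and the curve stays a valid survival function (it does
    # shift the at-risk counts, hence the values, as the estimator must)
    kmC <- kaplanMeier(c(t1, 50), c(e1, 0))
    expect_identical(kmC$steps$time[kmC$steps$n_event > 0],
        kmA$steps$time[kmA$steps$n_event > 0])
    sC <- kmSurvival(kmC, grid)
    expect_true(all(diff(sC) <= 0) && sC[1L] == 1)

    expect_error(kaplanMeier(numeric(0), numeric(0)), "empty")
})

test_that("log-rank equals the brute-force O/E/V oracle on a fixture", {
    # 8-patient two-group fixture with ties and censoring
    time <- c(3, 5, 5, 8, 10, 12, 12, 15)
    event <- c(1, 1, 0, 1, 1, 0, 1, 1)
    grp <- c("a", "b", "a", "b", "a", "b", "a", "b")
    res <- logrankTest(time, event, grp)
    orc <- oracleLogrank2(time, event, grp == "a")
    expect_equal(res$chi_square, orc$chi_square, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)
    expect_equal(unname(res$observed[["a"]]), orc$observed)
    expect_equal(unname(res$expected[["a"]]), orc$expected, tolerance = 1e-10)
    # totals balance
    expect_equal(sum(res$observed), sum(res$expected))
    expect_equal(sum(res$observed), sum(event))

    # identical groups: statistic 0, p 1
    same <- logrankTest(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
        rep(c("x", "y"), each = 3L))
    expect_equal(same$chi_square, 0, tolerance = 1e-12)
    expect_equal(same$p_value, 1)

    # invariant under group relabeling
    swap <- logrankTest(time, event, ifelse(grp == "a", "b", "a"))
    expect_equal(swap$chi_square, res$chi_square, tolerance = 1e-12)

    expect_error(logrankTest(c(1, 2), c(1, 1), c("a", "a")),
        "fewer than 2")
    expect_error(logrankTest(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("batched two-group log-rank matches survdiff and the oracle", {
    set.seed(17)
    n <- 60L
    time <- round(rexp(n, 0.05), 0) + 1
    event <- rbinom(n, 1L, 0.7)
    Z <- matrix(runif(n * 25L) > 0.5, n, 25L)
    keep <- colSums(Z) > 2 & colSums(!Z) > 2
    Z <- Z[, keep, drop = FALSE]
    batch <- ectoMark:::.logrank2Batch(time, event, Z)
    for (j in seq_len(ncol(Z))) {
        ref <- logrankTest(time, event, Z[, j])
        orc <- oracleLogrank2(time, event, Z[, j])
        expect_equal(batch$chi_square[j], ref$chi_square,
            tolerance = 1e-10)
        expect_equal(batch$chi_square[j], orc$chi_square,
            tolerance = 1e-10)
        expect_equal(batch$observed[j], orc$observed)
        expect_equal(batch$expected[j], orc$expected, tolerance = 1e-10)
    }
})

test_that("log-rank p agrees with a permutation p within Monte-Carlo error", {
    set.seed(23)
    n <- 30L
    time <- rexp(n, 0.05) + 0.5
    event <- rbinom(n, 1L, 0.8)
    grp <- rep(c(TRUE, FALSE), each = 15L)
    obs <- logrankTest(time, event, grp)
    B <- 10000L
    perms <- vapply(seq_len(B), function(i) sample(grp), logical(n))
    null <- ectoMark:::.logrank2Batch(time, event, perms)$chi_square
    pPerm <- (1 + sum(null >= obs$chi_square - 1e-12)) / (1 + B)
    se <- sqrt(pPerm * (1 - pPerm) / B)
    expect_lt(abs(pPerm - obs$p_value), max(4 * se, 0.02))
})

test_that("Cox fit recovers a true hazard ratio and is well calibrated", {
    d <- simTwoGroupExp(2000L, hr = 2.5, seed = 31L)
    fit <- coxFit(d$time, d$event, cbind(group = d$group))
    expect_true(fit$converged)
    expect_gt(fit$hazard_ratio[[1L]], 2.2)
    expect_lt(fit$hazard_ratio[[1L]], 2.8)
    expect_equal(unname(fit$hazard_ratio),
        unname(exp(fit$coefficients)))

    # null covariate: |beta| < 3 SE in at least 95% of replicates
    ok <- vapply(1:100, function(i) {
        set.seed(500 + i)
        n <- 300L
        tEvent <- rexp(n, 0.03)
        time <- pmin(tEvent, 60)
        event <- as.numeric(tEvent <= 60)
        x <- rnorm(n)
        f <- coxFit(pmax(time, 1e-9), event, cbind(x = x))
        abs(f$coefficients[[1L]]) < 3 * f$se[[1L]]
    }, logical(1L))
    expect_gte(mean(ok), 0.95)
})

test_that("Efron and Breslow coincide without ties and beta is scale-equivariant", {
    set.seed(41)
    n <- 150L
    x <- rnorm(n)
    tEvent <- rexp(n, 0.05 * exp(0.5 * x))
    time <- pmin(tEvent, 40); event <- as.numeric(tEvent <= 40)
    time <- time + runif(n, 0, 1e-4)  # break ties
    fe <- coxFit(time, event, cbind(x = x), ties = "efron")
    fb <- coxFit(time, event, cbind(x = x), ties = "breslow")
    expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)

    f10 <- coxFit(time, event, cbind(x = 10 * x))
    expect_equal(f10$coefficients[[1L]], fe$coefficients[[1L]] / 10,
        tolerance = 1e-8)
})

test_that("Cox degenerate inputs are refused or flagged, not silent", {
    d <- simTwoGroupExp(100L, hr = 2, seed = 51L)
    expect_error(coxFit(d$time, d$event, cbind(const = rep(1, 100L))),
        "constant covariate")
    expect_error(coxFit(d$time, rep(0, 100L), cbind(g = d$group)),
        "at least one event")
    expect_error(coxFit(d$time, d$event,
        cbind(a = d$group, b = d$group)), "rank-deficient")
    # perfect separation: all events in one group, flagged
    time <- c(rexp(30, 1) + 10, rexp(30, 1))
    event <- rep(c(0, 1), each = 30L)
    grp <- rep(c(0, 1), each = 30L)
    fit <- coxFit(pmax(time, 1e-9), event, cbind(g = grp))
    expect_true(fit$separation || !fit$converged)
})
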