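# Independent brute-force oracles used to pin down the implementations.
# These deliberately share no code with the package internals.

# Two-group log-rank by explicit accumulation of O/E/V over event times.
oracleLogrank2 <- function(time, event, group1) {
    stopifnot(is.logical(group1))
    eventTimes <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in eventTimes) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & group1)
        d <- sum(event == 1 & time == t)
        d1 <- sum(event == 1 & time == t & group1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chisq <- if (V > 0) (O - E)^2 / V else 0
    list(observed = O, expected = E, variance = V, chi_square = chisq,
        p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# Step-by-step weighted running sum; ES = signed extremum.
oracleGseaES <- function(metric, members, weight = 1) {
    ord <- order(-metric, names(metric))
    metric <- metric[ord]
    hit <- names(metric) %in% members
    w <- abs(metric)^weight
    denomHit <- sum(w[hit])
    nMiss <- sum(!hit)
    rs <- 0; hi <- -Inf; lo <- Inf
    for (i in seq_along(metric)) {
        rs <- rs + if (hit[i]) w[i] / denomHit else -1 / nMiss
        hi <- max(hi, rs); lo <- min(lo, rs)
    }
    # same tie policy as the engine: an exact positive/negative tie
    # resolves to the positive deviation
    unname(if (hi >= -lo - 1e-12) hi else lo)
}

# IHC decision rules re-derived independently as explicit lookup logic.
oracleIHCCall <- function(marker, intensity, percent) {
    if (marker == "AREG") return(if (percent > 50) "high" else "low")
    if (marker == "CCNA1") {
        prop <- if (percent <= 10) 1 else 2
    } else if (marker == "DDX20") {
        prop <- if (percent <= 33) 1 else if (percent <= 66) 2 else 3
    } else stop("unknown marker")
    if (intensity * prop >= 3) "high" else "low"
}

# Small reusable configs -----------------------------------------------

smallPanelConfig <- function(seed = 1L)
    simConfig(n_tissues = 12L, n_samples_per_tissue = 4L, n_genes = 120L,
        n_tissue_specific = 15L, seed = seed)

smallCohortConfig <- function(seed = 1L, ...)
    simConfig(n_genes = 60L, n_tissue_specific = 0L,
        n_ectopic_candidates = 20L, n_true_prognostic = 3L,
        n_patients = 120L, covariate_effects = numeric(0), seed = seed, ...)

# Exponential two-group survival data with a known hazard ratio.
simTwoGroupExp <- function(n, hr, baseline = 0.02, censor = 80,
        seed = 1L) {
    set.seed(seed)
    g <- rep(c(0, 1), length.out = n)
    tEvent <- rexp(n, rate = baseline * hr^g)
    time <- pmin(tEvent, censor)
    list(time = pmax(time, 1e-9), event = as.numeric(tEvent <= censor),
        group = g)
}

# grouped expression matrix with planted log2 shifts in the positive group
makeGroupedExpr <- function(nGenes = 50L, nPer = 30L, shiftGenes = 5L,
        log2shift = 2, sdlog = 0.3, seed = 1L) {
    set.seed(seed)
    n <- 2L * nPer
    base <- runif(nGenes, 2, 6)
    lx <- matrix(rnorm(nGenes * n, rep(base, n), sdlog), nGenes, n)
    groups <- rep(c("positive", "negative"), each = nPer)
    if (shiftGenes > 0L)
        lx[seq_len(shiftGenes), groups == "positive"] <-
            lx[seq_len(shiftGenes), groups == "positive"] + log2shift
    x <- 2^lx - 1
    dimnames(x) <- list(sprintf("g%03d", seq_len(nGenes)),
        sprintf("p%02d", seq_len(n)))
    list(expr = x, groups = groups)
}
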