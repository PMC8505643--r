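#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

.checkSurv <- function(time, event) {
    if (!length(time))
        stop("empty survival input", call. = FALSE)
    if (length(event) != length(time))
        stop("time and event must have equal length", call. = FALSE)
    if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
        stop("survival times must be finite and positive", call. = FALSE)
    if (!all(event %in% c(0, 1)))
        stop("event indicator must be 0/1", call. = FALSE)
    invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive survival times (months).
#' @param event 0/1 event indicator.
#' @return list of class \code{"KMCurve"} with the step-function table
#'   (\code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{surv}) including the implicit S(0) = 1 start, and the median
#'   survival (smallest time with S(t) <= 0.5, \code{NA} if never reached).
#' @examples
#' km <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
#' kmSurvival(km, 2.5)  # 2/3
#' @export
kaplanMeier <- function(time, event) {
    .checkSurv(time, event)
    fit <- survfit(Surv(time, event) ~ 1, conf.type = "none")
    steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
        n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
    med <- steps$time[steps$surv <= 0.5]
    structure(list(steps = steps, n = length(time),
        events = sum(event),
        median = if (length(med)) med[1L] else NA_real_),
        class = "KMCurve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous: S(t) is the product over event times <= t.
#'
#' @param km a \code{\link{kaplanMeier}} result.
#' @param t times at which to evaluate.
#' @return survival probabilities.
#' @export
kmSurvival <- function(km, t) {
    s <- c(1, km$steps$surv)
    idx <- findInterval(t, km$steps$time)
    s[idx + 1L]
}

#' @export
print.KMCurve <- function(x, ...) {
    cat("Kaplan-Meier curve:", x$n, "subjects,", x$events, "events; median",
        if (is.na(x$median)) "not reached" else round(x$median, 2), "\n")
    invisible(x)
}

#' k-group log-rank test
#'
#' Standard log-rank comparison of survival across k >= 2 groups via
#' observed vs expected event counts accumulated over distinct event times
#' (hypergeometric variance; chi-square on k-1 df).
#'
#' Degenerate inputs (an empty group, or zero events overall) raise an
#' explicit statistical-degeneracy error rather than returning NaN.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator.
#' @param group group labels (>= 2 distinct values).
#' @return list of class \code{"LogrankResult"}: \code{chi_square},
#'   \code{df}, \code{p_value}, per-group \code{observed} and
#'   \code{expected} event counts, \code{n} per group.
#' @export
logrankTest <- function(time, event, group) {
    .checkSurv(time, event)
    group <- as.factor(group)
    if (nlevels(droplevels(group)) < 2L)
        stop("log-rank degeneracy: fewer than 2 non-empty groups",
            call. = FALSE)
    group <- droplevels(group)
    if (sum(event) < 1)
        stop("log-rank degeneracy: no events", call. = FALSE)
    sd <- survdiff(Surv(time, event) ~ group)
    df <- nlevels(group) - 1L
    structure(list(
        chi_square = sd$chisq,
        df = df,
        p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
        observed = stats::setNames(as.numeric(sd$obs), levels(group)),
        expected = stats::setNames(as.numeric(sd$exp), levels(group)),
        n = stats::setNames(as.numeric(sd$n), levels(group))),
        class = "LogrankResult")
}

#' @export
print.LogrankResult <- function(x, ...) {
    cat("Log-rank test: chi-square =", signif(x$chi_square, 4), "on", x$df,
        "df, p =", signif(x$p_value, 4), "\n")
    invisible(x)
}

# Vectorised two-group log-rank over many dichotomisations of one cohort.
# memberships: n x m logical/0-1 matrix, one column per split (TRUE = high
# group). Returns per-split observed, expected, variance, chi-square, p.
# Same O/E/V accumulation as survdiff; used by the threshold scan and by
# permutation tests where thousands of splits share one (time, event).
.logrank2Batch <- function(time, event, memberships) {
    memberships <- as.matrix(memberships) * 1
    ord <- order(time)
    time <- time[ord]; event <- event[ord]
    Z <- memberships[ord, , drop = FALSE]
    tf <- factor(time, levels = unique(time))
    # totals per distinct time (all times, to walk the risk sets)
    dAll <- rowsum(event, tf, reorder = FALSE)[, 1L]
    nAtRiskIdx <- rev(cumsum(rev(table(tf))))  # n at risk entering each time
    d1 <- rowsum(Z * event, tf, reorder = FALSE)
    # at-risk counts in group 1 entering each distinct time
    cs <- apply(Z[nrow(Z):1L, , drop = FALSE], 2L, cumsum)
    cs <- matrix(cs, nrow = nrow(Z))
    cs <- cs[nrow(cs):1L, , drop = FALSE]
    firstIdx <- match(levels(tf), as.character(tf))
    n1 <- cs[firstIdx, , drop = FALSE]
    keep <- dAll > 0
    dj <- dAll[keep]; nj <- as.numeric(nAtRiskIdx[keep])
    d1j <- d1[keep, , drop = FALSE]
    n1j <- n1[keep, , drop = FALSE]
    pj <- n1j / nj
    O <- colSums(d1j)
    E <- colSums(dj * pj)
    vmult <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
    V <- colSums(vmult * pj * (1 - pj))
    chisq <- ifelse(V > 0, (O - E)^2 / V, 0)
    p <- ifelse(V > 0, stats::pchisq(chisq, 1L, lower.tail = FALSE), NA_real_)
    list(observed = O, expected = E, variance = V, chi_square = chisq,
        p_value = p)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit with the Efron tie correction by default
#' (Breslow available), reporting per-covariate Wald tests and the
#' likelihood-ratio test of the full model. Monotone-likelihood /
#' separation problems are surfaced through the \code{converged} and
#' \code{separation} flags rather than silently returning huge estimates.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (complete cases only; the caller handles exclusion).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list of class \code{"CoxFit"}: \code{coefficients},
#'   \code{hazard_ratio}, \code{se}, \code{z}, \code{p}, \code{loglik}
#'   (null, fitted), \code{lr_test} (statistic, df, p), \code{converged},
#'   \code{separation}, \code{ties}, \code{n}, \code{events}.
#' @export
coxFit <- function(time, event, covariates, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    .checkSurv(time, event)
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    if (anyNA(X))
        stop("missing covariate values; exclude incomplete cases first",
            call. = FALSE)
    if (sum(event) < 1)
        stop("Cox fit requires at least one event", call. = FALSE)
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant covariate(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    if (qr(X)$rank < ncol(X))
        stop("rank-deficient covariate matrix (collinear covariates)",
            call. = FALSE)
    warned <- character(0)
    fit <- withCallingHandlers(
        coxph(Surv(time, event) ~ X, ties = ties,
            control = coxph.control(eps = 1e-10, iter.max = 50)),
        warning = function(w) {
            warned <<- c(warned, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    beta <- stats::setNames(as.numeric(fit$coefficients), colnames(X))
    se <- sqrt(diag(as.matrix(fit$var)))
    z <- beta / se
    separation <- any(grepl("infinite|did not converge", warned)) |
        any(abs(beta) > 15)
    lrStat <- 2 * (fit$loglik[2L] - fit$loglik[1L])
    structure(list(
        coefficients = beta,
        hazard_ratio = exp(beta),
        se = stats::setNames(se, colnames(X)),
        z = z,
        p = 2 * stats::pnorm(-abs(z)),
        loglik = fit$loglik,
        lr_test = list(statistic = lrStat, df = ncol(X),
            p = stats::pchisq(lrStat, ncol(X), lower.tail = FALSE)),
        converged = !any(grepl("Ran out of iterations|did not converge",
            warned)),
        separation = separation,
        ties = ties,
        n = length(time),
        events = sum(event)),
        class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
    cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
        ", events = ", x$events, "\n", sep = "")
    tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratio,
        se = x$se, z = x$z, p = x$p)
    print(signif(tab, 4))
    if (x$separation) cat("  warning: possible separation / monotone",
        "likelihood; estimates unreliable\n")
    invisible(x)
}
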