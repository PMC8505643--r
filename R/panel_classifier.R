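#' Score patients by activation count of a gene panel
#'
#' Counts activated panel genes per patient and assigns the risk group:
#' 0 or 1 activation = "good" prognosis, 2 or more = "poor". This is the
#' grouping rule of the 3-gene (AREG/CCNA1/DDX20) classifier.
#'
#' @param activations an \code{\link{callActivations}} result or a binary
#'   genes x patients matrix.
#' @param panelGenes panel gene IDs (rows of the activation matrix).
#' @return data.frame of class \code{"PanelScores"}: patient_id,
#'   activation_count, risk_group (factor good/poor).
#' @export
scorePanel <- function(activations, panelGenes) {
    calls <- if (inherits(activations, "ActivationMatrix"))
        activations$calls else as.matrix(activations)
    miss <- setdiff(panelGenes, rownames(calls))
    if (length(miss))
        stop("panel gene(s) missing from activation matrix: ",
            paste(miss, collapse = ", "), call. = FALSE)
    sub <- calls[panelGenes, , drop = FALSE]
    if (!all(sub %in% c(0, 1)))
        stop("activation calls must be binary", call. = FALSE)
    count <- as.integer(colSums(sub))
    out <- data.frame(patient_id = colnames(calls),
        activation_count = count,
        risk_group = factor(ifelse(count <= 1L, "good", "poor"),
            levels = c("good", "poor")),
        stringsAsFactors = FALSE)
    class(out) <- c("PanelScores", "data.frame")
    out
}

#' Kaplan-Meier / log-rank / Cox stratification by activation count
#'
#' Emits KM curves per activation-count group and per risk group, the
#' k-group and two-group log-rank tests, a Cox model with the activation
#' count as a single numeric covariate (hazard ratio per additional
#' activated gene), and a Cox model on the binary risk group. Degenerate
#' configurations (a single populated group, no events) skip the affected
#' test with an explicit notice instead of failing.
#'
#' @param scores a \code{\link{scorePanel}} result (or any data.frame with
#'   patient_id, activation_count, risk_group).
#' @param time,event survival data aligned with \code{scores} rows.
#' @return list of class \code{"StratificationReport"}.
#' @export
stratifiedSurvival <- function(scores, time, event) {
    .checkSurv(time, event)
    if (nrow(scores) != length(time))
        stop("scores and survival must be aligned on patients",
            call. = FALSE)
    notices <- character(0)
    countGroup <- factor(scores$activation_count,
        levels = sort(unique(scores$activation_count)))
    kmByCount <- lapply(split(seq_along(time), countGroup), function(idx)
        kaplanMeier(time[idx], event[idx]))
    kmByRisk <- lapply(split(seq_along(time), scores$risk_group,
            drop = FALSE),
        function(idx) if (length(idx)) kaplanMeier(time[idx], event[idx])
            else NULL)

    tryLR <- function(grp, label) {
        tryCatch(logrankTest(time, event, grp), error = function(e) {
            notices <<- c(notices, paste0(label, " skipped: ",
                conditionMessage(e)))
            NULL
        })
    }
    lrCount <- tryLR(countGroup, "k-group log-rank")
    lrRisk <- tryLR(scores$risk_group, "two-group log-rank")

    tryCox <- function(covs, label) {
        tryCatch(coxFit(time, event, covs), error = function(e) {
            notices <<- c(notices, paste0(label, " skipped: ",
                conditionMessage(e)))
            NULL
        })
    }
    coxCount <- tryCox(cbind(activation_count = scores$activation_count),
        "Cox on activation count")
    coxRisk <- tryCox(cbind(risk_poor =
        as.numeric(scores$risk_group == "poor")), "Cox on risk group")

    structure(list(
        km_by_count = kmByCount,
        km_by_risk = kmByRisk,
        logrank_count = lrCount,
        logrank_risk = lrRisk,
        cox_count = coxCount,
        cox_risk = coxRisk,
        group_sizes = table(countGroup),
        risk_sizes = table(scores$risk_group),
        n = length(time), events = sum(event),
        notices = notices),
        class = "StratificationReport")
}

#' @export
print.StratificationReport <- function(x, ...) {
    cat("Stratification of", x$n, "patients (", x$events, "events )\n")
    cat("  by activation count:",
        paste(names(x$group_sizes), as.integer(x$group_sizes),
            sep = "=", collapse = ", "), "\n")
    cat("  risk groups:",
        paste(names(x$risk_sizes), as.integer(x$risk_sizes),
            sep = "=", collapse = ", "), "\n")
    if (!is.null(x$logrank_risk))
        cat("  two-group log-rank p =", signif(x$logrank_risk$p_value, 4),
            "\n")
    if (!is.null(x$cox_count))
        cat("  Cox HR per activation =",
            signif(x$cox_count$hazard_ratio[[1L]], 4),
            "( p =", signif(x$cox_count$p[[1L]], 4), ")\n")
    for (msg in x$notices) cat("  note:", msg, "\n")
    invisible(x)
}

#' Derive analysis covariates from a clinical table
#'
#' Dichotomises TNM stage into early ((T1 or T2) and (N0 or N1)) versus
#' late ((T >= 3) or (N >= 2)); distant metastasis (M1) is classed late
#' regardless of T/N (configurable). Site is classed TBOT for tonsil /
#' base-of-tongue tumours. Unknown inputs propagate as NA and are excluded
#' from stratified analyses downstream.
#'
#' @param clinical data.frame with t_stage, n_stage, m_stage, hpv, site,
#'   age, gender (e.g. \code{\link{clinicalData}} output).
#' @param m1_is_late treat M1 as late stage (default TRUE).
#' @return data.frame of class \code{"CovariateTable"}: patient_id,
#'   stage_class (early/late), hpv, site_class (TBOT/other), age, gender,
#'   grade if present.
#' @export
deriveClinicalCovariates <- function(clinical, m1_is_late = TRUE) {
    tn <- suppressWarnings(cbind(as.numeric(clinical$t_stage),
        as.numeric(clinical$n_stage)))
    m <- suppressWarnings(as.numeric(clinical$m_stage))
    early <- tn[, 1L] %in% c(1, 2) & tn[, 2L] %in% c(0, 1)
    late <- (!is.na(tn[, 1L]) & tn[, 1L] >= 3) |
        (!is.na(tn[, 2L]) & tn[, 2L] >= 2)
    if (m1_is_late) late <- late | (!is.na(m) & m == 1)
    stage <- rep(NA_character_, nrow(clinical))
    stage[late] <- "late"
    stage[!late & early & !is.na(tn[, 1L]) & !is.na(tn[, 2L])] <- "early"
    siteRaw <- tolower(as.character(clinical$site))
    tbot <- c("tbot", "tonsil", "base of tongue", "base_of_tongue")
    site <- ifelse(siteRaw %in% tbot, "TBOT",
        ifelse(is.na(siteRaw) | siteRaw %in% c("na", "unknown", ""),
            NA_character_, "other"))
    hpv <- as.character(clinical$hpv)
    hpv[!hpv %in% c("positive", "negative")] <- NA_character_
    out <- data.frame(patient_id = clinical$patient_id,
        stage_class = factor(stage, levels = c("early", "late")),
        hpv = factor(hpv, levels = c("negative", "positive")),
        site_class = factor(site, levels = c("other", "TBOT")),
        age = clinical$age,
        gender = factor(clinical$gender),
        stringsAsFactors = FALSE)
    if ("grade" %in% colnames(clinical)) out$grade <- clinical$grade
    class(out) <- c("CovariateTable", "data.frame")
    out
}

#' Panel stratification within clinical subgroups
#'
#' Reruns \code{\link{stratifiedSurvival}} within each level of a clinical
#' covariate (stage early/late, HPV status, TBOT vs other site). Patients
#' with an unknown level are excluded. Subgroups in which the classifier
#' degenerates (fewer than two populated risk groups, or a risk group
#' smaller than \code{min_group_size}) are flagged, mirroring the
#' near-universal panel positivity of HPV-positive tumours.
#'
#' @param scores a \code{\link{scorePanel}} result.
#' @param covariates a \code{\link{deriveClinicalCovariates}} result
#'   aligned with \code{scores}.
#' @param time,event survival data aligned with \code{scores}.
#' @param variable one of \code{"stage_class"}, \code{"hpv"},
#'   \code{"site_class"} (any factor column of \code{covariates}).
#' @param min_group_size risk-group size below which the subgroup is
#'   flagged degenerate.
#' @return named list, one \code{"SubgroupReport"} per level: the
#'   stratification report, the subgroup size and a \code{degenerate} flag.
#' @export
subgroupAnalysis <- function(scores, covariates, time, event, variable,
        min_group_size = 5L) {
    if (!variable %in% colnames(covariates))
        stop("unknown covariate: ", variable, call. = FALSE)
    lev <- covariates[[variable]]
    if (!is.factor(lev)) lev <- factor(lev)
    out <- lapply(levels(lev), function(lv) {
        idx <- which(!is.na(lev) & lev == lv)
        if (!length(idx))
            return(structure(list(level = lv, n = 0L, degenerate = TRUE,
                report = NULL, reason = "empty subgroup"),
                class = "SubgroupReport"))
        sub <- scores[idx, , drop = FALSE]
        riskTab <- table(sub$risk_group)
        degenerate <- sum(riskTab > 0) < 2L || any(riskTab < min_group_size)
        rep <- stratifiedSurvival(sub, time[idx], event[idx])
        structure(list(level = lv, n = length(idx),
            degenerate = degenerate, report = rep,
            reason = if (degenerate)
                "fewer than two adequately populated risk groups" else NA),
            class = "SubgroupReport")
    })
    names(out) <- levels(lev)
    out
}

#' Multivariate Cox analysis of the panel classifier
#'
#' Fits a Cox model with the binary panel risk group (poor vs good; or the
#' 0-3 activation count if \code{use_count = TRUE}) together with clinical
#' covariates: age (continuous), gender, stage (early/late), HPV and site
#' as indicator codes. Complete-case exclusion; exclusion counts are
#' reported. Collinear covariates raise an error; per-covariate separation
#' is flagged on the fit.
#'
#' @param scores a \code{\link{scorePanel}} result.
#' @param covariates a \code{\link{deriveClinicalCovariates}} result.
#' @param time,event survival data aligned with \code{scores}.
#' @param terms covariate names among \code{"age"}, \code{"gender"},
#'   \code{"stage_class"}, \code{"hpv"}, \code{"site_class"}.
#' @param use_count use the 0-3 activation count instead of the binary
#'   risk group.
#' @return list of class \code{"MultivariateReport"}: the \code{CoxFit},
#'   per-term hazard ratios with 95\% CIs, and complete-case counts.
#' @export
multivariateCox <- function(scores, covariates, time, event,
        terms = c("age", "gender", "stage_class"), use_count = FALSE) {
    known <- c("age", "gender", "stage_class", "hpv", "site_class")
    bad <- setdiff(terms, known)
    if (length(bad))
        stop("unknown covariate term(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    X <- data.frame(row.names = seq_along(time))
    X$panel <- if (use_count) scores$activation_count
        else as.numeric(scores$risk_group == "poor")
    for (tm in terms) {
        v <- covariates[[tm]]
        X[[tm]] <- if (is.factor(v)) {
            ref <- levels(v)[1L]
            as.numeric(v != ref)
        } else as.numeric(v)
    }
    colnames(X)[1L] <- if (use_count) "activation_count" else "risk_poor"
    cc <- stats::complete.cases(X)
    nExcluded <- sum(!cc)
    if (!any(cc))
        stop("no complete cases for the multivariate model", call. = FALSE)
    fit <- coxFit(time[cc], event[cc], X[cc, , drop = FALSE])
    ci <- cbind(lower = exp(fit$coefficients - 1.96 * fit$se),
        upper = exp(fit$coefficients + 1.96 * fit$se))
    structure(list(fit = fit,
        table = data.frame(term = names(fit$coefficients),
            hazard_ratio = fit$hazard_ratio, ci_lower = ci[, "lower"],
            ci_upper = ci[, "upper"], p = fit$p, row.names = NULL),
        n_used = sum(cc), n_excluded = nExcluded),
        class = "MultivariateReport")
}

#' @export
print.MultivariateReport <- function(x, ...) {
    cat("Multivariate Cox model:", x$n_used, "complete cases (",
        x$n_excluded, "excluded )\n")
    tab <- x$table
    tab[, -1L] <- signif(tab[, -1L], 4)
    print(tab)
    invisible(x)
}
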