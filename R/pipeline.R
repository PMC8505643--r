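#' Run the full discovery pipeline on synthetic or supplied data
#'
#' Orchestrates the stages of the biomarker discovery procedure on one
#' configuration: synthetic data generation (or supplied inputs), normal
#' tissue cataloguing, the threshold-stability screen, activation calling,
#' panel classification with subgroup and multivariate analyses, IHC
#' scoring, and the positive-vs-negative expression signature with GSEA.
#' Every report embeds the configuration, the seed and the package
#' version; reports are written as JSON/TSV into \code{outDir}.
#'
#' Rerunning into a directory that already holds a pipeline report refuses
#' unless \code{overwrite = TRUE}; it never silently overwrites.
#'
#' @param simCfg a \code{\link{simConfig}} describing the synthetic study.
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing and returns results only.
#' @param screenCrit a \code{\link{screenCriteria}}.
#' @param panelSize number of top-ranked selected genes forming the
#'   classifier panel (3 in the published test).
#' @param activationStrategy strategy for \code{\link{deriveActivationRule}}.
#' @param doSubgroups,doMultivariate,doSignature,doIHC stage toggles.
#' @param gseaPermutations permutations for the signature GSEA.
#' @param overwrite allow rerunning into a non-empty output directory.
#' @return list of class \code{"PipelineResult"} with each stage's report.
#' @export
runPipeline <- function(simCfg = simConfig(), outDir = NULL,
        screenCrit = screenCriteria(), panelSize = 3L,
        activationStrategy = c("background_based", "interval_midpoint",
            "fixed_percentile"),
        doSubgroups = TRUE, doMultivariate = TRUE, doSignature = TRUE,
        doIHC = TRUE, gseaPermutations = 200L, overwrite = FALSE) {
    activationStrategy <- match.arg(activationStrategy)
    validateSimConfig(simCfg)
    if (!is.null(outDir)) {
        sentinel <- file.path(outDir, "pipeline_report.json")
        if (file.exists(sentinel) && !overwrite)
            stop("output directory already holds a pipeline report; ",
                "use overwrite = TRUE or a fresh directory", call. = FALSE)
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    }
    log <- character(0)
    note <- function(...) log <<- c(log, paste0(...))

    ## stage 1: synthetic study data
    panelSim <- simulateNormalTissuePanel(simCfg)
    cohortSim <- simulateTumorCohort(simCfg)
    cohort <- cohortSim$cohort
    cd <- clinicalData(cohort)
    note("simulate: ", nrow(cohort), " genes, ", ncol(cohort),
        " patients, ", sum(cd$event), " events")

    ## stage 2: normal-tissue catalog
    catalog <- selectTissuePredominantGenes(panelSim$panel)
    candidates <- intersect(catalog$candidates,
        cohortSim$truth$candidate_genes)
    if (!length(candidates)) candidates <- catalog$candidates
    note("catalog: ", length(catalog$candidates), " candidates")

    ## stage 3: survival threshold-stability screen
    screen <- runScreen(cohort, candidates, screenCrit)
    note("screen: ", length(screen$selected), " genes pass all 3 criteria")
    panelGenes <- utils::head(screen$results$gene_id[screen$results$selected],
        panelSize)
    if (length(panelGenes) < panelSize) {
        note("screen: fewer than ", panelSize,
            " selected; topping up by Cox rank")
        panelGenes <- utils::head(unique(c(panelGenes,
            screen$results$gene_id)), panelSize)
    }

    ## stage 4: activation calls for the panel
    rules <- lapply(panelGenes, function(g) {
        if (activationStrategy == "background_based")
            deriveActivationRule(g, "background_based",
                profile = geneTissueProfile(panelSim$panel, g))
        else if (activationStrategy == "interval_midpoint")
            deriveActivationRule(g, "interval_midpoint",
                scan = screen$scans[[g]])
        else deriveActivationRule(g, "fixed_percentile", percentile = 60)
    })
    act <- callActivations(cohort, rules)
    scores <- scorePanel(act, panelGenes)
    note("activate: panel ", paste(panelGenes, collapse = ","),
        "; mean count ", round(mean(scores$activation_count), 2))

    ## stage 5: classification + subgroups + multivariate
    strat <- stratifiedSurvival(scores, cd$os_months, cd$event)
    covars <- deriveClinicalCovariates(cd)
    subgroups <- NULL
    if (doSubgroups)
        subgroups <- lapply(c("stage_class", "hpv", "site_class"),
            function(v) subgroupAnalysis(scores, covars, cd$os_months,
                cd$event, v))
    multivariate <- NULL
    if (doMultivariate)
        multivariate <- tryCatch(
            multivariateCox(scores, covars, cd$os_months, cd$event),
            error = function(e) {
                note("multivariate skipped: ", conditionMessage(e))
                NULL
            })

    ## stage 6: IHC emulation on the same truth
    ihc <- NULL
    if (doIHC && all(panelGenes %in% rownames(cohortSim$truth$activation_matrix))) {
        markerTruth <- cohortSim$truth$activation_matrix[panelGenes, ,
            drop = FALSE]
        rownames(markerTruth) <- c("AREG", "CCNA1", "DDX20")[
            seq_along(panelGenes)]
        ihcTab <- simulateIHCTable(simCfg, markerTruth)
        ihc <- ihcCohortAnalysis(ihcTab, cd)
        note("ihc: ", ihc$n_joined, " patients scored")
    }

    ## stage 7: signature + GSEA
    signature <- NULL
    if (doSignature) {
        groups <- ifelse(scores$risk_group == "poor", "positive", "negative")
        if (min(table(groups)) >= 2) {
            de <- differentialExpression(cohort, groups)
            sets <- selectSignatureGenes(de)
            metric <- stats::setNames(de$log_ratio, de$gene_id)
            gsea <- NULL
            if (length(sets$up) >= 3 &&
                    length(sets$up) < length(metric)) {
                gsea <- gseaEnrichment(metric, sets$up,
                    nPermutations = gseaPermutations, seed = simCfg$seed)
            }
            signature <- list(de = de, sets = sets, gsea = gsea)
            note("signature: ", length(sets$up), " up / ",
                length(sets$down), " down genes")
        } else note("signature skipped: a risk group has < 2 patients")
    }

    result <- structure(list(
        config = simCfg, criteria = screenCrit,
        version = as.character(utils::packageVersion("ectoMark")),
        catalog = catalog, screen = screen, panel_genes = panelGenes,
        activation = act, scores = scores, stratification = strat,
        subgroups = subgroups, multivariate = multivariate, ihc = ihc,
        signature = signature, truth = cohortSim$truth,
        panel_truth = panelSim$truth, log = log),
        class = "PipelineResult")
    if (!is.null(outDir)) writePipelineReports(result, outDir)
    result
}

# strip non-serialisable bulk, keep the auditable numbers
.screenJson <- function(screen) {
    list(criteria = unclass(screen$criteria),
        n_candidates = screen$n_candidates,
        n_patients = screen$n_patients, n_events = screen$n_events,
        selected = screen$selected, results = screen$results)
}

.stratJson <- function(s) {
    if (is.null(s)) return(NULL)
    list(group_sizes = as.list(s$group_sizes),
        risk_sizes = as.list(s$risk_sizes),
        logrank_risk_p = if (!is.null(s$logrank_risk))
            s$logrank_risk$p_value else NA,
        logrank_count_p = if (!is.null(s$logrank_count))
            s$logrank_count$p_value else NA,
        cox_hr_per_activation = if (!is.null(s$cox_count))
            unname(s$cox_count$hazard_ratio[1L]) else NA,
        cox_count_p = if (!is.null(s$cox_count))
            unname(s$cox_count$p[1L]) else NA,
        km_median_by_count = lapply(s$km_by_count, `[[`, "median"),
        notices = s$notices)
}

#' Write the JSON/TSV reports of a pipeline run
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param outDir output directory.
#' @return Invisibly, the paths written.
#' @export
writePipelineReports <- function(result, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    w <- function(x, name) {
        p <- file.path(outDir, name)
        jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
            pretty = TRUE, na = "null")
        paths <<- c(paths, p)
    }
    header <- list(package = "ectoMark", version = result$version,
        seed = result$config$seed,
        config = unclass(result$config))
    w(c(header, list(log = result$log,
        panel_genes = result$panel_genes)), "pipeline_report.json")
    w(list(criteria = unclass(result$catalog$criteria),
        candidates = result$catalog$candidates), "catalog.json")
    w(.screenJson(result$screen), "screen.json")
    w(list(thresholds = as.list(result$activation$thresholds),
        provenance = lapply(result$activation$rules, `[[`, "provenance")),
        "activation_rules.json")
    w(.stratJson(result$stratification), "stratification.json")
    if (!is.null(result$multivariate))
        w(list(table = result$multivariate$table,
            n_used = result$multivariate$n_used,
            n_excluded = result$multivariate$n_excluded),
            "multivariate.json")
    if (!is.null(result$subgroups)) {
        sg <- lapply(result$subgroups, function(byVar)
            lapply(byVar, function(lv) list(level = lv$level, n = lv$n,
                degenerate = lv$degenerate,
                report = .stratJson(lv$report))))
        w(sg, "subgroups.json")
    }
    if (!is.null(result$ihc))
        w(list(stratification = .stratJson(result$ihc$stratification),
            per_marker_p = lapply(result$ihc$per_marker, function(m)
                if (is.list(m)) m$p_value else m)), "ihc.json")
    if (!is.null(result$signature)) {
        w(list(n_up = length(result$signature$sets$up),
            n_down = length(result$signature$sets$down),
            up = result$signature$sets$up,
            down = result$signature$sets$down,
            gsea = if (!is.null(result$signature$gsea))
                list(es = result$signature$gsea$es,
                    nes = result$signature$gsea$nes,
                    p = result$signature$gsea$p_value,
                    n_permutations =
                        result$signature$gsea$n_permutations,
                    seed = result$signature$gsea$seed) else NULL),
            "signature.json")
        p <- file.path(outDir, "de_table.tsv")
        utils::write.table(result$signature$de, p, sep = "\t",
            quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    p <- file.path(outDir, "activations.tsv")
    utils::write.table(
        data.frame(gene_id = rownames(result$activation$calls),
            result$activation$calls, check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    invisible(paths)
}

#' @export
print.PipelineResult <- function(x, ...) {
    cat("ectoMark pipeline run (seed", x$config$seed, ", version",
        x$version, ")\n")
    for (l in x$log) cat(" -", l, "\n")
    invisible(x)
}
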