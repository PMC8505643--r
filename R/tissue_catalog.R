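#' Selection criteria for tissue-predominant silent genes
#'
#' A gene qualifies as a candidate ectopic biomarker when it is predominant
#' in one tissue while silent (or very lowly expressed) in every normal
#' non-germline somatic tissue. The quantitative cutoffs are not dictated
#' by the biology alone, so they are explicit parameters recorded in every
#' catalog report.
#'
#' @param silence_ceiling maximum allowed tissue summary (expression units)
#'   across non-germline somatic tissues.
#' @param predominance_floor minimum summary in the predominant tissue.
#' @param predominance_ratio minimum ratio of the predominant-tissue summary
#'   to the best other somatic summary (>= 1).
#' @param summary_statistic per-tissue summary over samples: "median" or
#'   "mean".
#' @return list of class \code{"TissueCriteria"}.
#' @export
tissueCriteria <- function(silence_ceiling = 1.0, predominance_floor = 10.0,
        predominance_ratio = 5.0,
        summary_statistic = c("median", "mean")) {
    summary_statistic <- match.arg(summary_statistic)
    if (silence_ceiling < 0)
        stop("silence_ceiling must be >= 0", call. = FALSE)
    if (predominance_floor <= silence_ceiling)
        stop("predominance_floor must exceed silence_ceiling", call. = FALSE)
    if (predominance_ratio < 1)
        stop("predominance_ratio must be >= 1", call. = FALSE)
    structure(list(silence_ceiling = silence_ceiling,
        predominance_floor = predominance_floor,
        predominance_ratio = predominance_ratio,
        summary_statistic = summary_statistic),
        class = "TissueCriteria")
}

.tissueSummaries <- function(panel, statistic) {
    x <- exprValues(panel)
    tissue <- tissueLabels(panel)
    fun <- if (statistic == "median") stats::median else mean
    # genes x tissues matrix of per-tissue summaries
    vapply(split(seq_len(ncol(x)), tissue),
        function(idx) apply(x[, idx, drop = FALSE], 1L, fun),
        numeric(nrow(x)))
}

#' Per-gene tissue expression profile
#'
#' Summarises a gene across the tissues of a normal panel: per-tissue
#' summary (median by default), the predominant (argmax) tissue, the
#' maximum summary over non-germline somatic tissues, and the background
#' ceiling (maximum single-sample value over non-germline tissues, the
#' upper envelope used to derive activation thresholds).
#'
#' @param panel a \linkS4class{NormalTissuePanel}.
#' @param geneId gene identifier present in the panel.
#' @param criteria a \code{\link{tissueCriteria}} (only the summary
#'   statistic is used here).
#' @return list of class \code{"TissueProfile"}.
#' @export
geneTissueProfile <- function(panel, geneId, criteria = tissueCriteria()) {
    x <- exprValues(panel)
    if (!geneId %in% rownames(x))
        stop("unknown gene: ", geneId, call. = FALSE)
    tissue <- tissueLabels(panel)
    if (any(table(tissue) < 1L))
        stop("every tissue needs at least one sample", call. = FALSE)
    germ <- germlineTissues(panel)
    fun <- if (criteria$summary_statistic == "median") stats::median else mean
    v <- x[geneId, ]
    summ <- vapply(split(v, tissue), fun, numeric(1L))
    somatic <- !(names(summ) %in% germ)
    structure(list(
        gene_id = geneId,
        tissue_summary = summ,
        predominant_tissue = names(summ)[which.max(summ)],
        max_somatic_nongermline = if (any(somatic))
            max(summ[somatic]) else 0,
        background_ceiling = if (any(!(tissue %in% germ)))
            max(v[!(tissue %in% germ)]) else 0,
        summary_statistic = criteria$summary_statistic),
        class = "TissueProfile")
}

#' Select tissue-predominant silent genes from a normal panel
#'
#' A gene is selected iff (1) its maximum summary over non-germline somatic
#' tissues is at most \code{silence_ceiling}, (2) its summary in the
#' predominant tissue is at least \code{predominance_floor}, and (3) the
#' predominant-tissue summary exceeds the best other somatic summary by at
#' least \code{predominance_ratio} (a small epsilon guards the ratio for
#' genes silent everywhere else). Germline/placenta tissues are excluded
#' from the silence requirement but eligible as the predominant tissue.
#'
#' @param panel a \linkS4class{NormalTissuePanel}.
#' @param criteria a \code{\link{tissueCriteria}}.
#' @return list of class \code{"TissueCatalog"}: \code{candidates} (sorted
#'   gene IDs), \code{profiles} (data.frame, one row per gene with the
#'   summaries, ceilings and selection flag) and the criteria used.
#' @export
selectTissuePredominantGenes <- function(panel, criteria = tissueCriteria()) {
    x <- exprValues(panel)
    if (nrow(x) == 0L || ncol(x) == 0L)
        stop("empty expression panel", call. = FALSE)
    eps <- 1e-6
    tissue <- tissueLabels(panel)
    germ <- germlineTissues(panel)
    summ <- .tissueSummaries(panel, criteria$summary_statistic)
    somatic <- !(colnames(summ) %in% germ)
    somaticSamples <- !(tissue %in% germ)

    top <- max.col(summ, ties.method = "first")
    predominantTissue <- colnames(summ)[top]
    topSummary <- summ[cbind(seq_len(nrow(summ)), top)]
    maxSomatic <- if (any(somatic))
        apply(summ[, somatic, drop = FALSE], 1L, max) else rep(0, nrow(summ))
    # best somatic summary excluding the predominant tissue itself
    summOther <- summ
    summOther[cbind(seq_len(nrow(summ)), top)] <- -Inf
    bestOtherSomatic <- if (any(somatic))
        apply(summOther[, somatic, drop = FALSE], 1L, max)
        else rep(0, nrow(summ))
    bestOtherSomatic[!is.finite(bestOtherSomatic)] <- 0
    backgroundCeiling <- if (any(somaticSamples))
        apply(x[, somaticSamples, drop = FALSE], 1L, max)
        else rep(0, nrow(x))

    selected <- maxSomatic <= criteria$silence_ceiling &
        topSummary >= criteria$predominance_floor &
        topSummary / pmax(bestOtherSomatic, eps) >=
            criteria$predominance_ratio

    profiles <- data.frame(gene_id = rownames(x),
        predominant_tissue = predominantTissue,
        predominant_summary = topSummary,
        max_somatic_nongermline = maxSomatic,
        best_other_somatic = bestOtherSomatic,
        background_ceiling = backgroundCeiling,
        selected = selected,
        row.names = NULL, stringsAsFactors = FALSE)
    structure(list(
        candidates = sort(rownames(x)[selected]),
        profiles = profiles,
        criteria = criteria),
        class = "TissueCatalog")
}

#' Derive an activation threshold from a gene's somatic background ceiling
#'
#' The threshold separating "activated" from background expression in
#' tumours is a multiple of the gene's upper background envelope in normal
#' somatic tissues; a floor constant keeps the threshold positive for genes
#' that are fully silent in the normal panel.
#'
#' @param profile a \code{\link{geneTissueProfile}} result, or any list with
#'   a \code{background_ceiling} element.
#' @param multiplier real >= 1.
#' @param floor_constant minimum ceiling substituted for fully silent genes
#'   (expression units).
#' @return threshold in expression units.
#' @examples
#' deriveBackgroundCeiling(list(background_ceiling = 0), multiplier = 2)
#' @export
deriveBackgroundCeiling <- function(profile, multiplier = 2,
        floor_constant = 0.1) {
    if (multiplier < 1)
        stop("multiplier must be >= 1", call. = FALSE)
    multiplier * max(profile$background_ceiling, floor_constant)
}

#' @export
print.TissueCatalog <- function(x, ...) {
    cat("TissueCatalog:", nrow(x$profiles), "genes profiled,",
        length(x$candidates), "selected\n")
    cat("  criteria: silence <=", x$criteria$silence_ceiling,
        "| predominance >=", x$criteria$predominance_floor,
        "| ratio >=", x$criteria$predominance_ratio,
        "|", x$criteria$summary_statistic, "summary\n")
    invisible(x)
}
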