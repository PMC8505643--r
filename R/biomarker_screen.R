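#' Criteria for the threshold-stability biomarker screen
#'
#' Per candidate gene, three conjunctive criteria select prognostic
#' candidates: (1) a significant Cox association between overexpression and
#' shorter survival (p < \code{cox_alpha}, hazard ratio > 1), (2) at least
#' one expression threshold splitting the cohort into groups with
#' significantly different survival (log-rank p < \code{logrank_alpha}),
#' and (3) a contiguous run of such significant percentile thresholds wider
#' than \code{min_interval_width} percentile points.
#'
#' @param cox_alpha significance level for the Cox criterion.
#' @param logrank_alpha significance level for each threshold's log-rank.
#' @param min_interval_width required width (exclusive) of the longest
#'   significant percentile run, in percentile points.
#' @param percentile_grid ordered percentiles scanned (strictly increasing,
#'   within (0, 100)).
#' @param direction_required if TRUE, significance additionally requires
#'   the high-expression group to fare worse (observed > expected events).
#' @param min_group_size minimum patients per group for a split to be
#'   evaluable.
#' @param min_group_events minimum events per group for a split to be
#'   evaluable.
#' @param interval_mode \code{"contiguous"} (width of the longest maximal
#'   run) or \code{"count"} (total significant points minus one, a
#'   sensitivity alternative).
#' @return list of class \code{"ScreenCriteria"}.
#' @export
screenCriteria <- function(cox_alpha = 0.05, logrank_alpha = 0.05,
        min_interval_width = 50, percentile_grid = 10:90,
        direction_required = TRUE, min_group_size = 5L,
        min_group_events = 1L,
        interval_mode = c("contiguous", "count")) {
    interval_mode <- match.arg(interval_mode)
    if (any(diff(percentile_grid) <= 0) || any(percentile_grid <= 0) ||
            any(percentile_grid >= 100))
        stop("percentile_grid must be strictly increasing within (0, 100)",
            call. = FALSE)
    if (cox_alpha <= 0 || cox_alpha >= 1 || logrank_alpha <= 0 ||
            logrank_alpha >= 1)
        stop("alphas must lie in (0, 1)", call. = FALSE)
    if (min_interval_width <= 0 || min_interval_width >= 100)
        stop("min_interval_width must lie in (0, 100)", call. = FALSE)
    structure(list(cox_alpha = cox_alpha, logrank_alpha = logrank_alpha,
        min_interval_width = min_interval_width,
        percentile_grid = as.numeric(percentile_grid),
        direction_required = direction_required,
        min_group_size = as.integer(min_group_size),
        min_group_events = as.integer(min_group_events),
        interval_mode = interval_mode),
        class = "ScreenCriteria")
}

#' Scan percentile expression thresholds with the log-rank test
#'
#' For every percentile q of the grid, the q-th percentile of the gene's
#' expression (linear-interpolation quantile) dichotomises patients into
#' high (> threshold) and low (<= threshold) groups; ties at the threshold
#' go to the low group. Splits leaving either group with fewer than
#' \code{min_group_size} patients or \code{min_group_events} events are
#' non-evaluable rather than errors. An evaluable split is significant when
#' its two-group log-rank p-value is below \code{logrank_alpha} and (if
#' direction is required) the high group has more observed than expected
#' events.
#'
#' @param expr per-patient expression of one gene.
#' @param time,event survival data aligned with \code{expr}.
#' @param criteria a \code{\link{screenCriteria}}.
#' @return data.frame of class \code{"ThresholdScan"}: one row per grid
#'   percentile with threshold, group sizes/events, log-rank p, direction
#'   and the evaluable/significant flags.
#' @export
scanThresholds <- function(expr, time, event, criteria = screenCriteria()) {
    .checkSurv(time, event)
    if (length(expr) != length(time))
        stop("expression and survival must be aligned on patients",
            call. = FALSE)
    q <- criteria$percentile_grid
    thr <- stats::quantile(expr, q / 100, names = FALSE, type = 7)
    Z <- outer(expr, thr, `>`)
    nHigh <- colSums(Z)
    nLow <- length(expr) - nHigh
    eHigh <- colSums(Z * event)
    eLow <- sum(event) - eHigh
    evaluable <- nHigh >= criteria$min_group_size &
        nLow >= criteria$min_group_size &
        eHigh >= criteria$min_group_events &
        eLow >= criteria$min_group_events
    p <- rep(NA_real_, length(q))
    highWorse <- rep(NA, length(q))
    if (any(evaluable)) {
        lr <- .logrank2Batch(time, event, Z[, evaluable, drop = FALSE])
        p[evaluable] <- lr$p_value
        highWorse[evaluable] <- lr$observed > lr$expected
    }
    significant <- !is.na(p) & p < criteria$logrank_alpha &
        (!criteria$direction_required | (!is.na(highWorse) & highWorse))
    out <- data.frame(percentile = q, threshold = thr,
        n_high = nHigh, n_low = nLow, events_high = eHigh, events_low = eLow,
        evaluable = evaluable, logrank_p = p, high_worse = highWorse,
        significant = significant)
    class(out) <- c("ThresholdScan", "data.frame")
    out
}

#' Width of the longest run of significant thresholds
#'
#' The stability criterion measures, in percentile points, the span
#' (max q - min q) of the longest maximal run of consecutive grid
#' percentiles all flagged significant. No significant point, or a single
#' isolated one, gives width 0. With \code{interval_mode = "count"} the
#' width is instead the total number of significant points minus one.
#'
#' @param scan a \code{\link{scanThresholds}} result.
#' @param interval_mode see \code{\link{screenCriteria}}.
#' @return width in percentile points.
#' @export
longestSignificantInterval <- function(scan,
        interval_mode = c("contiguous", "count")) {
    interval_mode <- match.arg(interval_mode)
    sig <- scan$significant
    if (!any(sig)) return(0)
    if (interval_mode == "count") return(sum(sig) - 1)
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    widths <- ifelse(r$values,
        scan$percentile[ends] - scan$percentile[starts], 0)
    max(widths)
}

#' Screen one gene against the three selection criteria
#'
#' Criterion 1 fits a univariate Cox model on the z-scored expression and
#' requires p < \code{cox_alpha} with coefficient > 0 (overexpression
#' associated with shorter survival). Criterion 2 requires at least one
#' significant threshold in the percentile scan; criterion 3 requires the
#' longest significant run to exceed \code{min_interval_width} percentile
#' points. A gene with constant expression fails criterion 1 (recorded, not
#' an error).
#'
#' @inheritParams scanThresholds
#' @param geneId identifier recorded in the result.
#' @return list of class \code{"GeneScreenResult"}.
#' @export
screenGene <- function(expr, time, event, criteria = screenCriteria(),
        geneId = NA_character_) {
    coxP <- NA_real_
    coxHR <- NA_real_
    coxBeta <- NA_real_
    if (stats::sd(expr) > 0) {
        fit <- tryCatch(
            coxFit(time, event, cbind(expr_z = as.numeric(scale(expr)))),
            error = function(e) NULL)
        if (!is.null(fit) && !fit$separation) {
            coxP <- fit$p[[1L]]
            coxHR <- fit$hazard_ratio[[1L]]
            coxBeta <- fit$coefficients[[1L]]
        }
    }
    scan <- scanThresholds(expr, time, event, criteria)
    width <- longestSignificantInterval(scan, criteria$interval_mode)
    c1 <- !is.na(coxP) && coxP < criteria$cox_alpha && coxBeta > 0
    c2 <- any(scan$significant)
    c3 <- width > criteria$min_interval_width
    structure(list(gene_id = geneId, cox_p = coxP,
        cox_hazard_ratio = coxHR, scan = scan, interval_width = width,
        passes_criterion_1 = c1, passes_criterion_2 = c2,
        passes_criterion_3 = c3, selected = c1 && c2 && c3),
        class = "GeneScreenResult")
}

#' Run the biomarker screen over candidate genes of a cohort
#'
#' Applies \code{\link{screenGene}} to every candidate and returns a report
#' ordered by Cox p-value (gene ID as tie-break; genes with no Cox fit
#' last). Raw, uncorrected p-values are used by design, matching the
#' discovery procedure; the number of candidates tested is recorded so the
#' multiplicity burden is visible.
#'
#' @param cohort a \linkS4class{TumorCohort} (or a genes x patients matrix
#'   if \code{time} and \code{event} are supplied).
#' @param candidates candidate gene IDs (subset of the cohort's genes).
#' @param criteria a \code{\link{screenCriteria}}.
#' @param time,event optional survival data overriding the cohort clinical
#'   table.
#' @return list of class \code{"ScreenReport"}: a per-gene \code{results}
#'   data.frame (ranked), the list of per-gene \code{scans}, the criteria
#'   and counts.
#' @export
runScreen <- function(cohort, candidates, criteria = screenCriteria(),
        time = NULL, event = NULL) {
    if (is(cohort, "TumorCohort")) {
        x <- exprValues(cohort)
        cd <- clinicalData(cohort)
        if (is.null(time)) { time <- cd$os_months; event <- cd$event }
    } else x <- as.matrix(cohort)
    if (!length(candidates))
        stop("empty candidate list", call. = FALSE)
    miss <- setdiff(candidates, rownames(x))
    if (length(miss))
        stop("candidates absent from cohort: ",
            paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    res <- lapply(candidates, function(g)
        screenGene(x[g, ], time, event, criteria, geneId = g))
    tab <- data.frame(
        gene_id = candidates,
        cox_p = vapply(res, `[[`, numeric(1L), "cox_p"),
        cox_hazard_ratio = vapply(res, `[[`, numeric(1L),
            "cox_hazard_ratio"),
        interval_width = vapply(res, `[[`, numeric(1L), "interval_width"),
        n_significant = vapply(res, function(r) sum(r$scan$significant),
            integer(1L)),
        passes_criterion_1 = vapply(res, `[[`, logical(1L),
            "passes_criterion_1"),
        passes_criterion_2 = vapply(res, `[[`, logical(1L),
            "passes_criterion_2"),
        passes_criterion_3 = vapply(res, `[[`, logical(1L),
            "passes_criterion_3"),
        selected = vapply(res, `[[`, logical(1L), "selected"),
        stringsAsFactors = FALSE)
    ord <- order(tab$cox_p, tab$gene_id, na.last = TRUE)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    scans <- lapply(res, `[[`, "scan")
    names(scans) <- candidates
    structure(list(results = tab, scans = scans, criteria = criteria,
        n_candidates = length(candidates), n_patients = length(time),
        n_events = sum(event), selected = tab$gene_id[tab$selected]),
        class = "ScreenReport")
}

#' @export
print.ScreenReport <- function(x, ...) {
    cat("Biomarker screen:", x$n_candidates, "candidates on",
        x$n_patients, "patients (", x$n_events, "events );",
        length(x$selected), "selected\n")
    cat("  raw p-values across", x$n_candidates,
        "tests -- no multiplicity correction applied\n")
    print(utils::head(x$results, 10L))
    invisible(x)
}
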