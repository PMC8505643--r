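#' Composite IHC score and high/low call for one marker
#'
#' Marker-specific rules translate staining intensity (0-3) and the
#' percentage of positive tumour cells into a high/low call:
#' \describe{
#'   \item{AREG}{high iff percent positive > 50 (intensity recorded but not
#'     used by the call).}
#'   \item{CCNA1}{proportion score 1 if percent <= 10, else 2; composite =
#'     intensity x proportion score; high iff composite >= 3.}
#'   \item{DDX20}{proportion score 1 if percent <= 33, 2 if 33 < percent
#'     <= 66, 3 if percent > 66; composite = intensity x proportion score;
#'     high iff composite >= 3.}
#' }
#' Category edges are continuous half-open intervals; the published
#' category labels (<33\%, 34-66\%, >66\%) leave integer gaps that this
#' completion closes. For CCNA1 the product rule is authoritative; a
#' disjunctive variant (high iff intensity = 3 or percent > 10) is
#' available via \code{ccna1_rule = "disjunctive"} for sensitivity
#' analysis, as the published prose admits both readings.
#'
#' @param marker one of \code{"AREG"}, \code{"CCNA1"}, \code{"DDX20"}.
#' @param intensity integer 0-3.
#' @param percent_positive percentage in [0, 100].
#' @param ccna1_rule \code{"product"} (default) or \code{"disjunctive"}.
#' @return list of class \code{"IHCMarkerScore"}: marker,
#'   proportion_score (NA for AREG), composite (NA for AREG), call
#'   ("high"/"low").
#' @examples
#' scoreIHCMarker("CCNA1", intensity = 3, percent_positive = 5)$call  # high
#' scoreIHCMarker("DDX20", intensity = 2, percent_positive = 20)$call # low
#' @export
scoreIHCMarker <- function(marker, intensity, percent_positive,
        ccna1_rule = c("product", "disjunctive")) {
    ccna1_rule <- match.arg(ccna1_rule)
    marker <- match.arg(marker, c("AREG", "CCNA1", "DDX20"))
    if (length(intensity) != 1L || !(intensity %in% 0:3))
        stop("intensity must be an integer in 0..3", call. = FALSE)
    if (length(percent_positive) != 1L || is.na(percent_positive) ||
            percent_positive < 0 || percent_positive > 100)
        stop("percent_positive must lie in [0, 100]", call. = FALSE)
    prop <- NA_integer_
    comp <- NA_integer_
    if (marker == "AREG") {
        call <- if (percent_positive > 50) "high" else "low"
    } else if (marker == "CCNA1") {
        prop <- if (percent_positive <= 10) 1L else 2L
        comp <- as.integer(intensity) * prop
        call <- if (ccna1_rule == "product") {
            if (comp >= 3L) "high" else "low"
        } else {
            if (intensity == 3L || percent_positive > 10) "high" else "low"
        }
    } else {
        prop <- if (percent_positive <= 33) 1L
            else if (percent_positive <= 66) 2L else 3L
        comp <- as.integer(intensity) * prop
        call <- if (comp >= 3L) "high" else "low"
    }
    structure(list(marker = marker, intensity = as.integer(intensity),
        percent_positive = percent_positive, proportion_score = prop,
        composite = comp, call = call), class = "IHCMarkerScore")
}

#' Score an IHC table per patient and marker
#'
#' Applies \code{\link{scoreIHCMarker}} to every record and aggregates per
#' patient the count of "high" markers and the derived risk group (0-1 high
#' = good, 2-3 high = poor), the IHC analogue of the transcriptomic panel
#' score.
#'
#' @param ihc data.frame with patient_id, marker, intensity,
#'   percent_positive (see \code{\link{readIHCTable}}).
#' @param markers the markers required for every patient.
#' @param ccna1_rule passed to \code{\link{scoreIHCMarker}}.
#' @return list of class \code{"IHCScores"}: per-record \code{calls}
#'   data.frame and per-patient \code{scores} (patient_id, high_count,
#'   risk_group).
#' @export
scoreIHCPatients <- function(ihc, markers = c("AREG", "CCNA1", "DDX20"),
        ccna1_rule = c("product", "disjunctive")) {
    ccna1_rule <- match.arg(ccna1_rule)
    have <- split(ihc$marker, ihc$patient_id)
    bad <- names(have)[!vapply(have, function(m) all(markers %in% m),
        logical(1L))]
    if (length(bad)) {
        miss <- unique(unlist(lapply(have[bad], function(m)
            setdiff(markers, m))))
        stop("patient(s) missing marker(s) ", paste(miss, collapse = ", "),
            ": ", paste(utils::head(bad, 5L), collapse = ", "),
            call. = FALSE)
    }
    ihc <- ihc[ihc$marker %in% markers, , drop = FALSE]
    res <- mapply(function(m, i, p)
        scoreIHCMarker(m, i, p, ccna1_rule)$call,
        ihc$marker, ihc$intensity, ihc$percent_positive)
    calls <- data.frame(patient_id = ihc$patient_id, marker = ihc$marker,
        intensity = ihc$intensity,
        percent_positive = ihc$percent_positive,
        call = unname(res), stringsAsFactors = FALSE)
    hi <- tapply(calls$call == "high", calls$patient_id, sum)
    scores <- data.frame(patient_id = names(hi),
        activation_count = as.integer(hi),
        risk_group = factor(ifelse(hi <= 1, "good", "poor"),
            levels = c("good", "poor")),
        stringsAsFactors = FALSE)
    rownames(scores) <- NULL
    structure(list(calls = calls, scores = scores, markers = markers,
        ccna1_rule = ccna1_rule), class = "IHCScores")
}

#' Survival analysis of an IHC-scored cohort
#'
#' Joins per-patient IHC panel scores to a clinical table on patient_id and
#' delegates to \code{\link{stratifiedSurvival}}; per-marker two-group
#' (high vs low) log-rank analyses are also emitted.
#'
#' @param ihc data.frame of IHC records.
#' @param clinical data.frame with patient_id, os_months, event.
#' @param markers markers scored.
#' @param ccna1_rule passed to \code{\link{scoreIHCMarker}}.
#' @return list of class \code{"IHCCohortReport"}: the panel
#'   \code{stratification} report, \code{per_marker} log-rank results, the
#'   \code{scores} table, and join diagnostics.
#' @export
ihcCohortAnalysis <- function(ihc, clinical,
        markers = c("AREG", "CCNA1", "DDX20"),
        ccna1_rule = c("product", "disjunctive")) {
    sc <- scoreIHCPatients(ihc, markers, ccna1_rule)
    scores <- sc$scores
    unmatched <- setdiff(scores$patient_id, clinical$patient_id)
    if (length(unmatched))
        stop("IHC patients absent from clinical table: ",
            paste(utils::head(unmatched, 5L), collapse = ", "),
            call. = FALSE)
    idx <- match(scores$patient_id, clinical$patient_id)
    time <- clinical$os_months[idx]
    event <- clinical$event[idx]
    strat <- stratifiedSurvival(scores, time, event)
    perMarker <- lapply(markers, function(m) {
        mc <- sc$calls[sc$calls$marker == m, , drop = FALSE]
        mIdx <- match(scores$patient_id, mc$patient_id)
        grp <- mc$call[mIdx]
        tryCatch(logrankTest(time, event, grp),
            error = function(e) conditionMessage(e))
    })
    names(perMarker) <- markers
    structure(list(stratification = strat, per_marker = perMarker,
        scores = scores,
        n_joined = nrow(scores),
        clinical_only = setdiff(clinical$patient_id, scores$patient_id)),
        class = "IHCCohortReport")
}
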