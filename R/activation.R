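#' Derive a binary activation rule for one gene
#'
#' Three strategies translate the activation-threshold concept into a
#' per-gene rule:
#' \describe{
#'   \item{background_based}{threshold = multiplier x the gene's background
#'     ceiling from the normal panel (\code{\link{deriveBackgroundCeiling}});
#'     appropriate when tumour and normal expression units are
#'     cross-comparable (RNA-seq-like).}
#'   \item{interval_midpoint}{threshold percentile = midpoint of the longest
#'     significant run of the gene's threshold scan; appropriate for
#'     cohort-internal calibration (microarray-like units).}
#'   \item{fixed_percentile}{a configured percentile of the cohort's own
#'     expression distribution.}
#' }
#'
#' @param geneId gene identifier.
#' @param strategy one of \code{"background_based"},
#'   \code{"interval_midpoint"}, \code{"fixed_percentile"}.
#' @param profile a \code{\link{geneTissueProfile}} (required for
#'   background_based).
#' @param scan a \code{\link{scanThresholds}} result (required for
#'   interval_midpoint).
#' @param percentile percentile in (0, 100) for fixed_percentile.
#' @param multiplier,floor_constant see
#'   \code{\link{deriveBackgroundCeiling}}.
#' @return list of class \code{"ActivationRule"} with either
#'   \code{threshold_value} (expression units) or \code{threshold_percentile}
#'   set, plus a provenance note.
#' @export
deriveActivationRule <- function(geneId,
        strategy = c("background_based", "interval_midpoint",
            "fixed_percentile"),
        profile = NULL, scan = NULL, percentile = NULL,
        multiplier = 2, floor_constant = 0.1) {
    strategy <- match.arg(strategy)
    rule <- list(gene_id = geneId, strategy = strategy,
        threshold_value = NA_real_, threshold_percentile = NA_real_,
        provenance = NA_character_)
    if (strategy == "background_based") {
        if (is.null(profile))
            stop("background_based strategy needs a tissue profile",
                call. = FALSE)
        rule$threshold_value <- deriveBackgroundCeiling(profile, multiplier,
            floor_constant)
        rule$provenance <- sprintf(
            "%g x max(normal somatic ceiling %.4g, floor %g)",
            multiplier, profile$background_ceiling, floor_constant)
    } else if (strategy == "interval_midpoint") {
        if (is.null(scan))
            stop("interval_midpoint strategy needs a threshold scan",
                call. = FALSE)
        sig <- scan$significant
        if (!any(sig))
            stop("no significant threshold run for ", geneId,
                "; fall back to background_based or fixed_percentile",
                call. = FALSE)
        r <- rle(sig)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        widths <- ifelse(r$values,
            scan$percentile[ends] - scan$percentile[starts], -1)
        k <- which.max(widths)
        rule$threshold_percentile <-
            (scan$percentile[starts[k]] + scan$percentile[ends[k]]) / 2
        rule$provenance <- sprintf(
            "midpoint of longest significant run [%g, %g]",
            scan$percentile[starts[k]], scan$percentile[ends[k]])
    } else {
        if (is.null(percentile) || percentile <= 0 || percentile >= 100)
            stop("fixed_percentile strategy needs a percentile in (0, 100)",
                call. = FALSE)
        rule$threshold_percentile <- percentile
        rule$provenance <- sprintf("fixed percentile %g", percentile)
    }
    class(rule) <- "ActivationRule"
    rule
}

#' Call binary gene activations across a cohort
#'
#' A gene is called activated in a patient iff its expression strictly
#' exceeds the rule's threshold. Percentile rules are resolved against the
#' cohort's own expression distribution (linear-interpolation quantile), so
#' the call is invariant to strictly monotone transforms of the
#' expression scale.
#'
#' @param cohort a \linkS4class{TumorCohort} or genes x patients matrix.
#' @param rules list of \code{\link{deriveActivationRule}} results, one per
#'   panel gene.
#' @return list of class \code{"ActivationMatrix"}: binary \code{calls}
#'   (genes x patients) and the resolved per-gene \code{thresholds}.
#' @export
callActivations <- function(cohort, rules) {
    x <- if (is(cohort, "TumorCohort")) exprValues(cohort)
        else as.matrix(cohort)
    genes <- vapply(rules, `[[`, character(1L), "gene_id")
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
        stop("no expression for rule gene(s): ",
            paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(genes))
        stop("duplicate rules for a gene", call. = FALSE)
    thr <- vapply(rules, function(r) {
        if (!is.na(r$threshold_value)) r$threshold_value
        else stats::quantile(x[r$gene_id, ], r$threshold_percentile / 100,
            names = FALSE, type = 7)
    }, numeric(1L))
    names(thr) <- genes
    calls <- (x[genes, , drop = FALSE] > thr) * 1L
    structure(list(calls = calls, thresholds = thr, rules = rules),
        class = "ActivationMatrix")
}

#' @export
print.ActivationMatrix <- function(x, ...) {
    cat("ActivationMatrix:", nrow(x$calls), "genes x", ncol(x$calls),
        "patients;", sum(x$calls), "activations (",
        round(100 * mean(x$calls), 1), "% )\n")
    invisible(x)
}
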