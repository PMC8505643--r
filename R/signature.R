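#' Differential expression between classifier-positive and negative tumours
#'
#' Per gene: Welch two-sample t-test on log2(x + 1)-transformed expression
#' (Student's variant by flag); log_ratio is the difference of group means
#' on that scale (positive minus negative) and fold_change is the signed
#' linear-scale ratio, sign following log_ratio. Genes with zero variance
#' in both groups get p = 1 and t = 0 rather than NaN.
#'
#' @param expr genes x patients matrix (raw scale; log2(x+1) is applied
#'   internally) or a \linkS4class{TumorCohort}.
#' @param groups vector over patients with values \code{"positive"} and
#'   \code{"negative"} (both groups need >= 2 patients).
#' @param var_equal use the pooled-variance Student t-test.
#' @return data.frame of class \code{"DETable"}: gene_id, mean_positive,
#'   mean_negative (log2 scale), log_ratio, t_statistic, p_value,
#'   fold_change.
#' @export
differentialExpression <- function(expr, groups, var_equal = FALSE) {
    x <- if (is(expr, "TumorCohort")) exprValues(expr) else as.matrix(expr)
    groups <- as.character(groups)
    if (length(groups) != ncol(x))
        stop("one group label per patient column is required", call. = FALSE)
    if (!all(groups %in% c("positive", "negative")))
        stop("groups must be 'positive' or 'negative'", call. = FALSE)
    pos <- groups == "positive"
    n1 <- sum(pos); n2 <- sum(!pos)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 patients", call. = FALSE)
    lx <- log2(x + 1)
    m1 <- rowMeans(lx[, pos, drop = FALSE])
    m2 <- rowMeans(lx[, !pos, drop = FALSE])
    v1 <- apply(lx[, pos, drop = FALSE], 1L, stats::var)
    v2 <- apply(lx[, !pos, drop = FALSE], 1L, stats::var)
    lr <- m1 - m2
    if (var_equal) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2, length(se))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tstat <- ifelse(se > 0, lr / se, 0)
    p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
    # zero variance in both groups but a mean shift: se = 0 denominator;
    # only possible with constant groups, call it p = 1 explicitly
    fc <- sign(lr) * 2^abs(lr)
    fc[lr == 0] <- 1
    out <- data.frame(gene_id = rownames(x), mean_positive = m1,
        mean_negative = m2, log_ratio = lr, t_statistic = tstat,
        p_value = p, fold_change = fc, row.names = NULL,
        stringsAsFactors = FALSE)
    class(out) <- c("DETable", "data.frame")
    out
}

#' Select signature gene sets from a DE table
#'
#' Up-set: fold change > \code{fc_min} and p < \code{p_max}; down-set:
#' fold change < -\code{fc_min} and p < \code{p_max} (the discovery
#' thresholds are |FC| > 2, p < 0.01).
#'
#' @param de a \code{\link{differentialExpression}} table.
#' @param fc_min linear fold-change threshold (> 1).
#' @param p_max p-value threshold.
#' @return list of class \code{"SignatureSets"} with \code{up} and
#'   \code{down} gene ID vectors (disjoint by construction).
#' @export
selectSignatureGenes <- function(de, fc_min = 2, p_max = 0.01) {
    if (fc_min <= 1)
        stop("fc_min must exceed 1", call. = FALSE)
    up <- de$gene_id[de$fold_change > fc_min & de$p_value < p_max]
    down <- de$gene_id[de$fold_change < -fc_min & de$p_value < p_max]
    structure(list(up = up, down = down, fc_min = fc_min, p_max = p_max),
        class = "SignatureSets")
}

#' @export
print.SignatureSets <- function(x, ...) {
    cat("Signature gene sets (|FC| >", x$fc_min, ", p <", x$p_max, "):",
        length(x$up), "up,", length(x$down), "down\n")
    invisible(x)
}

.runningSum <- function(metric, isHit, weight) {
    w <- abs(metric)^weight
    hitW <- sum(w[isHit])
    nMiss <- sum(!isHit)
    step <- ifelse(isHit, w / hitW, -1 / nMiss)
    cumsum(step)
}

# signed extremum of the running sum; an exact tie between the positive
# and negative deviation (within fp noise) resolves to the positive score
.esFromRunningSum <- function(rs) {
    hi <- max(rs); lo <- min(rs)
    if (hi >= -lo - 1e-12) hi else lo
}

#' Weighted running-sum gene set enrichment score
#'
#' Genes are ranked by the metric in decreasing order (ties broken by gene
#' ID); walking down the list, the running sum rises by
#' |metric|^weight / sum over hits at member genes and falls by
#' 1/(N - N_hits) otherwise. The enrichment score is the signed extremum of
#' the running sum; when the positive and negative deviations tie exactly
#' (possible with small lists), the positive score is reported. The nominal p-value and the normalised score come from
#' random gene-label permutations (random member sets of the same size)
#' under the given seed; phenotype permutation is available when the full
#' expression matrix and group labels are supplied.
#'
#' @param metric named numeric vector of ranking values (e.g. the DE
#'   log ratios), finite.
#' @param geneSet character vector of member gene IDs (a proper, non-empty
#'   subset of the ranked genes after intersection).
#' @param weight exponent on |metric| (1 = standard weighting, 0 =
#'   unweighted Kolmogorov-Smirnov-like statistic).
#' @param nPermutations number of permutations for p and NES (0 skips).
#' @param seed integer seed for the permutations.
#' @param permutation \code{"gene"} (default) or \code{"phenotype"}.
#' @param expr,groups expression matrix and group labels, required for
#'   phenotype permutation: each permutation reshuffles the labels,
#'   recomputes the DE log ratios and re-scores the set.
#' @return list of class \code{"GSEAResult"}: \code{es}, \code{nes},
#'   \code{p_value}, \code{n_hits}, \code{running_sum} (with the ranked
#'   gene order), permutation details.
#' @export
gseaEnrichment <- function(metric, geneSet, weight = 1,
        nPermutations = 1000L, seed = 1L,
        permutation = c("gene", "phenotype"), expr = NULL, groups = NULL) {
    permutation <- match.arg(permutation)
    if (is.null(names(metric)))
        stop("metric must be named by gene ID", call. = FALSE)
    if (anyNA(metric) || any(!is.finite(metric)))
        stop("metric values must be finite", call. = FALSE)
    ord <- order(-metric, names(metric))
    metric <- metric[ord]
    genes <- names(metric)
    hits <- genes %in% geneSet
    nHits <- sum(hits)
    if (nHits == 0L)
        stop("gene set does not intersect the ranked genes", call. = FALSE)
    if (nHits == length(genes))
        stop("gene set covers every ranked gene; a proper subset is ",
            "required", call. = FALSE)
    rs <- .runningSum(metric, hits, weight)
    es <- .esFromRunningSum(rs)

    nullEs <- numeric(0)
    pval <- NA_real_
    nes <- NA_real_
    if (nPermutations > 0L) {
        set.seed(as.integer(seed))
        if (permutation == "gene") {
            nullEs <- vapply(seq_len(nPermutations), function(i) {
                ph <- logical(length(genes))
                ph[sample.int(length(genes), nHits)] <- TRUE
                .esFromRunningSum(.runningSum(metric, ph, weight))
            }, numeric(1L))
        } else {
            if (is.null(expr) || is.null(groups))
                stop("phenotype permutation needs expr and groups",
                    call. = FALSE)
            nullEs <- vapply(seq_len(nPermutations), function(i) {
                g <- sample(groups)
                de <- differentialExpression(expr, g)
                m <- stats::setNames(de$log_ratio, de$gene_id)
                o <- order(-m, names(m))
                m <- m[o]
                h <- names(m) %in% geneSet
                .esFromRunningSum(.runningSum(m, h, weight))
            }, numeric(1L))
        }
        sameSign <- nullEs[sign(nullEs) == sign(es)]
        pval <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
        meanSame <- mean(abs(sameSign))
        nes <- if (length(sameSign) && meanSame > 0) es / meanSame
            else NA_real_
    }
    structure(list(es = es, nes = nes, p_value = pval, n_hits = nHits,
        n_genes = length(genes), weight = weight,
        running_sum = stats::setNames(rs, genes),
        n_permutations = as.integer(nPermutations),
        permutation = permutation, seed = as.integer(seed)),
        class = "GSEAResult")
}

#' @export
print.GSEAResult <- function(x, ...) {
    cat("GSEA:", x$n_hits, "of", x$n_genes, "genes in set; ES =",
        signif(x$es, 4), "NES =", signif(x$nes, 4), "nominal p =",
        signif(x$p_value, 4), "(", x$n_permutations, x$permutation,
        "permutations, seed", x$seed, ")\n")
    invisible(x)
}

#' Correlation between two differential-expression signatures
#'
#' Pearson correlation of the log ratios over the genes shared by two DE
#' tables (at least 3 shared genes with finite values required).
#'
#' @param deA,deB \code{\link{differentialExpression}} tables.
#' @return list: \code{correlation}, \code{n_shared}.
#' @export
signatureCorrelation <- function(deA, deB) {
    shared <- intersect(deA$gene_id, deB$gene_id)
    a <- deA$log_ratio[match(shared, deA$gene_id)]
    b <- deB$log_ratio[match(shared, deB$gene_id)]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L)
        stop("fewer than 3 shared genes with finite log ratios",
            call. = FALSE)
    list(correlation = stats::cor(a[ok], b[ok]), n_shared = sum(ok))
}
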