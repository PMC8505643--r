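#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' NormalTissuePanel: expression of genes across normal tissues
#'
#' A \linkS4class{SummarizedExperiment} holding a genes x samples matrix of
#' non-negative expression values (TPM/FPKM-like) for a panel of normal
#' tissues, with one tissue label per sample and a germline/placenta flag
#' per tissue. This is the input for cataloguing genes that are predominant
#' in one tissue and silent in all non-germline somatic tissues.
#'
#' @slot platform character tag, \code{"rnaseq-like"} or
#'   \code{"microarray-like"}.
#' @export
setClass("NormalTissuePanel",
    contains = "SummarizedExperiment",
    representation(platform = "character"))

#' TumorCohort: tumour expression with clinical annotation
#'
#' A \linkS4class{SummarizedExperiment} whose assay is a genes x patients
#' expression matrix and whose \code{colData} is the clinical table
#' (overall-survival months, event indicator, age, gender, TNM, HPV status,
#' anatomic site, grade).
#'
#' @slot platform character tag, \code{"rnaseq-like"} or
#'   \code{"microarray-like"}.
#' @export
setClass("TumorCohort",
    contains = "SummarizedExperiment",
    representation(platform = "character"))

.validPlatform <- function(p) {
    if (length(p) != 1L || !p %in% c("rnaseq-like", "microarray-like"))
        return("platform must be 'rnaseq-like' or 'microarray-like'")
    NULL
}

.validExprAssay <- function(object) {
    msg <- character(0)
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        return("assay 'expr' is missing")
    x <- assay(object, "expr")
    if (anyNA(x) || any(!is.finite(x)))
        msg <- c(msg, "expression values must be finite and non-missing")
    else if (any(x < 0))
        msg <- c(msg, "expression values must be non-negative")
    if (anyDuplicated(rownames(x)))
        msg <- c(msg, "duplicate gene IDs")
    if (anyDuplicated(colnames(x)))
        msg <- c(msg, "duplicate sample IDs")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        msg <- c(msg, "gene and sample IDs are required as dimnames")
    msg
}

setValidity("NormalTissuePanel", function(object) {
    msg <- c(.validPlatform(object@platform), .validExprAssay(object))
    cd <- colData(object)
    if (!all(c("tissue", "germline") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'tissue' and 'germline'")
    else {
        if (anyNA(cd$tissue)) msg <- c(msg, "missing tissue labels")
        if (!is.logical(cd$germline))
            msg <- c(msg, "'germline' must be logical")
        else {
            # the flag is a property of the tissue, not of the sample
            byTissue <- tapply(cd$germline, cd$tissue, function(z)
                length(unique(z)))
            if (any(byTissue > 1L))
                msg <- c(msg, "inconsistent germline flag within a tissue")
        }
    }
    if (length(msg)) msg else TRUE
})

.clinicalRequired <- c("os_months", "event", "age", "gender",
    "t_stage", "n_stage", "m_stage", "hpv", "site")

setValidity("TumorCohort", function(object) {
    msg <- c(.validPlatform(object@platform), .validExprAssay(object))
    cd <- colData(object)
    miss <- setdiff(.clinicalRequired, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("clinical columns missing: ",
            paste(miss, collapse = ", ")))
    else {
        if (anyNA(cd$os_months) || any(cd$os_months <= 0))
            msg <- c(msg, "os_months must be positive")
        if (!all(cd$event %in% c(0, 1)))
            msg <- c(msg, "event must be 0/1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a NormalTissuePanel
#'
#' @param expr numeric matrix, genes x samples, non-negative, with dimnames.
#' @param tissue character vector of tissue labels, one per sample column.
#' @param germlineTissues character vector naming the tissues to flag as
#'   germline/placenta (excluded from the somatic silence requirement).
#' @param platform expression platform tag.
#' @return A \linkS4class{NormalTissuePanel}.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' NormalTissuePanel(m, tissue = c("lung", "lung", "testis", "testis"))
#' @export
NormalTissuePanel <- function(expr, tissue,
        germlineTissues = c("testis", "ovary", "placenta"),
        platform = c("rnaseq-like", "microarray-like")) {
    platform <- match.arg(platform)
    if (length(tissue) != ncol(expr))
        stop("one tissue label per sample column is required")
    cd <- DataFrame(tissue = as.character(tissue),
        germline = as.character(tissue) %in% germlineTissues,
        row.names = colnames(expr))
    new("NormalTissuePanel",
        SummarizedExperiment(assays = list(expr = expr), colData = cd),
        platform = platform)
}

#' Construct a TumorCohort
#'
#' @param expr numeric matrix, genes x patients, non-negative, with dimnames;
#'   column names are patient IDs.
#' @param clinical data.frame with one row per patient (matched to columns
#'   of \code{expr} by \code{patient_id} or row order) holding at least
#'   \code{os_months}, \code{event}, \code{age}, \code{gender},
#'   \code{t_stage}, \code{n_stage}, \code{m_stage}, \code{hpv}, \code{site}.
#' @param platform expression platform tag.
#' @return A \linkS4class{TumorCohort}.
#' @export
TumorCohort <- function(expr, clinical,
        platform = c("rnaseq-like", "microarray-like")) {
    platform <- match.arg(platform)
    clinical <- as.data.frame(clinical)
    if ("patient_id" %in% colnames(clinical)) {
        if (!setequal(clinical$patient_id, colnames(expr)))
            stop("clinical patient_id set does not match expression columns")
        clinical <- clinical[match(colnames(expr), clinical$patient_id), ,
            drop = FALSE]
        rownames(clinical) <- clinical$patient_id
        clinical$patient_id <- NULL
    } else if (nrow(clinical) != ncol(expr)) {
        stop("clinical table must have one row per patient")
    } else {
        rownames(clinical) <- colnames(expr)
    }
    new("TumorCohort",
        SummarizedExperiment(assays = list(expr = expr),
            colData = DataFrame(clinical)),
        platform = platform)
}

#' @describeIn NormalTissuePanel-class expression matrix accessor.
#' @param object a panel or cohort object.
#' @export
exprValues <- function(object) assay(object, "expr")

#' @describeIn NormalTissuePanel-class tissue label per sample.
#' @export
tissueLabels <- function(object) colData(object)$tissue

#' @describeIn NormalTissuePanel-class names of tissues flagged germline.
#' @export
germlineTissues <- function(object) {
    cd <- colData(object)
    sort(unique(cd$tissue[cd$germline]))
}

#' @describeIn TumorCohort-class clinical table accessor (plain data.frame).
#' @param object a \code{TumorCohort}.
#' @export
clinicalData <- function(object) {
    df <- as.data.frame(colData(object))
    df <- cbind(patient_id = rownames(df), df)
    rownames(df) <- NULL
    df
}

#' @describeIn TumorCohort-class platform tag accessor.
#' @export
platformTag <- function(object) object@platform

setMethod("show", "NormalTissuePanel", function(object) {
    cat("NormalTissuePanel (", object@platform, ")\n", sep = "")
    cat(" ", nrow(object), "genes x", ncol(object), "samples in",
        length(unique(tissueLabels(object))), "tissues\n")
    gl <- germlineTissues(object)
    cat("  germline/placenta tissues:",
        if (length(gl)) paste(gl, collapse = ", ") else "none", "\n")
})

setMethod("show", "TumorCohort", function(object) {
    cd <- colData(object)
    cat("TumorCohort (", object@platform, ")\n", sep = "")
    cat(" ", nrow(object), "genes x", ncol(object), "patients;",
        sum(cd$event == 1), "events, median follow-up",
        round(stats::median(cd$os_months), 1), "months\n")
})
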