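#' Read a genes x samples expression matrix from TSV
#'
#' Expects a tab-separated UTF-8 file with a header row of sample IDs and a
#' first column of gene IDs ('.' decimal separator). Validation rejects
#' duplicate gene or sample IDs, negative, missing or non-finite values,
#' and ragged rows; a failing file never yields a partial object.
#'
#' @param path file path.
#' @param platform expression platform tag attached to the matrix.
#' @return numeric matrix with gene rownames, sample colnames and a
#'   \code{"platform"} attribute.
#' @export
readExpressionMatrix <- function(path,
        platform = c("rnaseq-like", "microarray-like")) {
    platform <- match.arg(platform)
    df <- tryCatch(
        utils::read.delim(path, header = TRUE, check.names = FALSE,
            colClasses = "character", stringsAsFactors = FALSE),
        error = function(e) stop("format error reading '", path, "': ",
            conditionMessage(e), call. = FALSE))
    if (ncol(df) < 2L)
        stop("format error in '", path,
            "': need a gene-ID column plus at least one sample", call. = FALSE)
    geneIds <- df[[1L]]
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        stop("format error in '", path, "': duplicated gene ID(s): ",
            paste(unique(dup), collapse = ", "), call. = FALSE)
    sampleIds <- colnames(df)[-1L]
    dup <- sampleIds[duplicated(sampleIds)]
    if (length(dup))
        stop("format error in '", path, "': duplicated sample ID(s): ",
            paste(unique(dup), collapse = ", "), call. = FALSE)
    vals <- suppressWarnings(vapply(df[-1L], as.numeric,
        numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
        dimnames = list(geneIds, sampleIds))
    badRow <- which(apply(vals, 1L, function(r) anyNA(r) | any(!is.finite(r))))
    if (length(badRow))
        stop("format error in '", path, "': non-numeric or missing value ",
            "at data line ", badRow[1L] + 1L, " (gene ", geneIds[badRow[1L]],
            ")", call. = FALSE)
    badRow <- which(apply(vals, 1L, function(r) any(r < 0)))
    if (length(badRow))
        stop("format error in '", path, "': negative value at data line ",
            badRow[1L] + 1L, " (gene ", geneIds[badRow[1L]], ")",
            call. = FALSE)
    attr(vals, "platform") <- platform
    vals
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix, genes x samples, with dimnames.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

.clinicalColumns <- c("patient_id", "os_months", "event", "age", "gender",
    "t_stage", "n_stage", "m_stage", "hpv", "site")

#' Read a clinical table from TSV
#'
#' Required columns: patient_id, os_months, event, age, gender, t_stage,
#' n_stage, m_stage, hpv, site (grade optional). Unknown categorical values
#' are encoded by the literal token \code{NA} and preserved as \code{NA}.
#'
#' @param path file path.
#' @return data.frame, one row per patient.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    miss <- setdiff(.clinicalColumns, colnames(df))
    if (length(miss))
        stop("format error in '", path, "': missing required column(s): ",
            paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$patient_id))
        stop("format error in '", path, "': duplicated patient_id",
            call. = FALSE)
    if (anyNA(df$os_months) || any(df$os_months <= 0))
        stop("format error in '", path, "': os_months must be positive",
            call. = FALSE)
    if (!all(df$event %in% c(0L, 1L)))
        stop("format error in '", path, "': event must be 0/1", call. = FALSE)
    df
}

#' Write a clinical table as TSV
#' @param clinical data.frame as returned by \code{\link{readClinicalTable}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClinicalTable <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read an IHC staining table from TSV
#'
#' Columns: patient_id, marker, intensity (integer 0-3), percent_positive
#' (0-100).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readIHCTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("patient_id", "marker", "intensity", "percent_positive")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("format error in '", path, "': missing required column(s): ",
            paste(miss, collapse = ", "), call. = FALSE)
    if (!all(df$intensity %in% 0:3))
        stop("format error in '", path, "': intensity must be 0..3",
            call. = FALSE)
    if (anyNA(df$percent_positive) || any(df$percent_positive < 0) ||
            any(df$percent_positive > 100))
        stop("format error in '", path,
            "': percent_positive must lie in [0, 100]", call. = FALSE)
    df
}

#' Write an IHC staining table as TSV
#' @param ihc data.frame with patient_id, marker, intensity,
#'   percent_positive.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeIHCTable <- function(ihc, path) {
    utils::write.table(ihc, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name TAB description TAB member genes (tab-separated).
#' Empty sets and duplicate member IDs within a set are rejected.
#'
#' @param path file path.
#' @return named list of gene sets; each element is a list with
#'   \code{name}, \code{description} and \code{genes}.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdemo\tg1\tg2", tf)
#' readGMT(tf)
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop("format error in '", path, "': no gene sets", call. = FALSE)
    sets <- lapply(seq_along(lines), function(i) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop("format error in '", path, "' line ", i,
                ": a gene set needs a name, a description and at least one ",
                "member", call. = FALSE)
        genes <- parts[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            stop("format error in '", path, "' line ", i, ": empty gene set '",
                parts[1L], "'", call. = FALSE)
        if (anyDuplicated(genes))
            stop("format error in '", path, "' line ", i,
                ": duplicated member in set '", parts[1L], "'", call. = FALSE)
        list(name = parts[1L], description = parts[2L], genes = genes)
    })
    names(sets) <- vapply(sets, `[[`, character(1L), "name")
    if (anyDuplicated(names(sets)))
        stop("format error in '", path, "': duplicated gene set name",
            call. = FALSE)
    sets
}

#' Write gene sets in GMT format
#' @param sets named list as returned by \code{\link{readGMT}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(sets, function(s)
        paste(c(s$name, s$description, s$genes), collapse = "\t"),
        character(1L))
    writeLines(lines, path)
    invisible(path)
}
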