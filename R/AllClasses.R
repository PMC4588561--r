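#' HFIMatrix: gene-by-sample high functional impact calls
#'
#' An `HFIMatrix` extends [SummarizedExperiment::SummarizedExperiment]
#' with two assays over genes (rows) and samples (columns):
#' `counts`, the number of analysis-set HFI variant calls of each gene
#' in each sample, and `affected`, the derived binary matrix
#' (`counts >= 1`) used for gene-level "variant kinase" designation and
#' all group contrasts. Sample metadata lives in `colData`, gene
#' annotation (when supplied) in `rowData`.
#'
#' @seealso [buildHFIMatrix()]
#' @name HFIMatrix-class
#' @aliases HFIMatrix-class
#' @exportClass HFIMatrix
setClass("HFIMatrix", contains = "SummarizedExperiment")

setValidity("HFIMatrix", function(object) {
  an <- assayNames(object)
  if (!all(c("counts", "affected") %in% an)) {
    return("assays must contain 'counts' and 'affected'")
  }
  cnt <- assay(object, "counts")
  aff <- assay(object, "affected")
  if (any(cnt < 0) || any(cnt != floor(cnt))) {
    return("'counts' must be non-negative integers")
  }
  if (!identical(dim(cnt), dim(aff))) {
    return("'counts' and 'affected' must have identical dimensions")
  }
  if (!all((cnt >= 1) == (aff > 0))) {
    return("'affected' must equal counts >= 1")
  }
  TRUE
})

#' @rdname HFIMatrix-class
#' @param counts Gene-by-sample matrix of non-negative integer HFI
#'   counts with row and column names.
#' @param colData Sample metadata (`data.frame` or `DataFrame`) whose
#'   rows match the columns of `counts`.
#' @param rowData Optional gene annotation whose rows match the rows of
#'   `counts`.
#' @return An `HFIMatrix`.
#' @export
HFIMatrix <- function(counts, colData = NULL, rowData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  affected <- counts >= 1L
  args <- list(assays = S4Vectors::SimpleList(counts = counts,
                                              affected = affected))
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  if (!is.null(rowData)) args$rowData <- S4Vectors::DataFrame(rowData)
  se <- do.call(SummarizedExperiment, args)
  new("HFIMatrix", se)
}

#' @describeIn HFIMatrix-class The integer HFI count matrix.
#' @param object,x An `HFIMatrix`.
#' @export
setGeneric("hfiCounts", function(x) standardGeneric("hfiCounts"))

#' @rdname HFIMatrix-class
#' @export
setMethod("hfiCounts", "HFIMatrix", function(x) assay(x, "counts"))

#' @describeIn HFIMatrix-class The logical gene-affected matrix
#'   (`counts >= 1`).
#' @export
setGeneric("hfiAffected", function(x) standardGeneric("hfiAffected"))

#' @rdname HFIMatrix-class
#' @export
setMethod("hfiAffected", "HFIMatrix", function(x) assay(x, "affected"))

setMethod("show", "HFIMatrix", function(object) {
  cnt <- hfiCounts(object)
  cat("HFIMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  HFI variant calls:", sum(cnt), "\n")
  if (ncol(object)) {
    cs <- colSums(cnt)
    cat(sprintf("  per-sample HFI calls: mean %.1f (range %d-%d)\n",
                mean(cs), min(cs), max(cs)))
  }
  if (nrow(object)) {
    top <- head(order(-rowSums(cnt)), 5L)
    cat("  most affected genes:",
        paste(rownames(object)[top], collapse = ", "), "\n")
  }
  callNextMethod()
})
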