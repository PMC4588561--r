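## Controlled vocabularies shared by the readers, the classifier and the
## simulator. These are exported as functions (not bare constants) so
## user code never needs to reach into package internals.

#' Controlled vocabularies of the variant data model
#'
#' @description
#' `variantClasses()` returns the recognized variant consequence
#' classes; `maCategories()` the Mutation Assessor functional-importance
#' categories; `kssVerdicts()` the kinase-specific score verdicts;
#' `kinaseGroups()` the ten canonical kinase groups (genes outside the
#' kinome are annotated `"non_kinase"`).
#'
#' @return A character vector of admissible values.
#' @examples
#' variantClasses()
#' kinaseGroups()
#' @export
variantClasses <- function() {
  c("synonymous", "missense", "stop_gain", "stop_loss",
    "frameshift_indel", "inframe_indel", "other")
}

#' @rdname variantClasses
#' @export
maCategories <- function() {
  c("high", "medium", "low", "neutral", "missing")
}

#' @rdname variantClasses
#' @export
kssVerdicts <- function() {
  c("yes", "no", "missing")
}

#' @rdname variantClasses
#' @export
kinaseGroups <- function() {
  c("AGC", "Atypical", "CAMK", "CK1", "CMGC",
    "Other", "RGC", "STE", "TK", "TKL")
}

## consequence classes that change the protein sequence; "other"
## (UTR/intronic/intergenic calls from the panel) is neither synonymous
## nor non-synonymous coding
nonSynonymousClasses <- function() {
  c("missense", "stop_gain", "stop_loss",
    "frameshift_indel", "inframe_indel")
}

structuralHFIClasses <- function() {
  c("stop_gain", "stop_loss", "frameshift_indel")
}

## unique-variant key within and across samples
variantKey <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

## "." and "" are the interchange-format missing markers
.blank <- function(x) is.na(x) | x == "" | x == "."
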