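## Consensus high-functional-impact (HFI) rule.
##
## A variant is HFI when either
##   (a) Mutation Assessor places it in the high or medium
##       functional-importance category AND at least one of the two
##       other predictors (SIFT < 0.05, kinase-specific score "yes")
##       also calls it deleterious; or
##   (b) it is a stop-gain, stop-loss or frame-shifting indel,
##       regardless of predictor scores.
## Synonymous variants are never HFI through clause (a); in-frame
## indels are not HFI through clause (b). Missing scores count as
## non-deleterious: they can never satisfy a clause.

#' Per-predictor deleteriousness verdicts
#'
#' Evaluates the three functional predictors on each variant:
#' Mutation Assessor (deleterious when the category is `high` or
#' `medium`), SIFT (deleterious when the score is present and strictly
#' below 0.05) and the kinase-specific score (deleterious when the
#' verdict is `yes`). Missing scores yield `FALSE`, never an error.
#'
#' @param variants A validated variant data frame
#'   (see [readVariantTable()]).
#' @param siftCutoff SIFT deleteriousness cutoff; scores strictly below
#'   it are deleterious. Default 0.05.
#' @return A `data.frame` with logical columns `ma`, `sift`, `kss`.
#' @examples
#' v <- data.frame(ma_category = c("medium", "neutral"),
#'                 sift_score = c(0.01, 0.05),
#'                 kss_deleterious = c("missing", "no"))
#' predictorVerdicts(v)
#' @export
predictorVerdicts <- function(variants, siftCutoff = 0.05) {
  data.frame(
    ma = variants$ma_category %in% c("high", "medium"),
    sift = !is.na(variants$sift_score) &
      variants$sift_score < siftCutoff,
    kss = variants$kss_deleterious %in% "yes"
  )
}

#' Classify variants as high functional impact (HFI)
#'
#' Applies the consensus HFI decision rule (see the package vignette)
#' to every row of a variant table. The rule clauses are tried in
#' order stop-gain, stop-loss, frameshift, consensus; `rule_fired`
#' records the first that matched (`"none"` otherwise).
#'
#' @inheritParams predictorVerdicts
#' @return A `data.frame` with columns `is_hfi` (logical),
#'   `rule_fired` (one of `stop_gain`, `stop_loss`, `frameshift`,
#'   `consensus`, `none`) and `n_predictors_deleterious` (0--3), one
#'   row per input variant. `is_hfi` is `TRUE` iff `rule_fired` is not
#'   `"none"`.
#' @examples
#' v <- data.frame(variant_class = c("stop_gain", "missense"),
#'                 ma_category = c("missing", "medium"),
#'                 sift_score = c(NA, 0.001),
#'                 kss_deleterious = c("missing", "yes"))
#' classifyHFI(v)
#' @export
classifyHFI <- function(variants, siftCutoff = 0.05) {
  pv <- predictorVerdicts(variants, siftCutoff)
  n <- nrow(pv)
  rule <- rep("none", n)
  cls <- variants$variant_class
  consensus <- pv$ma & (pv$sift | pv$kss) & cls != "synonymous"
  rule[consensus] <- "consensus"
  rule[cls == "frameshift_indel"] <- "frameshift"
  rule[cls == "stop_loss"] <- "stop_loss"
  rule[cls == "stop_gain"] <- "stop_gain"
  data.frame(
    is_hfi = rule != "none",
    rule_fired = rule,
    n_predictors_deleterious = as.integer(pv$ma + pv$sift + pv$kss)
  )
}

#' Restrict variants to the HFI analysis set
#'
#' The analysis set contains the non-synonymous (protein-altering)
#' variants that are HFI and whose read depth strictly exceeds
#' `minCoverage` (so the default retains coverage 21 and drops
#' coverage 20). Synonymous calls and calls of class `other`
#' (non-coding panel regions) are excluded. Order-stable; the input
#' is not modified.
#'
#' @inheritParams predictorVerdicts
#' @param minCoverage Coverage threshold; calls must exceed it
#'   strictly. Default 20.
#' @param coverageMode `"call"` applies the threshold to each call's
#'   own read depth; `"median"` applies it to the median depth across
#'   all samples carrying the same unique variant
#'   (`chrom:pos:ref:alt`).
#' @return The subset of `variants` passing all filters.
#' @export
filterAnalysisSet <- function(variants, minCoverage = 20,
                              coverageMode = c("call", "median"),
                              siftCutoff = 0.05) {
  coverageMode <- match.arg(coverageMode)
  if (nrow(variants) == 0L) return(variants)
  cov <- variants$coverage
  if (coverageMode == "median") {
    cov <- stats::ave(as.numeric(variants$coverage),
                      variantKey(variants), FUN = stats::median)
  }
  hfi <- classifyHFI(variants, siftCutoff)$is_hfi
  keep <- hfi & variants$variant_class %in% nonSynonymousClasses() &
    cov > minCoverage
  variants[keep, , drop = FALSE]
}

#' Predictor consensus over unique variants
#'
#' Deduplicates variants across samples by `(chrom, pos, ref, alt)`
#' (predictor annotations are properties of the variant, so the first
#' record is taken) and tabulates the agreement structure of the three
#' predictors: the seven-region Venn partition, the number of unique
#' variants called deleterious by at least two predictors, and by all
#' three.
#'
#' @inheritParams predictorVerdicts
#' @return A list with `nUnique` (unique variants), `nTwoPlus`,
#'   `nAllThree`, and `venn`, a named integer vector over
#'   `ma_only`, `sift_only`, `kss_only`, `ma_sift`, `ma_kss`,
#'   `sift_kss`, `all_three`, `none`.
#' @export
countPredictorConsensus <- function(variants, siftCutoff = 0.05) {
  empty <- c(ma_only = 0L, sift_only = 0L, kss_only = 0L,
             ma_sift = 0L, ma_kss = 0L, sift_kss = 0L,
             all_three = 0L, none = 0L)
  if (nrow(variants) == 0L) {
    return(list(nUnique = 0L, nTwoPlus = 0L, nAllThree = 0L,
                venn = empty))
  }
  uniq <- variants[!duplicated(variantKey(variants)), , drop = FALSE]
  pv <- predictorVerdicts(uniq, siftCutoff)
  region <- character(nrow(pv))
  region[!pv$ma & !pv$sift & !pv$kss] <- "none"
  region[pv$ma & !pv$sift & !pv$kss] <- "ma_only"
  region[!pv$ma & pv$sift & !pv$kss] <- "sift_only"
  region[!pv$ma & !pv$sift & pv$kss] <- "kss_only"
  region[pv$ma & pv$sift & !pv$kss] <- "ma_sift"
  region[pv$ma & !pv$sift & pv$kss] <- "ma_kss"
  region[!pv$ma & pv$sift & pv$kss] <- "sift_kss"
  region[pv$ma & pv$sift & pv$kss] <- "all_three"
  venn <- empty
  tab <- table(region)
  venn[names(tab)] <- as.integer(tab)
  nDel <- pv$ma + pv$sift + pv$kss
  list(nUnique = nrow(uniq),
       nTwoPlus = sum(nDel >= 2L),
       nAllThree = sum(nDel == 3L),
       venn = venn)
}
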