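## Cohort-level comparisons built on the exact tests.

#' Compare gene-level HFI frequencies between two clinical groups
#'
#' For every gene affected in at least one included sample, builds the
#' 2x2 table of affected counts against the two group sizes, computes
#' the two-sided Fisher exact p-value, and applies the Bonferroni
#' correction with family size equal to the number of genes tested in
#' this contrast. Samples whose covariate value is not in `level1` or
#' `level2` (including unknowns) are excluded, as are samples failing
#' the optional `within` filter.
#'
#' @param x An [HFIMatrix-class] whose `colData` carries the clinical
#'   covariates.
#' @param covariate Name of the `colData` column defining the
#'   contrast, e.g. `"er_status"`, `"grade"`, `"response"`, `"site"`.
#' @param level1,level2 Character vectors of covariate levels forming
#'   group 1 and group 2 (e.g. `level1 = c("1", "2")`,
#'   `level2 = "3"` for a grade 1/2 vs 3 contrast). They must not
#'   overlap.
#' @param within Optional named list restricting the included samples,
#'   e.g. `list(her2_status = "negative")`; each element names a
#'   `colData` column and the values allowed for inclusion.
#' @return A `data.frame` sorted by ascending unadjusted p (ties by
#'   gene symbol) with columns `gene`, `n1_affected`, `n1_total`,
#'   `n2_affected`, `n2_total`, `p_unadjusted`, `p_bonferroni`,
#'   `m_tests`; group sizes are also in attributes `n1` and `n2`.
#' @examples
#' \dontrun{
#' compareGroups(mat, "er_status", "negative", "positive",
#'               within = list(her2_status = "negative"))
#' }
#' @export
compareGroups <- function(x, covariate, level1, level2,
                          within = NULL) {
  md <- as.data.frame(colData(x))
  if (!covariate %in% names(md)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  if (length(intersect(level1, level2))) {
    stop("contrast levels overlap", call. = FALSE)
  }
  include <- rep(TRUE, nrow(md))
  for (nm in names(within)) {
    if (!nm %in% names(md)) {
      stop("unknown 'within' covariate: ", nm, call. = FALSE)
    }
    include <- include & md[[nm]] %in% within[[nm]]
  }
  g1 <- include & md[[covariate]] %in% level1
  g2 <- include & md[[covariate]] %in% level2
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 == 0L || n2 == 0L) {
    stop("contrast level with zero samples", call. = FALSE)
  }
  aff <- hfiAffected(x)
  allGenes <- rownames(aff)
  if (is.null(allGenes)) allGenes <- character(0)
  a <- rowSums(aff[, g1, drop = FALSE])
  c_ <- rowSums(aff[, g2, drop = FALSE])
  keep <- (a + c_) >= 1
  a <- a[keep]
  c_ <- c_[keep]
  genes <- allGenes[keep]
  m <- length(genes)
  p <- vapply(seq_len(m), function(i) {
    as.numeric(fisherExact2x2(a[i], n1 - a[i], c_[i], n2 - c_[i]))
  }, numeric(1))
  out <- data.frame(gene = genes,
                    n1_affected = as.integer(a),
                    n1_total = rep(n1, m),
                    n2_affected = as.integer(c_),
                    n2_total = rep(n2, m),
                    p_unadjusted = p,
                    p_bonferroni = bonferroni(p, m),
                    m_tests = rep(m, m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_unadjusted, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

.presenceMatrix <- function(variants, samples) {
  key <- variantKey(variants)
  tab <- table(factor(key, levels = sort(unique(key))),
               factor(variants$sample_id, levels = samples))
  matrix(tab > 0, nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Somatic-germline variant co-occurrence screen
#'
#' Screens every pair of one known somatic variant (COSMIC-annotated)
#' and one known germline variant (dbSNP-annotated) for co-occurrence
#' or mutual exclusivity across samples, at unique-variant resolution
#' (`chrom:pos:ref:alt`). Each pair yields the 2x2 table of joint
#' presence/absence over all samples, a two-sided Fisher p-value, and
#' a Bonferroni correction over all pairs screened. Pairs with a
#' degenerate table (an empty margin) are flagged and given p = 1.
#'
#' @param variants Analysis-set variant data frame with `dbsnp_id` /
#'   `cosmic_id` columns.
#' @param samples Character vector of all sample ids in the cohort
#'   (absence of a variant in a sample is informative).
#' @return A `data.frame` with one row per (somatic, germline) pair:
#'   the variant keys, cells `n_both`, `n_somatic_only`,
#'   `n_germline_only`, `n_neither`, `odds_ratio`, `direction`
#'   (`co-occurrence`, `exclusivity` or `none`), `degenerate`,
#'   `p_unadjusted`, `p_bonferroni`; sorted by ascending p.
#' @export
cooccurrenceScreen <- function(variants, samples) {
  som <- variants[!is.na(variants$cosmic_id), , drop = FALSE]
  germ <- variants[!is.na(variants$dbsnp_id), , drop = FALSE]
  empty <- data.frame(somatic_variant = character(),
                      germline_variant = character(),
                      n_both = integer(), n_somatic_only = integer(),
                      n_germline_only = integer(),
                      n_neither = integer(), odds_ratio = numeric(),
                      direction = character(), degenerate = logical(),
                      p_unadjusted = numeric(),
                      p_bonferroni = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(som) == 0L || nrow(germ) == 0L) return(empty)
  sm <- .presenceMatrix(som, samples) * 1L
  gm <- .presenceMatrix(germ, samples) * 1L
  pairs <- expand.grid(somatic = rownames(sm), germline = rownames(gm),
                       stringsAsFactors = FALSE)
  keep <- pairs$somatic != pairs$germline
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  ## joint counts for all pairs at once
  both <- tcrossprod(sm, gm)              # somatic x germline
  nS <- rowSums(sm)
  nG <- rowSums(gm)
  a <- as.vector(both)[keep]
  b <- unname(nS[pairs$somatic]) - a
  c_ <- unname(nG[pairs$germline]) - a
  d <- length(samples) - a - b - c_
  degenerate <- (a + b) == 0 | (c_ + d) == 0 |
    (a + c_) == 0 | (b + d) == 0
  p <- vapply(seq_along(a), function(i) {
    if (degenerate[i]) 1 else
      as.numeric(fisherExact2x2(a[i], b[i], c_[i], d[i]))
  }, numeric(1))
  ad <- a * d
  bc <- b * c_
  direction <- ifelse(degenerate | ad == bc, "none",
                      ifelse(ad > bc, "co-occurrence", "exclusivity"))
  out <- data.frame(somatic_variant = pairs$somatic,
                    germline_variant = pairs$germline,
                    n_both = a, n_somatic_only = b,
                    n_germline_only = c_, n_neither = d,
                    odds_ratio = ad / bc, direction = direction,
                    degenerate = degenerate, p_unadjusted = p,
                    p_bonferroni = bonferroni(p, length(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_unadjusted, out$somatic_variant,
                   out$germline_variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare per-sample kinase-group loads between biopsy sites
#'
#' For each kinase group, compares the per-sample variant loads (rows
#' of [perSampleGroupLoads()]) of primary versus metastatic samples
#' with the unpaired two-sided Wilcoxon rank-sum test, Bonferroni
#' corrected over the number of groups.
#'
#' @param loads Kinase-group-by-sample numeric matrix.
#' @param site Character vector (`"primary"` / `"metastatic"`) along
#'   the columns of `loads`, or a metadata data frame with
#'   `sample_id` and `site` columns.
#' @return A `data.frame` with one row per kinase group:
#'   `kinase_group`, group sizes, median loads, `p_unadjusted`,
#'   `p_bonferroni`.
#' @export
compareGroupLoads <- function(loads, site) {
  if (is.data.frame(site)) {
    site <- site$site[match(colnames(loads), site$sample_id)]
  }
  if (length(site) != ncol(loads)) {
    stop("'site' must label every column of 'loads'", call. = FALSE)
  }
  pri <- site == "primary"
  met <- site == "metastatic"
  if (!any(pri) || !any(met)) {
    stop("both primary and metastatic samples are required",
         call. = FALSE)
  }
  p <- apply(loads, 1L, function(z) {
    wilcoxonRankSum(z[pri], z[met])
  })
  out <- data.frame(kinase_group = rownames(loads),
                    n_primary = sum(pri), n_metastatic = sum(met),
                    median_primary = apply(loads[, pri, drop = FALSE],
                                           1L, stats::median),
                    median_metastatic =
                      apply(loads[, met, drop = FALSE], 1L,
                            stats::median),
                    p_unadjusted = as.numeric(p),
                    p_bonferroni = bonferroni(as.numeric(p),
                                              nrow(loads)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Technical-replicate variant call concordance
#'
#' Concordance between two variant call sets from the same source
#' sample, keyed by `(chrom, pos, ref, alt)`. The default metric is
#' the Jaccard index (intersection over union); `"recall"` instead
#' reports the fraction of replicate-1 calls recovered in replicate 2.
#' Concordance is reported overall and stratified by coverage bin,
#' where each call is binned by the minimum of the two replicate
#' coverages (its single coverage when present in only one replicate).
#'
#' @param rep1,rep2 Data frames with `chrom`, `pos`, `ref`, `alt` and
#'   `coverage` columns.
#' @param coverageBins Increasing break points; bins are left-closed,
#'   right-open (`c(0, 20, Inf)` gives `[0,20)` and `[20,Inf)`).
#' @param metric `"jaccard"` or `"recall"`.
#' @return A list with `overall` (numeric; `NA` with attribute
#'   `degenerate = TRUE` when the union is empty), `byBin` (a
#'   `data.frame` of per-bin counts and concordance) and `metric`.
#' @export
replicateConcordance <- function(rep1, rep2,
                                 coverageBins = c(0, 20, Inf),
                                 metric = c("jaccard", "recall")) {
  metric <- match.arg(metric)
  key1 <- variantKey(rep1)
  key2 <- variantKey(rep2)
  cov1 <- tapply(rep1$coverage, key1, min)
  cov2 <- tapply(rep2$coverage, key2, min)
  keys <- union(names(cov1), names(cov2))
  if (!length(keys)) {
    return(list(overall = structure(NA_real_, degenerate = TRUE),
                byBin = data.frame(bin = character(),
                                   n_union = integer(),
                                   n_intersection = integer(),
                                   concordance = numeric()),
                metric = metric))
  }
  in1 <- keys %in% names(cov1)
  in2 <- keys %in% names(cov2)
  minCov <- pmin(cov1[keys], cov2[keys], na.rm = TRUE)
  conc <- function(i1, i2) {
    denom <- if (metric == "jaccard") sum(i1 | i2) else sum(i1)
    if (denom == 0) NA_real_ else sum(i1 & i2) / denom
  }
  bin <- cut(minCov, coverageBins, right = FALSE,
             include.lowest = TRUE)
  byBin <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- !is.na(bin) & bin == b
    data.frame(bin = b, n_union = sum(sel),
               n_intersection = sum(in1[sel] & in2[sel]),
               concordance = conc(in1[sel], in2[sel]),
               stringsAsFactors = FALSE)
  }))
  list(overall = conc(in1, in2), byBin = byBin, metric = metric)
}
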