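## Aggregation of analysis-set HFI calls to gene x sample and
## kinase-group resolution.

## Deterministic sample ordering used for the gene x sample matrix:
## hierarchical by ER, HER2, grade, N stage, T stage, pCR status,
## with unknowns last and sample id as the final tie-break.
.sampleOrder <- function(md) {
  rk <- function(x, levels) {
    r <- match(x, levels)
    r[is.na(r)] <- length(levels) + 1L
    r
  }
  ordinal <- function(x) {
    lev <- sort(setdiff(unique(x), "unknown"))
    rk(x, lev)
  }
  order(rk(md$er_status, c("negative", "positive")),
        rk(md$her2_status, c("negative", "positive")),
        rk(md$grade, c("1", "2", "3")),
        ordinal(md$n_stage),
        ordinal(md$t_stage),
        rk(md$response, c("pCR", "RD")),
        md$sample_id)
}

#' Build the gene-by-sample HFI matrix
#'
#' Tabulates analysis-set HFI variant calls (the output of
#' [filterAnalysisSet()]) into an [HFIMatrix-class]. Every sample in
#' the metadata appears as a column (all-zero columns included); rows
#' are the genes with at least one HFI call. Row order is by
#' descending total count then gene symbol; column order follows the
#' clinical hierarchy ER, HER2, grade, N stage, T stage, response,
#' with unknowns last.
#'
#' @param variants Analysis-set variant data frame.
#' @param metadata Validated sample metadata; every `sample_id` in
#'   `variants` must appear here.
#' @param genes Optional gene annotation; matching rows are attached
#'   as `rowData`.
#' @return An [HFIMatrix-class].
#' @export
buildHFIMatrix <- function(variants, metadata, genes = NULL) {
  unknown <- setdiff(variants$sample_id, metadata$sample_id)
  if (length(unknown)) {
    stop("variant(s) reference unknown sample(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  md <- metadata[.sampleOrder(metadata), , drop = FALSE]
  samples <- md$sample_id
  geneLevels <- sort(unique(variants$gene))
  counts <- table(factor(variants$gene, levels = geneLevels),
                  factor(variants$sample_id, levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(geneLevels),
                   ncol = length(samples),
                   dimnames = list(geneLevels, samples))
  if (nrow(counts) > 1L) {
    ord <- base::order(-rowSums(counts), rownames(counts))
    counts <- counts[ord, , drop = FALSE]
  }
  rowData <- NULL
  if (!is.null(genes)) {
    rowData <- genes[match(rownames(counts), genes$gene), ,
                     drop = FALSE]
    rownames(rowData) <- rownames(counts)
  }
  rownames(md) <- md$sample_id
  HFIMatrix(counts, colData = md, rowData = rowData)
}

#' Per-sample HFI variant summary
#'
#' Mean, minimum and maximum number of analysis-set HFI variant calls
#' per sample (column sums of the count matrix).
#'
#' @param x An [HFIMatrix-class].
#' @return A `data.frame` with columns `mean`, `min`, `max`.
#' @export
perSampleHFISummary <- function(x) {
  cs <- colSums(hfiCounts(x))
  if (!length(cs)) cs <- 0
  data.frame(mean = mean(cs), min = min(cs), max = max(cs))
}

#' Filter out genes with demonstrably low expression
#'
#' Retains genes whose log2 normalized expression is at or above the
#' threshold. Genes with missing expression are retained: absence of
#' evidence of expression is not evidence of low expression, and the
#' filter's purpose is to remove genes demonstrably unexpressed in the
#' tissue.
#'
#' @param genes Validated gene-annotation data frame.
#' @param threshold Log2 expression threshold (default 6.0); values
#'   strictly below it are dropped.
#' @return The retained rows of `genes`.
#' @export
expressionFilter <- function(genes, threshold = 6.0) {
  keep <- is.na(genes$expression_log2) |
    genes$expression_log2 >= threshold
  genes[keep, , drop = FALSE]
}

#' Collapse a probe-by-sample expression matrix to gene level
#'
#' When several probe sets target the same gene, keeps the probe with
#' the highest average (log2) expression; ties on the mean are broken
#' by greater variance, remaining ties by probe identifier order.
#' Probes mapped to no gene are excluded with a warning giving their
#' count.
#'
#' @param expr Numeric probe-by-sample matrix (log2 scale) with probe
#'   identifiers as row names.
#' @param probeToGene Named character vector mapping probe identifier
#'   to gene symbol (`NA` or absent = unmapped).
#' @return A gene-by-sample matrix; the attribute `"probe"` records
#'   the selected probe per gene.
#' @export
collapseProbesets <- function(expr, probeToGene) {
  genes <- probeToGene[rownames(expr)]
  unmapped <- is.na(genes)
  if (any(unmapped)) {
    warning(sum(unmapped), " probe(s) mapped to no gene; excluded")
  }
  expr <- expr[!unmapped, , drop = FALSE]
  genes <- genes[!unmapped]
  means <- rowMeans(expr)
  vars <- apply(expr, 1L, stats::var)
  ord <- order(genes, -means, -vars, rownames(expr))
  first <- !duplicated(genes[ord])
  sel <- ord[first]
  out <- expr[sel, , drop = FALSE]
  probes <- rownames(out)
  rownames(out) <- unname(genes[sel])
  structure(out, probe = stats::setNames(probes, unname(genes[sel])))
}

.loadGeneUniverse <- function(x, genes, expressionThreshold) {
  matGenes <- rownames(x)
  known <- matGenes %in% genes$gene
  if (!all(known)) {
    stop("gene(s) without annotation: ",
         paste(matGenes[!known], collapse = ", "), call. = FALSE)
  }
  expressed <- expressionFilter(genes, expressionThreshold)
  expressed[expressed$kinase_group != "non_kinase", , drop = FALSE]
}

#' Length-normalized HFI variant load per kinase group
#'
#' The variant load of a gene is its total number of analysis-set HFI
#' variant calls across the included samples divided by the gene's
#' nucleotide length; the load of a kinase group is the mean load of
#' its genes. Loads are computed over the expressed kinase genes
#' (after [expressionFilter()]); expressed kinase genes with zero HFI
#' calls contribute a load of 0 to their group mean, and non-kinase
#' genes are excluded.
#'
#' @param x An [HFIMatrix-class].
#' @param genes Validated gene annotation covering every gene of `x`.
#' @param samples Optional character vector of sample ids to pool over
#'   (default: all columns).
#' @param expressionThreshold Passed to [expressionFilter()].
#' @return A list with `perGene` (`gene`, `kinase_group`, `n_hfi`,
#'   `load`) and `groups` (`kinase_group`, `n_genes`, `group_load`).
#' @seealso [perSampleGroupLoads()] for the per-sample variant of the
#'   computation used in site comparisons.
#' @export
computeGroupLoads <- function(x, genes, samples = NULL,
                              expressionThreshold = 6.0) {
  uni <- .loadGeneUniverse(x, genes, expressionThreshold)
  cnt <- hfiCounts(x)
  if (is.null(samples)) samples <- colnames(cnt)
  missing <- setdiff(samples, colnames(cnt))
  if (length(missing)) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(samples)) stop("sample subset is empty", call. = FALSE)
  total <- rowSums(cnt[, samples, drop = FALSE])
  nHFI <- unname(total[match(uni$gene, names(total))])
  nHFI[is.na(nHFI)] <- 0
  load <- nHFI / uni$coding_length_nt
  perGene <- data.frame(gene = uni$gene,
                        kinase_group = uni$kinase_group,
                        n_hfi = as.integer(nHFI), load = load,
                        stringsAsFactors = FALSE)
  groupLoad <- tapply(load, uni$kinase_group, mean)
  nGenes <- tapply(load, uni$kinase_group, length)
  groups <- data.frame(kinase_group = names(groupLoad),
                       n_genes = as.integer(nGenes),
                       group_load = as.numeric(groupLoad),
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$kinase_group), , drop = FALSE]
  rownames(groups) <- NULL
  list(perGene = perGene, groups = groups)
}

#' Per-sample kinase-group variant loads
#'
#' For each sample, the load of each kinase group is the mean over the
#' group's expressed genes of that sample's HFI count divided by gene
#' length. This is the per-sample quantity compared between primary
#' and metastatic samples by [compareGroupLoads()].
#'
#' @inheritParams computeGroupLoads
#' @return A numeric kinase-group-by-sample matrix.
#' @export
perSampleGroupLoads <- function(x, genes, expressionThreshold = 6.0) {
  uni <- .loadGeneUniverse(x, genes, expressionThreshold)
  cnt <- hfiCounts(x)
  full <- matrix(0, nrow(uni), ncol(cnt),
                 dimnames = list(uni$gene, colnames(cnt)))
  inMat <- intersect(uni$gene, rownames(cnt))
  full[inMat, ] <- cnt[inMat, , drop = FALSE]
  loads <- full / uni$coding_length_nt
  groups <- sort(unique(uni$kinase_group))
  out <- t(vapply(groups, function(g) {
    colMeans(loads[uni$kinase_group == g, , drop = FALSE])
  }, numeric(ncol(cnt))))
  rownames(out) <- groups
  out
}
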