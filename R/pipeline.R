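## End-to-end pipeline: classify -> matrix -> loads -> compare, with
## paper-style report tables and a machine-readable run manifest.

.defaultContrasts <- function() {
  list(
    er = list(covariate = "er_status", level1 = "negative",
              level2 = "positive",
              within = list(her2_status = "negative")),
    response = list(covariate = "response", level1 = "pCR",
                    level2 = "RD",
                    within = list(er_status = "negative",
                                  pr_status = "negative",
                                  her2_status = "negative")),
    grade = list(covariate = "grade", level1 = c("1", "2"),
                 level2 = "3", within = NULL),
    site = list(covariate = "site", level1 = "primary",
                level2 = "metastatic", within = NULL)
  )
}

## paper-style rendering: percentages to one decimal, p-values to two
## decimals, full precision kept alongside
.formatComparison <- function(cmp) {
  data.frame(
    gene = cmp$gene,
    n1_affected = cmp$n1_affected, n1_total = cmp$n1_total,
    pct1 = sprintf("%.1f", 100 * cmp$n1_affected / cmp$n1_total),
    n2_affected = cmp$n2_affected, n2_total = cmp$n2_total,
    pct2 = sprintf("%.1f", 100 * cmp$n2_affected / cmp$n2_total),
    p_value = sprintf("%.2f", cmp$p_unadjusted),
    p_unadjusted = cmp$p_unadjusted,
    p_bonferroni = cmp$p_bonferroni,
    stringsAsFactors = FALSE
  )
}

#' Run the full HFI analysis pipeline
#'
#' Executes classify -> matrix -> loads -> compare on the three
#' interchange tables and writes the report bundle to `outDir`:
#' `variants.hfi.tsv` (input columns plus the HFI decision),
#' `hfi_matrix.tsv`, `sample_summary.tsv`, `group_loads.tsv`, one
#' `comparison_<name>.tsv` per contrast (counts with percentages and
#' p-values in the published table style), optionally
#' `cooccurrence.tsv`, and `manifest.json` recording package version,
#' thresholds and input checksums. The pipeline is deterministic:
#' identical inputs and settings produce byte-identical outputs. On
#' any stage failure the partial outputs are removed and the error
#' names the failing stage.
#'
#' @param variantsFile,samplesFile,genesFile Paths to the interchange
#'   tables (see [readVariantTable()] and friends).
#' @param outDir Output directory; must not contain the input files.
#' @param minCoverage,coverageMode Passed to [filterAnalysisSet()].
#' @param expressionThreshold Passed to [expressionFilter()] via the
#'   load computation.
#' @param contrasts Named list of contrast specifications
#'   (`covariate`, `level1`, `level2`, optional `within`); the default
#'   runs the ER (within HER2-negative), response (within
#'   triple-negative), grade 1/2-vs-3 and primary-vs-metastatic
#'   contrasts, each skipped with a warning when a group is empty.
#' @param cooccurrence Also run the somatic-germline co-occurrence
#'   screen (can be slow on large cohorts).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the in-memory results (`analysisSet`,
#'   `matrix`, `summary`, `loads`, `comparisons`, `cooccurrence`,
#'   `manifest`).
#' @export
runPipeline <- function(variantsFile, samplesFile, genesFile, outDir,
                        minCoverage = 20,
                        coverageMode = c("call", "median"),
                        expressionThreshold = 6.0,
                        contrasts = .defaultContrasts(),
                        cooccurrence = FALSE, verbose = FALSE) {
  coverageMode <- match.arg(coverageMode)
  inputs <- c(variants = variantsFile, samples = samplesFile,
              genes = genesFile)
  for (f in inputs) {
    if (!file.exists(f)) stop("input file not found: ", f,
                              call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (any(normalizePath(inputs) %in%
            normalizePath(file.path(outDir,
                                    c("variants.hfi.tsv",
                                      "hfi_matrix.tsv",
                                      "sample_summary.tsv",
                                      "group_loads.tsv",
                                      "manifest.json")),
                          mustWork = FALSE))) {
    stop("outputs would overwrite inputs", call. = FALSE)
  }
  say <- function(...) if (verbose) message("[kinomeHFI] ", ...)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    .writeTSV(df, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  say("reading inputs")
  variants <- stage("read", readVariantTable(variantsFile))
  samples <- stage("read", readSampleMetadata(samplesFile))
  genes <- stage("read", readGeneAnnotation(genesFile))

  say("classifying ", nrow(variants), " variant calls")
  decisions <- stage("classify", classifyHFI(variants))
  emit(cbind(variants, decisions), "variants.hfi.tsv")
  analysis <- stage("filter",
                    filterAnalysisSet(variants, minCoverage,
                                      coverageMode))
  if (nrow(analysis) == 0L) {
    warning("no variants pass the analysis filters; ",
            "matrix and comparisons are empty")
  }

  say("building the gene x sample matrix (",
      nrow(analysis), " analysis-set calls)")
  mat <- stage("matrix", buildHFIMatrix(analysis, samples, genes))
  cnt <- hfiCounts(mat)
  emit(data.frame(gene = rownames(cnt), cnt, check.names = FALSE),
       "hfi_matrix.tsv")
  summ <- perSampleHFISummary(mat)
  emit(summ, "sample_summary.tsv")

  say("computing kinase-group loads")
  loads <- stage("loads",
                 computeGroupLoads(mat, genes,
                                   expressionThreshold =
                                     expressionThreshold))
  emit(loads$groups, "group_loads.tsv")

  comparisons <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    say("contrast: ", nm)
    cmp <- tryCatch(
      compareGroups(mat, ct$covariate, ct$level1, ct$level2,
                    within = ct$within),
      error = function(e) {
        warning("contrast '", nm, "' skipped: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(cmp)) {
      comparisons[[nm]] <- cmp
      emit(.formatComparison(cmp),
           paste0("comparison_", nm, ".tsv"))
    }
  }

  cooc <- NULL
  if (isTRUE(cooccurrence)) {
    say("somatic-germline co-occurrence screen")
    cooc <- stage("cooccur",
                  cooccurrenceScreen(analysis, samples$sample_id))
    emit(cooc, "cooccurrence.tsv")
  }

  manifest <- list(
    package = "kinomeHFI",
    version = as.character(utils::packageVersion("kinomeHFI")),
    settings = list(min_coverage = minCoverage,
                    coverage_mode = coverageMode,
                    expression_threshold = expressionThreshold,
                    contrasts = names(comparisons),
                    cooccurrence = isTRUE(cooccurrence)),
    inputs = as.list(tools::md5sum(inputs)),
    n_variant_calls = nrow(variants),
    n_analysis_set = nrow(analysis),
    n_genes_affected = nrow(mat),
    n_samples = ncol(mat)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outDir)
  invisible(list(analysisSet = analysis, matrix = mat,
                 summary = summ, loads = loads,
                 comparisons = comparisons, cooccurrence = cooc,
                 manifest = manifest))
}
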