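## Tab-delimited interchange formats. All three tables are UTF-8 TSV
## with a header row; "." (or an empty field) denotes a missing value.
## Readers validate every row against the data-model invariants and
## fail with row-number diagnostics rather than silently coercing.

variantColumns <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                    "variant_class", "coverage", "ma_category",
                    "sift_score", "kss_deleterious", "dbsnp_id",
                    "cosmic_id")

metadataColumns <- c("sample_id", "er_status", "pr_status",
                     "her2_status", "grade", "t_stage", "n_stage",
                     "response", "site", "replicate_of")

geneColumns <- c("gene", "kinase_group", "coding_length_nt",
                 "expression_log2")

.readTSV <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character(), check.names = FALSE,
                          quote = "", comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[required]
}

.numOrNA <- function(x) {
  out <- rep(NA_real_, length(x))
  keep <- !.blank(x)
  out[keep] <- suppressWarnings(as.numeric(x[keep]))
  bad <- keep & is.na(out)
  attr(out, "unparseable") <- which(bad)
  out
}

.fail <- function(problems) {
  stop("invalid rows:\n  ",
       paste(utils::head(problems, 20L), collapse = "\n  "),
       if (length(problems) > 20L)
         paste0("\n  ... and ", length(problems) - 20L, " more"),
       call. = FALSE)
}

.checkRows <- function(bad, msg, problems) {
  if (any(bad)) {
    c(problems, paste0("row ", which(bad), ": ", msg))
  } else {
    problems
  }
}

#' Read and validate an annotated variant table
#'
#' Reads a tab-delimited table of annotated variant calls (one row per
#' call in one sample) into a validated data frame. Missing predictor
#' fields (`"."` or empty) become the explicit `missing` category (or
#' `NA` for the numeric SIFT score); they are never coerced to a
#' default score. Rows that violate the data-model invariants abort the
#' read with row-number diagnostics naming the violated constraint.
#'
#' @details Required columns: `sample_id`, `gene`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `variant_class` (one of
#'   [variantClasses()]), `coverage` (read depth, >= 0), `ma_category`
#'   (one of [maCategories()]), `sift_score` (in \[0, 1\] or missing),
#'   `kss_deleterious` (one of [kssVerdicts()]), `dbsnp_id`,
#'   `cosmic_id` (identifiers; presence flags a known germline /
#'   somatic variant). `(sample_id, chrom, pos, ref, alt)` must be
#'   unique.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A `data.frame` with one validated row per variant call;
#'   `pos` and `coverage` are integer, `sift_score` numeric (`NA` when
#'   missing), identifiers are `NA` when absent.
#' @seealso [writeVariantTable()], [readSampleMetadata()],
#'   [readGeneAnnotation()]
#' @export
readVariantTable <- function(path) {
  df <- .readTSV(path, variantColumns, "variant")
  validateVariants(df)
}

#' Validate a variant data frame against the data-model invariants
#'
#' @param df A data frame with the columns of [readVariantTable()]
#'   (character or already-typed).
#' @return The validated, typed data frame (invisibly the same rows).
#' @export
validateVariants <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(variantColumns, names(df))
  if (length(miss)) {
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[variantColumns]
  p <- character()

  pos <- .numOrNA(as.character(df$pos))
  p <- .checkRows(.blank(as.character(df$pos)) | is.na(pos) |
                    pos < 1 | pos != floor(pos),
                  "pos must be a positive 1-based integer", p)
  cov <- .numOrNA(as.character(df$coverage))
  p <- .checkRows(.blank(as.character(df$coverage)) | is.na(cov) |
                    cov < 0 | cov != floor(cov),
                  "coverage must be a non-negative integer", p)
  sift <- .numOrNA(as.character(df$sift_score))
  p <- .checkRows(seq_len(nrow(df)) %in% attr(sift, "unparseable"),
                  "sift_score is not numeric", p)
  p <- .checkRows(!is.na(sift) & (sift < 0 | sift > 1),
                  "sift_score outside [0, 1]", p)

  ma <- as.character(df$ma_category)
  ma[.blank(ma)] <- "missing"
  p <- .checkRows(!ma %in% maCategories(),
                  "ma_category not one of maCategories()", p)
  kss <- as.character(df$kss_deleterious)
  kss[.blank(kss)] <- "missing"
  p <- .checkRows(!kss %in% kssVerdicts(),
                  "kss_deleterious not one of kssVerdicts()", p)
  cls <- as.character(df$variant_class)
  p <- .checkRows(!cls %in% variantClasses(),
                  "variant_class not one of variantClasses()", p)

  ref <- as.character(df$ref); alt <- as.character(df$alt)
  p <- .checkRows(.blank(ref) | .blank(alt),
                  "ref and alt alleles are required", p)
  substitution <- cls %in% c("synonymous", "missense",
                             "stop_gain", "stop_loss")
  indel <- cls %in% c("frameshift_indel", "inframe_indel")
  sameLen <- nchar(ref) == nchar(alt)
  p <- .checkRows(substitution & !sameLen,
                  "substitution classes require len(ref) == len(alt)", p)
  p <- .checkRows(indel & sameLen,
                  "indel classes require len(ref) != len(alt)", p)
  p <- .checkRows(.blank(as.character(df$sample_id)) |
                    .blank(as.character(df$gene)) |
                    .blank(as.character(df$chrom)),
                  "sample_id, gene and chrom are required", p)

  key <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  p <- .checkRows(duplicated(key) | duplicated(key, fromLast = TRUE),
                  "duplicate (sample, chrom, pos, ref, alt) record", p)

  if (length(p)) .fail(p)

  data.frame(
    sample_id = as.character(df$sample_id),
    gene = as.character(df$gene),
    chrom = as.character(df$chrom),
    pos = as.integer(pos),
    ref = ref,
    alt = alt,
    variant_class = cls,
    coverage = as.integer(cov),
    ma_category = ma,
    sift_score = as.numeric(sift),
    kss_deleterious = kss,
    dbsnp_id = ifelse(.blank(as.character(df$dbsnp_id)), NA_character_,
                      as.character(df$dbsnp_id)),
    cosmic_id = ifelse(.blank(as.character(df$cosmic_id)), NA_character_,
                       as.character(df$cosmic_id)),
    stringsAsFactors = FALSE
  )
}

.writeTSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x)) x <- sprintf("%.15g", x)
    x[is.na(df[[j]]) | x == "NA"] <- "."
    out[[j]] <- x
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write a variant table (inverse of [readVariantTable()])
#'
#' Missing values are serialized as `"."`; reading the file back yields
#' the same records.
#'
#' @param df Validated variant data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariantTable <- function(df, path) {
  .writeTSV(validateVariants(df)[variantColumns], path)
}

#' Read and validate a sample-metadata table
#'
#' Clinical covariates of the sequenced samples: hormone-receptor and
#' HER2 status, histologic grade, T/N stage, response to neoadjuvant
#' chemotherapy (pCR = pathologic complete response, RD = residual
#' disease) and biopsy site. Unknown values (`"."` or empty) map to the
#' explicit `unknown` category (response to `not_applicable`) and are
#' preserved, so downstream contrasts can exclude them.
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `er_status`, `pr_status`, `her2_status` (positive/negative/
#'   unknown), `grade` (1/2/3/unknown), `t_stage`, `n_stage`,
#'   `response` (pCR/RD/not_applicable), `site` (primary/metastatic)
#'   and `replicate_of` (sample id of the source aliquot for technical
#'   replicates, or missing).
#' @return A validated `data.frame`, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTSV(path, metadataColumns, "sample metadata")
  validateMetadata(df)
}

#' @rdname readSampleMetadata
#' @param df A data frame with the metadata columns.
#' @export
validateMetadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(metadataColumns, names(df))
  if (length(miss)) {
    stop("sample metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[metadataColumns]
  p <- character()

  unk <- function(x) {
    x <- as.character(x); x[.blank(x)] <- "unknown"; x
  }
  status <- c("positive", "negative", "unknown")
  er <- unk(df$er_status); pr <- unk(df$pr_status)
  her2 <- unk(df$her2_status)
  p <- .checkRows(!er %in% status, "er_status invalid", p)
  p <- .checkRows(!pr %in% status, "pr_status invalid", p)
  p <- .checkRows(!her2 %in% status, "her2_status invalid", p)
  grade <- unk(df$grade)
  p <- .checkRows(!grade %in% c("1", "2", "3", "unknown"),
                  "grade must be 1, 2, 3 or unknown", p)
  resp <- as.character(df$response)
  resp[.blank(resp)] <- "not_applicable"
  p <- .checkRows(!resp %in% c("pCR", "RD", "not_applicable"),
                  "response must be pCR, RD or not_applicable", p)
  site <- as.character(df$site)
  p <- .checkRows(!site %in% c("primary", "metastatic"),
                  "site must be primary or metastatic", p)
  p <- .checkRows(resp != "not_applicable" & site != "primary",
                  "response is only recorded for primary samples", p)
  sid <- as.character(df$sample_id)
  p <- .checkRows(.blank(sid), "sample_id is required", p)
  p <- .checkRows(duplicated(sid) | duplicated(sid, fromLast = TRUE),
                  "duplicate sample_id", p)
  if (length(p)) .fail(p)

  data.frame(
    sample_id = sid, er_status = er, pr_status = pr, her2_status = her2,
    grade = grade, t_stage = unk(df$t_stage), n_stage = unk(df$n_stage),
    response = resp, site = site,
    replicate_of = ifelse(.blank(as.character(df$replicate_of)),
                          NA_character_, as.character(df$replicate_of)),
    stringsAsFactors = FALSE
  )
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(df, path) {
  .writeTSV(validateMetadata(df)[metadataColumns], path)
}

#' Is a sample triple-negative?
#'
#' ER-negative, PR-negative and HER2-negative; any unknown status makes
#' the triple-negative call `NA`.
#'
#' @param metadata A validated sample-metadata data frame.
#' @return A logical vector along the rows of `metadata`.
#' @export
isTripleNegative <- function(metadata) {
  neg <- function(x) ifelse(x == "unknown", NA, x == "negative")
  neg(metadata$er_status) & neg(metadata$pr_status) &
    neg(metadata$her2_status)
}

#' Read and validate a gene-annotation table
#'
#' One row per gene in the analysis universe: kinase-group membership
#' (one of [kinaseGroups()] or `non_kinase`), the nucleotide length
#' used to normalize variant loads, and a log2 expression value
#' (missing allowed).
#'
#' @param path Path to a tab-delimited file with columns `gene`,
#'   `kinase_group`, `coding_length_nt`, `expression_log2`.
#' @return A validated `data.frame`, one row per gene.
#' @export
readGeneAnnotation <- function(path) {
  df <- .readTSV(path, geneColumns, "gene annotation")
  validateGenes(df)
}

#' @rdname readGeneAnnotation
#' @param df A data frame with the gene-annotation columns.
#' @export
validateGenes <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(geneColumns, names(df))
  if (length(miss)) {
    stop("gene annotation is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[geneColumns]
  p <- character()
  gene <- as.character(df$gene)
  p <- .checkRows(.blank(gene), "gene symbol is required", p)
  p <- .checkRows(duplicated(gene) | duplicated(gene, fromLast = TRUE),
                  "duplicate gene symbol", p)
  grp <- as.character(df$kinase_group)
  p <- .checkRows(!grp %in% c(kinaseGroups(), "non_kinase"),
                  "kinase_group not one of kinaseGroups() or non_kinase",
                  p)
  len <- .numOrNA(as.character(df$coding_length_nt))
  p <- .checkRows(is.na(len) | len < 1 | len != floor(len),
                  "coding_length_nt must be a positive integer", p)
  expr <- .numOrNA(as.character(df$expression_log2))
  p <- .checkRows(seq_len(nrow(df)) %in% attr(expr, "unparseable"),
                  "expression_log2 is not numeric", p)
  if (length(p)) .fail(p)

  data.frame(gene = gene, kinase_group = grp,
             coding_length_nt = as.integer(len),
             expression_log2 = as.numeric(expr),
             stringsAsFactors = FALSE)
}

#' @rdname readGeneAnnotation
#' @export
writeGeneAnnotation <- function(df, path) {
  .writeTSV(validateGenes(df)[geneColumns], path)
}
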