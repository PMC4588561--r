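## Optional VCF import. The interchange format is the post-annotation
## TSV; this importer maps annotation INFO keys of a VCF (v4.x) onto
## that schema through a user-supplied field mapping, one record per
## ALT allele. It requires the VariantAnnotation package.

#' Import annotated variants from a VCF file
#'
#' Maps INFO fields of an annotated VCF onto the variant interchange
#' schema (see [readVariantTable()]), producing one record per ALT
#' allele per sample. The mapping names, for each schema column, the
#' INFO key that carries it; coverage is taken from the per-genotype
#' `DP` field when present, else from an INFO key named in the
#' mapping. Fields without a mapped key become missing values, never
#' default scores.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param mapping Named list (or path to a YAML file with one) mapping
#'   schema columns `gene`, `variant_class`, `ma_category`,
#'   `sift_score`, `kss_deleterious`, `dbsnp_id`, `cosmic_id` and
#'   optionally `coverage` to INFO keys. `variant_class` values must
#'   already use the [variantClasses()] vocabulary, or a named
#'   character vector `mapping$class_recode` can translate them.
#' @return A validated variant data frame.
#' @export
importVariantVCF <- function(path, mapping) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("importVariantVCF() requires the VariantAnnotation package",
         call. = FALSE)
  }
  if (is.character(mapping) && length(mapping) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML mapping requires the yaml package",
           call. = FALSE)
    }
    mapping <- yaml::read_yaml(mapping)
  }
  if (is.null(mapping$gene) || is.null(mapping$variant_class)) {
    stop("mapping must name INFO keys for at least 'gene' and ",
         "'variant_class'", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  nAlt <- lengths(rr$ALT)
  idx <- rep(seq_along(rr), nAlt)

  pull <- function(field, default = NA_character_) {
    key <- mapping[[field]]
    if (is.null(key) || !key %in% names(info)) {
      return(rep(default, length(idx)))
    }
    x <- info[[key]]
    if (is(x, "List") || is.list(x)) {
      x <- vapply(x, function(e) {
        if (length(e)) as.character(e[1]) else NA_character_
      }, character(1))
    }
    as.character(x)[idx]
  }

  samples <- colnames(vcf)
  sampleId <- if (length(samples) == 1L) samples else
    if (!is.null(mapping$sample_id)) mapping$sample_id else
      stop("multi-sample VCF needs mapping$sample_id", call. = FALSE)

  coverage <- rep(NA_character_, length(idx))
  geno <- VariantAnnotation::geno(vcf)
  if ("DP" %in% names(geno) && length(samples) == 1L) {
    coverage <- as.character(geno$DP[idx, 1L])
  } else {
    coverage <- pull("coverage")
  }

  cls <- pull("variant_class")
  recode <- mapping$class_recode
  if (!is.null(recode)) {
    hit <- cls %in% names(recode)
    cls[hit] <- unlist(recode)[cls[hit]]
  }

  df <- data.frame(
    sample_id = rep(sampleId, length(idx)),
    gene = pull("gene"),
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = as.character(GenomicRanges::start(rr))[idx],
    ref = as.character(rr$REF)[idx],
    alt = as.character(unlist(rr$ALT)),
    variant_class = cls,
    coverage = coverage,
    ma_category = pull("ma_category"),
    sift_score = pull("sift_score"),
    kss_deleterious = pull("kss_deleterious"),
    dbsnp_id = pull("dbsnp_id"),
    cosmic_id = pull("cosmic_id"),
    stringsAsFactors = FALSE
  )
  validateVariants(df)
}
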