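# Independent oracles and fixture builders. Each oracle is coded from
# first principles, deliberately avoiding the code paths of the
# package functions it checks.

# brute-force two-sided Fisher p: enumerate the full hypergeometric
# support, probabilities from binomial coefficients
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 + r2 == 0) return(1)
  support <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, support) * choose(r2, k - support) /
    choose(r1 + r2, k)
  pObs <- probs[support == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force two-sided rank-sum p: enumerate every assignment of the
# pooled observations to group 1 with combn
oracleWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(pooled), n1), 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# independently coded HFI predicate (scalar, explicit branching)
oracleHFI <- function(cls, ma, sift, kss) {
  if (cls == "stop_gain") return(TRUE)
  if (cls == "stop_loss") return(TRUE)
  if (cls == "frameshift_indel") return(TRUE)
  if (cls == "synonymous") return(FALSE)
  anchor <- ma %in% c("high", "medium")
  second <- FALSE
  if (!is.na(sift) && sift < 0.05) second <- TRUE
  if (kss == "yes") second <- TRUE
  anchor && second
}

# random valid variant records for round-trip and property tests
randomVariants <- function(n, sampleIds = sprintf("S%02d", 1:4)) {
  cls <- sample(variantClasses(), n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (cls[i] %in% c("frameshift_indel", "inframe_indel")) {
      paste0(ref[i], paste(sample(c("A", "C", "G", "T"),
                                  if (cls[i] == "inframe_indel") 3 else 1,
                                  replace = TRUE), collapse = ""))
    } else {
      sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    }
  }, character(1))
  sift <- round(runif(n), 4)
  sift[runif(n) < 0.2] <- NA
  df <- data.frame(
    sample_id = sample(sampleIds, n, replace = TRUE),
    gene = sample(sprintf("GENE%02d", 1:8), n, replace = TRUE),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = ref, alt = alt, variant_class = cls,
    coverage = sample.int(500, n, replace = TRUE),
    ma_category = sample(maCategories(), n, replace = TRUE),
    sift_score = sift,
    kss_deleterious = sample(kssVerdicts(), n, replace = TRUE),
    dbsnp_id = ifelse(runif(n) < 0.5, sprintf("rs%d", 1:n),
                      NA_character_),
    cosmic_id = ifelse(runif(n) < 0.2, sprintf("COSM%d", 1:n),
                       NA_character_),
    stringsAsFactors = FALSE
  )
  df[!duplicated(paste(df$sample_id, df$chrom, df$pos, df$ref,
                       df$alt)), ]
}

# minimal single-variant record for classifier tests
mkVariant <- function(cls = "missense", ma = "missing", sift = NA,
                      kss = "missing", coverage = 100L) {
  data.frame(variant_class = cls, ma_category = ma,
             sift_score = sift, kss_deleterious = kss,
             coverage = coverage, chrom = "chr1", pos = 1L,
             ref = "G",
             alt = if (cls %in% c("frameshift_indel",
                                  "inframe_indel")) "GA" else "T",
             stringsAsFactors = FALSE)
}

variantKeyForTest <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# a guaranteed analysis-set HFI call (used to encode fixture cohorts)
hfiCall <- function(sample_id, gene, pos) {
  data.frame(sample_id = sample_id, gene = gene, chrom = "chr1",
             pos = pos, ref = "G", alt = "T",
             variant_class = "missense", coverage = 400L,
             ma_category = "high", sift_score = 0.001,
             kss_deleterious = "yes", dbsnp_id = NA_character_,
             cosmic_id = NA_character_, stringsAsFactors = FALSE)
}

# build a cohort whose per-gene affected counts in two groups encode a
# published contingency table. `counts` is a data.frame with columns
# gene, k1, k2; group sizes n1, n2; `assign` returns the metadata
# data.frame for the n1 + n2 samples (group 1 first).
tableFixture <- function(counts, n1, n2, metadata) {
  stopifnot(nrow(metadata) == n1 + n2)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    g <- counts$gene[i]
    aff <- c(metadata$sample_id[seq_len(counts$k1[i])],
             metadata$sample_id[n1 + seq_len(counts$k2[i])])
    for (s in aff) {
      rows[[length(rows) + 1L]] <- hfiCall(s, g, 1000L + i)
    }
  }
  do.call(rbind, rows)
}

baseMetadata <- function(sampleIds) {
  data.frame(sample_id = sampleIds, er_status = "unknown",
             pr_status = "unknown", her2_status = "unknown",
             grade = "unknown", t_stage = "unknown",
             n_stage = "unknown", response = "not_applicable",
             site = "primary", replicate_of = NA_character_,
             stringsAsFactors = FALSE)
}
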