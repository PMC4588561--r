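## Seeded synthetic-cohort generator.
##
## Emulates the statistical structure of annotated targeted kinome
## sequencing of a neoadjuvant breast-cancer cohort: ~1052 variant
## calls per sample (negative binomial, range roughly 500-1550), ~97%
## cataloged in dbSNP or COSMIC, a few-hundred-fold mean coverage,
## predictor scores drawn conditionally on a latent "truly
## deleterious" flag, and clinical covariates with optional planted
## gene-subtype enrichments, somatic-germline co-occurring pairs and
## site-specific kinase-group load multipliers. Every planted effect
## and each sample's true per-gene HFI counts are returned as ground
## truth.

.defaultGroupSizes <- c(AGC = 63, Atypical = 40, CAMK = 74, CK1 = 12,
                        CMGC = 61, Other = 83, RGC = 5, STE = 47,
                        TK = 90, TKL = 43)

.checkProb <- function(x, nm) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("'", nm, "' must be probabilities in [0, 1]", call. = FALSE)
  }
}

#' Configuration of the synthetic cohort generator
#'
#' Returns a validated configuration object for [simulateCohort()].
#' Defaults encode the cohort the generator emulates: 92 samples
#' (19 metastatic), clinical covariate frequencies matching a
#' neoadjuvant breast-cancer series, a mean of 1052 variant calls per
#' sample, 97% of calls cataloged in dbSNP/COSMIC, and mean coverage
#' 369x. See the package vignette for the rationale behind each value.
#'
#' @param nSamples Number of samples.
#' @param metastaticFraction Fraction of samples from metastatic
#'   lesions (the rest are primary).
#' @param erProbs,prProbs,her2Probs Named probabilities over
#'   `positive`, `negative`, `unknown`.
#' @param gradeProbs Named probabilities over `1`, `2`, `3`,
#'   `unknown`.
#' @param tStageProbs,nStageProbs Named probabilities over stage
#'   labels (may include `unknown`).
#' @param pCRProb Probability of pathologic complete response for a
#'   primary sample.
#' @param meanVariantsPerSample,variantCountDispersion Negative
#'   binomial mean and size of the per-sample variant-call count.
#' @param classProbs Named probabilities over [variantClasses()].
#' @param fracKnown Fraction of calls carrying a dbSNP or COSMIC
#'   identifier.
#' @param knownSplit Named probabilities over `both`, `dbsnp`,
#'   `cosmic` for a known call's catalog membership.
#' @param coverageMean,coverageDispersion Negative binomial mean and
#'   size of per-call read depth.
#' @param latentDeleteriousProb Probability that a missense or
#'   in-frame variant is truly deleterious (structural stop-gain /
#'   stop-loss / frameshift calls are deleterious by construction).
#' @param maProbsDeleterious,maProbsBenign Mutation Assessor category
#'   probabilities conditional on the latent flag.
#' @param siftDeleteriousRate Named (`deleterious`, `benign`)
#'   probabilities that the SIFT score falls below 0.05.
#' @param kssYesProb Named (`deleterious`, `benign`) probabilities of
#'   a `yes` kinase-specific verdict.
#' @param missingProb Named (`ma`, `sift`, `kss`) probabilities that
#'   a predictor annotation is missing.
#' @param groupSizes Named integer vector of kinase-group sizes
#'   (defaults to the canonical ten-group kinome of 518 genes).
#' @param nNonKinase Number of additional non-kinase cancer genes on
#'   the panel.
#' @param geneLengthMeanlog,geneLengthSdlog,minGeneLength Log-normal
#'   gene-length model (nucleotides).
#' @param exprMean,exprSd,exprMissingProb Gene log2-expression model.
#' @param plantedEnrichments `NULL` or a `data.frame` with columns
#'   `gene`, `covariate`, `level`, `odds_ratio`,
#'   `baseline_prevalence`: samples in `level` of `covariate` are
#'   HFI-affected in `gene` with the odds-ratio-shifted prevalence,
#'   others with the baseline.
#' @param plantedCooccurrence `NULL` or a `data.frame` with columns
#'   `odds_ratio`, `prev_somatic`, `prev_germline`: pairs of one
#'   COSMIC-flagged and one dbSNP-flagged HFI variant with the given
#'   per-sample marginal prevalences and joint odds ratio.
#' @param loadMultipliers `NULL` or a named numeric vector of HFI-load
#'   multipliers applied to metastatic samples per kinase group.
#' @return A `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(nSamples = 92,
                             metastaticFraction = 19 / 92,
                             erProbs = c(positive = 0.48,
                                         negative = 0.51,
                                         unknown = 0.01),
                             prProbs = c(positive = 0.36,
                                         negative = 0.63,
                                         unknown = 0.01),
                             her2Probs = c(positive = 0.02,
                                           negative = 0.59,
                                           unknown = 0.39),
                             gradeProbs = c("1" = 0.01, "2" = 0.29,
                                            "3" = 0.61,
                                            unknown = 0.09),
                             tStageProbs = c(T0 = 0.02, T1 = 0.10,
                                             T2 = 0.46, T3 = 0.18,
                                             T4 = 0.22,
                                             unknown = 0.02),
                             nStageProbs = c(N0 = 0.24, N1 = 0.75,
                                             unknown = 0.01),
                             pCRProb = 0.35,
                             meanVariantsPerSample = 1052,
                             variantCountDispersion = 28,
                             classProbs = c(synonymous = 0.26,
                                            missense = 0.135,
                                            stop_gain = 0.002,
                                            stop_loss = 0.0005,
                                            frameshift_indel = 0.003,
                                            inframe_indel = 0.0025,
                                            other = 0.597),
                             fracKnown = 0.97,
                             knownSplit = c(both = 0.05,
                                            dbsnp = 0.85,
                                            cosmic = 0.10),
                             coverageMean = 369,
                             coverageDispersion = 2,
                             latentDeleteriousProb = 0.02,
                             maProbsDeleterious = c(high = 0.55,
                                                    medium = 0.33,
                                                    low = 0.07,
                                                    neutral = 0.05),
                             maProbsBenign = c(high = 0.08,
                                               medium = 0.37,
                                               low = 0.25,
                                               neutral = 0.30),
                             siftDeleteriousRate =
                               c(deleterious = 0.85, benign = 0.25),
                             kssYesProb = c(deleterious = 0.75,
                                            benign = 0.10),
                             missingProb = c(ma = 0.03, sift = 0.08,
                                             kss = 0.35),
                             groupSizes = .defaultGroupSizes,
                             nNonKinase = 68,
                             geneLengthMeanlog = log(2500),
                             geneLengthSdlog = 0.5,
                             minGeneLength = 300,
                             exprMean = 7.5, exprSd = 1.5,
                             exprMissingProb = 0.10,
                             plantedEnrichments = NULL,
                             plantedCooccurrence = NULL,
                             loadMultipliers = NULL) {
  cfg <- as.list(environment())
  .checkProb(c(metastaticFraction, erProbs, prProbs, her2Probs,
               gradeProbs, tStageProbs, nStageProbs, pCRProb,
               classProbs, fracKnown, knownSplit,
               latentDeleteriousProb, maProbsDeleterious,
               maProbsBenign, siftDeleteriousRate, kssYesProb,
               missingProb, exprMissingProb), "probability parameters")
  stopifnot(nSamples >= 1, meanVariantsPerSample > 0,
            variantCountDispersion > 0, coverageMean > 0,
            coverageDispersion > 0, all(groupSizes >= 0),
            nNonKinase >= 0, minGeneLength >= 1)
  if (!setequal(names(groupSizes), kinaseGroups())) {
    stop("'groupSizes' must name the ten kinase groups",
         call. = FALSE)
  }
  if (abs(sum(classProbs) - 1) > 1e-6 ||
      !setequal(names(classProbs), variantClasses())) {
    stop("'classProbs' must be a distribution over variantClasses()",
         call. = FALSE)
  }
  pe <- plantedEnrichments
  if (!is.null(pe)) {
    need <- c("gene", "covariate", "level", "odds_ratio",
              "baseline_prevalence")
    if (!all(need %in% names(pe))) {
      stop("'plantedEnrichments' needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(pe$odds_ratio <= 0)) {
      stop("planted odds ratios must be > 0", call. = FALSE)
    }
    .checkProb(pe$baseline_prevalence, "baseline_prevalence")
    if (any(pe$baseline_prevalence %in% c(0, 1) &
              pe$odds_ratio != 1)) {
      stop("planted enrichment infeasible: a degenerate baseline ",
           "prevalence cannot carry an odds ratio", call. = FALSE)
    }
  }
  pc <- plantedCooccurrence
  if (!is.null(pc)) {
    need <- c("odds_ratio", "prev_somatic", "prev_germline")
    if (!all(need %in% names(pc))) {
      stop("'plantedCooccurrence' needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(pc$odds_ratio <= 0)) {
      stop("planted odds ratios must be > 0", call. = FALSE)
    }
    .checkProb(c(pc$prev_somatic, pc$prev_germline), "prevalences")
    ## fail early on infeasible joint distributions
    for (i in seq_len(nrow(pc))) {
      .jointProb(pc$prev_somatic[i], pc$prev_germline[i],
                 pc$odds_ratio[i])
    }
  }
  if (!is.null(loadMultipliers)) {
    bad <- setdiff(names(loadMultipliers), kinaseGroups())
    if (length(bad) || any(loadMultipliers <= 0)) {
      stop("'loadMultipliers' must be positive and named by kinase ",
           "groups", call. = FALSE)
    }
  }
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nSamples, "samples,",
      sum(x$groupSizes), "kinases +", x$nNonKinase,
      "other cancer genes\n")
  cat(sprintf("  mean variants/sample %.0f, %.0f%% cataloged, mean coverage %.0fx\n",
              x$meanVariantsPerSample, 100 * x$fracKnown,
              x$coverageMean))
  cat("  planted effects:",
      if (is.null(x$plantedEnrichments)) 0
      else nrow(x$plantedEnrichments), "enrichment(s),",
      if (is.null(x$plantedCooccurrence)) 0
      else nrow(x$plantedCooccurrence), "co-occurring pair(s),",
      if (is.null(x$loadMultipliers)) 0
      else length(x$loadMultipliers), "load multiplier(s)\n")
  invisible(x)
}

## joint P(both) for two Bernoulli margins with a given odds ratio
## (root of the standard quadratic); errors when infeasible
.jointProb <- function(pS, pG, or) {
  if (or != 1 && (pS <= 0 || pS >= 1 || pG <= 0 || pG >= 1)) {
    stop("planted co-occurrence odds ratio infeasible: a degenerate ",
         "marginal prevalence cannot carry an association",
         call. = FALSE)
  }
  if (or == 1) {
    p11 <- pS * pG
  } else {
    aa <- or - 1
    bb <- -(1 + (pS + pG) * (or - 1))
    cc <- or * pS * pG
    disc <- bb^2 - 4 * aa * cc
    if (disc < 0) {
      stop("planted co-occurrence odds ratio infeasible for the ",
           "given prevalences", call. = FALSE)
    }
    p11 <- (-bb - sqrt(disc)) / (2 * aa)
  }
  lo <- max(0, pS + pG - 1)
  hi <- min(pS, pG)
  if (is.na(p11) || p11 < lo - 1e-9 || p11 > hi + 1e-9) {
    stop("planted co-occurrence odds ratio infeasible for the ",
         "given prevalences", call. = FALSE)
  }
  min(max(p11, lo), hi)
}

## odds-ratio-shifted prevalence
.shiftPrevalence <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

.sampleCat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.simGenes <- function(cfg) {
  groups <- rep(names(cfg$groupSizes), cfg$groupSizes)
  nK <- length(groups)
  gene <- c(sprintf("KIN%04d", seq_len(nK)),
            if (cfg$nNonKinase > 0)
              sprintf("CGN%03d", seq_len(cfg$nNonKinase)))
  group <- c(groups, rep("non_kinase", cfg$nNonKinase))
  n <- length(gene)
  len <- pmax(cfg$minGeneLength,
              round(stats::rlnorm(n, cfg$geneLengthMeanlog,
                                  cfg$geneLengthSdlog)))
  expr <- stats::rnorm(n, cfg$exprMean, cfg$exprSd)
  expr[stats::runif(n) < cfg$exprMissingProb] <- NA_real_
  data.frame(gene = gene, kinase_group = group,
             coding_length_nt = as.integer(len),
             expression_log2 = expr, stringsAsFactors = FALSE)
}

.simMetadata <- function(cfg) {
  n <- cfg$nSamples
  sid <- sprintf("S%03d", seq_len(n))
  nMet <- round(cfg$metastaticFraction * n)
  site <- rep("primary", n)
  if (nMet > 0) site[sample(n, nMet)] <- "metastatic"
  resp <- rep("not_applicable", n)
  pri <- site == "primary"
  resp[pri] <- ifelse(stats::runif(sum(pri)) < cfg$pCRProb,
                      "pCR", "RD")
  data.frame(sample_id = sid,
             er_status = .sampleCat(n, cfg$erProbs),
             pr_status = .sampleCat(n, cfg$prProbs),
             her2_status = .sampleCat(n, cfg$her2Probs),
             grade = .sampleCat(n, cfg$gradeProbs),
             t_stage = .sampleCat(n, cfg$tStageProbs),
             n_stage = .sampleCat(n, cfg$nStageProbs),
             response = resp, site = site,
             replicate_of = NA_character_,
             stringsAsFactors = FALSE)
}

.BASES <- c("A", "C", "G", "T")

## one sample's background variant calls, as a list of columns.
## geneWeights are the length-proportional sampling weights; genes
## whose affected status is defined by a planted enrichment carry
## weight zero so the planted odds ratio is realized exactly.
.simSampleVariants <- function(cfg, sid, genes, geneWeights) {
  n <- stats::rnbinom(1L, size = cfg$variantCountDispersion,
                      mu = cfg$meanVariantsPerSample)
  if (n == 0L) return(NULL)
  cls <- .sampleCat(n, cfg$classProbs)
  gi <- sample.int(nrow(genes), n, replace = TRUE,
                   prob = geneWeights)
  pos <- 1L + as.integer(floor(stats::runif(n) *
                                 genes$coding_length_nt[gi]))
  ref <- .BASES[sample.int(4L, n, replace = TRUE)]
  alt <- .BASES[(match(ref, .BASES) +
                   sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L]
  ins <- .BASES[sample.int(4L, n, replace = TRUE)]
  fs <- cls == "frameshift_indel"
  alt[fs] <- paste0(ref[fs], ins[fs])
  inf <- cls == "inframe_indel"
  alt[inf] <- paste0(ref[inf], ins[inf], ins[inf], ins[inf])
  coverage <- stats::rnbinom(n, size = cfg$coverageDispersion,
                             mu = cfg$coverageMean)

  structural <- cls %in% structuralHFIClasses()
  scored <- cls %in% c("missense", "inframe_indel")
  latent <- structural |
    (scored & stats::runif(n) < cfg$latentDeleteriousProb)

  ma <- character(n)
  ma[latent] <- .sampleCat(sum(latent), cfg$maProbsDeleterious)
  ma[!latent] <- .sampleCat(sum(!latent), cfg$maProbsBenign)
  ma[stats::runif(n) < cfg$missingProb[["ma"]]] <- "missing"

  siftRate <- numeric(n)
  siftRate[latent] <- cfg$siftDeleteriousRate[["deleterious"]]
  siftRate[!latent] <- cfg$siftDeleteriousRate[["benign"]]
  siftLow <- stats::runif(n) < siftRate
  u <- stats::runif(n)
  sift <- 0.05 + 0.95 * u
  sift[siftLow] <- 0.05 * u[siftLow]
  sift[stats::runif(n) < cfg$missingProb[["sift"]]] <- NA_real_

  kssRate <- numeric(n)
  kssRate[latent] <- cfg$kssYesProb[["deleterious"]]
  kssRate[!latent] <- cfg$kssYesProb[["benign"]]
  kss <- rep("no", n)
  kss[stats::runif(n) < kssRate] <- "yes"
  kss[stats::runif(n) < cfg$missingProb[["kss"]]] <- "missing"

  known <- stats::runif(n) < cfg$fracKnown
  cat3 <- .sampleCat(n, cfg$knownSplit)
  dbsnp <- rep(NA_character_, n)
  isDb <- known & cat3 %in% c("both", "dbsnp")
  dbsnp[isDb] <- paste0("rs", gi[isDb], "x", pos[isDb])
  cosmic <- rep(NA_character_, n)
  isCos <- known & cat3 %in% c("both", "cosmic")
  cosmic[isCos] <- paste0("COSM", gi[isCos], "x", pos[isCos])

  out <- list(sample_id = rep(sid, n), gene = genes$gene[gi],
              chrom = genes$chrom[gi], pos = pos, ref = ref,
              alt = alt, variant_class = cls,
              coverage = as.integer(coverage), ma_category = ma,
              sift_score = sift, kss_deleterious = kss,
              dbsnp_id = dbsnp, cosmic_id = cosmic, latent = latent)
  ## drop within-sample duplicate sites
  key <- paste(out$chrom, out$pos, out$ref, out$alt)
  keep <- !duplicated(key)
  lapply(out, `[`, keep)
}

## a guaranteed-HFI, guaranteed-analysis-set injected variant
.injectVariant <- function(cfg, sid, gene, genes, pos = NULL,
                           dbsnp = NA_character_,
                           cosmic = NA_character_) {
  gi <- match(gene, genes$gene)
  if (is.null(pos)) {
    pos <- 1L + as.integer(floor(stats::runif(1) *
                                   genes$coding_length_nt[gi]))
  }
  cov <- max(21L, as.integer(stats::rnbinom(1L,
                                            size = cfg$coverageDispersion,
                                            mu = cfg$coverageMean)))
  list(sample_id = sid, gene = gene, chrom = genes$chrom[gi],
       pos = as.integer(pos), ref = "G", alt = "T",
       variant_class = "missense", coverage = cov,
       ma_category = "high", sift_score = 0.001,
       kss_deleterious = "yes", dbsnp_id = dbsnp, cosmic_id = cosmic,
       latent = TRUE)
}

#' Simulate a synthetic annotated-variant cohort
#'
#' Generates a full cohort in the interchange formats of
#' [readVariantTable()], [readSampleMetadata()] and
#' [readGeneAnnotation()], together with a ground-truth record of the
#' latent deleterious flag of every call, each sample's true per-gene
#' HFI counts, and every planted effect. The same `config` and `seed`
#' always produce byte-identical output; per-sample variant streams
#' use substream seeds derived as `(seed + 77777 * sample index) mod
#' (2^31 - 1)`, so a sample's calls do not depend on the order in
#' which samples are generated.
#'
#' @param config A [simulationConfig()].
#' @param seed Integer random seed.
#' @return A list with `variants`, `samples`, `genes` (validated data
#'   frames) and `groundTruth`, a list holding `latent` (per-call
#'   flags keyed by sample and variant), `trueCounts` (gene-by-sample
#'   true HFI count matrix over the analysis filters), and the planted
#'   `enrichments`, `cooccurrence` and `loadMultipliers` bookkeeping.
#' @seealso [writeCohort()], [simulateReplicates()]
#' @export
simulateCohort <- function(config = simulationConfig(), seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(as.integer(seed))
  genes <- .simGenes(cfg)
  genes$chrom <- paste0("chr", 1 + (seq_len(nrow(genes)) %% 22))
  md <- .simMetadata(cfg)

  pe <- cfg$plantedEnrichments
  if (!is.null(pe)) {
    bad <- setdiff(pe$gene, genes$gene)
    if (length(bad)) {
      stop("planted gene(s) not in the simulated universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    badCov <- setdiff(pe$covariate, names(md))
    if (length(badCov)) {
      stop("planted covariate(s) unknown: ",
           paste(badCov, collapse = ", "), call. = FALSE)
    }
  }

  geneWeights <- as.numeric(genes$coding_length_nt)
  if (!is.null(pe)) geneWeights[genes$gene %in% pe$gene] <- 0
  cols <- vector("list", cfg$nSamples)
  for (i in seq_len(cfg$nSamples)) {
    set.seed((as.integer(seed) + 77777L * i) %% 2147483647L)
    cols[[i]] <- .simSampleVariants(cfg, md$sample_id[i], genes,
                                    geneWeights)
  }
  cols <- Filter(Negate(is.null), cols)
  nm <- names(cols[[1]])
  variants <- lapply(stats::setNames(nm, nm), function(f) {
    unlist(lapply(cols, `[[`, f), use.names = FALSE)
  })

  ## deterministic stream for planted effects, independent of the
  ## per-sample substreams
  set.seed((as.integer(seed) + 999983L) %% 2147483647L)
  gt <- list(enrichments = NULL, cooccurrence = NULL,
             loadMultipliers = cfg$loadMultipliers)
  extra <- list()

  if (!is.null(pe)) {
    book <- vector("list", nrow(pe))
    for (j in seq_len(nrow(pe))) {
      inLevel <- md[[pe$covariate[j]]] %in%
        strsplit(pe$level[j], "|", fixed = TRUE)[[1]]
      p1 <- .shiftPrevalence(pe$baseline_prevalence[j],
                             pe$odds_ratio[j])
      pAff <- ifelse(inLevel, p1, pe$baseline_prevalence[j])
      affected <- stats::runif(cfg$nSamples) < pAff
      for (s in which(affected)) {
        extra[[length(extra) + 1L]] <-
          .injectVariant(cfg, md$sample_id[s], pe$gene[j], genes)
      }
      book[[j]] <- data.frame(gene = pe$gene[j],
                              covariate = pe$covariate[j],
                              level = pe$level[j],
                              odds_ratio = pe$odds_ratio[j],
                              sample_id = md$sample_id,
                              in_level = inLevel,
                              planted_affected = affected,
                              stringsAsFactors = FALSE)
    }
    gt$enrichments <- do.call(rbind, book)
  }

  pc <- cfg$plantedCooccurrence
  if (!is.null(pc)) {
    book <- vector("list", nrow(pc))
    for (j in seq_len(nrow(pc))) {
      p11 <- .jointProb(pc$prev_somatic[j], pc$prev_germline[j],
                        pc$odds_ratio[j])
      p10 <- pc$prev_somatic[j] - p11
      p01 <- pc$prev_germline[j] - p11
      cell <- sample(c("both", "som", "germ", "none"), cfg$nSamples,
                     replace = TRUE,
                     prob = c(p11, p10, p01,
                              1 - p11 - p10 - p01))
      gS <- genes$gene[sample.int(nrow(genes), 1L)]
      gG <- genes$gene[sample.int(nrow(genes), 1L)]
      posS <- 1L
      posG <- 2L
      for (s in seq_len(cfg$nSamples)) {
        if (cell[s] %in% c("both", "som")) {
          extra[[length(extra) + 1L]] <-
            .injectVariant(cfg, md$sample_id[s], gS, genes,
                           pos = posS,
                           cosmic = sprintf("COSMPAIR%d", j))
        }
        if (cell[s] %in% c("both", "germ")) {
          extra[[length(extra) + 1L]] <-
            .injectVariant(cfg, md$sample_id[s], gG, genes,
                           pos = posG,
                           dbsnp = sprintf("rsPAIR%d", j))
        }
      }
      book[[j]] <- data.frame(pair = j, somatic_gene = gS,
                              germline_gene = gG,
                              odds_ratio = pc$odds_ratio[j],
                              sample_id = md$sample_id, cell = cell,
                              stringsAsFactors = FALSE)
    }
    gt$cooccurrence <- do.call(rbind, book)
  }

  lm <- cfg$loadMultipliers
  if (!is.null(lm)) {
    ## expected background HFI calls per sample (analytic, from the
    ## generator's own parameters), apportioned by gene length
    pHFI <- .expectedHFIRate(cfg)
    met <- which(md$site == "metastatic")
    for (g in names(lm)) {
      inGroup <- which(genes$kinase_group == g)
      rGene <- cfg$meanVariantsPerSample * pHFI *
        genes$coding_length_nt[inGroup] /
        sum(genes$coding_length_nt)
      for (s in met) {
        nExtra <- stats::rpois(length(inGroup),
                               pmax(0, (lm[[g]] - 1) * rGene))
        for (k in which(nExtra > 0)) {
          for (r in seq_len(nExtra[k])) {
            extra[[length(extra) + 1L]] <-
              .injectVariant(cfg, md$sample_id[s],
                             genes$gene[inGroup[k]], genes)
          }
        }
      }
    }
  }

  if (length(extra)) {
    nm <- names(variants)
    planted <- lapply(stats::setNames(nm, nm), function(f) {
      unlist(lapply(extra, `[[`, f), use.names = FALSE)
    })
    variants <- Map(c, variants, planted)
  }

  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (length(extra)) {
    ## injected calls can collide with background sites
    key <- paste(variants$sample_id, variants$chrom, variants$pos,
                 variants$ref, variants$alt)
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  latent <- variants$latent
  variants$latent <- NULL
  rownames(variants) <- NULL

  ## true HFI counts under the analysis filters: truly deleterious or
  ## structural, non-synonymous, coverage > 20
  isTrue <- latent &
    variants$variant_class %in% nonSynonymousClasses() &
    variants$coverage > 20
  trueCounts <- table(
    factor(variants$gene[isTrue],
           levels = sort(unique(variants$gene[isTrue]))),
    factor(variants$sample_id[isTrue], levels = md$sample_id))
  gt$latent <- data.frame(sample_id = variants$sample_id,
                          key = variantKey(variants),
                          latent_deleterious = latent,
                          stringsAsFactors = FALSE)
  gt$trueCounts <- matrix(as.integer(trueCounts),
                          nrow = nrow(trueCounts),
                          ncol = ncol(trueCounts),
                          dimnames = list(rownames(trueCounts),
                                          colnames(trueCounts)))

  ## the generator emits correctly typed, invariant-satisfying records
  ## by construction; re-validation of the full table is left to the
  ## callers that need it (the writers validate on output)
  list(variants = variants,
       samples = validateMetadata(md),
       genes = validateGenes(genes),
       groundTruth = gt)
}

## P(a background call is an analysis-set HFI call), from the
## generator's own conditional predictor model
.expectedHFIRate <- function(cfg) {
  pMA <- function(p) (p[["high"]] + p[["medium"]]) *
    (1 - cfg$missingProb[["ma"]])
  pS <- function(r) r * (1 - cfg$missingProb[["sift"]])
  pK <- function(r) r * (1 - cfg$missingProb[["kss"]])
  cons <- function(ma, s, k) ma * (1 - (1 - s) * (1 - k))
  pDel <- cons(pMA(cfg$maProbsDeleterious),
               pS(cfg$siftDeleteriousRate[["deleterious"]]),
               pK(cfg$kssYesProb[["deleterious"]]))
  pBen <- cons(pMA(cfg$maProbsBenign),
               pS(cfg$siftDeleteriousRate[["benign"]]),
               pK(cfg$kssYesProb[["benign"]]))
  lat <- cfg$latentDeleteriousProb
  pScored <- cfg$classProbs[["missense"]] +
    cfg$classProbs[["inframe_indel"]]
  pStruct <- sum(cfg$classProbs[structuralHFIClasses()])
  pScored * (lat * pDel + (1 - lat) * pBen) + pStruct
}

#' Write a simulated cohort to disk
#'
#' Writes `variants.tsv`, `samples.tsv` and `genes.tsv` in the
#' interchange formats plus `ground_truth.json`.
#'
#' @param cohort Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVariantTable(cohort$variants, file.path(dir, "variants.tsv"))
  writeSampleMetadata(cohort$samples, file.path(dir, "samples.tsv"))
  writeGeneAnnotation(cohort$genes, file.path(dir, "genes.tsv"))
  gt <- cohort$groundTruth
  gt$trueCounts <- list(genes = rownames(gt$trueCounts),
                        samples = colnames(gt$trueCounts),
                        counts = unname(apply(gt$trueCounts, 1L,
                                              as.integer,
                                              simplify = FALSE)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Simulate a technical replicate pair
#'
#' Produces two replicate call sets from one sample's calls by
#' dropping each call independently from each replicate, with a
#' coverage-dependent drop probability. With the default drop
#' probability `q = 1/9` at coverage >= 20, the expected Jaccard
#' concordance of the well-covered stratum is
#' `(1 - q) / (1 + q) = 0.8`.
#'
#' @param variants One sample's variant calls.
#' @param dropProbHighCov Per-replicate drop probability for calls
#'   with coverage at or above `coverageCut`.
#' @param dropProbLowCov Drop probability below `coverageCut`.
#' @param coverageCut Coverage boundary between the two regimes
#'   (default 20).
#' @return A list with `rep1`, `rep2` (subsets of `variants`) and
#'   `groundTruth`, a data frame flagging each call's membership.
#' @export
simulateReplicates <- function(variants, dropProbHighCov = 1 / 9,
                               dropProbLowCov = 0.35,
                               coverageCut = 20) {
  .checkProb(c(dropProbHighCov, dropProbLowCov), "drop probabilities")
  n <- nrow(variants)
  q <- ifelse(variants$coverage >= coverageCut,
              dropProbHighCov, dropProbLowCov)
  in1 <- stats::runif(n) >= q
  in2 <- stats::runif(n) >= q
  list(rep1 = variants[in1, , drop = FALSE],
       rep2 = variants[in2, , drop = FALSE],
       groundTruth = data.frame(key = variantKey(variants),
                                coverage = variants$coverage,
                                in_rep1 = in1, in_rep2 = in2,
                                stringsAsFactors = FALSE))
}
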