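test_that("Fisher exact reproduces hand-checkable published values", {
  expect_equal(round(fisherExact2x2(3, 21, 0, 44), 2), 0.04)  # SCYL2
  expect_equal(round(fisherExact2x2(0, 24, 4, 40), 2), 0.29)  # GAB1
  expect_equal(round(fisherExact2x2(7, 36, 1, 38), 2), 0.06)  # TESK2
  expect_equal(round(fisherExact2x2(3, 15, 0, 19), 2), 0.11)  # BRCA2
})

test_that("degenerate and signal-free tables give p = 1", {
  p <- fisherExact2x2(0, 0, 0, 0)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_equal(as.numeric(fisherExact2x2(0, 12, 0, 7)), 1)
})

test_that("Fisher p is symmetric under group and outcome swaps", {
  set.seed(31)
  for (i in 1:50) {
    t <- sample.int(15, 4, replace = TRUE) - 1L
    p <- as.numeric(fisherExact2x2(t[1], t[2], t[3], t[4]))
    expect_equal(as.numeric(fisherExact2x2(t[3], t[4], t[1], t[2])),
                 p)  # swap rows
    expect_equal(as.numeric(fisherExact2x2(t[2], t[1], t[4], t[3])),
                 p)  # swap columns
    expect_lte(p, 1)
    expect_gt(p, 0)
  }
})

test_that("Fisher p matches stats::fisher.test on random tables", {
  set.seed(37)
  for (i in 1:100) {
    t <- sample.int(40, 4, replace = TRUE) - 1L
    if (sum(t) == 0) next
    ours <- as.numeric(fisherExact2x2(t[1], t[2], t[3], t[4]))
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("rank-sum p-values: forced extremes and identical samples", {
  # complete separation of 3 vs 3: the most extreme of C(6,3) = 20
  # equally likely splits, doubled
  expect_equal(wilcoxonRankSum(1:3, 4:6), 0.1)
  # identical multisets are as null as it gets
  x <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxonRankSum(x, x), 1)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("rank-sum agrees with stats::wilcox.test on both paths", {
  set.seed(41)
  for (i in 1:40) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    x <- runif(n1); y <- runif(n2)  # continuous: no ties, exact path
    expect_equal(wilcoxonRankSum(x, y),
                 suppressWarnings(stats::wilcox.test(x, y)$p.value),
                 tolerance = 1e-10)
  }
  for (i in 1:40) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x <- sample(1:6, n1, replace = TRUE)  # heavy ties: normal path
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(wilcoxonRankSum(x, y),
                 suppressWarnings(
                   stats::wilcox.test(x, y, exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("exact rank-sum equals full enumeration at small n", {
  set.seed(43)
  for (i in 1:25) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    x <- runif(n1); y <- runif(n2)
    expect_equal(wilcoxonRankSum(x, y), oracleWilcoxP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("group comparison builds published-style contingency results", {
  # encode the strongest ER-status row: 7/43 affected vs 1/39
  n1 <- 43L; n2 <- 39L
  md <- baseMetadata(sprintf("P%02d", seq_len(n1 + n2)))
  md$er_status <- rep(c("negative", "positive"), c(n1, n2))
  md$her2_status <- "negative"
  counts <- data.frame(gene = c("TESK2", "RIOK2"), k1 = c(7L, 15L),
                       k2 = c(1L, 21L))
  variants <- tableFixture(counts, n1, n2, md)
  mat <- buildHFIMatrix(filterAnalysisSet(variants), md)
  cmp <- compareGroups(mat, "er_status", "negative", "positive",
                       within = list(her2_status = "negative"))
  tesk2 <- cmp[cmp$gene == "TESK2", ]
  expect_equal(tesk2$n1_affected, 7L)
  expect_equal(tesk2$n1_total, 43L)
  expect_equal(tesk2$n2_affected, 1L)
  expect_equal(tesk2$n2_total, 39L)
  expect_equal(round(tesk2$p_unadjusted, 2), 0.06)
  expect_equal(cmp$m_tests[1], 2L)
  expect_equal(cmp$p_bonferroni, pmin(1, cmp$p_unadjusted * 2))
  # Bonferroni is monotone: both orderings agree
  expect_equal(order(cmp$p_unadjusted), order(cmp$p_bonferroni))
})

test_that("group comparison excludes unknowns and absent genes", {
  md <- baseMetadata(sprintf("P%d", 1:10))
  md$er_status <- c(rep("negative", 4), rep("positive", 4),
                    "unknown", "unknown")
  v <- rbind(hfiCall("P1", "G1", 1L), hfiCall("P9", "G2", 2L))
  mat <- buildHFIMatrix(filterAnalysisSet(v), md)
  cmp <- compareGroups(mat, "er_status", "negative", "positive")
  expect_equal(cmp$n1_total[1], 4L)
  # G2 is affected only in an unknown-ER sample: not tested
  expect_equal(cmp$gene, "G1")
  expect_error(compareGroups(mat, "er_status", "negative",
                             "borderline"), "zero samples")
  expect_error(compareGroups(mat, "er_status", "negative",
                             c("positive", "negative")), "overlap")
})

test_that("null cohorts keep unadjusted positives near the nominal rate", {
  set.seed(47)
  nGenes <- 120; n1 <- 46; n2 <- 46
  md <- baseMetadata(sprintf("P%02d", seq_len(n1 + n2)))
  md$er_status <- rep(c("negative", "positive"), c(n1, n2))
  pvals <- numeric(0)
  for (rep in 1:5) {
    aff <- matrix(runif(nGenes * (n1 + n2)) < 0.15, nGenes)
    rows <- which(aff, arr.ind = TRUE)
    v <- hfiCall(md$sample_id[rows[, 2]],
                 sprintf("G%03d", rows[, 1]), rows[, 1])
    mat <- buildHFIMatrix(filterAnalysisSet(v), md)
    cmp <- compareGroups(mat, "er_status", "negative", "positive")
    pvals <- c(pvals, cmp$p_unadjusted)
  }
  # Fisher is conservative on discrete tables, so the observed rate
  # sits at or below nominal, within binomial error
  frac <- mean(pvals < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / length(pvals)))
})

test_that("co-occurrence screen flags perfect overlap and direction", {
  samples <- sprintf("S%02d", 1:20)
  carriers <- samples[1:10]
  som <- hfiCall(carriers, "GS", 1L)
  som$cosmic_id <- "COSM1"
  germ <- hfiCall(carriers, "GG", 2L)
  germ$dbsnp_id <- "rs1"
  res <- cooccurrenceScreen(rbind(som, germ), samples)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_both, 10L)
  expect_equal(res$n_neither, 10L)
  expect_equal(res$direction, "co-occurrence")
  expect_equal(res$p_unadjusted,
               as.numeric(fisherExact2x2(10, 0, 0, 10)))

  # mutually exclusive carriers
  germ2 <- hfiCall(samples[11:20], "GG", 2L)
  germ2$dbsnp_id <- "rs1"
  res2 <- cooccurrenceScreen(rbind(som, germ2), samples)
  expect_equal(res2$direction, "exclusivity")

  # a variant present in every sample has an empty margin: degenerate
  germ3 <- hfiCall(samples, "GG", 2L)
  germ3$dbsnp_id <- "rs1"
  res3 <- cooccurrenceScreen(rbind(som, germ3), samples)
  expect_true(res3$degenerate)
  expect_equal(res3$p_unadjusted, 1)
})

test_that("co-occurrence screen controls false positives on null pairs", {
  set.seed(53)
  samples <- sprintf("S%02d", 1:40)
  hits <- 0L
  nScreens <- 40L
  for (rep in seq_len(nScreens)) {
    vs <- list()
    for (k in 1:6) {
      carr <- samples[runif(40) < 0.3]
      if (!length(carr)) next
      v <- hfiCall(carr, sprintf("G%d", k), k)
      if (k <= 3) v$cosmic_id <- sprintf("COSM%d", k)
      else v$dbsnp_id <- sprintf("rs%d", k)
      vs[[k]] <- v
    }
    res <- cooccurrenceScreen(do.call(rbind, vs), samples)
    if (nrow(res) && any(res$p_bonferroni < 0.05)) hits <- hits + 1L
  }
  # family-wise error should be near or below 5%; allow generous
  # binomial slack at 40 screens
  expect_lte(hits / nScreens, 0.15)
})

test_that("a strongly co-occurring planted pair is detected", {
  set.seed(59)
  pc <- data.frame(odds_ratio = 20, prev_somatic = 0.35,
                   prev_germline = 0.35)
  detected <- 0L
  for (i in 1:10) {
    co <- simulateCohort(simulationConfig(plantedCooccurrence = pc),
                         seed = 900 + i)
    analysis <- filterAnalysisSet(co$variants)
    keyed <- analysis[!is.na(analysis$cosmic_id) |
                        !is.na(analysis$dbsnp_id), ]
    keep <- grepl("PAIR", paste(keyed$cosmic_id, keyed$dbsnp_id))
    res <- cooccurrenceScreen(keyed[keep, ], co$samples$sample_id)
    if (nrow(res) && res$p_bonferroni[1] < 0.05) {
      detected <- detected + 1L
    }
  }
  expect_gte(detected, 6L)  # majority of simulations
})

test_that("group load comparison: identical loads are null, shifts rank first", {
  loads <- matrix(rep(c(1, 2, 3, 4), 10), nrow = 2, byrow = FALSE,
                  dimnames = list(c("TK", "TKL"),
                                  sprintf("S%02d", 1:20)))
  site <- rep(c("primary", "metastatic"), each = 10)
  res <- compareGroupLoads(loads, site)
  expect_equal(res$p_bonferroni, c(1, 1))

  set.seed(61)
  loads2 <- matrix(rexp(100, 10), nrow = 5,
                   dimnames = list(c("TK", "TKL", "STE", "CMGC",
                                     "AGC"), sprintf("S%02d", 1:20)))
  loads2["TKL", site == "metastatic"] <-
    loads2["TKL", site == "metastatic"] + 1  # separating shift
  res2 <- compareGroupLoads(loads2, site)
  expect_equal(res2$kinase_group[which.min(res2$p_unadjusted)],
               "TKL")
})

test_that("permuting site labels yields null-calibrated load p-values", {
  set.seed(67)
  loads <- matrix(rexp(5 * 30, 10), nrow = 5,
                  dimnames = list(c("TK", "TKL", "STE", "CMGC",
                                    "AGC"), sprintf("S%02d", 1:30)))
  site <- rep(c("primary", "metastatic"), c(20, 10))
  p <- replicate(200, {
    compareGroupLoads(loads, sample(site))$p_unadjusted[2]
  })
  frac <- mean(p < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("replicate concordance is Jaccard over keyed calls", {
  set.seed(71)
  calls <- randomVariants(100)
  calls <- calls[!duplicated(variantKeyForTest(calls)), ]
  expect_equal(replicateConcordance(calls, calls)$overall, 1)

  half <- nrow(calls) %/% 2
  a <- calls[1:half, ]; b <- calls[(half + 1):nrow(calls), ]
  expect_equal(replicateConcordance(a, b)$overall, 0)

  # 80 calls vs the same 60 plus 20 novel: 60 / 100
  rep1 <- calls[1:80, ]
  rep2 <- rbind(calls[1:60, ], calls[81:100, ])
  expect_equal(replicateConcordance(rep1, rep2)$overall, 0.6)
  # asymmetric recall of rep1 in rep2
  expect_equal(replicateConcordance(rep1, rep2,
                                    metric = "recall")$overall,
               60 / 80)

  empty <- replicateConcordance(calls[0, ], calls[0, ])
  expect_true(is.na(empty$overall))
  expect_true(attr(empty$overall, "degenerate"))
})

test_that("concordance stratifies by the minimum replicate coverage", {
  calls <- randomVariants(50)
  calls <- calls[!duplicated(variantKeyForTest(calls)), ]
  calls$coverage <- 100L
  low <- calls[1:5, ]
  low$coverage <- 5L
  rep1 <- rbind(calls, low)   # duplicates keyed: min coverage 5
  res <- replicateConcordance(rep1, calls)
  lowBin <- res$byBin[res$byBin$bin == "[0,20)", ]
  expect_equal(lowBin$n_union, 5L)
})
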