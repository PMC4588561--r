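test_that("predictor verdicts follow the cutoffs, missing is false", {
  v <- rbind(mkVariant(ma = "medium", sift = 0.01),
             mkVariant(ma = "neutral", sift = 0.05, kss = "no"),
             mkVariant())
  pv <- predictorVerdicts(v)
  expect_equal(pv$ma, c(TRUE, FALSE, FALSE))
  expect_equal(pv$sift, c(TRUE, FALSE, FALSE))  # 0.05 is not < 0.05
  expect_equal(pv$kss, c(FALSE, FALSE, FALSE))
})

test_that("the consensus rule needs the anchor plus a second predictor", {
  # structural variant with no scores at all is still HFI
  d <- classifyHFI(mkVariant("stop_gain"))
  expect_true(d$is_hfi)
  expect_equal(d$rule_fired, "stop_gain")

  # anchor alone is not enough
  d <- classifyHFI(mkVariant(ma = "high", sift = 0.5, kss = "no"))
  expect_false(d$is_hfi)
  expect_equal(d$rule_fired, "none")

  # synonymous is never HFI, whatever the scores say
  d <- classifyHFI(mkVariant("synonymous", ma = "high", sift = 0.001,
                             kss = "yes", coverage = 400L))
  expect_false(d$is_hfi)

  # full agreement
  d <- classifyHFI(mkVariant(ma = "medium", sift = 0.001,
                             kss = "yes"))
  expect_true(d$is_hfi)
  expect_equal(d$rule_fired, "consensus")
  expect_equal(d$n_predictors_deleterious, 3L)

  # in-frame indels have no structural route
  d <- classifyHFI(mkVariant("inframe_indel"))
  expect_false(d$is_hfi)
})

test_that("is_hfi always equals rule_fired != none", {
  set.seed(7)
  v <- randomVariants(300)
  d <- classifyHFI(v)
  expect_equal(d$is_hfi, d$rule_fired != "none")
})

test_that("flipping a predictor to deleterious never revokes HFI", {
  set.seed(11)
  v <- randomVariants(250)
  before <- classifyHFI(v)$is_hfi
  flips <- list(
    function(x) { x$ma_category <- "high"; x },
    function(x) { x$sift_score <- 0.001; x },
    function(x) { x$kss_deleterious <- "yes"; x }
  )
  for (flip in flips) {
    after <- classifyHFI(flip(v))$is_hfi
    expect_true(all(after >= before))
  }
})

test_that("the analysis filter applies strict >20 coverage", {
  v <- rbind(mkVariant(ma = "high", sift = 0.001, coverage = 20L),
             mkVariant(ma = "high", sift = 0.001, coverage = 21L))
  v$pos <- c(1L, 2L)
  kept <- filterAnalysisSet(v)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$coverage, 21L)
})

test_that("analysis filter equals an independent predicate and is idempotent", {
  set.seed(21)
  v <- randomVariants(400)
  kept <- filterAnalysisSet(v)
  keep <- vapply(seq_len(nrow(v)), function(i) {
    oracleHFI(v$variant_class[i], v$ma_category[i], v$sift_score[i],
              v$kss_deleterious[i]) &&
      v$variant_class[i] %in% c("missense", "stop_gain", "stop_loss",
                                "frameshift_indel", "inframe_indel") &&
      v$coverage[i] > 20
  }, logical(1))
  expect_equal(kept, v[keep, , drop = FALSE])
  expect_equal(filterAnalysisSet(kept), kept)  # idempotent
  expect_true(all(rownames(kept) %in% rownames(v)))  # subset
})

test_that("median coverage mode pools depth across carriers", {
  v <- rbind(mkVariant(ma = "high", sift = 0.001, coverage = 5L),
             mkVariant(ma = "high", sift = 0.001, coverage = 100L),
             mkVariant(ma = "high", sift = 0.001, coverage = 40L))
  v$sample_id <- c("S1", "S2", "S3")
  # same site in all three samples: median coverage 40 > 20
  expect_equal(nrow(filterAnalysisSet(v, coverageMode = "median")), 3L)
  # per-call mode drops the 5x carrier
  expect_equal(nrow(filterAnalysisSet(v, coverageMode = "call")), 2L)
})

test_that("predictor consensus counts unique variants by agreement", {
  expect_equal(countPredictorConsensus(mkVariant()[0, ])$nUnique, 0L)

  # three variants, each deleterious by exactly one distinct predictor
  v <- rbind(mkVariant(ma = "high"),
             mkVariant(sift = 0.01),
             mkVariant(kss = "yes"))
  v$pos <- 1:3
  cc <- countPredictorConsensus(v)
  expect_equal(cc$nTwoPlus, 0L)
  expect_equal(unname(cc$venn[c("ma_only", "sift_only", "kss_only")]),
               c(1L, 1L, 1L))

  # planted partition over all eight verdict combinations
  combos <- expand.grid(ma = c(FALSE, TRUE), sift = c(FALSE, TRUE),
                        kss = c(FALSE, TRUE))
  reps <- 1:8  # combo i appears i times (as recurrent calls too)
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(combos))) {
    for (r in seq_len(reps[i])) {
      pos <- pos + 1L
      rows[[pos]] <- mkVariant(
        ma = if (combos$ma[i]) "medium" else "low",
        sift = if (combos$sift[i]) 0.01 else 0.9,
        kss = if (combos$kss[i]) "yes" else "no")
      rows[[pos]]$pos <- i  # same site for all reps of a combo
      rows[[pos]]$sample_id <- sprintf("S%d", r)
    }
  }
  cc <- countPredictorConsensus(do.call(rbind, rows))
  expect_equal(cc$nUnique, 8L)
  expect_equal(unname(cc$venn["none"]), 1L)
  expect_equal(unname(cc$venn["all_three"]), 1L)
  expect_equal(cc$nTwoPlus, 4L)
  expect_equal(cc$nAllThree, 1L)
})
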