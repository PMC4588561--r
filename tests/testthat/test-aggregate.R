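test_that("the HFI matrix covers all samples and counts every call", {
  md <- baseMetadata(c("S1", "S2", "S3"))
  # no variants: zero genes, all samples still present
  m0 <- buildHFIMatrix(hfiCall("S1", "G", 1L)[0, ], md)
  expect_equal(dim(m0), c(0L, 3L))

  v <- rbind(hfiCall("S1", "GA", 1L), hfiCall("S1", "GA", 2L),
             hfiCall("S2", "GB", 3L))
  m <- buildHFIMatrix(v, md)
  expect_equal(hfiCounts(m)["GA", "S1"], 2L)
  expect_true(hfiAffected(m)["GA", "S1"])
  expect_false(hfiAffected(m)["GB", "S1"])
  expect_equal(sum(hfiCounts(m)), nrow(v))  # conservation
  # column sums equal each sample's analysis-set call count
  expect_equal(colSums(hfiCounts(m))[c("S1", "S2", "S3")],
               c(S1 = 2, S2 = 1, S3 = 0))
  expect_error(buildHFIMatrix(hfiCall("S9", "G", 1L), md),
               "unknown sample.*S9")
})

test_that("matrix construction is invariant to input row order", {
  set.seed(73)
  v <- filterAnalysisSet(randomVariants(300))
  md <- baseMetadata(sprintf("S%02d", 1:4))
  v$sample_id <- sample(md$sample_id, nrow(v), replace = TRUE)
  m1 <- buildHFIMatrix(v, md)
  m2 <- buildHFIMatrix(v[sample(nrow(v)), ], md)
  expect_identical(hfiCounts(m1), hfiCounts(m2))
  expect_equal(sum(hfiCounts(m1)), nrow(v))
  # gene order: descending total count, ties by symbol
  tot <- rowSums(hfiCounts(m1))
  expect_true(all(diff(tot) <= 0))
})

test_that("samples are ordered by the clinical hierarchy", {
  md <- baseMetadata(c("B", "A", "C"))
  md$er_status <- c("positive", "negative", "negative")
  md$grade <- c("1", "3", "1")
  m <- buildHFIMatrix(hfiCall("A", "G", 1L), md)
  expect_equal(colnames(m), c("C", "A", "B"))  # ER-neg first, grade
})

test_that("per-sample summary matches brute-force column sums", {
  md <- baseMetadata(c("S1", "S2"))
  v <- rbind(hfiCall("S1", sprintf("G%d", 1:5), 1:5),
             hfiCall("S2", sprintf("G%d", 1:40), 101:140))
  m <- buildHFIMatrix(v, md)
  s <- perSampleHFISummary(m)
  expect_equal(s$mean, 22.5)
  expect_equal(s$min, 5)
  expect_equal(s$max, 40)

  m0 <- buildHFIMatrix(v[0, ], md)
  expect_equal(unlist(perSampleHFISummary(m0)),
               c(mean = 0, min = 0, max = 0))

  set.seed(79)
  v2 <- filterAnalysisSet(randomVariants(200))
  md2 <- baseMetadata(sprintf("S%02d", 1:4))
  v2$sample_id <- sample(md2$sample_id, nrow(v2), replace = TRUE)
  m2 <- buildHFIMatrix(v2, md2)
  cs <- colSums(hfiCounts(m2))
  expect_equal(perSampleHFISummary(m2),
               data.frame(mean = mean(cs), min = min(cs),
                          max = max(cs)))
})

test_that("expression filter drops only demonstrably low genes", {
  g <- data.frame(gene = c("A", "B", "C"),
                  kinase_group = "TK", coding_length_nt = 1000L,
                  expression_log2 = c(5.99, 6.0, NA))
  kept <- expressionFilter(g)
  expect_equal(kept$gene, c("B", "C"))  # 5.99 dropped, 6.0 and NA kept

  set.seed(83)
  g2 <- data.frame(gene = sprintf("G%03d", 1:200),
                   kinase_group = "TK", coding_length_nt = 1000L,
                   expression_log2 = c(runif(180, 2, 12),
                                       rep(NA, 20)))
  kept2 <- expressionFilter(g2, threshold = 7)
  manual <- g2[is.na(g2$expression_log2) |
                 g2$expression_log2 >= 7, ]
  expect_equal(kept2, manual)
})

test_that("probe-set collapsing keeps the highest-mean probe", {
  e <- matrix(c(8.1, 8.1, 7.9, 7.9, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB")
  out <- collapseProbesets(e, map)
  expect_equal(rownames(out), c("GA", "GB"))
  expect_equal(attr(out, "probe")[["GA"]], "p1")  # 8.1 > 7.9
  expect_equal(unname(out["GB", ]), c(5, 6))

  # tie on mean resolved by variance, then probe id
  e2 <- matrix(c(7, 9, 8, 8, 9, 7), nrow = 3, byrow = TRUE,
               dimnames = list(c("q3", "q2", "q1"), c("s1", "s2")))
  out2 <- collapseProbesets(e2, c(q1 = "G", q2 = "G", q3 = "G"))
  expect_equal(attr(out2, "probe")[["G"]], "q1")  # var ties: id order

  expect_warning(collapseProbesets(e, c(p1 = "GA", p2 = "GA")),
                 "1 probe")
})

test_that("probe collapsing equals brute-force argmax on random data", {
  set.seed(89)
  nProbe <- 50
  e <- matrix(rnorm(nProbe * 6, 8), nProbe,
              dimnames = list(sprintf("pr%02d", 1:nProbe), NULL))
  colnames(e) <- sprintf("s%d", 1:6)
  map <- setNames(sprintf("G%d", sample(1:12, nProbe, TRUE)),
                  rownames(e))
  out <- collapseProbesets(e, map)
  for (g in unique(map)) {
    probes <- names(map)[map == g]
    mns <- rowMeans(e[probes, , drop = FALSE])
    best <- probes[which.max(mns)]
    expect_equal(attr(out, "probe")[[g]], best)
    expect_equal(out[g, ], e[best, ])
  }
})

test_that("group loads divide pooled counts by gene length", {
  md <- baseMetadata(c("S1", "S2"))
  genes <- data.frame(gene = c("KA", "KB", "NK"),
                      kinase_group = c("TK", "TK", "non_kinase"),
                      coding_length_nt = c(3000L, 1000L, 500L),
                      expression_log2 = c(8, 8, 8))
  v <- hfiCall("S1", c("KA", "KA", "KA"), 1:3)
  m <- buildHFIMatrix(v, md, genes)
  gl <- computeGroupLoads(m, genes)
  # one gene with 3 calls over 3000 nt: load 0.001; the zero-count
  # expressed gene KB pulls the TK group mean to 0.0005
  expect_equal(gl$perGene$load[gl$perGene$gene == "KA"], 0.001)
  expect_equal(gl$groups$group_load[gl$groups$kinase_group == "TK"],
               0.0005)
  # non-kinase genes never enter group loads
  expect_false("non_kinase" %in% gl$groups$kinase_group)

  expect_error(computeGroupLoads(m, genes[-1, ]), "KA")
})

test_that("group loads are order-invariant and subset-monotone", {
  set.seed(97)
  md <- baseMetadata(sprintf("S%02d", 1:6))
  genes <- data.frame(gene = sprintf("K%02d", 1:20),
                      kinase_group = sample(c("TK", "TKL", "STE"), 20,
                                            TRUE),
                      coding_length_nt = sample(500:5000, 20),
                      expression_log2 = 8)
  v <- filterAnalysisSet(randomVariants(400))
  v$gene <- sample(genes$gene, nrow(v), replace = TRUE)
  v$sample_id <- sample(md$sample_id, nrow(v), replace = TRUE)
  m <- buildHFIMatrix(v, md, genes)
  g1 <- computeGroupLoads(m, genes)
  g2 <- computeGroupLoads(m, genes[sample(nrow(genes)), ])
  expect_equal(g1$groups, g2$groups)

  sub <- computeGroupLoads(m, genes, samples = md$sample_id[1:3])
  full <- g1$perGene$n_hfi[match(sub$perGene$gene, g1$perGene$gene)]
  expect_true(all(sub$perGene$n_hfi <= full))

  # pooled group load equals the sum over samples of per-sample loads
  psl <- perSampleGroupLoads(m, genes)
  expect_equal(rowSums(psl)[g1$groups$kinase_group],
               setNames(g1$groups$group_load,
                        g1$groups$kinase_group))
})
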