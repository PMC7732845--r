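test_that("bhAdjust equals p.adjust and the brute-force step-up oracle", {
  set.seed(101)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_equal(q, oracleBH(p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("significanceCriterion validates mode and threshold", {
  expect_identical(significanceCriterion("bh_fdr", 0.01)$mode, "bh_fdr")
  expect_error(significanceCriterion("bh_fdr", 0), "\\(0, 1\\)")
  expect_error(significanceCriterion("bh_fdr", 1), "\\(0, 1\\)")
  expect_error(significanceCriterion("bonferroni", 0.05))
})

test_that("differentialExpression matches per-row t.test exactly (Welch and Student)", {
  qm <- toyQuant(n_prot = 8, seed = 21)
  lm2 <- log2(quantValues(qm))
  for (ve in c(FALSE, TRUE)) {
    de <- differentialExpression(qm, var.equal = ve)
    for (i in seq_len(nrow(lm2))) {
      tt <- t.test(lm2[i, 4:6], lm2[i, 1:3], var.equal = ve)
      expect_equal(de$t[i], unname(tt$statistic))
      expect_equal(de$p[i], tt$p.value)
      expect_equal(de$log2FC[i], mean(lm2[i, 4:6]) - mean(lm2[i, 1:3]))
    }
    expect_equal(de$q, p.adjust(de$p, "BH"))
    expect_identical(de$direction, ifelse(de$log2FC >= 0, "up", "down"))
  }
})

test_that("differentialExpression handles degenerate rows and tiny designs", {
  m <- matrix(c(rep(4, 4),            # constant everywhere: t = 0, p = 1
                2, 2, 8, 8),          # constant per group, different means
              2, 4, byrow = TRUE,
              dimnames = list(c("flat", "sep"), paste0("s", 1:4)))
  qm <- QuantMatrix(m, c("control", "control", "case", "case"), "syn")
  de <- differentialExpression(qm)
  expect_equal(de[de$protein == "flat", "t"], 0)
  expect_equal(de[de$protein == "flat", "p"], 1)
  expect_equal(de[de$protein == "sep", "t"], Inf)
  expect_equal(de[de$protein == "sep", "p"], 0)
  qm1 <- QuantMatrix(m[, 2:4], c("control", "case", "case"), "syn")
  expect_error(differentialExpression(qm1), ">= 2 samples per group")
})

test_that("classifySignificant uses strict thresholds in both modes", {
  de <- toyDE(c("a", "b", "c", "d"), c(1, -1, 0.5, -2),
              q = c(0.01, 0.05, 0.049, 0.2), p = c(0.001, 0.05, 0.01, 0.1))
  crit <- significanceCriterion("bh_fdr", 0.05)
  s <- classifySignificant(de, crit)
  expect_identical(s$up, c("a", "c"))   # q = 0.05 excluded (strict)
  expect_identical(s$down, character())
  s2 <- classifySignificant(de, significanceCriterion("nominal_p", 0.05))
  expect_identical(s2$up, c("a", "c"))
  expect_identical(s2$down, character())  # p = 0.05 excluded
  de$log2FC[1] <- 0
  expect_message(s3 <- classifySignificant(de, crit), "log2FC == 0")
  expect_false("a" %in% c(s3$up, s3$down))
})

test_that("zscoreCluster: z rows standardized; linkage matches the oracle", {
  qm <- toyQuant(n_prot = 8, seed = 31)
  zc <- zscoreCluster(qm)
  expect_equal(unname(rowMeans(zc$zmat)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(zc$zmat, 1, sd)), rep(1, 8), tolerance = 1e-10)
  # 1 - Pearson, average linkage: compare cophenetic matrices with the naive oracle
  D <- 1 - cor(t(zc$zmat))
  coph <- as.matrix(cophenetic(zc$row_hclust))
  oracle <- oracleAverageLinkCophenetic(D)
  dimnames(oracle) <- dimnames(coph)
  expect_equal(coph, oracle, tolerance = 1e-10)
  # two identical rows merge first at distance 0
  m <- quantValues(qm)
  m <- rbind(m, dup1 = m[1, ] * 3)  # scaled copy: correlation 1 after z-scoring
  qm2 <- QuantMatrix(m, quantGroups(qm), "syn")
  zc2 <- zscoreCluster(qm2)
  h <- zc2$row_hclust
  expect_equal(min(h$height), 0, tolerance = 1e-12)
  first <- sort(h$labels[-h$merge[1, ]])
  expect_identical(first, sort(c(rownames(m)[1], "dup1")))
  # constant rows are dropped with a message
  m[2, ] <- 7
  qm3 <- QuantMatrix(m, quantGroups(qm), "syn")
  expect_message(zc3 <- zscoreCluster(qm3), "constant rows")
  expect_false(rownames(m)[2] %in% rownames(zc3$zmat))
})
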