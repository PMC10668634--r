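test_that("default study design yields a 2000 x 9 matrix with 3/3/3 groups", {
  sim <- simulateStudy(defaultStudyDesign(seed = 7))
  expect_identical(dim(exprValues(sim$matrix)), c(2000L, 9L))
  expect_equal(unname(table(sim$annotation$group)[c("typeI", "typeII",
                                                    "dualpos")]),
               rep(3L, 3), ignore_attr = TRUE)
  expect_identical(scaleTag(sim$matrix), "log2")
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- simulateStudy(defaultStudyDesign(seed = 7))
  b <- simulateStudy(defaultStudyDesign(seed = 7))
  expect_identical(exprValues(a$matrix), exprValues(b$matrix))
  c <- simulateStudy(defaultStudyDesign(seed = 8))
  expect_gt(max(abs(exprValues(a$matrix) - exprValues(c$matrix))), 0)

  sp <- epithelialPopulationSpec(nCells = 500, seed = 3)
  expect_identical(simulateCells(sp), simulateCells(sp))

  p1 <- simulateReferencePanels(seed = 1)
  p2 <- simulateReferencePanels(seed = 2)
  expect_gt(max(abs(exprValues(p1$E11_5$matrix) -
                      exprValues(p2$E11_5$matrix))), 0)
})

test_that("a null design produces statistically indistinguishable groups", {
  draws <- 100
  pvals <- vapply(seq_len(draws), function(i) {
    prog <- GeneProgram("p", 1:50,
                        c(a = 0, b = 0), dispersion = 0.3)
    d <- StudyDesign(200L, c(a = 3L, b = 3L), list(prog),
                     noiseSd = 0.3, seed = 1000L + i)
    sim <- simulateStudy(d)
    v <- exprValues(sim$matrix)
    progMeans <- colMeans(v[1:50, ])
    ga <- progMeans[sim$annotation$group == "a"]
    gb <- progMeans[sim$annotation$group == "b"]
    stats::t.test(ga, gb)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("dual-positive samples carry positive shifts on BOTH single-type programs", {
  design <- defaultStudyDesign(seed = 7)
  sim <- simulateStudy(design)
  v <- exprValues(sim$matrix)
  dp <- sim$annotation$sample_id[sim$annotation$group == "dualpos"]
  t1 <- sim$annotation$sample_id[sim$annotation$group == "typeI"]
  t2 <- sim$annotation$sample_id[sim$annotation$group == "typeII"]
  typeIProg <- 1:150; typeIIProg <- 151:300; embProg <- 301:450
  # dualpos is high on the typeI program (vs typeII samples) and on the
  # typeII program (vs typeI samples), and uniquely high on embryonic
  expect_gt(mean(v[typeIProg, dp]) - mean(v[typeIProg, t2]), 1)
  expect_gt(mean(v[typeIIProg, dp]) - mean(v[typeIIProg, t1]), 1)
  expect_gt(mean(v[embProg, dp]) - mean(v[embProg, c(t1, t2)]), 1)
})

test_that("reference panels have planted within-type structure", {
  panels <- simulateReferencePanels(seed = 1)
  expect_length(panels, 3L)
  for (p in panels) {
    expect_gte(ncol(exprValues(p$matrix)), 6L)
    # every planted program is >= 150 genes (top-100 well defined)
    expect_true(all(lengths(p$planted) >= 150L))
    # after removing per-gene baselines, samples of a type correlate
    # with each other more than with the other type
    v <- exprValues(p$matrix)
    centered <- v - rowMeans(v)
    cc <- cor(centered)
    for (ty in unique(p$annotation$group)) {
      inTy <- p$annotation$sample_id[p$annotation$group == ty]
      outTy <- setdiff(p$annotation$sample_id, inTy)
      within <- mean(cc[inTy, inTy][upper.tri(cc[inTy, inTy])])
      between <- mean(cc[inTy, outTy])
      expect_gt(within, between)
    }
  }
})

test_that("cell-line module panel plants an exact low-rank structure", {
  kras <- simulateKrasPanel(seed = 11)
  expect_length(geneIds(kras$module), 1000L)
  expect_identical(scaleTag(kras$matrix), "raw")

  # zero noise: rank-3 NMF reconstructs the module block to < 1e-6
  k0 <- simulateKrasPanel(nCellLines = 12, moduleSize = 30,
                          noiseSd = 0, seed = 3)
  sub <- exprValues(k0$matrix)[geneIds(k0$module), ]
  model <- fitNmf(ExpressionMatrix(sub, "raw"), 3, nRestarts = 5,
                  tol = 1e-12, maxIter = 5000, seed = 5)
  relErr <- utils::tail(objectiveTrace(model), 1) / sqrt(sum(sub^2))
  expect_lt(relErr, 1e-6)

  # low noise, small module: NMF clusters recover every planted state
  k1 <- simulateKrasPanel(nCellLines = 12, moduleSize = 10,
                          noiseSd = 0.01, seed = 2)
  sub1 <- exprValues(k1$matrix)[geneIds(k1$module), ]
  m1 <- fitNmf(ExpressionMatrix(sub1, "raw"), 3, nRestarts = 10,
               seed = 5)
  cl <- assignClusters(m1)
  expect_equal(clusterPurity(cl[k1$annotation$sample_id],
                             k1$annotation$group), 1.0)

  expect_error(simulateKrasPanel(moduleSize = 5000), "moduleSize")
})

test_that("simulated cell labels follow the requested fractions", {
  sp <- CellPopulationSpec(1000L, c(typeI = 0.5, typeII = 0.5),
                           list(typeI = c(M = 4), typeII = c(M = 1)),
                           seed = 9)
  cells <- simulateCells(sp)
  k <- sum(cells$true_label == "typeI")
  ci <- qbinom(c(0.0005, 0.9995), 1000, 0.5)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])

  only <- CellPopulationSpec(50L, c(dualpos = 1.0),
                             list(dualpos = c(M = 4)), seed = 1)
  expect_true(all(simulateCells(only)$true_label == "dualpos"))

  expect_error(CellPopulationSpec(0L, c(a = 1), list(a = c(M = 1))),
               "nCells")
  expect_error(CellPopulationSpec(10L, c(a = 0.6, b = 0.6),
                                  list(a = c(M = 1), b = c(M = 2))),
               "sum to 1")
})

test_that("CT tables invert the delta-delta-CT formula", {
  ct <- simulateCtTable(c(geneX = 4), noiseSd = 0)
  expect_identical(unname(foldChange(ct, "geneX")), 4)
  ct1 <- simulateCtTable(c(geneY = 1), noiseSd = 0)
  expect_identical(unname(foldChange(ct1, "geneY")), 1)
  expect_error(simulateCtTable(c(bad = -2)), "positive")

  # noisy generator: mean recovered log2 FC within 0.15 of truth
  rec <- vapply(1:50, function(i) {
    ct <- simulateCtTable(c(g = 4), noiseSd = 0.1, seed = 100 + i)
    log2(foldChange(ct, "g"))
  }, numeric(1))
  expect_lt(abs(mean(rec) - 2), 0.15)
})
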