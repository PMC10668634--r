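test_that("rank normalization maps to (0,1] with average ties", {
  expect_equal(rankNormalize(c(3, 1, 2)), c(1, 1 / 3, 2 / 3))
  expect_equal(unname(rankNormalize(rep(7, 4))), rep(0.625, 4))
  set.seed(3)
  x <- rnorm(50)
  expect_equal(rankNormalize(x), rankNormalize(exp(2 * x) + 10))
  expect_error(rankNormalize(c(1, NA, 2)), "finite")
  expect_error(rankNormalize(5), "at least 2")
})

test_that("two-gene enrichment scores hit the +1/-1 extremes at w = 0", {
  r <- rankNormalize(c(gTop = 10, gBot = 1))
  expect_equal(enrichmentScore(r, "gTop", w = 0), 1)
  expect_equal(enrichmentScore(r, "gBot", w = 0), -1)
})

test_that("uniformly interleaved sets score near zero", {
  set.seed(8)
  es <- vapply(1:100, function(i) {
    prof <- rankNormalize(setNames(rnorm(100), paste0("g", 1:100)))
    # set = every 10th position of the descending ranking
    ord <- names(sort(prof, decreasing = TRUE))
    enrichmentScore(prof, ord[seq(5, 95, by = 10)], w = 0)
  }, numeric(1))
  expect_lt(max(abs(es)), 5)
})

test_that("enrichment scores equal an independent brute-force oracle", {
  set.seed(13)
  # 10-gene worked fixture at w = 0.75
  prof <- rankNormalize(setNames(rnorm(10), paste0("g", 1:10)))
  set10 <- c("g2", "g5", "g9")
  expect_equal(enrichmentScore(prof, set10, w = 0.75),
               bruteForceES(prof, set10, w = 0.75), tolerance = 1e-12)
  # randomized fixtures up to 200 genes, w in {0, 0.75, 1.5}
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    prof <- rankNormalize(setNames(rnorm(n), paste0("g", seq_len(n))))
    genes <- sample(names(prof), sample(3:(n %/% 2), 1))
    for (w in c(0, 0.75, 1.5))
      expect_equal(enrichmentScore(prof, genes, w),
                   bruteForceES(prof, genes, w), tolerance = 1e-12)
  }
})

test_that("degenerate gene sets raise informative errors", {
  r <- rankNormalize(setNames(1:5, paste0("g", 1:5)))
  err <- tryCatch(enrichmentScore(r, c("zz1", "zz2")),
                  error = function(e) e)
  expect_identical(err$overlap, 0L)
  expect_error(enrichmentScore(r, paste0("g", 1:5)), "degenerate")
})

test_that("collection scoring recovers the planted enrichment pattern", {
  design <- defaultStudyDesign(seed = 7)
  sim <- simulateStudy(design)
  sets <- programGeneSets(design)
  em <- scoreCollection(sim$matrix, sets, w = 0.75)
  s <- enrichmentScores(em)
  grp <- split(sim$annotation$sample_id, sim$annotation$group)
  gm <- sapply(grp, function(g) rowMeans(s[, g, drop = FALSE]))
  # embryonic program: dualpos above both single-positive groups
  expect_gt(gm["embryonic", "dualpos"], gm["embryonic", "typeI"])
  expect_gt(gm["embryonic", "dualpos"], gm["embryonic", "typeII"])
  # typeI program: dualpos between-or-above the single-positive means
  expect_gte(gm["typeI", "dualpos"], min(gm["typeI", c("typeI", "typeII")]))
  # duplicate of a set under a new name scores identically
  dup <- GeneSetCollection(c(sets@sets,
                             GeneSet("embryonic_copy",
                                     geneIds(getGeneSet(sets, "embryonic")))))
  s2 <- enrichmentScores(scoreCollection(sim$matrix, dup, w = 0.75))
  expect_equal(unname(s2["embryonic_copy", ]), unname(s2["embryonic", ]))
})

test_that("scores are invariant under strictly monotone per-sample transforms", {
  design <- defaultStudyDesign(seed = 3)
  sim <- simulateStudy(design)
  sets <- programGeneSets(design)
  a <- enrichmentScores(scoreCollection(sim$matrix, sets))
  warped <- ExpressionMatrix(exp(0.5 * exprValues(sim$matrix)), "raw")
  b <- enrichmentScores(scoreCollection(warped, sets))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("column-separable scoring and overlap-threshold dropping", {
  design <- defaultStudyDesign(seed = 5)
  sim <- simulateStudy(design)
  sets <- programGeneSets(design)
  batch <- enrichmentScores(scoreCollection(sim$matrix, sets))
  one <- ExpressionMatrix(exprValues(sim$matrix)[, 4, drop = FALSE],
                          "log2")
  single <- enrichmentScores(scoreCollection(one, sets))
  expect_equal(batch[, 4, drop = FALSE], single)

  tiny <- GeneSetCollection(list(GeneSet("tooSmall", c("g0001", "zz")),
                                 getGeneSet(sets, "embryonic")))
  expect_warning(out <- scoreCollection(sim$matrix, tiny), "dropped")
  expect_identical(rownames(enrichmentScores(out)), "embryonic")
  onlyTiny <- GeneSetCollection(list(GeneSet("tooSmall", c("g0001", "zz"))))
  expect_warning(expect_error(scoreCollection(sim$matrix, onlyTiny),
                              "all gene sets dropped"))
})
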