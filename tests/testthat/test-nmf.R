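test_that("an exact rank-1 matrix is factorized to numerical precision", {
  set.seed(2)
  u <- runif(30, 0.5, 2); v <- runif(6, 0.5, 2)
  m <- tinyMatrix(outer(u, v), scale = "raw")
  model <- fitNmf(m, 1, nRestarts = 3, tol = 1e-13, maxIter = 5000,
                  seed = 4)
  relErr <- utils::tail(objectiveTrace(model), 1) /
    sqrt(sum(exprValues(m)^2))
  expect_lt(relErr, 1e-6)
  expect_true(all(basisMatrix(model) >= 0))
  expect_true(all(coefMatrix(model) >= 0))
})

test_that("rank-3 factorization clusters the default study by cell type", {
  sim <- simulateStudy(defaultStudyDesign(seed = 7))
  model <- suppressMessages(fitNmf(sim$matrix, 3, nRestarts = 20,
                                   seed = 7))
  cl <- assignClusters(model)
  expect_equal(clusterPurity(cl[sim$annotation$sample_id],
                             sim$annotation$group), 1.0)
  expect_equal(unname(sort(table(cl))), c(3L, 3L, 3L), ignore_attr = TRUE)
})

test_that("the objective trace is non-increasing at every iteration", {
  set.seed(10)
  m <- tinyMatrix(matrix(runif(40 * 8, 0, 3), 40, 8), scale = "raw")
  model <- fitNmf(m, 3, nRestarts = 2, seed = 6)
  tr <- objectiveTrace(model)
  expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1)))
})

test_that("the returned restart is the best of all restarts", {
  set.seed(20)
  m <- tinyMatrix(matrix(runif(30 * 7, 0, 2), 30, 7), scale = "raw")
  multi <- fitNmf(m, 2, nRestarts = 6, seed = 9)
  finals <- vapply(seq_len(6), function(r) {
    fit <- oncostates:::withSeed(
      oncostates:::childSeed(9, r),
      oncostates:::nmfSingle(exprValues(m), 2, 2000L, 1e-6))
    utils::tail(fit$trace, 1)
  }, numeric(1))
  expect_equal(utils::tail(objectiveTrace(multi), 1), min(finals))
})

test_that("the final objective matches an independent reference NMF within 1%", {
  set.seed(31)
  V <- matrix(runif(50 * 9, 0, 2), 50, 9)
  m <- tinyMatrix(V, scale = "raw")
  model <- fitNmf(m, 3, nRestarts = 10, tol = 1e-9, maxIter = 5000,
                  seed = 3)
  ours <- utils::tail(objectiveTrace(model), 1)
  csv <- tempfile(fileext = ".csv")
  utils::write.table(V, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.decomposition import NMF",
    "V = np.loadtxt(sys.argv[1], delimiter=',')",
    "best = None",
    "for s in range(5):",
    "    nmf = NMF(n_components=3, init='random', random_state=s,",
    "              max_iter=5000, tol=1e-9)",
    "    W = nmf.fit_transform(V); H = nmf.components_",
    "    err = np.linalg.norm(V - W @ H)",
    "    best = err if best is None or err < best else best",
    "print(best)"), script)
  ref <- as.numeric(system2("python", c(script, csv), stdout = TRUE))
  expect_lt(abs(ours - ref) / ref, 0.01)
})

test_that("log-scale input is shifted nonnegative and ranks are validated", {
  m <- tinyMatrix(matrix(c(-2, 1, 0, 3, 5, -1), 2, 3))
  expect_message(model <- fitNmf(m, 1, nRestarts = 2, seed = 1),
                 "shifted")
  expect_true(all(basisMatrix(model) >= 0))
  expect_error(fitNmf(m, 5, seed = 1), "rank")
})

test_that("cluster assignment takes the argmax with lowest-index ties", {
  H <- matrix(c(0.1, 0.8, 0.1, 0.5, 0.5, 0, 0.2, 0.2, 0.6), 3, 3,
              dimnames = list(paste0("F", 0:2), paste0("s", 1:3)))
  W <- matrix(1 / 4, 4, 3, dimnames = list(paste0("g", 1:4),
                                           paste0("F", 0:2)))
  model <- new("NMFModel", W = W, H = H, rank = 3L, seed = 1L,
               objectiveTrace = c(2, 1), shift = 0)
  cl <- assignClusters(model)
  expect_identical(unname(cl), c("F1", "F0", "F2"))
})

test_that("projection onto a frozen basis is self-consistent", {
  set.seed(40)
  kras <- simulateKrasPanel(nCellLines = 15, moduleSize = 40,
                            noiseSd = 0.02, seed = 8)
  sub <- tinyMatrix(exprValues(kras$matrix)[geneIds(kras$module), ],
                    genes = geneIds(kras$module),
                    samples = sampleIds(kras$matrix), scale = "raw")
  model <- fitNmf(sub, 3, nRestarts = 10, tol = 1e-10, maxIter = 5000,
                  seed = 2)
  Hnew <- projectOntoW(model, sub)
  expect_equal(Hnew, sampleWeights(model), tolerance = 1e-3)

  # a profile equal to one basis column is recovered one-hot
  W <- basisMatrix(model)
  onehot <- tinyMatrix(W[, 2, drop = FALSE] * 50,
                       genes = rownames(W), samples = "probe",
                       scale = "raw")
  h <- projectOntoW(model, onehot)
  expect_equal(unname(h[, 1]), c(0, 1, 0), tolerance = 1e-3)

  # all-zero profile stays zero and is flagged
  zero <- tinyMatrix(matrix(0, nrow(W), 1), genes = rownames(W),
                     samples = "blank", scale = "raw")
  expect_warning(hz <- projectOntoW(model, zero), "all-zero")
  expect_true(all(hz == 0))

  # insufficient gene overlap is rejected
  small <- tinyMatrix(matrix(1, 3, 1),
                      genes = rownames(W)[1:3], samples = "tiny",
                      scale = "raw")
  expect_error(projectOntoW(model, small), "50%")
})

test_that("projection is equivariant under gene and sample permutation", {
  set.seed(50)
  W <- matrix(runif(30 * 3), 30, 3,
              dimnames = list(paste0("g", 1:30), paste0("F", 0:2)))
  V <- tinyMatrix(matrix(runif(30 * 5, 0, 2), 30, 5),
                  genes = rownames(W), scale = "raw")
  H <- projectOntoW(W, V)
  gp <- sample(30); sp <- sample(5)
  Vp <- ExpressionMatrix(exprValues(V)[gp, sp], "raw")
  Hp <- projectOntoW(W[gp, ], Vp)
  expect_equal(Hp, H[, sp], tolerance = 1e-9)
})
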