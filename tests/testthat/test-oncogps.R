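test_that("in-package k-means matches the reference implementation's inertia", {
  set.seed(12)
  for (rep in 1:3) {
    X <- rbind(cbind(rnorm(20, 0), rnorm(20, 0)),
               cbind(rnorm(20, 4), rnorm(20, 4)),
               cbind(rnorm(15, 8), rnorm(15, 0)))
    ours <- lloydKMeans(X, 3, nRestarts = 50, seed = rep)
    ref <- stats::kmeans(X, 3, nstart = 50)
    expect_lt(abs(ours$inertia - ref$tot.withinss) /
                ref$tot.withinss, 0.01)
    # well-separated clusters are recovered exactly
    truth <- rep(1:3, c(20, 20, 15))
    expect_equal(clusterPurity(ours$cluster, truth), 1.0)
  }
})

test_that("map construction recovers planted cell-line states", {
  kras <- simulateKrasPanel(nCellLines = 18, moduleSize = 60,
                            noiseSd = 0.02, seed = 4)
  map <- buildMap(kras$matrix, kras$module, kNodes = 3, nStates = 3,
                  nRestarts = 10, seed = 5)
  st <- referenceStates(map)
  expect_equal(clusterPurity(st[kras$annotation$sample_id],
                             kras$annotation$group), 1.0)
})

# shared default map for the geometry blocks below
sharedKrasPanel <- simulateKrasPanel(seed = 11)
sharedKrasMap <- suppressMessages(
  buildMap(sharedKrasPanel$matrix, sharedKrasPanel$module, seed = 7))

test_that("the default configuration builds a nine-node map on the unit circle", {
  coords <- nodeCoords(sharedKrasMap)
  expect_identical(nrow(coords), 9L)
  expect_equal(unname(sqrt(rowSums(coords^2))), rep(1, 9))
  expect_false(anyDuplicated(coords, MARGIN = 1) > 0)
  # node F0 sits at the top of the circle
  expect_equal(unname(coords["F0", ]), c(0, 1), tolerance = 1e-12)
})

test_that("low-overlap modules are rejected", {
  kras <- simulateKrasPanel(nCellLines = 9, moduleSize = 50, seed = 2)
  badModule <- GeneSet("off", sprintf("x%04d", 1:50))
  expect_error(buildMap(kras$matrix, badModule, kNodes = 3),
               "80%")
})

test_that("the pull formula places one-hot and uniform weights exactly", {
  map <- sharedKrasMap
  W <- basisMatrix(map)
  coords <- nodeCoords(map)
  onehot <- tinyMatrix(W[, 4, drop = FALSE] * 10, genes = rownames(W),
                       samples = "pure", scale = "raw")
  pr <- projectSamples(map, onehot)
  expect_equal(c(pr$x, pr$y), unname(coords[4, ]), tolerance = 1e-3)
  # equal combination of all basis columns (columns are L1-normalized)
  unif <- tinyMatrix(rowSums(W), genes = rownames(W),
                     samples = "center", scale = "raw")
  pu <- projectSamples(map, unif)
  expect_equal(c(pu$x, pu$y), unname(colMeans(coords)), tolerance = 1e-3)
})

test_that("projections stay in the node convex hull and are continuous", {
  map <- sharedKrasMap
  kras <- sharedKrasPanel
  pr <- projectSamples(map, kras$matrix)
  # hull check: recompute xy independently as an explicit convex
  # combination of node coordinates
  coords <- nodeCoords(map)
  wcols <- as.matrix(pr[, rownames(coords)])
  p <- map@pullExponent
  for (i in seq_len(nrow(pr))) {
    lam <- wcols[i, ]^p / sum(wcols[i, ]^p)
    expect_true(all(lam >= 0) && abs(sum(lam) - 1) < 1e-9)
    expect_equal(unname(c(pr$x[i], pr$y[i])),
                 unname(colSums(coords * lam)), tolerance = 1e-9)
  }
  expect_lte(max(sqrt(pr$x^2 + pr$y^2)), 1 + 1e-9)

  # numerical continuity: an epsilon-perturbation moves xy by O(eps)
  v <- exprValues(kras$matrix)[, 1, drop = FALSE]
  set.seed(2)
  eps <- 1e-4
  vp <- v + matrix(rnorm(nrow(v), 0, eps), ncol = 1)
  colnames(vp) <- colnames(v)
  p1 <- projectSamples(map, ExpressionMatrix(pmax(v, 0), "raw"))
  p2 <- projectSamples(map, ExpressionMatrix(pmax(vp, 0), "raw"))
  expect_lt(sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2), 1e-2)
})

test_that("rotating the node layout rotates every projection identically", {
  map <- sharedKrasMap
  kras <- sharedKrasPanel
  phi <- pi / 5
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rotated <- new("OncoGPSMap", module = map@module, model = map@model,
                 nodeCoords = nodeCoords(map) %*% R,
                 states = map@states, nStates = map@nStates,
                 pullExponent = map@pullExponent, seed = map@seed)
  a <- projectSamples(map, kras$matrix)
  b <- projectSamples(rotated, kras$matrix)
  expect_equal(unname(as.matrix(a[, c("x", "y")]) %*% R),
               unname(as.matrix(b[, c("x", "y")])), tolerance = 1e-9)
})

test_that("samples planted with one state's activity project to that state", {
  kras <- sharedKrasPanel
  map <- sharedKrasMap
  sim <- simulateStudy(defaultStudyDesign(seed = 7))
  dp <- sim$annotation$sample_id[sim$annotation$group == "dualpos"]
  planted <- addStateActivity(sim$matrix, dp, kras, state = 2,
                              scale = 2)
  pr <- projectSamples(map, planted)
  # which map state corresponds to planted state 2 (majority vote)
  st <- referenceStates(map)
  inState2 <- kras$annotation$sample_id[kras$annotation$group == "state2"]
  target <- as.integer(names(which.max(table(st[inState2]))))
  got <- pr$nearest_state[match(dp, pr$sample_id)]
  expect_true(all(got == target))
})

test_that("a map survives a JSON round-trip with identical projections", {
  map <- sharedKrasMap
  kras <- sharedKrasPanel
  path <- withr::local_tempfile(fileext = ".json")
  writeOncoGPSMap(map, path)
  back <- readOncoGPSMap(path)
  expect_equal(nodeCoords(back), nodeCoords(map))
  expect_identical(referenceStates(back), referenceStates(map))
  a <- projectSamples(map, kras$matrix)
  b <- projectSamples(back, kras$matrix)
  expect_equal(a, b, tolerance = 1e-12)
})
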