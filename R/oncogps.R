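#' Seeded Lloyd k-means with k-means++ initialization
#'
#' Minimal in-package implementation used for Onco-GPS state calling:
#' k-means++ seeding, Lloyd iterations to convergence, best of
#' \code{nRestarts} by within-cluster sum of squares. Empty clusters
#' are re-seeded at the point farthest from its centroid.
#'
#' @param X observations x features numeric matrix.
#' @param k number of clusters.
#' @param nRestarts random restarts, default 50.
#' @param maxIter Lloyd iteration cap, default 100.
#' @param seed integer seed.
#' @return list with \code{cluster} (integer vector), \code{centers}
#'   (k x features), \code{inertia} (total within-cluster SS).
#' @export
lloydKMeans <- function(X, k, nRestarts = 50L, maxIter = 100L, seed = 7L) {
  X <- as.matrix(X)
  stopIfNot(k >= 1L && k <= nrow(X),
            "k must lie in [1, number of observations]")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(childSeed(seed, 7000 + r),
                    kmeansSingle(X, k, maxIter))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

kmeansSingle <- function(X, k, maxIter) {
  n <- nrow(X)
  # k-means++ seeding
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(X, 1, function(row)
      min(colSums((t(centers) - row)^2)))
    if (sum(d2) == 0) {
      centers <- rbind(centers, X[sample.int(n, 1L), , drop = FALSE])
    } else {
      centers <- rbind(centers,
                       X[sample.int(n, 1L, prob = d2), , drop = FALSE])
    }
  }
  cluster <- integer(n)
  for (it in seq_len(maxIter)) {
    D <- distToCenters(X, centers)
    newCluster <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(newCluster == j)) {       # re-seed an empty cluster
        far <- which.max(D[cbind(seq_len(n), newCluster)])
        centers[j, ] <- X[far, ]
        newCluster[far] <- j
      }
    }
    if (it > 1L && all(newCluster == cluster)) break
    cluster <- newCluster
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[cluster == j, , drop = FALSE])
  }
  D <- distToCenters(X, centers)
  inertia <- sum(D[cbind(seq_len(n), cluster)])
  list(cluster = cluster, centers = centers, inertia = inertia)
}

distToCenters <- function(X, centers) {
  # squared Euclidean distances, observations x centers
  xs <- rowSums(X^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * X %*% t(centers)
}

#' Build an Onco-GPS style state map from a reference panel
#'
#' Restricts the reference matrix to the module genes (at least 80\%
#' of the module must be present), fits NMF at rank \code{kNodes},
#' places the factor nodes at equally spaced positions on the unit
#' circle (ordered by factor index, node F0 at the top), and groups
#' the reference samples into \code{nStates} transcriptional states by
#' seeded k-means on their L1-normalized factor-weight profiles.
#'
#' @param reference raw/nonnegative-scale [ExpressionMatrix-class] of
#'   the reference panel (e.g. a cell-line compendium).
#' @param module [GeneSet-class] of module genes to decompose.
#' @param kNodes number of NMF factors / map nodes, default 9.
#' @param nStates number of transcriptional states, default 3.
#' @param pullExponent projection sharpening exponent, default 2.
#' @param nRestarts NMF restarts, default 10.
#' @param seed integer seed.
#' @return An [OncoGPSMap-class].
#' @export
buildMap <- function(reference, module, kNodes = 9L, nStates = 3L,
                     pullExponent = 2, nRestarts = 10L, seed = 7L) {
  stopifnot(is(reference, "ExpressionMatrix"), is(module, "GeneSet"))
  stopIfNot(kNodes >= 2L, "kNodes must be >= 2")
  stopIfNot(nStates >= 1L, "nStates must be >= 1")
  present <- intersect(module@genes, geneIds(reference))
  stopIfNot(length(present) >= 0.8 * length(module@genes),
            "module overlaps the reference by less than 80%")
  sub <- ExpressionMatrix(
    exprValues(reference)[present, , drop = FALSE],
    scaleTag(reference))
  model <- fitNmf(sub, kNodes, nRestarts = nRestarts,
                  seed = childSeed(seed, 1))
  theta <- pi / 2 - 2 * pi * (seq_len(kNodes) - 1L) / kNodes
  coords <- cbind(x = cos(theta), y = sin(theta))
  rownames(coords) <- paste0("F", seq_len(kNodes) - 1L)
  weights <- sampleWeights(model)
  km <- lloydKMeans(t(weights), nStates, nRestarts = 50L,
                    seed = childSeed(seed, 2))
  states <- stats::setNames(as.integer(km$cluster), colnames(weights))
  new("OncoGPSMap", module = module, model = model,
      nodeCoords = coords, states = states,
      nStates = as.integer(nStates), pullExponent = pullExponent,
      seed = as.integer(seed))
}

#' Project samples onto an Onco-GPS map
#'
#' Factor weights come from [projectOntoW()] against the map's basis;
#' the planar position is the power-normalized weighted pull toward the
#' node coordinates,
#' \eqn{xy = \sum_j c_j w_j^p / \sum_j w_j^p} with \code{p} the map's
#' pull exponent — a convex combination, so every projection lies in
#' the convex hull of the nodes. Each sample's state is that of the
#' nearest reference sample in factor-weight space (Euclidean).
#' Degenerate all-zero-weight samples are placed at the node centroid
#' and flagged.
#'
#' @param map an [OncoGPSMap-class].
#' @param samples an [ExpressionMatrix-class] covering at least 50\% of
#'   the module genes.
#' @return data.frame with \code{sample_id}, \code{x}, \code{y},
#'   \code{nearest_state}, \code{degenerate}, plus one weight column
#'   per factor.
#' @export
projectSamples <- function(map, samples) {
  stopifnot(is(map, "OncoGPSMap"), is(samples, "ExpressionMatrix"))
  Hnew <- projectOntoW(basisMatrix(map), samples)
  coords <- nodeCoords(map)
  p <- map@pullExponent
  refW <- sampleWeights(map@model)
  out <- lapply(seq_len(ncol(Hnew)), function(j) {
    w <- Hnew[, j]
    degenerate <- sum(w) < 1e-12
    if (degenerate) {
      xy <- colMeans(coords)
      st <- NA_integer_
    } else {
      wp <- w^p
      xy <- colSums(coords * wp) / sum(wp)
      d2 <- colSums((refW - w)^2)
      st <- map@states[[which.min(d2)]]
    }
    data.frame(sample_id = colnames(Hnew)[j], x = xy[[1]], y = xy[[2]],
               nearest_state = st, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cbind(res, as.data.frame(t(Hnew)))
}

#' Serialize / restore an Onco-GPS map as JSON
#'
#' @param map an [OncoGPSMap-class].
#' @param path destination JSON file.
#' @return \code{path} (write) or the restored [OncoGPSMap-class]
#'   (read).
#' @export
writeOncoGPSMap <- function(map, path) {
  stopifnot(is(map, "OncoGPSMap"))
  obj <- list(
    module = list(name = map@module@name,
                  description = map@module@description,
                  genes = map@module@genes),
    W = list(values = map@model@W, genes = rownames(map@model@W)),
    H = list(values = map@model@H, samples = colnames(map@model@H)),
    rank = map@model@rank, modelSeed = map@model@seed,
    objectiveTrace = map@model@objectiveTrace, shift = map@model@shift,
    nodeCoords = map@nodeCoords,
    states = as.list(map@states),
    nStates = map@nStates, pullExponent = map@pullExponent,
    seed = map@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeOncoGPSMap
#' @export
readOncoGPSMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- as.integer(obj$rank)
  fn <- paste0("F", seq_len(k) - 1L)
  W <- matrix(as.numeric(obj$W$values), ncol = k,
              dimnames = list(obj$W$genes, fn))
  H <- matrix(as.numeric(obj$H$values), nrow = k, byrow = FALSE,
              dimnames = list(fn, obj$H$samples))
  model <- new("NMFModel", W = W, H = H, rank = k,
               seed = as.integer(obj$modelSeed),
               objectiveTrace = as.numeric(obj$objectiveTrace),
               shift = as.numeric(obj$shift))
  coords <- matrix(as.numeric(obj$nodeCoords), ncol = 2,
                   dimnames = list(fn, c("x", "y")))
  new("OncoGPSMap",
      module = GeneSet(obj$module$name, obj$module$genes,
                       obj$module$description),
      model = model, nodeCoords = coords,
      states = stats::setNames(as.integer(unlist(obj$states)),
                               names(obj$states)),
      nStates = as.integer(obj$nStates),
      pullExponent = as.numeric(obj$pullExponent),
      seed = as.integer(obj$seed))
}
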