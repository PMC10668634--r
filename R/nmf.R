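#' Fit a non-negative matrix factorization by multiplicative updates
#'
#' Lee-Seung multiplicative updates minimizing the Frobenius
#' reconstruction error \eqn{\|V - WH\|_F}, best of \code{nRestarts}
#' random initializations. Log-scale matrices containing negative
#' entries are shifted by their global minimum before fitting (the
#' shift is recorded in the model and reported with a message).
#' Convergence when the relative objective change falls below
#' \code{tol} or after \code{maxIter} iterations; the winning restart's
#' objective trace is kept (it is non-increasing, a property of the
#' updates). W columns are L1-normalized with the scale absorbed into
#' the rows of H. Deterministic given \code{seed}.
#'
#' @param m an [ExpressionMatrix-class] or numeric matrix.
#' @param k factorization rank, 1 <= k <= min(genes, samples).
#' @param nRestarts random restarts, default 20.
#' @param maxIter iteration cap per restart, default 2000.
#' @param tol relative-change convergence tolerance, default 1e-6.
#' @param seed integer seed.
#' @return An [NMFModel-class].
#' @export
fitNmf <- function(m, k, nRestarts = 20L, maxIter = 2000L, tol = 1e-6,
                   seed = 7L) {
  V <- if (is(m, "ExpressionMatrix")) exprValues(m) else m
  stopIfNot(is.matrix(V) && is.numeric(V), "m must be a numeric matrix")
  stopIfNot(k >= 1L && k <= min(dim(V)),
            "rank k must lie in [1, min(genes, samples)]")
  shift <- 0
  if (min(V) < 0) {
    shift <- -min(V)
    message("input contains negative values; shifted by ",
            formatNum(shift), " before factorization")
    V <- V + shift
  }
  if (any(V < 0)) stop("negative entries after shift", call. = FALSE)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(childSeed(seed, r), nmfSingle(V, k, maxIter, tol))
    if (is.null(best) ||
        utils::tail(fit$trace, 1) < utils::tail(best$trace, 1))
      best <- fit
  }
  # absorb W column scale into H rows so factors are comparable
  cs <- colSums(best$W)
  cs[cs == 0] <- 1
  W <- sweep(best$W, 2, cs, "/")
  H <- sweep(best$H, 1, cs, "*")
  fn <- paste0("F", seq_len(k) - 1L)
  dimnames(W) <- list(rownames(V), fn)
  dimnames(H) <- list(fn, colnames(V))
  new("NMFModel", W = W, H = H, rank = as.integer(k),
      seed = as.integer(seed), objectiveTrace = best$trace,
      shift = shift)
}

# One multiplicative-update run from a random uniform start.
nmfSingle <- function(V, k, maxIter, tol) {
  eps <- .Machine$double.eps
  n <- nrow(V); p <- ncol(V)
  scale <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(n * k, 0, 1), n, k) * scale + eps
  H <- matrix(stats::runif(k * p, 0, 1), k, p) * scale + eps
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    obj <- sqrt(sum((V - W %*% H)^2))
    trace <- c(trace, obj)
    if (is.finite(prev) && prev - obj < tol * max(prev, eps)) break
    prev <- obj
  }
  list(W = W, H = H, trace = trace)
}

#' Assign each sample to its dominant NMF factor
#'
#' Argmax over each column of H; exact ties go to the lowest factor
#' index.
#'
#' @param model an [NMFModel-class].
#' @return named character vector: sample -> factor label (F0..).
#' @export
assignClusters <- function(model) {
  stopifnot(is(model, "NMFModel"))
  H <- coefMatrix(model)
  idx <- apply(H, 2, which.max)   # which.max takes the first maximum
  stats::setNames(rownames(H)[idx], colnames(H))
}

#' Project new expression profiles onto a fixed factor basis
#'
#' Solves \eqn{\min_{H \ge 0} \|V - W H\|_F} with W frozen, by
#' multiplicative updates on H from a deterministic uniform start (so
#' no seed is needed). Profiles are restricted to the genes shared with
#' W (at least 50\% of W's genes must be present); negative (log-scale)
#' values are shifted by the global minimum first. Columns of the
#' result are L1-normalized to factor weights; all-zero profiles stay
#' zero and are flagged with a warning.
#'
#' @param W nonnegative genes x k basis matrix with gene rownames (or
#'   an [NMFModel-class] / [OncoGPSMap-class] to take it from).
#' @param newProfiles an [ExpressionMatrix-class] or numeric matrix.
#' @param maxIter,tol update controls, defaults 2000 and 1e-8.
#' @return k x samples matrix of nonnegative factor weights, columns
#'   summing to 1 (or 0 for all-zero profiles).
#' @export
projectOntoW <- function(W, newProfiles, maxIter = 2000L, tol = 1e-8) {
  if (is(W, "OncoGPSMap")) W <- basisMatrix(W)
  if (is(W, "NMFModel")) W <- basisMatrix(W)
  V <- if (is(newProfiles, "ExpressionMatrix")) exprValues(newProfiles)
       else newProfiles
  stopIfNot(!is.null(rownames(W)) && !is.null(rownames(V)),
            "W and profiles must carry gene rownames")
  shared <- intersect(rownames(W), rownames(V))
  stopIfNot(length(shared) >= 0.5 * nrow(W),
            "profiles cover fewer than 50% of the basis genes")
  Wm <- W[shared, , drop = FALSE]
  Vm <- V[shared, , drop = FALSE]
  if (min(Vm) < 0) Vm <- Vm - min(Vm)
  k <- ncol(Wm)
  eps <- .Machine$double.eps
  H <- matrix(mean(Vm) / max(mean(Wm) * k, eps), k, ncol(Vm))
  WtV <- crossprod(Wm, Vm)
  WtW <- crossprod(Wm)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * WtV / (WtW %*% H + eps)
    obj <- sqrt(sum((Vm - Wm %*% H)^2))
    if (is.finite(prev) && prev - obj < tol * max(prev, eps)) break
    prev <- obj
  }
  cs <- colSums(H)
  zero <- cs < 1e-12
  if (any(zero))
    warning(sum(zero), " all-zero profile(s); weights left at zero",
            call. = FALSE)
  H[, !zero] <- sweep(H[, !zero, drop = FALSE], 2, cs[!zero], "/")
  H[, zero] <- 0
  dimnames(H) <- list(colnames(Wm), colnames(Vm))
  H
}
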