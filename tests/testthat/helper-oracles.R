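# Shared fixtures and independent oracles used across the suite.

# Small named expression matrix builder.
tinyMatrix <- function(values, genes = NULL, samples = NULL,
                       scale = "log2") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  ExpressionMatrix(m, scale)
}

# Independent brute-force enrichment score: explicit double loop over
# the descending-rank positions, recomputing both ECDFs from scratch at
# every position. O(n * |set|), deliberately naive.
bruteForceES <- function(rankedProfile, genes, w) {
  ord <- order(-rankedProfile, names(rankedProfile))
  r <- rankedProfile[ord]
  ids <- names(r)
  inSet <- ids %in% genes
  n <- length(r)
  nIn <- sum(inSet)
  denomIn <- sum(r[inSet]^w)
  es <- 0
  for (i in seq_len(n)) {
    pin <- 0
    pout <- 0
    for (j in seq_len(i)) {
      if (inSet[j]) pin <- pin + r[j]^w else pout <- pout + 1
    }
    es <- es + pin / denomIn - pout / (n - nIn)
  }
  unname(es)
}

# Full hypergeometric enumeration of every 2x2 table with the observed
# margins; two-sided Fisher p sums the probabilities of all tables at
# most as probable as the observed one (with the usual 1e-7 slack).
enumFisherP <- function(a, b) {
  n1 <- a[2]; n2 <- b[2]; K <- a[1] + b[1]
  xs <- max(0, K - n2):min(n1, K)
  probs <- stats::dhyper(xs, n1, n2, K)
  pObs <- stats::dhyper(a[1], n1, n2, K)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Cluster purity of an assignment against true labels.
clusterPurity <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  tab <- table(assigned, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

# Gaussian IC closed form sanity values are |rho|; draw a correlated
# bivariate normal pair deterministically.
gaussianPair <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}
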