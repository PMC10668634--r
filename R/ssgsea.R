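#' Rank-normalize one expression profile
#'
#' Ascending ranks mapped to (0, 1] by r/n, ties receiving the average
#' rank. The output is a deterministic, permutation-equivariant
#' function of the input: any strictly increasing transform of the
#' values yields identical normalized ranks.
#'
#' @param profile numeric vector (optionally named) of one sample's
#'   per-gene expression values; all finite, length >= 2.
#' @return numeric vector of normalized ranks, same names and order.
#' @export
rankNormalize <- function(profile) {
  stopIfNot(length(profile) >= 2L, "need at least 2 genes")
  stopIfNot(all(is.finite(profile)), "non-finite expression value")
  r <- rank(profile, ties.method = "average") / length(profile)
  names(r) <- names(profile)
  r
}

#' Single-sample enrichment score of a gene set
#'
#' Genes are sorted by normalized rank, highest expression first, and
#' the score is the running-sum total of the difference between the
#' weighted in-set ECDF and the out-of-set ECDF:
#' \deqn{ES = \sum_i [P^w_{in}(i) - P_{out}(i)]}
#' with \eqn{P^w_{in}(i) = \sum_{j \le i, j \in S} r_j^w / \sum_{j \in S}
#' r_j^w} and \eqn{P_{out}(i) = |\{j \le i, j \notin S\}| / (n - |S|)}.
#' A positive score means the set concentrates at the top of the
#' ranked list; a negative score, at the bottom. With \code{w = 0} this
#' is the unweighted running-sum total.
#'
#' @param rankedProfile named numeric of normalized ranks (from
#'   [rankNormalize()]).
#' @param geneSet a [GeneSet-class] (or character vector of gene ids).
#' @param w nonnegative weight exponent, default 0.75.
#' @return single numeric enrichment score.
#' @export
enrichmentScore <- function(rankedProfile, geneSet, w = 0.75) {
  genes <- if (is(geneSet, "GeneSet")) geneSet@genes else geneSet
  stopIfNot(!is.null(names(rankedProfile)),
            "rankedProfile must be named by gene id")
  stopIfNot(w >= 0, "weight exponent must be nonnegative")
  inSet <- names(rankedProfile) %in% genes
  overlap <- sum(inSet)
  if (overlap == 0L) {
    e <- simpleError("gene set has zero overlap with the profile")
    e$overlap <- 0L
    stop(e)
  }
  n <- length(rankedProfile)
  if (overlap == n)
    stop("gene set covers every profiled gene (degenerate denominator)",
         call. = FALSE)
  ord <- order(-rankedProfile, names(rankedProfile))
  r <- rankedProfile[ord]
  inS <- inSet[ord]
  wts <- ifelse(inS, r^w, 0)
  pIn <- cumsum(wts) / sum(wts)
  pOut <- cumsum(!inS) / (n - overlap)
  sum(pIn - pOut)
}

#' Score a gene-set collection on every sample (ssGSEA)
#'
#' Each sample's profile is rank-normalized independently and every
#' gene set scored by [enrichmentScore()]; scores are therefore
#' invariant to any strictly monotone per-sample transform of the
#' expression values. Sets overlapping the matrix gene space by fewer
#' than \code{minOverlap} genes are dropped with a warning.
#'
#' @param m an [ExpressionMatrix-class] (any scale).
#' @param sets a [GeneSetCollection-class].
#' @param w weight exponent, default 0.75.
#' @param minOverlap minimum set/matrix gene overlap, default 5.
#' @param normalize if TRUE, min-max rescale the full score matrix to
#'   [0, 1] (off by default).
#' @return An [EnrichmentMatrix-class] (sets x samples).
#' @export
scoreCollection <- function(m, sets, w = 0.75, minOverlap = 5L,
                            normalize = FALSE) {
  stopifnot(is(m, "ExpressionMatrix"), is(sets, "GeneSetCollection"))
  genes <- geneIds(m)
  keep <- vapply(sets@sets, function(s) {
    ov <- sum(s@genes %in% genes)
    ov >= minOverlap && ov < length(genes)
  }, logical(1))
  if (!all(keep))
    warning(sum(!keep), " gene set(s) below the overlap threshold (",
            minOverlap, ") dropped: ",
            paste(utils::head(geneSetNames(sets)[!keep], 5),
                  collapse = ", "), call. = FALSE)
  if (!any(keep))
    stop("all gene sets dropped for insufficient overlap", call. = FALSE)
  setList <- sets@sets[keep]
  vals <- exprValues(m)
  scores <- matrix(NA_real_, length(setList), ncol(vals),
                   dimnames = list(vapply(setList, slot, character(1),
                                          "name"),
                                   colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    r <- rankNormalize(vals[, j])
    for (i in seq_along(setList))
      scores[i, j] <- enrichmentScore(r, setList[[i]], w)
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  new("EnrichmentMatrix", scores = scores, weightExponent = w)
}
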