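#' Accessors for package containers
#'
#' Small generic accessors so downstream code never touches slots
#' directly.
#'
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "EnrichmentMatrix", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)

#' Names of the gene sets in a collection
#' @param x a [GeneSetCollection-class].
#' @return character vector of set names, in collection order.
#' @export
geneSetNames <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  vapply(x@sets, slot, character(1), name = "name")
}

#' Extract one gene set from a collection by name
#' @param x a [GeneSetCollection-class].
#' @param name set name.
#' @return the [GeneSet-class].
#' @export
getGeneSet <- function(x, name) {
  i <- match(name, geneSetNames(x))
  if (is.na(i)) stop("no gene set named '", name, "'", call. = FALSE)
  x@sets[[i]]
}

#' @rdname accessors
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname accessors
#' @export
setGeneric("enrichmentScores", function(x) standardGeneric("enrichmentScores"))
#' @rdname accessors
#' @export
setMethod("enrichmentScores", "EnrichmentMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setMethod("basisMatrix", "NMFModel", function(x) x@W)
#' @rdname accessors
#' @export
setMethod("basisMatrix", "OncoGPSMap", function(x) x@model@W)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "NMFModel", function(x) x@H)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "NMFModel", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname accessors
#' @export
setMethod("nodeCoords", "OncoGPSMap", function(x) x@nodeCoords)

#' @rdname accessors
#' @export
setGeneric("referenceStates", function(x) standardGeneric("referenceStates"))
#' @rdname accessors
#' @export
setMethod("referenceStates", "OncoGPSMap", function(x) x@states)

#' Per-sample factor weights of an NMF model
#'
#' Each column of H renormalized to sum to one; the interpretable
#' "fractional program usage" of every sample. All-zero columns are
#' left at zero.
#'
#' @param x an [NMFModel-class].
#' @return k x samples matrix with columns summing to 1 (or 0).
#' @export
sampleWeights <- function(x) {
  stopifnot(is(x, "NMFModel"))
  H <- x@H
  cs <- colSums(H)
  nz <- cs > 0
  H[, nz] <- sweep(H[, nz, drop = FALSE], 2, cs[nz], "/")
  H
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(object@values), ncol(object@values), object@scaleTag))
  cat("  samples:", paste(utils::head(colnames(object@values), 5),
                          collapse = ", "),
      if (ncol(object@values) > 5) "..." else "", "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes): %s%s\n", object@name,
              length(object@genes),
              paste(utils::head(object@genes, 5), collapse = ", "),
              if (length(object@genes) > 5) ", ..." else ""))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection of %d sets\n", length(object@sets)))
  for (s in utils::head(object@sets, 10))
    cat(sprintf("  %s (%d genes)\n", s@name, length(s@genes)))
  if (length(object@sets) > 10) cat("  ...\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d sets x %d samples (w = %g)\n",
              nrow(object@scores), ncol(object@scores),
              object@weightExponent))
})

setMethod("show", "NMFModel", function(object) {
  cat(sprintf(
    "NMFModel: rank %d, %d genes x %d samples, final error %.6g (%d iterations)\n",
    object@rank, nrow(object@W), ncol(object@H),
    utils::tail(object@objectiveTrace, 1), length(object@objectiveTrace)))
})

setMethod("show", "OncoGPSMap", function(object) {
  cat(sprintf(
    "OncoGPSMap: %d nodes, %d states, %d module genes, %d reference samples\n",
    object@model@rank, object@nStates, length(object@module@genes),
    ncol(object@model@H)))
})
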