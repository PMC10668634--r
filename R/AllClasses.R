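#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Gene-by-sample expression matrix
#'
#' Container for a validated gene x sample expression matrix. Gene and
#' sample identifiers are the dimnames of the \code{values} slot and are
#' treated as opaque, case-sensitive strings. The \code{scaleTag}
#' records whether values are raw (nonnegative, e.g. TPM/counts) or
#' log2-scale (any real); the pipeline never interprets the unit beyond
#' that distinction.
#'
#' @slot values numeric matrix, genes in rows, samples in columns, with
#'   complete unique dimnames and no missing values.
#' @slot scaleTag either \code{"raw"} or \code{"log2"}. Raw-scale values
#'   must be nonnegative.
#'
#' @seealso [ExpressionMatrix()] for the validating constructor,
#'   [readExpression()] / [writeExpression()] for TSV/GCT I/O.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  }
  if (ncol(v) < 1L) msg <- c(msg, "at least one sample required")
  if (nrow(v) < 1L) msg <- c(msg, "at least one gene required")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("raw", "log2"))
    msg <- c(msg, "scaleTag must be one of 'raw', 'log2'")
  else if (object@scaleTag == "raw" && !anyNA(v) && any(v < 0))
    msg <- c(msg, "raw-scale values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param scaleTag \code{"log2"} (default) or \code{"raw"}.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "raw")
#' @export
ExpressionMatrix <- function(values, scaleTag = c("log2", "raw")) {
  scaleTag <- match.arg(scaleTag)
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, scaleTag = scaleTag)
}

#' Named gene set
#'
#' A named, described, non-empty list of unique gene identifiers (GMT
#' semantics).
#'
#' @slot name single string, unique within a collection.
#' @slot description free-text single string (may be empty).
#' @slot genes character vector of unique gene ids, length >= 1.
#' @export
setClass("GeneSet",
  representation(name = "character", description = "character",
                 genes = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@description) != 1L)
    msg <- c(msg, "description must be a single string")
  if (length(object@genes) < 1L) msg <- c(msg, "gene list must be non-empty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in set")
  if (anyNA(object@genes)) msg <- c(msg, "NA gene ids not allowed")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,description,genes see slots.
#' @return A validated [GeneSet-class].
#' @export
GeneSet <- function(name, genes, description = "") {
  new("GeneSet", name = as.character(name),
      description = as.character(description),
      genes = as.character(genes))
}

#' Ordered collection of uniquely named gene sets
#'
#' @slot sets list of [GeneSet-class] objects with unique names.
#' @seealso [readGmt()], [writeGmt()]
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (!all(vapply(object@sets, is, logical(1), class2 = "GeneSet")))
    msg <- c(msg, "all elements must be GeneSet objects")
  else {
    nm <- vapply(object@sets, slot, character(1), name = "name")
    if (anyDuplicated(nm)) msg <- c(msg, "duplicate set names")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets list of [GeneSet-class] objects.
#' @return A validated [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets = list()) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  obj <- new("GeneSetCollection", sets = unname(sets))
  obj
}

#' Gene-set by sample enrichment score matrix
#'
#' Scores from single-sample gene-set enrichment ([scoreCollection()]).
#'
#' @slot scores numeric matrix, gene sets in rows, samples in columns.
#' @slot weightExponent nonnegative weight exponent used in the running
#'   ECDF difference.
#' @export
setClass("EnrichmentMatrix",
  representation(scores = "matrix", weightExponent = "numeric"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must carry set (row) and sample (column) names")
  if (anyNA(s)) msg <- c(msg, "missing scores not allowed")
  if (length(object@weightExponent) != 1L || object@weightExponent < 0)
    msg <- c(msg, "weightExponent must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Non-negative matrix factorization model
#'
#' Result of [fitNmf()]: V ~ W H with all entries nonnegative, W columns
#' L1-normalized (scale absorbed into the rows of H) so that factors are
#' comparable expression programs. Factors are named F0..F{k-1}.
#'
#' @slot W nonnegative genes x k basis matrix (columns sum to 1).
#' @slot H nonnegative k x samples coefficient matrix.
#' @slot rank integer factorization rank k.
#' @slot seed integer seed that initialized the restarts.
#' @slot objectiveTrace Frobenius reconstruction error of the winning
#'   restart at every iteration; non-increasing.
#' @slot shift nonnegative scalar added to the input before fitting when
#'   it contained negative (log-scale) values.
#' @seealso [assignClusters()], [sampleWeights()], [projectOntoW()]
#' @export
setClass("NMFModel",
  representation(W = "matrix", H = "matrix", rank = "integer",
                 seed = "integer", objectiveTrace = "numeric",
                 shift = "numeric"))

setValidity("NMFModel", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (ncol(object@W) != object@rank || nrow(object@H) != object@rank)
    msg <- c(msg, "rank inconsistent with W/H dimensions")
  if (object@rank > min(nrow(object@W), ncol(object@H)))
    msg <- c(msg, "rank must not exceed min(genes, samples)")
  tr <- object@objectiveTrace
  if (length(tr) && any(diff(tr) > 1e-9 * pmax(tr[-length(tr)], 1)))
    msg <- c(msg, "objective trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Onco-GPS style state map
#'
#' Reference decomposition of an oncogene-module expression matrix:
#' NMF factors become map nodes laid out on the unit circle and
#' reference samples are grouped into transcriptional states by k-means
#' on their factor-weight profiles. New samples are placed on the map
#' with [projectSamples()].
#'
#' @slot module the [GeneSet-class] of module genes the map is built on.
#' @slot model the reference [NMFModel-class] (fit on module genes).
#' @slot nodeCoords k x 2 matrix of node positions on the unit circle,
#'   ordered by factor index.
#' @slot states named integer vector: reference sample -> state label.
#' @slot nStates number of states.
#' @slot pullExponent positive exponent sharpening the weighted pull of
#'   a sample toward the nodes.
#' @slot seed integer seed.
#' @export
setClass("OncoGPSMap",
  representation(module = "GeneSet", model = "NMFModel",
                 nodeCoords = "matrix", states = "integer",
                 nStates = "integer", pullExponent = "numeric",
                 seed = "integer"))

setValidity("OncoGPSMap", function(object) {
  msg <- character()
  if (nrow(object@nodeCoords) != object@model@rank ||
      ncol(object@nodeCoords) != 2L)
    msg <- c(msg, "nodeCoords must be a rank x 2 matrix")
  if (anyDuplicated(object@nodeCoords, MARGIN = 1))
    msg <- c(msg, "node coordinates must be distinct")
  if (length(object@states) != ncol(object@model@H))
    msg <- c(msg, "every reference sample must carry a state label")
  if (length(object@pullExponent) != 1L || object@pullExponent <= 0)
    msg <- c(msg, "pullExponent must be a single positive number")
  if (length(msg)) msg else TRUE
})
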