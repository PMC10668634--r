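#' Derive a cell-type signature from a reference panel
#'
#' One-vs-rest differential expression of \code{cellType} against all
#' other samples of the panel pooled, genes ranked by signal-to-noise
#' ratio; the top \code{nTop} genes become the signature. Direction
#' \code{"up"} (default) ranks by SNR descending (upregulated marker
#' genes); \code{"abs"} ranks by |SNR|. Ties are broken by gene id
#' (lexicographic), so derivation is deterministic and invariant to
#' sample column order.
#'
#' @param panel log-scale [ExpressionMatrix-class].
#' @param ann annotation data.frame for the panel.
#' @param cellType group label to derive the signature for.
#' @param nTop signature size (default 100).
#' @param panelName prefix for the signature name
#'   ("<panelName>_<cellType>"); default "panel".
#' @param direction \code{"up"} or \code{"abs"}.
#' @return A [GeneSet-class] of exactly \code{nTop} genes.
#' @export
deriveSignature <- function(panel, ann, cellType, nTop = 100L,
                            panelName = "panel",
                            direction = c("up", "abs")) {
  direction <- match.arg(direction)
  ann <- validateAnnotation(ann, panel)
  if (!cellType %in% ann$group)
    stop("unknown cell type: '", cellType, "'", call. = FALSE)
  stopIfNot(nTop >= 1L && nTop <= nrow(exprValues(panel)),
            "nTop must lie in [1, number of genes]")
  ann2 <- ann
  ann2$group <- ifelse(ann2$group == cellType, cellType, ".rest")
  de <- differentialExpression(panel, ann2, cellType, ".rest")
  key <- if (direction == "up") de$snr else abs(de$snr)
  ord <- order(-key, de$gene_id)
  GeneSet(paste0(panelName, "_", cellType),
          de$gene_id[ord[seq_len(nTop)]],
          sprintf("top %d %s-SNR genes, %s vs rest", nTop, direction,
                  cellType))
}

#' Derive signatures for every (panel, cell type) pair
#'
#' @param panels named list of panels, each a list with \code{matrix}
#'   and \code{annotation} (as returned by
#'   [simulateReferencePanels()]).
#' @param nTop signature size per cell type, default 100.
#' @param direction passed to [deriveSignature()].
#' @return A [GeneSetCollection-class] with one set per (panel, cell
#'   type) pair, uniquely named "<panel>_<cellType>".
#' @export
deriveAll <- function(panels, nTop = 100L, direction = c("up", "abs")) {
  direction <- match.arg(direction)
  stopIfNot(length(panels) >= 1L && !is.null(names(panels)),
            "panels must be a non-empty named list")
  sets <- list()
  for (pn in names(panels)) {
    p <- panels[[pn]]
    for (ty in unique(p$annotation$group))
      sets <- c(sets, deriveSignature(p$matrix, p$annotation, ty, nTop,
                                      panelName = pn,
                                      direction = direction))
  }
  GeneSetCollection(sets)
}
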