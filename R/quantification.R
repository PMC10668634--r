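#' Relative quantification by the delta-delta-CT method
#'
#' Replicate CT values are averaged per (condition, gene) first; then
#' \eqn{dCT = CT_{target} - CT_{housekeeping}} within each condition,
#' \eqn{\Delta\Delta CT = dCT_{treated} - dCT_{control}}, and the fold
#' change is \eqn{2^{-\Delta\Delta CT}}.
#'
#' @param table CT data.frame with columns \code{sample_id},
#'   \code{condition} (control/treated), \code{gene_id}, \code{ct}.
#' @param targetGene gene to quantify (or a vector of genes).
#' @param housekeepingGene normalizer, default "GAPDH".
#' @return named numeric vector of fold changes (one per target gene).
#' @export
foldChange <- function(table, targetGene, housekeepingGene = "GAPDH") {
  validateCtTable(table)
  meanCt <- function(gene, cond) {
    v <- table$ct[table$gene_id == gene & table$condition == cond]
    if (!length(v))
      stop("no CT rows for gene '", gene, "' in condition '", cond,
           "'", call. = FALSE)
    mean(v)
  }
  for (cond in c("control", "treated"))
    if (!any(table$gene_id == housekeepingGene &
               table$condition == cond))
      stop("missing housekeeping rows ('", housekeepingGene,
           "') in condition '", cond, "'", call. = FALSE)
  vapply(targetGene, function(g) {
    dCt <- vapply(c("control", "treated"), function(cond)
      meanCt(g, cond) - meanCt(housekeepingGene, cond), numeric(1))
    2^-(dCt[["treated"]] - dCt[["control"]])
  }, numeric(1))
}

validateCtTable <- function(table) {
  stopIfNot(is.data.frame(table) &&
              all(c("sample_id", "condition", "gene_id", "ct") %in%
                    names(table)),
            "CT table needs sample_id, condition, gene_id, ct columns")
  stopIfNot(all(table$condition %in% c("control", "treated")),
            "condition must be 'control' or 'treated'")
  stopIfNot(all(is.finite(table$ct)) && all(table$ct > 0) &&
              all(table$ct < 45),
            "CT values must lie in (0, 45)")
  invisible(table)
}

#' Gate specification for marker-threshold population calling
#'
#' Thresholds (one per marker, log10 intensity) and a rule table
#' mapping every +/- sign pattern over the markers to a population
#' label. The rules must cover all 2^m patterns exactly once
#' (a partition of the sign-pattern space); several patterns may map
#' to the same label.
#'
#' @param thresholds named numeric: marker -> gate threshold.
#' @param rules named character: pattern -> label, where a pattern is
#'   the marker names joined with their sign, e.g. "PDPN+TdTm-".
#'   Patterns must list the markers in the order of \code{thresholds}.
#' @return a validated gate-spec list (class \code{gateSpec}).
#' @examples
#' gateSpec(c(PDPN = 2.5, TdTm = 2.5),
#'          c("PDPN+TdTm-" = "typeI", "PDPN-TdTm+" = "typeII",
#'            "PDPN+TdTm+" = "dualpos", "PDPN-TdTm-" = "negative"))
#' @export
gateSpec <- function(thresholds, rules) {
  stopIfNot(!is.null(names(thresholds)) && all(is.finite(thresholds)),
            "thresholds must be named and finite")
  markers <- names(thresholds)
  signs <- expand.grid(rep(list(c("+", "-")), length(markers)),
                       stringsAsFactors = FALSE)
  expected <- apply(signs, 1, function(s)
    paste0(markers, s, collapse = ""))
  stopIfNot(setequal(names(rules), expected) &&
              !anyDuplicated(names(rules)),
            "rules must partition the sign-pattern space; expected ",
            "patterns: ", paste(expected, collapse = ", "))
  structure(list(thresholds = thresholds, rules = rules),
            class = "gateSpec")
}

#' Default two-marker epithelial gate
#'
#' Midpoint thresholds between the negative (0.5) and positive (4.5)
#' marker levels of [epithelialPopulationSpec()]; double-negative
#' events are labeled "negative".
#'
#' @return a \code{gateSpec}.
#' @export
epithelialGate <- function() {
  gateSpec(c(PDPN = 2.5, TdTm = 2.5),
           c("PDPN+TdTm-" = "typeI", "PDPN-TdTm+" = "typeII",
             "PDPN+TdTm+" = "dualpos", "PDPN-TdTm-" = "negative"))
}

#' Gate cells into populations by marker thresholds
#'
#' Each cell is assigned the label of its sign pattern (marker value
#' above threshold = "+"). Counts are conserved and percentages sum to
#' 100 exactly.
#'
#' @param cells data.frame with one column per gate marker (e.g. from
#'   [simulateCells()]).
#' @param gates a \code{gateSpec} from [gateSpec()].
#' @return data.frame: \code{population}, \code{count},
#'   \code{percent}, one row per label occurring in the rules (in rule
#'   order), including zero-count populations.
#' @export
gateCells <- function(cells, gates) {
  stopIfNot(inherits(gates, "gateSpec"), "gates must be a gateSpec")
  stopIfNot(is.data.frame(cells) && nrow(cells) >= 1L,
            "empty cell table")
  markers <- names(gates$thresholds)
  missing <- setdiff(markers, names(cells))
  if (length(missing))
    stop("marker(s) absent from cell table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  signs <- vapply(markers, function(mk)
    ifelse(cells[[mk]] > gates$thresholds[[mk]], "+", "-"),
    character(nrow(cells)))
  if (nrow(cells) == 1L) signs <- matrix(signs, nrow = 1)
  pattern <- apply(signs, 1, function(s) paste0(markers, s, collapse = ""))
  label <- gates$rules[pattern]
  labels <- unique(unname(gates$rules))
  count <- vapply(labels, function(l) sum(label == l), integer(1))
  data.frame(population = labels, count = count,
             percent = 100 * count / nrow(cells),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two binomial fractions (odds ratio + Fisher exact test)
#'
#' Builds the 2x2 table of successes/failures, reports the
#' Haldane-corrected odds ratio
#' \eqn{(a+\tfrac12)(d+\tfrac12)/[(b+\tfrac12)(c+\tfrac12)]} and the
#' two-sided Fisher exact p-value.
#'
#' @param a,b each a length-2 vector \code{c(count, total)}.
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @examples
#' compareFractions(c(7, 10), c(2, 10))
#' @export
compareFractions <- function(a, b) {
  for (v in list(a, b)) {
    stopIfNot(length(v) == 2L && all(v >= 0) && v[2] >= 1L,
              "each argument must be c(count, total) with total >= 1")
    stopIfNot(v[1] <= v[2], "count exceeds total")
  }
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), 2, 2,
                byrow = TRUE)
  orH <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
    ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = orH, p_value = min(p, 1))
}
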