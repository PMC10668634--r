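#' Two-group differential expression on a log-scale matrix
#'
#' Per-gene two-sided t-test between two annotated sample groups, with
#' Benjamini-Hochberg FDR across all genes and a variance-floored
#' signal-to-noise ratio \eqn{(\mu_A-\mu_B)/(s_A+s_B)} where each
#' group sd is floored at \code{max(0.2 |mean|, 0.2)} (the
#' long-standing GSEA convention, which keeps the statistic stable at
#' n = 3 per group). The default is the classical pooled-variance
#' Student test: at three samples per group it holds its nominal size,
#' where the Welch correction (available via \code{test = "welch"})
#' becomes noticeably conservative.
#'
#' @param m log-scale [ExpressionMatrix-class].
#' @param ann annotation data.frame (\code{sample_id}, \code{group}).
#' @param groupA,groupB group labels to contrast (A minus B).
#' @param test \code{"student"} (pooled variance, default) or
#'   \code{"welch"} (unequal variance).
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{log2_fc}, \code{t_stat}, \code{p_value}, \code{fdr_bh},
#'   \code{snr}, in input gene order.
#' @export
differentialExpression <- function(m, ann, groupA, groupB,
                                   test = c("student", "welch")) {
  test <- match.arg(test)
  stopifnot(is(m, "ExpressionMatrix"))
  ann <- validateAnnotation(ann, m)
  for (g in c(groupA, groupB))
    if (!g %in% ann$group)
      stop("unknown group label: '", g, "'", call. = FALSE)
  sa <- ann$sample_id[ann$group == groupA]
  sb <- ann$sample_id[ann$group == groupB]
  stopIfNot(length(sa) >= 2L && length(sb) >= 2L,
            "each group needs at least 2 samples")
  A <- exprValues(m)[, sa, drop = FALSE]
  B <- exprValues(m)[, sb, drop = FALSE]
  tt <- tTestRows(A, B, pooled = (test == "student"))
  snr <- snrRows(A, B)
  data.frame(gene_id = geneIds(m),
             log2_fc = tt$diff,
             t_stat = tt$t,
             p_value = tt$p,
             fdr_bh = benjaminiHochberg(tt$p),
             snr = snr,
             stringsAsFactors = FALSE)
}

# Vectorized two-sample t-test over matrix rows (two-sided): pooled
# variance (Student) or Welch-Satterthwaite.
tTestRows <- function(A, B, pooled = TRUE) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  if (pooled) {
    vp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- vp * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- ifelse(se2 > 0,
                 se2^2 / ((va / na)^2 / (na - 1) +
                            (vb / nb)^2 / (nb - 1)),
                 na + nb - 2)
  }
  diff <- ma - mb
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), 0)
  p[t == 0 & se2 == 0] <- 1
  list(diff = diff, t = t, p = pmin(p, 1), df = df)
}

# Variance-floored signal-to-noise ratio over matrix rows.
snrRows <- function(A, B) {
  ma <- rowMeans(A); mb <- rowMeans(B)
  sa <- apply(A, 1, stats::sd); sb <- apply(B, 1, stats::sd)
  sa <- pmax(sa, 0.2 * abs(ma), 0.2)
  sb <- pmax(sb, 0.2 * abs(mb), 0.2)
  (ma - mb) / (sa + sb)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validating wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order, clipped to [0, 1].
#' @export
benjaminiHochberg <- function(pValues) {
  stopIfNot(length(pValues) >= 1L, "empty p-value list")
  stopIfNot(all(is.finite(pValues)) &&
              all(pValues >= 0) && all(pValues <= 1),
            "p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}
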