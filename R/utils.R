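# Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are pure in (params, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One global seed propagates to per-operation child seeds by fixed
# offsets, kept inside 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Consistent numeric formatting for all TSV output: 9 significant digits.
formatNum <- function(x) {
  out <- sprintf("%.9g", x)
  out[x == round(x) & abs(x) < 1e15] <-
    sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

writeTsvMatrix <- function(values, path, idColumn = "gene_id") {
  lines <- c(paste(c(idColumn, colnames(values)), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i], formatNum(values[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
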