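#' Read a gene-by-sample expression matrix (TSV or GCT 1.2)
#'
#' Plain TSV (header row of sample ids, first column of gene ids) is the
#' default dialect; files whose first line is \code{#1.2} are parsed as
#' GCT version 1.2 (the declared dimensions must match the body).
#' Duplicate gene rows are collapsed by taking the per-sample maximum
#' (the GSEA convention) with a warning; duplicate sample columns are an
#' error. Sample order on disk is preserved exactly.
#'
#' @param path file to read.
#' @param scaleTag declared scale of the values, \code{"log2"} (default)
#'   or \code{"raw"}; raw-scale files must be nonnegative.
#' @return An [ExpressionMatrix-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, scaleTag = c("log2", "raw")) {
  scaleTag <- match.arg(scaleTag)
  stopIfNot(file.exists(path), "file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    vals <- readGctBody(path)
  } else if (startsWith(first, "#")) {
    stop("unsupported GCT version line: ", first, call. = FALSE)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("malformed header: need a gene-id column plus >= 1 sample",
           call. = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric expression values in ", path, call. = FALSE)
    rownames(vals) <- as.character(df[[1]])
  }
  vals <- collapseDuplicateGenes(vals)
  if (scaleTag == "raw" && any(vals < 0))
    stop("negative value encountered in a raw-scale matrix", call. = FALSE)
  ExpressionMatrix(vals, scaleTag)
}

readGctBody <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file", call. = FALSE)
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2L) stop("malformed GCT dimension line", call. = FALSE)
  ng <- as.integer(dims[1]); ns <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "Name")
    stop("malformed GCT header row", call. = FALSE)
  samples <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng || length(samples) != ns)
    stop(sprintf(
      "GCT declared dimensions (%d x %d) do not match body (%d x %d)",
      ng, ns, length(body), length(samples)), call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(parts) != ns + 2L
  if (any(bad))
    stop("GCT data row with wrong field count (line ",
         which(bad)[1] + 3L, ")", call. = FALSE)
  vals <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(ns)))
  if (ns == 1L) vals <- matrix(vals, ncol = 1L)
  rownames(vals) <- vapply(parts, `[`, character(1), 1L)
  colnames(vals) <- samples
  vals
}

collapseDuplicateGenes <- function(vals) {
  ids <- rownames(vals)
  if (!anyDuplicated(ids)) return(vals)
  dup <- unique(ids[duplicated(ids)])
  warning(length(dup), " duplicated gene id(s) collapsed by maximum: ",
          paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  keep <- unique(ids)
  out <- matrix(NA_real_, length(keep), ncol(vals),
                dimnames = list(keep, colnames(vals)))
  for (g in keep) {
    rows <- vals[ids == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2, max)
  }
  out
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' Values are written with 9 significant digits, so a write/read
#' round-trip reproduces the matrix to better than 1e-9 relative
#' tolerance.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path destination file.
#' @param format \code{"tsv"} (default) or \code{"gct"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path, format = c("tsv", "gct")) {
  stopifnot(is(m, "ExpressionMatrix"))
  validObject(m)
  format <- match.arg(format)
  v <- m@values
  if (format == "tsv") return(writeTsvMatrix(v, path))
  lines <- c("#1.2",
             paste(nrow(v), ncol(v), sep = "\t"),
             paste(c("Name", "Description", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], "na", formatNum(v[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, tab-separated fields
#' \code{name, description, gene, gene, ...}. Lines with fewer than
#' three fields are rejected; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    GeneSet(f[1], f[-(1:2)], description = f[2])
  })
  GeneSetCollection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param x a [GeneSetCollection-class].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  validObject(x)
  lines <- vapply(x@sets, function(s) {
    d <- if (nzchar(s@description)) s@description else "na"
    paste(c(s@name, d, s@genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' TSV with columns \code{sample_id}, \code{group} and any number of
#' additional covariate columns.
#'
#' @param path TSV file.
#' @param matrix optional [ExpressionMatrix-class]; if given, every
#'   annotated sample must be present in it.
#' @return data.frame with character \code{sample_id} and \code{group}.
#' @export
readSampleAnnotation <- function(path, matrix = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validateAnnotation(df, matrix)
}

#' @rdname readSampleAnnotation
#' @param ann annotation data.frame.
#' @export
writeSampleAnnotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validateAnnotation <- function(ann, matrix = NULL) {
  stopIfNot(is.data.frame(ann) &&
              all(c("sample_id", "group") %in% names(ann)),
            "annotation needs 'sample_id' and 'group' columns")
  ann$sample_id <- as.character(ann$sample_id)
  ann$group <- as.character(ann$group)
  stopIfNot(!anyDuplicated(ann$sample_id), "duplicate sample_id in annotation")
  if (!is.null(matrix)) {
    missing <- setdiff(ann$sample_id, sampleIds(matrix))
    stopIfNot(length(missing) == 0L,
              "annotated samples absent from matrix: ",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  ann
}
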