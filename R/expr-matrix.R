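#' Expression matrix container
#'
#' A thin S3 wrapper around a dense numeric matrix (genes in rows,
#' observations -- cells or bulk samples -- in columns) carrying a declared
#' `layer`: `"counts"` (non-negative integers) or `"lognorm"`
#' (log-normalized continuous values, with the log base recorded in the
#' `logbase` attribute).
#'
#' @param values Numeric matrix, genes x observations, with unique non-empty
#'   rownames (gene ids) and colnames (observation ids).
#' @param layer `"counts"` or `"lognorm"`.
#' @param logbase Base of the logarithm for `lognorm` layers (default natural).
#' @return An object of class `expr_matrix` (a matrix with attributes).
#' @export
#' @examples
#' m <- matrix(rpois(6, 2), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' em <- expression_matrix(m, "counts")
#' expr_layer(em)
expression_matrix <- function(values, layer = c("counts", "lognorm"),
                              logbase = exp(1)) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x observations)")
  }
  gn <- rownames(values)
  on <- colnames(values)
  if (is.null(gn) || is.null(on) || any(gn == "") || any(on == "")) {
    stop("`values` must have non-empty rownames (genes) and colnames (observations)")
  }
  if (anyDuplicated(gn)) stop("duplicate gene ids: ", gn[duplicated(gn)][1L])
  if (anyDuplicated(on)) stop("duplicate observation ids: ", on[duplicated(on)][1L])
  if (layer == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts layer must contain non-negative integers")
    }
  }
  structure(values, layer = layer,
            logbase = if (layer == "lognorm") logbase else NULL,
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
expr_layer <- function(x) attr(x, "layer") %||% "lognorm"

expr_logbase <- function(x) attr(x, "logbase") %||% exp(1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d observations, layer=%s\n",
              nrow(x), ncol(x), expr_layer(x)))
  invisible(x)
}

as_plain_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Read an expression matrix from disk
#'
#' Supports a dense TSV (first column gene ids, header line of observation
#' ids) and MatrixMarket triplet format with `<path>.rownames` /
#' `<path>.colnames` sidecar files (one id per line).
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @param layer Declared layer of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            layer = c("lognorm", "counts")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("TSV must have a header and at least one gene row")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    obs <- header[-1L]
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nf <- lengths(body)
    if (any(nf != length(header))) {
      stop("ragged row at line ", which(nf != length(header))[1L] + 1L)
    }
    genes <- vapply(body, `[[`, "", 1L)
    vals <- suppressWarnings(
      vapply(body, function(r) as.numeric(r[-1L]), numeric(length(obs))))
    vals <- if (length(obs) == 1L) matrix(vals, nrow = 1L) else t(vals)
    if (anyNA(vals)) {
      bad <- which(apply(is.na(vals), 1L, any))[1L]
      stop("non-numeric cell at line ", bad + 1L)
    }
    dimnames(vals) <- list(genes, obs)
  } else {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".rownames"))
    obs <- readLines(paste0(path, ".colnames"))
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, obs)
  }
  expression_matrix(vals, layer)
}

#' Write an expression matrix to disk
#'
#' @inheritParams read_expression
#' @param x An `expr_matrix`.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    header <- paste(c("gene", colnames(x)), collapse = "\t")
    rows <- paste(rownames(x),
                  apply(as_plain_matrix(x), 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(header, rows), path)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(as_plain_matrix(x), sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(x), paste0(path, ".rownames"))
    writeLines(colnames(x), paste0(path, ".colnames"))
  }
  invisible(path)
}
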