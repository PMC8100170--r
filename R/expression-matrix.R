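#' Construct an expression matrix
#'
#' A thin S3 container for a gene-by-sample matrix of non-negative
#' expression values, tagged with its unit. FPKM matrices may hold any
#' non-negative reals; count matrices must be non-negative integers.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids
#'   as colnames.
#' @param unit Either `"FPKM"` or `"counts"`.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `unit` attribute).
#' @export
expression_matrix <- function(values, unit = c("FPKM", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id: ", dup[1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  if (unit == "counts") {
    off <- which(values != round(values), arr.ind = TRUE)
    if (nrow(off))
      stop(sprintf("non-integer count at gene '%s', sample '%s'",
                   rownames(values)[off[1L, 1L]], colnames(values)[off[1L, 2L]]))
  }
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

#' Unit of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"FPKM"` or `"counts"`.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are samples. Validation
#' rejects duplicate gene ids, negative values, and (for counts)
#' non-integer values, naming the offending cell.
#'
#' @param path Path to the TSV file.
#' @param unit Declared unit of the values, `"FPKM"` or `"counts"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("FPKM", "counts")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression matrix needs a gene_id column plus at least one sample")
  gene_ids <- df[[1L]]
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df),
                                       dimnames = list(NULL, names(df)[-1L]))
  if (anyNA(vals)) stop("non-numeric expression value in ", path)
  rownames(vals) <- gene_ids
  m <- expression_matrix(vals, unit)
  message(sprintf("read %d genes x %d samples [%s] from %s",
                  nrow(m), ncol(m), unit, path))
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: tab separators, `.` decimal,
#' first header cell `gene_id`, full precision.
#'
#' @param x An `expr_matrix` (or gene-by-sample numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x),
                   format(unclass(x)[, , drop = FALSE], digits = 17,
                          trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
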