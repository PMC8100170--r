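#' Per-tissue median log2 expression
#'
#' Collapses an FPKM matrix to one median log2(FPKM + pseudocount) value
#' per gene and tissue. A pooled pseudo-tissue (e.g. "osteocyte" spanning
#' tibia, femur and humerus samples) is simply a tissue group listing all
#' its samples.
#'
#' @param mat An `expr_matrix` with unit FPKM.
#' @param tissue_groups Named list mapping tissue name to sample ids.
#' @param pseudocount Added inside the log (default 1).
#' @return Gene-by-tissue numeric matrix of median log2 expression.
#' @export
tissue_medians <- function(mat, tissue_groups, pseudocount = 1) {
  if (expr_unit(mat) != "FPKM") stop("tissue medians require FPKM values")
  med <- vapply(names(tissue_groups), function(t) {
    ids <- tissue_groups[[t]]
    if (!length(ids)) stop("tissue with no samples: ", t)
    miss <- setdiff(ids, colnames(mat))
    if (length(miss)) stop(sprintf("tissue '%s': unknown sample '%s'",
                                   t, miss[1L]))
    apply(log2(unclass(mat)[, ids, drop = FALSE] + pseudocount), 1L,
          stats::median)
  }, numeric(nrow(mat)))
  rownames(med) <- rownames(mat)
  med
}

#' Quantile-normalise a gene-by-tissue matrix
#'
#' Forces every column onto a common reference distribution (the
#' row-wise mean of the sorted columns); ties within a column receive
#' the mean of the reference values they span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric gene-by-tissue matrix.
#' @return Matrix of the same shape with identical per-column sorted
#'   value multisets.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (ncol(m) < 2L) {
    warning("single column: quantile normalisation is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Tau tissue-specificity index
#'
#' For each gene, expression values across `N_t` tissues are floored at
#' zero, scaled by the per-gene maximum (`x_hat_i = x_i / max_j x_j`) and
#' combined as `tau = sum_i (1 - x_hat_i) / (N_t - 1)`. Tau is 0 for
#' perfectly uniform expression, 1 for single-tissue expression, and
#' undefined for genes with no positive value in any tissue. Genes are
#' binned as low (`tau < 0.15`), moderate (`0.15 <= tau <= 0.85`) or
#' high (`tau > 0.85`) specificity.
#'
#' @param normalized Gene-by-tissue matrix (typically quantile-normalised
#'   median log2 expression).
#' @return A data.frame with columns `gene_id`, `tau`, `spec_class`.
#' @export
compute_tau <- function(normalized) {
  if (!is.matrix(normalized)) normalized <- as.matrix(normalized)
  nt <- ncol(normalized)
  if (nt < 2L) stop("Tau requires at least 2 tissues")
  x <- pmax(unclass(normalized), 0)
  mx <- apply(x, 1L, max)
  tau <- rep(NA_real_, nrow(x))
  pos <- mx > 0
  tau[pos] <- rowSums(1 - x[pos, , drop = FALSE] / mx[pos]) / (nt - 1)
  spec_class <- rep("undefined", length(tau))
  spec_class[!is.na(tau) & tau < 0.15] <- "low"
  spec_class[!is.na(tau) & tau >= 0.15 & tau <= 0.85] <- "moderate"
  spec_class[!is.na(tau) & tau > 0.85] <- "high"
  ids <- rownames(normalized)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(normalized)))
  data.frame(gene_id = ids, tau = tau,
             spec_class = spec_class, stringsAsFactors = FALSE)
}
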