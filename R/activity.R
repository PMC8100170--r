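#' Fit a per-sample active-expression model
#'
#' Bulk RNA-seq log2-FPKM values are bimodal: a near-zero mass of
#' untranscribed genes and a roughly Gaussian active component. The model
#' places the active-component mean `mu` at the maximum of a Gaussian
#' kernel density estimate of log2(FPKM) over strictly positive values
#' (Scott's bandwidth `sd(x) * n^(-1/5)`, 4096-point regular grid spanning
#' the data range +/- 3 bandwidths, first grid maximum on ties), and
#' estimates the spread as the half-normal standard deviation
#' `sqrt(mean((x - mu)^2))` over values above `mu`. A gene is actively
#' expressed when its zFPKM `(log2(FPKM) - mu)/sd` exceeds `z_cutoff`;
#' the equivalent FPKM threshold `2^(mu + z_cutoff * sd)` is stored so
#' both scales can be used interchangeably.
#'
#' @param fpkm Non-negative FPKM values for one sample.
#' @param z_cutoff Activity cutoff on the zFPKM scale (default -2.6).
#' @param min_positive Minimum number of strictly positive values
#'   required to fit (default 50).
#' @param grid_n Number of KDE grid points (default 4096).
#' @param sample_id Optional sample label carried in the result.
#' @return An object of class `activity_model`: list with `sample_id`,
#'   `mu`, `sd`, `z_cutoff`, `fpkm_threshold`, `n_positive`, `bandwidth`.
#' @export
fit_activity_model <- function(fpkm, z_cutoff = -2.6, min_positive = 50,
                               grid_n = 4096, sample_id = NA_character_) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  x <- log2(fpkm[fpkm > 0])
  n <- length(x)
  if (n < min_positive)
    stop(sprintf("only %d positive values (< %d required)", n, min_positive))
  sx <- stats::sd(x)
  if (sx == 0)
    stop("degenerate density: all positive values identical")
  bw <- sx * n^(-1 / 5)
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = grid_n,
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  mu <- d$x[which.max(d$y)]
  above <- x[x > mu]
  if (!length(above))
    stop("degenerate density: no values above the fitted peak")
  sd_half <- sqrt(mean((above - mu)^2))
  structure(list(sample_id = sample_id, mu = mu, sd = sd_half,
                 z_cutoff = z_cutoff,
                 fpkm_threshold = 2^(mu + z_cutoff * sd_half),
                 n_positive = n, bandwidth = bw),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf(
    "activity_model [%s]: mu=%.3f sd=%.3f z_cutoff=%.2f FPKM threshold=%.4g\n",
    x$sample_id, x$mu, x$sd, x$z_cutoff, x$fpkm_threshold))
  invisible(x)
}

#' Fit activity models for every sample of an FPKM matrix
#'
#' @param mat An `expr_matrix` with unit FPKM.
#' @param ... Passed on to [fit_activity_model()].
#' @return Named list of `activity_model`, one per sample.
#' @export
fit_activity_models <- function(mat, ...) {
  if (expr_unit(mat) != "FPKM") stop("activity models require FPKM values")
  stats::setNames(
    lapply(colnames(mat), function(s)
      fit_activity_model(mat[, s], sample_id = s, ...)),
    colnames(mat))
}

#' Transform an FPKM matrix to zFPKM
#'
#' `z = (log2(fpkm) - mu)/sd` per sample; zero FPKM maps to `-Inf`, which
#' lies below any finite cutoff and so always yields an inactive call.
#'
#' @param mat An `expr_matrix` with unit FPKM.
#' @param models Named list of [fit_activity_model()] results, one per
#'   sample of `mat`.
#' @return Numeric gene-by-sample matrix of zFPKM values.
#' @export
zfpkm_transform <- function(mat, models) {
  if (expr_unit(mat) != "FPKM") stop("zFPKM requires FPKM values")
  miss <- setdiff(colnames(mat), names(models))
  if (length(miss)) stop("no activity model for sample: ", miss[1L])
  z <- vapply(colnames(mat), function(s) {
    m <- models[[s]]
    ifelse(mat[, s] > 0, (log2(mat[, s]) - m$mu) / m$sd, -Inf)
  }, numeric(nrow(mat)))
  rownames(z) <- rownames(mat)
  z
}

#' Replicate-level active / inactive / variable calls
#'
#' Within each sample group a gene is `active` when its zFPKM is strictly
#' above the cutoff in all replicates, `inactive` when at or below the
#' cutoff in all replicates, and `variable` otherwise (above in at least
#' one but not all replicates). The three classes partition the genes of
#' every group.
#'
#' @param zfpkm Gene-by-sample zFPKM matrix.
#' @param groups Named list mapping group name to replicate sample ids.
#' @param z_cutoff Activity cutoff (default -2.6); strict `>` is "above".
#' @return An `activity_calls` object: character gene-by-group matrix
#'   with levels `active`/`inactive`/`variable` and a `z_cutoff`
#'   attribute.
#' @export
call_activity <- function(zfpkm, groups, z_cutoff = -2.6) {
  if (!length(groups)) stop("no groups supplied")
  status <- vapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (!length(ids)) stop("empty group: ", g)
    miss <- setdiff(ids, colnames(zfpkm))
    if (length(miss)) stop(sprintf("group '%s': unknown sample '%s'",
                                   g, miss[1L]))
    above <- zfpkm[, ids, drop = FALSE] > z_cutoff
    n_above <- rowSums(above)
    ifelse(n_above == length(ids), "active",
           ifelse(n_above == 0L, "inactive", "variable"))
  }, character(nrow(zfpkm)))
  rownames(status) <- rownames(zfpkm)
  structure(status, z_cutoff = z_cutoff,
            class = c("activity_calls", "matrix"))
}

#' Union of active genes across sample groups
#'
#' @param calls An `activity_calls` matrix (or several column-bound).
#' @param scope Character vector of group names to take the union over.
#' @return Character vector of genes active in at least one group of
#'   `scope`.
#' @export
active_union <- function(calls, scope = colnames(calls)) {
  if (!length(scope)) stop("empty scope")
  miss <- setdiff(scope, colnames(calls))
  if (length(miss)) stop("unknown group: ", miss[1L])
  sub <- unclass(calls)[, scope, drop = FALSE]
  rownames(calls)[rowSums(sub == "active") > 0L]
}

#' Pearson correlation between samples over a gene subset
#'
#' Computes the sample-by-sample Pearson correlation restricted to a set
#' of genes (typically the actively expressed ones). A zero-variance
#' sample yields `NA` correlations rather than an error; the diagonal is
#' fixed at 1. When `groups` is given, the mean of the between-sample
#' entries for each pair of groups is also returned.
#'
#' @param mat Gene-by-sample numeric matrix (e.g. an `expr_matrix`).
#' @param gene_subset Character vector of gene ids (>= 3).
#' @param groups Optional named list mapping group name to sample ids.
#' @return List with `r` (correlation matrix) and `group_means` (group
#'   pair matrix of mean correlations, or `NULL`). Within-group means
#'   exclude the self-correlation diagonal.
#' @export
sample_correlation <- function(mat, gene_subset, groups = NULL) {
  gene_subset <- intersect(gene_subset, rownames(mat))
  if (length(gene_subset) < 3L)
    stop("need at least 3 genes present in the matrix")
  sub <- unclass(mat)[gene_subset, , drop = FALSE]
  r <- suppressWarnings(stats::cor(sub, method = "pearson"))
  diag(r) <- 1
  group_means <- NULL
  if (!is.null(groups)) {
    gn <- names(groups)
    group_means <- matrix(NA_real_, length(gn), length(gn),
                          dimnames = list(gn, gn))
    for (a in gn) for (b in gn) {
      block <- r[groups[[a]], groups[[b]], drop = FALSE]
      if (a == b) {
        vals <- block[lower.tri(block)]
        group_means[a, b] <- if (length(vals)) mean(vals) else NA_real_
      } else {
        group_means[a, b] <- mean(block)
      }
    }
  }
  list(r = r, group_means = group_means)
}
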