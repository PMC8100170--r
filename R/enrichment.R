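#' Library-size normalisation of a count matrix
#'
#' Scales every sample (column) by `mean(library sizes) / library size`
#' so that all column totals equal the mean library size. This is the
#' only normalisation applied before computing per-gene fold-changes
#' between paired conditions.
#'
#' @param counts An `expr_matrix` with unit counts.
#' @return Numeric gene-by-sample matrix of normalised counts.
#' @export
libsize_normalize <- function(counts) {
  if (expr_unit(counts) != "counts")
    stop("library-size normalisation expects a counts matrix")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero-total sample: ", colnames(counts)[totals == 0][1L])
  sweep(unclass(counts), 2L, mean(totals) / totals, `*`)
}

#' Per-gene log2 fold-changes between paired conditions
#'
#' For every animal of the enrichment cohort (one osteocyte-enriched and
#' one whole-bone sample from the same mouse), computes the per-gene
#' `LFC_a = log2((enriched_a + c) / (whole_a + c))` on library-size
#' normalised counts, plus the per-gene mean over animals.
#'
#' @param normalized Gene-by-sample matrix of normalised counts.
#' @param samples Sample table (see [read_sample_table()]); only rows
#'   with `cohort == "enrichment"` are used.
#' @param pseudocount `c` added to both numerator and denominator
#'   (default 1).
#' @return List with `lfc` (gene-by-animal matrix) and `mean_lfc`
#'   (named numeric vector).
#' @export
compute_lfc <- function(normalized, samples, pseudocount = 1) {
  s <- samples[samples$cohort == "enrichment", , drop = FALSE]
  if (!nrow(s)) stop("no enrichment-cohort samples in the sample table")
  animals <- unique(s$animal_id)
  pick <- function(a, cond) {
    id <- s$sample_id[s$animal_id == a & s$condition == cond]
    if (length(id) != 1L)
      stop(sprintf("animal '%s': expected exactly one %s sample", a, cond))
    if (!id %in% colnames(normalized))
      stop(sprintf("sample '%s' absent from the matrix", id))
    id
  }
  lfc <- vapply(animals, function(a) {
    e <- normalized[, pick(a, "osteocyte_enriched")]
    w <- normalized[, pick(a, "whole_bone")]
    log2((e + pseudocount) / (w + pseudocount))
  }, numeric(nrow(normalized)))
  rownames(lfc) <- rownames(normalized)
  colnames(lfc) <- animals
  list(lfc = lfc, mean_lfc = rowMeans(lfc))
}

# E-step log-density matrix, n x k
.gmm_logdens <- function(x, w, mu, s) {
  k <- length(w)
  ld <- matrix(0, length(x), k)
  for (j in seq_len(k))
    ld[, j] <- log(w[j]) + stats::dnorm(x, mu[j], s[j], log = TRUE)
  ld
}

.gmm_em <- function(x, w, mu, s, tol, max_iter, sd_floor) {
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- .gmm_logdens(x, w, mu, s)
    m <- do.call(pmax, as.data.frame(ld))
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(ld - lse)
    nk <- colSums(r)
    if (any(nk < 1e-10)) return(NULL)  # empty component: degenerate
    w <- nk / n
    mu <- colSums(r * x) / nk
    s_new <- sqrt(colSums(r * (outer(x, mu, `-`))^2) / nk)
    if (any(s_new < sd_floor)) return(NULL)
    s <- s_new
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = s, loglik = ll, loglik_trace = trace,
       n_iter = it)
}

#' Fit a Gaussian mixture to per-gene log fold-changes
#'
#' The log fold-change distribution between osteocyte-enriched and
#' whole-bone samples is multi-modal: most genes sit near zero, depleted
#' genes below, and a small strongly enriched component above. For each
#' candidate component count `k`, k-means clustering (10 seeded
#' restarts, best inertia) supplies initial means, standard deviations
#' and weights; expectation-maximisation with unequal per-component
#' variances then runs until the log-likelihood gain drops below `tol`
#' or `max_iter` is reached. The `k` minimising
#' `BIC = -2 loglik + (3k - 1) ln(n)` is returned, its components ranked
#' by descending mean. A component standard deviation collapsing below
#' `sd_floor` triggers a jittered re-initialisation (up to `restarts`
#' times) before erroring.
#'
#' @param lfc_values Numeric vector, one mean LFC per gene.
#' @param k_candidates Candidate component counts (default 1:6).
#' @param seed Integer seed controlling k-means initialisation.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param sd_floor Lower bound on component standard deviations
#'   (default 1e-3).
#' @param restarts Jittered re-initialisations on degeneracy (default 5).
#' @return An object of class `gmm_fit`: list with `k`, `weights`,
#'   `means`, `sds` (ranked by descending mean), `loglik`,
#'   `loglik_trace`, `bic`, `bic_by_k`, `rank_by_mean`, `posterior`
#'   (n-by-k matrix, columns in ranked order), `n`.
#' @export
fit_lfc_gmm <- function(lfc_values, k_candidates = 1:6, seed = 1,
                        tol = 1e-8, max_iter = 2000, sd_floor = 1e-3,
                        restarts = 5) {
  x <- as.numeric(lfc_values)
  n <- length(x)
  if (n < 10 * max(k_candidates))
    stop(sprintf("need >= %d values for k up to %d",
                 10 * max(k_candidates), max(k_candidates)))
  fits <- vector("list", length(k_candidates))
  bics <- stats::setNames(numeric(length(k_candidates)),
                          paste0("k", k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[[i]]
    set.seed(seed + k)
    if (k == 1L) {
      init <- list(w = 1, mu = mean(x), s = max(stats::sd(x), sd_floor))
    } else {
      km <- stats::kmeans(x, centers = k, nstart = 10)
      cs <- vapply(seq_len(k), function(j) {
        v <- x[km$cluster == j]
        if (length(v) > 1L) stats::sd(v) else sd_floor
      }, numeric(1L))
      init <- list(w = as.numeric(km$size) / n,
                   mu = as.numeric(km$centers),
                   s = pmax(cs, sd_floor))
    }
    fit <- NULL
    for (r in 0:restarts) {
      if (r > 0L) {  # jitter the initial means, widen the sds
        init$mu <- init$mu + stats::rnorm(k, 0, stats::sd(x) / 10)
        init$s <- pmax(init$s * 2, sd_floor * 10)
      }
      fit <- .gmm_em(x, init$w, init$mu, init$s, tol, max_iter, sd_floor)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop(sprintf("EM degenerate for k = %d after %d restarts", k, restarts))
    fit$k <- k
    fit$bic <- -2 * fit$loglik + (3 * k - 1) * log(n)
    bics[[i]] <- fit$bic
    fits[[i]] <- fit
  }
  best <- fits[[which.min(bics)]]
  # rank components by descending mean; ties by larger weight, lower index
  ord <- order(-best$means, -best$weights, seq_len(best$k))
  ld <- .gmm_logdens(x, best$weights, best$means, best$sds)
  m <- do.call(pmax, as.data.frame(ld))
  post <- exp(ld - (m + log(rowSums(exp(ld - m)))))
  structure(list(k = best$k,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 sds = best$sds[ord],
                 loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 bic = best$bic,
                 bic_by_k = bics,
                 rank_by_mean = ord,
                 posterior = post[, ord, drop = FALSE],
                 n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: k = %d (BIC %.1f, n = %d)\n", x$k, x$bic, x$n))
  cat("components (ranked by descending mean):\n")
  print(data.frame(weight = round(x$weights, 4),
                   mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  invisible(x)
}

#' Enrichment threshold from a mixture fit
#'
#' The threshold separating genuinely osteocyte-enriched genes from the
#' bulk of the distribution is placed two standard deviations above the
#' mean of the component with the second-highest mean LFC, excluding
#' genes likely to belong to sub-optimal components.
#'
#' @param fit A `gmm_fit` with at least 2 components.
#' @return The threshold, in LFC units.
#' @export
enrichment_threshold <- function(fit) {
  if (fit$k < 2L) stop("enrichment threshold requires k >= 2 components")
  fit$means[2L] + 2 * fit$sds[2L]
}

#' Call osteocyte-enriched genes from per-animal fold-changes
#'
#' For each gene a `conf`-level confidence interval of the mean LFC is
#' computed over per-animal values (t interval,
#' `mean +/- t_{(1+conf)/2, n-1} * sd/sqrt(n)`). A gene is enriched when
#' the lower confidence bound lies strictly above the threshold. A gene
#' with zero variance across animals has a degenerate point interval and
#' is called on `mean > threshold`. When `fit` is supplied, per-gene
#' posterior component membership probabilities (columns ranked by
#' descending component mean) are appended.
#'
#' @param lfc Gene-by-animal LFC matrix from [compute_lfc()].
#' @param threshold Enrichment threshold in LFC units.
#' @param conf Confidence level (default 0.95).
#' @param fit Optional `gmm_fit` used to compute posteriors at each
#'   gene's mean LFC.
#' @return A data.frame with columns `gene_id`, `mean_lfc`, `ci_low`,
#'   `ci_high`, `enriched` (and `posterior_1..k` if `fit` is given),
#'   plus a `threshold` attribute.
#' @export
call_enriched <- function(lfc, threshold, conf = 0.95, fit = NULL) {
  if (ncol(lfc) < 2L) stop("need >= 2 animals per gene")
  n <- ncol(lfc)
  mean_lfc <- rowMeans(lfc)
  sds <- apply(lfc, 1L, stats::sd)
  half <- stats::qt((1 + conf) / 2, df = n - 1L) * sds / sqrt(n)
  ci_low <- mean_lfc - half
  ci_high <- mean_lfc + half
  enriched <- ifelse(sds == 0, mean_lfc > threshold, ci_low > threshold)
  out <- data.frame(gene_id = rownames(lfc), mean_lfc = mean_lfc,
                    ci_low = ci_low, ci_high = ci_high, enriched = enriched,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fit)) {
    ld <- .gmm_logdens(mean_lfc, fit$weights, fit$means, fit$sds)
    m <- do.call(pmax, as.data.frame(ld))
    post <- exp(ld - (m + log(rowSums(exp(ld - m)))))
    colnames(post) <- paste0("posterior_", seq_len(fit$k))
    out <- cbind(out, post)
  }
  attr(out, "threshold") <- threshold
  out
}
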