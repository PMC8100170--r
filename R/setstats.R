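#' Upper-tail hypergeometric over-representation test
#'
#' Tests whether `k` successes in a sample of `n` is more than expected
#' when `K` of the `N` population genes are successes:
#' `p = P(X >= k)` (inclusive upper tail), evaluated in log-space by
#' [stats::phyper()] so that populations of ~16,000 genes with p-values
#' around 1e-23 do not underflow. Fold-enrichment is the observed success
#' rate over the population rate, `(k/n)/(K/N)`.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k Successes in the sample.
#' @return An object of class `hypergeom_result`: one-row data.frame
#'   with columns `N`, `K`, `n`, `k`, `p_raw`, `fe`.
#' @export
hypergeom_test <- function(N, K, n, k) {
  for (v in c("N", "K", "n", "k")) {
    val <- get(v)
    if (length(val) != 1L || is.na(val) || val < 0 || val != round(val))
      stop(v, " must be a single non-negative integer")
  }
  if (K > N) stop("violated: K <= N")
  if (n > N) stop("violated: n <= N")
  if (k > n) stop("violated: k <= n")
  if (k > K) stop("violated: k <= K")
  p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  fe <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  structure(data.frame(N = N, K = K, n = n, k = k, p_raw = p, fe = fe),
            class = c("hypergeom_result", "data.frame"))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving. `m` defaults to the number
#' of p-values (the usual family size) but can be set explicitly when
#' the family is larger than the vector at hand.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m == length(p)) return(stats::p.adjust(p, method = "bonferroni"))
  pmin(1, m * p)
}

#' Over-representation of a signature across gene-set groups
#'
#' One inclusive upper-tail hypergeometric test per group (e.g. disease
#' groups of the nosology of genetic skeletal disorders): `N` = universe
#' size, `K` = group members in the universe, `n` = signature genes,
#' `k` = group members in the signature. Groups with fewer than
#' `min_group` members in the universe are not tested; groups entirely
#' outside the universe are skipped with a warning. Bonferroni
#' adjustment uses the number of groups actually tested.
#'
#' @param groups Named list of character vectors (gene sets).
#' @param signature Character vector of signature genes; must be a
#'   subset of `universe`.
#' @param universe Character vector: the gene population.
#' @param min_group Minimum in-universe group size (default 3).
#' @return Data.frame with one row per tested group: `group`, `N`, `K`,
#'   `n`, `k`, `p_raw`, `p_adj`, `fe`, ordered by `p_raw`.
#' @export
group_enrichment <- function(groups, signature, universe, min_group = 3) {
  out_sig <- setdiff(signature, universe)
  if (length(out_sig))
    stop("signature gene outside the universe: ", out_sig[1L])
  N <- length(unique(universe))
  sig <- unique(signature)
  n <- length(sig)
  rows <- list()
  for (g in names(groups)) {
    in_univ <- intersect(groups[[g]], universe)
    if (!length(in_univ)) {
      warning("group entirely outside the universe, skipped: ", g)
      next
    }
    if (length(in_univ) < min_group) next
    k <- length(intersect(in_univ, sig))
    res <- hypergeom_test(N, length(in_univ), n, k)
    rows[[g]] <- cbind(data.frame(group = g, stringsAsFactors = FALSE), res)
  }
  if (!length(rows))
    return(data.frame(group = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), fe = numeric(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- bonferroni(res$p_raw)
  res[order(res$p_raw), ]
}

#' Nearest-gene over-representation at GWAS loci
#'
#' Tests whether the genes nearest to genome-wide-significant lead
#' variants are over-represented for a member set (e.g. the signature
#' orthologs). Genes nearest to multiple loci are counted once; the
#' deduplicated nearest-gene list is intersected with the universe to
#' form the sample.
#'
#' @param nearest Character vector of nearest-gene ids (repeats allowed).
#' @param members Character vector: the member set (successes).
#' @param universe Character vector: the gene population.
#' @return A `hypergeom_result` (see [hypergeom_test()]).
#' @export
nearest_gene_enrichment <- function(nearest, members, universe) {
  samp <- intersect(unique(nearest), universe)
  if (!length(samp))
    stop("no nearest genes remain after intersecting with the universe")
  memb <- intersect(unique(members), universe)
  hypergeom_test(N = length(unique(universe)), K = length(memb),
                 n = length(samp), k = length(intersect(samp, memb)))
}

#' Map mouse genes to human orthologs within a universe
#'
#' Expands each mouse gene to all of its human partners in the ortholog
#' map (many-to-many maps expand fully), keeps the partners present in
#' the human universe, and reports how many input genes had no mapping.
#'
#' @param mouse_genes Character vector of mouse gene ids.
#' @param map Data.frame with columns `mouse_gene_id`, `human_gene_id`
#'   (see [read_ortholog_map()]).
#' @param universe Character vector of human gene ids.
#' @return Character vector of human gene ids (unique, in universe),
#'   with an `n_unmapped` attribute.
#' @export
map_orthologs <- function(mouse_genes, map, universe) {
  mouse_genes <- unique(mouse_genes)
  hit <- map[map$mouse_gene_id %in% mouse_genes, , drop = FALSE]
  n_unmapped <- length(setdiff(mouse_genes, hit$mouse_gene_id))
  if (n_unmapped)
    message(n_unmapped, " mouse gene(s) had no ortholog mapping")
  out <- intersect(unique(hit$human_gene_id), universe)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
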