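#' Contaminant-tissue exclusion set
#'
#' Genes with significantly higher expression in blood, bone marrow or
#' skeletal muscle relative to osteocyte-enriched bone are treated as
#' contaminants rather than osteocyte genes. A gene is excluded when, in
#' any of the contrast tissues, `p_value < alpha` (strict) and `lfc > 0`
#' under the table's orientation (positive = higher in the contrast
#' tissue).
#'
#' @param dge_table Data.frame from [read_exclusion_table()] with columns
#'   `gene`, `contrast_tissue`, `lfc`, `p_value`.
#' @param alpha Significance cutoff (default 0.05, strict `<`).
#' @param tissues Allowed contrast tissues.
#' @return Character vector of excluded gene ids; the triggering tissues
#'   per gene are attached as a `tissues` attribute (named list).
#' @export
exclusion_set <- function(dge_table, alpha = 0.05,
                          tissues = c("blood", "bone_marrow", "muscle")) {
  if (!nrow(dge_table)) {
    out <- character(0)
    attr(out, "tissues") <- list()
    return(out)
  }
  bad <- setdiff(unique(dge_table$contrast_tissue), tissues)
  if (length(bad)) stop("unknown contrast tissue: ", bad[1L])
  hit <- dge_table$p_value < alpha & dge_table$lfc > 0
  sub <- dge_table[hit, , drop = FALSE]
  out <- unique(sub$gene)
  attr(out, "tissues") <- split(sub$contrast_tissue, sub$gene)[out]
  out
}

#' Define the osteocyte transcriptome signature
#'
#' Applies the three-rule filter: a gene belongs to the signature iff it
#' is (1) actively expressed in osteocytes from any of the configured
#' sample types, (2) significantly enriched in osteocytes relative to
#' whole bone, and (3) not significantly higher in blood, bone marrow or
#' muscle.
#'
#' @param active_any Character vector: genes active in any osteocyte
#'   sample type.
#' @param enriched Character vector: genes called enriched.
#' @param excluded Character vector: contaminant-tissue exclusion set.
#' @param universe Optional character vector the flags are reported over;
#'   defaults to the union of the three inputs.
#' @return An object of class `signature_set`: data.frame with columns
#'   `gene_id`, `active_any`, `enriched`, `excluded_tissue`,
#'   `in_signature`, plus a `counts` attribute with the per-stage totals
#'   (`n_active`, `n_enriched`, `n_active_enriched`, `n_excluded_of_those`,
#'   `n_signature`).
#' @export
define_signature <- function(active_any, enriched, excluded,
                             universe = NULL) {
  if (is.null(universe))
    universe <- sort(unique(c(active_any, enriched, excluded)))
  df <- data.frame(gene_id = universe,
                   active_any = universe %in% active_any,
                   enriched = universe %in% enriched,
                   excluded_tissue = universe %in% excluded,
                   stringsAsFactors = FALSE)
  df$in_signature <- df$active_any & df$enriched & !df$excluded_tissue
  ae <- df$active_any & df$enriched
  counts <- c(n_active = sum(df$active_any),
              n_enriched = sum(df$enriched),
              n_active_enriched = sum(ae),
              n_excluded_of_those = sum(ae & df$excluded_tissue),
              n_signature = sum(df$in_signature))
  structure(df, counts = counts, class = c("signature_set", "data.frame"))
}

#' @export
print.signature_set <- function(x, ...) {
  n <- attr(x, "counts")
  cat(sprintf(paste0(
    "signature_set over %d genes:\n",
    "  active (any sample type): %d\n",
    "  enriched:                 %d\n",
    "  active & enriched:        %d\n",
    "  of those, tissue-excluded:%d\n",
    "  final signature:          %d\n"),
    nrow(x), n[["n_active"]], n[["n_enriched"]], n[["n_active_enriched"]],
    n[["n_excluded_of_those"]], n[["n_signature"]]))
  invisible(x)
}

#' Genes in a signature set
#' @param x A `signature_set`.
#' @return Character vector of signature gene ids.
#' @export
signature_genes <- function(x) x$gene_id[x$in_signature]
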