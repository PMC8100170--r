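#' Simulate a multi-group FPKM cohort with planted active genes
#'
#' Emulates the bimodal per-sample log2-FPKM distribution of bulk
#' RNA-seq: inactive genes contribute a near-zero mass (exact zeros with
#' probability `dropout`, otherwise small exponential noise) and active
#' genes a log-normal active component. The default shape mirrors an
#' osteocyte bone-comparison cohort: three skeletal sites with eight
#' replicates each. Active genes are active in every group; the truth
#' table records the planted label per gene.
#'
#' @param n_genes Number of genes (default 5000).
#' @param groups Character vector of sample-group (tissue) names.
#' @param replicates Replicates per group (default 8).
#' @param active_fraction Fraction of genes planted active (default 0.5);
#'   exactly `round(active_fraction * n_genes)` genes are labelled.
#' @param active_meanlog2,active_sdlog2 Mean and sd of the active
#'   component in log2-FPKM units (defaults 5 and 1.5).
#' @param dropout Probability that an inactive gene yields FPKM 0 in a
#'   sample (default 0.7).
#' @param inactive_scale Scale of the exponential near-zero noise for
#'   non-dropout inactive measurements (default 0.05 FPKM).
#' @param noise_sd Per-replicate multiplicative noise, sd in log2 units
#'   (default 0.25).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments and this seed.
#' @return List with `fpkm` (an `expr_matrix`), `samples` (sample
#'   table) and `truth` (data.frame `gene_id`, `is_active`).
#' @export
simulate_cohort <- function(n_genes = 5000,
                            groups = c("tibia", "femur", "humerus"),
                            replicates = 8, active_fraction = 0.5,
                            active_meanlog2 = 5, active_sdlog2 = 1.5,
                            dropout = 0.7, inactive_scale = 0.05,
                            noise_sd = 0.25, seed = 1) {
  if (active_fraction <= 0 || active_fraction >= 1)
    stop("active_fraction must lie strictly between 0 and 1")
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n_active <- round(active_fraction * n_genes)
  is_active <- c(rep(TRUE, n_active), rep(FALSE, n_genes - n_active))
  sample_ids <- as.vector(t(outer(groups, seq_len(replicates),
                                  function(g, r) sprintf("%s_rep%d", g, r))))
  ns <- length(sample_ids)
  base <- stats::rnorm(n_genes, active_meanlog2, active_sdlog2)
  vals <- matrix(0, n_genes, ns, dimnames = list(gene_ids, sample_ids))
  act <- which(is_active)
  vals[act, ] <- 2^(base[act] +
                      matrix(stats::rnorm(length(act) * ns, 0, noise_sd),
                             length(act), ns))
  inact <- which(!is_active)
  zero <- matrix(stats::runif(length(inact) * ns) < dropout,
                 length(inact), ns)
  noise <- matrix(stats::rexp(length(inact) * ns, rate = 1 / inactive_scale),
                  length(inact), ns)
  vals[inact, ] <- ifelse(zero, 0, noise)
  samples <- data.frame(
    sample_id = sample_ids,
    cohort = "bone_comparison",
    tissue = rep(groups, each = replicates),
    condition = "other",
    animal_id = sprintf("bc_m%02d", seq_len(ns)),
    age_weeks = 16L,
    sex = rep_len(c("F", "M"), ns),
    replicate = rep(seq_len(replicates), times = length(groups)),
    stringsAsFactors = FALSE)
  list(fpkm = expression_matrix(vals, "FPKM"),
       samples = samples,
       truth = data.frame(gene_id = gene_ids, is_active = is_active,
                          stringsAsFactors = FALSE))
}

#' Simulate a paired osteocyte-enrichment count experiment
#'
#' Each gene is assigned to one component of a Gaussian mixture of true
#' log2 fold-changes between osteocyte-enriched and whole-bone tissue;
#' the defaults plant a small strongly enriched component (mean 4.5), a
#' moderately enriched component (mean 1.0, sd 0.3), a null bulk and a
#' depleted component. Per animal, whole-bone counts are negative
#' binomial around a log-normal per-gene baseline and enriched counts
#' around `baseline * 2^LFC`, with per-sample library-size factors; the
#' left/right-limb pairing of the cohort is preserved. Baselines of
#' net-enriched genes are scaled down so both conditions have equal
#' expected total output (osteocyte transcripts are dilute in whole
#' bone); without this the planted mixture would only be identifiable up
#' to a composition shift after library-size normalisation. The truth table
#' records each gene's component (ranked by descending generating mean),
#' its true LFC, and the planted enriched label: a gene is enriched when
#' its component's generating mean lies above
#' `mean_2 + 2 * sd_2` (parameters of the second-ranked component); that
#' cut is also returned as the `truth_threshold` attribute.
#'
#' @param n_genes Number of genes (default 10000).
#' @param n_animals Paired animals (default 5, >= 3).
#' @param weights,means,sds Mixture parameters of the true LFC
#'   distribution (defaults 0.05/0.15/0.45/0.35, 4.5/1.0/0/-1.5,
#'   0.6/0.3/0.4/0.5).
#' @param base_meanlog,base_sdlog Log-normal baseline count parameters
#'   (defaults log(500) and 1).
#' @param nb_size Negative-binomial size (dispersion) parameter,
#'   fixed at 10.
#' @param lib_size_factor_sd Log-normal sd of per-sample library-size
#'   factors (default 0.15).
#' @param seed Integer seed.
#' @return List with `counts` (an `expr_matrix`), `samples` (sample
#'   table) and `truth` (data.frame `gene_id`, `component`, `true_lfc`,
#'   `is_enriched`).
#' @export
simulate_enrichment_experiment <- function(n_genes = 10000, n_animals = 5,
                                           weights = c(0.05, 0.15, 0.45, 0.35),
                                           means = c(4.5, 1.0, 0, -1.5),
                                           sds = c(0.6, 0.3, 0.4, 0.5),
                                           base_meanlog = log(500),
                                           base_sdlog = 1, nb_size = 10,
                                           lib_size_factor_sd = 0.15,
                                           seed = 1) {
  if (abs(sum(weights) - 1) > 1e-9) stop("component weights must sum to 1")
  if (length(means) != length(weights) || length(sds) != length(weights))
    stop("weights, means and sds must have equal length")
  if (n_animals < 3) stop("need n_animals >= 3")
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  ord <- order(-means)  # component 1 = highest generating mean
  rank_of <- match(seq_along(means), ord)
  comp_raw <- sample(seq_along(weights), n_genes, replace = TRUE,
                     prob = weights)
  true_lfc <- stats::rnorm(n_genes, means[comp_raw], sds[comp_raw])
  component <- rank_of[comp_raw]
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  # Counts only measure relative abundance, so any constant offset of the
  # planted LFCs cancels under library-size normalisation; the mixture is
  # recoverable on its stated scale only if the two conditions have equal
  # expected total output. Balance the composition by scaling down the
  # whole-bone baselines of net-enriched genes (osteocyte transcripts are
  # dilute in whole bone) until sum(base * 2^lfc) = sum(base).
  delta <- base * (2^true_lfc - 1)
  pos <- delta > 0
  base[pos] <- base[pos] * (-sum(delta[!pos]) / sum(delta[pos]))
  animals <- sprintf("oe_m%02d", seq_len(n_animals))
  sample_ids <- as.vector(rbind(paste0(animals, "_ost"),
                                paste0(animals, "_whole")))
  libf <- stats::rlnorm(length(sample_ids), 0, lib_size_factor_sd)
  names(libf) <- sample_ids
  counts <- matrix(0L, n_genes, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (a in seq_len(n_animals)) {
    ost <- paste0(animals[a], "_ost")
    whl <- paste0(animals[a], "_whole")
    counts[, ost] <- stats::rnbinom(n_genes,
                                    mu = base * 2^true_lfc * libf[ost],
                                    size = nb_size)
    counts[, whl] <- stats::rnbinom(n_genes, mu = base * libf[whl],
                                    size = nb_size)
  }
  storage.mode(counts) <- "double"
  samples <- data.frame(
    sample_id = sample_ids,
    cohort = "enrichment",
    tissue = "humerus",
    condition = rep(c("osteocyte_enriched", "whole_bone"), times = n_animals),
    animal_id = rep(animals, each = 2L),
    age_weeks = 10L,
    sex = "M",
    replicate = 1L,
    stringsAsFactors = FALSE)
  truth_threshold <- means[ord][2L] + 2 * sds[ord][2L]
  # a gene is planted enriched when its component sits above the cut, so
  # an all-null mixture plants nothing
  truth <- data.frame(gene_id = gene_ids, component = component,
                      true_lfc = true_lfc,
                      is_enriched = means[comp_raw] > truth_threshold,
                      stringsAsFactors = FALSE)
  attr(truth, "truth_threshold") <- truth_threshold
  attr(truth, "component_means") <- means[ord]
  list(counts = expression_matrix(counts, "counts"),
       samples = samples, truth = truth)
}

#' Simulate a multi-tissue FPKM panel with planted tissue-specific genes
#'
#' Background genes are expressed at similar levels across all tissues
#' (low Tau); a planted fraction is expressed in exactly one target
#' tissue and silent elsewhere (Tau near 1). Default panel: osteocytes
#' plus 12 non-skeletal tissues, two samples each.
#'
#' @param n_genes Number of genes (default 3000).
#' @param tissues Tissue names (>= 3); the first is the osteocyte
#'   pseudo-tissue by convention.
#' @param replicates Samples per tissue (default 2).
#' @param specific_fraction Fraction of genes planted tissue-specific
#'   (default 0.05).
#' @param background_meanlog2,background_sdlog2 Background expression in
#'   log2-FPKM units (defaults 4 and 1).
#' @param tissue_noise_sd Per-tissue log2 wobble of background genes
#'   (default 0.3).
#' @param specific_meanlog2 Log2-FPKM of planted genes in their target
#'   tissue (default 8).
#' @param seed Integer seed.
#' @return List with `fpkm` (an `expr_matrix`), `samples` and `truth`
#'   (data.frame `gene_id`, `specific_tissue`, `NA` for background).
#' @export
simulate_tissue_panel <- function(n_genes = 3000,
                                  tissues = c("osteocyte", "brain", "heart",
                                              "liver", "kidney", "lung",
                                              "spleen", "muscle", "fat",
                                              "skin", "intestine", "stomach",
                                              "thymus"),
                                  replicates = 2, specific_fraction = 0.05,
                                  background_meanlog2 = 4,
                                  background_sdlog2 = 1,
                                  tissue_noise_sd = 0.3,
                                  specific_meanlog2 = 8, seed = 1) {
  if (length(tissues) < 3L) stop("need at least 3 tissues")
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  nt <- length(tissues)
  sample_ids <- as.vector(t(outer(tissues, seq_len(replicates),
                                  function(t, r) sprintf("%s_s%d", t, r))))
  tissue_of <- rep(tissues, each = replicates)
  n_spec <- round(specific_fraction * n_genes)
  target <- rep(NA_character_, n_genes)
  if (n_spec > 0)
    target[seq_len(n_spec)] <- sample(tissues, n_spec, replace = TRUE)
  base <- stats::rnorm(n_genes, background_meanlog2, background_sdlog2)
  tshift <- matrix(stats::rnorm(n_genes * nt, 0, tissue_noise_sd),
                   n_genes, nt, dimnames = list(gene_ids, tissues))
  vals <- matrix(0, n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    t <- tissue_of[j]
    lv <- base + tshift[, t] + stats::rnorm(n_genes, 0, 0.1)
    fp <- 2^lv
    spec <- !is.na(target)
    fp[spec] <- ifelse(target[spec] == t,
                       2^(specific_meanlog2 +
                            stats::rnorm(sum(spec), 0, 0.25)),
                       0)
    vals[, j] <- fp
  }
  samples <- data.frame(
    sample_id = sample_ids,
    cohort = "tissue_panel",
    tissue = tissue_of,
    condition = "other",
    animal_id = sprintf("tp_m%02d", seq_along(sample_ids)),
    age_weeks = 16L,
    sex = "F",
    replicate = rep(seq_len(replicates), times = nt),
    stringsAsFactors = FALSE)
  list(fpkm = expression_matrix(vals, "FPKM"),
       samples = samples,
       truth = data.frame(gene_id = gene_ids, specific_tissue = target,
                          stringsAsFactors = FALSE))
}

#' Simulate a gene-set universe with one planted over-represented group
#'
#' Builds a universe of genes, a member set (e.g. a transcriptome
#' signature) covering `member_fraction` of it, and `n_groups` gene-set
#' groups. Members enter each background group binomially at the
#' baseline rate; the planted group carries exactly
#' `round(size * min(1, planted_fe * member_fraction))` members so its
#' fold-enrichment is realised, not merely expected. At `planted_fe = 1`
#' the planted group is drawn like any other (a pure null collection).
#'
#' @param universe_size Number of universe genes (default 16000).
#' @param member_fraction Fraction of the universe in the member set
#'   (default 0.0625, ~1000 of 16000).
#' @param n_groups Number of groups (default 20).
#' @param group_size_range Integer range of group sizes (default
#'   c(10, 40)).
#' @param planted_fe Planted fold-enrichment of the one planted group
#'   (default 5; 1 = null).
#' @param seed Integer seed.
#' @return List with `groups` (named list), `members`, `universe` and
#'   `truth` (list with `planted_group`, `planted_fe`).
#' @export
simulate_gene_sets <- function(universe_size = 16000,
                               member_fraction = 0.0625, n_groups = 20,
                               group_size_range = c(10, 40),
                               planted_fe = 5, seed = 1) {
  if (planted_fe < 1) stop("planted_fe must be >= 1")
  p1 <- min(1, planted_fe * member_fraction)
  set.seed(seed)
  universe <- sprintf("h%05d", seq_len(universe_size))
  n_mem <- round(member_fraction * universe_size)
  members <- sort(sample(universe, n_mem))
  non_members <- setdiff(universe, members)
  size_pool <- seq(group_size_range[1L], group_size_range[2L])
  sizes <- if (length(size_pool) == 1L) rep(size_pool, n_groups)
    else sample(size_pool, n_groups, replace = TRUE)
  planted <- 1L
  groups <- stats::setNames(vector("list", n_groups),
                            sprintf("grp%02d", seq_len(n_groups)))
  for (i in seq_len(n_groups)) {
    # the planted group realises its fold-enrichment exactly (so the truth
    # label is what the data contain); under the null (fe = 1) it is drawn
    # like every other group
    n_succ <- if (i == planted && planted_fe > 1) round(sizes[i] * p1)
      else stats::rbinom(1L, sizes[i], member_fraction)
    if (n_succ > length(members) || sizes[i] - n_succ > length(non_members))
      stop("infeasible planted_fe for the given sizes")
    groups[[i]] <- sample(c(sample(members, n_succ),
                            sample(non_members, sizes[i] - n_succ)))
  }
  list(groups = groups, members = members, universe = universe,
       truth = list(planted_group = names(groups)[planted],
                    planted_fe = planted_fe))
}
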