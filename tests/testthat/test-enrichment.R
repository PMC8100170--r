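test_that("library-size normalisation equalises column totals", {
  vals <- matrix(c(600000, 400000, 1200000, 800000), 2, 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  m <- expression_matrix(vals, "counts")
  norm <- libsize_normalize(m)
  # totals 1e6 and 2e6 -> scale factors 1.5 and 0.75
  expect_equal(norm[, "s1"] / vals[, "s1"], c(gA = 1.5, gB = 1.5))
  expect_equal(norm[, "s2"] / vals[, "s2"], c(gA = 0.75, gB = 0.75))
  expect_equal(colSums(norm), c(s1 = 1.5e6, s2 = 1.5e6))
  # equal totals: identity
  eq <- expression_matrix(matrix(c(3, 7, 5, 5), 2, 2,
                                 dimnames = dimnames(vals)), "counts")
  expect_equal(unname(libsize_normalize(eq)), unname(unclass(eq)))
  zero <- expression_matrix(matrix(c(1, 1, 0, 0), 2, 2,
                                   dimnames = dimnames(vals)), "counts")
  expect_error(libsize_normalize(zero), "zero-total")
  expect_error(libsize_normalize(expression_matrix(vals, "FPKM")),
               "counts matrix")
})

test_that("paired per-animal LFCs and their mean evaluate the log ratio", {
  animals <- sprintf("m%d", 1:5)
  samples <- data.frame(
    sample_id = c(paste0(animals, "_ost"), paste0(animals, "_whole")),
    cohort = "enrichment", tissue = "humerus",
    condition = rep(c("osteocyte_enriched", "whole_bone"), each = 5),
    animal_id = rep(animals, 2), age_weeks = 10L, sex = "M", replicate = 1L,
    stringsAsFactors = FALSE)
  base <- 10000
  mk <- function(ost, whole) {
    m <- cbind(matrix(rep(ost, each = 1), nrow = length(ost))[, rep(1, 5)],
               matrix(rep(whole, each = 1), nrow = length(whole))[, rep(1, 5)])
    dimnames(m) <- list(paste0("g", seq_along(ost)), samples$sample_id)
    m
  }
  m <- mk(c(base, 4 * base), c(base, base))
  lfc <- compute_lfc(m, samples)
  expect_equal(unname(lfc$mean_lfc["g1"]), 0)
  expect_equal(unname(lfc$mean_lfc["g2"]), 2, tolerance = 1e-3)
  # per-animal means are plain arithmetic
  per_animal <- c(1.8, 2.0, 2.2, 1.9, 2.1)
  m2 <- m
  m2["g1", paste0(animals, "_whole")] <- base
  m2["g1", paste0(animals, "_ost")] <- (base + 1) * 2^per_animal - 1
  lfc2 <- compute_lfc(m2, samples)
  expect_equal(unname(lfc2$lfc["g1", ]), per_animal, tolerance = 1e-12)
  expect_equal(unname(lfc2$mean_lfc["g1"]), 2.0)
  # unpaired animal is named
  expect_error(compute_lfc(m, samples[-1, ]), "m1")
})

test_that("BIC prefers a single component for single-Gaussian data", {
  set.seed(77)
  x <- rnorm(5000, mean = 1, sd = 2)
  fit <- fit_lfc_gmm(x, k_candidates = 1:4, seed = 3)
  expect_identical(fit$k, 1L)
  # analytic oracle: MLE log-likelihood and BIC of one Gaussian
  mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  ll <- sum(dnorm(x, mu, s, log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$bic, -2 * ll + 2 * log(length(x)), tolerance = 1e-6)
})

test_that("EM recovers a well-separated four-component mixture", {
  set.seed(123)
  n <- 10000
  comp <- sample(1:4, n, TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  truth_means <- c(-2, 0, 2, 5)
  x <- rnorm(n, truth_means[comp], 0.3)
  fit <- fit_lfc_gmm(x, k_candidates = 1:4, seed = 11)
  expect_identical(fit$k, 4L)
  expect_equal(sort(fit$means), sort(truth_means), tolerance = 0.1)
  # EM guarantees
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(rowSums(fit$posterior), rep(1, n), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  expect_identical(sort(fit$rank_by_mean), 1:4)
})

test_that("mixture fit agrees with an independent EM implementation", {
  set.seed(456)
  comp <- sample(1:3, 4000, TRUE, prob = c(0.2, 0.5, 0.3))
  x <- rnorm(4000, c(-3, 0, 3)[comp], c(0.4, 0.5, 0.4)[comp])
  fit <- fit_lfc_gmm(x, k_candidates = 3, seed = 2)
  suppressMessages(library(mclust))
  ref <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("enrichment threshold targets the second-ranked component", {
  mk <- function(means, sds, weights = rep(1 / length(means), length(means))) {
    ord <- order(-means, -weights)
    structure(list(k = length(means), means = means[ord], sds = sds[ord],
                   weights = weights[ord]), class = "gmm_fit")
  }
  f <- mk(means = c(-1, 0.2, 1.0, 3.5), sds = c(0.5, 0.4, 0.3, 0.6))
  expect_equal(enrichment_threshold(f), 1.0 + 2 * 0.3)
  f2 <- mk(means = c(0, 4), sds = c(1, 1))
  expect_equal(enrichment_threshold(f2), 0 + 2 * 1)
  # strictly increasing in component 2's sd
  f3 <- mk(means = c(-1, 0.2, 1.0, 3.5), sds = c(0.5, 0.4, 0.5, 0.6))
  expect_gt(enrichment_threshold(f3), enrichment_threshold(f))
  f1 <- mk(means = 0, sds = 1)
  expect_error(enrichment_threshold(f1), "k >= 2")
})

test_that("enriched calls use the lower t-interval bound, strictly", {
  lfc <- rbind(flat = rep(5, 5),
               low = c(0.9, 1.0, 1.1, 1.0, 1.0),
               mid = c(2.0, 2.5, 3.0, 2.2, 2.8))
  colnames(lfc) <- paste0("m", 1:5)
  calls <- call_enriched(lfc, threshold = 1.63)
  # degenerate CI collapses to the point
  expect_equal(calls$ci_low[calls$gene_id == "flat"], 5)
  expect_true(calls$enriched[calls$gene_id == "flat"])
  expect_false(calls$enriched[calls$gene_id == "low"])
  # hand t-interval, df = 4: 2.5 +/- 2.776 * 0.41231/sqrt(5)
  expect_equal(calls$ci_low[calls$gene_id == "mid"], 1.98805,
               tolerance = 1e-4)
  expect_equal(calls$ci_high[calls$gene_id == "mid"], 3.01195,
               tolerance = 1e-4)
  expect_true(calls$enriched[calls$gene_id == "mid"])
  expect_true(all(calls$ci_low <= calls$mean_lfc &
                    calls$mean_lfc <= calls$ci_high))
  expect_error(call_enriched(lfc[, 1, drop = FALSE], 1), ">= 2 animals")
})

test_that("posterior columns from a fit sum to one per gene", {
  set.seed(8)
  x <- c(rnorm(300, 0, 0.5), rnorm(100, 3, 0.5))
  lfc <- matrix(rep(x, 3) + rnorm(1200, 0, 0.05), ncol = 3,
                dimnames = list(sprintf("g%03d", 1:400), paste0("m", 1:3)))
  fit <- fit_lfc_gmm(rowMeans(lfc), k_candidates = 2, seed = 4)
  calls <- call_enriched(lfc, threshold = 1.5, fit = fit)
  post <- as.matrix(calls[, grepl("^posterior_", names(calls))])
  expect_equal(unname(rowSums(post)), rep(1, 400), tolerance = 1e-9)
})
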