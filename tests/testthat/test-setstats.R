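# exhaustive-enumeration oracle for the inclusive upper tail
enum_upper_tail <- function(N, K, n, k) {
  ks <- k:min(n, K)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    for (k in max(0, n - (N - K)):min(n, K)) {
      res <- hypergeom_test(N, K, n, k)
      expect_equal(res$p_raw, enum_upper_tail(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric pmf sums to one over its support", {
  set.seed(12)
  for (i in 1:25) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n - (N - K)):min(n, K)
    total <- sum(dhyper(ks, K, N - K, n))
    expect_equal(total, 1, tolerance = 1e-12)
    # P(X >= min of support) covers everything
    expect_equal(hypergeom_test(N, K, n, ks[1])$p_raw, 1, tolerance = 1e-12)
  }
})

test_that("small worked example and boundary cases", {
  # C(10,5) = 252 draws; 66 have >= 3 of the 4 successes
  expect_equal(hypergeom_test(10, 4, 5, 3)$p_raw, 66 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_test(50, 10, 8, 0)$p_raw, 1)
  expect_error(hypergeom_test(10, 11, 5, 3), "K <= N")
  expect_error(hypergeom_test(10, 4, 11, 3), "n <= N")
  expect_error(hypergeom_test(10, 4, 5, 6), "k <= n")
  expect_error(hypergeom_test(10, 4, 5, 5), "k <= K")
})

test_that("extreme p-values survive large populations without underflow", {
  res <- hypergeom_test(15368, 432, 1043, 90)
  expect_gt(res$p_raw, 0)
  expect_lt(res$p_raw, 1e-20)
  expect_equal(res$fe, (90 / 1043) / (432 / 15368), tolerance = 1e-12)
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1.0)
  expect_equal(bonferroni(c(0.2, 0.3), m = 1), c(0.2, 0.3) * 1)
  p <- c(0.001, 0.04, 0.2)
  expect_identical(order(bonferroni(p)), order(p))
  expect_equal(bonferroni(p), pmin(1, 3 * p))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group enrichment applies the size filter and family correction", {
  universe <- sprintf("h%04d", 1:500)
  signature <- universe[1:50]
  groups <- list(
    tiny = universe[1:2],                        # < 3 in universe: dropped
    planted = universe[c(1:12, 490:495)],        # 12/18 in the signature
    background = universe[101:130],
    outside = c("x1", "x2", "x3"))               # skipped with warning
  res <- NULL
  expect_warning(res <- group_enrichment(groups, signature, universe),
                 "outside the universe")
  expect_setequal(res$group, c("planted", "background"))
  expect_equal(res$p_adj, pmin(1, 2 * res$p_raw))
  expect_identical(res$group[which.min(res$p_adj)], "planted")
  # extreme case: group equals the signature
  res2 <- group_enrichment(list(all = signature), signature, universe)
  expect_identical(res2$k, res2$K)
  expect_equal(res2$fe, (res2$k / res2$n) / (res2$K / res2$N))
  expect_error(group_enrichment(list(g = universe[1:5]),
                                c(signature, "zz"), universe),
               "outside the universe")
})

test_that("planted over-represented group attains the smallest adjusted p", {
  sim <- simulate_gene_sets(universe_size = 4000, member_fraction = 0.05,
                            n_groups = 12, group_size_range = c(25, 35),
                            planted_fe = 6, seed = 99)
  res <- group_enrichment(sim$groups, sim$members, sim$universe)
  expect_identical(res$group[which.min(res$p_adj)],
                   sim$truth$planted_group)
})

test_that("nearest-gene enrichment counts repeated nearest genes once", {
  universe <- sprintf("h%04d", 1:300)
  members <- universe[1:60]
  nearest <- c("h0001", "h0001", "h0001", "h0002", "h0150", "h0200", "zzz")
  res <- nearest_gene_enrichment(nearest, members, universe)
  expect_identical(res$n, 4L)  # deduplicated, 'zzz' outside universe
  expect_identical(res$k, 2L)
  expect_identical(res$K, 60L)
  expect_error(nearest_gene_enrichment(c("a", "b"), members, universe),
               "no nearest genes")
})

test_that("ortholog mapping expands many-to-many and respects the universe", {
  map <- data.frame(mouse_gene_id = c("Sost", "Sost", "Dmp1", "Mepe"),
                    human_gene_id = c("SOST", "SOSTDC1", "DMP1", "MEPE"),
                    stringsAsFactors = FALSE)
  universe <- c("SOST", "SOSTDC1", "DMP1")
  out <- NULL
  expect_message(
    out <- map_orthologs(c("Sost", "Dmp1", "Mepe", "Phex"), map, universe),
    "no ortholog mapping")
  expect_setequal(as.character(out), c("SOST", "SOSTDC1", "DMP1"))
  expect_identical(attr(out, "n_unmapped"), 1L)  # Phex unmapped; Mepe mapped
})
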