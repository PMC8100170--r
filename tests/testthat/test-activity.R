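# KDE oracle: same Gaussian-kernel estimate evaluated by brute force on a
# 10x finer grid; the argmax must agree with the model fit.
kde_argmax_oracle <- function(x, grid_n = 40960) {
  bw <- sd(x) * length(x)^(-1 / 5)
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = grid_n)
  dens <- vapply(grid, function(t) mean(dnorm(t, mean = x, sd = bw)),
                 numeric(1L))
  grid[which.max(dens)]
}

test_that("activity model recovers the active-component peak", {
  set.seed(2024)
  n <- 1000
  active <- 2^rnorm(n / 2, mean = 5, sd = 1.5)
  fpkm <- c(rep(0, n / 2), active)
  m <- fit_activity_model(fpkm)
  expect_equal(m$mu, 5, tolerance = 0.15)
  oracle <- kde_argmax_oracle(log2(fpkm[fpkm > 0]))
  expect_equal(m$mu, oracle, tolerance = 0.01)
  # threshold closed form and monotone equivalence with the z scale
  expect_equal(m$fpkm_threshold, 2^(m$mu + m$z_cutoff * m$sd))
  z <- ifelse(fpkm > 0, (log2(fpkm) - m$mu) / m$sd, -Inf)
  expect_identical(z > m$z_cutoff, fpkm > m$fpkm_threshold)
})

test_that("activity model rejects degenerate and undersized inputs", {
  expect_error(fit_activity_model(rep(8, 100)), "degenerate")
  expect_error(fit_activity_model(c(rep(0, 100), rexp(10))), "positive values")
  expect_error(fit_activity_model(c(-1, rexp(100))), "non-negative")
})

test_that("zFPKM transform evaluates the standardisation exactly", {
  vals <- matrix(c(2^3, 0, 32, 8), 2, 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  m <- expression_matrix(vals, "FPKM")
  models <- list(s1 = list(mu = 3, sd = 1), s2 = list(mu = 3, sd = 2))
  z <- zfpkm_transform(m, models)
  expect_equal(z["gA", "s1"], 0)           # fpkm = 2^mu
  expect_identical(z["gB", "s1"], -Inf)    # fpkm = 0
  expect_equal(z["gA", "s2"], 1)           # (5 - 3)/2
  expect_true(z["gB", "s1"] < -2.6)
  expect_error(zfpkm_transform(m, models["s1"]), "s2")
})

test_that("replicate calls follow the all/none/some rule with strict >", {
  z <- rbind(
    all_above  = rep(0, 8),
    some_above = c(rep(0, 3), rep(-5, 5)),
    none_above = rep(-5, 8),
    boundary   = c(-2.6, rep(0, 7)))  # exactly at the cutoff once
  colnames(z) <- paste0("r", 1:8)
  calls <- call_activity(z, list(tibia = colnames(z)))
  expect_identical(unclass(calls)[, "tibia"],
                   c(all_above = "active", some_above = "variable",
                     none_above = "inactive", boundary = "variable"))
  expect_error(call_activity(z, list(tibia = character(0))), "empty group")
  expect_error(call_activity(z, list(tibia = c("r1", "nope"))), "nope")
})

test_that("activity classes partition the genes of every group", {
  sim <- simulate_cohort(n_genes = 1200, seed = 31)
  models <- fit_activity_models(sim$fpkm)
  z <- zfpkm_transform(sim$fpkm, models)
  groups <- split(sim$samples$sample_id, sim$samples$tissue)
  calls <- call_activity(z, groups)
  for (g in colnames(calls)) {
    tab <- table(factor(unclass(calls)[, g],
                        levels = c("active", "inactive", "variable")))
    expect_identical(sum(tab), nrow(z))
  }
})

test_that("active calls recover planted labels with high fidelity", {
  sim <- simulate_cohort(n_genes = 3000, seed = 7)
  models <- fit_activity_models(sim$fpkm)
  z <- zfpkm_transform(sim$fpkm, models)
  groups <- split(sim$samples$sample_id, sim$samples$tissue)
  calls <- call_activity(z, groups)
  planted <- sim$truth$gene_id[sim$truth$is_active]
  for (g in colnames(calls)) {
    called <- rownames(calls)[unclass(calls)[, g] == "active"]
    tp <- length(intersect(called, planted))
    expect_gte(tp / length(planted), 0.95)  # recall
    expect_gte(tp / length(called), 0.95)   # precision
  }
})

test_that("active union pools groups and rejects unknown scope", {
  status <- cbind(tibia = c(gA = "active", gB = "variable", gC = "inactive"),
                  femur = c(gA = "inactive", gB = "variable", gC = "active"))
  calls <- structure(status, class = c("activity_calls", "matrix"))
  expect_setequal(active_union(calls, c("tibia", "femur")), c("gA", "gC"))
  expect_setequal(active_union(calls, "tibia"), "gA")
  expect_error(active_union(calls, c("tibia", "skull")), "unknown group")
  expect_error(active_union(calls, character(0)), "empty scope")
  # disjoint active sets add up
  expect_length(active_union(calls, c("tibia", "femur")), 2L)
})

test_that("sample correlation matches the covariance/sd ratio", {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,    # exact multiple of s1
                   4, 1, 3, 2), 4, 3,
                 dimnames = list(paste0("g", 1:4), c("s1", "s2", "s3")))
  out <- sample_correlation(vals, rownames(vals))
  expect_equal(diag(out$r), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(out$r["s1", "s2"], 1)  # affine invariance
  manual <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  expect_equal(out$r["s1", "s3"], manual(vals[, 1], vals[, 3]),
               tolerance = 1e-12)
  # zero-variance sample yields NA, not an error
  vals[, 3] <- 5
  out2 <- sample_correlation(vals, rownames(vals))
  expect_true(is.na(out2$r["s1", "s3"]))
  expect_equal(out2$r["s3", "s3"], 1)
  expect_error(sample_correlation(vals, c("g1", "g2")), "at least 3")
})
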