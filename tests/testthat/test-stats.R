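test_that("permutation test handles degenerate and strong-effect cases", {
  x <- c(1, 2, 3, 4, 5)
  pt <- permutation_test(x, x, n_perm = 500, seed = 1)
  expect_equal(pt$p_value, 1)             # all differences zero

  set.seed(2)
  sea <- rnorm(16)
  alt <- sea + rnorm(16, mean = 1, sd = 0.5)
  pt2 <- permutation_test(sea, alt, n_perm = 5000, seed = 3)
  expect_lt(pt2$p_value, 0.001)
  expect_gt(pt2$observed_diff, 0)
  # seed reproducibility
  pt3 <- permutation_test(sea, alt, n_perm = 5000, seed = 3)
  expect_identical(pt2$p_value, pt3$p_value)
  expect_error(permutation_test(sea[1:2], alt[1:2]), "3 complete")
  expect_error(permutation_test(c(sea, NA), c(alt, 1)), "missing|same")
})

test_that("Monte-Carlo p matches exhaustive sign-flip enumeration", {
  set.seed(4)
  sea <- rnorm(10)
  alt <- sea + rnorm(10, 0.6, 1)
  exact <- permutation_test(sea, alt, exact = TRUE)
  mc <- permutation_test(sea, alt, n_perm = 20000, seed = 5)
  expect_equal(exact$n_permutations, 1024)
  # binomial Monte-Carlo tolerance around the exact p
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 20000)
  expect_lt(abs(mc$p_value - exact$p_value), 4 * se + 2e-4)
  # exact variant is deterministic without a seed
  expect_identical(exact$p_value,
                   permutation_test(sea, alt, exact = TRUE)$p_value)
})

test_that("unpaired scheme runs and detects a large shift", {
  set.seed(6)
  sea <- rnorm(16)
  alt <- rnorm(16, mean = 3)
  pt <- permutation_test(sea, alt, n_perm = 2000, seed = 7,
                         scheme = "unpaired")
  expect_lt(pt$p_value, 0.01)
})

test_that("Cohen's D follows the pooled-SD closed form", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  sea <- rnorm(4000, 0, 1)
  alt <- rnorm(4000, 1, 1)
  expect_equal(cohens_d(sea, alt), 1, tolerance = 0.05)
  expect_equal(cohens_d(alt, sea), -cohens_d(sea, alt))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "variance")
  # paired dz variant
  d <- cohens_d(sea[1:100], sea[1:100] + rnorm(100, 1, 0.1), form = "dz")
  expect_gt(d, 5)
})

test_that("age correlation recovers exact linear relations", {
  ages <- c(20, 25, 31, 38, 44)
  expect_equal(age_correlation(ages, ages)$r, 1)
  expect_equal(age_correlation(-ages, ages)$r, -1)
  expect_error(age_correlation(rep(1, 5), ages), "variance")
  expect_error(age_correlation(1:3, 1:3), ">= 4")
})

test_that("age residualization is orthogonal to age and variance-preserving", {
  set.seed(9)
  ages <- runif(32, 19, 45)
  vals <- 0.5 * ages + rnorm(32)
  r <- regress_out_age(vals, ages)
  expect_lt(abs(mean(r)), 1e-10 * stats::sd(vals))
  expect_lt(abs(stats::cor(r, ages)), 1e-10)
  # age-independent values keep (nearly) their variance
  vals0 <- rnorm(32)
  r0 <- regress_out_age(vals0, ages)
  expect_gte(stats::var(r0) / stats::var(vals0), 0.9)
  expect_error(regress_out_age(vals, rep(30, 32)), "constant")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.05, 0.05)), c(0.05, 0.05))
  set.seed(10)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("run_contrasts tests every cell with within-family FDR", {
  set.seed(11)
  subjects <- sprintf("S%02d", 1:8)
  grid <- tidyr::expand_grid(
    subject_id = subjects, condition = c("sea", "altitude"),
    band = c("delta", "alpha"), scope = c("global", "region:frontal"),
    metric = c("relative_power", "overall_fc")
  )
  ages <- stats::setNames(runif(8, 19, 45), subjects)
  grid$age <- ages[grid$subject_id]
  grid$value <- rnorm(nrow(grid)) +
    ifelse(grid$condition == "altitude" & grid$metric == "overall_fc", 2, 0)
  res <- run_contrasts(grid, n_perm = 500, seed = 12)
  expect_equal(nrow(res), 8)              # 2 metrics x 2 bands x 2 scopes
  expect_true(all(res$p_fdr >= res$p_raw))
  expect_true(all(res$observed_diff[res$metric == "overall_fc"] > 1))
  # results reproducible under the same seed regardless of call order
  res2 <- run_contrasts(grid, n_perm = 500, seed = 12)
  expect_identical(res$p_raw, res2$p_raw)
  # incomplete pairs are rejected
  expect_error(run_contrasts(grid[-1, ], n_perm = 500), "incomplete")
})
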