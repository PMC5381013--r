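test_that("variance-ratio F-test matches the printed clinical endpoints", {
  a <- f_test_sd(42.6, 200, 36.6, 200)
  expect_equal(a$f_statistic, (42.6 / 36.6)^2)
  expect_equal(round(a$p_two_sided, 2), 0.03)
  b <- f_test_sd(45.2, 200, 39.3, 200)
  expect_equal(round(b$p_two_sided, 3), 0.049)
  expect_equal(b$percent_reduction, 100 * (1 - 39.3 / 45.2))
})

test_that("the F-test is symmetric and handles equal SDs", {
  # under the 2*min(tails) rule p = 1 exactly when the group sizes match
  eq <- f_test_sd(30, 50, 30, 50)
  expect_equal(eq$f_statistic, 1)
  expect_equal(eq$p_two_sided, 1)
  expect_equal(eq$percent_reduction, 0)
  set.seed(42)
  for (i in 1:20) {
    sa <- runif(1, 10, 60); sb <- runif(1, 10, 60)
    na <- sample(5:300, 1); nb <- sample(5:300, 1)
    expect_equal(f_test_sd(sa, na, sb, nb)$p_two_sided,
                 f_test_sd(sb, nb, sa, na)$p_two_sided)
  }
  expect_error(f_test_sd(-1, 10, 5, 10), "SDs")
  expect_error(f_test_sd(5, 1, 5, 10), "n >= 2")
})

test_that("sample sizes reproduce the 26-to-20 pair and scale correctly", {
  hi <- sample_size_two_means(50, 45.2, 0.05, 0.80)
  lo <- sample_size_two_means(50, 39.3, 0.05, 0.80)
  expect_equal(hi$n_total, 26L)
  expect_equal(lo$n_total, 20L)
  expect_equal(round(100 * (1 - lo$n_total / hi$n_total)), 23)
  # homogeneity: doubling sd exactly quadruples the unrounded per-group n
  expect_equal(sample_size_two_means(50, 90)$n_per_group_exact,
               4 * sample_size_two_means(50, 45)$n_per_group_exact)
  expect_error(sample_size_two_means(0, 10), "delta")
  expect_error(sample_size_two_means(10, 10, alpha = 1.2), "alpha")
})

test_that("sample size is monotone in sd, delta and power", {
  sds <- seq(10, 60, by = 5)
  ns <- vapply(sds, function(s) sample_size_two_means(50, s)$n_total,
               integer(1))
  expect_true(all(diff(ns) >= 0))
  deltas <- seq(20, 80, by = 5)
  nd <- vapply(deltas, function(d) sample_size_two_means(d, 45)$n_total,
               integer(1))
  expect_true(all(diff(nd) <= 0))
  powers <- c(0.5, 0.7, 0.8, 0.9, 0.95)
  np <- vapply(powers, function(p)
    sample_size_two_means(50, 45, power = p)$n_total, integer(1))
  expect_true(all(diff(np) >= 0))
})

test_that("paired comparison of identical vectors gives t = 0, p = 1", {
  x <- c(1010, 1025, 1038, 1051)
  res <- compare_means(x, x, mode = "paired")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(compare_means(1:4, 1:5, mode = "paired"), "equal lengths")
  expect_error(compare_means(1, 1:5), "at least 2")
})

test_that("sex-difference simulation at the printed summary statistics is significant", {
  ps <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      males <- rnorm(100, 1015, 38.6)
      females <- rnorm(100, 1046, 41.1)
      compare_means(females, males, mode = "unpaired")$p
    })
  }, numeric(1))
  # power for p < 0.001 at these means/SDs and n = 100/100 is about 0.98
  expect_gte(sum(ps < 0.001), 95)
  expect_gte(sum(ps < 0.05), 100)
})

test_that("Mann-Whitney exact path agrees with full enumeration", {
  res <- compare_means(c(1, 2, 3), c(4, 5, 6), mode = "mann_whitney")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p, 0.1)
  withr::with_seed(31, {
    for (i in 1:25) {
      n_x <- sample(2:5, 1); n_y <- sample(2:5, 1)
      vals <- sample(1000, n_x + n_y)  # distinct, no ties
      x <- vals[seq_len(n_x)]; y <- vals[-seq_len(n_x)]
      got <- compare_means(x, y, mode = "mann_whitney")$p
      expect_equal(got, mw_enumerate_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("pearson_r is exact on linear data and affine-invariant", {
  x <- c(1, 3, 4, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2, 1, 5, 4, 9)
  base <- pearson_r(x, y)
  shifted <- pearson_r(3.2 * x - 40, 0.5 * y + 7)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
  expect_error(pearson_r(x, y[1:3]), "equal length")
  expect_error(pearson_r(rep(1, 5), y), "constant")
})

test_that("Pitman-Morgan paired variance test behaves at the null and under change", {
  withr::with_seed(5, {
    x <- rnorm(100, 0, 10)
    same <- pitman_morgan(x, x + rnorm(100, 0, 1))
    expect_gt(same$p_two_sided, 0.05)
    shrunk <- pitman_morgan(x, 0.3 * x)
    expect_lt(shrunk$p_two_sided, 0.001)
  })
  expect_error(pitman_morgan(1:5, 1:4), "equal lengths")
})

test_that("quartile cut points satisfy their defining property", {
  coh <- quick_cohort(n = 200, seed = 13)
  qc <- quartile_compare(coh, "hematocrit", "t1_myo")
  s <- coh$hematocrit
  expect_gte(mean(s <= qc$cut_points["lower"]), 0.25)
  expect_gte(mean(s >= qc$cut_points["upper"]), 0.25)
  expect_equal(sum(qc$n), qc$n[["bottom"]] + qc$n[["top"]])
  expect_error(quartile_compare(coh[1:5, ]), "at least 8")
  coh$hematocrit <- 40
  expect_error(quartile_compare(coh, "hematocrit"), "constant")
})

test_that("stratifying on a variable independent of T1 gives uniform p-values", {
  # equal wall-thickness means across sexes break the only path (sex) that
  # could couple thickness to T1, making the null exact
  ps <- vapply(1:200, function(s) {
    coh <- quick_cohort(n = 150, seed = 6000 + s,
                        wall_mean_male = 10, wall_mean_female = 10)
    quartile_compare(coh, "wall_thickness", "t1_myo")$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("range reduction matches direct arithmetic", {
  expect_equal(round(range_reduction(c(908, 1183), c(941, 1146))), 25)
  x <- c(10, 20, 30)
  expect_equal(range_reduction(x, x), 0)
  expect_equal(range_reduction(c(0, 100), c(0, 50)), 50)
  expect_error(range_reduction(rep(5, 4), x), "constant")
  expect_error(range_reduction(numeric(0), x), "nonempty")
})
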