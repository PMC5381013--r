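test_that("T1 to R1 conversion is the guarded reciprocal", {
  expect_equal(t1_to_r1(1000), 0.001)
  expect_equal(t1_to_r1(1562.5), 0.00064)
  expect_equal(t1_to_r1(t1_to_r1(1234)), 1234)  # involution
  expect_error(t1_to_r1(0), "positive")
  expect_error(t1_to_r1(-5), "positive")
})

test_that("blood summary averages LV and RV in the T1 domain first", {
  row <- quick_cohort(n = 1, seed = 1)
  row$t1_blood_lv <- 1600; row$t1_blood_rv <- 1500
  bs <- blood_summary(row)
  expect_equal(bs$mean_blood_t1, 1550)
  expect_equal(bs$mean_blood_r1, 1 / 1550)  # reciprocal of the mean
  row$t1_blood_lv <- 1562.5; row$t1_blood_rv <- 1562.5
  expect_equal(blood_summary(row)$mean_blood_r1, 0.00064)
  row$t1_blood_rv <- NA_real_
  expect_error(blood_summary(row), "t1_blood_rv")
})

test_that("exact linear data is recovered with R^2 = 1", {
  coh <- quick_cohort(n = 40, seed = 6)
  bs <- blood_summary(coh)
  coh$t1_myo <- 1000 - 62500 * (bs$mean_blood_r1 - mean(bs$mean_blood_r1))
  m <- derive_model(coh, "mean_blood_r1")
  expect_equal(unname(m$constants), -62500, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("model coefficients agree with a normal-equations oracle", {
  coh <- quick_cohort(n = 150, seed = 7)
  bs <- blood_summary(coh)
  m <- derive_model(coh)
  X <- cbind(bs$mean_blood_r1, bs$mean_blood_r1star)
  beta <- ols_normal_equations(X, coh$t1_myo)
  expect_equal(m$intercept, beta[1], tolerance = 1e-7)
  expect_equal(unname(m$constants), unname(beta[-1]), tolerance = 1e-7)
})

test_that("collinear or degenerate designs are rejected with a diagnosis", {
  coh <- quick_cohort(n = 50, seed = 8)
  expect_error(derive_model(coh, c("mean_blood_r1", "mean_blood_r1")),
               "duplicated")
  coh2 <- coh
  # make R1* an exact affine copy of R1
  bs <- blood_summary(coh)
  coh2$t1star_blood_lv <- 1 / (2 * bs$mean_blood_r1) + 10
  coh2$t1star_blood_rv <- 1 / (2 * bs$mean_blood_r1) - 10
  expect_error(derive_model(coh2), "collinear")
  coh3 <- coh
  coh3$hematocrit <- rep(40, nrow(coh3))
  expect_error(derive_model(coh3, "hematocrit"), "zero-variance")
  expect_error(derive_model(coh[1:3, ]), "too small")
  expect_error(derive_model(coh, "age"), "unknown predictor")
})

test_that("correction is the identity at the reference means", {
  coh <- quick_cohort(n = 80, seed = 9)
  m <- derive_model(coh)
  at_ref <- coh[1, ]
  # place the subject exactly at the model's reference blood values
  t1_ref <- 1 / m$reference_means[["mean_blood_r1"]]
  t1s_ref <- 1 / m$reference_means[["mean_blood_r1star"]]
  at_ref$t1_blood_lv <- at_ref$t1_blood_rv <- t1_ref
  at_ref$t1star_blood_lv <- at_ref$t1star_blood_rv <- t1s_ref
  expect_equal(apply_correction(at_ref, m), at_ref$t1_myo)
})

test_that("single-predictor correction matches direct substitution", {
  m <- structure(list(
    predictor_names = "mean_blood_r1",
    constants = c(mean_blood_r1 = -62500),
    reference_means = c(mean_blood_r1 = 0.00064),
    intercept = 1070, r_squared = 0.2,
    standardized_betas = c(mean_blood_r1 = -0.45),
    n_fit = 200L, residual_sd = 38, response_sd = 42.6,
    cohort_label = "derivation", units = c(mean_blood_r1 = "ms^-1"),
    created = "2026-01-01"), class = "t1_correction_model")
  row <- quick_cohort(n = 1, seed = 2)
  row$t1_myo <- 1030
  # X_patient chosen so Xbar - X = 0.00004 ms^-1
  t1_b <- 1 / (0.00064 - 0.00004)
  row$t1_blood_lv <- row$t1_blood_rv <- t1_b
  expect_equal(apply_correction(row, m), 1030 + (-62500) * 0.00004)
  expect_equal(apply_correction(row, m), 1027.5)
})

test_that("in-sample correction preserves the mean and shrinks SD by sqrt(1 - R^2)", {
  for (s in 1:3) {
    coh <- quick_cohort(n = 200, seed = s)
    m <- derive_model(coh)
    corr <- apply_correction(coh, m)
    expect_equal(mean(corr), mean(coh$t1_myo), tolerance = 1e-12)
    expect_lt(abs(sd(corr) / (sd(coh$t1_myo) * sqrt(1 - m$r_squared)) - 1),
              1e-10)
    # corrected values equal intercept + sum(c * Xbar) + OLS residuals
    X <- as.matrix(blood_summary(coh)[, m$predictor_names])
    resid <- coh$t1_myo - (m$intercept + X %*% m$constants)
    base <- m$intercept + sum(m$constants * m$reference_means)
    expect_equal(corr, as.vector(base + resid), tolerance = 1e-10)
  }
})

test_that("out-of-sample correction reduces SD when coupling is real", {
  reduced <- vapply(1:100, function(s) {
    der <- quick_cohort(n = 200, seed = s)
    val <- quick_cohort(n = 200, seed = 50000 + s, label = "validation")
    m <- derive_model(der)
    sd(apply_correction(val, m)) < sd(val$t1_myo)
  }, logical(1))
  expect_gte(mean(reduced), 0.95)
})

test_that("generating slopes are recovered within OLS confidence intervals", {
  # partial-volume channel off so the generating slopes are exactly the
  # regression truth; coverage of the 95% CI should be near nominal
  gamma1 <- -15000; gamma2 <- -340000
  covered1 <- covered2 <- logical(100)
  for (s in 1:100) {
    coh <- quick_cohort(n = 200, seed = s, mbv_mean = 0, mbv_sd = 0)
    bs <- blood_summary(coh)
    fit <- lm(coh$t1_myo ~ bs$mean_blood_r1 + bs$mean_blood_r1star)
    ci <- confint(fit)
    covered1[s] <- ci[2, 1] <= gamma1 && gamma1 <= ci[2, 2]
    covered2[s] <- ci[3, 1] <= gamma2 && gamma2 <= ci[3, 2]
  }
  expect_gte(sum(covered1), 93)
  expect_gte(sum(covered2), 93)
})

test_that("models round-trip through the file format at full precision", {
  coh <- quick_cohort(n = 100, seed = 10)
  m <- derive_model(coh, c("mean_blood_r1", "mean_blood_r1star"))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$constants, m$constants)
  expect_identical(back$reference_means, m$reference_means)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$r_squared, m$r_squared)
  expect_identical(back$standardized_betas, m$standardized_betas)
  expect_identical(back$n_fit, m$n_fit)
  expect_identical(back$units, m$units)
  expect_identical(back$cohort_label, m$cohort_label)
  unlink(f)
})

test_that("malformed model files fail loudly", {
  coh <- quick_cohort(n = 100, seed = 11)
  m <- derive_model(coh)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  txt <- readLines(f)
  # unknown predictor name
  writeLines(gsub("mean_blood_r1star", "mean_blood_t2star", txt), f)
  expect_error(load_model(f), "unknown predictor")
  # truncated file: parse error, not silent defaults
  writeLines(txt[1:5], f)
  expect_error(load_model(f), "parse|missing")
  writeLines("{}", f)
  expect_error(load_model(f), "format")
  expect_error(load_model(tempfile()), "no such model file")
  unlink(f)
})

test_that("rates in the wrong unit are caught by range validation", {
  coh <- quick_cohort(n = 30, seed = 12)
  # s^-1 instead of ms^-1: T1 values 1000x too small
  coh$t1_blood_lv <- coh$t1_blood_lv / 1000
  coh$t1_blood_rv <- coh$t1_blood_rv / 1000
  expect_error(derive_model(coh, "mean_blood_r1"), "check units")
})
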