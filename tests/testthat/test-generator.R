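test_that("parameter validation rejects impossible settings", {
  expect_error(generator_params(n = 0), "positive integer")
  expect_error(generator_params(male_fraction = 1.2), "male_fraction")
  expect_error(generator_params(noise_sd = -1), "standard deviations")
  expect_error(generator_params(hct_bounds = c(40, 30)), "hct_bounds")
  expect_error(generator_params(hct_bounds = c(-5, 120)), "hct_bounds")
})

test_that("degenerate sex mixture yields a single-sex cohort", {
  coh <- simulate_cohort(generator_params(n = 50, male_fraction = 1),
                         "derivation")
  expect_equal(nrow(coh), 50)
  expect_true(all(coh$sex == "male"))
})

test_that("derivation preset reproduces the calibrated summary statistics", {
  coh <- simulate_cohort(patient_derivation_preset(n = 200, seed = 1),
                         "derivation")
  expect_lt(abs(mean(coh$hematocrit) - 40), 1)
  expect_lt(abs(sd(coh$t1_myo) - 42.6), 5)
  expect_lt(abs(mean(coh$t1_myo) - 1030), 10)
  bs <- blood_summary(coh)
  expect_lt(abs(mean(bs$mean_blood_r1) - 0.00064), 0.00002)
  expect_lt(abs(mean(bs$mean_blood_r1star) - 0.00061), 0.00002)
  expect_true(all(coh$hematocrit > 25 & coh$hematocrit < 57))
  # latent columns present on synthetic records
  expect_true(all(c("t1_tissue_true", "mbv") %in% names(coh)))
})

test_that("with all randomness off, myocardial T1 is a two-point function of sex", {
  coh <- quick_cohort(
    n = 200, seed = 4,
    hct_sd_male = 0, hct_sd_female = 0, r1_noise_sd = 0,
    r1star_offset_sd = 0, tissue_t1_sd = 0, mbv_sd = 0, noise_sd = 0,
    gamma_r1 = 0, gamma_r1star = 0, residual_sex_gap = 12)
  vals <- tapply(coh$t1_myo, coh$sex, unique)
  expect_length(unlist(vals), 2)
  # closed-form SD of a two-point mixture with sample proportion p-hat
  n <- nrow(coh)
  p_hat <- mean(coh$sex == "female")
  gap <- abs(diff(unname(unlist(vals))))
  expected_sd <- sqrt(n / (n - 1) * p_hat * (1 - p_hat)) * gap
  expect_equal(sd(coh$t1_myo), expected_sd, tolerance = 1e-12)
})

test_that("identical seed and parameters give an identical cohort", {
  p <- patient_derivation_preset(n = 60, seed = 99)
  a <- simulate_cohort(p, "derivation")
  b <- simulate_cohort(p, "derivation")
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  d <- simulate_cohort(p, "derivation", seed = 100)
  expect_false(identical(a$t1_myo, d$t1_myo))
  unlink(c(f1, f2))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_cohort(patient_derivation_preset(n = 20, seed = 7),
                            "derivation"))
  expect_identical(.Random.seed, before)
})

test_that("stronger R1 coupling strengthens the T1/blood-R1 correlation", {
  mean_abs_r <- function(gamma) {
    mean(vapply(1:8, function(s) {
      coh <- quick_cohort(n = 300, seed = s, gamma_r1 = gamma)
      abs(cor(coh$t1_myo, blood_summary(coh)$mean_blood_r1))
    }, numeric(1)))
  }
  rs <- vapply(c(-15000, -150000, -400000), mean_abs_r, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("with residual_sex_gap = 0 the sex gap is fully blood-mediated", {
  # regress out the blood predictors; the remaining sex coefficient should
  # be centred on zero across replicates
  coefs <- vapply(1:30, function(s) {
    coh <- quick_cohort(n = 400, seed = s)
    bs <- blood_summary(coh)
    fit <- lm(coh$t1_myo ~ bs$mean_blood_r1 + bs$mean_blood_r1star +
                I(coh$sex == "female"))
    coef(fit)[[4]]
  }, numeric(1))
  ci <- mean(coefs) + c(-1, 1) * qt(0.975, 29) * sd(coefs) / sqrt(30)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("volunteer preset is calibrated to a homogeneous cohort", {
  p <- volunteer_preset()
  expect_equal(p$n, 77L)
  expect_equal(p$male_fraction, 0.49)
  sds <- vapply(1:10, function(s)
    sd(simulate_cohort(volunteer_preset(seed = s), "volunteer")$t1_myo),
    numeric(1))
  expect_lt(abs(mean(sds) - 37.5), 5)
})

test_that("a patient model applied to volunteers gives no significant SD change", {
  der <- simulate_cohort(patient_derivation_preset(n = 200, seed = 11),
                         "derivation")
  model <- derive_model(der)
  ps <- vapply(1:50, function(s) {
    vol <- simulate_cohort(volunteer_preset(seed = 1000 + s), "volunteer")
    corr <- apply_correction(vol, model)
    f_test_sd(sd(vol$t1_myo), nrow(vol), sd(corr), nrow(vol))$p_two_sided
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("preset files round-trip through the key-value text format", {
  p <- patient_validation_preset(n = 123, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_generator_params(p, f)
  q <- read_generator_params(f)
  expect_equal(unclass(p), unclass(q))
  unlink(f)
  expect_error(read_generator_params(tempfile()), "no such preset")
})
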