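#' Simulate a cohort of subject records
#'
#' Draws `params$n` subjects from the generative model described in
#' [generator_params()].  The chain is, per subject:
#'
#' 1. sex ~ Bernoulli(`male_fraction`);
#' 2. hematocrit ~ Normal(sex-specific mean, sex-specific SD), truncated to
#'    `hct_bounds` by resampling;
#' 3. latent mean blood R1 = `r1_intercept + r1_slope * hct` + noise;
#' 4. latent mean blood R1* = R1 + offset (noisy, mean `r1star_offset_mean`);
#' 5. LV/RV blood T1 (and T1*) split symmetrically around 1/R1 (1/R1*) by
#'    `lv_rv_t1_offset`;
#' 6. latent tissue T1 and MBV;
#' 7. observed septal myocardial T1 = tissue T1
#'    + partial-volume term `1/((1-mbv)/T1_tissue + mbv*R1_blood) - T1_tissue`
#'    + `gamma_r1 * (R1 - mu_R1)` + `gamma_r1star * (R1* - mu_R1*)`
#'    + `residual_sex_gap` (females) + measurement noise,
#'
#' where `mu_R1`/`mu_R1*` are the population reference rates implied by the
#' parameters (not the sample means), so that cohorts of different sizes
#' share the same generating surface.  All randomness flows from the single
#' integer `seed`; the global RNG state is left untouched.
#'
#' @param params A [generator_params()] object (or preset).
#' @param cohort_label One of `"derivation"`, `"validation"`, `"volunteer"`.
#' @param seed Optional override of `params$seed`.
#' @return A `t1_cohort`: a data frame with one row per subject and columns
#'   `subject_id`, `cohort`, `sex`, `age`, `hematocrit`, `t1_myo`,
#'   `t1_blood_lv`, `t1_blood_rv`, `t1star_blood_lv`, `t1star_blood_rv`,
#'   `wall_thickness`, plus the synthetic-only latent columns
#'   `t1_tissue_true` and `mbv`.
#' @examples
#' coh <- simulate_cohort(patient_derivation_preset(n = 50), "derivation")
#' summary(coh$t1_myo)
#' @export
simulate_cohort <- function(params, cohort_label = "derivation",
                            seed = NULL) {
  params <- validate_generator_params(params)
  cohort_label <- match.arg(cohort_label, cohort_labels)
  if (!is.null(seed)) params$seed <- as.integer(seed)
  withr::with_seed(params$seed, simulate_cohort_impl(params, cohort_label))
}

cohort_labels <- c("derivation", "validation", "volunteer")

simulate_cohort_impl <- function(p, cohort_label) {
  n <- p$n
  male <- stats::rbinom(n, 1L, p$male_fraction) == 1L

  hct_mean <- ifelse(male, p$hct_mean_male, p$hct_mean_female)
  hct_sd <- ifelse(male, p$hct_sd_male, p$hct_sd_female)
  hct <- rnorm_truncated(n, hct_mean, hct_sd, p$hct_bounds)

  r1 <- p$r1_intercept + p$r1_slope * hct + stats::rnorm(n, 0, p$r1_noise_sd)
  r1star <- r1 + stats::rnorm(n, p$r1star_offset_mean, p$r1star_offset_sd)
  if (any(r1 <= 0) || any(r1star <= 0))
    stop("generated non-positive blood relaxation rate; check parameters",
         call. = FALSE)

  # population reference rates implied by the parameters
  mu_hct <- p$male_fraction * p$hct_mean_male +
    (1 - p$male_fraction) * p$hct_mean_female
  mu_r1 <- p$r1_intercept + p$r1_slope * mu_hct
  mu_r1star <- mu_r1 + p$r1star_offset_mean

  t1_blood <- 1 / r1
  t1star_blood <- 1 / r1star
  half <- p$lv_rv_t1_offset / 2
  t1_blood_lv <- t1_blood + half
  t1_blood_rv <- t1_blood - half
  t1star_blood_lv <- t1star_blood + half
  t1star_blood_rv <- t1star_blood - half

  t1_tissue <- stats::rnorm(n, p$tissue_t1_mean, p$tissue_t1_sd)
  mbv <- stats::rnorm(n, p$mbv_mean, p$mbv_sd)
  mbv <- pmin(pmax(mbv, 0), 0.5)

  pv <- 1 / ((1 - mbv) / t1_tissue + mbv * r1) - t1_tissue
  t1_myo <- t1_tissue + pv +
    p$gamma_r1 * (r1 - mu_r1) +
    p$gamma_r1star * (r1star - mu_r1star) +
    p$residual_sex_gap * (!male) +
    stats::rnorm(n, 0, p$noise_sd)

  age <- rnorm_truncated(n, p$age_mean, p$age_sd, c(18, 90))
  wall_mean <- ifelse(male, p$wall_mean_male, p$wall_mean_female)
  wall <- rnorm_truncated(n, wall_mean, p$wall_sd, c(3, 30))

  out <- data.frame(
    subject_id = sprintf("%s-%04d", substr(cohort_label, 1, 3), seq_len(n)),
    cohort = cohort_label,
    sex = ifelse(male, "male", "female"),
    age = age,
    hematocrit = hct,
    t1_myo = t1_myo,
    t1_blood_lv = t1_blood_lv,
    t1_blood_rv = t1_blood_rv,
    t1star_blood_lv = t1star_blood_lv,
    t1star_blood_rv = t1star_blood_rv,
    wall_thickness = wall,
    t1_tissue_true = t1_tissue,
    mbv = mbv,
    stringsAsFactors = FALSE
  )
  as_t1_cohort(out)
}

# Truncated-normal draws by resampling (no boundary atoms).  With sd = 0 the
# mean is returned (clamped into the bounds) without iteration.
rnorm_truncated <- function(n, mean, sd, bounds) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  if (all(sd == 0)) return(pmin(pmax(mean, bounds[1]), bounds[2]))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- x <= bounds[1] | x >= bounds[2]
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  stop("truncation bounds too tight: resampling did not terminate",
       call. = FALSE)
}
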