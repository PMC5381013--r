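#' Configuration for a derivation/validation run
#'
#' Each cohort source is either a generator preset name
#' (`"patient_derivation"`, `"patient_validation"`, `"volunteer"`), a
#' `t1_generator_params` object, a cohort CSV path, or a `t1_cohort`
#' already in memory.  A seed is required whenever any synthetic stage is
#' requested.
#'
#' @param derivation,validation Cohort sources (validation optional).
#' @param volunteer Optional volunteer-arm cohort source.
#' @param predictors Predictor set for the correction model.
#' @param seed Integer seed for all synthetic stages.
#' @param n Cohort size used when a source is a preset name.
#' @param out_dir Optional directory for persisted artifacts (model file,
#'   cohort tables, report).
#' @param t_test_variant `"pooled"` or `"welch"` unpaired t.
#' @param f_test_variant `"independent"` (variance-ratio F) or `"paired"`
#'   (Pitman-Morgan) for corrected-vs-uncorrected SD comparisons.
#' @return A `t1_run_config` list.
#' @export
run_config <- function(derivation = "patient_derivation",
                       validation = "patient_validation",
                       volunteer = NULL,
                       predictors = c("mean_blood_r1", "mean_blood_r1star"),
                       seed = 1L, n = 200,
                       out_dir = NULL,
                       t_test_variant = c("pooled", "welch"),
                       f_test_variant = c("independent", "paired")) {
  cfg <- list(derivation = derivation, validation = validation,
              volunteer = volunteer, predictors = predictors,
              seed = as.integer(seed), n = as.integer(n),
              out_dir = out_dir,
              t_test_variant = match.arg(t_test_variant),
              f_test_variant = match.arg(f_test_variant),
              percentile_rule = "linear-interpolation (type 7)")
  needs_seed <- any(vapply(list(derivation, validation, volunteer),
                           function(s) is.character(s) &&
                             length(s) == 1 && s %in% preset_names ||
                             inherits(s, "t1_generator_params"),
                           logical(1)))
  if (needs_seed && (is.null(cfg$seed) || is.na(cfg$seed)))
    stop("a seed is required when any synthetic stage is requested",
         call. = FALSE)
  class(cfg) <- "t1_run_config"
  cfg
}

# resolve a cohort source to a t1_cohort; seed_offset decorrelates stages
resolve_cohort <- function(source, label, cfg, seed_offset = 0L) {
  if (is.null(source)) return(NULL)
  if (inherits(source, "t1_cohort")) return(source)
  if (inherits(source, "t1_generator_params"))
    return(simulate_cohort(source, label, seed = cfg$seed + seed_offset))
  if (is.character(source) && length(source) == 1) {
    if (source %in% preset_names) {
      p <- preset_from_file(source,
                            n = if (source == "volunteer") 77 else cfg$n,
                            seed = cfg$seed + seed_offset)
      return(simulate_cohort(p, label))
    }
    return(read_cohort(source))
  }
  stop("cannot interpret cohort source for the ", label, " stage",
       call. = FALSE)
}

cohort_descriptives <- function(cohort, corrected = NULL) {
  bs <- blood_summary(cohort)
  male <- cohort$sex == "male"
  desc <- list(
    n = nrow(cohort),
    male_n = sum(male),
    age = c(mean = mean(cohort$age), sd = stats::sd(cohort$age)),
    hematocrit = c(mean = mean(cohort$hematocrit),
                   sd = stats::sd(cohort$hematocrit)),
    wall_thickness = c(mean = mean(cohort$wall_thickness),
                       sd = stats::sd(cohort$wall_thickness)),
    t1_myo = c(mean = mean(cohort$t1_myo), sd = stats::sd(cohort$t1_myo)),
    mean_blood_r1 = c(mean = mean(bs$mean_blood_r1),
                      sd = stats::sd(bs$mean_blood_r1)),
    mean_blood_r1star = c(mean = mean(bs$mean_blood_r1star),
                          sd = stats::sd(bs$mean_blood_r1star))
  )
  if (!is.null(corrected))
    desc$t1_myo_corrected <- c(mean = mean(corrected),
                               sd = stats::sd(corrected))
  desc
}

correlation_table <- function(cohort) {
  bs <- blood_summary(cohort)
  vars <- list(hematocrit = cohort$hematocrit,
               mean_blood_r1 = bs$mean_blood_r1,
               mean_blood_r1star = bs$mean_blood_r1star,
               wall_thickness = cohort$wall_thickness)
  do.call(rbind, lapply(names(vars), function(nm) {
    pr <- pearson_r(vars[[nm]], cohort$t1_myo)
    data.frame(variable = nm, r = pr$r, p = pr$p, n = pr$n)
  }))
}

sd_comparison <- function(cohort, corrected, cfg) {
  if (cfg$f_test_variant == "paired") {
    pm <- pitman_morgan(cohort$t1_myo, corrected)
    list(variant = "paired (Pitman-Morgan)",
         sd_uncorrected = pm$sd_x, sd_corrected = pm$sd_y,
         statistic = pm$t_statistic, p = pm$p_two_sided,
         percent_reduction = 100 * (1 - pm$sd_y / pm$sd_x))
  } else {
    vc <- f_test_sd(stats::sd(cohort$t1_myo), nrow(cohort),
                    stats::sd(corrected), nrow(cohort))
    list(variant = "independent (variance-ratio F)",
         sd_uncorrected = vc$sd_a, sd_corrected = vc$sd_b,
         statistic = vc$f_statistic, p = vc$p_two_sided,
         percent_reduction = vc$percent_reduction)
  }
}

sex_gap <- function(cohort, values, cfg) {
  male <- values[cohort$sex == "male"]
  female <- values[cohort$sex == "female"]
  cm <- compare_means(female, male, mode = "unpaired",
                      var_equal = cfg$t_test_variant == "pooled")
  list(male = c(mean = mean(male), sd = stats::sd(male), n = length(male)),
       female = c(mean = mean(female), sd = stats::sd(female),
                  n = length(female)),
       gap = mean(female) - mean(male),
       statistic = cm$statistic, p = cm$p)
}

stage_fragment <- function(cohort, corrected, cfg) {
  list(
    descriptives = cohort_descriptives(cohort, corrected),
    correlations = correlation_table(cohort),
    sd_comparison = sd_comparison(cohort, corrected, cfg),
    sex_gap_uncorrected = sex_gap(cohort, cohort$t1_myo, cfg),
    sex_gap_corrected = sex_gap(cohort, corrected, cfg),
    quartiles = list(
      hematocrit_uncorrected =
        quartile_compare(cohort, "hematocrit", "t1_myo"),
      hematocrit_corrected =
        quartile_compare(cohort, "hematocrit", corrected),
      wall_thickness_uncorrected =
        quartile_compare(cohort, "wall_thickness", "t1_myo"),
      wall_thickness_corrected =
        quartile_compare(cohort, "wall_thickness", corrected)
    ),
    range_reduction = range_reduction(cohort$t1_myo, corrected),
    sample_size = list(
      uncorrected = sample_size_two_means(50, stats::sd(cohort$t1_myo)),
      corrected = sample_size_two_means(50, stats::sd(corrected))
    )
  )
}

#' Run the derivation stage
#'
#' Simulates or loads the derivation cohort, fits the correction model,
#' and summarizes the in-sample effect of correction: SD before/after with
#' the configured variance test, sex gaps, quartile analyses, range
#' reduction, and the sample-size consequence.  If `config$out_dir` is set
#' the model file and cohort table are persisted there.
#'
#' @param config A [run_config()].
#' @return List with `model` (a `t1_correction_model`) and `fragment` (the
#'   derivation part of the run report).
#' @export
run_derivation <- function(config) {
  stopifnot(inherits(config, "t1_run_config"))
  cohort <- resolve_cohort(config$derivation, "derivation", config,
                           seed_offset = 0L)
  model <- derive_model(cohort, config$predictors)
  corrected <- apply_correction(cohort, model)
  fragment <- stage_fragment(cohort, corrected, config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(config$out_dir, "correction_model.json"))
    write_cohort(cohort, file.path(config$out_dir, "derivation_cohort.csv"))
  }
  list(model = model, fragment = fragment, cohort = cohort)
}

#' Run the validation stage
#'
#' Applies a frozen correction model (reference means and constants from
#' its derivation cohort) to an independent cohort and reports the
#' out-of-sample variance comparison, sex gaps, quartile analyses, and
#' sample-size pair.
#'
#' @param config A [run_config()].
#' @param model A `t1_correction_model` from [run_derivation()],
#'   [derive_model()] or [load_model()].
#' @param source Which configured cohort to validate on: `"validation"` or
#'   `"volunteer"`.
#' @return List with `fragment` and `cohort`.
#' @export
run_validation <- function(config, model, source = c("validation",
                                                     "volunteer")) {
  stopifnot(inherits(config, "t1_run_config"))
  source <- match.arg(source)
  offset <- if (source == "volunteer") 20000L else 10000L
  label <- if (source == "volunteer") "volunteer" else "validation"
  cohort <- resolve_cohort(config[[source]], label, config,
                           seed_offset = offset)
  if (is.null(cohort)) stop("no ", source, " cohort configured",
                            call. = FALSE)
  corrected <- apply_correction(cohort, model)
  fragment <- stage_fragment(cohort, corrected, config)
  if (!is.null(config$out_dir))
    write_cohort(cohort,
                 file.path(config$out_dir, paste0(label, "_cohort.csv")))
  list(fragment = fragment, cohort = cohort)
}

#' Run the full derivation/validation study
#'
#' Composes [run_derivation()], [run_validation()], and (when configured)
#' the volunteer arm, into a single reproducible run report.  Identical
#' configuration and seed give an identical report (timestamps aside).
#'
#' @param config A [run_config()].
#' @return A `t1_run_report`: `config` (with convention flags echoed),
#'   `config_hash` (MD5 of the canonical serialized configuration),
#'   `model`, and per-stage fragments `derivation`, `validation`,
#'   `volunteer`.
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "t1_run_config"))
  der <- run_derivation(config)
  report <- list(
    package_version = as.character(utils::packageVersion("bloodt1")),
    config = config,
    config_hash = config_hash(config),
    model = der$model,
    derivation = der$fragment
  )
  if (!is.null(config$validation))
    report$validation <- run_validation(config, der$model, "validation")$fragment
  if (!is.null(config$volunteer))
    report$volunteer <- run_validation(config, der$model, "volunteer")$fragment
  class(report) <- "t1_run_report"
  if (!is.null(config$out_dir))
    write_report(report, file.path(config$out_dir, "run_report.json"))
  report
}

#' MD5 hash of a run configuration
#'
#' The configuration is canonically serialized (YAML, cohort objects
#' replaced by digests of their values) and hashed, so a report can be
#' checked against the configuration that produced it.
#'
#' @param config A [run_config()].
#' @return Unnamed MD5 hex string.
#' @export
config_hash <- function(config) {
  canon <- lapply(unclass(config), function(v) {
    if (inherits(v, "t1_cohort")) {
      tmp <- tempfile(fileext = ".csv")
      on.exit(unlink(tmp), add = TRUE)
      write_cohort(v, tmp)
      unname(tools::md5sum(tmp))
    } else if (inherits(v, "t1_generator_params")) {
      unclass(v)
    } else v
  })
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(canon, tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

#' Write a run report as structured text
#'
#' @param report A `t1_run_report`.
#' @param path Output path (JSON).
#' @export
write_report <- function(report, path) {
  stripped <- rapply(unclass(report), unclass, how = "replace")
  writeLines(jsonlite::toJSON(stripped, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE, dataframe = "rows"),
             path)
  invisible(path)
}

#' @export
print.t1_run_report <- function(x, ...) {
  cat("== bloodt1 run report ==\n")
  cat(sprintf("package %s, seed %d, config hash %s\n",
              x$package_version, x$config$seed, x$config_hash))
  cat(sprintf("conventions: %s t-test, %s variance test, %s percentiles\n",
              x$config$t_test_variant, x$config$f_test_variant,
              x$config$percentile_rule))
  cat(sprintf("\nmodel: %s on n = %d, R^2 = %.3f\n",
              paste(x$model$predictor_names, collapse = " + "),
              x$model$n_fit, x$model$r_squared))
  for (stage in intersect(c("derivation", "validation", "volunteer"),
                          names(x))) {
    f <- x[[stage]]
    d <- f$descriptives
    cat(sprintf("\n-- %s cohort (n = %d, %d male) --\n",
                stage, d$n, d$male_n))
    cat(sprintf("  myocardial T1: %.0f +/- %.1f ms uncorrected, %.0f +/- %.1f ms corrected\n",
                d$t1_myo["mean"], d$t1_myo["sd"],
                d$t1_myo_corrected["mean"], d$t1_myo_corrected["sd"]))
    sc <- f$sd_comparison
    cat(sprintf("  SD reduction %.1f%% (%s, p = %s)\n",
                sc$percent_reduction, sc$variant, format_p(sc$p)))
    gu <- f$sex_gap_uncorrected; gc <- f$sex_gap_corrected
    cat(sprintf("  sex gap (F - M): %.1f ms (p = %s) -> %.1f ms (p = %s) after correction\n",
                gu$gap, format_p(gu$p), gc$gap, format_p(gc$p)))
    qh <- f$quartiles$hematocrit_uncorrected
    cat(sprintf("  hematocrit quartile cuts: <%.1f%% vs >%.1f%%, uncorrected p = %s, corrected p = %s\n",
                qh$cut_points["lower"], qh$cut_points["upper"],
                format_p(qh$p), format_p(f$quartiles$hematocrit_corrected$p)))
    ss <- f$sample_size
    cat(sprintf("  sample size for a 50 ms difference: %d -> %d total\n",
                ss$uncorrected$n_total, ss$corrected$n_total))
    cat(sprintf("  range reduction %.1f%%\n", f$range_reduction))
  }
  invisible(x)
}
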