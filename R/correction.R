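#' Convert T1 to the relaxation rate R1
#'
#' `R1 = 1/T1`.  Rates, unlike times, are linear in the concentration of
#' relaxing species, which is why the correction model works on R1/R1*.
#'
#' @param t1 T1 values in ms; must be positive.
#' @return R1 in ms^-1.
#' @examples
#' t1_to_r1(1562.5)  # 0.00064 ms^-1, a typical mean blood R1
#' @export
t1_to_r1 <- function(t1) {
  if (!is.numeric(t1) || any(is.na(t1)) || any(t1 <= 0))
    stop("`t1` must be positive (ms)", call. = FALSE)
  1 / t1
}

#' Per-subject blood summary
#'
#' Averages the LV and RV blood-pool values in the T1 domain first and then
#' converts to rates: `mean_blood_t1 = (t1_blood_lv + t1_blood_rv)/2`,
#' `mean_blood_r1 = 1/mean_blood_t1`, likewise for T1*.
#'
#' @param cohort A `t1_cohort` or any data frame carrying the blood columns.
#' @return A data frame with columns `mean_blood_t1`, `mean_blood_t1star`,
#'   `mean_blood_r1`, `mean_blood_r1star` and `hematocrit`, one row per
#'   subject.
#' @export
blood_summary <- function(cohort) {
  need <- c("t1_blood_lv", "t1_blood_rv")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("missing blood column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need)
    if (any(is.na(cohort[[col]])) || any(cohort[[col]] <= 0))
      stop("missing or non-positive values in `", col, "`", call. = FALSE)
  mt1 <- (cohort$t1_blood_lv + cohort$t1_blood_rv) / 2
  out <- data.frame(mean_blood_t1 = mt1, mean_blood_r1 = 1 / mt1)
  has_star <- all(c("t1star_blood_lv", "t1star_blood_rv") %in% names(cohort)) &&
    !anyNA(cohort$t1star_blood_lv) && !anyNA(cohort$t1star_blood_rv)
  if (has_star) {
    if (any(cohort$t1star_blood_lv <= 0) || any(cohort$t1star_blood_rv <= 0))
      stop("non-positive blood T1* values", call. = FALSE)
    mt1s <- (cohort$t1star_blood_lv + cohort$t1star_blood_rv) / 2
    out$mean_blood_t1star <- mt1s
    out$mean_blood_r1star <- 1 / mt1s
  } else {
    out$mean_blood_t1star <- NA_real_
    out$mean_blood_r1star <- NA_real_
  }
  out$hematocrit <- if ("hematocrit" %in% names(cohort))
    cohort$hematocrit else NA_real_
  out
}

correction_predictors <- c("mean_blood_r1", "mean_blood_r1star", "hematocrit")

# plausible ranges used for unit-safety checks (10x outside -> reject)
predictor_ranges <- list(
  mean_blood_r1 = c(4e-4, 9e-4),
  mean_blood_r1star = c(4e-4, 9e-4),
  hematocrit = c(15, 65)
)
predictor_units <- c(mean_blood_r1 = "ms^-1", mean_blood_r1star = "ms^-1",
                     hematocrit = "%")

check_predictor_units <- function(name, values) {
  rng <- predictor_ranges[[name]]
  if (is.null(rng)) return(invisible())
  lo <- rng[1] / 10; hi <- rng[2] * 10
  if (any(values < lo | values > hi, na.rm = TRUE))
    stop(sprintf(paste0("`%s` values outside the plausible range [%g, %g] %s ",
                        "by more than 10x; check units (rates must be ms^-1, ",
                        "not s^-1)"),
                 name, rng[1], rng[2], predictor_units[[name]]),
         call. = FALSE)
  invisible()
}

predictor_matrix <- function(cohort, predictor_names) {
  bs <- blood_summary(cohort)
  unknown <- setdiff(predictor_names, correction_predictors)
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  X <- sapply(predictor_names, function(nm) bs[[nm]])
  X <- matrix(X, nrow = nrow(bs),
              dimnames = list(NULL, predictor_names))
  if (anyNA(X)) {
    bad <- predictor_names[colSums(is.na(X)) > 0]
    stop("predictor(s) with missing values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in predictor_names) check_predictor_units(nm, X[, nm])
  X
}

#' Derive a blood correction model by multivariate regression
#'
#' Fits ordinary least squares of septal myocardial T1 on the chosen blood
#' predictors in a derivation cohort.  The fitted coefficients are the
#' correction constants, and the cohort means of the predictors are frozen
#' as the model's reference means, making the model portable to other
#' cohorts (see [apply_correction()]).
#'
#' @param cohort A `t1_cohort` with `t1_myo` and the blood columns.
#' @param predictor_names Ordered subset of `"mean_blood_r1"`,
#'   `"mean_blood_r1star"`, `"hematocrit"`.  The default is the final
#'   two-predictor model (hematocrit adds nothing once the image-based
#'   rates are in the model).
#' @return A `t1_correction_model` with elements `predictor_names`,
#'   `constants` (ms per predictor unit), `reference_means`, `intercept`,
#'   `r_squared`, `standardized_betas` (coefficient * SD(x)/SD(y)),
#'   `n_fit`, `residual_sd`, `cohort_label` and `units`.
#' @examples
#' coh <- simulate_cohort(patient_derivation_preset(n = 200), "derivation")
#' m <- derive_model(coh)
#' m$r_squared
#' @export
derive_model <- function(cohort,
                         predictor_names = c("mean_blood_r1",
                                             "mean_blood_r1star")) {
  if (anyDuplicated(predictor_names))
    stop("duplicated predictor name(s): ",
         paste(unique(predictor_names[duplicated(predictor_names)]),
               collapse = ", "), call. = FALSE)
  if (!"t1_myo" %in% names(cohort))
    stop("cohort lacks `t1_myo`", call. = FALSE)
  X <- predictor_matrix(cohort, predictor_names)
  y <- cohort$t1_myo
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1)
    stop(sprintf("cohort too small: n = %d with %d predictor(s); need n > %d",
                 n, k, k + 1), call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor(s): ",
         paste(predictor_names[sds == 0], collapse = ", "), call. = FALSE)
  if (k > 1) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    if (any(abs(cc) > 1 - 1e-12)) {
      ij <- which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)[1, ]
      stop(sprintf("perfectly collinear predictors: %s and %s",
                   predictor_names[ij[2]], predictor_names[ij[1]]),
           call. = FALSE)
    }
  }

  df <- data.frame(.t1_myo = y, X, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", predictor_names),
                                      response = ".t1_myo"), data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs))
    stop("rank-deficient design: collinear predictors", call. = FALSE)
  constants <- coefs[-1]
  names(constants) <- predictor_names

  model <- list(
    predictor_names = predictor_names,
    constants = constants,
    reference_means = colMeans(X),
    intercept = unname(coefs[1]),
    r_squared = 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2),
    standardized_betas = constants * sds / stats::sd(y),
    n_fit = n,
    residual_sd = stats::sd(stats::residuals(fit)),
    response_sd = stats::sd(y),
    cohort_label = if ("cohort" %in% names(cohort))
      as.character(cohort$cohort[1]) else NA_character_,
    units = predictor_units[predictor_names],
    # date-resolution provenance keeps repeated runs byte-identical
    created = format(Sys.Date())
  )
  class(model) <- "t1_correction_model"
  model
}

#' @export
print.t1_correction_model <- function(x, ...) {
  cat("<t1_correction_model>\n")
  cat(sprintf("  fitted on n = %d (%s cohort), R^2 = %.3f\n",
              x$n_fit, x$cohort_label, x$r_squared))
  for (i in seq_along(x$predictor_names))
    cat(sprintf("  %-18s constant = %12.6g ms/(%s), reference mean = %.6g, std beta = %.3f\n",
                x$predictor_names[i], x$constants[i], x$units[i],
                x$reference_means[i], x$standardized_betas[i]))
  invisible(x)
}

#' Apply a blood correction model
#'
#' Corrects myocardial T1 per subject as
#' `T1_corrected = T1_uncorrected + sum_j constant_j * (Xbar_j - X_j)`,
#' where `Xbar_j` are the model's frozen reference means (those of its
#' derivation cohort) and `X_j` the subject's predictor values.  Using the
#' frozen means shifts only the corrected cohort mean, never its SD, so
#' every SD endpoint is invariant to that convention.
#'
#' @param cohort A `t1_cohort` (or data frame) carrying `t1_myo` and every
#'   predictor named by the model.
#' @param model A `t1_correction_model` from [derive_model()] or
#'   [load_model()].
#' @return Numeric vector of corrected myocardial T1 (ms), one per subject.
#' @examples
#' coh <- simulate_cohort(patient_derivation_preset(n = 200), "derivation")
#' m <- derive_model(coh)
#' sd(coh$t1_myo); sd(apply_correction(coh, m))  # shrinks by sqrt(1 - R^2)
#' @export
apply_correction <- function(cohort, model) {
  stopifnot(inherits(model, "t1_correction_model"))
  if (!"t1_myo" %in% names(cohort))
    stop("cohort lacks `t1_myo`", call. = FALSE)
  X <- predictor_matrix(cohort, model$predictor_names)
  delta <- sweep(-X, 2, model$reference_means, `+`)  # Xbar - X
  cohort$t1_myo + as.vector(delta %*% model$constants)
}

#' Save or load a correction model
#'
#' Models are serialized as structured JSON text with explicit unit strings
#' per predictor and fit provenance (cohort label, n, creation time).
#' Numeric fields are written at full double precision so the round trip is
#' bit-exact.
#'
#' @param model A `t1_correction_model`.
#' @param path File path (JSON).
#' @return `load_model()` returns a `t1_correction_model`; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "t1_correction_model"))
  payload <- list(
    format = "bloodt1/correction-model",
    version = 1L,
    predictor_names = model$predictor_names,
    constants = as.list(stats::setNames(num_to_hex(model$constants),
                                        model$predictor_names)),
    reference_means = as.list(stats::setNames(num_to_hex(model$reference_means),
                                              model$predictor_names)),
    units = as.list(stats::setNames(unname(model$units),
                                    model$predictor_names)),
    intercept = num_to_hex(model$intercept),
    r_squared = num_to_hex(model$r_squared),
    standardized_betas = as.list(stats::setNames(
      num_to_hex(model$standardized_betas), model$predictor_names)),
    n_fit = model$n_fit,
    residual_sd = num_to_hex(model$residual_sd),
    response_sd = num_to_hex(model$response_sd),
    cohort_label = model$cohort_label,
    created = model$created
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}

# doubles as %a hex strings: lossless, locale-proof text round trip
num_to_hex <- function(x) sprintf("%a", as.numeric(x))
hex_to_num <- function(s) {
  v <- suppressWarnings(vapply(s, function(si)
    strtoi_double(si), numeric(1), USE.NAMES = FALSE))
  v
}
strtoi_double <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("malformed numeric field in model file: ", s,
                     call. = FALSE)
  v
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("no such model file: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse model file: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(payload$format, "bloodt1/correction-model"))
    stop("not a bloodt1 correction-model file (missing format marker)",
         call. = FALSE)
  required <- c("predictor_names", "constants", "reference_means", "units",
                "intercept", "r_squared", "standardized_betas", "n_fit",
                "residual_sd", "response_sd", "cohort_label", "created")
  miss <- setdiff(required, names(payload))
  if (length(miss))
    stop("model file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pn <- payload$predictor_names
  unknown <- setdiff(pn, correction_predictors)
  if (length(unknown))
    stop("model file names unknown predictor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  named_num <- function(field) {
    vals <- unlist(payload[[field]])
    miss <- setdiff(pn, names(vals))
    if (length(miss))
      stop("model file `", field, "` missing entries for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    stats::setNames(hex_to_num(vals[pn]), pn)
  }
  model <- list(
    predictor_names = pn,
    constants = named_num("constants"),
    reference_means = named_num("reference_means"),
    intercept = strtoi_double(payload$intercept),
    r_squared = strtoi_double(payload$r_squared),
    standardized_betas = named_num("standardized_betas"),
    n_fit = as.integer(payload$n_fit),
    residual_sd = strtoi_double(payload$residual_sd),
    response_sd = strtoi_double(payload$response_sd),
    cohort_label = payload$cohort_label,
    units = stats::setNames(unlist(payload$units)[pn], pn),
    created = payload$created
  )
  class(model) <- "t1_correction_model"
  model
}
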