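#' Build a 2D short-axis digital phantom
#'
#' Lays out a mid-ventricular short-axis slice on a square pixel grid:
#' a circular LV blood pool, a myocardial ring whose RV-facing sector is
#' labelled `septum` (the remainder `free_wall`), and an adjacent RV blood
#' pool crescent.  Each labelled pixel carries its region's ground-truth T1
#' plus optional Gaussian per-pixel jitter.
#'
#' @param region_t1 Named vector of ground-truth T1 (ms) for `lv_blood`,
#'   `rv_blood`, `septum`, `free_wall`; all > 0.
#' @param grid_size Grid side length in pixels.
#' @param pixel_size_mm Pixel size (mm).
#' @param jitter_sd Per-pixel T1 jitter SD (ms).
#' @param seed Integer seed for the jitter.
#' @param septum_half_angle Half-width (radians) of the RV-facing sector of
#'   the ring labelled as septum.
#' @return A `t1_phantom`: list with `t1` (matrix, ms; NA outside labelled
#'   regions), `labels` (character matrix with `"background"` elsewhere),
#'   `region_t1` (ground truth), `pixel_size_mm`.
#' @export
build_phantom <- function(region_t1 = c(lv_blood = 1562.5, rv_blood = 1540,
                                        septum = 1030, free_wall = 1030),
                          grid_size = 64, pixel_size_mm = 2,
                          jitter_sd = 0, seed = 1L,
                          septum_half_angle = pi / 3.5) {
  needed <- c("lv_blood", "rv_blood", "septum", "free_wall")
  miss <- setdiff(needed, names(region_t1))
  if (length(miss))
    stop("`region_t1` missing region(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(region_t1[needed] <= 0))
    stop("all region T1 values must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  n <- as.integer(grid_size)
  if (n < 16) stop("`grid_size` must be at least 16", call. = FALSE)

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index

  lv_c <- c(0.62, 0.50) * n
  lv_r <- 0.17 * n
  ring_outer <- 0.28 * n
  rv_c <- c(0.24, 0.50) * n
  rv_r <- 0.16 * n

  d_lv <- sqrt((xs - lv_c[1])^2 + (ys - lv_c[2])^2)
  d_rv <- sqrt((xs - rv_c[1])^2 + (ys - rv_c[2])^2)
  lv <- d_lv <= lv_r
  ring <- d_lv > lv_r & d_lv <= ring_outer
  # angle from the LV centre; the RV lies toward -x (angle pi)
  ang <- atan2(ys - lv_c[2], xs - lv_c[1])
  septum <- ring & abs(abs(ang) - pi) < septum_half_angle
  free_wall <- ring & !septum
  rv <- d_rv <= rv_r & !ring & !lv

  if (!any(septum))
    stop("geometry leaves an empty septum band", call. = FALSE)

  labels <- matrix("background", n, n)
  labels[rv] <- "rv_blood"
  labels[free_wall] <- "free_wall"
  labels[septum] <- "septum"
  labels[lv] <- "lv_blood"

  t1 <- matrix(NA_real_, n, n)
  for (reg in needed) t1[labels == reg] <- region_t1[[reg]]
  if (jitter_sd > 0) {
    idx <- which(labels != "background")
    t1[idx] <- withr::with_seed(seed,
      t1[idx] + stats::rnorm(length(idx), 0, jitter_sd))
    t1[idx] <- pmax(t1[idx], 1)
  }

  out <- list(t1 = t1, labels = labels,
              region_t1 = region_t1[needed],
              pixel_size_mm = pixel_size_mm)
  class(out) <- "t1_phantom"
  out
}

#' @export
print.t1_phantom <- function(x, ...) {
  counts <- table(x$labels[x$labels != "background"])
  cat(sprintf("<t1_phantom> %dx%d grid, %.1f mm pixels\n",
              nrow(x$t1), ncol(x$t1), x$pixel_size_mm))
  for (reg in names(x$region_t1))
    cat(sprintf("  %-10s T1 = %7.1f ms  (%d px)\n", reg, x$region_t1[[reg]],
                counts[[reg]]))
  invisible(x)
}

#' Acquire T1 and T1* maps from a phantom
#'
#' Simulates the full imaging path: for every labelled pixel, synthesizes
#' 5(3)3 MOLLI samples from the pixel's ground-truth T1 (via
#' [synthesize_signal()]) and fits the three-parameter model (via
#' [fit_molli()]), yielding per-pixel T1* and Look-Locker-corrected T1
#' maps.
#'
#' @param phantom A [build_phantom()] object.
#' @param scheme A [molli_scheme()].
#' @param amplitude Equilibrium signal (a.u.).
#' @param inversion_efficiency Inversion efficiency in (0, 1].
#' @param noise_sd Per-sample noise SD (a.u.); e.g. 1% noise at the default
#'   amplitude of 1000 is `noise_sd = 10`.
#' @param seed Integer seed for all per-pixel noise.
#' @param readout_rate Readout-induced rate increment (ms^-1).
#' @return List with matrices `t1_map` and `t1star_map` (ms; NA outside
#'   labelled regions).
#' @export
acquire_maps <- function(phantom, scheme = molli_scheme(), amplitude = 1000,
                         inversion_efficiency = 1, noise_sd = 0, seed = 1L,
                         readout_rate = 1.7e-4) {
  stopifnot(inherits(phantom, "t1_phantom"))
  ti <- scheme_tis(scheme)
  idx <- which(!is.na(phantom$t1))
  t1_true <- phantom$t1[idx]
  t1s_true <- 1 / (1 / t1_true + readout_rate)
  a <- amplitude * t1s_true / t1_true
  b <- a + inversion_efficiency * amplitude
  # signals: pixels x inversion times, one seed for the whole acquisition
  s <- matrix(a, length(a), length(ti)) - b * exp(-outer(1 / t1s_true, ti))
  if (noise_sd > 0)
    s <- s + withr::with_seed(seed,
      matrix(stats::rnorm(length(s), 0, noise_sd), nrow(s), ncol(s)))

  t1_map <- t1star_map <- matrix(NA_real_, nrow(phantom$t1),
                                 ncol(phantom$t1))
  for (j in seq_along(idx)) {
    fit <- fit_molli(data.frame(ti = ti, signal = s[j, ]))
    t1_map[idx[j]] <- fit$t1_ll
    t1star_map[idx[j]] <- fit$t1_star
  }
  list(t1_map = t1_map, t1star_map = t1star_map)
}

# 4-neighbourhood binary erosion repeated `margin` times
erode_mask <- function(mask, margin) {
  m <- mask
  for (i in seq_len(margin)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    down <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    left <- cbind(m[, -1, drop = FALSE], FALSE)
    right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m & up & down & left & right
  }
  m
}

#' Extract ROI measurements from maps
#'
#' Computes the arithmetic mean of each region's pixels.  The septal ROI is
#' first eroded by `erosion_margin` pixels to emulate conservative ROI
#' placement away from the blood-pool interface; blood-pool ROIs use the
#' full labelled regions.
#'
#' @param t1_map,t1star_map Matrices from [acquire_maps()] (or the phantom
#'   ground truth).
#' @param labels Character label matrix sharing the grid.
#' @param erosion_margin Pixels to erode off the septal ROI (>= 0).
#' @return Named list: `t1_myo_septum`, `t1_blood_lv`, `t1_blood_rv`,
#'   `t1star_blood_lv`, `t1star_blood_rv` (ms), plus `n_septum_px`.
#' @export
measure_rois <- function(t1_map, t1star_map, labels, erosion_margin = 1) {
  if (!all(dim(t1_map) == dim(labels)) ||
      !all(dim(t1star_map) == dim(labels)))
    stop("maps and labels must share the same grid", call. = FALSE)
  if (erosion_margin < 0) stop("`erosion_margin` must be >= 0",
                               call. = FALSE)
  sept <- labels == "septum"
  if (erosion_margin > 0) sept <- erode_mask(sept, erosion_margin)
  if (!any(sept))
    stop("septal ROI empty after erosion by ", erosion_margin, " pixel(s)",
         call. = FALSE)
  region_mean <- function(map, mask) mean(map[mask], na.rm = TRUE)
  list(
    t1_myo_septum = region_mean(t1_map, sept),
    t1_blood_lv = region_mean(t1_map, labels == "lv_blood"),
    t1_blood_rv = region_mean(t1_map, labels == "rv_blood"),
    t1star_blood_lv = region_mean(t1star_map, labels == "lv_blood"),
    t1star_blood_rv = region_mean(t1star_map, labels == "rv_blood"),
    n_septum_px = sum(sept)
  )
}

#' End-to-end phantom demo: one synthetic subject
#'
#' Builds a phantom, acquires T1/T1* maps through the MOLLI signal path,
#' measures the ROIs, and packages the result as a one-row cohort table
#' suitable for [apply_correction()].
#'
#' @inheritParams build_phantom
#' @inheritParams acquire_maps
#' @param subject_id,sex,hematocrit,age,wall_thickness Demographics for the
#'   cohort row (not derivable from the image).
#' @param erosion_margin Septal ROI erosion (pixels).
#' @return List with `phantom`, `maps`, `rois` and `cohort_row` (a
#'   one-row `t1_cohort`).
#' @export
molli_demo <- function(region_t1 = c(lv_blood = 1562.5, rv_blood = 1540,
                                     septum = 1030, free_wall = 1030),
                       grid_size = 64, jitter_sd = 0, noise_sd = 10,
                       seed = 1L, scheme = molli_scheme(),
                       erosion_margin = 1,
                       subject_id = "phantom-001", sex = "male",
                       hematocrit = 40, age = 50, wall_thickness = 10) {
  phantom <- build_phantom(region_t1 = region_t1, grid_size = grid_size,
                           jitter_sd = jitter_sd, seed = seed)
  maps <- acquire_maps(phantom, scheme = scheme, noise_sd = noise_sd,
                       seed = seed + 1L)
  rois <- measure_rois(maps$t1_map, maps$t1star_map, phantom$labels,
                       erosion_margin = erosion_margin)
  row <- data.frame(
    subject_id = subject_id, cohort = "derivation", sex = sex, age = age,
    hematocrit = hematocrit,
    t1_myo = rois$t1_myo_septum,
    t1_blood_lv = rois$t1_blood_lv,
    t1_blood_rv = rois$t1_blood_rv,
    t1star_blood_lv = rois$t1star_blood_lv,
    t1star_blood_rv = rois$t1star_blood_rv,
    wall_thickness = wall_thickness,
    stringsAsFactors = FALSE
  )
  list(phantom = phantom, maps = maps, rois = rois,
       cohort_row = as_t1_cohort(row))
}

#' Write or read a map as plain matrix text
#'
#' Maps are stored as whitespace-delimited numeric text with `#`-prefixed
#' sidecar metadata lines (pixel size); label matrices can be stored the
#' same way after integer encoding.
#'
#' @param map Numeric matrix.
#' @param path File path.
#' @param pixel_size_mm Pixel size recorded in the header.
#' @return `read_map()` returns a list with `map` and `pixel_size_mm`.
#' @export
write_map <- function(map, path, pixel_size_mm = 2) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bloodt1 map, pixel_size_mm: %.17g, dim: %d %d",
                     pixel_size_mm, nrow(map), ncol(map)), con)
  utils::write.table(map, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# bloodt1 map", header))
    stop("not a bloodt1 map file", call. = FALSE)
  px <- as.numeric(sub(".*pixel_size_mm: ([-0-9.e+]+),.*", "\\1", header))
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  list(map = m, pixel_size_mm = px)
}
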