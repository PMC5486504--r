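# Inverse-CDF sampler for the truncated normal (used for mean+-SD calibrated
# metrics; Pa-valued metrics are truncated at 0, LSAR at [0, 1]).
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  pl <- stats::pnorm((lower - mean) / sd)
  pu <- stats::pnorm((upper - mean) / sd)
  u <- stats::runif(n, pl, pu)
  mean + sd * stats::qnorm(u)
}

# Closed-form mean of the truncated normal (oracle-facing helper).
truncnorm_mean <- function(mean, sd, lower = 0, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Log-normal parameters from a printed median and a single "quartiles"
# number, interpreted either as the interquartile range (default) or as Q3.
lnorm_from_quartiles <- function(median, quartiles,
                                 interpretation = c("iqr", "q3")) {
  interpretation <- match.arg(interpretation)
  z75 <- stats::qnorm(0.75)
  meanlog <- log(median)
  sdlog <- if (interpretation == "q3") {
    if (quartiles <= median) stop("config error: Q3 must exceed the median")
    (log(quartiles) - meanlog) / z75
  } else {
    asinh(quartiles / (2 * median)) / z75
  }
  list(meanlog = meanlog, sdlog = sdlog)
}

dist_spec_norm <- function(mean, sd) list(dist = "truncnorm", mean = mean, sd = sd)
dist_spec_lnorm <- function(median, quartiles) {
  list(dist = "lognormal", median = median, quartiles = quartiles)
}

#' Default metric calibration for the four study groups
#'
#' Per-group sampling distributions for MWSS, HWSS, PWSS (Pa) and LSAR,
#' calibrated to the published group descriptives of a 72-aneurysm cohort:
#' within the narrow-necked stratum all four metrics are mean+-SD
#' (truncated normal); within the wide-necked stratum MWSS is
#' median/quartiles (log-normal) and the rest mean+-SD. The aneurysm-parent
#' ratios are never sampled: they are recomputed per record from the sampled
#' MWSS, HWSS and PWSS so that the metric invariants hold by construction.
#'
#' @return A nested list `group -> metric -> distribution spec`.
#' @export
default_metric_calibration <- function() {
  list(
    `ruptured-narrow` = list(
      MWSS = dist_spec_norm(1.96, 1.30),
      HWSS = dist_spec_norm(9.08, 6.64),
      PWSS = dist_spec_norm(7.85, 3.98),
      LSAR = dist_spec_norm(0.340, 0.308)),
    `unruptured-narrow` = list(
      MWSS = dist_spec_norm(3.33, 1.45),
      HWSS = dist_spec_norm(8.19, 3.69),
      PWSS = dist_spec_norm(7.14, 3.08),
      LSAR = dist_spec_norm(0.093, 0.125)),
    `ruptured-wide` = list(
      MWSS = dist_spec_lnorm(4.04, 5.24),
      HWSS = dist_spec_norm(14.58, 10.93),
      PWSS = dist_spec_norm(8.94, 6.13),
      LSAR = dist_spec_norm(0.075, 0.082)),
    `unruptured-wide` = list(
      MWSS = dist_spec_lnorm(4.44, 2.96),
      HWSS = dist_spec_norm(9.95, 3.73),
      PWSS = dist_spec_norm(7.73, 2.53),
      LSAR = dist_spec_norm(0.026, 0.032))
  )
}

#' Configure a synthetic aneurysm cohort
#'
#' The default composition emulates the study population: 72 aneurysms,
#' 41 ruptured and 31 unruptured, each label split between the narrow-necked
#' (aspect ratio >= 1.4, neck < 4 mm) and wide-necked strata. The published
#' tables do not report the per-label stratum counts, so both labels default
#' to an even split.
#'
#' @param n_ruptured,n_unruptured Group sizes.
#' @param narrow_fraction Named numeric: fraction of each label assigned to
#'   the narrow-necked stratum.
#' @param mode `"metric"` (metrics drawn from group-calibrated
#'   distributions) or `"geometry"` (geometry parameters drawn, CFD run).
#' @param seed Integer seed; recorded in the output. Each record derives its
#'   own substream from it, so cohorts are reproducible under parallel or
#'   per-record execution.
#' @param calibration Metric-mode distributions, see
#'   [default_metric_calibration()].
#' @param quartile_interpretation `"iqr"` or `"q3"`: reading of the single
#'   printed "quartiles" figure for median-reported metrics.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ruptured = 41, n_unruptured = 31,
                          narrow_fraction = c(ruptured = 0.5,
                                              unruptured = 0.5),
                          mode = c("metric", "geometry"),
                          seed = 1L,
                          calibration = default_metric_calibration(),
                          quartile_interpretation = c("iqr", "q3")) {
  mode <- match.arg(mode)
  quartile_interpretation <- match.arg(quartile_interpretation)
  if (n_ruptured <= 0 || n_unruptured <= 0) stop("config error: counts must be > 0")
  if (any(narrow_fraction < 0 | narrow_fraction > 1)) {
    stop("config error: narrow_fraction must be in [0, 1]")
  }
  for (g in names(calibration)) {
    cal <- calibration[[g]]
    for (mname in names(cal)) {
      d <- cal[[mname]]
      if (d$dist == "truncnorm" && d$sd <= 0) {
        stop("config error: non-positive scale for ", g, " ", mname)
      }
      if (d$dist == "lognormal" && (d$median <= 0 || d$quartiles <= 0)) {
        stop("config error: non-positive location/scale for ", g, " ", mname)
      }
    }
    mw <- cal$MWSS; hw <- cal$HWSS
    mw_loc <- if (mw$dist == "truncnorm") mw$mean else mw$median
    hw_loc <- if (hw$dist == "truncnorm") hw$mean else hw$median
    if (hw_loc < mw_loc) {
      stop("config error: HWSS location below MWSS location for group ", g)
    }
  }
  structure(list(n_ruptured = as.integer(n_ruptured),
                 n_unruptured = as.integer(n_unruptured),
                 narrow_fraction = narrow_fraction,
                 mode = mode, seed = as.integer(seed),
                 calibration = calibration,
                 quartile_interpretation = quartile_interpretation),
            class = "cohort_config")
}

cohort_group_plan <- function(config) {
  n_nar_r <- round(config$n_ruptured * config$narrow_fraction[["ruptured"]])
  n_nar_u <- round(config$n_unruptured * config$narrow_fraction[["unruptured"]])
  data.frame(
    group = c("ruptured-narrow", "ruptured-wide",
              "unruptured-narrow", "unruptured-wide"),
    rupture_label = c("ruptured", "ruptured", "unruptured", "unruptured"),
    neck_category = c("narrow", "wide", "narrow", "wide"),
    n = c(n_nar_r, config$n_ruptured - n_nar_r,
          n_nar_u, config$n_unruptured - n_nar_u)
  )
}

record_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 10007 + idx * 7919) %% 2147483647)
}

draw_metric <- function(spec, interpretation) {
  if (spec$dist == "truncnorm") {
    lim <- spec[["upper"]] %||% Inf
    rtruncnorm(1, spec$mean, spec$sd, lower = 0, upper = lim)
  } else {
    pars <- lnorm_from_quartiles(spec$median, spec$quartiles, interpretation)
    stats::rlnorm(1, pars$meanlog, pars$sdlog)
  }
}

sample_record_morphology <- function(category) {
  if (category == "narrow") {
    neck <- stats::runif(1, 1.5, 3.9)
    ar <- stats::runif(1, 1.4, 3.10)
    height <- ar * neck
  } else {
    neck <- stats::runif(1, 2.5, 6.0)
    ar <- stats::runif(1, 0.49, 1.39)
    height <- ar * neck
  }
  # dome arc length of the 2-D profile scales with the sac perimeter; a
  # semicircular-cap surrogate keeps it consistent with height and neck
  dome <- pi * (height + neck / 2) / 2
  list(height = height, neck_width = neck, aspect_ratio = ar,
       dome_measure = dome)
}

#' Sample a metric-mode synthetic cohort
#'
#' Draws the four base metrics (MWSS, HWSS, PWSS, LSAR) per record from the
#' group-calibrated distributions, enforces `HWSS >= MWSS` by redrawing the
#' pair when violated, truncates LSAR to `[0, 1]` and Pa-valued metrics at
#' zero, and derives the M-P and H-P ratios from the sampled values.
#' Morphology (height, neck width, aspect ratio) is drawn uniformly over
#' the stratum-consistent clinical ranges so every record also carries a
#' valid neck classification.
#'
#' @param config A `cohort_config` with `mode = "metric"`.
#' @return A data frame of class `aneurysm_cohort`, one row per aneurysm,
#'   with the seed and config recorded as attributes.
#' @export
sample_metric_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "metric") stop("config error: mode must be 'metric'")
  plan <- cohort_group_plan(config)
  rows <- list()
  idx <- 0L
  for (gi in seq_len(nrow(plan))) {
    grp <- plan$group[gi]
    cal <- config$calibration[[grp]]
    if (is.null(cal)) stop("config error: no calibration for group ", grp)
    for (k in seq_len(plan$n[gi])) {
      idx <- idx + 1L
      set.seed(record_seed(config$seed, idx))
      morph <- sample_record_morphology(plan$neck_category[gi])
      for (try in 1:100) {
        mwss <- draw_metric(cal$MWSS, config$quartile_interpretation)
        hwss <- draw_metric(cal$HWSS, config$quartile_interpretation)
        if (hwss >= mwss) break
      }
      if (hwss < mwss) hwss <- mwss  # degenerate calibration fallback
      pwss <- draw_metric(cal$PWSS, config$quartile_interpretation)
      lsar_spec <- cal$LSAR
      lsar <- rtruncnorm(1, lsar_spec$mean, lsar_spec$sd, 0, 1)
      rows[[idx]] <- data.frame(
        id = sprintf("an%03d", idx),
        rupture_label = plan$rupture_label[gi],
        neck_category = plan$neck_category[gi],
        group = grp,
        height = morph$height, neck_width = morph$neck_width,
        aspect_ratio = morph$aspect_ratio, dome_measure = morph$dome_measure,
        MWSS = mwss, HWSS = hwss, PWSS = pwss, LSAR = lsar,
        MP_ratio = mwss / pwss, HP_ratio = hwss / pwss
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aneurysm_cohort", "data.frame")
  attr(out, "seed") <- config$seed
  attr(out, "config") <- config
  out
}

# Stratum-conditional geometry parameter draws. Narrow-necked sacs are deep
# constricted-neck shapes; wide-necked sacs are hemispherical bumps or
# shallow circular sacs (possibly with neck >= 4 mm). Rejection sampling
# enforces the intended classification.
draw_geometry_params <- function(category) {
  if (category == "narrow") {
    w <- stats::runif(1, 1.6, 2.8)
    r <- stats::runif(1, 1.8, 3.0)
    off_min <- sqrt(r^2 - (w / 2)^2)
    off <- off_min + stats::runif(1, 0.3, 2.5)
    list(shape_family = "circular-sac-with-neck", neck_width = w,
         sac_size = r, sac_offset = off)
  } else if (stats::runif(1) < 0.5) {
    r <- stats::runif(1, 1.6, 3.0)
    list(shape_family = "hemispherical-bump", neck_width = 2 * r,
         sac_size = r, sac_offset = 0)
  } else {
    r <- stats::runif(1, 2.1, 3.0)
    w <- stats::runif(1, 3.0, 2 * r - 0.2)
    off_min <- sqrt(r^2 - (w / 2)^2)
    off <- off_min + stats::runif(1, 0, 0.5)
    list(shape_family = "circular-sac-with-neck", neck_width = w,
         sac_size = r, sac_offset = off)
  }
}

#' Sample a geometry-mode synthetic cohort
#'
#' Draws parametric sidewall geometries per stratum (deep constricted-neck
#' sacs for the narrow stratum; hemispherical bumps and shallow or
#' wide-necked circular sacs for the wide stratum). Each accepted geometry
#' is verified post hoc with [classify_neck()]; draws landing in the wrong
#' stratum are rejected and redrawn, and the per-stratum rejection counts
#' are recorded. A stratum rejecting more than 90% of its draws is an
#' infeasible specification and raises an error.
#'
#' @param config A `cohort_config` with `mode = "geometry"`.
#' @param parent_caliber,parent_length,neck_center,resolution Geometry
#'   parameters shared by all records (mm / points).
#' @return A list with `geometries` (list of `aneurysm_geometry`), `labels`
#'   (data frame: id, rupture label, intended stratum, measured morphology)
#'   and `rejections` (per-stratum counts).
#' @export
sample_geometry_cohort <- function(config, parent_caliber = 3.24,
                                   parent_length = 30, neck_center = 18,
                                   resolution = 200) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "geometry") stop("config error: mode must be 'geometry'")
  plan <- cohort_group_plan(config)
  geoms <- list()
  labels <- list()
  rejections <- c(narrow = 0L, wide = 0L)
  attempts <- c(narrow = 0L, wide = 0L)
  idx <- 0L
  for (gi in seq_len(nrow(plan))) {
    cat_i <- plan$neck_category[gi]
    for (k in seq_len(plan$n[gi])) {
      idx <- idx + 1L
      set.seed(record_seed(config$seed, idx))
      geom <- NULL
      for (try in 1:50) {
        attempts[cat_i] <- attempts[cat_i] + 1L
        pars <- draw_geometry_params(cat_i)
        g <- try(make_geometry(pars$shape_family,
                               parent_caliber = parent_caliber,
                               neck_width = pars$neck_width,
                               sac_size = pars$sac_size,
                               sac_offset = pars$sac_offset,
                               parent_length = parent_length,
                               neck_center = neck_center,
                               resolution = resolution), silent = TRUE)
        if (inherits(g, "try-error")) {
          rejections[cat_i] <- rejections[cat_i] + 1L
          next
        }
        m <- measure_morphology(g)
        if (m$neck_category == cat_i) {
          geom <- g
          break
        }
        rejections[cat_i] <- rejections[cat_i] + 1L
      }
      if (is.null(geom)) {
        stop("config error: stratum '", cat_i,
             "' rejected > 90% of draws (infeasible specification)")
      }
      m <- measure_morphology(geom)
      geoms[[idx]] <- geom
      labels[[idx]] <- data.frame(
        id = sprintf("an%03d", idx),
        rupture_label = plan$rupture_label[gi],
        neck_category = cat_i, group = plan$group[gi],
        height = m$height, neck_width = m$neck_width,
        aspect_ratio = m$aspect_ratio, dome_measure = m$dome_measure)
    }
  }
  for (cat_i in names(rejections)) {
    if (attempts[cat_i] > 0 &&
        rejections[cat_i] / attempts[cat_i] > 0.9) {
      stop("config error: stratum '", cat_i,
           "' rejected > 90% of draws (infeasible specification)")
    }
  }
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  list(geometries = geoms, labels = labels, rejections = rejections,
       attempts = attempts, seed = config$seed)
}

#' Run the CFD pipeline over a geometry cohort
#'
#' Meshes, simulates and post-processes each geometry independently. A
#' failing record (e.g. solver non-convergence) is flagged and excluded
#' rather than aborting the cohort; the failure reason is kept in the
#' `failures` attribute.
#'
#' @param geom_cohort Result of [sample_geometry_cohort()], or a list with
#'   `geometries` and `labels`.
#' @param flow A `flow_conditions`.
#' @param cell_size Grid spacing, mm.
#' @param numerics A `numerics_config`.
#' @param hwss_mode,threshold_factor Passed to [compute_metrics()].
#' @param probe_distance,probe_extent Passed to [build_mesh()].
#' @param vtk_dir If non-`NULL`, a directory receiving one VTK wall-field
#'   file per record (`wall_<id>.vtk`).
#' @return An `aneurysm_cohort` data frame (successful records only) with a
#'   `failures` attribute.
#' @export
run_cohort_cfd <- function(geom_cohort, flow = flow_conditions(),
                           cell_size = 0.405,
                           numerics = numerics_config(),
                           hwss_mode = "time_average",
                           threshold_factor = 0.1,
                           probe_distance = 10, probe_extent = 2,
                           vtk_dir = NULL) {
  geoms <- geom_cohort$geometries
  labels <- geom_cohort$labels
  stopifnot(length(geoms) == nrow(labels))
  rows <- list()
  failures <- list()
  for (k in seq_along(geoms)) {
    rec <- tryCatch({
      mesh <- build_mesh(geoms[[k]], cell_size,
                         probe_distance = probe_distance,
                         probe_extent = probe_extent)
      field <- simulate_pulsatile(mesh, flow, numerics)
      ser <- time_average_wss(wall_shear_series(field, mesh))
      m <- compute_metrics(ser, threshold_factor = threshold_factor,
                           hwss_mode = hwss_mode)
      if (!is.null(vtk_dir)) {
        dir.create(vtk_dir, showWarnings = FALSE, recursive = TRUE)
        write_vtk_wall(ser, file.path(vtk_dir,
                                      paste0("wall_", labels$id[k], ".vtk")))
      }
      cbind(labels[k, , drop = FALSE],
            data.frame(MWSS = m$MWSS, HWSS = m$HWSS, PWSS = m$PWSS,
                       LSAR = m$LSAR, MP_ratio = m$MP_ratio,
                       HP_ratio = m$HP_ratio))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[labels$id[k]]] <- conditionMessage(rec)
    } else {
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aneurysm_cohort", "data.frame")
  attr(out, "failures") <- failures
  attr(out, "seed") <- geom_cohort$seed
  out
}

#' @export
print.aneurysm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic aneurysm cohort: %d records (%d ruptured, %d unruptured)\n",
              nrow(x), sum(x$rupture_label == "ruptured"),
              sum(x$rupture_label == "unruptured")))
  tab <- table(x$group)
  cat("  groups:", paste(names(tab), as.integer(tab), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Cohort CSV / JSON-sidecar interchange
#'
#' Writes the cohort as one CSV row per record plus a JSON sidecar capturing
#' the seed and configuration; `read_cohort` restores the data frame.
#'
#' @param cohort An `aneurysm_cohort`.
#' @param path CSV file path (the sidecar gets `.json` appended).
#' @return `write_cohort` invisibly returns `path`; `read_cohort` returns
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  sidecar <- list(seed = attr(cohort, "seed"),
                  n = nrow(cohort),
                  mode = if (!is.null(cfg)) cfg$mode else NA,
                  schema_version = "1.0")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("aneurysm_cohort", "data.frame")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "seed") <- meta$seed
  }
  out
}
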