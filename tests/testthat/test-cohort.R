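test_that("the default metric cohort reproduces the study composition", {
  cohort <- sample_metric_cohort(cohort_config(seed = 3))
  expect_equal(nrow(cohort), 72L)
  expect_equal(sum(cohort$rupture_label == "ruptured"), 41L)
  expect_equal(sum(cohort$rupture_label == "unruptured"), 31L)
  expect_setequal(unique(cohort$group),
                  c("ruptured-narrow", "ruptured-wide",
                    "unruptured-narrow", "unruptured-wide"))
  # group tag is consistent with label and stratum
  expect_identical(cohort$group,
                   paste(cohort$rupture_label, cohort$neck_category,
                         sep = "-"))
  # morphology consistent with stratum
  narrow <- cohort$neck_category == "narrow"
  expect_true(all(cohort$aspect_ratio[narrow] >= 1.4))
  expect_true(all(cohort$neck_width[narrow] < 4))
  expect_true(all(cohort$aspect_ratio[!narrow] < 1.4 |
                    cohort$neck_width[!narrow] >= 4))
})

test_that("cohorts are reproducible from the seed", {
  c1 <- sample_metric_cohort(cohort_config(seed = 42))
  c2 <- sample_metric_cohort(cohort_config(seed = 42))
  expect_identical(c1, c2)
  c3 <- sample_metric_cohort(cohort_config(seed = 43))
  expect_false(isTRUE(all.equal(c1$MWSS, c3$MWSS)))
})

test_that("ratios are derived from the sampled base metrics", {
  cohort <- sample_metric_cohort(cohort_config(seed = 5))
  expect_equal(cohort$MP_ratio, cohort$MWSS / cohort$PWSS, tolerance = 1e-12)
  expect_equal(cohort$HP_ratio, cohort$HWSS / cohort$PWSS, tolerance = 1e-12)
  expect_true(all(cohort$HWSS >= cohort$MWSS))
  expect_true(all(cohort$LSAR >= 0 & cohort$LSAR <= 1))
  expect_true(all(cohort[c("MWSS", "HWSS", "PWSS")] >= 0))
})

test_that("the truncated-normal sampler matches the closed-form moment", {
  set.seed(101)
  x <- aneuflow:::rtruncnorm(10000, mean = 1.96, sd = 1.30, lower = 0)
  mu_oracle <- oracle_truncnorm_mean(1.96, 1.30, lower = 0)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu_oracle), 3 * se)
  expect_true(all(x >= 0))

  # doubly truncated (the LSAR case)
  set.seed(102)
  y <- aneuflow:::rtruncnorm(10000, 0.34, 0.308, lower = 0, upper = 1)
  mu2 <- oracle_truncnorm_mean(0.34, 0.308, 0, 1)
  expect_lt(abs(mean(y) - mu2), 3 * sd(y) / sqrt(length(y)))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("group means converge to the calibrated locations (LLN)", {
  cfg <- cohort_config(n_ruptured = 10000, n_unruptured = 2,
                       narrow_fraction = c(ruptured = 1, unruptured = 0.5),
                       seed = 9)
  cohort <- sample_metric_cohort(cfg)
  rn <- cohort[cohort$group == "ruptured-narrow", ]
  expect_equal(nrow(rn), 10000L)
  # PWSS and LSAR are sampled independently of the HWSS/MWSS coupling
  mu_p <- oracle_truncnorm_mean(7.85, 3.98, 0)
  expect_lt(abs(mean(rn$PWSS) - mu_p), 3 * sd(rn$PWSS) / sqrt(nrow(rn)))
  mu_l <- oracle_truncnorm_mean(0.34, 0.308, 0, 1)
  expect_lt(abs(mean(rn$LSAR) - mu_l), 3 * sd(rn$LSAR) / sqrt(nrow(rn)))
})

test_that("log-normal calibration honours the printed median under both readings", {
  for (interp in c("iqr", "q3")) {
    pars <- aneuflow:::lnorm_from_quartiles(4.04, 5.24, interp)
    expect_equal(exp(pars$meanlog), 4.04)
    expect_gt(pars$sdlog, 0)
  }
  # Q3 reading: the 75th percentile equals the printed number
  pars <- aneuflow:::lnorm_from_quartiles(4.04, 5.24, "q3")
  expect_equal(qlnorm(0.75, pars$meanlog, pars$sdlog), 5.24,
               tolerance = 1e-9)
  # IQR reading: Q3 - Q1 equals the printed number
  pars <- aneuflow:::lnorm_from_quartiles(4.04, 5.24, "iqr")
  expect_equal(qlnorm(0.75, pars$meanlog, pars$sdlog) -
                 qlnorm(0.25, pars$meanlog, pars$sdlog), 5.24,
               tolerance = 1e-9)
})

test_that("inconsistent distribution specifications are rejected", {
  cal <- default_metric_calibration()
  cal$`ruptured-narrow`$MWSS$sd <- -1
  expect_error(cohort_config(calibration = cal), "config error")
  cal <- default_metric_calibration()
  cal$`ruptured-narrow`$HWSS <- aneuflow:::dist_spec_norm(1.0, 0.5)
  expect_error(cohort_config(calibration = cal), "HWSS location")
  expect_error(cohort_config(n_ruptured = 0), "config error")
})

test_that("geometry-mode strata agree with post hoc classification", {
  cfg <- cohort_config(n_ruptured = 6, n_unruptured = 6, mode = "geometry",
                       seed = 21)
  gc1 <- sample_geometry_cohort(cfg)
  expect_equal(length(gc1$geometries), 12L)
  for (k in seq_along(gc1$geometries)) {
    m <- measure_morphology(gc1$geometries[[k]])
    expect_identical(m$neck_category, gc1$labels$neck_category[k])
  }
  narrow <- gc1$labels$neck_category == "narrow"
  expect_true(all(gc1$labels$aspect_ratio[narrow] >= 1.4))
  # deterministic redraw
  gc2 <- sample_geometry_cohort(cfg)
  expect_identical(gc1$labels, gc2$labels)
})

test_that("a CFD cohort run populates all six metrics and isolates records", {
  geoms <- list(
    make_geometry("hemispherical-bump", sac_size = 2),
    make_geometry("circular-sac-with-neck", neck_width = 2, sac_size = 2.2,
                  sac_offset = 2.4))
  labels <- data.frame(id = c("a1", "a2"),
                       rupture_label = c("ruptured", "unruptured"),
                       neck_category = c("wide", "narrow"),
                       group = c("ruptured-wide", "unruptured-narrow"),
                       height = NA, neck_width = NA, aspect_ratio = NA,
                       dome_measure = NA)
  fl <- channel_flow(re = 20, pulsatile = TRUE)
  cohort <- suppressWarnings(
    run_cohort_cfd(list(geometries = geoms, labels = labels, seed = 1),
                   flow = fl, cell_size = 0.405,
                   numerics = numerics_config(n_steps_per_cycle = 40)))
  expect_equal(nrow(cohort), 2L)
  for (f in c("MWSS", "HWSS", "PWSS", "LSAR", "MP_ratio", "HP_ratio")) {
    expect_true(all(is.finite(cohort[[f]])))
  }
  expect_length(attr(cohort, "failures"), 0)
})

test_that("zero-pulsatility cohort metrics equal steady-state metrics", {
  geom <- make_geometry("hemispherical-bump", sac_size = 2)
  mesh <- build_mesh(geom, cell_size = 0.405)
  fl <- channel_flow(re = 20, pulsatile = FALSE)
  fld <- suppressWarnings(
    simulate_pulsatile(mesh, fl, numerics_config(n_steps_per_cycle = 40)))
  ser <- time_average_wss(wall_shear_series(fld, mesh))
  m_avg <- compute_metrics(ser)
  # a converged constant-inflow run is time-invariant: the last snapshot
  # alone reproduces the cycle-averaged metrics
  last <- wall_shear_series_from_values(
    ser$wss[, ncol(ser$wss), drop = FALSE] %*% t(c(1, 1)),
    c(0, 1), region = ser$elements$region, weight = ser$elements$weight)
  m_last <- compute_metrics(last)
  expect_equal(m_last$MWSS, m_avg$MWSS, tolerance = 1e-3)
  expect_equal(m_last$LSAR, m_avg$LSAR, tolerance = 1e-6)
})

test_that("cohort CSV round-trips with its JSON sidecar", {
  cohort <- sample_metric_cohort(cohort_config(n_ruptured = 8,
                                               n_unruptured = 6, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- read_cohort(f)
  expect_equal(back$MWSS, cohort$MWSS, tolerance = 1e-12)
  expect_identical(back$group, cohort$group)
  expect_equal(attr(back, "seed"), 2L)
})
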