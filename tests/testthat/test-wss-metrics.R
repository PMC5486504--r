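test_that("cycle averaging: rectified sine, constant, and refined-quadrature oracle", {
  # A |sin(2 pi t / T)| with A = pi/2 has cycle mean 2A/pi = 1
  t <- seq(0, 1, length.out = 1001)[-1001]
  w <- matrix((pi / 2) * abs(sin(2 * pi * t)), nrow = 1)
  ser <- wall_shear_series_from_values(w, t, region = "sac", weight = 1,
                                       period = 1)
  expect_equal(time_average_wss(ser)$time_averaged, 1, tolerance = 1e-3)

  # a constant series averages to itself exactly
  wc <- matrix(3.7, nrow = 1, ncol = 50)
  serc <- wall_shear_series_from_values(wc, seq(0, 0.98, by = 0.02),
                                        region = "sac", weight = 1,
                                        period = 1)
  expect_equal(time_average_wss(serc)$time_averaged, 3.7, tolerance = 1e-12)

  # arbitrary smooth series vs a 10x-oversampled Riemann-sum oracle
  f <- function(t) 2 + sin(2 * pi * t) + 0.5 * cos(6 * pi * t + 1)
  t200 <- seq(0, 1, length.out = 201)[-201]
  ser2 <- wall_shear_series_from_values(matrix(f(t200), nrow = 1), t200,
                                        region = "sac", weight = 1, period = 1)
  tf <- seq(0, 1, length.out = 2001)[-2001]
  oracle <- mean(abs(f(tf + 0.5 / 2000)))  # midpoint Riemann at 10x sampling
  expect_equal(time_average_wss(ser2)$time_averaged, oracle,
               tolerance = 1e-3)

  # non-monotone times are rejected
  bad <- wall_shear_series_from_values(matrix(1, 1, 3), c(0, 0.2, 0.1),
                                       region = "sac", weight = 1)
  expect_error(time_average_wss(bad), "strictly increasing")
})

test_that("wall shear from a Poiseuille field matches the closed form and scales with mu", {
  run <- poiseuille_run(16L)
  ser <- time_average_wss(wall_shear_series(run$field, run$mesh))
  H <- 3.24e-3
  exact <- 6 * 3.5e-3 * channel_q() / H^2
  mid <- abs(ser$elements$x - 5) < 2.5
  expect_true(all(abs(ser$time_averaged[mid] / exact - 1) < 0.05))

  # linearity in viscosity at a fixed field
  ser2 <- wall_shear_series(run$field, run$mesh, mu = 7.0e-3)
  expect_equal(ser2$wss, 2 * wall_shear_series(run$field, run$mesh)$wss,
               tolerance = 1e-12)
})

test_that("uniform fields give unit ratios and zero low-shear area", {
  ser <- synthetic_series(sac_values = rep(2.5, 10),
                          probe_values = rep(2.5, 4))
  m <- compute_metrics(ser)
  expect_equal(m$MWSS, 2.5)
  expect_equal(m$HWSS, 2.5)
  expect_equal(m$PWSS, 2.5)
  expect_equal(m$MP_ratio, 1)
  expect_equal(m$HP_ratio, 1)
  expect_equal(m$LSAR, 0)
})

test_that("LSAR hits 0.5 and 1 on constructed partitions", {
  # half the sac arc length at 0.05 PWSS, half at 2 PWSS
  ser <- synthetic_series(sac_values = c(rep(0.05, 5), rep(2.0, 5)),
                          probe_values = rep(1.0, 4))
  expect_equal(compute_metrics(ser)$LSAR, 0.5)
  # all below threshold
  ser1 <- synthetic_series(sac_values = rep(0.01, 8),
                           probe_values = rep(1.0, 4))
  expect_equal(compute_metrics(ser1)$LSAR, 1.0)
  # boundary elements exactly at the threshold are not low-shear
  ser2 <- synthetic_series(sac_values = rep(0.1, 8),
                           probe_values = rep(1.0, 4))
  expect_equal(compute_metrics(ser2)$LSAR, 0)
})

test_that("metrics are scale-equivariant and ratios scale-invariant", {
  for (seed in 1:5) {
    set.seed(seed)
    sac <- runif(20, 0, 3)
    probe <- runif(5, 1, 4)
    wts <- runif(20, 0.5, 2)
    m1 <- compute_metrics(synthetic_series(sac, probe, sac_weights = wts))
    for (c0 in c(0.3, 2, 17)) {
      m2 <- compute_metrics(synthetic_series(c0 * sac, c0 * probe,
                                             sac_weights = wts))
      expect_equal(m2$MWSS, c0 * m1$MWSS, tolerance = 1e-12)
      expect_equal(m2$HWSS, c0 * m1$HWSS, tolerance = 1e-12)
      expect_equal(m2$PWSS, c0 * m1$PWSS, tolerance = 1e-12)
      expect_equal(m2$MP_ratio, m1$MP_ratio, tolerance = 1e-12)
      expect_equal(m2$HP_ratio, m1$HP_ratio, tolerance = 1e-12)
      expect_equal(m2$LSAR, m1$LSAR, tolerance = 1e-12)
    }
  }
})

test_that("LSAR is monotone in the threshold factor and metric order holds", {
  for (seed in 1:5) {
    set.seed(seed)
    ser <- synthetic_series(runif(25, 0, 1), runif(5, 1, 4),
                            sac_weights = runif(25, 0.5, 2))
    factors <- c(0.1, 0.08, 0.05, 0.02, 0.005)
    lsars <- vapply(factors, function(f) {
      compute_metrics(ser, threshold_factor = f)$LSAR
    }, numeric(1))
    expect_true(all(diff(lsars) <= 0))
    m <- compute_metrics(ser)
    expect_gte(m$HWSS, m$MWSS)
    expect_gte(m$HP_ratio, m$MP_ratio)
    expect_true(m$LSAR >= 0 && m$LSAR <= 1)
  }
})

test_that("metrics are invariant under element reordering", {
  set.seed(7)
  sac <- runif(15); probe <- runif(4, 1, 2); wts <- runif(15, 0.5, 2)
  m1 <- compute_metrics(synthetic_series(sac, probe, sac_weights = wts))
  perm <- sample(15)
  m2 <- compute_metrics(synthetic_series(sac[perm], probe,
                                         sac_weights = wts[perm]))
  for (f in c("MWSS", "HWSS", "PWSS", "LSAR", "MP_ratio", "HP_ratio")) {
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  # zero parent WSS cannot normalize the ratios
  ser0 <- synthetic_series(rep(1, 5), rep(0, 3))
  expect_error(compute_metrics(ser0), "PWSS is zero")
  # missing regions
  w <- matrix(1, 4, 2)
  no_probe <- wall_shear_series_from_values(w, c(0, 1),
                                            region = rep("sac", 4),
                                            weight = rep(1, 4))
  expect_error(compute_metrics(no_probe), "parent_probe")
  no_sac <- wall_shear_series_from_values(w, c(0, 1),
                                          region = rep("parent_probe", 4),
                                          weight = rep(1, 4))
  expect_error(compute_metrics(no_sac), "sac")
  # mismatched field/mesh pairs
  run <- poiseuille_run(16L)
  other <- build_mesh(straight_channel(parent_length = 8), cell_size = 0.405)
  expect_error(wall_shear_series(run$field, other), "consistency")
})

test_that("peak-mode HWSS is at least the time-averaged HWSS", {
  set.seed(11)
  n_t <- 40
  t <- seq(0, 0.975, by = 0.025)
  wss <- matrix(abs(rnorm(12 * n_t, 2, 1)), 12, n_t)
  ser <- wall_shear_series_from_values(
    wss, t, region = c(rep("sac", 8), rep("parent_probe", 4)),
    weight = rep(1, 12), period = 1)
  m_avg <- compute_metrics(ser, hwss_mode = "time_average")
  m_peak <- compute_metrics(ser, hwss_mode = "peak")
  expect_gte(m_peak$HWSS, m_avg$HWSS)
})
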