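# Shared fixtures. Expensive solver runs are cached so validation and
# acceptance tests reuse the same fields.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Physiological fluid with the channel Reynolds number (caliber-based) set
# to `re`; pulsatile runs keep the physiological max/mean ratio 301/185.
channel_flow <- function(re = 5, pulsatile = FALSE, caliber = 3.24,
                         n_cycles = 3) {
  H <- caliber * 1e-3
  U <- re * 3.5e-3 / (1050 * H)
  Qm <- U * pi * H^2 / 4 * 60e6  # ml/min giving 4Q/(pi D^2) = U at D = caliber
  flow_conditions(mean_flow = Qm,
                  max_flow = if (pulsatile) Qm * 301 / 185 else Qm,
                  n_cycles = n_cycles, reference_diameter = caliber)
}

channel_q <- function(re = 5, caliber = 3.24) {
  H <- caliber * 1e-3
  U <- re * 3.5e-3 / (1050 * H)
  U * H  # per-depth flow, m^2/s
}

poiseuille_run <- function(cells_across, length_mm = 10, re = 5,
                           n_steps = 100) {
  cached(sprintf("pois_%d_%g", cells_across, length_mm), {
    ch <- straight_channel(parent_length = length_mm, parent_caliber = 3.24)
    mesh <- build_mesh(ch, cell_size = 3.24 / cells_across)
    fl <- channel_flow(re)
    field <- simulate_pulsatile(mesh, fl,
                                numerics_config(n_steps_per_cycle = n_steps))
    list(mesh = mesh, flow = fl, field = field)
  })
}

# max relative wall-shear error against 6 mu q / h^2 over the mid-channel
poiseuille_wss_error <- function(cells_across) {
  run <- poiseuille_run(cells_across)
  ser <- time_average_wss(wall_shear_series(run$field, run$mesh))
  H <- 3.24e-3
  exact <- 6 * 3.5e-3 * channel_q() / H^2
  mid <- abs(ser$elements$x - 5) < 2.5
  max(abs(ser$time_averaged[mid] / exact - 1))
}

womersley_run <- function() {
  cached("womersley_32", {
    ch <- straight_channel(parent_length = 10, parent_caliber = 3.24)
    mesh <- build_mesh(ch, cell_size = 3.24 / 32)
    fl <- channel_flow(re = 5, pulsatile = TRUE)
    field <- simulate_pulsatile(mesh, fl,
                                numerics_config(n_steps_per_cycle = 200))
    list(mesh = mesh, flow = fl, field = field)
  })
}

# relative L2 error of the near-centerline velocity time series vs the
# analytic oscillatory-channel solution, sampled at x = 7 mm
womersley_l2_error <- function() {
  run <- womersley_run()
  mesh <- run$mesh
  field <- run$field
  h <- mesh$cell_size
  icol <- round(7 / h)
  j <- 16L
  ycell <- (j - 0.5) * h * 1e-3
  un <- 0.5 * (field$u[icol, j, ] + field$u[icol + 1, j, ])
  q_mean <- channel_q()
  q_amp <- q_mean * (301 / 185 - 1)
  ua <- analytic_channel_solution(ycell, field$times, 3.24e-3, q_mean, q_amp,
                                  period = field$period)
  sqrt(mean((un - ua)^2)) / sqrt(mean(ua^2))
}

# wall-shear series with explicit values on a sac + probe element set
synthetic_series <- function(sac_values, probe_values,
                             sac_weights = rep(1, length(sac_values)),
                             times = c(0, 1), period = 1) {
  n_s <- length(sac_values)
  n_p <- length(probe_values)
  wss <- matrix(rep(c(sac_values, probe_values), length(times)),
                ncol = length(times))
  wall_shear_series_from_values(
    wss, times,
    region = c(rep("sac", n_s), rep("parent_probe", n_p)),
    weight = c(sac_weights, rep(1, n_p)),
    period = period)
}

# exhaustive Mann-Whitney oracle: U statistic and exact two-sided p by
# enumeration of all rank assignments (no ties assumed)
mw_exact_oracle <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
  list(U = U_obs, p = p)
}

# closed-form truncated-normal mean (independent of the package sampler)
oracle_truncnorm_mean <- function(mean, sd, lower = 0, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}
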