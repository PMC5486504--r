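#' Fluid and pulsatile inflow conditions
#'
#' Blood is modeled as an incompressible Newtonian fluid. The defaults are
#' the physiological values used throughout: density 1050 kg/m^3, dynamic
#' viscosity 3.5e-3 Pa.s, transcranial-Doppler-derived inflow with mean
#' 185 ml/min, maximum 301 ml/min at 64 bpm, and three simulated cycles of
#' which the last is analyzed.
#'
#' @param density Fluid density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa.s.
#' @param mean_flow Cycle-mean volumetric flow, ml/min.
#' @param max_flow Cycle-maximum volumetric flow, ml/min.
#' @param heart_rate Heart rate, beats per minute.
#' @param n_cycles Number of pulsatile cycles to simulate (the last is the
#'   output).
#' @param reference_diameter Effective vessel caliber in mm used for the
#'   Reynolds and Womersley numbers and for converting volumetric flow to
#'   the 2-D channel inflow. `NULL` defers to the mesh's parent caliber.
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(density = 1050, viscosity = 3.5e-3,
                            mean_flow = 185, max_flow = 301,
                            heart_rate = 64, n_cycles = 3,
                            reference_diameter = NULL) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  if (mean_flow < 0 || max_flow < mean_flow) {
    stop("need 0 <= mean_flow <= max_flow")
  }
  if (heart_rate <= 0) stop("heart_rate must be > 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(density = density, viscosity = viscosity,
                 mean_flow = mean_flow, max_flow = max_flow,
                 heart_rate = heart_rate, n_cycles = n_cycles,
                 reference_diameter = reference_diameter),
            class = "flow_conditions")
}

#' @export
print.flow_conditions <- function(x, ...) {
  cat(sprintf(paste0("Flow conditions: rho=%g kg/m^3, mu=%g Pa.s, ",
                     "Q=%g (max %g) ml/min, %g bpm, %d cycles\n"),
              x$density, x$viscosity, x$mean_flow, x$max_flow,
              x$heart_rate, x$n_cycles))
  if (!is.null(x$reference_diameter)) {
    cat(sprintf("  reference diameter %.4g mm (Re=%.1f, alpha=%.3f)\n",
                x$reference_diameter, reynolds_number(x), womersley_number(x)))
  }
  invisible(x)
}

#' Pulsatile inflow waveform
#'
#' Single-harmonic waveform `Q(t) = Q_mean + (Q_max - Q_mean) sin(2 pi f t)`
#' with `f = heart_rate / 60`. It reproduces the three quantities the inflow
#' is specified by: time mean `Q_mean`, maximum `Q_max`, and period
#' `60 / heart_rate`.
#'
#' @param t Time(s) in seconds.
#' @param flow A `flow_conditions` object.
#' @return Instantaneous flow rate(s), ml/min.
#' @export
inlet_waveform <- function(t, flow) {
  stopifnot(inherits(flow, "flow_conditions"), all(t >= 0))
  f <- bpm_to_hz(flow$heart_rate)
  flow$mean_flow + (flow$max_flow - flow$mean_flow) * sin(2 * pi * f * t)
}

#' Reynolds and Womersley numbers
#'
#' `reynolds_number` uses the circular-vessel mean-flow form
#' `Re = rho U D / mu` with `U = Q / (pi (D/2)^2)`, i.e.
#' `Re = 4 rho Q / (mu pi D)`. `womersley_number` is
#' `alpha = (D/2) sqrt(omega rho / mu)` with `omega = 2 pi heart_rate / 60`.
#' The inverse helpers recover the diameter implied by a printed value of
#' either number.
#'
#' @param flow A `flow_conditions` with `reference_diameter` set (mm).
#' @return A dimensionless number (or a diameter in mm for the inverses).
#' @export
reynolds_number <- function(flow) {
  stopifnot(inherits(flow, "flow_conditions"))
  D <- mm_to_m(flow$reference_diameter %||%
                 stop("reference_diameter must be set"))
  Q <- mlmin_to_m3s(flow$mean_flow)
  4 * flow$density * Q / (flow$viscosity * pi * D)
}

#' @rdname reynolds_number
#' @export
womersley_number <- function(flow) {
  stopifnot(inherits(flow, "flow_conditions"))
  D <- mm_to_m(flow$reference_diameter %||%
                 stop("reference_diameter must be set"))
  omega <- 2 * pi * bpm_to_hz(flow$heart_rate)
  (D / 2) * sqrt(omega * flow$density / flow$viscosity)
}

#' @rdname reynolds_number
#' @param re Target Reynolds number.
#' @export
diameter_from_reynolds <- function(flow, re) {
  stopifnot(inherits(flow, "flow_conditions"), re > 0)
  Q <- mlmin_to_m3s(flow$mean_flow)
  m_to_mm(4 * flow$density * Q / (flow$viscosity * pi * re))
}

#' @rdname reynolds_number
#' @param alpha Target Womersley number.
#' @export
diameter_from_womersley <- function(flow, alpha) {
  stopifnot(inherits(flow, "flow_conditions"), alpha > 0)
  omega <- 2 * pi * bpm_to_hz(flow$heart_rate)
  m_to_mm(2 * alpha / sqrt(omega * flow$density / flow$viscosity))
}

#' Numerical settings for the SIMPLE solver
#'
#' Defaults are standard robust settings for a staggered-grid SIMPLE scheme:
#' velocity under-relaxation 0.7, pressure under-relaxation 0.3, first-order
#' upwind convection with central diffusion, implicit Euler in time with 200
#' steps per cycle, and a per-step mass-residual tolerance of 1e-6 (scaled
#' by the instantaneous inlet mass flux).
#'
#' @param n_steps_per_cycle Time steps per cardiac cycle.
#' @param alpha_u,alpha_p Velocity / pressure under-relaxation factors.
#' @param tol_mass Scaled mass-imbalance tolerance per time step.
#' @param tol_u Relative velocity-change tolerance per time step.
#' @param max_outer SIMPLE iteration cap per time step.
#' @param n_sweeps Gauss-Seidel momentum sweeps per SIMPLE iteration.
#' @param cg_rtol,cg_maxit Pressure-correction CG relative tolerance and cap.
#' @return A list of class `numerics_config`.
#' @export
numerics_config <- function(n_steps_per_cycle = 200,
                            alpha_u = 0.7, alpha_p = 0.3,
                            tol_mass = 1e-6, tol_u = 1e-4,
                            max_outer = 400, n_sweeps = 3,
                            cg_rtol = 1e-4, cg_maxit = 20000) {
  stopifnot(n_steps_per_cycle >= 8, alpha_u > 0, alpha_u <= 1,
            alpha_p > 0, alpha_p <= 1, tol_mass > 0, max_outer >= 1)
  structure(list(n_steps_per_cycle = as.integer(n_steps_per_cycle),
                 alpha_u = alpha_u, alpha_p = alpha_p,
                 tol_mass = tol_mass, tol_u = tol_u,
                 max_outer = as.integer(max_outer),
                 n_sweeps = as.integer(n_sweeps),
                 cg_rtol = cg_rtol, cg_maxit = as.integer(cg_maxit)),
            class = "numerics_config")
}

#' Simulate pulsatile flow on a masked staggered grid
#'
#' Integrates the unsteady incompressible Navier-Stokes equations with a
#' finite-volume discretization and SIMPLE pressure-velocity coupling.
#' Boundary conditions: flat (uniform) velocity profile at the inlet scaled
#' to the instantaneous waveform, zero pressure at the outlet, no-slip rigid
#' walls. `n_cycles` cycles are integrated from rest and only the last cycle
#' is returned.
#'
#' The volumetric waveform is converted to the 2-D channel analog by taking
#' the circular-vessel mean velocity `U(t) = 4 Q(t) / (pi D^2)` at the
#' reference diameter `D` (defaulting to the parent caliber) and applying it
#' uniformly across the inlet, which preserves the caliber-based channel
#' Reynolds number.
#'
#' Every time step's SIMPLE loop must reach the mass/momentum residual
#' tolerance; otherwise the solver stops with an error carrying the residual
#' history. A warning is issued when the advective CFL number exceeds 1
#' (implicit time stepping remains stable, but temporal resolution of
#' advection is then coarse).
#'
#' @param mesh An `aneurysm_mesh`.
#' @param flow A `flow_conditions` object.
#' @param numerics A `numerics_config`.
#' @return An object of class `flow_field`: `times` (s, within the last
#'   cycle), `u`, `v` (face velocities, m/s, arrays `[faces, time]`), `p`
#'   (cell pressures, Pa), `residual_log` data frame, `cfl_max`, `period`,
#'   and the discretization metadata needed for post-processing.
#' @export
simulate_pulsatile <- function(mesh, flow, numerics = numerics_config()) {
  stopifnot(inherits(mesh, "aneurysm_mesh"),
            inherits(flow, "flow_conditions"),
            inherits(numerics, "numerics_config"))
  h <- mm_to_m(mesh$cell_size)
  D <- mm_to_m(flow$reference_diameter %||% mesh$geom$parent_caliber)
  period <- 60 / flow$heart_rate
  dt <- period / numerics$n_steps_per_cycle
  n_steps <- numerics$n_steps_per_cycle * flow$n_cycles
  t_levels <- seq_len(n_steps) * dt
  Q_si <- mlmin_to_m3s(inlet_waveform(t_levels, flow))
  uin <- 4 * Q_si / (pi * D^2)  # flat inlet profile, m/s

  res <- simple_solve_cpp(mesh$fluid, h, flow$density, flow$viscosity,
                          uin, as.integer(mesh$inlet_rows - 1L),
                          numerics$n_steps_per_cycle, flow$n_cycles, dt,
                          numerics$alpha_u, numerics$alpha_p,
                          numerics$tol_mass, numerics$tol_u,
                          numerics$max_outer, numerics$n_sweeps,
                          numerics$cg_rtol, numerics$cg_maxit)

  if (res$failed_step > 0) {
    hist <- paste(signif(utils::tail(res$failure_residuals, 8), 4),
                  collapse = ", ")
    stop("SIMPLE failed to converge at time step ", res$failed_step,
         " within ", numerics$max_outer,
         " iterations; trailing mass residuals: ", hist)
  }
  if (res$cfl_max > 1) {
    warning(sprintf(
      "advective CFL reached %.2f (> 1); implicit stepping is stable but",
      res$cfl_max),
      " consider more steps per cycle for temporal accuracy")
  }

  log <- as.data.frame(res$residual_log)
  names(log) <- c("step", "simple_iterations", "mass_residual")

  structure(list(
    times = seq_len(numerics$n_steps_per_cycle) * dt,
    u = res$u, v = res$v, p = res$p,
    residual_log = log, cfl_max = res$cfl_max,
    period = period, dt = dt,
    cell_size = mesh$cell_size, nx = mesh$nx, ny = mesh$ny,
    inlet_velocity = uin, flow = flow, numerics = numerics
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field: %d x %d grid, last cycle (%d steps of %.4g s)\n",
              x$nx, x$ny, length(x$times), x$dt))
  cat(sprintf("  max CFL %.2f, worst mass residual %.3g\n",
              x$cfl_max, max(x$residual_log$mass_residual)))
  invisible(x)
}

#' Analytic plane-channel velocity (steady + oscillatory)
#'
#' Closed-form solution for fully developed laminar flow in a 2-D channel of
#' height `h` driven by a per-depth flow rate
#' `q(t) = q_mean + q_amp sin(omega t)`: the steady part is the plane
#' Poiseuille parabola `u = 6 q_mean y (h - y) / h^3`, the oscillatory part
#' is the Womersley-type profile
#' `u_osc = Im[ q_amp * g(y) / (integral of g) * exp(i omega t) ]` with
#' `g(y) = 1 - cosh(lambda (y - h/2)) / cosh(lambda h / 2)` and
#' `lambda = sqrt(i omega / nu)`. The zero-frequency limit reduces to the
#' steady parabola. Used as the solver validation oracle.
#'
#' @param y Wall-normal position(s), m (0 and `h` are the walls).
#' @param t Time(s), s.
#' @param h Channel height, m.
#' @param q_mean,q_amp Mean and oscillatory-amplitude per-depth flow, m^2/s.
#' @param period Oscillation period, s (`Inf` for steady).
#' @param rho,mu Density (kg/m^3) and viscosity (Pa.s).
#' @return Matrix `length(y)` x `length(t)` of velocities, m/s.
#' @export
analytic_channel_solution <- function(y, t, h, q_mean, q_amp = 0,
                                      period = Inf, rho = 1050, mu = 3.5e-3) {
  stopifnot(all(y >= -1e-12), all(y <= h + 1e-12), h > 0)
  us <- 6 * q_mean * y * (h - y) / h^3
  out <- matrix(us, nrow = length(y), ncol = length(t))
  if (q_amp != 0 && is.finite(period)) {
    nu <- mu / rho
    omega <- 2 * pi / period
    lam <- sqrt(1i * omega / nu)
    g <- 1 - cosh(lam * (y - h / 2)) / cosh(lam * h / 2)
    g_int <- h - (2 / lam) * tanh(lam * h / 2)
    uhat <- q_amp * g / g_int
    out <- out + Im(outer(uhat, exp(1i * omega * t)))
  }
  out
}
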