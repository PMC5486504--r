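#' Extract instantaneous wall shear stress at every wall element
#'
#' WSS is the tangential viscous drag on the wall,
#' `mu * |d u_t / d n|`, evaluated by a one-sided difference between the
#' no-slip wall and the tangential velocity at the adjacent fluid cell
#' center (half a cell away): `wss = 2 mu |u_t| / cell_size`. Horizontal
#' wall faces use the cell-centered `u`, vertical faces the cell-centered
#' `v`.
#'
#' @param field A `flow_field` from [simulate_pulsatile()].
#' @param mesh The `aneurysm_mesh` the field was computed on.
#' @param mu Dynamic viscosity, Pa.s. Defaults to the field's.
#' @return An object of class `wall_shear_series`: the wall-element table
#'   (with region tags and arc-length weights), `times` (s), the period,
#'   and `wss`, an `n_elements` x `n_times` matrix of instantaneous WSS
#'   magnitudes in Pa. `time_averaged` is `NULL` until
#'   [time_average_wss()] is applied.
#' @export
wall_shear_series <- function(field, mesh, mu = NULL) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "aneurysm_mesh"))
  if (field$nx != mesh$nx || field$ny != mesh$ny ||
      abs(field$cell_size - mesh$cell_size) > 1e-12) {
    stop("consistency error: flow field and mesh discretizations differ")
  }
  mu <- mu %||% field$flow$viscosity
  we <- mesh$wall_elements
  h <- mm_to_m(mesh$cell_size)
  nx <- mesh$nx
  n_t <- length(field$times)
  n_e <- nrow(we)

  horiz <- we$face %in% c("N", "S")
  wss <- matrix(0.0, n_e, n_t)
  u <- field$u  # (nx+1) x ny x n_t
  v <- field$v  # nx x (ny+1) x n_t
  iu_w <- we$i; iu_e <- we$i + 1L   # 1-based u-face columns of cell (i,j)
  jv_s <- we$j; jv_n <- we$j + 1L
  for (k in seq_len(n_t)) {
    uc <- 0.5 * (u[cbind(iu_w, we$j, k)] + u[cbind(iu_e, we$j, k)])
    vc <- 0.5 * (v[cbind(we$i, jv_s, k)] + v[cbind(we$i, jv_n, k)])
    wss[, k] <- (2 * mu / h) * ifelse(horiz, abs(uc), abs(vc))
  }

  structure(list(elements = we, times = field$times,
                 period = field$period, wss = wss,
                 time_averaged = NULL, mu = mu),
            class = "wall_shear_series")
}

#' Cycle-average the WSS magnitude at every wall element
#'
#' Computes the time-averaged WSS, `(1/T) * integral over the cycle of
#' |wss_i| dt`, per wall element by trapezoidal quadrature. The series is
#' treated as periodic: the sample at the start of the cycle is identified
#' with the one at the end, closing the integration window.
#'
#' @param series A `wall_shear_series`.
#' @return The series with `time_averaged` (Pa per element) filled in.
#' @export
time_average_wss <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  t <- series$times
  if (length(t) < 2) stop("input error: need >= 2 time samples")
  if (any(diff(t) <= 0)) stop("input error: times must be strictly increasing")
  w <- abs(series$wss)
  T_span <- series$period
  if (is.null(T_span) || !is.finite(T_span)) T_span <- diff(range(t))
  # periodic closure: prepend the last sample at t[n] - T
  tt <- c(t[length(t)] - T_span, t)
  ww <- cbind(w[, ncol(w)], w)
  dtv <- diff(tt)
  avg <- as.vector((0.5 * (ww[, -1, drop = FALSE] +
                           ww[, -ncol(ww), drop = FALSE])) %*% dtv) / T_span
  series$time_averaged <- avg
  series
}

#' Build a wall-shear series directly from values (for analysis/testing)
#'
#' Constructs a `wall_shear_series` from an explicit element table and WSS
#' matrix, bypassing the solver. Used to feed the metric calculators with
#' synthetic or externally computed wall data.
#'
#' @param wss `n_elements` x `n_times` matrix of WSS magnitudes, Pa.
#' @param times Sample times, s.
#' @param region Character vector of region tags per element
#'   (`"sac"`, `"parent_probe"`, `"other"`).
#' @param weight Arc-length weights per element, mm.
#' @param period Cycle period, s.
#' @return A `wall_shear_series`.
#' @export
wall_shear_series_from_values <- function(wss, times, region, weight,
                                          period = NULL) {
  wss <- as.matrix(wss)
  stopifnot(nrow(wss) == length(region), length(region) == length(weight),
            ncol(wss) == length(times))
  if (any(wss < 0)) stop("wss magnitudes must be non-negative")
  elements <- data.frame(i = NA_integer_, j = NA_integer_, face = NA_character_,
                         x = NA_real_, y = NA_real_,
                         weight = weight, region = region)
  structure(list(elements = elements, times = times,
                 period = period %||% diff(range(times)),
                 wss = wss, time_averaged = NULL, mu = NA_real_),
            class = "wall_shear_series")
}

#' Compute the hemodynamic metric suite for one aneurysm
#'
#' From the cycle-averaged wall field:
#' * `MWSS` — arc-length-weighted mean of time-averaged WSS over the sac;
#' * `HWSS` — highest sac WSS (max of the time-averaged field by default;
#'   `hwss_mode = "peak"` takes the max over elements *and* times);
#' * `PWSS` — weighted mean time-averaged WSS over the parent reference
#'   (probe) segment;
#' * `LSAR` — fraction of sac arc length whose time-averaged WSS is
#'   strictly below `threshold_factor * PWSS` (default 10% of PWSS);
#' * `MP_ratio = MWSS / PWSS`, `HP_ratio = HWSS / PWSS`.
#'
#' Elements exactly at the low-shear threshold are not counted as low-shear
#' ("below" is read strictly).
#'
#' @param series A `wall_shear_series` with `time_averaged` present (see
#'   [time_average_wss()]); if absent it is computed first.
#' @param threshold_factor Low-shear threshold as a fraction of PWSS.
#' @param hwss_mode `"time_average"` or `"peak"`.
#' @return An object of class `hemodynamic_metrics`.
#' @export
compute_metrics <- function(series, threshold_factor = 0.1,
                            hwss_mode = c("time_average", "peak")) {
  stopifnot(inherits(series, "wall_shear_series"))
  hwss_mode <- match.arg(hwss_mode)
  if (is.null(series$time_averaged)) series <- time_average_wss(series)
  el <- series$elements
  ta <- series$time_averaged
  sac <- el$region == "sac"
  probe <- el$region == "parent_probe"
  if (!any(sac)) stop("tagging error: no sac wall elements")
  if (!any(probe)) stop("tagging error: no parent_probe wall elements")

  w_sac <- el$weight[sac]
  mwss <- sum(w_sac * ta[sac]) / sum(w_sac)
  hwss <- if (hwss_mode == "time_average") {
    max(ta[sac])
  } else {
    max(series$wss[sac, , drop = FALSE])
  }
  pwss <- sum(el$weight[probe] * ta[probe]) / sum(el$weight[probe])
  if (pwss <= 0) {
    stop("undefined-ratio error: PWSS is zero (degenerate flow)")
  }
  thr <- threshold_factor * pwss
  lsar <- sum(w_sac[ta[sac] < thr]) / sum(w_sac)

  structure(list(MWSS = mwss, HWSS = hwss, PWSS = pwss, LSAR = lsar,
                 MP_ratio = mwss / pwss, HP_ratio = hwss / pwss,
                 low_shear_threshold = thr,
                 hwss_mode = hwss_mode,
                 threshold_factor = threshold_factor),
            class = "hemodynamic_metrics")
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat(sprintf(paste0("WSS metrics: MWSS %.4g Pa, HWSS %.4g Pa, PWSS %.4g Pa\n",
                     "  LSAR %.4g, M-P %.4g, H-P %.4g ",
                     "(low-shear threshold %.4g Pa)\n"),
              x$MWSS, x$HWSS, x$PWSS, x$LSAR, x$MP_ratio, x$HP_ratio,
              x$low_shear_threshold))
  invisible(x)
}

#' One-row data frame of metrics (CSV interchange form)
#'
#' @param m A `hemodynamic_metrics`.
#' @param id Optional identifier.
#' @return A one-row data frame.
#' @export
metrics_as_row <- function(m, id = NA_character_) {
  stopifnot(inherits(m, "hemodynamic_metrics"))
  data.frame(id = id, MWSS = m$MWSS, HWSS = m$HWSS, PWSS = m$PWSS,
             LSAR = m$LSAR, MP_ratio = m$MP_ratio, HP_ratio = m$HP_ratio)
}
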