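# Vectorized point-in-cavity test for the sac region (y >= wall).
sac_contains <- function(geom, x, y) {
  H <- geom$parent_caliber
  x0 <- geom$neck_center
  r <- geom$sac_size
  if (geom$shape_family == "hemispherical-bump") {
    (y >= H) & ((x - x0)^2 + (y - H)^2 < r^2)
  } else {
    c0 <- geom$sac_offset
    w <- geom$neck_width
    y_join <- c0 - sqrt(r^2 - (w / 2)^2)
    in_circle <- (x - x0)^2 + (y - H - c0)^2 < r^2
    in_neck <- abs(x - x0) < w / 2 & (y - H) < y_join + 1e-12
    (y >= H) & (in_circle | in_neck)
  }
}

#' Discretize a geometry onto a masked staggered Cartesian grid
#'
#' The domain is covered by square cells of side `cell_size`; a cell is fluid
#' if its center lies in the parent lumen or inside the sac cavity (staircase
#' masking). Wall elements are the faces separating a fluid cell from solid
#' or from the domain boundary; each is tagged by region:
#'
#' * `sac` — faces bordering sac-cavity cells. Their arc-length weights are
#'   obtained by projecting the true sac boundary polyline onto the nearest
#'   sac face, so the sac weight total equals the true sac arc length (up to
#'   discretization of the polyline) rather than the staircase perimeter.
#' * `parent_probe` — parent-wall reference segment (see
#'   [locate_parent_probe()]), tagged automatically when `tag_probe = TRUE`.
#' * `other` — remaining wall faces, weight `cell_size` each (exact for the
#'   axis-aligned parent walls).
#'
#' @param geom An `aneurysm_geometry` or `channel_geometry`.
#' @param cell_size Grid spacing, mm. Must be at most `parent_caliber / 8`.
#' @param tag_probe Tag the parent reference segment (ignored for plain
#'   channels).
#' @param probe_distance,probe_extent,probe_side Passed to
#'   [locate_parent_probe()].
#' @return An object of class `aneurysm_mesh`: `cell_size`, `nx`, `ny`,
#'   `fluid` (logical `nx` x `ny` matrix), `wall_elements` (data frame with
#'   cell indices, face orientation, face-center coordinates, arc-length
#'   weight in mm and region tag), `inlet_rows`, `outlet_rows`,
#'   `n_parent_rows`, and the generating geometry.
#' @export
build_mesh <- function(geom, cell_size, tag_probe = TRUE,
                       probe_distance = 10, probe_extent = 2,
                       probe_side = "upstream") {
  has_sac <- inherits(geom, "aneurysm_geometry")
  if (!has_sac && !inherits(geom, "channel_geometry")) {
    stop("geom must be an aneurysm_geometry or channel_geometry")
  }
  H <- geom$parent_caliber
  L <- geom$parent_length
  if (cell_size > H / 8 + 1e-12) {
    stop("resolution too coarse: cell_size must be <= parent_caliber / 8 = ",
         signif(H / 8, 6), " mm")
  }
  h <- cell_size
  nx <- max(1L, round(L / h))
  y_top <- if (has_sac) max(geom$sac_boundary[, "y"]) else H
  ny <- as.integer(ceiling(y_top / h)) + 2L

  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  fluid <- matrix(rep(yc < H, each = nx), nx, ny)
  if (has_sac) {
    pts <- expand.grid(x = xc, y = yc)
    fluid <- fluid | matrix(sac_contains(geom, pts$x, pts$y), nx, ny)
  }

  n_parent_rows <- sum(yc < H)
  if (n_parent_rows < 8L) {
    stop("resolution too coarse: fewer than 8 fluid rows across the parent")
  }
  inlet_rows <- which(fluid[1, ])
  outlet_rows <- which(fluid[nx, ])

  # 4-connectivity flood fill from the inlet column
  reach <- matrix(FALSE, nx, ny)
  frontier <- cbind(1L, inlet_rows)
  reach[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    nb <- rbind(cbind(frontier[, 1] + 1L, frontier[, 2]),
                cbind(frontier[, 1] - 1L, frontier[, 2]),
                cbind(frontier[, 1], frontier[, 2] + 1L),
                cbind(frontier[, 1], frontier[, 2] - 1L))
    ok <- nb[, 1] >= 1L & nb[, 1] <= nx & nb[, 2] >= 1L & nb[, 2] <= ny
    nb <- nb[ok, , drop = FALSE]
    new <- nb[fluid[nb] & !reach[nb], , drop = FALSE]
    if (nrow(new) > 0) new <- unique(new)
    reach[new] <- TRUE
    frontier <- new
  }
  if (any(fluid & !reach)) {
    stop("geometry error: fluid region is not 4-connected from the inlet")
  }

  # wall elements: faces of fluid cells adjacent to solid / domain boundary
  we <- enumerate_wall_elements(fluid, h, nx, ny)
  sac_cell <- if (has_sac) yc[we$j] > H else rep(FALSE, nrow(we))
  we$region <- ifelse(sac_cell, "sac", "other")

  mesh <- structure(list(
    cell_size = h, nx = nx, ny = ny, fluid = fluid,
    wall_elements = we,
    inlet_rows = inlet_rows, outlet_rows = outlet_rows,
    n_parent_rows = n_parent_rows,
    geom = geom
  ), class = "aneurysm_mesh")

  if (has_sac) {
    if (!any(we$region == "sac")) {
      stop("resolution too coarse: no fluid cells resolved inside the sac")
    }
    mesh <- project_sac_weights(mesh, geom)
    if (tag_probe) {
      mesh <- locate_parent_probe(mesh, geom,
                                  probe_distance = probe_distance,
                                  probe_extent = probe_extent,
                                  side = probe_side)
    }
  }
  mesh
}

enumerate_wall_elements <- function(fluid, h, nx, ny) {
  idx <- which(fluid, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  solid_at <- function(ii, jj) {
    out <- ii < 1L | ii > nx | jj < 1L | jj > ny
    inb <- !out
    res <- out
    res[inb] <- !fluid[cbind(ii[inb], jj[inb])]
    res
  }
  rows <- list()
  # north face at (xc, j*h)
  n_wall <- solid_at(i, j + 1L)
  rows$N <- data.frame(i = i[n_wall], j = j[n_wall], face = rep("N", sum(n_wall)),
                       x = (i[n_wall] - 0.5) * h, y = j[n_wall] * h)
  s_wall <- solid_at(i, j - 1L)
  rows$S <- data.frame(i = i[s_wall], j = j[s_wall], face = rep("S", sum(s_wall)),
                       x = (i[s_wall] - 0.5) * h, y = (j[s_wall] - 1) * h)
  # east/west faces; inlet (i=1, west) and outlet (i=nx, east) are open
  e_wall <- solid_at(i + 1L, j) & i < nx
  rows$E <- data.frame(i = i[e_wall], j = j[e_wall], face = rep("E", sum(e_wall)),
                       x = i[e_wall] * h, y = (j[e_wall] - 0.5) * h)
  w_wall <- solid_at(i - 1L, j) & i > 1L
  rows$W <- data.frame(i = i[w_wall], j = j[w_wall], face = rep("W", sum(w_wall)),
                       x = (i[w_wall] - 1) * h, y = (j[w_wall] - 0.5) * h)
  we <- do.call(rbind, rows)
  rownames(we) <- NULL
  we$weight <- h
  we
}

# Distribute the true sac-polyline arc length over the sac wall faces:
# each polyline sub-segment's length is assigned to the nearest sac face
# center, so sum(sac weights) equals the polyline arc length.
project_sac_weights <- function(mesh, geom) {
  we <- mesh$wall_elements
  sac_idx <- which(we$region == "sac")
  sac <- geom$sac_boundary
  # resample the polyline finely so assignment is smooth
  seg <- sqrt(diff(sac[, 1])^2 + diff(sac[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_fine <- max(2000L, 10L * length(sac_idx))
  sm <- (seq_len(n_fine) - 0.5) / n_fine * total
  px <- stats::approx(s, sac[, 1], xout = sm)$y
  py <- stats::approx(s, sac[, 2], xout = sm)$y
  fx <- we$x[sac_idx]; fy <- we$y[sac_idx]
  nearest <- vapply(seq_len(n_fine), function(k) {
    which.min((fx - px[k])^2 + (fy - py[k])^2)
  }, integer(1))
  wts <- tabulate(nearest, nbins = length(sac_idx)) * (total / n_fine)
  we$weight[sac_idx] <- wts
  mesh$wall_elements <- we
  mesh
}

#' Tag the parent-vessel reference (probe) segment
#'
#' Marks wall elements on the sac-bearing parent wall, centered a fixed
#' distance from the nearer neck endpoint, as `parent_probe`. The probe is
#' where the parent-vessel reference WSS (PWSS) is averaged; 10 mm from the
#' neck is the conventional location. The upstream (inflow) side is the
#' default reference; `side = "downstream"` is accepted.
#'
#' @param mesh An `aneurysm_mesh`.
#' @param geom The generating `aneurysm_geometry`.
#' @param probe_distance Distance from the nearer neck endpoint to the probe
#'   center, mm.
#' @param probe_extent Length of wall tagged, mm.
#' @param side `"upstream"` or `"downstream"` of the neck.
#' @return The mesh with `parent_probe` tags set.
#' @export
locate_parent_probe <- function(mesh, geom, probe_distance = 10,
                                probe_extent = 2, side = "upstream") {
  stopifnot(inherits(mesh, "aneurysm_mesh"),
            inherits(geom, "aneurysm_geometry"))
  side <- match.arg(side, c("upstream", "downstream"))
  w2 <- geom$neck_width / 2
  if (side == "upstream") {
    x_probe <- (geom$neck_center - w2) - probe_distance
    lo <- x_probe - probe_extent / 2
    hi <- x_probe + probe_extent / 2
    if (lo < 0) {
      stop("parameter error: parent too short upstream for probe_distance ",
           probe_distance, " mm (probe would start at x = ",
           signif(lo, 4), " mm)")
    }
    if (hi > geom$neck_center - w2) {
      stop("parameter error: probe segment overlaps the neck")
    }
  } else {
    x_probe <- (geom$neck_center + w2) + probe_distance
    lo <- x_probe - probe_extent / 2
    hi <- x_probe + probe_extent / 2
    if (hi > geom$parent_length) {
      stop("parameter error: parent too short downstream for probe_distance ",
           probe_distance, " mm")
    }
    if (lo < geom$neck_center + w2) {
      stop("parameter error: probe segment overlaps the neck")
    }
  }
  we <- mesh$wall_elements
  h <- mesh$cell_size
  y_wall <- mesh$n_parent_rows * h  # discrete sac-bearing wall height
  on_wall <- we$face == "N" & abs(we$y - y_wall) < h / 2 & we$region == "other"
  in_span <- we$x >= lo & we$x <= hi
  sel <- on_wall & in_span
  if (!any(sel)) stop("parameter error: no wall elements in the probe span")
  we$region[sel] <- "parent_probe"
  mesh$wall_elements <- we
  mesh$probe <- list(distance = probe_distance, extent = probe_extent,
                     side = side, center_x = x_probe)
  mesh
}

#' @export
print.aneurysm_mesh <- function(x, ...) {
  reg <- table(x$wall_elements$region)
  cat(sprintf("Staggered mesh: %d x %d cells (h = %.4g mm), %d fluid\n",
              x$nx, x$ny, x$cell_size, sum(x$fluid)))
  cat("  wall elements:",
      paste(names(reg), as.integer(reg), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
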