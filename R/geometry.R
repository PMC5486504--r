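#' Construct a parametric sidewall-aneurysm geometry
#'
#' Builds an idealized two-dimensional sidewall aneurysm: a straight parent
#' channel (lumen `y` in `[0, parent_caliber]`) with a sac cavity attached to
#' the upper wall (`y = parent_caliber`). Two shape families are supported:
#'
#' * `"hemispherical-bump"`: the sac is a half-disc of radius `sac_size`
#'   sitting on the wall; the neck width equals the sac diameter, so the
#'   aspect ratio is 0.5 (a canonical wide-necked shape).
#' * `"circular-sac-with-neck"`: the sac is a full disc of radius `sac_size`
#'   whose center sits `sac_offset` above the wall, joined to the lumen by a
#'   constricted neck of width `neck_width`; deep high-aspect-ratio sacs are
#'   produced by raising `sac_offset`.
#'
#' Together the two families span the aspect-ratio range seen clinically
#' (roughly 0.5 to above 3).
#'
#' All lengths are in millimetres. The sac boundary is returned as an ordered
#' polyline running from one neck endpoint to the other, strictly outside the
#' parent lumen except at the neck.
#'
#' @param shape_family `"hemispherical-bump"` or `"circular-sac-with-neck"`.
#' @param parent_caliber Channel height (stand-in for vessel diameter), mm.
#' @param neck_width Neck opening width, mm. Ignored (set to `2 * sac_size`)
#'   for the hemispherical family.
#' @param sac_size Sac radius, mm.
#' @param sac_offset Height of the sac-circle center above the wall, mm
#'   (circular family only). Must be at least
#'   `sqrt(sac_size^2 - (neck_width / 2)^2)` so the disc does not protrude
#'   below the wall outside the neck.
#' @param parent_length Parent channel length, mm.
#' @param neck_center Position of the neck midpoint along the wall, mm.
#' @param resolution Number of points used to discretize the sac boundary
#'   polyline.
#' @return An object of class `aneurysm_geometry` with fields
#'   `parent_length`, `parent_caliber`, `neck_center`, `neck_width`,
#'   `sac_boundary` (two-column matrix, mm), `shape_family`, and the shape
#'   parameters.
#' @examples
#' geom <- make_geometry("hemispherical-bump", sac_size = 2)
#' measure_morphology(geom)
#' @export
make_geometry <- function(shape_family = c("hemispherical-bump",
                                           "circular-sac-with-neck"),
                          parent_caliber = 3.24,
                          neck_width = NULL,
                          sac_size = 2,
                          sac_offset = 0,
                          parent_length = 30,
                          neck_center = 18,
                          resolution = 200) {
  shape_family <- match.arg(shape_family)
  for (nm in c("parent_caliber", "sac_size", "parent_length", "neck_center")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter error: `", nm, "` must be a positive finite scalar")
    }
  }
  if (resolution < 8) stop("parameter error: `resolution` must be >= 8")

  H <- parent_caliber
  x0 <- neck_center

  if (shape_family == "hemispherical-bump") {
    r <- sac_size
    neck_width <- 2 * r
    th <- seq(pi, 0, length.out = resolution)
    sac <- cbind(x = x0 + r * cos(th), y = H + r * sin(th))
  } else {
    if (is.null(neck_width)) {
      stop("parameter error: `neck_width` is required for circular-sac-with-neck")
    }
    if (neck_width <= 0) stop("parameter error: `neck_width` must be > 0")
    r <- sac_size
    w <- neck_width
    if (w >= 2 * r) {
      stop("parameter error: neck_width (", w,
           " mm) must be smaller than the sac diameter (", 2 * r, " mm)")
    }
    y_join_min <- sqrt(r^2 - (w / 2)^2)
    if (sac_offset < y_join_min - 1e-12) {
      stop("parameter error: sac_offset (", sac_offset,
           " mm) must be >= sqrt(sac_size^2 - (neck_width/2)^2) = ",
           signif(y_join_min, 6),
           " mm so the sac does not protrude below the wall")
    }
    c0 <- sac_offset
    # vertical neck segments join the wall to the circle at y_join
    y_join <- c0 - sqrt(r^2 - (w / 2)^2)
    # junction angles on the circle (center (x0, H + c0)); the dome arc runs
    # from the left junction over the top to the right junction
    th_right <- atan2(y_join - c0, w / 2)   # in (-pi/2, 0]
    th_left <- pi - th_right
    n_arc <- max(resolution - 4L, 9L)
    if (n_arc %% 2L == 0L) n_arc <- n_arc + 1L  # odd: apex theta = pi/2 exact
    th_seq <- seq(th_left, th_right, length.out = n_arc)
    arc <- cbind(x = x0 + r * cos(th_seq), y = H + c0 + r * sin(th_seq))
    # first/last segments are the vertical neck legs (degenerate when the
    # circle touches the wall, y_join ~ 0)
    sac <- rbind(c(x0 - w / 2, H), arc, c(x0 + w / 2, H))
    colnames(sac) <- c("x", "y")
  }

  geom <- structure(list(
    parent_length = parent_length,
    parent_caliber = parent_caliber,
    neck_center = neck_center,
    neck_width = neck_width,
    sac_boundary = sac,
    shape_family = shape_family,
    sac_size = sac_size,
    sac_offset = if (shape_family == "hemispherical-bump") 0 else sac_offset,
    resolution = as.integer(resolution)
  ), class = "aneurysm_geometry")

  validate_geometry(geom)
  geom
}

#' Straight parent channel without a sac
#'
#' A degenerate geometry used for solver validation (plane Poiseuille and
#' pulsatile channel benchmarks).
#'
#' @param parent_length Channel length, mm.
#' @param parent_caliber Channel height, mm.
#' @return An object of class `channel_geometry`.
#' @export
straight_channel <- function(parent_length = 30, parent_caliber = 3.24) {
  if (parent_length <= 0 || parent_caliber <= 0) {
    stop("parameter error: lengths must be positive")
  }
  structure(list(parent_length = parent_length,
                 parent_caliber = parent_caliber),
            class = "channel_geometry")
}

validate_geometry <- function(geom) {
  sac <- geom$sac_boundary
  H <- geom$parent_caliber
  x0 <- geom$neck_center
  w <- geom$neck_width
  if (nrow(sac) < 3) stop("geometry error: sac boundary has < 3 points")
  ends <- sac[c(1, nrow(sac)), , drop = FALSE]
  want <- rbind(c(x0 - w / 2, H), c(x0 + w / 2, H))
  if (max(abs(ends - want)) > 1e-9) {
    stop("geometry error: sac boundary endpoints do not coincide with the ",
         "neck endpoints")
  }
  if (any(sac[-c(1, nrow(sac)), "y"] < H - 1e-9)) {
    stop("geometry error: sac boundary dips inside the parent lumen")
  }
  sac_xmax <- max(abs(sac[, "x"] - x0)) # half-extent
  if (x0 - sac_xmax < 1e-9 || x0 + sac_xmax > geom$parent_length - 1e-9) {
    stop("parameter error: sac overlaps the inlet or outlet; increase ",
         "parent_length or move neck_center")
  }
  neck_extent <- w
  if (geom$parent_length < 10 + neck_extent) {
    stop("parameter error: parent_length must be >= 10 mm + neck extent ",
         "to fit the parent sampling site")
  }
  invisible(geom)
}

#' Measure sidewall-aneurysm morphology
#'
#' Height is the maximum distance from the neck midpoint to any point of the
#' sac boundary (the dome); this is the maximal-distance reading of the
#' clinical height definition. Aspect ratio is height / neck width. The dome
#' measure is the sac boundary arc length, the two-dimensional stand-in for
#' dome area.
#'
#' @param geom An `aneurysm_geometry`.
#' @return An object of class `morphology_measures` with fields `height`,
#'   `neck_width`, `aspect_ratio`, `dome_measure` (all mm except the
#'   dimensionless aspect ratio) and `neck_category`.
#' @export
measure_morphology <- function(geom) {
  stopifnot(inherits(geom, "aneurysm_geometry"))
  sac <- geom$sac_boundary
  if (nrow(sac) < 3) stop("geometry error: degenerate sac boundary (< 3 points)")
  neck_mid <- c(geom$neck_center, geom$parent_caliber)
  d <- sqrt((sac[, "x"] - neck_mid[1])^2 + (sac[, "y"] - neck_mid[2])^2)
  height <- max(d)
  seg <- sqrt(diff(sac[, "x"])^2 + diff(sac[, "y"])^2)
  dome <- sum(seg)
  m <- structure(list(
    height = height,
    neck_width = geom$neck_width,
    aspect_ratio = height / geom$neck_width,
    dome_measure = dome,
    neck_category = NA_character_
  ), class = "morphology_measures")
  m$neck_category <- classify_neck(m)
  m
}

#' Classify an aneurysm neck as narrow or wide
#'
#' Narrow-necked: aspect ratio >= 1.4 *and* neck width < 4 mm. Wide-necked
#' otherwise (aspect ratio < 1.4, or neck width >= 4 mm). A neck of 4 mm or
#' more forces the wide category even at high aspect ratio: the absolute
#' neck-width clause overrides, matching the clinical wide-neck convention.
#'
#' @param m A `morphology_measures` object, or a numeric aspect ratio (in
#'   which case `neck_width` must be given).
#' @param neck_width Neck width in mm when `m` is a bare aspect ratio.
#' @return `"narrow"` or `"wide"`.
#' @export
classify_neck <- function(m, neck_width = NULL) {
  if (inherits(m, "morphology_measures")) {
    ar <- m$aspect_ratio
    nw <- m$neck_width
  } else {
    ar <- m
    nw <- neck_width
    if (is.null(nw)) stop("neck_width required when `m` is an aspect ratio")
  }
  if (ar >= 1.4 && nw < 4) "narrow" else "wide"
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat("Sidewall aneurysm geometry (", x$shape_family, ")\n", sep = "")
  cat(sprintf("  parent: %.2f x %.2f mm, neck %.2f mm at x = %.2f mm\n",
              x$parent_length, x$parent_caliber, x$neck_width, x$neck_center))
  cat(sprintf("  sac boundary: %d points, sac radius %.2f mm, offset %.2f mm\n",
              nrow(x$sac_boundary), x$sac_size, x$sac_offset))
  invisible(x)
}

#' @export
print.morphology_measures <- function(x, ...) {
  cat(sprintf(paste0("Morphology: height %.3f mm, neck %.3f mm, AR %.3f, ",
                     "dome %.3f mm (%s-necked)\n"),
              x$height, x$neck_width, x$aspect_ratio, x$dome_measure,
              x$neck_category))
  invisible(x)
}

#' Geometry serialization
#'
#' Geometries round-trip losslessly through two plain-text forms: a JSON
#' parameter file (the constructor arguments) and a CSV polyline (`x,y` in
#' mm with a header row).
#'
#' @param geom An `aneurysm_geometry`.
#' @param path File path.
#' @return `geometry_to_json`/`polyline_to_csv` invisibly return `path`;
#'   the readers return an `aneurysm_geometry` / two-column matrix.
#' @export
geometry_to_json <- function(geom, path) {
  stopifnot(inherits(geom, "aneurysm_geometry"))
  pars <- list(shape_family = geom$shape_family,
               parent_caliber = geom$parent_caliber,
               neck_width = geom$neck_width,
               sac_size = geom$sac_size,
               sac_offset = geom$sac_offset,
               parent_length = geom$parent_length,
               neck_center = geom$neck_center,
               resolution = geom$resolution)
  jsonlite::write_json(pars, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometry_to_json
#' @export
geometry_from_json <- function(path) {
  pars <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (pars$shape_family == "hemispherical-bump") {
    make_geometry("hemispherical-bump",
                  parent_caliber = pars$parent_caliber,
                  sac_size = pars$sac_size,
                  parent_length = pars$parent_length,
                  neck_center = pars$neck_center,
                  resolution = pars$resolution)
  } else {
    make_geometry("circular-sac-with-neck",
                  parent_caliber = pars$parent_caliber,
                  neck_width = pars$neck_width,
                  sac_size = pars$sac_size,
                  sac_offset = pars$sac_offset,
                  parent_length = pars$parent_length,
                  neck_center = pars$neck_center,
                  resolution = pars$resolution)
  }
}

#' @rdname geometry_to_json
#' @export
polyline_to_csv <- function(geom, path) {
  stopifnot(inherits(geom, "aneurysm_geometry"))
  df <- as.data.frame(geom$sac_boundary)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname geometry_to_json
#' @export
polyline_from_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x", "y")])
}
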