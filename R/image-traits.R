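# Plant segmentation and image-derived canopy traits.
#
# Conventions (fixed across the package): images are rows x cols x 3 arrays
# with channel intensities in [0, 255]; masks are logical matrices;
# coordinates are (row, col), 0-based, origin top-left; "vertical" for leaf
# angles is the decreasing-row direction.

#' Hue/saturation/brightness segmentation thresholds
#'
#' Defaults capture green foliage on a light background: hue 60-180 degrees,
#' saturation >= 0.25, brightness >= 0.20. Hue intervals may wrap around 360
#' (e.g. `c(330, 30)` for reds).
#'
#' @param hue_deg Length-2 hue interval in degrees, each in \[0, 360).
#' @param saturation Length-2 saturation interval in \[0, 1\].
#' @param brightness Length-2 brightness interval in \[0, 1\].
#' @return An object of class `hsb_thresholds`.
#' @export
hsb_thresholds <- function(hue_deg = c(60, 180),
                           saturation = c(0.25, 1),
                           brightness = c(0.20, 1)) {
  stopifnot(length(hue_deg) == 2L, length(saturation) == 2L, length(brightness) == 2L,
            all(hue_deg >= 0 & hue_deg < 360),
            all(saturation >= 0 & saturation <= 1), saturation[1L] <= saturation[2L],
            all(brightness >= 0 & brightness <= 1), brightness[1L] <= brightness[2L])
  structure(list(hue_deg = as.numeric(hue_deg),
                 saturation = as.numeric(saturation),
                 brightness = as.numeric(brightness)),
            class = "hsb_thresholds")
}

#' @export
print.hsb_thresholds <- function(x, ...) {
  cat(sprintf("HSB thresholds: hue [%g, %g] deg, sat [%g, %g], bright [%g, %g]\n",
              x$hue_deg[1L], x$hue_deg[2L], x$saturation[1L], x$saturation[2L],
              x$brightness[1L], x$brightness[2L]))
  invisible(x)
}

in_interval <- function(x, iv) x >= iv[1L] & x <= iv[2L]

in_hue_interval <- function(h, iv) {
  if (iv[1L] <= iv[2L]) h >= iv[1L] & h <= iv[2L] else h >= iv[1L] | h <= iv[2L]
}

#' Segment the plant from an RGB image
#'
#' A pixel is foreground iff its hue, saturation and brightness all fall in
#' the threshold intervals; optionally only the largest 8-connected
#' foreground component is kept (removes speckle and the calibration ruler).
#'
#' @param image rows x cols x 3 numeric array, intensities in \[0, 255\].
#' @param thresholds An [hsb_thresholds()] object.
#' @param keep_largest Keep only the largest 8-connected component.
#' @return Logical matrix, `TRUE` = plant.
#' @export
segment_plant <- function(image, thresholds = hsb_thresholds(), keep_largest = TRUE) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] >= 3L)
  dm <- dim(image)[1:2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1L]),
                            g = as.vector(image[, , 2L]),
                            b = as.vector(image[, , 3L]),
                            maxColorValue = 255)
  fg <- in_hue_interval(hsv[1L, ] * 360, thresholds$hue_deg) &
    in_interval(hsv[2L, ], thresholds$saturation) &
    in_interval(hsv[3L, ], thresholds$brightness)
  mask <- matrix(fg, nrow = dm[1L], ncol = dm[2L])
  if (!any(mask)) {
    rlang::abort("no plant detected: no pixel passed the HSB thresholds",
                 class = "phosphoscreen_error_no_plant", thresholds = thresholds)
  }
  if (keep_largest) mask <- largest_component(mask)
  mask
}

# Largest 8-connected foreground component, via the pixel adjacency graph.
largest_component <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  vid <- integer(nr * nc) # linear pixel index -> vertex id
  vid[idx] <- seq_along(idx)
  pos <- which(mask, arr.ind = TRUE)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  edges <- lapply(shifts, function(s) {
    r2 <- pos[, 1L] + s[1L]; c2 <- pos[, 2L] + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    cbind(vid[idx[ok]], vid[(c2[ok] - 1L) * nr + r2[ok]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  out <- matrix(FALSE, nr, nc)
  out[idx[comp$membership == which.max(comp$csize)]] <- TRUE
  out
}

#' Pixel-to-millimetre calibration from a ruler line
#'
#' @param line_endpoints 2 x 2 matrix of the drawn line's endpoints
#'   (row, col).
#' @param known_length_mm Physical length of the line in mm.
#' @return An object of class `scale_calibration` with field `mm_per_px`.
#' @export
calibrate <- function(line_endpoints, known_length_mm) {
  ep <- as_point_matrix(line_endpoints)
  stopifnot(nrow(ep) == 2L)
  if (!is.finite(known_length_mm) || known_length_mm <= 0) {
    stop("known_length_mm must be a positive finite number", call. = FALSE)
  }
  px <- sqrt(sum((ep[1L, ] - ep[2L, ]) ^ 2))
  if (px == 0) stop("calibration endpoints coincide", call. = FALSE)
  structure(list(mm_per_px = known_length_mm / px), class = "scale_calibration")
}

#' Shorthand calibration from a known scale
#' @param mm_per_px Millimetres per pixel, > 0.
#' @return A `scale_calibration` object.
#' @export
scale_calibration <- function(mm_per_px) {
  stopifnot(is.finite(mm_per_px), mm_per_px > 0)
  structure(list(mm_per_px = as.numeric(mm_per_px)), class = "scale_calibration")
}

#' Projected (silhouette) area of a mask
#'
#' Foreground pixel count converted to physical units.
#'
#' @param mask Logical matrix.
#' @param cal A `scale_calibration`.
#' @return Area in mm^2.
#' @export
projected_area <- function(mask, cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  n <- sum(mask)
  if (n == 0L) stop("empty mask: no foreground pixels", call. = FALSE)
  n * cal$mm_per_px ^ 2
}

#' Whole plant area from the three views
#'
#' Sum of the projected areas of the top view and the two side views.
#'
#' @param top,front,back Projected areas in mm^2, non-negative.
#' @return WPA in mm^2.
#' @export
whole_plant_area <- function(top, front, back) {
  areas <- c(top, front, back)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("areas must be finite and non-negative", call. = FALSE)
  }
  top + front + back
}

#' Top-view canopy geometry
#'
#' Computes the image-derived geometric trait set from a segmented top view:
#' projected area, convex hull area and perimeter, calliper (maximum Feret)
#' length, minimum enclosing circle, and moment-ellipse eccentricity.
#' Geometry uses the pixel-center convention: a single pixel has projected
#' area of one pixel but zero hull area.
#'
#' @param mask Logical matrix, `TRUE` = plant.
#' @param cal A `scale_calibration`.
#' @param view View tag recorded in the output (default `"top"`).
#' @return One-row tibble: `view`, `projected_area_mm2`, `hull_area_mm2`,
#'   `hull_perimeter_mm`, `calliper_length_mm`, `mec_row_px`, `mec_col_px`,
#'   `mec_diameter_mm`, `eccentricity`.
#' @export
top_view_geometry <- function(mask, cal, view = "top") {
  stopifnot(inherits(cal, "scale_calibration"))
  if (!any(mask)) stop("empty mask: no foreground pixels", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE) - 1 # 0-based pixel centers
  mm <- cal$mm_per_px
  hull <- convex_hull(pts)
  hull_area <- polygon_area(hull)
  if (nrow(pts) >= 3L && hull_area == 0) {
    warning("foreground pixels are collinear; hull area is zero", call. = FALSE)
  }
  mec <- min_enclosing_circle(pts)
  tibble::tibble(
    view = view,
    projected_area_mm2 = nrow(pts) * mm ^ 2,
    hull_area_mm2 = hull_area * mm ^ 2,
    hull_perimeter_mm = polygon_perimeter(hull) * mm,
    calliper_length_mm = calliper_length(hull) * mm,
    mec_row_px = mec$center[1L],
    mec_col_px = mec$center[2L],
    mec_diameter_mm = mec$diameter * mm,
    eccentricity = moment_eccentricity(pts)
  )
}

#' Leaf inclination angle
#'
#' Angle between the upward vertical (the stem axis in a rectified side
#' view; decreasing row direction) and the lamina-joint-to-blade vector,
#' in degrees in \[0, 180\]. Both arguments may be matrices with one
#' (row, col) landmark pair per row.
#'
#' @param lamina_joint (row, col) of the lamina joint.
#' @param blade_point (row, col) of a point on the leaf blade.
#' @return Numeric vector of angles in degrees.
#' @export
leaf_angle <- function(lamina_joint, blade_point) {
  j <- matrix(as.numeric(lamina_joint), ncol = 2L)
  b <- matrix(as.numeric(blade_point), ncol = 2L)
  stopifnot(nrow(j) == nrow(b))
  v <- b - j
  len <- sqrt(rowSums(v ^ 2))
  if (any(len == 0)) stop("blade point coincides with lamina joint", call. = FALSE)
  # upward vertical is (-1, 0) in (row, col)
  cosang <- pmin(1, pmax(-1, -v[, 1L] / len))
  acos(cosang) * 180 / pi
}

#' Extract geometric traits from a directory of plant images
#'
#' Batch interface over [segment_plant()] and [top_view_geometry()]. Each
#' PNG is segmented with the supplied thresholds; calibration and view tag
#' are taken from the image's JSON sidecar (written by
#' [write_plant_image()]) unless overridden by `cal`.
#'
#' @param image_paths Character vector of PNG paths.
#' @param thresholds An [hsb_thresholds()] object.
#' @param cal Optional `scale_calibration` applied to every image; if
#'   `NULL`, each image's sidecar supplies the scale.
#' @return Tibble, one row per image, keyed by `image_id` and `view`.
#' @export
extract_image_traits <- function(image_paths, thresholds = hsb_thresholds(),
                                 cal = NULL) {
  purrr::map_dfr(image_paths, function(path) {
    img <- read_plant_image(path)
    meta <- attr(img, "sidecar")
    this_cal <- cal
    if (is.null(this_cal)) {
      if (is.null(meta)) stop("no sidecar metadata for ", path,
                              "; supply `cal`", call. = FALSE)
      this_cal <- scale_calibration(meta$scale_mm_per_px)
    }
    view <- if (!is.null(meta)) meta$view else "top"
    mask <- segment_plant(img, thresholds)
    geo <- top_view_geometry(mask, this_cal, view = view)
    dplyr::bind_cols(
      tibble::tibble(image_id = sub("\\.png$", "", basename(path))), geo)
  })
}
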