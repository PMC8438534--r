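# Synthetic plant-image generator with exact ground truth.
#
# The renderer is deliberately schematic: leaves are filled quadrilaterals
# radiating from a single stem point, because the goal is exact, provable
# geometry, not realism. Every polygon corner is offset 0.25 px from the
# integer pixel-center grid, so no pixel center ever falls on an
# axis-aligned edge and rectangle areas rasterize exactly.

STEM_WIDTH_MM <- 4

#' Specification of a synthetic plant
#'
#' @param leaves Data frame with one row per leaf and columns `length_mm`
#'   (> 0), `width_mm` (> 0), `inclination_deg` (angle from the vertical
#'   stem axis, \[0, 90\]) and `azimuth_deg` (compass direction of the leaf
#'   in the top view, \[0, 360)).
#' @param n_tillers Tiller count (metadata; the rendered crown is a single
#'   rosette).
#' @param stem_height_mm Stem height, > 0.
#' @param foreground_hue_deg Foliage hue in degrees; must lie inside the
#'   default green segmentation window (60-180) so the default pipeline can
#'   recover the plant.
#' @param background_color RGB triple in \[0, 255\].
#' @param scale_mm_per_px Physical size of one pixel.
#' @param image_size_px Canvas size `c(rows, cols)`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units); ground truth always refers to the noise-free
#'   geometry.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(leaves,
                       n_tillers = 1L,
                       stem_height_mm = 200,
                       foreground_hue_deg = 120,
                       background_color = c(245, 245, 245),
                       scale_mm_per_px = 1,
                       image_size_px = c(560, 560),
                       noise_sd = 0) {
  leaves <- tibble::as_tibble(leaves)
  stopifnot(nrow(leaves) >= 1L,
            all(c("length_mm", "width_mm", "inclination_deg", "azimuth_deg")
                %in% names(leaves)),
            all(leaves$length_mm > 0), all(leaves$width_mm > 0),
            all(leaves$inclination_deg >= 0 & leaves$inclination_deg <= 90),
            all(leaves$azimuth_deg >= 0 & leaves$azimuth_deg < 360),
            n_tillers >= 1L, stem_height_mm > 0, scale_mm_per_px > 0,
            length(image_size_px) == 2L, all(image_size_px >= 32L),
            length(background_color) == 3L,
            all(background_color >= 0 & background_color <= 255),
            noise_sd >= 0)
  if (foreground_hue_deg < 60 || foreground_hue_deg > 180) {
    stop("foreground_hue_deg must lie in the default green window [60, 180] ",
         "so the default segmentation recovers the plant", call. = FALSE)
  }
  structure(list(leaves = leaves, n_tillers = as.integer(n_tillers),
                 stem_height_mm = stem_height_mm,
                 foreground_hue_deg = foreground_hue_deg,
                 background_color = as.numeric(background_color),
                 scale_mm_per_px = scale_mm_per_px,
                 image_size_px = as.integer(image_size_px),
                 noise_sd = noise_sd),
            class = "plant_spec")
}

#' Random but valid synthetic plant specification
#'
#' Samples a rosette of 4-8 leaves with lengths 80-180 mm, widths 6-14 mm,
#' inclinations 30-80 degrees and spread azimuths -- roughly the habit of a
#' month-old rice seedling -- guaranteed to fit the default canvas.
#'
#' @param seed Integer seed.
#' @param n_leaves Number of leaves (default sampled in 4-8).
#' @param noise_sd Pixel noise level passed through to [plant_spec()].
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(seed, n_leaves = NULL, noise_sd = 0) {
  with_local_seed(seed, {
    if (is.null(n_leaves)) n_leaves <- sample(4:8, 1L)
    az <- (seq_len(n_leaves) - 1L) * 360 / n_leaves + stats::runif(1L, 0, 360 / n_leaves)
    leaves <- tibble::tibble(
      length_mm = stats::runif(n_leaves, 80, 180),
      width_mm = stats::runif(n_leaves, 6, 14),
      inclination_deg = stats::runif(n_leaves, 30, 80),
      azimuth_deg = az %% 360
    )
    plant_spec(leaves,
               n_tillers = sample(1:4, 1L),
               stem_height_mm = stats::runif(1L, 150, 250),
               foreground_hue_deg = stats::runif(1L, 90, 150),
               noise_sd = noise_sd)
  })
}

# run code under a temporary RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# leaf polygons in 0-based (row, col) px for one view; +0.25 px grid offset
plant_polygons <- function(spec, view) {
  rows <- spec$image_size_px[1L]; cols <- spec$image_size_px[2L]
  sc <- spec$scale_mm_per_px
  off <- 0.25
  polys <- list()
  joints <- NULL
  n <- nrow(spec$leaves)
  if (view == "top") {
    p0 <- c(floor(rows / 2) + off, floor(cols / 2) + off)
    for (i in seq_len(n)) {
      lf <- spec$leaves[i, ]
      L <- lf$length_mm * sin(lf$inclination_deg * pi / 180) / sc
      W <- lf$width_mm / sc
      az <- lf$azimuth_deg * pi / 180
      u <- c(sin(az), cos(az))   # (d_row, d_col); azimuth 0 points +col
      nv <- c(-u[2L], u[1L])
      polys[[i]] <- rbind(p0 - nv * W / 2, p0 + nv * W / 2,
                          p0 + u * L + nv * W / 2, p0 + u * L - nv * W / 2)
    }
  } else {
    base <- c(rows - 11 + off, floor(cols / 2) + off)
    H <- spec$stem_height_mm / sc
    Ws <- STEM_WIDTH_MM / sc
    polys[["stem"]] <- rbind(base + c(0, -Ws / 2), base + c(0, Ws / 2),
                             base + c(-H, Ws / 2), base + c(-H, -Ws / 2))
    mirror <- if (view == "back") -1 else 1
    joints <- matrix(NA_real_, n, 4L)
    for (i in seq_len(n)) {
      lf <- spec$leaves[i, ]
      L <- lf$length_mm / sc
      W <- lf$width_mm / sc
      side <- mirror * (if (lf$azimuth_deg < 180) 1 else -1)
      th <- lf$inclination_deg * pi / 180
      u <- c(-cos(th), side * sin(th))
      nv <- c(-u[2L], u[1L])
      joint <- base + c(-H * i / (n + 1), 0)
      tip <- joint + u * L
      polys[[length(polys) + 1L]] <- rbind(joint - nv * W / 2, joint + nv * W / 2,
                                           tip + nv * W / 2, tip - nv * W / 2)
      joints[i, ] <- c(joint, tip)
    }
  }
  list(polys = polys, joints = joints)
}

# vectorized even-odd point-in-polygon; pts and poly are (row, col)
points_in_polygon <- function(pts, poly) {
  x <- pts[, 2L]; y <- pts[, 1L]
  px <- poly[, 2L]; py <- poly[, 1L]
  k <- length(px)
  inside <- rep(FALSE, length(x))
  j <- k
  for (i in seq_len(k)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

rasterize_polygons <- function(polys, rows, cols) {
  mask <- matrix(FALSE, rows, cols)
  for (poly in polys) {
    r_rng <- floor(min(poly[, 1L])):ceiling(max(poly[, 1L]))
    c_rng <- floor(min(poly[, 2L])):ceiling(max(poly[, 2L]))
    r_rng <- r_rng[r_rng >= 0 & r_rng < rows]
    c_rng <- c_rng[c_rng >= 0 & c_rng < cols]
    if (!length(r_rng) || !length(c_rng)) next
    grid <- as.matrix(expand.grid(r = r_rng, c = c_rng))
    hit <- points_in_polygon(grid, poly)
    mask[grid[hit, , drop = FALSE] + 1] <- TRUE
  }
  mask
}

# Andrew's monotone-chain hull: independent of grDevices::chull, used only
# for ground truth.
monotone_chain_hull <- function(pts) {
  pts <- unique(pts[order(pts[, 2L], pts[, 1L]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  half <- function(idx) {
    out <- integer(0)
    for (i in idx) {
      while (length(out) >= 2L &&
             cross2(pts[out[length(out) - 1L], ], pts[out[length(out)], ],
                    pts[i, ]) <= 0) {
        out <- out[-length(out)]
      }
      out <- c(out, i)
    }
    out
  }
  lower <- half(seq_len(n))
  upper <- half(rev(seq_len(n)))
  pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
}

# Ground truth geometry for a noise-free mask, by brute force only.
mask_ground_truth <- function(mask, sc) {
  pts <- which(mask, arr.ind = TRUE) - 1
  hull <- monotone_chain_hull(pts)
  mec <- bf_min_enclosing_circle(hull)
  ctr <- sweep(pts, 2L, colMeans(pts))
  s <- crossprod(ctr) / nrow(pts)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1L] <= 0) 0 else sqrt(max(0, 1 - ev[2L] / ev[1L]))
  list(foreground_pixel_count = nrow(pts),
       projected_area_mm2 = nrow(pts) * sc ^ 2,
       hull_area_mm2 = polygon_area(hull) * sc ^ 2,
       hull_perimeter_mm = polygon_perimeter(hull) * sc,
       calliper_length_mm = bf_max_pairwise_distance(hull) * sc,
       mec_diameter_mm = mec$diameter * sc,
       eccentricity = ecc)
}

#' Render a synthetic plant image with ground truth
#'
#' Draws the plant of `spec` as seen from one of the three camera positions
#' used in shoot phenotyping (top view plus front/back side views), together
#' with a pure-red calibration line of known physical length, and returns
#' both the image and the exact geometry of the rendered foreground. Ground
#' truth is computed from the noise-free mask by brute-force geometry
#' (monotone-chain hull, exhaustive calliper and enclosing-circle search)
#' that shares no code with the measurement pipeline.
#'
#' @param spec A [plant_spec()].
#' @param view One of `"top"`, `"front"`, `"back"`.
#' @param seed Integer seed driving the pixel noise (and nothing else).
#' @return A `plant_render` list: `image` (rows x cols x 3, \[0, 255\]),
#'   `mask` (noise-free foreground), `truth` (ground-truth list; for side
#'   views also `leaf_angles`, a tibble of landmark coordinates and exact
#'   angles), and `sidecar` (calibration metadata).
#' @export
render_plant <- function(spec, view = c("top", "front", "back"), seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  view <- match.arg(view)
  rows <- spec$image_size_px[1L]; cols <- spec$image_size_px[2L]
  pp <- plant_polygons(spec, view)
  for (i in seq_along(pp$polys)) {
    poly <- pp$polys[[i]]
    if (min(poly[, 1L]) < 1 || max(poly[, 1L]) > rows - 6 ||
        min(poly[, 2L]) < 1 || max(poly[, 2L]) > cols - 2) {
      nm <- names(pp$polys)[i]
      what <- if (!is.null(nm) && identical(nm, "stem")) "stem" else paste("leaf", i)
      stop(sprintf("%s exceeds the %d x %d canvas in view '%s'",
                   what, rows, cols, view), call. = FALSE)
    }
  }
  mask <- rasterize_polygons(pp$polys, rows, cols)

  truth <- mask_ground_truth(mask, spec$scale_mm_per_px)
  if (view != "top") {
    n <- nrow(spec$leaves)
    truth$leaf_angles <- tibble::tibble(
      leaf_position = seq_len(n),
      joint_row = pp$joints[, 1L], joint_col = pp$joints[, 2L],
      blade_row = pp$joints[, 3L], blade_col = pp$joints[, 4L],
      angle_deg = spec$leaves$inclination_deg
    )
  }

  img <- array(rep(spec$background_color, each = rows * cols), c(rows, cols, 3L))
  fg_rgb <- grDevices::col2rgb(
    grDevices::hsv(spec$foreground_hue_deg / 360, 0.75, 0.55))[, 1L]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fg_rgb[ch]
    img[, , ch] <- plane
  }
  # calibration line in pure red along the bottom margin
  calib_len_px <- min(100L, cols - 20L)
  calib_row <- rows - 4L # 0-based
  calib_cols <- 10L + 0:(calib_len_px - 1L)
  img[calib_row + 1L, calib_cols + 1L, 1L] <- 255
  img[calib_row + 1L, calib_cols + 1L, 2:3] <- 0

  if (spec$noise_sd > 0) {
    img <- with_local_seed(seed, {
      img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    })
    img <- pmin(pmax(img, 0), 255)
  }

  sidecar <- list(
    view = view,
    scale_mm_per_px = spec$scale_mm_per_px,
    calib_line = list(c(calib_row, calib_cols[1L]),
                      c(calib_row, calib_cols[calib_len_px])),
    calib_mm = (calib_len_px - 1L) * spec$scale_mm_per_px
  )
  structure(list(image = img, mask = mask, truth = truth, sidecar = sidecar),
            class = "plant_render")
}

#' Write a rendered plant to PNG with a JSON sidecar
#'
#' @param render A `plant_render` from [render_plant()].
#' @param path Output PNG path; the sidecar goes to `<path>.json` with the
#'   `.png` extension replaced.
#' @return `path`, invisibly.
#' @export
write_plant_image <- function(render, path) {
  stopifnot(inherits(render, "plant_render"))
  png::writePNG(render$image / 255, target = path)
  jsonlite::write_json(render$sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.png$", ".json", path)

#' Read a plant image (and its sidecar, if present)
#'
#' @param path PNG path.
#' @return rows x cols x 3 array in \[0, 255\]; any sidecar metadata is
#'   attached as attribute `"sidecar"`.
#' @export
read_plant_image <- function(path) {
  img <- png::readPNG(path) * 255
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    attr(img, "sidecar") <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  img
}
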