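# Planar geometry kernels for top-view canopy traits.
#
# All functions work on an n x 2 matrix of pixel-center coordinates
# (row, col), 0-based, origin top-left. Euclidean distance is isotropic so
# the (row, col) ordering never affects areas, lengths or radii.

#' Convex hull of a point set
#'
#' Returns the hull vertices in counter-clockwise order with collinear
#' boundary points removed, so downstream rotating-calipers code sees a
#' strictly convex polygon.
#'
#' @param pts Numeric matrix with two columns (row, col).
#' @return Matrix of hull vertices (two columns), counter-clockwise.
#' @export
convex_hull <- function(pts) {
  pts <- unique(as_point_matrix(pts))
  if (nrow(pts) <= 2L) return(pts)
  idx <- grDevices::chull(pts[, 2L], pts[, 1L])
  hull <- pts[rev(idx), , drop = FALSE] # chull is clockwise in (x, y)
  drop_collinear(hull)
}

as_point_matrix <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("point set must have two columns (row, col)", call. = FALSE)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  pts
}

# cross product z-component of (b - a) x (c - a) in (x = col, y = row) axes
cross2 <- function(a, b, c) {
  (b[2L] - a[2L]) * (c[1L] - a[1L]) - (b[1L] - a[1L]) * (c[2L] - a[2L])
}

drop_collinear <- function(hull, tol = 1e-12) {
  n <- nrow(hull)
  if (n <= 3L) return(hull)
  keep <- vapply(seq_len(n), function(i) {
    a <- hull[if (i == 1L) n else i - 1L, ]
    b <- hull[i, ]
    c <- hull[if (i == n) 1L else i + 1L, ]
    abs(cross2(a, b, c)) > tol
  }, logical(1))
  hull[keep, , drop = FALSE]
}

#' Polygon area by the shoelace formula
#'
#' @param poly Vertex matrix (two columns), any consistent winding.
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 2L]; y <- poly[, 1L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#'
#' @param poly Vertex matrix (two columns).
#' @return Sum of edge lengths, closing the polygon.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  if (n < 2L) return(0)
  nxt <- c(seq_len(n)[-1L], 1L)
  sum(sqrt(rowSums((poly[nxt, , drop = FALSE] - poly) ^ 2)))
}

#' Maximum calliper (Feret) diameter by rotating calipers
#'
#' Longest distance between any two points of the set, computed in O(h) over
#' the convex hull by the classic antipodal-pair sweep. This is the canopy
#' "calliper length" when applied to a top-view mask.
#'
#' @param pts Point matrix (two columns), or a precomputed hull.
#' @return Maximum pairwise Euclidean distance.
#' @export
calliper_length <- function(pts) {
  hull <- convex_hull(pts)
  n <- nrow(hull)
  if (n <= 1L) return(0)
  if (n == 2L) return(sqrt(sum((hull[1L, ] - hull[2L, ]) ^ 2)))
  d2 <- function(i, j) sum((hull[i, ] - hull[j, ]) ^ 2)
  # twice the signed area of triangle (i, j, k); monotone unimodal in k for
  # each hull edge, which the antipodal advance relies on
  tri2 <- function(i, j, k) abs(cross2(hull[i, ], hull[j, ], hull[k, ]))
  best <- 0
  k <- 2L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    repeat {
      k_next <- if (k == n) 1L else k + 1L
      if (tri2(i, j, k_next) > tri2(i, j, k)) k <- k_next else break
    }
    best <- max(best, d2(i, k), d2(j, k))
  }
  sqrt(best)
}

#' Minimum enclosing circle (Welzl's algorithm)
#'
#' Smallest circle containing every point of the set; run on the convex hull
#' vertices for speed. Deterministic: no random restarts.
#'
#' @param pts Point matrix (two columns).
#' @return List with `center` (row, col), `radius`, and `diameter`.
#' @export
min_enclosing_circle <- function(pts) {
  hull <- convex_hull(pts)
  if (nrow(hull) == 0L) stop("cannot enclose an empty point set", call. = FALSE)
  circ <- welzl(hull, matrix(numeric(0), 0L, 2L))
  list(center = circ$center, radius = circ$radius, diameter = 2 * circ$radius)
}

in_circle <- function(p, circ, tol = 1e-9) {
  sqrt(sum((p - circ$center) ^ 2)) <= circ$radius + tol
}

circle_from_2 <- function(a, b) {
  center <- (a + b) / 2
  list(center = center, radius = sqrt(sum((a - center) ^ 2)))
}

circle_from_3 <- function(a, b, c) {
  # circumcircle via perpendicular-bisector intersection; NULL if collinear
  d <- 2 * (a[2L] * (b[1L] - c[1L]) + b[2L] * (c[1L] - a[1L]) + c[2L] * (a[1L] - b[1L]))
  if (abs(d) < 1e-12) return(NULL)
  a2 <- sum(a ^ 2); b2 <- sum(b ^ 2); c2 <- sum(c ^ 2)
  ux <- (a2 * (b[1L] - c[1L]) + b2 * (c[1L] - a[1L]) + c2 * (a[1L] - b[1L])) / d
  uy <- (a2 * (c[2L] - b[2L]) + b2 * (a[2L] - c[2L]) + c2 * (b[2L] - a[2L])) / d
  center <- c(uy, ux)
  list(center = center, radius = sqrt(sum((a - center) ^ 2)))
}

trivial_circle <- function(bnd) {
  n <- nrow(bnd)
  if (n == 0L) return(list(center = c(0, 0), radius = -1)) # contains nothing
  if (n == 1L) return(list(center = bnd[1L, ], radius = 0))
  if (n == 2L) return(circle_from_2(bnd[1L, ], bnd[2L, ]))
  # smallest of the three 2-point circles that covers the remaining point,
  # else the circumcircle
  combos <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
  best <- NULL
  for (co in combos) {
    circ <- circle_from_2(bnd[co[1L], ], bnd[co[2L], ])
    if (in_circle(bnd[co[3L], ], circ) && (is.null(best) || circ$radius < best$radius)) {
      best <- circ
    }
  }
  if (!is.null(best)) return(best)
  circ <- circle_from_3(bnd[1L, ], bnd[2L, ], bnd[3L, ])
  if (is.null(circ)) { # collinear triple: span of the two farthest
    d <- as.matrix(stats::dist(bnd))
    ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
    circ <- circle_from_2(bnd[ij[1L], ], bnd[ij[2L], ])
  }
  circ
}

welzl <- function(pts, bnd) {
  if (nrow(pts) == 0L || nrow(bnd) == 3L) return(trivial_circle(bnd))
  p <- pts[nrow(pts), , drop = TRUE]
  rest <- pts[-nrow(pts), , drop = FALSE]
  circ <- welzl(rest, bnd)
  if (in_circle(p, circ, tol = 1e-10)) return(circ)
  welzl(rest, rbind(bnd, p))
}

#' Moment-ellipse eccentricity of a point set
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' foreground pixels: sqrt(1 - lambda2/lambda1) for eigenvalues
#' lambda1 >= lambda2 of the coordinate covariance. 0 for radially symmetric
#' shapes, approaching 1 for line-like shapes.
#'
#' @param pts Point matrix (two columns).
#' @return Eccentricity in \[0, 1).
#' @export
moment_eccentricity <- function(pts) {
  pts <- as_point_matrix(pts)
  n <- nrow(pts)
  if (n <= 1L) return(0)
  ctr <- sweep(pts, 2L, colMeans(pts))
  s <- crossprod(ctr) / n # population moments
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) return(0)
  e2 <- 1 - ev[2L] / ev[1L]
  sqrt(max(0, min(e2, 1 - 1e-15)))
}

# ---- brute-force reference implementations -------------------------------
# Exhaustive counterparts used for ground truth and cross-validation. They
# share no code path with the rotating-calipers / Welzl routines above.

#' Brute-force maximum pairwise distance
#'
#' Exhaustive reference for [calliper_length()]: the maximum over all point
#' pairs, with no convex-hull shortcut beyond optional pre-hulling by the
#' caller.
#'
#' @param pts Point matrix (two columns).
#' @return Maximum pairwise Euclidean distance.
#' @export
bf_max_pairwise_distance <- function(pts) {
  pts <- unique(as_point_matrix(pts))
  if (nrow(pts) <= 1L) return(0)
  max(stats::dist(pts))
}

#' Brute-force minimum enclosing circle
#'
#' Exhaustive reference for [min_enclosing_circle()]: enumerates every
#' two-point (diametral) and three-point (circumcircle) candidate, then
#' returns the smallest candidate that contains all points. Candidates are
#' scanned in order of increasing radius so the first feasible one wins.
#' Intended for point sets of at most a few hundred vertices.
#'
#' @param pts Point matrix (two columns).
#' @return List with `center`, `radius`, `diameter`.
#' @export
bf_min_enclosing_circle <- function(pts) {
  pts <- unique(as_point_matrix(pts))
  n <- nrow(pts)
  if (n == 0L) stop("cannot enclose an empty point set", call. = FALSE)
  if (n == 1L) return(list(center = pts[1L, ], radius = 0, diameter = 0))
  cand_center <- list()
  cand_radius <- numeric(0)
  push <- function(circ) {
    if (is.null(circ)) return()
    cand_center[[length(cand_center) + 1L]] <<- circ$center
    cand_radius[[length(cand_radius) + 1L]] <<- circ$radius
  }
  prs <- utils::combn(n, 2L)
  for (k in seq_len(ncol(prs))) push(circle_from_2(pts[prs[1L, k], ], pts[prs[2L, k], ]))
  if (n >= 3L) {
    trp <- utils::combn(n, 3L)
    for (k in seq_len(ncol(trp))) {
      push(circle_from_3(pts[trp[1L, k], ], pts[trp[2L, k], ], pts[trp[3L, k], ]))
    }
  }
  ord <- order(cand_radius)
  for (k in ord) {
    ctr <- cand_center[[k]]
    r <- cand_radius[[k]]
    if (all(sqrt(rowSums(sweep(pts, 2L, ctr) ^ 2)) <= r + 1e-9)) {
      return(list(center = ctr, radius = r, diameter = 2 * r))
    }
  }
  stop("no enclosing candidate found (numerical degeneracy)", call. = FALSE) # nocov
}
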