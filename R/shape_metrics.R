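#' Center of mass of the cortical region
#'
#' Unweighted mean of the foreground pixel centers, in mm. With
#' `weights` (a matrix of attenuation values) an attenuation-weighted
#' centroid is returned instead.
#'
#' @param mask Logical matrix.
#' @param voxel_size Pixel size in mm.
#' @param weights Optional numeric matrix of per-pixel weights.
#' @return Named numeric `c(x, y)` in mm.
#' @export
mask_centroid <- function(mask, voxel_size = 0.5, weights = NULL) {
  mask <- as.matrix(mask)
  idx <- which(mask)
  if (!length(idx)) stop("cannot compute the centroid of an empty mask")
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  w <- if (is.null(weights)) rep(1, length(idx)) else as.numeric(weights[idx])
  c(x = sum((c - 0.5) * voxel_size * w) / sum(w),
    y = sum((r - 0.5) * voxel_size * w) / sum(w))
}

contour_xy <- function(contour) {
  cbind(contour$x, contour$y)
}

#' Maximum diameter of a contour
#'
#' The largest Euclidean distance over all point pairs of the (periosteal)
#' contour, computed on the convex hull (on which the maximum is always
#' attained). Ties are broken toward the pair whose first endpoint has the
#' smallest y then x (image row, then column); endpoints are ordered the
#' same way.
#'
#' @param contour A contour tibble with columns `x`, `y` (mm).
#' @return A list with `length` (mm) and `endpoints` (2 x 2 matrix,
#'   rows = points, cols = x, y).
#' @export
max_diameter <- function(contour) {
  P <- contour_xy(contour)
  if (nrow(P) < 2L) stop("need at least two points for a diameter")
  hull <- unique(P[chull(P[, 1L], P[, 2L]), , drop = FALSE])
  if (nrow(hull) < 2L) hull <- unique(P)
  D <- as.matrix(stats::dist(hull))
  dmax <- max(D)
  cand <- which(D >= dmax - 1e-12 & upper.tri(D), arr.ind = TRUE)
  # order each candidate pair so the first endpoint is smaller by (y, x)
  pairs <- t(apply(cand, 1L, function(ij) {
    a <- hull[ij[1L], ]; b <- hull[ij[2L], ]
    if (a[2L] < b[2L] || (a[2L] == b[2L] && a[1L] <= b[1L])) c(a, b) else c(b, a)
  }))
  ord <- order(pairs[, 2L], pairs[, 1L], pairs[, 4L], pairs[, 3L])
  best <- pairs[ord[1L], ]
  ends <- rbind(best[1:2], best[3:4])
  colnames(ends) <- c("x", "y")
  list(length = dmax, endpoints = ends)
}

#' Minimum diameter: contour width at right angles to the maximum diameter
#'
#' Width of the contour's orthogonal projection onto the axis perpendicular
#' to the maximum-diameter direction (max projection minus min projection).
#' A chord-through-centroid variant is available via `chord = TRUE`.
#'
#' @param contour A contour tibble.
#' @param max_axis Either the result of [max_diameter()] or a length-2
#'   direction vector of the maximum-diameter axis.
#' @param chord If `TRUE`, measure the chord of the contour along the
#'   perpendicular line through the centroid instead of the projection
#'   width.
#' @param center Chord center, required when `chord = TRUE`.
#' @return Width in mm.
#' @export
min_diameter <- function(contour, max_axis, chord = FALSE, center = NULL) {
  u <- axis_direction(max_axis)
  perp <- c(-u[2L], u[1L])
  P <- contour_xy(contour)
  if (!chord) {
    proj <- P %*% perp
    max(proj) - min(proj)
  } else {
    if (is.null(center)) stop("chord variant needs a center point")
    tt <- polygon_line_crossings(P, center, perp)
    if (length(tt) < 2L) stop("perpendicular axis misses the contour")
    max(tt) - min(tt)
  }
}

axis_direction <- function(max_axis) {
  d <- if (is.list(max_axis)) {
    max_axis$endpoints[2L, ] - max_axis$endpoints[1L, ]
  } else {
    as.numeric(max_axis)
  }
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate axis: coincident endpoints")
  d / len
}

#' Angle of the maximum-diameter axis from the image vertical
#'
#' Unsigned angle between the endpoint segment and the image vertical
#' (the column direction, increasing row = down), folded into `[0, 180)`
#' degrees. A vertical axis scores 0, a horizontal one 90.
#'
#' @param endpoints 2 x 2 matrix of axis endpoints (rows = points,
#'   cols = x, y), or a [max_diameter()] result.
#' @return Angle in degrees in `[0, 180)`.
#' @export
axis_angle <- function(endpoints) {
  if (is.list(endpoints)) endpoints <- endpoints$endpoints
  d <- endpoints[2L, ] - endpoints[1L, ]
  if (all(d == 0)) stop("coincident endpoints have no direction")
  # angle from vertical: vertical direction is (0, 1) in (x, y-down)
  ang <- atan2(d[1L], d[2L]) * 180 / pi   # 0 when along +y
  ang %% 180
}

#' Perimeter of a closed contour
#'
#' Sum of the segment lengths of the closed polygon; for a chain-code
#' contour over pixel centers these are steps of `v` and `v * sqrt(2)`.
#' The digital perimeter of a smooth shape carries a small positive bias
#' (the traced polygon is jagged); see the package vignette.
#'
#' @param contour A contour tibble (or any data frame with `x`, `y`).
#' @return Perimeter in mm.
#' @export
contour_perimeter <- function(contour) {
  P <- contour_xy(contour)
  n <- nrow(P)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((P[j, , drop = FALSE] - P) ^ 2)))
}

#' Enclosed (shoelace) area of a closed contour
#'
#' @param contour A contour tibble.
#' @return Absolute polygon area in mm^2.
#' @export
contour_area <- function(contour) {
  abs(shoelace_signed(contour$x, contour$y))
}

# Exact pixel-count area of the digital region bounded by a chain-code
# contour over pixel centers. By Pick's theorem a simple lattice polygon
# has shoelace area I + B/2 - 1 (pixel^2 units), while the region contains
# I + B pixels, so counting area = shoelace + (B/2 + 1) v^2. This removes
# the half-pixel rim the center polygon cuts off and matches what pixel
# counting (the reference CSA method) reports.
digital_area <- function(contour, voxel_size) {
  contour_area(contour) + (nrow(contour) / 2 + 1) * voxel_size^2
}

# minimum distance from each point in P (n x 2) to the closed polygon Q
point_polygon_distance <- function(P, Q) {
  n <- nrow(Q)
  j <- c(2:n, 1L)
  A <- Q; B <- Q[j, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  best <- rep(Inf, nrow(P))
  for (k in seq_len(n)) {
    d <- cbind(P[, 1L] - A[k, 1L], P[, 2L] - A[k, 2L])
    t <- if (len2[k] > 0) pmin(1, pmax(0, (d %*% AB[k, ]) / len2[k])) else 0
    px <- A[k, 1L] + t * AB[k, 1L]
    py <- A[k, 2L] + t * AB[k, 2L]
    dist2 <- (P[, 1L] - px)^2 + (P[, 2L] - py)^2
    best <- pmin(best, dist2)
  }
  sqrt(best)
}

#' Cortical thickness profile around the ring
#'
#' For every periosteal vertex, the shortest distance to the endosteal
#' polygon (point-to-segment). The min / max / mean of this profile are
#' the whole-ring thickness statistics.
#'
#' @param periosteal,endosteal Contour tibbles.
#' @return A tibble with columns `x`, `y` (the periosteal vertex) and
#'   `thickness` (mm).
#' @export
thickness_profile <- function(periosteal, endosteal) {
  P <- contour_xy(periosteal)
  Q <- contour_xy(endosteal)
  tibble::tibble(x = P[, 1L], y = P[, 2L],
                 thickness = point_polygon_distance(P, Q))
}

# signed parameters t of the crossings of the line p0 + t*u with the
# closed polygon P
polygon_line_crossings <- function(P, p0, u) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  nrm <- c(-u[2L], u[1L])
  sA <- (P[, 1L] - p0[1L]) * nrm[1L] + (P[, 2L] - p0[2L]) * nrm[2L]
  sB <- sA[j]
  cross <- which(sA * sB < 0 | (sA == 0 & sB != 0))
  if (!length(cross)) return(numeric(0))
  tt <- vapply(cross, function(k) {
    A <- P[k, ]; B <- P[j[k], ]
    w <- sA[k] / (sA[k] - sB[k])
    X <- A + w * (B - A)
    (X[1L] - p0[1L]) * u[1L] + (X[2L] - p0[2L]) * u[2L]
  }, numeric(1))
  sort(tt)
}

#' Directional cortical thickness along the maximum-diameter axis
#'
#' Casts the maximum-diameter line through the centroid; on each side the
#' thickness is the distance between the outermost periosteal and the
#' outermost endosteal crossing points. Anterior is the side whose
#' periosteal crossing lies toward the image top (smaller y), reflecting
#' standard pQCT positioning; left / right are measured the same way along
#' the perpendicular axis, left being the smaller-x side.
#'
#' @param periosteal,endosteal Contour tibbles.
#' @param centroid `c(x, y)` in mm (see [mask_centroid()]).
#' @param max_axis A [max_diameter()] result or a direction vector.
#' @return Named numeric: `anterior`, `posterior`, `left`, `right` (mm).
#' @export
directional_thickness <- function(periosteal, endosteal, centroid, max_axis) {
  u <- axis_direction(max_axis)
  # orient u toward increasing y (so positive t = toward image bottom);
  # for a horizontal axis, toward increasing x
  if (u[2L] < 0 || (u[2L] == 0 && u[1L] < 0)) u <- -u
  P <- contour_xy(periosteal); Q <- contour_xy(endosteal)
  side_thickness <- function(dir_u) {
    tp <- polygon_line_crossings(P, centroid, dir_u)
    te <- polygon_line_crossings(Q, centroid, dir_u)
    if (length(tp) < 2L || length(te) < 2L) {
      stop("axis misses cortex: the measurement line does not cross both ",
           "boundaries twice")
    }
    # side of positive t and side of negative t
    pos <- max(tp) - max(te[te < max(tp)])
    neg <- abs(min(tp)) - abs(min(te[te > min(tp)]))
    if (!is.finite(pos) || !is.finite(neg) || pos <= 0 || neg <= 0) {
      stop("axis misses cortex: endosteal crossing beyond the periosteal one")
    }
    c(neg_side = neg, pos_side = pos)
  }
  along <- side_thickness(u)       # u points toward +y: pos side = bottom
  perp <- c(-u[2L], u[1L])
  if (perp[1L] < 0) perp <- -perp  # point toward +x: pos side = right
  across <- side_thickness(perp)
  c(anterior = unname(along["neg_side"]),
    posterior = unname(along["pos_side"]),
    left = unname(across["neg_side"]),
    right = unname(across["pos_side"]))
}

#' Summarize a segmented cross-section into a one-row shape result
#'
#' Computes every shape output from the mask and contour pair: centroid,
#' maximum / minimum diameter, axis angle, periosteal and endosteal
#' circumference, the directional and whole-ring cortical thicknesses,
#' cross-sectional areas, and the deviation of the periosteal boundary
#' from an ideal fitted circle and ellipse. Left / right thicknesses are
#' computed but sit at the end of the row, mirroring the convention of
#' reporting only anterior, posterior, minimum and mean.
#'
#' @param segmentation A `cortical_segmentation` from [segment_cortex()].
#' @return A one-row tibble of class `shape_result`. Columns include
#'   `max_diam_mm`, `min_diam_mm`, `axis_angle_deg`, `peri_circ_mm`,
#'   `endo_circ_mm`, `thk_anterior_mm`, `thk_posterior_mm`, `thk_min_mm`,
#'   `thk_max_mm`, `thk_mean_mm`, `tot_csa_mm2`, `cort_csa_mm2`,
#'   `err_circle_mm2`, `err_ellipse_alg`, plus fit parameters.
#' @examples
#' ph <- rasterize_phantom(phantom_spec(), image_geometry(128, 128, 0.5))
#' seg <- segment_cortex(ph$image, analysis_config(width = 128, height = 128))
#' summarize_shape(seg)
#' @export
summarize_shape <- function(segmentation) {
  stopifnot(inherits(segmentation, "cortical_segmentation"))
  cfg <- segmentation$config
  v <- cfg$voxel_size
  mask <- segmentation$mask
  peri <- segmentation$periosteal
  endo <- segmentation$endosteal
  weights <- NULL
  ctr <- mask_centroid(mask, v, weights)
  md <- max_diameter(peri)
  mind <- min_diameter(peri, md, chord = isTRUE(cfg$min_diameter_chord),
                       center = ctr)
  ang <- axis_angle(md)
  prof <- thickness_profile(peri, endo)
  dirthk <- directional_thickness(peri, endo, ctr, md)
  tot_csa <- digital_area(peri, v)
  cort_csa <- tot_csa - digital_area(endo, v)
  cfit <- fit_circle(peri)
  efit <- fit_ellipse(peri)
  out <- tibble::tibble(
    centroid_x_mm = unname(ctr["x"]),
    centroid_y_mm = unname(ctr["y"]),
    max_diam_mm = md$length,
    max_axis_x1_mm = md$endpoints[1L, "x"],
    max_axis_y1_mm = md$endpoints[1L, "y"],
    max_axis_x2_mm = md$endpoints[2L, "x"],
    max_axis_y2_mm = md$endpoints[2L, "y"],
    min_diam_mm = mind,
    axis_angle_deg = ang,
    peri_circ_mm = contour_perimeter(peri),
    endo_circ_mm = contour_perimeter(endo),
    thk_anterior_mm = unname(dirthk["anterior"]),
    thk_posterior_mm = unname(dirthk["posterior"]),
    thk_min_mm = min(prof$thickness),
    thk_max_mm = max(prof$thickness),
    thk_mean_mm = mean(prof$thickness),
    tot_csa_mm2 = tot_csa,
    cort_csa_mm2 = cort_csa,
    err_circle_mm2 = average_error_circle(peri, cfit),
    err_circle_alg = average_error_circle(peri, cfit, metric = "algebraic"),
    err_ellipse_alg = average_error_ellipse(peri, efit),
    err_ellipse_geom = average_error_ellipse(peri, efit, metric = "geometric"),
    circle_cx_mm = cfit$center[1L],
    circle_cy_mm = cfit$center[2L],
    circle_r_mm = cfit$radius,
    ellipse_cx_mm = efit$center[1L],
    ellipse_cy_mm = efit$center[2L],
    ellipse_a_mm = efit$semi_major,
    ellipse_b_mm = efit$semi_minor,
    ellipse_angle_deg = efit$orientation,
    thk_left_mm = unname(dirthk["left"]),
    thk_right_mm = unname(dirthk["right"])
  )
  validate_shape_result(out)
  class(out) <- c("shape_result", class(out))
  attr(out, "segmentation") <- segmentation
  attr(out, "fits") <- list(circle = cfit, ellipse = efit)
  out
}

validate_shape_result <- function(x) {
  with(x, {
    stopifnot(
      max_diam_mm >= min_diam_mm, min_diam_mm > 0,
      peri_circ_mm > endo_circ_mm, endo_circ_mm > 0,
      thk_min_mm <= thk_mean_mm, thk_mean_mm <= thk_max_mm,
      thk_min_mm > 0, thk_anterior_mm > 0, thk_posterior_mm > 0,
      thk_left_mm > 0, thk_right_mm > 0,
      tot_csa_mm2 > cort_csa_mm2, cort_csa_mm2 > 0,
      axis_angle_deg >= 0, axis_angle_deg < 180
    )
  })
  invisible(x)
}
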