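#' Specify a synthetic cortical-ring phantom
#'
#' Parametric description of a synthetic pQCT-like cross-section: a dense
#' cortical ring (values far above threshold) around a low-value medullary
#' cavity, with optional endosteal trabeculization, Gaussian noise and a
#' movement-artifact streak. Every phantom carries closed-form (or dense
#' numerical, for the tibia-like shape) ground truth for all shape
#' metrics.
#'
#' Shapes:
#' * `circular_annulus` — outer radius `outer`, inner radius `inner`.
#' * `eccentric_annulus` — as above with the cavity center displaced by
#'   `inner_offset` mm (x rightward, y downward). A downward (posterior)
#'   offset `dy` thins the posterior cortex: anterior = R - r + dy,
#'   posterior = R - r - dy.
#' * `elliptical_annulus` — outer semi-axes `outer = c(a, b)`, inner
#'   `inner = c(a_in, b_in)`, rotated by `rotation` degrees.
#' * `tibia_like` — rounded-triangle boundary, a low-order cosine
#'   perturbation of a circle sized to a young-adult tibia at the mid
#'   shaft (maximum diameter about 26-28 mm, mean cortical thickness
#'   about 4-5 mm).
#'
#' @param shape One of `"circular_annulus"`, `"eccentric_annulus"`,
#'   `"elliptical_annulus"`, `"tibia_like"`.
#' @param outer Outer radius (mm) or semi-axes `c(a, b)` for the
#'   elliptical shape; base radius for `tibia_like`.
#' @param inner Inner radius / semi-axes / base radius, strictly inside
#'   `outer`.
#' @param inner_offset Cavity center displacement `c(dx, dy)` mm.
#' @param rotation Rotation of the whole shape, degrees.
#' @param cortical_value,background_value Scanner units for ring and
#'   background (defaults 800 and 50, straddling the 450 threshold).
#' @param trabecul_fraction Fraction of the endosteal band speckled with
#'   cortical-valued pixels (0 = none).
#' @param trabecul_band Width of that band, mm.
#' @param noise_sd Gaussian noise SD in scanner units.
#' @param motion_streak If `TRUE`, draw a cortical-valued streak across
#'   the image to provoke the topology failure a movement artifact causes.
#' @param seed Integer seed driving all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("circular_annulus", "eccentric_annulus",
                                   "elliptical_annulus", "tibia_like"),
                         outer = 13, inner = 9,
                         inner_offset = c(0, 0), rotation = 0,
                         cortical_value = 800, background_value = 50,
                         trabecul_fraction = 0, trabecul_band = 1,
                         noise_sd = 0, motion_streak = FALSE, seed = 1L) {
  shape <- match.arg(shape)
  if (shape == "elliptical_annulus") {
    if (length(outer) == 1L) outer <- c(14, 9)
    if (length(inner) == 1L) inner <- outer - 4
    stopifnot(all(inner > 0), all(outer > inner))
  } else {
    stopifnot(length(outer) == 1L, length(inner) == 1L, inner > 0,
              outer > inner)
  }
  stopifnot(noise_sd >= 0, trabecul_fraction >= 0, trabecul_fraction <= 1,
            cortical_value > background_value)
  structure(list(shape = shape, outer = outer, inner = inner,
                 inner_offset = inner_offset, rotation = rotation,
                 cortical_value = cortical_value,
                 background_value = background_value,
                 trabecul_fraction = trabecul_fraction,
                 trabecul_band = trabecul_band,
                 noise_sd = noise_sd, motion_streak = motion_streak,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# tibia-like boundary radius at polar angle theta: rounded triangle with a
# mild two-fold term; amplitudes keep the curve simple and star-shaped
tibia_radius <- function(theta, base, rot = 0) {
  phi <- rot * pi / 180
  base * (1 + 0.12 * cos(3 * (theta - phi)) + 0.05 * cos(2 * (theta - phi)))
}

# dense boundary sample of the outer or inner generating curve, in mm
# coordinates centered on `center`
phantom_boundary <- function(spec, which = c("outer", "inner"),
                             center = c(0, 0), n = 4096L) {
  which <- match.arg(which)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phi <- spec$rotation * pi / 180
  off <- if (which == "inner") spec$inner_offset else c(0, 0)
  par <- spec[[which]]
  if (spec$shape == "elliptical_annulus") {
    xa <- par[1L] * cos(th); yb <- par[2L] * sin(th)
    x <- xa * cos(phi) - yb * sin(phi)
    y <- xa * sin(phi) + yb * cos(phi)
  } else if (spec$shape == "tibia_like") {
    r <- tibia_radius(th, par, spec$rotation)
    x <- r * cos(th); y <- r * sin(th)
  } else {
    x <- par * cos(th); y <- par * sin(th)
  }
  cbind(x = x + center[1L] + off[1L], y = y + center[2L] + off[2L])
}

# is each point (x, y) inside the outer/inner generating curve?
phantom_inside <- function(spec, which, x, y, center) {
  phi <- spec$rotation * pi / 180
  off <- if (which == "inner") spec$inner_offset else c(0, 0)
  px <- x - center[1L] - off[1L]
  py <- y - center[2L] - off[2L]
  par <- spec[[which]]
  if (spec$shape == "elliptical_annulus") {
    u <- px * cos(phi) + py * sin(phi)
    w <- -px * sin(phi) + py * cos(phi)
    (u / par[1L])^2 + (w / par[2L])^2 <= 1
  } else if (spec$shape == "tibia_like") {
    r <- sqrt(px^2 + py^2)
    r <= tibia_radius(atan2(py, px), par, spec$rotation)
  } else {
    px^2 + py^2 <= par^2
  }
}

# Ramanujan's second approximation to the ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

polygon_centroid <- function(P) {
  x <- P[, 1L]; y <- P[, 2L]
  n <- length(x); j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * A), sum((y + y[j]) * cr) / (6 * A))
}

# analytic / dense-numerical ground truth for a phantom centered at `center`
phantom_truth <- function(spec, center) {
  outer_b <- phantom_boundary(spec, "outer", center)
  inner_b <- phantom_boundary(spec, "inner", center, n = 2048L)
  s <- spec$shape
  if (s %in% c("circular_annulus", "eccentric_annulus")) {
    R <- spec$outer; r <- spec$inner
    off <- spec$inner_offset
    peri <- 2 * pi * R; endo <- 2 * pi * r
    max_d <- 2 * R; min_d <- 2 * R
    tot <- pi * R^2; cort <- pi * (R^2 - r^2)
    if (all(off == 0)) {
      thk <- c(anterior = R - r, posterior = R - r,
               left = R - r, right = R - r)
      dmean <- R - r
    } else {
      # directional thicknesses are taken through the ring centroid, which
      # sits opposite the displaced cavity: centroid = -off * r^2/(R^2-r^2);
      # evaluate the crossings on the dense generating curves
      ctr <- center - off * r^2 / (R^2 - r^2)
      thk <- directional_thickness(
        tibble::tibble(x = outer_b[, 1L], y = outer_b[, 2L]),
        tibble::tibble(x = inner_b[, 1L], y = inner_b[, 2L]),
        ctr, c(0, 1))
      dmean <- mean(point_polygon_distance(outer_b, inner_b))
    }
    dmin <- R - r - sqrt(sum(off^2)); dmax <- R - r + sqrt(sum(off^2))
  } else if (s == "elliptical_annulus") {
    a <- spec$outer[1L]; b <- spec$outer[2L]
    ai <- spec$inner[1L]; bi <- spec$inner[2L]
    peri <- ellipse_perimeter(a, b); endo <- ellipse_perimeter(ai, bi)
    max_d <- 2 * max(a, b); min_d <- 2 * min(a, b)
    tot <- pi * a * b; cort <- pi * (a * b - ai * bi)
    prof <- point_polygon_distance(outer_b, inner_b)
    dmin <- min(prof); dmax <- max(prof); dmean <- mean(prof)
    # along the major axis the ring is a - ai thick on both sides, along
    # the minor axis b - bi (rotation permutes these directions)
    thk <- c(anterior = a - ai, posterior = a - ai,
             left = b - bi, right = b - bi)
  } else {
    peri <- contour_perimeter(tibble::tibble(x = outer_b[, 1L],
                                             y = outer_b[, 2L]))
    endo <- contour_perimeter(tibble::tibble(x = inner_b[, 1L],
                                             y = inner_b[, 2L]))
    md <- max_diameter(tibble::tibble(x = outer_b[, 1L], y = outer_b[, 2L]))
    max_d <- md$length
    min_d <- min_diameter(tibble::tibble(x = outer_b[, 1L],
                                         y = outer_b[, 2L]), md)
    tot <- abs(shoelace_signed(outer_b[, 1L], outer_b[, 2L]))
    cort <- tot - abs(shoelace_signed(inner_b[, 1L], inner_b[, 2L]))
    prof <- point_polygon_distance(outer_b, inner_b)
    dmin <- min(prof); dmax <- max(prof); dmean <- mean(prof)
    ctr <- polygon_centroid(outer_b)
    dt <- directional_thickness(tibble::tibble(x = outer_b[, 1L],
                                               y = outer_b[, 2L]),
                                tibble::tibble(x = inner_b[, 1L],
                                               y = inner_b[, 2L]),
                                ctr, md)
    thk <- dt
  }
  err_circ <- average_error_circle(outer_b)
  err_ell <- average_error_ellipse(outer_b)
  tibble::tibble(
    shape = s,
    peri_circ_mm = peri, endo_circ_mm = endo,
    max_diam_mm = max_d, min_diam_mm = min_d,
    thk_anterior_mm = unname(thk["anterior"]),
    thk_posterior_mm = unname(thk["posterior"]),
    thk_left_mm = unname(thk["left"]),
    thk_right_mm = unname(thk["right"]),
    thk_min_mm = dmin, thk_max_mm = dmax, thk_mean_mm = dmean,
    tot_csa_mm2 = tot, cort_csa_mm2 = cort,
    err_circle_mm2 = err_circ, err_ellipse_alg = err_ell
  )
}

#' Rasterize a phantom into a scan image with ground truth
#'
#' A pixel is cortical iff its center lies inside the outer generating
#' curve and outside the inner one. The phantom is centered in the image;
#' the shape must fit with at least a 2-voxel margin. Truth comes from
#' closed forms for circles, Ramanujan's perimeter approximation for
#' ellipses, and dense (4096-point) numerical evaluation of the
#' generating curves for the tibia-like shape.
#'
#' @param spec A [phantom_spec()].
#' @param geometry An [image_geometry()].
#' @return A list of class `phantom`: `image` (a noiseless [scan_image()]),
#'   `mask` (the true cortical mask), `truth` (one-row tibble of ground
#'   truth), `center` (mm), `spec`, `geometry`.
#' @examples
#' ph <- rasterize_phantom(phantom_spec(), image_geometry(128, 128, 0.5))
#' ph$truth$peri_circ_mm    # 2 * pi * 13
#' @export
rasterize_phantom <- function(spec, geometry = image_geometry(128, 128, 0.5)) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- geometry$voxel_size
  W <- geometry$width * v; H <- geometry$height * v
  center <- c(W / 2, H / 2)
  extent <- max_extent(spec)
  if (extent + 2 * v > min(W, H) / 2) {
    stop("phantom (extent ", round(extent, 2), " mm) does not fit in the ",
         W, " x ", H, " mm image with a 2-voxel margin")
  }
  xs <- (seq_len(geometry$width) - 0.5) * v
  ys <- (seq_len(geometry$height) - 0.5) * v
  X <- matrix(xs, geometry$height, geometry$width, byrow = TRUE)
  Y <- matrix(ys, geometry$height, geometry$width)
  inside_out <- phantom_inside(spec, "outer", X, Y, center)
  inside_in <- phantom_inside(spec, "inner", X, Y, center)
  mask <- inside_out & !inside_in
  vals <- matrix(spec$background_value, geometry$height, geometry$width)
  vals[mask] <- spec$cortical_value
  structure(
    list(image = scan_image(vals, geometry), mask = mask,
         truth = phantom_truth(spec, center), center = center,
         spec = spec, geometry = geometry),
    class = "phantom"
  )
}

max_extent <- function(spec) {
  switch(spec$shape,
    circular_annulus = , eccentric_annulus = spec$outer,
    elliptical_annulus = max(spec$outer),
    tibia_like = spec$outer * 1.17
  )
}

#' @export
format.phantom <- function(x, ...) {
  sprintf("<phantom %s, %d cortical px, %s>",
          x$spec$shape, sum(x$mask), format(x$geometry))
}

#' @export
print.phantom <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Add endosteal trabeculization to a phantom image
#'
#' Emulates the dense trabecular speckle seen on the endosteal surface of
#' many scans: inside the cavity, within `trabecul_band` mm of the
#' endosteal boundary, a seeded random `trabecul_fraction` of pixels is
#' set to the cortical value. Deterministic for a fixed spec seed.
#'
#' @param phantom A [rasterize_phantom()] result.
#' @return The phantom with a modified `image` (truth untouched: the
#'   speckle is a perturbation, and with fraction 1 the effective
#'   endosteal radius shrinks by the band width).
#' @export
add_trabeculization <- function(phantom) {
  spec <- phantom$spec
  if (spec$trabecul_fraction == 0) return(phantom)
  g <- phantom$geometry; v <- g$voxel_size
  xs <- (seq_len(g$width) - 0.5) * v
  ys <- (seq_len(g$height) - 0.5) * v
  X <- matrix(xs, g$height, g$width, byrow = TRUE)
  Y <- matrix(ys, g$height, g$width)
  in_inner <- phantom_inside(spec, "inner", X, Y, phantom$center)
  # shrink the inner curve by the band width to find the band
  shrunk <- shrink_inner(spec, spec$trabecul_band)
  in_core <- phantom_inside(shrunk, "inner", X, Y, phantom$center)
  band <- which(in_inner & !in_core)
  set.seed(spec$seed)
  chosen <- band[runif(length(band)) < spec$trabecul_fraction]
  vals <- phantom$image$values
  vals[chosen] <- spec$cortical_value
  phantom$image <- scan_image(vals, g)
  phantom
}

shrink_inner <- function(spec, by) {
  s <- spec
  if (s$shape == "elliptical_annulus") {
    s$inner <- pmax(s$inner - by, 0.5)
  } else {
    s$inner <- max(s$inner - by, 0.5)
  }
  s
}

#' Add seeded noise and an optional motion-artifact streak
#'
#' Gaussian noise (SD `noise_sd` scanner units) is added pixel-wise and
#' clipped to `[0, 65535]`; when `motion_streak` is set, a 2-pixel-tall
#' cortical-valued streak is drawn across the full image width through
#' the ring, the signature of subject movement, which downstream
#' segmentation rejects via its topology checks.
#'
#' @param phantom A phantom (possibly already trabeculized).
#' @return The phantom with a modified `image`.
#' @export
add_noise_and_artifacts <- function(phantom) {
  spec <- phantom$spec
  g <- phantom$geometry
  vals <- phantom$image$values * 1.0
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 1L)
    vals <- vals + rnorm(length(vals), 0, spec$noise_sd)
  }
  if (isTRUE(spec$motion_streak)) {
    # 3 px tall so a single opening pass cannot erase it, as with a real
    # movement artifact smearing across the field of view
    row0 <- round(phantom$center[2L] / g$voxel_size)
    vals[(row0 - 1L):(row0 + 1L), ] <- spec$cortical_value
  }
  vals <- pmin(pmax(round(vals), 0), 65535)
  phantom$image <- scan_image(matrix(vals, g$height, g$width), g)
  phantom
}

#' Build a complete phantom: rasterize, trabeculize, add noise/artifacts
#'
#' @param spec A [phantom_spec()].
#' @param geometry An [image_geometry()].
#' @return A `phantom` list; see [rasterize_phantom()].
#' @export
build_phantom <- function(spec, geometry = image_geometry(128, 128, 0.5)) {
  add_noise_and_artifacts(add_trabeculization(rasterize_phantom(spec, geometry)))
}
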