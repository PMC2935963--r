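circle_contour <- function(R, n = 360L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tibble::tibble(x = center[1] + R * cos(th), y = center[2] + R * sin(th))
}

test_that("centroid is the mean of pixel centers", {
  m <- matrix(FALSE, 20, 20); m[10, 10] <- TRUE
  expect_equal(mask_centroid(m, 0.5), c(x = 4.75, y = 4.75))
  # symmetric annulus: centroid at its center, brute-force agreement
  ph <- rasterize_phantom(phantom_spec(), small_geom)
  ctr <- mask_centroid(ph$mask, 0.5)
  expect_equal(unname(ctr), c(32, 32), tolerance = 1e-9)
  set.seed(5)
  m2 <- random_blobs(12, 0.4)
  if (any(m2)) {
    idx <- which(m2)
    r <- (idx - 1) %% 12 + 1; c <- (idx - 1) %/% 12 + 1
    expect_equal(unname(mask_centroid(m2, 0.5)),
                 c(mean((c - 0.5) * 0.5), mean((r - 0.5) * 0.5)))
  }
})

test_that("max diameter matches geometry and the all-pairs oracle", {
  sq <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  md <- max_diameter(sq)
  expect_equal(md$length, sqrt(200), tolerance = 1e-9)
  expect_equal(max_diameter(circle_contour(9))$length, 18, tolerance = 1e-3)
  set.seed(17)
  for (i in 1:10) {
    P <- cbind(x = runif(200, 0, 30), y = runif(200, 0, 30))
    expect_equal(max_diameter(tibble::tibble(x = P[, 1], y = P[, 2]))$length,
                 max_diameter_oracle(P))
  }
})

test_that("minimum diameter is the projection width at right angles", {
  # axis-aligned 10 x 4 rectangle: max axis is the diagonal
  rect <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 4, 4))
  md <- max_diameter(rect)
  expect_equal(md$length, sqrt(116), tolerance = 1e-9)
  u <- (md$endpoints[2, ] - md$endpoints[1, ]) / md$length
  perp <- c(-u[2], u[1])
  proj <- as.matrix(rect[, c("x", "y")]) %*% perp
  expect_equal(min_diameter(rect, md), max(proj) - min(proj))
  expect_equal(min_diameter(circle_contour(9), max_diameter(circle_contour(9))),
               18, tolerance = 1e-3)
  ell <- tibble::tibble(x = 14 * cos(seq(0, 2 * pi, length.out = 720)),
                        y = 9 * sin(seq(0, 2 * pi, length.out = 720)))
  expect_equal(min_diameter(ell, max_diameter(ell)), 18, tolerance = 0.01)
})

test_that("axis angle is measured from the image vertical in [0, 180)", {
  expect_equal(axis_angle(rbind(c(0, 0), c(0, 10))), 0)
  expect_equal(axis_angle(rbind(c(0, 0), c(10, 0))), 90)
  expect_equal(axis_angle(rbind(c(0, 0), c(10, 10))), 45)
  expect_equal(axis_angle(rbind(c(0, 0), c(-10, 10))), 135)
  expect_error(axis_angle(rbind(c(1, 1), c(1, 1))), "coincident")
})

test_that("perimeter sums closed polygon segments", {
  expect_equal(contour_perimeter(tibble::tibble(x = c(0, 1, 1, 0),
                                                y = c(0, 0, 1, 1))), 4)
  # digital circle perimeter: above truth, within the +10% chain-code bias
  ph <- rasterize_phantom(phantom_spec(), small_geom)
  seg <- segment_cortex(ph$image, small_cfg)
  p <- contour_perimeter(seg$periosteal)
  expect_gte(p, 2 * pi * 13)
  expect_lte(p, 1.10 * 2 * pi * 13)
})

test_that("thickness profile equals the brute-force point-segment scan", {
  # concentric circles
  peri <- circle_contour(13, 180); endo <- circle_contour(9, 120)
  prof <- thickness_profile(peri, endo)
  expect_true(all(abs(prof$thickness - 4) < 0.05))
  # concentric squares with edge-sampled contours: face-to-face distance 5
  square_contour <- function(h, step = 1) {
    s <- seq(-h, h - step, by = step)
    tibble::tibble(
      x = c(s, rep(h, length(s)), rev(s + step), rep(-h, length(s))),
      y = c(rep(-h, length(s)), s, rep(h, length(s)), rev(s + step)))
  }
  expect_equal(min(thickness_profile(square_contour(10),
                                     square_contour(5))$thickness), 5)
  set.seed(29)
  for (i in 1:10) {
    ph <- random_ring()
    seg <- segment_cortex(ph$image, small_cfg)
    P <- cbind(seg$periosteal$x, seg$periosteal$y)
    Q <- cbind(seg$endosteal$x, seg$endosteal$y)
    keep <- seq(1, nrow(P), by = 4)   # thin out for the O(n*m) scalar oracle
    expect_equal(thickness_profile(seg$periosteal,
                                   seg$endosteal)$thickness[keep],
                 thickness_oracle(P[keep, , drop = FALSE], Q))
  }
})

test_that("directional thickness resolves the eccentric cavity analytically", {
  # hole shifted 2 mm downward: top cortex thickens to 6, bottom thins to 2
  ph <- rasterize_phantom(phantom_spec("eccentric_annulus",
                                       inner_offset = c(0, 2)),
                          small_geom)
  seg <- segment_cortex(ph$image, small_cfg)
  dt <- directional_thickness(seg$periosteal, seg$endosteal,
                              mask_centroid(seg$mask, 0.5), c(0, 1))
  expect_equal(unname(dt["anterior"]), 6, tolerance = 0.15)
  expect_equal(unname(dt["posterior"]), 2, tolerance = 0.15)
  # left/right run through the ring centroid, displaced away from the hole
  expect_equal(unname(dt["left"]), ph$truth$thk_left_mm, tolerance = 0.1)
  expect_equal(unname(dt["right"]), ph$truth$thk_right_mm, tolerance = 0.1)
  # 180-degree rotation swaps anterior and posterior exactly
  img180 <- scan_image(ph$image$values[128:1, 128:1], small_geom)
  seg180 <- segment_cortex(img180, small_cfg)
  dt180 <- directional_thickness(seg180$periosteal, seg180$endosteal,
                                 mask_centroid(seg180$mask, 0.5), c(0, 1))
  expect_equal(unname(dt["anterior"]), unname(dt180["posterior"]),
               tolerance = 1e-9)
  # isotropy for the concentric annulus
  ph0 <- rasterize_phantom(phantom_spec(), small_geom)
  seg0 <- segment_cortex(ph0$image, small_cfg)
  dt0 <- directional_thickness(seg0$periosteal, seg0$endosteal,
                               mask_centroid(seg0$mask, 0.5), c(0, 1))
  expect_true(all(abs(dt0 - 4) <= 0.5))
})

test_that("summarize fills a consistent result row for the annulus phantom", {
  ph <- rasterize_phantom(phantom_spec(), small_geom)
  res <- summarize_shape(segment_cortex(ph$image, small_cfg))
  expect_s3_class(res, "shape_result")
  expect_equal(res$tot_csa_mm2, pi * 169, tolerance = 0.02)
  expect_equal(res$cort_csa_mm2, pi * (169 - 81), tolerance = 0.02)
  expect_equal(res$thk_mean_mm, 4, tolerance = 0.1)
  expect_equal(res$peri_circ_mm / res$endo_circ_mm, 13 / 9, tolerance = 0.05)
  # contract invariants
  expect_true(res$max_diam_mm >= res$min_diam_mm)
  expect_true(res$peri_circ_mm > res$endo_circ_mm)
  expect_true(res$thk_min_mm <= res$thk_mean_mm &&
                res$thk_mean_mm <= res$thk_max_mm)
  expect_true(res$tot_csa_mm2 > res$cort_csa_mm2)
})

test_that("whole-ring thickness converges to the annulus width as v shrinks", {
  # error stays within a band proportional to the voxel size
  for (v in c(1, 0.5, 0.25)) {
    n <- as.integer(64 / v)
    ph <- rasterize_phantom(phantom_spec(), image_geometry(n, n, v))
    cfg <- analysis_config(width = n, height = n, voxel_size = v)
    res <- summarize_shape(segment_cortex(ph$image, cfg))
    expect_lt(abs(res$thk_mean_mm - 4), v / 4)
  }
})
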