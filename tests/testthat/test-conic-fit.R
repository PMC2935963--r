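test_that("circle fit is exact for points on a circle", {
  # 3 points interpolate exactly
  th3 <- c(0.3, 2.1, 4.4)
  f3 <- fit_circle(cbind(x = 5 * cos(th3), y = 5 * sin(th3)))
  expect_equal(unname(f3$center), c(0, 0), tolerance = 1e-9)
  expect_equal(f3$radius, 5, tolerance = 1e-9)
  # square corners: circumscribed circle
  fsq <- fit_circle(cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)))
  expect_equal(fsq$radius, sqrt(200) / 2, tolerance = 1e-9)
  expect_equal(unname(fsq$center), c(5, 5), tolerance = 1e-9)
  expect_error(fit_circle(cbind(x = 1:5, y = 2 * (1:5) + 1)), "collinear")
})

test_that("circle fit recovers radius under symmetric radial noise", {
  set.seed(101)
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  r <- 13 + 0.1 * rep(c(1, -1), length.out = 100)
  f <- fit_circle(cbind(x = r * cos(th), y = r * sin(th)))
  expect_equal(f$radius, 13, tolerance = 0.01)
})

test_that("ellipse fit recovers generating parameters exactly", {
  P <- ellipse_points(14, 9, 30, center = c(40, -17), n = 360)
  f <- fit_ellipse(P)
  expect_equal(f$semi_major, 14, tolerance = 1e-6)
  expect_equal(f$semi_minor, 9, tolerance = 1e-6)
  expect_equal(f$orientation, 30, tolerance = 1e-6)
  expect_equal(unname(f$center), c(40, -17), tolerance = 1e-6)
  # the constraint normalisation holds
  k <- f$conic
  expect_equal(4 * k[["a"]] * k[["c"]] - k[["b"]]^2, 1, tolerance = 1e-9)
  # a circle is an ellipse with vanishing eccentricity
  fc <- fit_ellipse(ellipse_points(10, 10, 0, n = 200))
  expect_lt(sqrt(1 - (fc$semi_minor / fc$semi_major)^2), 1e-6)
  expect_error(fit_ellipse(cbind(x = 1:10, y = 1:10 * 2)), "degenerate|singular")
})

test_that("noisy ellipse samples recover axes within one percent", {
  set.seed(202)
  P <- ellipse_points(14, 9, 25, n = 200, noise_sd = 0.1)
  f <- fit_ellipse(P)
  expect_equal(f$semi_major, 14, tolerance = 0.01)
  expect_equal(f$semi_minor, 9, tolerance = 0.01)
})

test_that("average errors vanish on perfect conics and scale as expected", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(x = 13 * cos(th), y = 13 * sin(th))
  expect_lt(average_error_circle(circ), 1e-10)
  ell <- ellipse_points(14, 9, 30, n = 360)
  expect_lt(average_error_ellipse(ell), 1e-10)
  # two points at radius r + d and r - d from an exact-fit circle: error d^2
  f <- fit_circle(circ)
  probe <- rbind(c(13.3, 0), c(-12.7, 0))
  colnames(probe) <- c("x", "y")
  expect_equal(average_error_circle(probe, f), 0.09, tolerance = 1e-9)
  # nested models: the direct ellipse fit cannot do worse algebraically
  # than the circle evaluated as a conic on the same points
  set.seed(7)
  wob <- cbind(x = (13 + rnorm(180, 0, 0.3)) * cos(th[seq(1, 360, 2)]),
               y = (13 + rnorm(180, 0, 0.3)) * sin(th[seq(1, 360, 2)]))
  fe <- fit_ellipse(wob)
  fc <- fit_circle(wob)
  circle_conic <- c(a = 1, b = 0, c = 1,
                    d = -2 * unname(fc$center[1]),
                    e = -2 * unname(fc$center[2]),
                    f = sum(fc$center^2) - fc$radius^2) / 2   # 4ac - b^2 = 1
  fake <- structure(list(conic = circle_conic), class = "ellipse_fit")
  expect_lte(average_error_ellipse(wob, fe), average_error_ellipse(wob, fake))
})

test_that("fits are equivariant under rotation and translation", {
  set.seed(303)
  base <- ellipse_points(12, 7, 0, n = 120, noise_sd = 0.05)
  f0 <- fit_ellipse(base)
  phi <- 73 * pi / 180
  shift <- c(25, -40)
  moved <- cbind(x = base[, 1] * cos(phi) - base[, 2] * sin(phi) + shift[1],
                 y = base[, 1] * sin(phi) + base[, 2] * cos(phi) + shift[2])
  f1 <- fit_ellipse(moved)
  expect_equal(f1$semi_major, f0$semi_major, tolerance = 1e-9)
  expect_equal(f1$semi_minor, f0$semi_minor, tolerance = 1e-9)
  expect_equal((f1$orientation - f0$orientation) %% 180, 73, tolerance = 1e-6)
  ctr_moved <- c(f0$center[1] * cos(phi) - f0$center[2] * sin(phi) + shift[1],
                 f0$center[1] * sin(phi) + f0$center[2] * cos(phi) + shift[2])
  expect_equal(unname(f1$center), unname(ctr_moved), tolerance = 1e-9)
  # the average errors are invariant
  expect_equal(average_error_ellipse(moved, f1), average_error_ellipse(base, f0),
               tolerance = 1e-9)
  fc0 <- fit_circle(base); fc1 <- fit_circle(moved)
  expect_equal(fc1$radius, fc0$radius, tolerance = 1e-9)
  expect_equal(average_error_circle(moved, fc1),
               average_error_circle(base, fc0), tolerance = 1e-9)
})

test_that("direct fit agrees with an iterative geometric oracle", {
  # oracle: minimise mean squared radial-like residual over the 5 geometric
  # parameters with optim, started away from the truth
  set.seed(404)
  P <- ellipse_points(11, 6, 40, center = c(3, -2), n = 90, noise_sd = 0.02)
  obj <- function(par) {
    ctr <- par[1:2]; ax <- abs(par[3:4]); phi <- par[5]
    p <- cbind(P[, 1] - ctr[1], P[, 2] - ctr[2])
    u <- p[, 1] * cos(phi) + p[, 2] * sin(phi)
    w <- -p[, 1] * sin(phi) + p[, 2] * cos(phi)
    mean(((u / ax[1])^2 + (w / ax[2])^2 - 1)^2)
  }
  fit <- fit_ellipse(P)
  orc <- optim(c(0, 0, 12, 5, 0.5), obj,
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$semi_major, abs(orc$par[3]), tolerance = 0.02)
  expect_equal(fit$semi_minor, abs(orc$par[4]), tolerance = 0.02)
  expect_equal(unname(fit$center), orc$par[1:2], tolerance = 0.05)
})

test_that("a triangular section deviates more from an ellipse than an ellipse", {
  ph_tri <- rasterize_phantom(phantom_spec("tibia_like", outer = 12,
                                           inner = 8.2), small_geom)
  ph_ell <- rasterize_phantom(phantom_spec("elliptical_annulus",
                                           outer = c(14, 9),
                                           inner = c(10, 5)), small_geom)
  r_tri <- summarize_shape(segment_cortex(ph_tri$image, small_cfg))
  r_ell <- summarize_shape(segment_cortex(ph_ell$image, small_cfg))
  expect_gt(r_tri$err_ellipse_alg, r_ell$err_ellipse_alg)
})

test_that("tidiers return tibbles with the fitted parameters", {
  f <- fit_ellipse(ellipse_points(14, 9, 30, n = 100))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("semi_major", "semi_minor") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$n, 100L)
  expect_lt(gl$eccentricity, 1)
  fc <- fit_circle(ellipse_points(5, 5, 0, n = 50))
  expect_equal(glance(fc)$radius, 5, tolerance = 1e-9)
})
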