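#' Algebraic least-squares circle fit
#'
#' Fits a circle by minimising the algebraic residual
#' `sum((x^2 + y^2 + D x + E y + F)^2)` (the Kasa formulation), which is a
#' linear least-squares problem and exact for points lying on a circle.
#'
#' @param points A contour tibble / data frame with columns `x`, `y`, or a
#'   two-column matrix (mm).
#' @return An object of class `circle_fit` with fields `center` (x, y mm),
#'   `radius` (mm) and `n`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)[-1]
#' fit_circle(cbind(x = 13 * cos(th), y = 13 * sin(th)))
#' @export
fit_circle <- function(points) {
  P <- as_points(points)
  if (nrow(P) < 3L) stop("circle fit needs at least 3 points")
  x <- P[, 1L]; y <- P[, 2L]
  X <- cbind(x, y, 1)
  if (qr(X)$rank < 3L) stop("degenerate circle fit: points are collinear")
  rhs <- -(x^2 + y^2)
  sol <- unname(qr.solve(X, rhs))
  D <- sol[1L]; E <- sol[2L]; FF <- sol[3L]
  r2 <- (D^2 + E^2) / 4 - FF
  if (r2 <= 0) stop("degenerate circle fit: non-positive squared radius")
  structure(list(center = c(x = -D / 2, y = -E / 2),
                 radius = sqrt(r2), n = nrow(P)),
            class = "circle_fit")
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    as.matrix(points[, c("x", "y")])
  } else {
    m <- as.matrix(points)
    stopifnot(ncol(m) == 2L)
    colnames(m) <- c("x", "y")
    m
  }
}

#' @export
format.circle_fit <- function(x, ...) {
  sprintf("<circle_fit center (%.3f, %.3f) mm, radius %.3f mm, n = %d>",
          x$center[1L], x$center[2L], x$radius, x$n)
}

#' @export
print.circle_fit <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Direct least-squares ellipse fit (Fitzgibbon method)
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` under the
#' ellipse-specificity constraint `4ac - b^2 = 1` by the generalized
#' eigenproblem of the direct least-squares method, in the numerically
#' stabilised scatter-matrix partitioning of Halir & Flusser. Points are
#' centered on their mean before fitting and the conic is shifted back,
#' which keeps the scatter matrix well conditioned for contours far from
#' the origin. Exact for points on an ellipse.
#'
#' @param points A contour tibble / data frame with `x`, `y`, or a
#'   two-column matrix (mm); at least 6 points not all on a line or
#'   line pair.
#' @return An object of class `ellipse_fit` with fields `center`,
#'   `semi_major`, `semi_minor` (mm), `orientation` (degrees from the
#'   +x axis, in `[0, 180)`), `conic` (a, b, c, d, e, f normalised so
#'   `4ac - b^2 = 1`) and `n`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)[-1]
#' fit_ellipse(cbind(x = 14 * cos(th), y = 9 * sin(th)))
#' @export
fit_ellipse <- function(points) {
  P <- as_points(points)
  if (nrow(P) < 6L) stop("ellipse fit needs at least 6 points")
  mx <- mean(P[, 1L]); my <- mean(P[, 2L])
  x <- P[, 1L] - mx; y <- P[, 2L] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-14) stop("degenerate ellipse fit: singular point scatter")
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  # premultiply by inverse of the constraint matrix C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  eig <- eigen(M)
  evec <- Re(eig$vectors)
  # pick the eigenvector with 4ac - b^2 > 0 (the unique ellipse solution)
  cond <- 4 * evec[1L, ] * evec[3L, ] - evec[2L, ]^2
  good <- which(cond > 0)
  if (!length(good)) {
    stop("ellipse fit failed: no elliptical eigen-solution (degenerate or ",
         "numerically unstable scatter)")
  }
  a1 <- evec[, good[1L]]
  a2 <- as.vector(T_ %*% a1)
  coefs <- c(a1, a2)
  # normalise so 4ac - b^2 = 1
  k <- 4 * coefs[1L] * coefs[3L] - coefs[2L]^2
  coefs <- coefs / sqrt(k)
  if (coefs[1L] < 0) coefs <- -coefs
  # shift back to the original frame: substitute x -> x - mx, y -> y - my
  a <- coefs[1L]; b <- coefs[2L]; cc <- coefs[3L]
  d <- coefs[4L]; e <- coefs[5L]; f <- coefs[6L]
  d0 <- d - 2 * a * mx - b * my
  e0 <- e - 2 * cc * my - b * mx
  f0 <- f + a * mx^2 + b * mx * my + cc * my^2 - d * mx - e * my
  conic <- c(a = a, b = b, c = cc, d = d0, e = e0, f = f0)
  geom <- conic_to_geometry(conic)
  structure(c(geom, list(conic = conic, n = nrow(P))), class = "ellipse_fit")
}

# recover center, semi-axes and orientation from conic coefficients
conic_to_geometry <- function(k) {
  a <- k[["a"]]; b <- k[["b"]]; cc <- k[["c"]]
  d <- k[["d"]]; e <- k[["e"]]; f <- k[["f"]]
  disc <- b^2 - 4 * a * cc
  if (disc >= 0) stop("conic is not an ellipse (discriminant >= 0)")
  cx <- (2 * cc * d - b * e) / disc
  cy <- (2 * a * e - b * d) / disc
  f0 <- a * cx^2 + b * cx * cy + cc * cy^2 + d * cx + e * cy + f
  M <- matrix(c(a, b / 2, b / 2, cc), 2L)
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values              # decreasing; both positive for an ellipse
  if (any(lam <= 0) || f0 >= 0) stop("conic is not a real ellipse")
  axes <- sqrt(-f0 / lam)       # lam max -> minor axis
  semi_minor <- axes[1L]; semi_major <- axes[2L]
  major_vec <- ev$vectors[, 2L]
  ang <- (atan2(major_vec[2L], major_vec[1L]) * 180 / pi) %% 180
  list(center = c(x = cx, y = cy),
       semi_major = semi_major, semi_minor = semi_minor,
       orientation = ang)
}

#' @export
format.ellipse_fit <- function(x, ...) {
  sprintf(paste0("<ellipse_fit center (%.3f, %.3f) mm, semi-axes ",
                 "(%.3f, %.3f) mm, %.1f deg, n = %d>"),
          x$center[1L], x$center[2L], x$semi_major, x$semi_minor,
          x$orientation, x$n)
}

#' @export
print.ellipse_fit <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Average deviation of a contour from its fitted ideal circle
#'
#' Geometric metric (default, mm^2): mean squared radial deviation
#' `mean((|p - center| - radius)^2)`; exactly 0 for a perfectly circular
#' contour. The algebraic variant is the mean squared Kasa residual.
#'
#' @param points Contour points (tibble / matrix).
#' @param fit A [fit_circle()] result; refitted from `points` when
#'   missing.
#' @param metric `"geometric"` (mm^2) or `"algebraic"`.
#' @return Mean squared deviation (scalar).
#' @export
average_error_circle <- function(points, fit = fit_circle(points),
                                 metric = c("geometric", "algebraic")) {
  metric <- match.arg(metric)
  P <- as_points(points)
  dx <- P[, 1L] - fit$center[1L]
  dy <- P[, 2L] - fit$center[2L]
  r <- sqrt(dx^2 + dy^2)
  if (metric == "geometric") {
    mean((r - fit$radius)^2)
  } else {
    mean((r^2 - fit$radius^2)^2)
  }
}

#' Average deviation of a contour from its fitted ideal ellipse
#'
#' Algebraic metric (default): mean squared residual of the normalised
#' conic (`4ac - b^2 = 1` scaling); exactly 0 for a perfectly elliptical
#' contour. The geometric variant divides each residual by the conic
#' gradient magnitude before squaring (the Sampson approximation of
#' orthogonal distance, mm^2).
#'
#' @param points Contour points (tibble / matrix).
#' @param fit A [fit_ellipse()] result; refitted from `points` when
#'   missing.
#' @param metric `"algebraic"` or `"geometric"`.
#' @return Mean squared residual (scalar).
#' @export
average_error_ellipse <- function(points, fit = fit_ellipse(points),
                                  metric = c("algebraic", "geometric")) {
  metric <- match.arg(metric)
  P <- as_points(points)
  k <- fit$conic
  x <- P[, 1L]; y <- P[, 2L]
  res <- k[["a"]] * x^2 + k[["b"]] * x * y + k[["c"]] * y^2 +
    k[["d"]] * x + k[["e"]] * y + k[["f"]]
  if (metric == "algebraic") {
    mean(res^2)
  } else {
    gx <- 2 * k[["a"]] * x + k[["b"]] * y + k[["d"]]
    gy <- 2 * k[["c"]] * y + k[["b"]] * x + k[["e"]]
    mean(res^2 / pmax(gx^2 + gy^2, .Machine$double.eps))
  }
}

#' @rdname tidiers
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "radius"),
    estimate = c(unname(x$center), x$radius)
  )
}

#' @rdname tidiers
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(radius = x$radius, n = x$n)
}

#' Broom-style tidiers for conic fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` a one-row
#' model summary.
#'
#' @param x A `circle_fit` or `ellipse_fit`.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "semi_major", "semi_minor",
             "orientation_deg", names(x$conic)),
    estimate = c(unname(x$center), x$semi_major, x$semi_minor,
                 x$orientation, unname(x$conic))
  )
}

#' @rdname tidiers
#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(semi_major = x$semi_major, semi_minor = x$semi_minor,
                 eccentricity = sqrt(1 - (x$semi_minor / x$semi_major)^2),
                 orientation_deg = x$orientation, n = x$n)
}

# sample points on a fit outline, for rendering and tests
outline_points <- function(fit, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (inherits(fit, "circle_fit")) {
    cbind(x = fit$center[1L] + fit$radius * cos(th),
          y = fit$center[2L] + fit$radius * sin(th))
  } else {
    phi <- fit$orientation * pi / 180
    xa <- fit$semi_major * cos(th); yb <- fit$semi_minor * sin(th)
    cbind(x = fit$center[1L] + xa * cos(phi) - yb * sin(phi),
          y = fit$center[2L] + xa * sin(phi) + yb * cos(phi))
  }
}
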