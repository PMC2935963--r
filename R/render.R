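layer_colors <- c(
  mask = "#2b6cb0", periosteal = "#e53e3e", endosteal = "#38a169",
  max_axis = "#d69e2e", min_axis = "#b7791f", thickness = "#805ad5",
  circle = "#00b5d8", ellipse = "#ed64a6", centroid = "#ffffff"
)

#' Render a quality-control overlay of an analysis
#'
#' Writes a raster overlay: the grayscale scan as the base with colored
#' vector layers on top (mask tint, periosteal / endosteal contours, the
#' maximum and minimum diameter axes, thickness rays, the fitted circle
#' and ellipse, and the centroid). Pixels are written directly, so the
#' output is byte-identical across runs with the same inputs. This is the
#' visual check that a bone was correctly analyzed; a wrong threshold or
#' seed is obvious at a glance.
#'
#' @param image The analyzed [scan_image()].
#' @param result A `shape_result` from [summarize_shape()] (carries its
#'   segmentation and fits).
#' @param path Output PNG path.
#' @param layers Character subset of `c("mask", "periosteal",
#'   "endosteal", "max_axis", "min_axis", "thickness", "circle",
#'   "ellipse", "centroid")`; at least one.
#' @param upscale Integer pixel-replication factor (`>= 1`).
#' @return `path`, invisibly.
#' @export
render_overlay <- function(image, result, path,
                           layers = c("mask", "periosteal", "endosteal",
                                      "max_axis", "circle", "ellipse",
                                      "centroid"),
                           upscale = 2L) {
  stopifnot(inherits(image, "scan_image"), inherits(result, "shape_result"))
  if (!length(layers)) stop("need at least one overlay layer")
  layers <- match.arg(layers, names(layer_colors), several.ok = TRUE)
  seg <- attr(result, "segmentation")
  fits <- attr(result, "fits")
  g <- image$geometry; v <- g$voxel_size
  if (!is.null(seg) &&
      (nrow(seg$mask) != g$height || ncol(seg$mask) != g$width)) {
    stop("image and segmentation have inconsistent geometry")
  }
  base <- image$values / max(1, max(image$values))
  ch <- list(r = base, g = base, b = base)
  put <- function(ch, rr, cc, col) {
    ok <- rr >= 1L & rr <= g$height & cc >= 1L & cc <= g$width
    idx <- (cc[ok] - 1L) * g$height + rr[ok]
    rgb <- grDevices::col2rgb(col) / 255
    ch$r[idx] <- rgb[1L]; ch$g[idx] <- rgb[2L]; ch$b[idx] <- rgb[3L]
    ch
  }
  put_mm <- function(ch, x, y, col) {
    put(ch, pmax(1L, pmin(g$height, as.integer(ceiling(y / v)))),
        pmax(1L, pmin(g$width, as.integer(ceiling(x / v)))), col)
  }
  draw_segment <- function(ch, p1, p2, col) {
    n <- max(2L, ceiling(sqrt(sum((p2 - p1)^2)) / (v / 2)))
    t <- seq(0, 1, length.out = n)
    put_mm(ch, p1[1L] + t * (p2[1L] - p1[1L]),
           p1[2L] + t * (p2[2L] - p1[2L]), col)
  }
  if ("mask" %in% layers && !is.null(seg)) {
    idx <- which(seg$mask)
    tint <- grDevices::col2rgb(layer_colors[["mask"]]) / 255
    ch$r[idx] <- 0.6 * ch$r[idx] + 0.4 * tint[1L]
    ch$g[idx] <- 0.6 * ch$g[idx] + 0.4 * tint[2L]
    ch$b[idx] <- 0.6 * ch$b[idx] + 0.4 * tint[3L]
  }
  if ("periosteal" %in% layers && !is.null(seg)) {
    ch <- put_mm(ch, seg$periosteal$x, seg$periosteal$y,
                 layer_colors[["periosteal"]])
  }
  if ("endosteal" %in% layers && !is.null(seg)) {
    ch <- put_mm(ch, seg$endosteal$x, seg$endosteal$y,
                 layer_colors[["endosteal"]])
  }
  if ("max_axis" %in% layers) {
    ch <- draw_segment(ch, c(result$max_axis_x1_mm, result$max_axis_y1_mm),
                       c(result$max_axis_x2_mm, result$max_axis_y2_mm),
                       layer_colors[["max_axis"]])
  }
  if ("min_axis" %in% layers) {
    u <- c(result$max_axis_x2_mm - result$max_axis_x1_mm,
           result$max_axis_y2_mm - result$max_axis_y1_mm)
    u <- u / sqrt(sum(u^2))
    perp <- c(-u[2L], u[1L]) * result$min_diam_mm / 2
    ctr <- c(result$centroid_x_mm, result$centroid_y_mm)
    ch <- draw_segment(ch, ctr - perp, ctr + perp, layer_colors[["min_axis"]])
  }
  if ("thickness" %in% layers && !is.null(seg)) {
    prof <- thickness_profile(seg$periosteal, seg$endosteal)
    keep <- seq(1L, nrow(prof), by = max(1L, nrow(prof) %/% 36L))
    ch <- put_mm(ch, prof$x[keep], prof$y[keep], layer_colors[["thickness"]])
  }
  if ("circle" %in% layers && !is.null(fits)) {
    pts <- outline_points(fits$circle, 720L)
    ch <- put_mm(ch, pts[, 1L], pts[, 2L], layer_colors[["circle"]])
  }
  if ("ellipse" %in% layers && !is.null(fits)) {
    pts <- outline_points(fits$ellipse, 720L)
    ch <- put_mm(ch, pts[, 1L], pts[, 2L], layer_colors[["ellipse"]])
  }
  if ("centroid" %in% layers) {
    ctr <- c(result$centroid_x_mm, result$centroid_y_mm)
    ch <- draw_segment(ch, ctr - c(v, 0) * 2, ctr + c(v, 0) * 2,
                       layer_colors[["centroid"]])
    ch <- draw_segment(ch, ctr - c(0, v) * 2, ctr + c(0, v) * 2,
                       layer_colors[["centroid"]])
  }
  upscale <- as.integer(upscale)
  stopifnot(upscale >= 1L)
  up <- function(m) kronecker(m, matrix(1, upscale, upscale))
  arr <- array(0, dim = c(g$height * upscale, g$width * upscale, 3L))
  arr[, , 1L] <- up(ch$r); arr[, , 2L] <- up(ch$g); arr[, , 3L] <- up(ch$b)
  png::writePNG(arr, path)
  invisible(path)
}

#' Export a cortical mask as an 8-bit black/white PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Plot a segmentation as a ggplot overlay
#'
#' @param object A `cortical_segmentation`.
#' @param ... Unused.
#' @return A ggplot: contours over the mask, y-axis reversed so the image
#'   reads as on screen.
#' @export
autoplot.cortical_segmentation <- function(object, ...) {
  ct <- contour_table(object)
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   colour = .data$role)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a shape result: contours, fitted conics and the diameter axis
#'
#' @param object A `shape_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_result <- function(object, ...) {
  seg <- attr(object, "segmentation")
  fits <- attr(object, "fits")
  layers_df <- contour_table(seg)
  for (nm in c("circle", "ellipse")) {
    pts <- outline_points(fits[[nm]], 360L)
    layers_df <- dplyr::bind_rows(
      layers_df,
      tibble::tibble(role = paste("fitted", nm), point = seq_len(nrow(pts)),
                     x_mm = pts[, 1L], y_mm = pts[, 2L]))
  }
  axis_df <- tibble::tibble(
    role = "max axis", point = 1:2,
    x_mm = c(object$max_axis_x1_mm, object$max_axis_x2_mm),
    y_mm = c(object$max_axis_y1_mm, object$max_axis_y2_mm))
  ggplot2::ggplot(dplyr::bind_rows(layers_df, axis_df),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               colour = .data$role)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  title = sprintf("max %.1f / min %.1f mm, mean thickness %.2f mm",
                                  object$max_diam_mm, object$min_diam_mm,
                                  object$thk_mean_mm)) +
    ggplot2::theme_minimal()
}
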