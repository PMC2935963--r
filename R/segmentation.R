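#' Threshold a scan image into bone / background
#'
#' A pixel is foreground iff its attenuation value is `>= threshold`.
#'
#' @param image A [scan_image()] or a plain numeric matrix.
#' @param threshold Attenuation threshold in scanner units (`>= 0`).
#' @return A logical matrix of the same dimensions.
#' @export
binarize <- function(image, threshold = 450) {
  stopifnot(threshold >= 0)
  vals <- if (inherits(image, "scan_image")) image$values else as.matrix(image)
  vals >= threshold
}

# linear-index offsets of the 8- or 4-neighbourhood as (dr, dc) pairs
neighbour_offsets <- function(connectivity = 8L) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  }
}

# vectorised frontier BFS from a set of linear start indices
flood_from <- function(binary, start_idx, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  offs <- neighbour_offsets(connectivity)
  visited <- matrix(FALSE, nr, nc)
  visited[start_idx] <- TRUE
  frontier <- start_idx
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[binary[idx] & !visited[idx]]
      if (length(idx)) {
        visited[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- nxt
  }
  visited
}

#' Select the seeded connected component of a binary grid
#'
#' The flooding step: starting from a seed placed on bone, keep only the
#' 8-connected foreground component containing it and discard everything
#' else (the fibula, noise specks, calibration objects).
#'
#' @param binary Logical matrix from [binarize()].
#' @param seed Integer `(row, col)` of the seed pixel; must be foreground.
#' @param connectivity Foreground connectivity, 8 (default) or 4.
#' @return Logical matrix containing only the seed's component.
#' @export
flood_select <- function(binary, seed, connectivity = 8L) {
  binary <- as.matrix(binary)
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(is.na(seed)) ||
      seed[1] < 1L || seed[1] > nrow(binary) ||
      seed[2] < 1L || seed[2] > ncol(binary)) {
    stop("seed (", paste(seed, collapse = ", "), ") is outside the image")
  }
  if (!isTRUE(binary[seed[1], seed[2]])) {
    stop("seed not on bone: pixel (", seed[1], ", ", seed[2],
         ") is below threshold; reposition the crosshair")
  }
  flood_from(binary, (seed[2] - 1L) * nrow(binary) + seed[1], connectivity)
}

# label all components of a binary grid; returns integer matrix (0 = bg)
label_components <- function(binary, connectivity = 8L) {
  labels <- matrix(0L, nrow(binary), ncol(binary))
  remaining <- which(binary)
  lab <- 0L
  while (length(remaining)) {
    lab <- lab + 1L
    comp <- flood_from(binary & labels == 0L, remaining[1L], connectivity)
    labels[comp] <- lab
    remaining <- which(binary & labels == 0L)
  }
  labels
}

# morphological opening with a 3x3 cross ("diamond") structuring element
open_cross <- function(mask, iterations = 1L) {
  if (iterations == 0L) return(mask)
  kern <- EBImage::makeBrush(3L, shape = "diamond")
  m <- mask * 1L
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  matrix(as.logical(m), nrow(mask), ncol(mask))
}

#' Morphological cleanup of a flooded cortical mask
#'
#' Applies `iterations` rounds of morphological opening (erosion then
#' dilation with a 3x3 cross structuring element) to strip background
#' noise and thin spurs, then re-selects the component containing the
#' seed so the result is again a single region. `iterations = 0` is the
#' identity.
#'
#' @param mask Logical matrix (the flooded component).
#' @param iterations Number of opening passes (`>= 0`).
#' @param seed `(row, col)` used to re-select the surviving component;
#'   when the seed pixel itself is eroded away the largest surviving
#'   component is kept instead.
#' @return Logical matrix.
#' @export
morph_clean <- function(mask, iterations = 1L, seed = NULL) {
  mask <- as.matrix(mask)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L)
  if (iterations == 0L) return(mask)
  opened <- open_cross(mask, iterations)
  if (!any(opened)) {
    stop("cortex eroded away by morphological cleanup: threshold too high ",
         "or cortical ring too thin")
  }
  if (!is.null(seed) && isTRUE(opened[seed[1], seed[2]])) {
    flood_from(opened, (seed[2] - 1L) * nrow(opened) + seed[1], 8L)
  } else {
    labs <- label_components(opened, 8L)
    sizes <- tabulate(labs[labs > 0L])
    labs == which.max(sizes)
  }
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion.
# Returns ordered (row, col) boundary pixels of the TRUE region, which
# must be a single connected component.
moore_trace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad so neighbour lookups never leave the grid
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pad)
  if (!length(fg)) stop("cannot trace an empty mask")
  # start pixel: topmost row, then leftmost column
  rows <- (fg - 1L) %% (nr + 2L) + 1L
  cols <- (fg - 1L) %/% (nr + 2L) + 1L
  ord <- order(rows, cols)
  start <- c(rows[ord[1L]], cols[ord[1L]])
  # clockwise neighbour ring on screen (x right, y down), starting west
  ring <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  if (sum(pad) == 1L) return(matrix(start - 1L, ncol = 2L))
  path_r <- integer(0); path_c <- integer(0)
  cur <- start
  back_dir <- 1L    # start is topmost-leftmost, so its west neighbour is bg
  second <- NULL
  max_steps <- 8L * sum(pad) + 8L
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) stop("boundary tracing did not terminate")
    found <- FALSE
    for (k in 0:7) {
      d <- (back_dir - 1L + k) %% 8L + 1L
      rr <- cur[1L] + ring[d, 1L]; cc <- cur[2L] + ring[d, 2L]
      if (pad[rr, cc]) {
        prev <- cur
        path_r <- c(path_r, cur[1L]); path_c <- c(path_c, cur[2L])
        # backtrack for the next scan: the neighbour examined just before
        # the hit (always background and 8-adjacent to the new pixel)
        prev_d <- (d - 2L) %% 8L + 1L
        back_pix <- cur + ring[prev_d, ]
        cur <- c(rr, cc)
        dd <- back_pix - cur
        back_dir <- which(ring[, 1L] == dd[1L] & ring[, 2L] == dd[2L])
        found <- TRUE
        break
      }
    }
    if (!found) break   # isolated pixel (guarded above)
    if (is.null(second)) {
      second <- cur     # remember the first transition start -> second
    } else if (all(prev == start) && all(cur == second)) {
      # the first transition repeated: full cycle; drop the re-appended start
      path_r <- path_r[-length(path_r)]
      path_c <- path_c[-length(path_c)]
      break
    }
  }
  cbind(path_r, path_c) - 1L   # unpad
}

# signed shoelace area using the standard formula in the y-down frame;
# visual counter-clockwise (screen) traversal gives a NEGATIVE value
shoelace_signed <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

new_contour <- function(x, y, role, voxel_size) {
  out <- tibble::tibble(x = x, y = y)
  attr(out, "role") <- role
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("pqct_contour", class(out))
  out
}

#' @export
format.pqct_contour <- function(x, ...) {
  sprintf("<pqct_contour %s, %d points, perimeter %.2f mm>",
          attr(x, "role"), nrow(x), contour_perimeter(x))
}

#' Trace the periosteal and endosteal boundaries of a cortical mask
#'
#' The periosteal contour is the Moore-neighbour trace of the outer
#' boundary of the cortical component; the endosteal contour is the trace
#' of the largest background hole it encloses (the medullary cavity).
#' Both are closed polygons over pixel centers in mm, oriented
#' counter-clockwise on screen (x right, y down).
#'
#' A mask with no enclosed hole is an open cortical ring and is rejected
#' loudly (typically a movement-artifact scan). When several holes are
#' present and more than one exceeds 5% of the total hole area, a warning
#' is raised and the largest is used.
#'
#' @param mask Logical matrix: one 8-connected cortical component.
#' @param voxel_size Pixel size in mm.
#' @return A list with elements `periosteal` and `endosteal`, each a
#'   contour tibble with columns `x`, `y` (mm).
#' @export
extract_boundaries <- function(mask, voxel_size = 0.5) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("cannot extract boundaries of an empty mask")
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])) {
    stop("cortical component touches the image border: likely movement ",
         "artifact or truncated field of view")
  }
  holes <- enclosed_holes(mask)
  if (holes$n == 0L) {
    stop("open cortical ring: the cortex does not enclose a medullary ",
         "cavity; scan is likely invalid (movement artifact) or the ",
         "threshold is too high")
  }
  if (holes$n_large > 1L) {
    warning("cortical ring encloses ", holes$n,
            " holes; using the largest as the medullary cavity")
  }
  peri_px <- moore_trace(mask)
  endo_px <- moore_trace(holes$largest)
  v <- voxel_size
  peri <- new_contour((peri_px[, 2L] - 0.5) * v, (peri_px[, 1L] - 0.5) * v,
                      "periosteal", v)
  endo <- new_contour((endo_px[, 2L] - 0.5) * v, (endo_px[, 1L] - 0.5) * v,
                      "endosteal", v)
  # normalise to counter-clockwise on screen: standard shoelace negative
  if (nrow(peri) > 2L && shoelace_signed(peri$x, peri$y) > 0) {
    peri <- peri[rev(seq_len(nrow(peri))), ]
  }
  if (nrow(endo) > 2L && shoelace_signed(endo$x, endo$y) > 0) {
    endo <- endo[rev(seq_len(nrow(endo))), ]
  }
  list(periosteal = peri, endosteal = endo)
}

# find background holes enclosed by the mask (4-connected background
# components not touching the border); returns the largest as a mask
enclosed_holes <- function(mask) {
  bg <- !mask
  labs <- label_components(bg, 4L)
  border_labs <- unique(c(labs[1, ], labs[nrow(labs), ],
                          labs[, 1], labs[, ncol(labs)]))
  border_labs <- border_labs[border_labs > 0L]
  hole_labs <- setdiff(unique(labs[labs > 0L]), border_labs)
  if (!length(hole_labs)) {
    return(list(n = 0L, n_large = 0L, largest = NULL, areas = integer(0)))
  }
  areas <- vapply(hole_labs, function(l) sum(labs == l), integer(1))
  big <- sum(areas > 0.05 * sum(areas))
  list(n = length(hole_labs), n_large = big,
       largest = labs == hole_labs[which.max(areas)], areas = areas)
}

#' Pick an automatic seed: brightest pixel of the largest bone component
#'
#' Batch replacement for the interactive crosshair: among above-threshold
#' pixels, take the largest 8-connected component and return its brightest
#' pixel (first in row-major order on ties).
#'
#' @param image A [scan_image()].
#' @param threshold Attenuation threshold.
#' @return Integer `(row, col)`.
#' @export
auto_seed <- function(image, threshold = 450) {
  binary <- binarize(image, threshold)
  if (!any(binary)) stop("no above-threshold pixels: cannot auto-seed")
  labs <- label_components(binary, 8L)
  sizes <- tabulate(labs[labs > 0L])
  comp <- labs == which.max(sizes)
  vals <- ifelse(comp, if (inherits(image, "scan_image")) image$values else image,
                 -1L)
  idx <- which(vals == max(vals))[1L]
  c((idx - 1L) %% nrow(binary) + 1L, (idx - 1L) %/% nrow(binary) + 1L)
}

#' Segment the cortical ring of a pQCT cross-section
#'
#' Full segmentation pipeline: [binarize()] at the configured threshold,
#' [flood_select()] from the seed, [morph_clean()] opening passes, then
#' [extract_boundaries()]. Deterministic for fixed inputs; any stage
#' failure is re-raised with the stage named.
#'
#' @param image A [scan_image()].
#' @param config An [analysis_config()].
#' @param seed `(row, col)` seed on cortical bone, or `NULL` to use
#'   [auto_seed()].
#' @return A list of class `cortical_segmentation` with elements `mask`
#'   (logical matrix), `periosteal`, `endosteal` (contour tibbles),
#'   `seed`, and `config`.
#' @examples
#' ph <- rasterize_phantom(phantom_spec(), image_geometry(128, 128, 0.5))
#' seg <- segment_cortex(ph$image, analysis_config(width = 128, height = 128))
#' nrow(seg$periosteal)
#' @export
segment_cortex <- function(image, config = analysis_config(), seed = NULL) {
  stopifnot(inherits(image, "scan_image"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("segmentation stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(seed)) {
    seed <- stage("auto_seed", auto_seed(image, config$threshold))
  }
  binary <- stage("binarize", binarize(image, config$threshold))
  flooded <- stage("flood_select",
                   flood_select(binary, seed, config$connectivity))
  mask <- stage("morph_clean",
                morph_clean(flooded, config$open_iterations, seed = seed))
  bounds <- stage("extract_boundaries",
                  extract_boundaries(mask, config$voxel_size))
  structure(
    list(mask = mask, periosteal = bounds$periosteal,
         endosteal = bounds$endosteal, seed = as.integer(seed),
         config = config),
    class = "cortical_segmentation"
  )
}

#' @export
format.cortical_segmentation <- function(x, ...) {
  sprintf("<cortical_segmentation: %d cortical px, peri %d pts, endo %d pts>",
          sum(x$mask), nrow(x$periosteal), nrow(x$endosteal))
}

#' @export
print.cortical_segmentation <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Export contours as a tidy table
#'
#' @param segmentation A `cortical_segmentation`.
#' @return A tibble with columns `role`, `point`, `x_mm`, `y_mm`.
#' @export
contour_table <- function(segmentation) {
  peri <- segmentation$periosteal; endo <- segmentation$endosteal
  dplyr::bind_rows(
    tibble::tibble(role = "periosteal", point = seq_len(nrow(peri)),
                   x_mm = peri$x, y_mm = peri$y),
    tibble::tibble(role = "endosteal", point = seq_len(nrow(endo)),
                   x_mm = endo$x, y_mm = endo$y)
  )
}
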