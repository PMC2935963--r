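#' Image geometry for raw pQCT cross-sections
#'
#' Describes the layout of a headerless raw pQCT export: grid dimensions,
#' physical pixel size and byte order. Samples are unsigned 16-bit integers,
#' row-major, row index increasing downward. The scanner exports used
#' throughout are 283 x 283 pixels at a 0.5 mm in-plane voxel.
#'
#' Physical coordinates: pixel (row r, col c), 1-based, occupies the square
#' `[(c-1)v, cv) x [(r-1)v, rv)` mm and its center is at
#' `((c - 0.5) v, (r - 0.5) v)`. x increases rightward with column, y
#' increases downward with row. All contour points are pixel centers.
#'
#' @param width,height Image dimensions in pixels.
#' @param voxel_size In-plane pixel side length in mm.
#' @param byte_order `"little"` (default; the scanner platform's native
#'   order) or `"big"`.
#' @return An object of class `image_geometry`.
#' @examples
#' image_geometry()                  # the default 283 x 283 @ 0.5 mm
#' image_geometry(64, 64, 0.25)
#' @export
image_geometry <- function(width = 283L, height = 283L, voxel_size = 0.5,
                           byte_order = c("little", "big")) {
  byte_order <- match.arg(byte_order)
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width > 0L, height > 0L, voxel_size > 0)
  structure(
    list(width = width, height = height, voxel_size = voxel_size,
         byte_order = byte_order),
    class = "image_geometry"
  )
}

#' @export
format.image_geometry <- function(x, ...) {
  sprintf("<image_geometry %d x %d px, voxel %g mm, %s-endian>",
          x$width, x$height, x$voxel_size, x$byte_order)
}

#' @export
print.image_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a scan image from a matrix of attenuation values
#'
#' @param values Numeric matrix, `height x width`, values in `[0, 65535]`
#'   (dimensionless scanner units).
#' @param geometry An [image_geometry()]; defaults to the matrix dimensions
#'   at `voxel_size`.
#' @param voxel_size Used when `geometry` is missing.
#' @return An object of class `scan_image` with fields `values` (integer
#'   matrix) and `geometry`.
#' @export
scan_image <- function(values, geometry = NULL, voxel_size = 0.5) {
  values <- as.matrix(values)
  if (is.null(geometry)) {
    geometry <- image_geometry(ncol(values), nrow(values), voxel_size)
  }
  if (nrow(values) != geometry$height || ncol(values) != geometry$width) {
    stop("value grid is ", nrow(values), " x ", ncol(values),
         " but geometry says ", geometry$height, " x ", geometry$width)
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 65535) {
    stop("attenuation values must lie in [0, 65535] with no missing entries")
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, geometry = geometry), class = "scan_image")
}

#' @export
format.scan_image <- function(x, ...) {
  sprintf("<scan_image %d x %d px, voxel %g mm, range [%d, %d]>",
          x$geometry$height, x$geometry$width, x$geometry$voxel_size,
          min(x$values), max(x$values))
}

#' @export
print.scan_image <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Read a headerless raw pQCT image
#'
#' Reads the scanner's `.raw` export: unsigned 16-bit samples, row-major,
#' the file's first sample landing at (row 1, col 1).
#'
#' @param path Path to the raw file.
#' @param geometry An [image_geometry()] giving dimensions, voxel size and
#'   byte order; the file length must be exactly `width * height * 2` bytes.
#' @return A [scan_image()].
#' @examples
#' img <- scan_image(matrix(0L, 16, 16), voxel_size = 0.5)
#' f <- tempfile(fileext = ".raw")
#' write_raw(img, f)
#' identical(read_raw(f, img$geometry)$values, img$values)
#' @export
read_raw <- function(path, geometry = image_geometry()) {
  if (!file.exists(path)) stop("cannot read raw image: no such file: ", path)
  expected <- geometry$width * geometry$height * 2L
  actual <- file.size(path)
  if (actual != expected) {
    stop("raw file size mismatch for ", path, ": expected ", expected,
         " bytes (", geometry$width, " x ", geometry$height,
         " x 2), found ", actual)
  }
  con <- file(path, "rb"); on.exit(close(con))
  raw_vals <- readBin(con, what = "integer", n = geometry$width * geometry$height,
                      size = 2L, signed = FALSE, endian = geometry$byte_order)
  # file is row-major; R matrices are column-major, so fill by row
  values <- matrix(raw_vals, nrow = geometry$height, ncol = geometry$width,
                   byrow = TRUE)
  scan_image(values, geometry)
}

#' Write a scan image as a headerless raw file
#'
#' Inverse of [read_raw()]: the written file reads back bit-identical.
#'
#' @param image A [scan_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write raw image to ", path,
                                           ": ", conditionMessage(e)))
  on.exit(close(con))
  # row-major on disk: transpose the column-major matrix before writing
  vals <- as.integer(t(image$values))
  writeBin(vals, con, size = 2L, endian = image$geometry$byte_order)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF or PNG as a scan image
#'
#' Convenience input dialect: standard image formats are rescaled from the
#' `[0, 1]` range the readers return back to 16-bit scanner units.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param voxel_size In-plane pixel size in mm.
#' @return A [scan_image()].
#' @export
read_scan <- function(path, voxel_size = 0.5) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "': use .raw, .tif or .png")
  )
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # take first channel
  scan_image(round(m * 65535), voxel_size = voxel_size)
}

default_config <- function() {
  list(
    threshold = 450,
    voxel_size = 0.5,
    width = 283L,
    height = 283L,
    open_iterations = 1L,
    connectivity = 8L,
    seed_policy = "auto",
    byte_order = "little",
    allow_threshold_override = FALSE,
    density_weighted_centroid = FALSE,
    min_diameter_chord = FALSE,
    subpixel = FALSE
  )
}

#' Assemble and validate an analysis configuration
#'
#' The configuration drives the whole pipeline: attenuation threshold,
#' voxel size, raw-image dimensions, morphological cleanup iterations,
#' connectivity and seed policy. The threshold slider of the original tool
#' spanned 200--1000; values outside that range are accepted only with
#' `allow_threshold_override = TRUE`.
#'
#' @param ... Named settings overriding the defaults: `threshold` (450),
#'   `voxel_size` (0.5 mm), `width`/`height` (283), `open_iterations` (1),
#'   `connectivity` (8), `seed_policy` (`"auto"` or `"manual"`),
#'   `byte_order`, `allow_threshold_override`,
#'   `density_weighted_centroid`, `min_diameter_chord`, `subpixel`.
#' @return A validated list of class `analysis_config`.
#' @examples
#' analysis_config()                      # the published defaults
#' analysis_config(threshold = 710)
#' @export
analysis_config <- function(...) {
  cfg <- modifyList(default_config(), list(...))
  extra <- setdiff(names(list(...)), names(default_config()))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  required <- c("threshold", "voxel_size", "width", "height")
  missing_keys <- required[!vapply(required, function(k)
    !is.null(cfg[[k]]) && !is.na(suppressWarnings(as.numeric(cfg[[k]]))),
    logical(1))]
  if (length(missing_keys)) {
    stop("config is missing required numeric key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  for (k in c("threshold", "voxel_size", "open_iterations")) {
    if (!is.numeric(cfg[[k]])) {
      val <- suppressWarnings(as.numeric(cfg[[k]]))
      if (is.na(val)) stop("config key '", k, "' is not numeric: ", cfg[[k]])
      cfg[[k]] <- val
    }
  }
  cfg$width <- as.integer(cfg$width); cfg$height <- as.integer(cfg$height)
  cfg$open_iterations <- as.integer(cfg$open_iterations)
  stopifnot(cfg$voxel_size > 0, cfg$width > 0L, cfg$height > 0L,
            cfg$open_iterations >= 0L)
  if (!cfg$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if ((cfg$threshold < 200 || cfg$threshold > 1000) &&
      !isTRUE(cfg$allow_threshold_override)) {
    stop("threshold ", cfg$threshold, " is outside the supported range ",
         "200-1000; set allow_threshold_override = TRUE to force it")
  }
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from a JSON file
#'
#' @param path Path to a JSON file whose keys match [analysis_config()].
#' @return A validated `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  parsed <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e) stop("cannot parse config ", path,
                                              ": ", conditionMessage(e)))
  if (!is.list(parsed)) stop("config must be a JSON object of key-value pairs")
  required <- c("threshold", "voxel_size", "width", "height")
  absent <- setdiff(required, names(parsed))
  if (length(absent)) {
    stop("config ", path, " is missing required key(s): ",
         paste(absent, collapse = ", "))
  }
  do.call(analysis_config, parsed)
}
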