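#' Total cross-sectional area from a raw image
#'
#' Counting-based CSA of the bone containing the seed: pixels at or above
#' threshold within the filled outer boundary of the seed component.
#' `csa_mm2` counts only above-threshold (cortical) pixels;
#' `csa_filled_mm2` additionally includes the enclosed medullary cavity
#' (the filled outer region), the quantity the circular ring model takes
#' as its total area.
#'
#' @param image A [scan_image()].
#' @param threshold Attenuation threshold in scanner units.
#' @param seed `(row, col)` on bone, or `NULL` for [auto_seed()].
#' @return A one-row tibble: `csa_mm2`, `csa_filled_mm2`, `n_pixels`,
#'   `n_pixels_filled`.
#' @export
total_csa <- function(image, threshold = 450, seed = NULL) {
  stopifnot(inherits(image, "scan_image"))
  binary <- binarize(image, threshold)
  if (!any(binary)) stop("no pixels at or above threshold ", threshold)
  if (is.null(seed)) seed <- auto_seed(image, threshold)
  comp <- flood_select(binary, seed, 8L)
  filled <- fill_holes(comp)
  v <- image$geometry$voxel_size
  above <- sum(binary & filled)
  tibble::tibble(
    csa_mm2 = above * v^2,
    csa_filled_mm2 = sum(filled) * v^2,
    n_pixels = above,
    n_pixels_filled = sum(filled)
  )
}

# fill the enclosed background holes of a single-component mask
fill_holes <- function(mask) {
  labs <- label_components(!mask, 4L)
  border_labs <- setdiff(unique(c(labs[1, ], labs[nrow(labs), ],
                                  labs[, 1], labs[, ncol(labs)])), 0L)
  mask | (labs > 0L & !matrix(labs %in% border_labs, nrow(labs), ncol(labs)))
}

#' Manufacturer-style circular ring estimates
#'
#' The circular ring model assumes a circular cross-section: from the
#' filled total area `A` and the cortical area `C` it derives the area
#' equivalent outer radius `sqrt(A / pi)` = `R` and inner radius
#' `sqrt((A - C) / pi)` = `r`, and
#' reports `2 pi R`, `2 pi r` and `R - r` as periosteal circumference,
#' endosteal circumference and mean cortical thickness. Exact when the
#' bone really is a circular ring; an underestimate of the true perimeters
#' otherwise (the circle minimises perimeter at fixed area).
#'
#' @param tot_csa_filled Total (filled) cross-sectional area, mm^2.
#' @param cort_csa Cortical area, mm^2; must satisfy
#'   `0 < cort_csa < tot_csa_filled` (a vanishing cavity is allowed via
#'   `cort_csa == tot_csa_filled`).
#' @return A one-row tibble: `peri_circ_ring_mm`, `endo_circ_ring_mm`,
#'   `mean_thickness_ring_mm`.
#' @examples
#' circular_estimates(pi * 12.5^2, pi * (12.5^2 - 7.5^2))
#' @export
circular_estimates <- function(tot_csa_filled, cort_csa) {
  if (!(tot_csa_filled >= cort_csa && cort_csa > 0)) {
    stop("need tot_csa_filled >= cort_csa > 0 (got ", tot_csa_filled,
         " and ", cort_csa, ")")
  }
  R <- sqrt(tot_csa_filled / pi)
  r <- sqrt((tot_csa_filled - cort_csa) / pi)
  tibble::tibble(
    peri_circ_ring_mm = 2 * pi * R,
    endo_circ_ring_mm = 2 * pi * r,
    mean_thickness_ring_mm = R - r
  )
}
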