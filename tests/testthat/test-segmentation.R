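test_that("binarize uses >= threshold semantics", {
  expect_identical(binarize(matrix(c(100, 450, 500, 449), 2, 2, byrow = TRUE),
                            450),
                   matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE))
  expect_false(any(binarize(matrix(0, 4, 4), 450)))
  expect_true(all(binarize(matrix(0, 4, 4), 0)))
})

test_that("flood_select keeps exactly the seeded component", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE     # blob A
  m[7:9, 7:9] <- TRUE     # blob B
  sel <- flood_select(m, c(3, 3))
  expect_true(all(sel[2:4, 2:4]))
  expect_false(any(sel[7:9, 7:9]))
  # single blob: identity
  expect_identical(flood_select(m & !sel | sel, c(3, 3)), sel)
  # diagonal chain is connected under 8-connectivity
  d <- matrix(FALSE, 8, 8)
  for (i in 1:6) d[i + 1, i + 1] <- TRUE
  expect_identical(flood_select(d, c(2, 2)), d)
  expect_error(flood_select(m, c(1, 1)), "seed not on bone")
  expect_error(flood_select(m, c(99, 1)), "outside the image")
})

test_that("flood_select agrees with a depth-first-search oracle", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_blobs(16)
    fg <- which(m)
    if (!length(fg)) next
    pick <- fg[sample(length(fg), 1L)]
    seed <- c((pick - 1L) %% 16L + 1L, (pick - 1L) %/% 16L + 1L)
    expect_identical(flood_select(m, seed), bfs_oracle(m, seed, 8L))
  }
})

test_that("morph_clean is an opening plus component re-selection", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_identical(morph_clean(sq, 0L), sq)           # identity at 0
  opened <- morph_clean(sq, 1L, seed = c(7, 7))
  expect_identical(opened, opening_oracle(sq, 1L))    # direct set morphology
  # isolated pixel is removed
  noisy <- sq; noisy[1, 1] <- TRUE
  expect_identical(morph_clean(noisy, 1L, seed = c(7, 7)), opened)
  # annihilation errors loudly
  thin <- matrix(FALSE, 8, 8); thin[4, 2:7] <- TRUE
  expect_error(morph_clean(thin, 1L, seed = c(4, 4)), "eroded away")
})

test_that("opening matches the set-morphology oracle on random grids", {
  set.seed(23)
  for (i in 1:40) {
    m <- random_blobs(18, p = 0.55)
    if (!any(opening_oracle(m, 1L))) next
    expect_identical(pqctshape:::open_cross(m, 1L), opening_oracle(m, 1L))
  }
})

test_that("boundary extraction returns nested closed ring contours", {
  ph <- rasterize_phantom(phantom_spec(outer = 10, inner = 6), small_geom)
  b <- extract_boundaries(ph$mask, 0.5)
  expect_gte(nrow(b$periosteal), 8)
  expect_gte(nrow(b$endosteal), 8)
  expect_gt(contour_area(b$periosteal), contour_area(b$endosteal))
  # every endosteal point lies inside the periosteal polygon
  expect_true(all(in_polygon(cbind(b$endosteal$x, b$endosteal$y),
                             cbind(b$periosteal$x, b$periosteal$y))))
  # solid disk has no cavity
  solid <- matrix(FALSE, 40, 40)
  xs <- (col(solid) - 20.5)^2 + (row(solid) - 20.5)^2
  solid[xs <= 100] <- TRUE
  expect_error(extract_boundaries(solid, 0.5), "open cortical ring")
})

test_that("chain-code steps give the documented perimeter for a 3x3 square", {
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  tr <- pqctshape:::moore_trace(m)
  expect_equal(nrow(tr), 8L)        # 8 boundary pixels
  ct <- tibble::tibble(x = (tr[, 2] - 0.5) * 0.5, y = (tr[, 1] - 0.5) * 0.5)
  expect_equal(contour_perimeter(ct), 4.0)
})

test_that("segmentation recovers the exact phantom mask and is idempotent", {
  ph <- rasterize_phantom(phantom_spec(), small_geom)
  seg <- segment_cortex(ph$image, small_cfg)
  # opening of a clean thick ring is the ring itself
  expect_identical(seg$mask, ph$mask)
  # sub-threshold noise does not change the mask
  phn <- build_phantom(phantom_spec(noise_sd = 40), small_geom)
  expect_identical(segment_cortex(phn$image, small_cfg)$mask, seg$mask)
  # re-embedding the mask as an image reproduces it
  re <- scan_image(ifelse(seg$mask, 65535L, 0L), small_geom)
  expect_identical(segment_cortex(re, small_cfg, seed = seg$seed)$mask,
                   seg$mask)
})

test_that("rotating the image by 90 degrees permutes the mask exactly", {
  ph <- rasterize_phantom(phantom_spec("eccentric_annulus",
                                       inner_offset = c(1.2, -0.8)),
                          small_geom)
  seg <- segment_cortex(ph$image, small_cfg)
  img90 <- scan_image(rot90_mat(ph$image$values), small_geom)
  seg90 <- segment_cortex(img90, small_cfg)
  expect_identical(seg90$mask, rot90_mat(seg$mask))
})

test_that("a motion-artifact streak is rejected with a topology error", {
  ph <- build_phantom(phantom_spec(motion_streak = TRUE), small_geom)
  expect_error(segment_cortex(ph$image, small_cfg),
               "touches the image border|open cortical ring")
})

test_that("polygon area and pixel count agree within the perimeter bound", {
  set.seed(31)
  for (i in 1:20) {
    ph <- random_ring()
    seg <- segment_cortex(ph$image, small_cfg)
    v <- 0.5
    filled_px <- sum(seg$mask) + sum(pqctshape:::enclosed_holes(seg$mask)$areas)
    expect_lt(abs(contour_area(seg$periosteal) - filled_px * v^2),
              contour_perimeter(seg$periosteal) * v)
  }
})
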