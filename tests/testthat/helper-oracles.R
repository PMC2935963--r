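# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms / code paths than the
# package internals.

# stack-based depth-first flood fill (vs the package's frontier BFS)
bfs_oracle <- function(binary, seed, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 4L) offs <- offs[abs(offs$dr) + abs(offs$dc) == 1, ]
  visited <- matrix(FALSE, nr, nc)
  if (!binary[seed[1], seed[2]]) return(visited)
  visited[seed[1], seed[2]] <- TRUE
  stack <- list(seed)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (i in seq_len(nrow(offs))) {
      r <- p[1] + offs$dr[i]; c <- p[2] + offs$dc[i]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          binary[r, c] && !visited[r, c]) {
        visited[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  visited
}

# plain O(n^2) all-pairs maximum distance
max_diameter_oracle <- function(P) {
  best <- 0
  for (i in seq_len(nrow(P) - 1L)) {
    d <- sqrt((P[i, 1] - P[-(1:i), 1])^2 + (P[i, 2] - P[-(1:i), 2])^2)
    best <- max(best, d)
  }
  best
}

# O(n * m) point-to-segment minimum distances, scalar loop
thickness_oracle <- function(P, Q) {
  m <- nrow(Q)
  jn <- c(2:m, 1L)
  sapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    min(sapply(seq_len(m), function(k) {
      a <- Q[k, ]; b <- Q[jn[k], ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      sqrt(sum((p - (a + t * ab))^2))
    }))
  })
}

# set-morphology opening with the 3x3 cross, built from explicit shifts
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

opening_oracle <- function(m, iterations = 1L) {
  er <- function(x) x & shift_mask(x, 1, 0) & shift_mask(x, -1, 0) &
    shift_mask(x, 0, 1) & shift_mask(x, 0, -1)
  di <- function(x) x | shift_mask(x, 1, 0) | shift_mask(x, -1, 0) |
    shift_mask(x, 0, 1) | shift_mask(x, 0, -1)
  for (i in seq_len(iterations)) m <- er(m)
  for (i in seq_len(iterations)) m <- di(m)
  m
}

# random blobby binary grid with clear borders
random_blobs <- function(n = 16L, p = 0.45) {
  m <- matrix(runif(n * n) < p, n, n)
  m[1, ] <- m[n, ] <- m[, 1] <- m[, n] <- FALSE
  m
}

# a valid random ring mask (rasterized eccentric annulus) plus its phantom
random_ring <- function(v = 0.5, n = 64L) {
  R <- runif(1, 9, 13)
  r <- runif(1, 4, R - 2.5)
  off <- runif(2, -1, 1) * (R - r - 2) / 2
  spec <- phantom_spec("eccentric_annulus", outer = R, inner = r,
                       inner_offset = off)
  rasterize_phantom(spec, image_geometry(n, n, v))
}

# dense points on a rotated, shifted ellipse
ellipse_points <- function(a, b, phi_deg = 0, center = c(0, 0), n = 200L,
                           noise_sd = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phi <- phi_deg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  cbind(x = x * cos(phi) - y * sin(phi) + center[1],
        y = x * sin(phi) + y * cos(phi) + center[2])
}

rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# even-odd ray-casting point-in-polygon test
in_polygon <- function(P, poly) {
  n <- nrow(poly)
  jp <- c(n, seq_len(n - 1L))
  vapply(seq_len(nrow(P)), function(i) {
    x <- P[i, 1]; y <- P[i, 2]
    inside <- FALSE
    for (k in seq_len(n)) {
      y1 <- poly[k, 2]; y2 <- poly[jp[k], 2]
      if ((y1 > y) != (y2 > y)) {
        xin <- poly[k, 1] + (y - y1) / (y2 - y1) * (poly[jp[k], 1] - poly[k, 1])
        if (x < xin) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

small_geom <- image_geometry(128, 128, 0.5)
small_cfg <- analysis_config(width = 128, height = 128)
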