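# Independent brute-force oracles used to validate the implementation.
# These deliberately use different algorithms (scalar loops, gift-wrapping,
# BFS queues) from the package's vectorized code paths.

# --- color space oracles ----------------------------------------------------

# Hexcone HSV, scalar textbook formulation.
oracle_hsv <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) 0
  else if (mx == r) ((g - b) / d) %% 6
  else if (mx == g) (b - r) / d + 2
  else (r - g) / d + 4
  c(h / 6, s, v)
}

# sRGB -> XYZ (D65) -> L*a*b*, scalar, published constants.
oracle_lab <- function(r, g, b) {
  lin <- function(v) if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  rl <- lin(r); gl <- lin(g); bl <- lin(b)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  # white = matrix image of (1,1,1); identical convention to the package
  xn <- 0.4124564 + 0.3575761 + 0.1804375
  yn <- 0.2126729 + 0.7151522 + 0.0721750
  zn <- 0.0193339 + 0.1191920 + 0.9503041
  fx <- f(x / xn); fy <- f(y / yn); fz <- f(z / zn)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

# Inverse HSV -> RGB used only for the round-trip property.
oracle_hsv_to_rgb <- function(h, s, v) {
  col <- grDevices::hsv(h, s, v)
  as.vector(grDevices::col2rgb(col)) / 255
}

# --- connected components oracle -------------------------------------------

# 8-connected components by explicit BFS flood fill.
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start_c in seq_len(w)) for (start_r in seq_len(h)) {
    if (!mask[start_r, start_c] || lab[start_r, start_c] > 0L) next
    cur <- cur + 1L
    queue <- list(c(start_r, start_c))
    lab[start_r, start_c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# --- region morphology oracle ----------------------------------------------

# BFS hole fill: background 4-connected to the border stays background.
oracle_fill <- function(m) {
  h <- nrow(m); w <- ncol(m)
  outside <- matrix(FALSE, h + 2L, w + 2L)
  pm <- matrix(FALSE, h + 2L, w + 2L)
  pm[2:(h + 1), 2:(w + 1)] <- m
  queue <- list(c(1L, 1L))
  outside[1, 1] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- p[1] + d[1]; cc <- p[2] + d[2]
      if (rr < 1 || rr > h + 2 || cc < 1 || cc > w + 2) next
      if (!pm[rr, cc] && !outside[rr, cc]) {
        outside[rr, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  !outside[2:(h + 1), 2:(w + 1)]
}

# Gift-wrapping (Jarvis march) convex hull of integer points (x, y).
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + pts[, 2] / (max(pts[, 2]) + 1))
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == n) 1L else p + 1L
    for (i in seq_len(n)) {
      if (i == q || i == p) next
      cr <- cross(pts[p, ], pts[i, ], pts[q, ])
      if (cr < 0) q <- i
      else if (cr == 0) {
        # collinear: take the farther point
        if (sum((pts[i, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))
          q <- i
      }
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

# Lattice points inside/on the hull, by exact integer half-plane tests;
# the hull orientation is determined from its signed area.
oracle_convex_area <- function(r, c) {
  pts <- unique(cbind(c, r))
  if (nrow(pts) == 1L) return(1L)
  hull <- oracle_hull(pts)
  nh <- nrow(hull)
  sgn <- 0
  if (nh > 2L) {
    area2 <- sum(hull[, 1] * hull[c(2:nh, 1), 2] -
                   hull[c(2:nh, 1), 1] * hull[, 2])
    sgn <- sign(area2)
  }
  total <- 0L
  for (gx in min(pts[, 1]):max(pts[, 1])) {
    for (gy in min(pts[, 2]):max(pts[, 2])) {
      if (nh <= 2L || sgn == 0) {
        a <- hull[1, ]; b <- hull[nh, ]
        cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
        dt <- (gx - a[1]) * (b[1] - a[1]) + (gy - a[2]) * (b[2] - a[2])
        if (cr == 0 && dt >= 0 && dt <= sum((b - a)^2)) total <- total + 1L
        next
      }
      ok <- TRUE
      for (i in seq_len(nh)) {
        a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
        cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
        if (sgn * cr < 0) { ok <- FALSE; break }
      }
      if (ok) total <- total + 1L
    }
  }
  total
}

# All 11 features by direct summation over the pixel list.
oracle_region_features <- function(pixels) {
  r <- pixels[, 1]; c <- pixels[, 2]; n <- length(r)
  top <- min(r); left <- min(c)
  h <- max(r) - top + 1L; w <- max(c) - left + 1L
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n)) m[r[i] - top + 1L, c[i] - left + 1L] <- TRUE
  # boundary pixel count, scalar
  perim <- 0L
  for (i in seq_len(n)) {
    rr <- r[i] - top + 1L; cc <- c[i] - left + 1L
    nb <- c(if (rr > 1) m[rr - 1, cc] else FALSE,
            if (rr < h) m[rr + 1, cc] else FALSE,
            if (cc > 1) m[rr, cc - 1] else FALSE,
            if (cc < w) m[rr, cc + 1] else FALSE)
    if (!all(nb)) perim <- perim + 1L
  }
  filled <- sum(oracle_fill(m))
  convex <- oracle_convex_area(r, c)
  rbar <- sum(r) / n; cbar <- sum(c) / n
  mu20 <- sum((r - rbar)^2) / n + 1 / 12
  mu02 <- sum((c - cbar)^2) / n + 1 / 12
  mu11 <- sum((r - rbar) * (c - cbar)) / n
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  major <- 2 * sqrt(2 * (mu20 + mu02 + common))
  minor <- 2 * sqrt(2 * max(mu20 + mu02 - common, 0))
  c(area = n,
    eccentricity = sqrt(max(1 - (minor / major)^2, 0)),
    extent = n / (h * w),
    perimeter = perim,
    major_axis_length = major,
    minor_axis_length = minor,
    convex_area = convex,
    filled_area = filled,
    equiv_diameter = sqrt(4 * n / pi),
    solidity = n / convex,
    roundness = min(4 * pi * filled / perim^2, 1))
}
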