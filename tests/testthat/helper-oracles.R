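# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: areas via Heron's formula, tiling optima via
# exhaustive path enumeration, containment via ray casting, distances via
# plain O(n^2) scans.

# Numerically stable Heron area (Kahan's ordering of the side lengths).
heron_area <- function(A, B, C) {
  a <- sqrt(sum((B - C) ^ 2))
  b <- sqrt(sum((A - C) ^ 2))
  c <- sqrt(sum((A - B) ^ 2))
  s <- sort(c(a, b, c), decreasing = TRUE)
  a <- s[1L]; b <- s[2L]; c <- s[3L]
  t <- (a + (b + c)) * (c - (a - b)) * (c + (a - b)) * (a + (b - c))
  if (t < 0) t <- 0
  sqrt(t) / 4
}

# Exhaustive minimum tiling cost over every monotone lattice path from the
# given start span: weights recomputed here with plain loops, every
# C(n+m, n) move sequence enumerated via combn.
oracle_min_tiling_cost <- function(lower, upper, i0, j0) {
  n <- nrow(lower$points); m <- nrow(upper$points)
  rl <- ((i0 - 1L) + 0:(n - 1L)) %% n + 1L
  ru <- ((j0 - 1L) + 0:(m - 1L)) %% m + 1L
  L <- cbind(lower$points, lower$z)[rl, , drop = FALSE]
  U <- cbind(upper$points, upper$z)[ru, , drop = FALSE]
  ring <- function(a, k) (a %% k) + 1L
  # Wi[a, b]: a-th lower advance with (b - 1) upper advances already made
  Wi <- matrix(0, n, m + 1L)
  for (a in seq_len(n)) {
    for (b in seq_len(m + 1L)) {
      Wi[a, b] <- heron_area(L[ring(a - 1L, n), ], L[ring(a, n), ],
                             U[ring(b - 1L, m), ])
    }
  }
  Wj <- matrix(0, n + 1L, m)
  for (a in seq_len(n + 1L)) {
    for (b in seq_len(m)) {
      Wj[a, b] <- heron_area(U[ring(b, m), ], U[ring(b - 1L, m), ],
                             L[ring(a - 1L, n), ])
    }
  }
  steps <- n + m
  combos <- utils::combn(steps, n)
  best <- Inf
  for (col in seq_len(ncol(combos))) {
    is_i <- rep(FALSE, steps)
    is_i[combos[, col]] <- TRUE
    ic <- cumsum(is_i)
    jc <- cumsum(!is_i)
    cost <- sum(ifelse(is_i, Wi[cbind(pmax(ic, 1L), jc + 1L)],
                       Wj[cbind(ic + 1L, pmax(jc, 1L))]))
    if (cost < best) best <- cost
  }
  best
}

# Brute-force nearest cross-contour point pair (2D, same slice).
oracle_nearest_pair <- function(c1, c2) {
  best <- NULL
  for (i in seq_len(nrow(c1$points))) {
    for (j in seq_len(nrow(c2$points))) {
      d <- sqrt(sum((c1$points[i, ] - c2$points[j, ]) ^ 2))
      if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
    }
  }
  best
}

# Minimum distance over non-adjacent ring point pairs (index gap > 2,
# wrapping); Inf when no such pair exists.
min_nonadjacent_distance <- function(points) {
  n <- nrow(points)
  best <- Inf
  if (n < 6L) return(best)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      gap <- min(j - i, n - (j - i))
      if (gap <= 2L) next
      d <- sqrt(sum((points[i, ] - points[j, ]) ^ 2))
      if (d < best) best <- d
    }
  }
  best
}

# Ray-casting point-in-polygon (strict interior assumed for test points).
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2L] > p[2L]) != (poly[j, 2L] > p[2L])) {
      xint <- poly[j, 1L] + (p[2L] - poly[j, 2L]) *
        (poly[i, 1L] - poly[j, 1L]) / (poly[i, 2L] - poly[j, 2L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

shoelace_area <- function(points) {
  n <- nrow(points)
  i2 <- c(2:n, 1L)
  abs(sum(points[, 1L] * points[i2, 2L] - points[i2, 1L] * points[, 2L])) / 2
}

# Random simple (star-shaped) ring for property tests.
random_star_contour <- function(n, z, r = 5) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.4 * r, r)
  contour(cbind(rad * cos(th), rad * sin(th)), z)
}

unit_square_contour <- function(z, side = 1, center = c(0, 0)) {
  h <- side / 2
  contour(rbind(center + c(-h, -h), center + c(h, -h),
                center + c(h, h), center + c(-h, h)), z)
}
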