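# Minimal-area triangulation of the band between two consecutive contours.
#
# The two rings define a span graph: a node P(i, j) is the span joining lower
# point i to upper point j; from P(i, j) the only moves are P(i+1, j) and
# P(i, j+1), and each move lays down one elementary triangle (a tile) made of
# one contour segment plus the opposite point. A complete tiling is a
# monotone path from the start span P(0, 0) to P(n, m); the weight of a move
# is the area of its tile, so the minimum-weight path is the minimal-area
# surface band. Both rings are cyclic, making the graph toroidal; it is cut
# open at the closest point pair between the two contours.

#' Area of a 3D triangle
#'
#' Half the magnitude of the cross product of two edge vectors:
#' `|(A - B) x (C - B)| / 2`. Collinear inputs give zero.
#'
#' @param A,B,C numeric vectors of length 3 (or length 2, taken as z = 0).
#' @return area in mm^2.
#' @export
triangle_area <- function(A, B, C) {
  to3 <- function(p) if (length(p) == 2L) c(p, 0) else p
  u <- to3(A) - to3(B)
  v <- to3(C) - to3(B)
  n <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  sqrt(sum(n * n)) / 2
}

# Vectorised tile areas: rows of a, b, c are 3D points.
tri_area_rows <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  ny <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  nz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(nx * nx + ny * ny + nz * nz) / 2
}

#' Normalise a contour for position and size
#'
#' Centres the ring at the origin (the centroid, taken as the vertex mean,
#' moves to (0, 0)) and scales the in-plane coordinates by the width and
#' height of the axis-aligned rectangular window enclosing the contour, so
#' the window becomes the unit square: `x' = (x - cx) / width`,
#' `y' = (y - cy) / height`. The slice coordinate z is untouched, so
#' inter-slice distance still enters tile areas. Normalisation removes
#' in-plane offset and scale differences between consecutive cross-sections
#' before the area cost is evaluated, which is what keeps two identical but
#' laterally offset circles tiling as a skewed cylinder instead of a double
#' cone.
#'
#' @param c a `contour` with a non-degenerate bounding window.
#' @return list with `contour` (normalised) and `params` (class
#'   `normalization_params`: `centroid` and `window`, sufficient to invert
#'   the map).
#' @export
normalize_contour <- function(c) {
  p <- c$points
  centroid <- colMeans(p)
  w <- max(p[, 1L]) - min(p[, 1L])
  h <- max(p[, 2L]) - min(p[, 2L])
  if (w <= 0 || h <= 0) stop("degenerate bounding window (zero width or height)")
  q <- cbind((p[, 1L] - centroid[1L]) / w, (p[, 2L] - centroid[2L]) / h)
  out <- contour(q, c$z)
  if (isTRUE(attr(c, "composite"))) attr(out, "composite") <- TRUE
  list(contour = out,
       params = structure(list(centroid = unname(centroid),
                               window = c(width = w, height = h)),
                          class = "normalization_params"))
}

#' Closest span between two contours
#'
#' Scans all cross-contour point pairs and returns the pair at minimal 3D
#' Euclidean distance; this span is where the toroidal span graph is cut open
#' and the tiling starts. Ties are broken by the lowest (i, j) index pair.
#'
#' @param lower,upper `contour` objects on consecutive slices.
#' @return integer vector `c(i, j)` of 1-based point indices.
#' @export
closest_span <- function(lower, upper) {
  pl <- contour_points3d(lower)
  pu <- contour_points3d(upper)
  dz2 <- (lower$z - upper$z) ^ 2
  d2 <- outer(pl[, 1L], pu[, 1L], "-") ^ 2 +
    outer(pl[, 2L], pu[, 2L], "-") ^ 2 + dz2
  hits <- which(d2 == min(d2), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(i = unname(hits[1L, 1L]), j = unname(hits[1L, 2L]))
}

# ring index helper: 0-based advance count -> 1-based row of the reindexed ring
ring_row <- function(adv, n) (adv %% n) + 1L

# Single DP sweep given reindexed cost-space coordinate matrices (rows 3D).
# Returns total cost, move sequence and the full cost table.
tiling_dp <- function(L, U) {
  n <- nrow(L); m <- nrow(U)
  # W_i[i, j]: weight of the advance-i move taken as i-th of its kind while
  # j upper advances have been made; tile (L[i-1], L[i], U[j]) in 0-based
  # advance terms.
  li <- function(adv) L[ring_row(adv, n), , drop = FALSE]
  uj <- function(adv) U[ring_row(adv, m), , drop = FALSE]
  # grids of advance counts
  gi <- matrix(0:(n - 1L), n, m + 1L)
  gj <- matrix(0:m, n, m + 1L, byrow = TRUE)
  W_i <- matrix(tri_area_rows(li(as.vector(gi)), li(as.vector(gi) + 1L),
                              uj(as.vector(gj))), n, m + 1L)
  gi2 <- matrix(0:n, n + 1L, m)
  gj2 <- matrix(0:(m - 1L), n + 1L, m, byrow = TRUE)
  W_j <- matrix(tri_area_rows(uj(as.vector(gj2) + 1L), uj(as.vector(gj2)),
                              li(as.vector(gi2))), n + 1L, m)
  cost <- matrix(Inf, n + 1L, m + 1L)
  from <- matrix(0L, n + 1L, m + 1L)  # 1 = advance i, 2 = advance j
  cost[1L, 1L] <- 0
  for (j in 1:(m + 1L)) {
    for (i in 1:(n + 1L)) {
      if (i == 1L && j == 1L) next
      ci <- if (i > 1L) cost[i - 1L, j] + W_i[i - 1L, j] else Inf
      cj <- if (j > 1L) cost[i, j - 1L] + W_j[i, j - 1L] else Inf
      if (ci <= cj) {           # tie prefers the lower-contour advance
        cost[i, j] <- ci; from[i, j] <- 1L
      } else {
        cost[i, j] <- cj; from[i, j] <- 2L
      }
    }
  }
  # backtrack
  moves <- character(n + m)
  i <- n + 1L; j <- m + 1L
  for (k in (n + m):1) {
    if (from[i, j] == 1L) {
      moves[k] <- "i"; i <- i - 1L
    } else {
      moves[k] <- "j"; j <- j - 1L
    }
  }
  list(total = cost[n + 1L, m + 1L], moves = moves, cost = cost)
}

#' Tile the surface band between two consecutive contours
#'
#' Cuts the toroidal span graph at the closest point pair between the two
#' rings (computed in the same coordinates as the cost), then finds the
#' minimum-total-area monotone path from P(0, 0) to P(n, m) by dynamic
#' programming: `cost[i, j] = min(cost[i-1, j] + W_lower, cost[i, j-1] +
#' W_upper)`, where each W is the area of the elementary triangle the move
#' lays down. When two paths meet at a node only the cheaper survives. With
#' `normalize = TRUE` (the default) the areas are evaluated on
#' position/size-normalised copies of the contours while the emitted tiles
#' carry the original coordinates, so normalisation acts purely as a cost
#' metric. Ties prefer the lower-contour advance.
#'
#' @param lower,upper `contour` objects (>= 3 points each) on consecutive
#'   slices, keyhole-free, branching already resolved.
#' @param normalize logical; evaluate tile areas on normalised contours.
#' @param start `"closest"` (single sweep from the closest span, the default)
#'   or `"exhaustive"` (re-run the sweep from every upper-ring offset and
#'   keep the globally cheapest, approximating the true toroidal cycle
#'   optimum).
#' @param keep_costs logical; retain the DP cost table in the result.
#' @return object of class `tiling_path`: `tiles` (list of `tile` objects
#'   with 3x3 `vertices` in outward winding, `provenance` `"lower"`/
#'   `"upper"`, `area` in original mm^2), `moves`, `spans` (the (n+m+1) x 2
#'   matrix of original 1-based index pairs along the path), `total_cost`
#'   (optimum in cost space), `area` (sum of original-space tile areas),
#'   `start` (original index pair of the start span), `n`, `m`.
#' @export
tile_pair <- function(lower, upper, normalize = TRUE,
                      start = c("closest", "exhaustive"),
                      keep_costs = FALSE) {
  start <- match.arg(start)
  n <- contour_size(lower); m <- contour_size(upper)
  if (n < 3L || m < 3L) stop("both contours need at least 3 points")
  cost_lower <- if (normalize) normalize_contour(lower)$contour else lower
  cost_upper <- if (normalize) normalize_contour(upper)$contour else upper
  s <- closest_span(cost_lower, cost_upper)
  run_one <- function(i0, j0) {
    rl <- ((i0 - 1L) + 0:(n - 1L)) %% n + 1L
    ru <- ((j0 - 1L) + 0:(m - 1L)) %% m + 1L
    L <- contour_points3d(cost_lower)[rl, , drop = FALSE]
    U <- contour_points3d(cost_upper)[ru, , drop = FALSE]
    dp <- tiling_dp(L, U)
    list(dp = dp, i0 = i0, j0 = j0, rl = rl, ru = ru)
  }
  best <- run_one(s[1L], s[2L])
  if (start == "exhaustive") {
    for (j0 in seq_len(m)) {
      if (j0 == s[2L]) next
      cand <- run_one(s[1L], j0)
      if (cand$dp$total < best$dp$total) best <- cand
    }
  }
  # realise tiles in original coordinates, following the optimal move order
  Lo <- contour_points3d(lower)[best$rl, , drop = FALSE]
  Uo <- contour_points3d(upper)[best$ru, , drop = FALSE]
  moves <- best$dp$moves
  tiles <- vector("list", n + m)
  spans <- matrix(0L, n + m + 1L, 2L)
  i <- 0L; j <- 0L
  spans[1L, ] <- c(best$rl[1L], best$ru[1L])
  for (k in seq_along(moves)) {
    if (moves[k] == "i") {
      v <- rbind(Lo[ring_row(i, n), ], Lo[ring_row(i + 1L, n), ],
                 Uo[ring_row(j, m), ])
      prov <- "lower"
      i <- i + 1L
    } else {
      v <- rbind(Uo[ring_row(j + 1L, m), ], Uo[ring_row(j, m), ],
                 Lo[ring_row(i, n), ])
      prov <- "upper"
      j <- j + 1L
    }
    tiles[[k]] <- structure(
      list(vertices = v, provenance = prov,
           area = triangle_area(v[1L, ], v[2L, ], v[3L, ])),
      class = "tile")
    spans[k + 1L, ] <- c(best$rl[ring_row(i, n)], best$ru[ring_row(j, m)])
  }
  structure(
    list(tiles = tiles, moves = moves, spans = spans,
         total_cost = best$dp$total,
         area = sum(vapply(tiles, function(t) t$area, double(1))),
         start = c(i = best$rl[1L], j = best$ru[1L]),
         n = n, m = m, normalized = normalize,
         costs = if (keep_costs) best$dp$cost else NULL),
    class = "tiling_path")
}

#' @export
print.tiling_path <- function(x, ...) {
  cat(sprintf(
    "<tiling_path: n = %d, m = %d, %d tiles, area %.6g mm^2 (cost %.6g%s)>\n",
    x$n, x$m, length(x$tiles), x$area, x$total_cost,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}
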