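# Cap triangulation: the tiled bands leave the first and last contours open;
# each is closed with a planar triangulation of the polygon interior using
# only the contour's own vertices. A plain Delaunay triangulation of the
# vertex set would place triangles outside a concave polygon, so the caps
# are built by ear clipping, which respects the ring edges by construction
# and yields exactly n - 2 interior triangles.

# Twice the signed area of 2D triangle (a, b, c); > 0 iff CCW.
cross2 <- function(a, b, c) {
  (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
}

# Closed point-in-triangle test (2D) for a CCW triangle: points on an edge
# count as inside, so a reflex vertex touching a candidate ear's closing
# edge blocks the ear.
point_in_tri <- function(p, a, b, c, eps) {
  d1 <- cross2(a, b, p); d2 <- cross2(b, c, p); d3 <- cross2(c, a, p)
  d1 >= -eps & d2 >= -eps & d3 >= -eps
}

# Any non-adjacent pair of ring edges properly crossing?
ring_self_intersects <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n - 1L && i == 1L) next
      if (segments_cross(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Ear-clipping triangulation of a simple CCW polygon. Returns an (n-2) x 3
# matrix of 1-based vertex indices, each triangle CCW in the plane.
ear_clip <- function(pts) {
  n <- nrow(pts)
  scale2 <- max(apply(pts, 2L, function(v) diff(range(v)))) ^ 2
  eps <- 1e-12 * scale2
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2L, 3L)
  k <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    nn <- length(idx)
    clipped <- FALSE
    for (v in seq_len(nn)) {
      u <- idx[if (v == 1L) nn else v - 1L]
      w <- idx[if (v == nn) 1L else v + 1L]
      a <- pts[u, ]; b <- pts[idx[v], ]; cc <- pts[w, ]
      conv <- cross2(a, b, cc)
      if (conv < -eps) next                    # reflex corner, not an ear
      others <- setdiff(idx, c(u, idx[v], w))
      blocked <- FALSE
      for (o in others) {
        if (point_in_tri(pts[o, ], a, b, cc, eps)) { blocked <- TRUE; break }
      }
      if (blocked) next
      k <- k + 1L
      tris[k, ] <- c(u, idx[v], w)
      idx <- idx[-v]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear clipping failed: polygon may be non-simple")
      eps <- eps * 1e3                         # retry with a looser tolerance
    }
  }
  tris[k + 1L, ] <- idx
  tris
}

#' Seal a boundary contour with a planar cap triangulation
#'
#' Triangulates the polygon interior using only the contour's own vertices
#' (no points are introduced), by ear clipping; this honours the ring edges
#' on concave cross-sections, where an unconstrained Delaunay triangulation
#' of the vertex set would spill outside the polygon. Triangle winding is
#' chosen so the cap normal points away from the model interior: `"down"`
#' (-z) for the bottom cap, `"up"` (+z) for the top cap, assuming
#' counter-clockwise contours and increasing z.
#'
#' @param c a simple, keyhole-free, counter-clockwise `contour`.
#' @param orientation `"up"` or `"down"`.
#' @return object of class `cap_triangulation`: `triangles` ((n-2) x 3
#'   matrix of 1-based indices into the contour's points), `orientation`,
#'   `contour`.
#' @export
seal_cap <- function(c, orientation = c("up", "down")) {
  orientation <- match.arg(orientation)
  if (contour_size(c) < 3L) stop("cannot cap a contour with fewer than 3 points")
  if (contour_winding(c) != "ccw") stop("cap contour must wind counter-clockwise")
  if (ring_self_intersects(c$points)) stop("cannot cap a self-intersecting contour")
  tris <- ear_clip(c$points)
  if (orientation == "down") tris <- tris[, c(1L, 3L, 2L), drop = FALSE]
  structure(list(triangles = tris, orientation = orientation, contour = c),
            class = "cap_triangulation")
}

#' Total area of a cap triangulation
#' @param cap a `cap_triangulation`.
#' @return summed triangle area in mm^2 (equals the polygon's shoelace area).
#' @export
cap_area <- function(cap) {
  p3 <- contour_points3d(cap$contour)
  sum(apply(cap$triangles, 1L, function(t) {
    triangle_area(p3[t[1L], ], p3[t[2L], ], p3[t[3L], ])
  }))
}
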