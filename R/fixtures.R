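# Deterministic synthetic contour stacks emulating segmented long-bone
# cross-sections. Every pipeline stage is testable against these with no
# imaging data: circular shafts (cylinder/cone), the laterally drifting
# shaft (skewed_cylinder), a condyle-like bifurcation (y_branch), a
# narrow-channel cross-section (keyhole_c) and random convex rings.

circle_ring <- function(n, r, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1L)) / n   # angle 0 at index 1: stable correspondences
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# C-shaped cross-section: an outer square with a narrow slot cut from the top
# edge; the slot walls are `channel_width` apart, far closer than any other
# non-adjacent pair, forming the keyhole channel.
keyhole_c_ring <- function(side, channel_width) {
  s <- side
  cx <- s / 2
  w <- channel_width / 2
  d <- 0.75 * s               # slot depth
  rbind(
    c(0, 0), c(s / 3, 0), c(2 * s / 3, 0), c(s, 0),      # bottom edge
    c(s, s / 3), c(s, 2 * s / 3), c(s, s),               # right edge
    c((s + cx + w) / 2, s),                              # top edge, right part
    c(cx + w, s), c(cx + w, s - d / 3), c(cx + w, s - 2 * d / 3),
    c(cx + w, s - d),                                    # right slot wall
    c(cx - w, s - d), c(cx - w, s - 2 * d / 3),
    c(cx - w, s - d / 3), c(cx - w, s),                  # left slot wall
    c((cx - w) / 2, s),                                  # top edge, left part
    c(0, s), c(0, 2 * s / 3), c(0, s / 3)                # left edge
  )
}

# Random convex n-gon: n random displacement vectors, re-centred to sum to
# zero, sorted by angle and accumulated — a closed convex CCW polygon.
random_convex_ring <- function(n, r) {
  repeat {
    v <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1))
    v <- sweep(v, 2L, colMeans(v))
    ang <- atan2(v[, 2L], v[, 1L])
    v <- v[order(ang), , drop = FALSE]
    p <- apply(v, 2L, cumsum)
    p <- sweep(p, 2L, colMeans(p))
    scale <- max(sqrt(rowSums(p ^ 2)))
    if (scale > 0) {
      p <- p * (r / scale)
      nxt <- c(2:n, 1L)
      if (!any(p[, 1L] == p[nxt, 1L] & p[, 2L] == p[nxt, 2L])) return(p)
    }
  }
}

#' Generate a synthetic contour stack
#'
#' Deterministic fixture generator: the same arguments (including `seed`)
#' always produce a bitwise-identical stack. Kinds:
#' \describe{
#'   \item{`cylinder`}{`n_slices` identical circles of `radius`.}
#'   \item{`skewed_cylinder`}{identical circles whose centres drift by
#'     `offset` mm in x per slice (with `offset = 2 * radius`, consecutive
#'     cross-sections are one diameter apart — the classic stress case for
#'     area-minimising tiling without normalisation).}
#'   \item{`cone`}{circles shrinking linearly from `radius` to
#'     `0.35 * radius`.}
#'   \item{`y_branch`}{single circle on the lower half of the stack, two
#'     disjoint half-size circles on the upper half — a simple bifurcation.}
#'   \item{`keyhole_c`}{a square cross-section of side `2 * radius / 5` mm
#'     with a slot of width `channel_width` cut into it; the slot walls
#'     conflict at any keyhole threshold above `channel_width` (0.5 mm is
#'     the documented test threshold for the default 0.2 mm channel).}
#'   \item{`random_convex`}{independent random convex `n_points`-gons of
#'     circumradius `radius` on each slice, driven by `seed`.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param n_points points per contour (circle-based kinds; `keyhole_c` has a
#'   fixed 20-point ring).
#' @param n_slices number of slices (>= 2).
#' @param spacing slice spacing in mm (CT-like spacings are 1-5 mm).
#' @param radius characteristic in-plane size in mm.
#' @param offset per-slice lateral drift in mm (`skewed_cylinder` only);
#'   default `2 * radius`.
#' @param channel_width keyhole channel width in mm (`keyhole_c` only).
#' @param seed integer seed (`random_convex` only).
#' @return a validated `contour_stack`.
#' @export
make_fixture <- function(kind = c("cylinder", "skewed_cylinder", "cone",
                                  "y_branch", "keyhole_c", "random_convex"),
                         n_points = 32L, n_slices = 5L, spacing = 2,
                         radius = 10, offset = NULL, channel_width = 0.2,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (n_slices < 2L) stop("need at least 2 slices")
  if (n_points < 3L) stop("need at least 3 points per contour")
  if (spacing <= 0 || radius <= 0) stop("spacing and radius must be positive")
  if (is.null(offset)) offset <- 2 * radius
  zs <- spacing * (0:(n_slices - 1L))
  slices <- switch(kind,
    cylinder = lapply(zs, function(z) {
      new_slice(z, contour(circle_ring(n_points, radius), z))
    }),
    skewed_cylinder = lapply(seq_along(zs), function(s) {
      z <- zs[s]
      new_slice(z, contour(
        circle_ring(n_points, radius, center = c(offset * (s - 1L), 0)), z))
    }),
    cone = lapply(seq_along(zs), function(s) {
      z <- zs[s]
      r <- radius + (0.35 * radius - radius) * (s - 1L) / (n_slices - 1L)
      new_slice(z, contour(circle_ring(n_points, r), z))
    }),
    y_branch = {
      lower_k <- ceiling(n_slices / 2)
      lapply(seq_along(zs), function(s) {
        z <- zs[s]
        if (s <= lower_k) {
          new_slice(z, contour(circle_ring(n_points, radius), z))
        } else {
          r2 <- 0.45 * radius
          new_slice(z, list(
            contour(circle_ring(n_points, r2, center = c(-0.6 * radius, 0)), z),
            contour(circle_ring(n_points, r2, center = c(0.6 * radius, 0)), z)))
        }
      })
    },
    keyhole_c = {
      if (channel_width <= 0) stop("channel_width must be positive")
      ring <- keyhole_c_ring(side = 2 * radius / 5, channel_width = channel_width)
      lapply(zs, function(z) new_slice(z, contour(ring, z)))
    },
    random_convex = {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      lapply(zs, function(z) {
        new_slice(z, contour(random_convex_ring(n_points, radius), z))
      })
    }
  )
  stack <- contour_stack(slices)
  v <- validate_stack(stack)
  if (length(v)) stop("fixture generation bug: ", paste(v, collapse = "; "))
  stack
}
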