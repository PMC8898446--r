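#' Construct a closed planar contour
#'
#' A contour is an ordered, implicitly closed ring of points lying in a plane
#' of constant `z`. The last point connects back to the first; the first point
#' is *not* repeated at the end, so a ring of `n` points has exactly `n`
#' segments. Coordinates are in millimetres.
#'
#' @param points numeric matrix (or coercible) with two columns, the in-plane
#'   x and y coordinates of the ring vertices in order.
#' @param z scalar slice coordinate (mm).
#' @return An object of class `contour` with elements `points` (n x 2 double
#'   matrix) and `z`.
#' @examples
#' sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), z = 0)
#' contour_winding(sq)
#' @export
contour <- function(points, z) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) {
    stop("contour points must have exactly two columns (x, y)")
  }
  dimnames(points) <- NULL
  structure(list(points = points, z = as.double(z)[1L]), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d points at z = %g%s>\n", nrow(x$points), x$z,
              if (isTRUE(attr(x, "composite"))) ", composite" else ""))
  invisible(x)
}

#' Number of points (= number of segments) of a contour
#' @param c a `contour`.
#' @return integer count.
#' @export
contour_size <- function(c) nrow(c$points)

#' Contour vertices as 3D coordinates
#' @param c a `contour`.
#' @return n x 3 matrix of (x, y, z) rows.
#' @export
contour_points3d <- function(c) {
  cbind(c$points, rep(c$z, nrow(c$points)))
}

#' Signed (shoelace) area of a contour's ring
#'
#' Positive for counter-clockwise winding viewed from +z.
#' @param c a `contour`.
#' @return signed area in mm^2.
#' @export
contour_signed_area <- function(c) {
  p <- c$points
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]) / 2
}

#' Winding direction of a contour
#'
#' @param c a `contour` with at least 3 points.
#' @return `"ccw"` or `"cw"` according to the sign of the shoelace area.
#'   A degenerate (zero-area) ring is an error.
#' @export
contour_winding <- function(c) {
  if (contour_size(c) < 3L) stop("contour has fewer than 3 points")
  a <- contour_signed_area(c)
  if (a == 0) stop("degenerate contour: zero signed area")
  if (a > 0) "ccw" else "cw"
}

#' Reverse the point order of a contour
#' @param c a `contour`.
#' @return the contour with opposite winding.
#' @export
reverse_contour <- function(c) {
  c$points <- c$points[rev(seq_len(nrow(c$points))), , drop = FALSE]
  c
}

# Normalise winding to CCW; errors on degenerate rings.
ensure_ccw <- function(c) {
  if (contour_winding(c) == "cw") reverse_contour(c) else c
}

#' Construct a slice
#'
#' A slice groups the contours that share one constant-z cutting plane.
#'
#' @param z scalar slice coordinate (mm).
#' @param contours list of `contour` objects, all at this z.
#' @return object of class `slice`.
#' @export
new_slice <- function(z, contours) {
  if (inherits(contours, "contour")) contours <- list(contours)
  structure(list(z = as.double(z)[1L], contours = contours), class = "slice")
}

#' Construct an ordered contour stack
#'
#' @param slices list of `slice` objects with strictly increasing z.
#' @return object of class `contour_stack`.
#' @seealso [validate_stack()] for the full invariant check.
#' @export
contour_stack <- function(slices) {
  structure(list(slices = slices), class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  k <- length(x$slices)
  nc <- vapply(x$slices, function(s) length(s$contours), integer(1))
  cat(sprintf("<contour_stack: %d slices, %d contours, z in [%g, %g]>\n",
              k, sum(nc),
              if (k) x$slices[[1L]]$z else NA, if (k) x$slices[[k]]$z else NA))
  invisible(x)
}

# Do segments (p1,p2) and (p3,p4) properly intersect (2D)?
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    sign(v)
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

# Any edge of contour a properly crossing an edge of contour b?
contours_intersect <- function(a, b) {
  pa <- a$points; pb <- b$points
  na <- nrow(pa); nb <- nrow(pb)
  # bounding-box reject
  if (max(pa[, 1L]) < min(pb[, 1L]) || max(pb[, 1L]) < min(pa[, 1L]) ||
      max(pa[, 2L]) < min(pb[, 2L]) || max(pb[, 2L]) < min(pa[, 2L])) {
    return(FALSE)
  }
  ia2 <- c(2:na, 1L); ib2 <- c(2:nb, 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_cross(pa[i, ], pa[ia2[i], ], pb[j, ], pb[ib2[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Validate a contour stack against the model invariants
#'
#' Checks, without ever raising on bad geometry: at least two slices; slice z
#' strictly increasing; every contour has >= 3 points, finite coordinates, a z
#' matching its slice, no two identical consecutive points, non-zero signed
#' area and counter-clockwise winding; contours within a slice pairwise
#' non-crossing. Composite contours produced by branching resolution (which
#' intentionally carry coincident bridge vertices) are exempt from the
#' pairwise-crossing check.
#'
#' @param stack a `contour_stack`.
#' @return character vector of violation messages; empty when the stack is
#'   valid. Messages carry 1-based slice and contour indices.
#' @export
validate_stack <- function(stack) {
  out <- character(0)
  if (!inherits(stack, "contour_stack")) {
    return("not a contour_stack object")
  }
  k <- length(stack$slices)
  if (k < 2L) out <- c(out, "fewer than 2 slices: no tiling is defined")
  zs <- vapply(stack$slices, function(s) s$z, double(1))
  if (k >= 2L && any(diff(zs) <= 0)) {
    bad <- which(diff(zs) <= 0)
    out <- c(out, sprintf("non-increasing z between slices %d and %d", bad, bad + 1L))
  }
  for (si in seq_len(k)) {
    sl <- stack$slices[[si]]
    for (ci in seq_along(sl$contours)) {
      cc <- sl$contours[[ci]]
      tag <- sprintf("slice %d contour %d", si, ci)
      p <- cc$points
      if (!all(is.finite(p)) || !is.finite(cc$z)) {
        out <- c(out, paste(tag, "has non-finite coordinates"))
        next
      }
      if (nrow(p) < 3L) {
        out <- c(out, paste(tag, "has fewer than 3 points"))
        next
      }
      if (!identical(cc$z, sl$z)) {
        out <- c(out, paste(tag, "z differs from slice z"))
      }
      nxt <- c(2:nrow(p), 1L)
      dup <- which(p[, 1L] == p[nxt, 1L] & p[, 2L] == p[nxt, 2L])
      if (length(dup)) {
        out <- c(out, paste(tag, "has identical consecutive points"))
      }
      a <- contour_signed_area(cc)
      if (a == 0) {
        out <- c(out, paste(tag, "is degenerate (zero signed area)"))
      } else if (a < 0) {
        out <- c(out, paste(tag, "winds clockwise (expect counter-clockwise)"))
      }
    }
    nc <- length(sl$contours)
    if (nc >= 2L) {
      for (i in seq_len(nc - 1L)) {
        for (j in (i + 1L):nc) {
          if (isTRUE(attr(sl$contours[[i]], "composite")) ||
              isTRUE(attr(sl$contours[[j]], "composite"))) next
          if (contours_intersect(sl$contours[[i]], sl$contours[[j]])) {
            out <- c(out, sprintf("slice %d contours %d and %d intersect", si, i, j))
          }
        }
      }
    }
  }
  out
}

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly through text
  s <- sprintf("%.17g", x)
  s[!is.finite(x)] <- "null"
  s
}

#' Write a contour stack to the canonical JSON file format
#'
#' The on-disk form is
#' `{"slices": [{"z": <num>, "contours": [[[x, y], ...], ...]}, ...]}` with
#' coordinates in mm, rings implicitly closed and the first point not
#' repeated. Numbers are written with 17 significant digits so that
#' write-then-read reproduces every coordinate bit-exactly.
#'
#' @param stack a `contour_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  slice_json <- vapply(stack$slices, function(sl) {
    ctr_json <- vapply(sl$contours, function(cc) {
      pts <- apply(cc$points, 1L, function(p) {
        paste0("[", fmt_num(p[1L]), ",", fmt_num(p[2L]), "]")
      })
      paste0("[", paste(pts, collapse = ","), "]")
    }, character(1))
    paste0('{"z":', fmt_num(sl$z),
           ',"contours":[', paste(ctr_json, collapse = ","), "]}")
  }, character(1))
  txt <- paste0('{"slices":[', paste(slice_json, collapse = ","), "]}")
  writeLines(txt, path)
  invisible(path)
}

#' Read a contour stack from the canonical JSON file format
#'
#' Winding is normalised to counter-clockwise on load (point order reversed
#' where needed) so downstream face orientations are consistent. The loaded
#' stack is validated; any invariant violation is an error.
#'
#' @param path path to a JSON contour-stack file (see [write_stack()]).
#' @return a validated `contour_stack`.
#' @export
read_stack <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$slices) || !is.list(doc$slices)) {
    stop("contour-stack file missing \"slices\" array")
  }
  slices <- lapply(seq_along(doc$slices), function(si) {
    sl <- doc$slices[[si]]
    if (is.null(sl$z) || !is.numeric(sl$z)) {
      stop(sprintf("slice %d missing numeric \"z\"", si))
    }
    if (is.null(sl$contours) || !is.list(sl$contours)) {
      stop(sprintf("slice %d missing \"contours\" array", si))
    }
    contours <- lapply(seq_along(sl$contours), function(ci) {
      ring <- sl$contours[[ci]]
      ok <- vapply(ring, function(p) is.numeric(unlist(p)) &&
                     length(unlist(p)) == 2L, logical(1))
      if (length(ring) == 0L || !all(ok)) {
        stop(sprintf("slice %d contour %d: points must be [x, y] pairs", si, ci))
      }
      pts <- do.call(rbind, lapply(ring, function(p) as.double(unlist(p))))
      ensure_ccw(contour(pts, sl$z))
    })
    new_slice(sl$z, contours)
  })
  stack <- contour_stack(slices)
  v <- validate_stack(stack)
  if (length(v)) {
    stop("invalid contour stack: ", paste(v, collapse = "; "))
  }
  stack
}
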