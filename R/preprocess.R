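# Branching resolution and keyhole removal: the two preprocessing stages run
# before any slice pair is tiled.

# Nearest cross-contour point pair; ties broken by lowest (i, j) index pair.
nearest_point_pair <- function(c1, c2) {
  p1 <- c1$points; p2 <- c2$points
  dx <- outer(p1[, 1L], p2[, 1L], "-")
  dy <- outer(p1[, 2L], p2[, 2L], "-")
  d2 <- dx * dx + dy * dy
  hits <- which(d2 == min(d2), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(i = unname(hits[1L, 1L]), j = unname(hits[1L, 2L]),
       dist = sqrt(min(d2)))
}

# Bridge two disjoint co-planar contours into one composite ring through
# their nearest point pair (p on c1, q on c2): c1[1..p], all of c2 starting
# and ending at q, then c1[p..n1]. p and q each appear twice; the two bridge
# edges are geometrically coincident, traversed in opposite directions.
bridge_two_contours <- function(c1, c2) {
  if (c1$z != c2$z) stop("contours to merge must lie on the same slice")
  if (contours_intersect(c1, c2)) stop("cannot merge overlapping contours")
  np <- nearest_point_pair(c1, c2)
  p <- np$i; q <- np$j
  n1 <- nrow(c1$points); n2 <- nrow(c2$points)
  ring2 <- if (q == 1L) seq_len(n2) else c(q:n2, 1:(q - 1L))
  pts <- rbind(c1$points[1:p, , drop = FALSE],
               c2$points[ring2, , drop = FALSE],
               c2$points[q, , drop = FALSE],
               c1$points[p:n1, , drop = FALSE])
  out <- contour(pts, c1$z)
  attr(out, "composite") <- TRUE
  attr(out, "bridge") <- c(p, q)
  out
}

#' Merge co-planar contours into one composite ring
#'
#' Resolves a branching instance by joining contours on the many-contour side
#' of a slice pair: the two globally nearest points between two contours are
#' connected by a pair of coincident bridge edges, producing a single closed
#' ring that visits every input point (the two bridge endpoints twice). With
#' more than two contours, the closest pair of contours (by minimum
#' cross-contour point distance) is merged first, repeatedly, until one ring
#' remains. All ties are broken by lowest index.
#'
#' @param contours list of `contour` objects on one slice, pairwise disjoint,
#'   consistent (counter-clockwise) winding. A single contour is returned
#'   unchanged.
#' @return a single `contour`; composite results carry attributes
#'   `composite = TRUE` and `bridge` (the index pair joined last).
#' @export
merge_branch_contours <- function(contours) {
  if (inherits(contours, "contour")) return(contours)
  if (length(contours) == 0L) stop("no contours to merge")
  if (length(contours) == 1L) return(contours[[1L]])
  work <- contours
  while (length(work) > 1L) {
    nc <- length(work)
    best <- NULL
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        d <- nearest_point_pair(work[[i]], work[[j]])$dist
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    merged <- bridge_two_contours(work[[best$i]], work[[best$j]])
    work <- c(list(merged), work[-c(best$i, best$j)])
  }
  work[[1L]]
}

#' Plan branching resolution for one slice pair
#'
#' A branching instance exists when the same structure is cut into `m`
#' contours on one slice and `n` on the adjacent slice with `m != n` (both
#' > 0). The plan merges contours on the side with more contours, closest
#' pair first, until the counts match; equal counts produce an empty plan.
#'
#' @param lower,upper `slice` objects.
#' @return object of class `branch_plan` with elements `side` (`"lower"`,
#'   `"upper"` or `"none"`) and `merges`, a list of merge steps, each holding
#'   the 1-based `indices` of the two contours merged (positions in the
#'   working list at that step) and the `bridge` point-index pair.
#' @export
plan_branching <- function(lower, upper) {
  m <- length(lower$contours); n <- length(upper$contours)
  if (m == 0L || n == 0L) stop("branching requires at least one contour per slice")
  plan <- structure(list(side = "none", merges = list()), class = "branch_plan")
  if (m == n) return(plan)
  side <- if (m > n) "lower" else "upper"
  work <- if (side == "lower") lower$contours else upper$contours
  target <- min(m, n)
  merges <- list()
  while (length(work) > target) {
    nc <- length(work)
    best <- NULL
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        d <- nearest_point_pair(work[[i]], work[[j]])$dist
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    merged <- bridge_two_contours(work[[best$i]], work[[best$j]])
    merges[[length(merges) + 1L]] <-
      list(indices = c(best$i, best$j), bridge = attr(merged, "bridge"))
    work <- c(list(merged), work[-c(best$i, best$j)])
  }
  plan$side <- side
  plan$merges <- merges
  attr(plan, "merged_contours") <- work
  plan
}

#' Default keyhole threshold for a contour
#'
#' 1.5 times the median segment length of the ring: short enough that the
#' regular spacing of a well-sampled contour never conflicts, long enough to
#' catch channels narrower than the local sampling density.
#'
#' @param c a `contour`.
#' @return threshold distance in mm.
#' @export
default_keyhole_threshold <- function(c) {
  p <- c$points
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  1.5 * stats::median(sqrt(rowSums((p[nxt, , drop = FALSE] - p) ^ 2)))
}

# Conflicting pairs: ring-index distance > 2 (wrapping) and Euclidean
# distance < threshold. Returns a 2-column matrix of 1-based index pairs
# (i < j), lexicographically ordered.
keyhole_conflicts <- function(points, threshold) {
  n <- nrow(points)
  if (n < 6L || threshold <= 0) return(matrix(integer(0), ncol = 2L))
  d2 <- as.matrix(stats::dist(points)) ^ 2
  idx <- which(upper.tri(d2), arr.ind = TRUE)
  gap <- pmin(abs(idx[, 1L] - idx[, 2L]), n - abs(idx[, 1L] - idx[, 2L]))
  keep <- gap > 2L & d2[idx] < threshold ^ 2
  hits <- idx[keep, , drop = FALSE]
  hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
}

#' Remove keyholes from a contour
#'
#' A keyhole is a narrow channel where non-adjacent points of the same ring
#' come within a threshold distance of each other; such channels destabilise
#' area-minimising tiling, which may connect into the channel. Every point is
#' compared with every other point of the same contour; a pair closer than
#' `threshold` whose ring-index distance exceeds 2 (wrapping) is a conflict.
#' Conflicts are resolved by deleting the points on the shorter arc strictly
#' between the conflicting pair and joining the pair with a direct edge; the
#' scan repeats until no conflict remains, which makes the operation
#' idempotent.
#'
#' @param c a `contour`.
#' @param threshold conflict distance in mm (>= 0); defaults to
#'   [default_keyhole_threshold()].
#' @return list with `contour` (the rebuilt ring) and `report`, a
#'   `keyhole_report` holding `conflicts` (matrix of original point-index
#'   pairs detected, in resolution order) and `removed` (original indices of
#'   deleted points).
#' @export
remove_keyholes <- function(c, threshold = default_keyhole_threshold(c)) {
  if (threshold < 0) stop("threshold must be >= 0")
  pts <- c$points
  orig <- seq_len(nrow(pts))
  conflicts <- matrix(integer(0), ncol = 2L)
  repeat {
    hits <- keyhole_conflicts(pts, threshold)
    if (nrow(hits) == 0L) break
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    conflicts <- rbind(conflicts, c(orig[i], orig[j]))
    n <- nrow(pts)
    inner <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
    outer_arc <- c(if (j < n) (j + 1L):n else integer(0),
                   if (i > 1L) 1:(i - 1L) else integer(0))
    drop_idx <- if (length(inner) <= length(outer_arc)) inner else outer_arc
    if (n - length(drop_idx) < 3L) {
      stop("keyhole removal would leave fewer than 3 points; threshold too large")
    }
    pts <- pts[-drop_idx, , drop = FALSE]
    orig <- orig[-drop_idx]
  }
  out <- contour(pts, c$z)
  report <- structure(
    list(conflicts = conflicts,
         removed = setdiff(seq_len(nrow(c$points)), orig),
         threshold = threshold),
    class = "keyhole_report")
  list(contour = out, report = report)
}

# Greedy centroid matching of contours across an equal-count slice pair;
# returns for each lower contour the index of its partner on the upper slice.
match_contours <- function(lower_contours, upper_contours) {
  nl <- length(lower_contours)
  if (nl != length(upper_contours)) stop("contour counts differ")
  if (nl == 1L) return(1L)
  cl <- t(vapply(lower_contours, function(c) colMeans(c$points), double(2)))
  cu <- t(vapply(upper_contours, function(c) colMeans(c$points), double(2)))
  d <- outer(seq_len(nl), seq_len(nl), Vectorize(function(i, j) {
    sqrt(sum((cl[i, ] - cu[j, ]) ^ 2))
  }))
  match <- integer(nl)
  free_l <- seq_len(nl); free_u <- seq_len(nl)
  while (length(free_l)) {
    sub <- d[free_l, free_u, drop = FALSE]
    hit <- which(sub == min(sub), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    li <- free_l[hit[1L, 1L]]; ui <- free_u[hit[1L, 2L]]
    match[li] <- ui
    free_l <- setdiff(free_l, li); free_u <- setdiff(free_u, ui)
  }
  match
}
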