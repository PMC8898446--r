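#' Reconstruct a watertight surface mesh from a contour stack
#'
#' Runs the full interpolation pipeline on an ordered stack of parallel
#' closed contours:
#' \enumerate{
#'   \item validation of the stack invariants;
#'   \item keyhole removal on every input contour (narrow channels whose
#'     walls are closer than the threshold are cut out);
#'   \item per consecutive slice pair, branching resolution — when the two
#'     slices carry different contour counts, contours on the richer side
#'     are bridged at their nearest points into composite rings until the
#'     counts match — followed by proximity matching of contours across the
#'     pair;
#'   \item minimal-area tiling of each matched contour pair ([tile_pair()]),
#'     with tile areas evaluated on position/size-normalised contours when
#'     `normalize = TRUE`;
#'   \item sealing of the first and last slices with planar caps
#'     ([seal_cap()]), when `seal = TRUE`.
#' }
#'
#' @param stack a `contour_stack` (see [contour_stack()], [read_stack()],
#'   [make_fixture()]).
#' @param normalize logical; evaluate tiling costs on normalised contours.
#' @param seal logical; close the boundary slices with caps.
#' @param keyhole_threshold conflict distance in mm for keyhole removal; a
#'   single number, or `NULL` (default) for the per-contour adaptive
#'   threshold of [default_keyhole_threshold()]. Use 0 to disable removal.
#' @param start tiling start-span strategy, `"closest"` or `"exhaustive"`
#'   (see [tile_pair()]).
#' @return a `surface_mesh` with attributes `keyhole_reports` (list of
#'   non-trivial `keyhole_report`s, tagged with slice/contour indices),
#'   `branch_plans` (list of non-empty `branch_plan`s, tagged with the slice
#'   pair) and `tilings` (the per-pair `tiling_path` list).
#' @examples
#' stack <- make_fixture("cylinder", n_points = 16, n_slices = 4, spacing = 2)
#' mesh <- reconstruct_surface(stack)
#' watertight_report(mesh)
#' @export
reconstruct_surface <- function(stack, normalize = TRUE, seal = TRUE,
                                keyhole_threshold = NULL,
                                start = c("closest", "exhaustive")) {
  start <- match.arg(start)
  v <- validate_stack(stack)
  if (length(v)) stop("invalid contour stack: ", paste(v, collapse = "; "))
  k <- length(stack$slices)

  # keyhole pass on the original contours (composites made later carry
  # intentionally coincident bridge vertices and are never re-scanned)
  keyhole_reports <- list()
  for (si in seq_len(k)) {
    sl <- stack$slices[[si]]
    for (ci in seq_along(sl$contours)) {
      cc <- sl$contours[[ci]]
      thr <- if (is.null(keyhole_threshold)) {
        default_keyhole_threshold(cc)
      } else {
        keyhole_threshold
      }
      res <- remove_keyholes(cc, thr)
      stack$slices[[si]]$contours[[ci]] <- res$contour
      if (nrow(res$report$conflicts) > 0L) {
        res$report$slice <- si
        res$report$contour <- ci
        keyhole_reports[[length(keyhole_reports) + 1L]] <- res$report
      }
    }
  }

  tilings <- list()
  branch_plans <- list()
  for (pi in seq_len(k - 1L)) {
    lower <- stack$slices[[pi]]
    upper <- stack$slices[[pi + 1L]]
    plan <- plan_branching(lower, upper)
    lc <- lower$contours
    uc <- upper$contours
    if (plan$side != "none") {
      merged <- attr(plan, "merged_contours")
      if (plan$side == "lower") lc <- merged else uc <- merged
      plan$pair <- c(pi, pi + 1L)
      branch_plans[[length(branch_plans) + 1L]] <- plan
    }
    match <- match_contours(lc, uc)
    for (mi in seq_along(match)) {
      tp <- tile_pair(lc[[mi]], uc[[match[mi]]], normalize = normalize,
                      start = start)
      attr(tp, "pair_tag") <- sprintf("tiling:%d-%d", pi, pi + 1L)
      tilings[[length(tilings) + 1L]] <- tp
    }
  }

  caps <- list()
  if (seal) {
    for (cc in stack$slices[[1L]]$contours) {
      caps[[length(caps) + 1L]] <- seal_cap(cc, "down")
    }
    for (cc in stack$slices[[k]]$contours) {
      caps[[length(caps) + 1L]] <- seal_cap(cc, "up")
    }
  }

  mesh <- assemble_mesh(stack, tilings, caps)
  attr(mesh, "keyhole_reports") <- keyhole_reports
  attr(mesh, "branch_plans") <- branch_plans
  attr(mesh, "tilings") <- tilings
  mesh
}
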