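test_that("two disjoint squares bridge at their brute-force nearest pair", {
  c1 <- unit_square_contour(0)                      # corners x = +/- 0.5
  c2 <- unit_square_contour(0, center = c(3, 0))    # corners x = 2.5 / 3.5
  merged <- merge_branch_contours(list(c1, c2))
  np <- oracle_nearest_pair(c1, c2)
  expect_equal(np$d, 2)                 # x = 0.5 side to x = 2.5 side
  bridge <- attr(merged, "bridge")
  # lexicographic winner of the brute-force tie set
  expect_identical(bridge, c(2L, 1L))
  expect_equal(sqrt(sum((c1$points[bridge[1], ] - c2$points[bridge[2], ])^2)),
               np$d)
  # composite ring: n1 + n2 + 2 points, every input point visited
  expect_identical(nrow(merged$points), 4L + 4L + 2L)
  all_pts <- rbind(c1$points, c2$points)
  for (r in seq_len(nrow(all_pts))) {
    hit <- any(merged$points[, 1] == all_pts[r, 1] &
                 merged$points[, 2] == all_pts[r, 2])
    expect_true(hit)
  }
  expect_identical(contour_winding(merged), "ccw")
})

test_that("merge tie-breaking picks the lowest index pair", {
  c1 <- unit_square_contour(0)
  c2 <- unit_square_contour(0, center = c(0, 3))   # offset in y only
  np_all <- list()
  dmin <- Inf
  for (i in 1:4) for (j in 1:4) {
    d <- sqrt(sum((c1$points[i, ] - c2$points[j, ]) ^ 2))
    if (d < dmin - 1e-12) { dmin <- d; np_all <- list(c(i, j)) }
    else if (abs(d - dmin) < 1e-12) np_all <- c(np_all, list(c(i, j)))
  }
  expect_gt(length(np_all), 1)          # genuine tie set
  merged <- merge_branch_contours(list(c1, c2))
  expect_identical(attr(merged, "bridge"), np_all[[1]])
})

test_that("single and multi-contour merge behaviour", {
  c1 <- unit_square_contour(0)
  expect_identical(merge_branch_contours(list(c1)), c1)
  # three small rings collapse to one composite visiting all points
  rings <- lapply(c(-4, 0, 4), function(cx) {
    contour(cbind(cx + cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6)), 0)
  })
  merged <- merge_branch_contours(rings)
  expect_identical(nrow(merged$points), 3L * 6L + 4L)  # two bridges
  expect_error(
    merge_branch_contours(list(unit_square_contour(0, side = 2),
                               unit_square_contour(0, side = 2, c(1, 0.5)))),
    "overlapping")
})

test_that("plan_branching is a no-op for equal counts and merges otherwise", {
  sq <- function(z, ...) new_slice(z, unit_square_contour(z, ...))
  expect_identical(plan_branching(sq(0), sq(1))$side, "none")
  expect_length(plan_branching(sq(0), sq(1))$merges, 0)

  two <- new_slice(1, list(unit_square_contour(1, center = c(-2, 0)),
                           unit_square_contour(1, center = c(2, 0))))
  plan <- plan_branching(sq(0), two)
  expect_identical(plan$side, "upper")
  expect_length(plan$merges, 1)

  three <- new_slice(1, list(unit_square_contour(1, center = c(-3, 0)),
                             unit_square_contour(1, center = c(0, 0)),
                             unit_square_contour(1, center = c(3.5, 0))))
  plan3 <- plan_branching(sq(0), three)
  expect_length(plan3$merges, 2)
  composite <- attr(plan3, "merged_contours")[[1]]
  expect_identical(nrow(composite$points), 3L * 4L + 4L)

  expect_error(plan_branching(new_slice(0, list()), sq(1)),
               "at least one contour")
})

test_that("keyhole removal leaves no close non-adjacent pairs and is idempotent", {
  st <- make_fixture("keyhole_c", n_slices = 2, spacing = 1)
  cc <- st$slices[[1]]$contours[[1]]
  thr <- 0.5
  expect_lt(min_nonadjacent_distance(cc$points), thr)   # channel present
  res <- remove_keyholes(cc, thr)
  expect_gte(min_nonadjacent_distance(res$contour$points), thr)
  expect_gt(nrow(res$report$conflicts), 0)
  expect_gt(length(res$report$removed), 0)
  # removed points are the slot-channel points (inside the keyhole)
  expect_true(all(cc$points[res$report$removed, 2] < max(cc$points[, 2])))
  # idempotence
  res2 <- remove_keyholes(res$contour, thr)
  expect_identical(res2$contour$points, res$contour$points)
  expect_identical(nrow(res2$report$conflicts), 0L)
  # still a valid simple ring
  expect_identical(contour_winding(res$contour), "ccw")
})

test_that("keyhole removal leaves convex and zero-threshold inputs unchanged", {
  ring <- make_fixture("cylinder", n_points = 24, n_slices = 2)$slices[[1]]$contours[[1]]
  res <- remove_keyholes(ring)                 # adaptive default threshold
  expect_identical(res$contour$points, ring$points)
  expect_identical(nrow(res$report$conflicts), 0L)
  keyed <- make_fixture("keyhole_c", n_slices = 2)$slices[[1]]$contours[[1]]
  res0 <- remove_keyholes(keyed, 0)
  expect_identical(res0$contour$points, keyed$points)
  expect_error(remove_keyholes(keyed, -1), ">= 0")
})
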