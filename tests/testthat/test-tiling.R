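test_that("triangle area matches Heron's formula on random triples", {
  expect_identical(triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_identical(triangle_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
  set.seed(11)
  for (rep in 1:1000) {
    A <- runif(3, -10, 10); B <- runif(3, -10, 10); C <- runif(3, -10, 10)
    expect_equal(triangle_area(A, B, C), heron_area(A, B, C),
                 tolerance = 1e-9)
  }
})

test_that("normalisation centres the vertex mean and scales the window to unit", {
  th <- 2 * pi * (0:7) / 8
  ell <- contour(cbind(5 + 2 * cos(th), 7 + sin(th)), 0)  # semi-axes (2, 1)
  res <- normalize_contour(ell)
  expect_equal(unname(res$params$window), c(4, 2))
  expect_equal(res$params$centroid, c(5, 7))
  expect_equal(colMeans(res$contour$points), c(0, 0), tolerance = 1e-12)
  # the point (7, 7) maps to (0.5, 0)
  expect_equal(unname(res$contour$points[1, ]), c(0.5, 0), tolerance = 1e-12)
  # translation invariance
  moved <- contour(sweep(ell$points, 2, c(-13.5, 4.25), "+"), 0)
  expect_equal(normalize_contour(moved)$contour$points,
               res$contour$points, tolerance = 1e-12)
  flat <- contour(rbind(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_error(normalize_contour(flat), "degenerate bounding window")
})

test_that("closest span matches an exhaustive pair scan", {
  expect_identical(unname(closest_span(unit_square_contour(0),
                                       unit_square_contour(1))), c(1L, 1L))
  set.seed(23)
  for (rep in 1:20) {
    lo <- random_star_contour(12, z = 0)
    up <- random_star_contour(15, z = 1.5)
    s <- closest_span(lo, up)
    d <- outer(seq_len(12), seq_len(15), Vectorize(function(i, j) {
      sqrt(sum((c(lo$points[i, ], 0) - c(up$points[j, ], 1.5)) ^ 2))
    }))
    hits <- which(d == min(d), arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    expect_identical(unname(s), unname(c(hits[1, 1], hits[1, 2])))
  }
  # upper ring rotated by one index: tie set resolved lexicographically
  sq <- unit_square_contour(0)
  rot <- contour(sq$points[c(2, 3, 4, 1), ], 1)
  s <- closest_span(sq, rot)
  expect_identical(unname(s), c(1L, 4L))   # point 1 reappears as row 4 above
})

test_that("aligned unit-square prism tiles to the closed-form lateral surface", {
  tp <- tile_pair(unit_square_contour(0), unit_square_contour(1),
                  normalize = FALSE)
  expect_length(tp$tiles, 8)
  expect_identical(tp$area, 4)             # perimeter x height
  expect_identical(tp$total_cost, 4)
  expect_identical(sum(tp$moves == "i"), 4L)
  expect_identical(sum(tp$moves == "j"), 4L)
  expect_error(tile_pair(unit_square_contour(0),
                         contour(rbind(c(0, 0), c(1, 0)), 1)),
               "at least 3 points")
})

test_that("inscribed regular prisms reach the closed-form lateral area", {
  for (n in c(8, 32, 128)) {
    r <- 7.5; h <- 2.5
    th <- 2 * pi * (0:(n - 1)) / n
    lo <- contour(cbind(r * cos(th), r * sin(th)), 0)
    up <- contour(cbind(r * cos(th), r * sin(th)), h)
    tp <- tile_pair(lo, up, normalize = FALSE)
    expect_equal(tp$area, 2 * n * r * sin(pi / n) * h, tolerance = 1e-9)
  }
})

test_that("the DP optimum equals exhaustive path enumeration (property)", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    lo <- random_star_contour(n, z = 0)
    up <- random_star_contour(m, z = runif(1, 0.5, 3))
    tp <- tile_pair(lo, up, normalize = FALSE)
    s <- closest_span(lo, up)
    expect_equal(tp$total_cost, oracle_min_tiling_cost(lo, up, s[1], s[2]),
                 tolerance = 1e-12)
    # tile count and segment coverage
    expect_length(tp$tiles, n + m)
    expect_identical(sum(tp$moves == "i"), n)
    expect_identical(sum(tp$moves == "j"), m)
  }
})

test_that("doubling slice spacing doubles the lateral area of a prism band", {
  set.seed(41)
  lo <- random_star_contour(17, z = 0)
  up1 <- contour(lo$points, 1.5)
  up2 <- contour(lo$points, 3)
  a1 <- tile_pair(lo, up1, normalize = FALSE)$area
  a2 <- tile_pair(lo, up2, normalize = FALSE)$area
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("normalisation recovers the skewed-cylinder correspondence", {
  n <- 24; r <- 5; h <- 2
  th <- 2 * pi * (0:(n - 1)) / n
  ring <- cbind(r * cos(th), r * sin(th))
  lo <- contour(ring, 0)
  up_aligned <- contour(ring, h)
  up_skewed <- contour(sweep(ring, 2, c(2 * r, 0), "+"), h)  # one diameter off
  tp_ref <- tile_pair(lo, up_aligned, normalize = TRUE)
  tp_skew <- tile_pair(lo, up_skewed, normalize = TRUE)
  expect_identical(tp_skew$spans, tp_ref$spans)
  expect_identical(tp_skew$moves, tp_ref$moves)
  # aligned congruent rings pair up index-to-index (identity matching)
  adv_i <- cumsum(tp_ref$moves == "i")
  adv_j <- cumsum(tp_ref$moves == "j")
  expect_true(all(abs(adv_i - adv_j) <= 1))
})

test_that("exhaustive start search never does worse than the closest-pair start", {
  set.seed(53)
  for (rep in 1:10) {
    lo <- random_star_contour(sample(5:9, 1), z = 0)
    up <- random_star_contour(sample(5:9, 1), z = 1)
    a <- tile_pair(lo, up, normalize = FALSE, start = "closest")$total_cost
    b <- tile_pair(lo, up, normalize = FALSE, start = "exhaustive")$total_cost
    expect_lte(b, a + 1e-12)
  }
})
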