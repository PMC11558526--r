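test_that("thinness is 1 for collinear sets and matches isotropic oracles", {
  t <- 1:10
  expect_equal(thinness(cbind(t, 2 * t, -t)), 1)
  set.seed(101)
  expect_lt(abs(thinness(matrix(rnorm(15000), ncol = 3)) - 1 / 3), 0.02)
  planar <- cbind(matrix(rnorm(10000), ncol = 2), 0)
  expect_lt(abs(thinness(planar) - 1 / 2), 0.02)
  expect_error(thinness(matrix(1, 5, 3)), "degenerate")
  expect_error(thinness(matrix(rnorm(6), 2, 3)), ">= 3")
})

test_that("thinness is invariant to rotation, translation and uniform scaling", {
  set.seed(55)
  pts <- l_shape(15, jitter = 0.01)
  base <- thinness(pts)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    s <- runif(1, 0.1, 10)
    moved <- s * pts %*% Q + matrix(rnorm(3), nrow(pts), 3, byrow = TRUE)
    expect_equal(thinness(moved), base, tolerance = 1e-9)
  }
})

test_that("curve ordering recovers the construction order up to reversal", {
  set.seed(6)
  t <- seq(0, 1, length.out = 20)
  pts <- cbind(t, 2 * t, -t)
  shuffle <- sample(nrow(pts))
  ord <- order_along_curve(pts[shuffle, ])
  recovered <- shuffle[ord]
  expect_true(identical(recovered, 1:20) || identical(recovered, 20:1))
  # an L-shaped thin set is walked arm by arm, no interleaving (a right-angle
  # bend caps thinness near 0.8, so the ordering threshold is relaxed)
  L <- l_shape(12)
  ordL <- order_along_curve(L, thinness_threshold = 0.75)
  expect_true(identical(ordL, seq_len(nrow(L))) ||
                identical(ordL, rev(seq_len(nrow(L)))))
  # minimal input
  expect_equal(sort(order_along_curve(cbind(1:3, 1:3, 1:3))), 1:3)
})

test_that("curve ordering refuses clouds that are not line-like", {
  set.seed(2)
  expect_error(order_along_curve(matrix(rnorm(300), ncol = 3)),
               "thinness|threshold")
})

test_that("inflection detection finds the constructed turn geometry", {
  # straight line: no inflections
  t <- seq(0, 1, length.out = 30)
  expect_equal(nrow(detect_inflections(cbind(t, t, t), window = 5)), 0)
  # one right-angle bend
  L <- l_shape(15)
  infl <- detect_inflections(L, window = 5)
  expect_equal(nrow(infl), 1)
  expect_equal(infl$angle, 90, tolerance = 5)
  expect_true(infl$perpendicular)
  expect_equal(infl$position, 15, tolerance = 2)
  # Z-shaped polyline: two right angles
  z <- rbind(cbind(seq(0, 1, length.out = 12), 0, 0),
             cbind(1, seq(0.1, 1, length.out = 10), 0),
             cbind(seq(1.1, 2, length.out = 10), 1, 0))
  inflz <- detect_inflections(z, window = 4)
  expect_equal(nrow(inflz), 2)
  expect_true(all(inflz$perpendicular))
  # too-short sequences warn and return nothing
  expect_warning(short <- detect_inflections(cbind(1:5, 1:5, 1:5), window = 5),
                 "short")
  expect_equal(nrow(short), 0)
})

test_that("inflections partition the ordering into contiguous labeled segments", {
  asg <- partition_by_inflections(1:30, c(10, 20))
  expect_setequal(unique(asg$labels), c("A", "B", "C"))
  expect_true(all(diff(match(asg$labels[asg$order], LETTERS)) >= 0) ||
                all(diff(match(asg$labels[asg$order], LETTERS)) <= 0))
  expect_equal(unname(table(asg$labels)[c("A", "B", "C")]), c(10, 10, 10),
               ignore_attr = TRUE)
  # no inflections: a single subset
  one <- partition_by_inflections(1:10, integer(0))
  expect_true(all(one$labels == "A"))
  expect_error(partition_by_inflections(1:10, c(5, 5)), "increasing")
})

test_that("subset A is the survivor end and reversal relabels consistently", {
  outcome <- c(rep("survived", 10), rep("died", 10))
  fwd <- partition_by_inflections(1:20, 10, outcome = outcome)
  expect_equal(fwd$summary$mortality[fwd$summary$subset == "A"], 0)
  expect_equal(fwd$summary$mortality[fwd$summary$subset == "B"], 1)
  # reversing the ordering must keep A at the all-survivor end
  rev_ <- partition_by_inflections(20:1, 10, outcome = outcome)
  expect_equal(rev_$summary$mortality[rev_$summary$subset == "A"], 0)
  expect_identical(fwd$labels, rev_$labels)
})

test_that("the pattern search recovers a planted collinear triplet", {
  px <- planted_matrix(n = 40, n_noise = 3, seed = 5)
  found <- search_patterns(px$m, top_k = 3)
  expect_gt(nrow(found), 0)
  expect_equal(unlist(found[1, c("di1", "di2", "di3")], use.names = FALSE),
               c("pl1", "pl2", "pl3"))
  # all-noise matrix: nothing exceeds the thinness threshold
  set.seed(77)
  noise <- matrix(rnorm(40 * 6), ncol = 6)
  expect_equal(nrow(search_patterns(noise)), 0)
  # k = 0 requested
  expect_equal(nrow(search_patterns(px$m, top_k = 0)), 0)
  expect_error(search_patterns(px$m[, 1:2]), ">= 3")
})

test_that("a fixture built with segment-specific outcomes yields the planted mortality", {
  # thin L-shaped structure whose first arm holds only survivors
  L <- l_shape(15, jitter = 0.002, seed = 3)
  outcome <- c(rep("survived", 15), rep("died", 8), rep("survived", 7))
  ord <- order_along_curve(L, thinness_threshold = 0.75)
  infl <- detect_inflections(L[ord, ], window = 5)
  asg <- partition_by_inflections(ord, infl, outcome = outcome)
  expect_equal(asg$summary$mortality[asg$summary$subset == "A"], 0)
})
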