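test_that("overlap index matches interval geometry on the stated cases", {
  r <- overlap_index(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$overlap_index, 0)
  expect_true(r$non_overlap)
  expect_equal(overlap_index(c(1, 3), c(2, 4))$overlap_index, 0.5)
  x <- rnorm(20)
  expect_equal(overlap_index(x, x)$overlap_index, 1)
  # degenerate zero-length interval: 1 inside, 0 outside
  expect_equal(overlap_index(c(2, 2), c(1, 4))$overlap_index, 1)
  expect_equal(overlap_index(c(9, 9), c(1, 4))$overlap_index, 0)
  expect_error(overlap_index(1, c(1, 2)), ">= 2")
  expect_error(overlap_index(c(1, NA, 2), c(1, 2)), "finite")
  expect_error(overlap_index(c(1, 2), c(1, 2), trim = c(0.5, 0.2)), "trim")
})

test_that("overlap index is symmetric and equals a brute-force oracle", {
  set.seed(11)
  brute <- function(a, b) {   # direct min/max interval intersection
    lo <- max(min(a), min(b)); hi <- min(max(a), max(b))
    inter <- max(0, hi - lo)
    inter / min(max(a) - min(a), max(b) - min(b))
  }
  for (i in 1:200) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    expect_equal(overlap_index(a, b)$overlap_index,
                 overlap_index(b, a)$overlap_index)
    expect_equal(overlap_index(a, b)$overlap_index, brute(a, b),
                 tolerance = 1e-12)
  }
})

test_that("shifting one sample out of range drives the overlap to exactly 0", {
  set.seed(4)
  a <- rnorm(40)
  hit_zero <- FALSE
  for (shift in seq(0, 12, by = 1)) {
    idx <- overlap_index(a, a + shift)$overlap_index
    if (shift == 0) expect_equal(idx, 1)
    if (shift >= diff(range(a))) {
      expect_identical(idx, 0)
      hit_zero <- TRUE
    }
  }
  expect_true(hit_zero)
})

test_that("trimmed intervals use the requested quantiles", {
  a <- 1:100
  r <- overlap_index(a, a + 200, trim = c(0.025, 0.975))
  expect_equal(r$interval_a,
               unname(quantile(a, c(0.025, 0.975), names = FALSE)))
  expect_identical(r$overlap_index, 0)
})

test_that("the discriminator scan ranks separating features first, deterministically", {
  set.seed(2)
  g <- rep(c("a", "b"), each = 15)
  sep <- c(rnorm(15, 0), rnorm(15, 30))       # fully separating
  over <- rnorm(30)                           # exchangeable
  m <- cbind(sep = sep, over = over)
  sc <- scan_discriminators(m, g)
  expect_equal(sc$feature[1], "sep")
  expect_equal(sc$overlap_index[1], 0)
  expect_true(sc$non_overlap[1])
  expect_identical(sc, scan_discriminators(m, g))
  # identical groups on a single feature -> one report with index 1
  one <- scan_discriminators(cbind(f = rep(1:5, 2)), rep(c("a", "b"), each = 5))
  expect_equal(nrow(one), 1)
  expect_equal(one$overlap_index, 1)
  # undersized group pairs are skipped with a warning
  expect_warning(
    sc2 <- scan_discriminators(cbind(f = rnorm(31)),
                               c(rep("a", 15), rep("b", 15), "c")),
    "skip")
  expect_equal(nrow(sc2), 1)
})

test_that("permuted labels produce no more zero-overlap features than true labels", {
  # separation-built fixture: a few features separate the true groups
  set.seed(21)
  n <- 16; g <- rep(c("a", "b"), each = n / 2)
  m <- cbind(matrix(rnorm(n * 3), ncol = 3),
             s1 = ifelse(g == "a", rnorm(n, 0), rnorm(n, 40)),
             s2 = ifelse(g == "a", rnorm(n, 0), rnorm(n, 40)))
  colnames(m)[1:3] <- paste0("x", 1:3)
  prop_zero <- function(lab)
    mean(scan_discriminators(m, lab)$overlap_index == 0)
  true_prop <- prop_zero(g)
  perm_props <- replicate(200, prop_zero(sample(g)))
  expect_true(mean(perm_props) <= true_prop)
  expect_true(true_prop >= 2 / 5)
})

test_that("rank comparison is exact at small n and matches enumeration", {
  r <- rank_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)   # 2/20 rank splits are as extreme
  expect_match(r$method, "exact")
  expect_equal(rank_compare(c(1, 2, 9), c(5, 6))$median_a, 2)
  tied <- rank_compare(rep(3, 4), rep(3, 5))
  expect_equal(tied$p_value, 1)
  expect_true(tied$tied)
  expect_equal(rank_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("exact p-values agree with the independent rank-sum oracle", {
  set.seed(8)
  for (i in 1:50) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    if (length(unique(c(a, b))) < length(c(a, b))) next  # oracle exact only without ties
    expect_equal(rank_compare(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation modes agree to 0.02 at n = 6 + 6", {
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, 0, 1.5))
    exact <- rank_compare(a, b)$p_value
    approx <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("large-sample mode matches the tie-corrected normal approximation", {
  set.seed(5)
  a <- round(rnorm(30), 1); b <- round(rnorm(25, 0.4), 1)  # ties present
  r <- rank_compare(a, b)
  expect_match(r$method, "normal")
  expect_equal(r$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("chi-square test matches the printed mortality contrast and closed form", {
  ct <- contingency_test(rbind(c(1090, 2515), c(46, 420)))
  expect_equal(round(100 * ct$proportions[1, 1], 1), 30.2)
  expect_equal(round(100 * ct$proportions[2, 1], 1), 9.9)
  expect_lt(ct$p_value, 0.01)
  flat <- contingency_test(rbind(c(5, 5), c(5, 5)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(contingency_test(rbind(c(10, 0), c(0, 10)))$chi2, 20)
  expect_error(contingency_test(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("chi-square equals the 2x2 closed form on random tables", {
  set.seed(13)
  closed <- function(t) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]; n <- sum(t)
    n * (a * d - b * c)^2 / (sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]))
  }
  for (i in 1:100) {
    t <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(contingency_test(t)$chi2, closed(t), tolerance = 1e-10)
  }
})

test_that("excess kurtosis has the known closed-form and sampling behavior", {
  expect_equal(excess_kurtosis(c(-1, -1, 1, 1)), -2)
  set.seed(99)
  expect_lt(abs(excess_kurtosis(rnorm(10000))), 0.15)
  set.seed(7)
  x <- rnorm(200)
  expect_gt(excess_kurtosis(c(x, 25)), excess_kurtosis(x))
  expect_error(excess_kurtosis(rep(1, 10)), "variance")
  expect_error(excess_kurtosis(c(1, 2, 3)), ">= 4")
})

test_that("excess kurtosis matches the independent moment implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  x <- rgamma(500, 2)
  expect_equal(excess_kurtosis(x), e1071::kurtosis(x, type = 1),
               tolerance = 1e-12)
})
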