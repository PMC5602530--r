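test_that("Pearson chi-squared matches hand evaluation and edge cases", {
  ## equal proportions -> 0 / 1
  r <- pearsonChi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  ## all expected counts 2.5: sum((O-E)^2/E) = 4 * 2.5^2/2.5 = 10
  r2 <- pearsonChi2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(unname(r2$statistic), 10)
  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(pearsonChi2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("chi-squared is invariant under transposition and row/column swaps", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rpois(4, 8) + 1, 2)
    s0 <- unname(pearsonChi2(m)$statistic)
    expect_equal(unname(pearsonChi2(t(m))$statistic), s0)
    expect_equal(unname(pearsonChi2(m[2:1, ])$statistic), s0)
    expect_equal(unname(pearsonChi2(m[, 2:1])$statistic), s0)
    ## independent route: base R without continuity correction
    expect_equal(s0, unname(suppressWarnings(
      chisq.test(m, correct = FALSE))$statistic), tolerance = 1e-12)
  }
})

test_that("Fisher exact test enumerates the hypergeometric support", {
  ## margins (2,2)/(2,2): three tables, observed is one of the two extremes
  expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3,
               tolerance = 1e-12)
  ## degenerate column margin -> single attainable table, p = 1
  expect_equal(fisherExact2x2(matrix(c(0, 0, 5, 5), 2))$p.value, 1)
  ## independent route: base R two-sided Fisher on random tables
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rpois(4, 5), 2)
    if (sum(m) == 0) next
    expect_equal(fisherExact2x2(m)$p.value, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U handles ties, exactness and shift invariance", {
  ## fully overlapping tied samples: U = n1 n2 / 2
  r <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r$statistic), 4.5)
  ## exact enumeration example
  r2 <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p.value, 1 / 3, tolerance = 1e-12)
  ## shift invariance
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  a <- mannWhitneyU(x, y); b <- mannWhitneyU(x + 100, y + 100)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p.value, b$p.value)
  expect_error(mannWhitneyU(numeric(0), y), "nonempty")
})

test_that("Mann-Whitney agrees with base R in exact and approximate regimes", {
  set.seed(6)
  ## exact regime (small, untied)
  for (i in 1:10) {
    x <- sample(seq(1, 200), 5); y <- sample(seq(201, 399, 2), 7) / 10
    ref <- wilcox.test(x, y, exact = TRUE)
    r <- mannWhitneyU(x, y)
    expect_equal(unname(r$statistic), unname(ref$statistic))
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-12)
  }
  ## approximate regime with ties and continuity correction
  for (i in 1:10) {
    x <- sample(1:10, 20, replace = TRUE)
    y <- sample(3:12, 25, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    r <- mannWhitneyU(x, y)
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches hand evaluation and base R", {
  r <- kruskalWallisH(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  ## untied ranks 1..6 in three groups: H = 12/42 * 89.5 - 21 = 4.571
  r2 <- kruskalWallisH(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r2$statistic), 4.571, tolerance = 5e-4)
  expect_equal(unname(r2$parameter), 2)
  ## permutation invariance
  r3 <- kruskalWallisH(list(c(5, 6), c(1, 2), c(3, 4)))
  expect_equal(r3$statistic, r2$statistic)
  ## independent route with ties
  set.seed(7)
  g <- list(sample(1:6, 9, TRUE), sample(2:8, 11, TRUE), sample(4:9, 8, TRUE))
  ref <- kruskal.test(g)
  mine <- kruskalWallisH(g)
  expect_equal(unname(mine$statistic), unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(kruskalWallisH(list(1:3)), "two nonempty groups")
})

test_that("Pearson correlation matches closed forms and base R", {
  expect_equal(unname(pearsonCorrelation(1:10, 2 * (1:10) + 1)$estimate), 1)
  expect_equal(unname(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1))$estimate), -1)
  r <- pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(unname(r$estimate), 0.8, tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ref <- cor.test(x, y)
  mine <- pearsonCorrelation(x, y)
  expect_equal(unname(mine$estimate), unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("all battery p-values stay in [0, 1] across random inputs", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rpois(4, 4), 2)
    expect_true(fisherExact2x2(m)$p.value >= 0 &&
                fisherExact2x2(m)$p.value <= 1)
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    p <- mannWhitneyU(x, y)$p.value
    expect_true(p >= 0 && p <= 1)
  }
})
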