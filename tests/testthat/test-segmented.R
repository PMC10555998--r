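test_that("noiseless piecewise truth is recovered exactly", {
  x <- rep(seq(0, 120, 10), each = 3)
  y <- pmax(x - 50, 0)  # slopes 0 then 1, joined at 50
  f <- fit_segmented(x, y, 1)
  expect_true(f$converged)
  expect_equal(f$psi, 50, tolerance = 1e-6)
  expect_equal(f$slopes, c(0, 1), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("exactly linear data leaves no gap and matches the line RSS", {
  x <- rep(seq(0, 120, 10), each = 2)
  y <- 3 + 0.5 * x
  f <- fit_segmented(x, y, 1)
  line_rss <- sum(lm(y ~ x)$residuals^2)
  expect_lt(abs(f$rss - line_rss), 1e-8)
})

test_that("breakpoints stay strictly inside the range and ordered", {
  set.seed(14)
  for (i in 1:15) {
    x <- rep(seq(0, 120, 10), each = 5)
    y <- 5 + 0.4 * pmax(x - sample(30:90, 1), 0) + rnorm(length(x), 0, 8)
    k <- sample(1:2, 1)
    f <- fit_segmented(x, y, k)
    expect_true(all(f$psi > min(x) & f$psi < max(x)))
    if (k == 2) expect_lt(f$psi[1], f$psi[2])
    # the piecewise model nests the straight line
    expect_lte(f$rss, sum(lm(y ~ x)$residuals^2) + 1e-8)
  }
})

test_that("brute force enumerates the admissible candidates", {
  # 5 distinct x: only the two central midpoints leave >= 2 points per side
  x <- c(0, 10, 20, 30, 40)
  y <- c(1, 0, 2, 8, 16)
  b <- brute_force_breakpoints(x, y, 1)
  cand <- c(15, 25)
  rss <- vapply(cand, function(ps) {
    sum(lm(y ~ x + pmax(x - ps, 0))$residuals^2)
  }, numeric(1))
  expect_equal(b$psi, cand[which.min(rss)])
  expect_equal(b$rss, min(rss), tolerance = 1e-10)

  # noiseless join lying exactly on a candidate midpoint is found exactly
  x2 <- rep(c(0, 20, 40, 60, 80, 100, 120), each = 2)
  y2 <- 2 + 0.8 * pmax(x2 - 50, 0)
  expect_equal(brute_force_breakpoints(x2, y2, 1)$psi, 50)
})

test_that("iterative fit matches the exhaustive oracle on random instances", {
  set.seed(21)
  for (i in 1:40) {
    nlev <- sample(10:15, 1)
    x <- rep(seq(0, 120, length.out = nlev), length.out = sample(20:30, 1))
    k <- sample(1:2, 1)
    psi_t <- sort(sample(seq(20, 100, 10), k))
    y <- 2 + 0.1 * x + rnorm(length(x), 0, 4)
    for (j in seq_len(k)) y <- y + runif(1, -1, 1) * pmax(x - psi_t[j], 0)
    f <- fit_segmented(x, y, k)
    b <- brute_force_breakpoints(x, y, k)
    expect_lte(f$rss, 1.001 * b$rss)
  }
})

test_that("fit agrees with an independent broken-line implementation", {
  # frozen reference values from the segmented package (v2.1.4), computed on
  # these exact seeded datasets
  set.seed(42)
  x <- rep(seq(0, 120, 10), each = 5)
  y <- 5 + 0.9 * pmax(x - 65, 0) + rnorm(length(x), 0, 6)
  f <- fit_segmented(x, y, 1)
  expect_equal(f$psi, 67.971247, tolerance = 1e-3)
  expect_equal(f$se_psi, 3.100495, tolerance = 1e-2)

  set.seed(99)
  y2 <- 10 + 1.2 * x - 1.9 * pmax(x - 30, 0) + 1.6 * pmax(x - 85, 0) +
    rnorm(length(x), 0, 7)
  f2 <- fit_segmented(x, y2, 2)
  expect_equal(f2$psi, c(34.810900, 83.013680), tolerance = 1e-3)
  expect_equal(f2$se_psi, c(2.011190, 2.231426), tolerance = 1e-2)
})

test_that("adding a breakpoint never increases the oracle minimum RSS", {
  set.seed(33)
  for (i in 1:10) {
    x <- rep(seq(0, 120, 10), each = 2)
    y <- rnorm(length(x), 10, 5)
    expect_lte(brute_force_breakpoints(x, y, 2)$rss,
               brute_force_breakpoints(x, y, 1)$rss + 1e-9)
  }
})

test_that("input contracts are enforced", {
  x <- rep(seq(0, 120, 10), each = 2)
  y <- rnorm(length(x))
  expect_error(fit_segmented(x, y, 3), "0, 1 or 2")
  expect_error(fit_segmented(x, y, 1, psi_init = 500), "inside")
  expect_error(fit_segmented(c(1, 2, 3), c(1, 2, 3), 1), "distinct x")
  expect_error(davies_test(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(davies_test(1:5, 1:5), "at least 6")
})

test_that("Davies p-value is 1 for a perfect line and affine invariant", {
  x <- rep(seq(0, 120, 10), each = 2)
  y <- 2 + 0.3 * x
  expect_equal(davies_test(x, y)$p.value, 1)

  set.seed(9)
  for (i in 1:5) {
    x <- runif(40, 0, 100)
    y <- 1 + 0.2 * x + 0.5 * pmax(x - 50, 0) + rnorm(40)
    p0 <- davies_test(x, y)$p.value
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    cc <- runif(1, 0.5, 3); dd <- runif(1, -5, 5)
    p1 <- davies_test(a * x + b, cc * y + dd)$p.value
    expect_equal(p0, p1, tolerance = 1e-10)
  }
})

test_that("Davies test detects the preset threshold with high power", {
  d <- make_design()
  m <- preset_scenarios("stable_single_threshold")
  rej <- 0
  for (i in 1:60) {
    o <- simulate_experiment(d, m, seed = 60000 + i)
    st <- o[o$salinity == "stable", ]
    rej <- rej + (davies_test(st$nutrient_g, st$mortality_pct)$p.value < 0.05)
  }
  expect_gte(rej / 60, 0.8)
})
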