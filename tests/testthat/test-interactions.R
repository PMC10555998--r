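test_that("survival conversion and DA follow their defining formulas", {
  expect_equal(to_survival(0), 100)
  expect_equal(to_survival(100), 0)
  expect_equal(to_survival(37.5), 62.5)
  expect_error(to_survival(120), "within")
  expect_error(to_survival(-1), "within")

  expect_equal(deviation_from_additivity(1, 1, 1), 0)
  expect_equal(deviation_from_additivity(0.8, 0.5, 0.4), 0)
  expect_equal(deviation_from_additivity(0.8, 0.5, 0.2), -0.2)
  expect_error(deviation_from_additivity(-0.1, 1, 1), ">= 0")
})

test_that("rescaled DA hits its anchor points", {
  expect_equal(as.numeric(rescale_da(0.8, 0.8, 0)), -1)     # total mortality
  expect_equal(as.numeric(rescale_da(0.8, 0.5, 0.5)), 1)    # = strongest
  expect_equal(as.numeric(rescale_da(1, 1, 1)), 0)          # no interaction
  expect_equal(as.numeric(rescale_da(0.8, 0.5, 0.4)), 0)    # multiplicative
  # degenerate denominators return the clip boundary and are flagged
  r <- rescale_da(0, 0, 0.5)
  expect_equal(as.numeric(r), 2)
  expect_true(attr(r, "degenerate"))
  r2 <- rescale_da(1, 1, 1.5)  # w_min - E = 0
  expect_equal(as.numeric(r2), 2)
  expect_true(attr(r2, "degenerate"))
  expect_error(rescale_da(-0.2, 1, 1), ">= 0")
})

test_that("rescaled DA is bounded on a dense grid of valid triples", {
  g <- seq(0, 1.5, by = 0.05)
  gr <- expand.grid(x = g, y = g, z = g)
  v <- rescale_da(gr$x, gr$y, gr$z)
  expect_true(all(v >= -1 & v <= 2))
  expect_equal(max(v), 2)
  expect_equal(min(v), -1)
})

test_that("classification bins partition [-1, 2] with the stated boundaries", {
  expect_equal(as.character(classify_interaction(-0.7)), "synergy")
  expect_equal(as.character(classify_interaction(0)), "additive")
  expect_equal(as.character(classify_interaction(1.5)), "suppression")
  # left-closed boundaries
  expect_equal(as.character(classify_interaction(c(-1, -0.5, 0.5, 1.3, 2))),
               c("synergy", "additive", "buffering", "suppression",
                 "suppression"))
  # no gaps or overlaps across the whole range
  v <- classify_interaction(seq(-1, 2, by = 0.001))
  expect_false(anyNA(v))
  expect_error(classify_interaction(2.1), "\\[-1, 2\\]")
})

test_that("multiplicative null model is a symmetric monotone cap", {
  expect_equal(multiplicative_null(0, 0), 0)
  expect_equal(multiplicative_null(1, 0.3), 1)
  expect_equal(multiplicative_null(0.4, 0.3), 0.58)
  g <- seq(0, 1, by = 0.05)
  gr <- expand.grid(a = g, b = g)
  v <- multiplicative_null(gr$a, gr$b)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, multiplicative_null(gr$b, gr$a))
  # monotone in each argument
  expect_true(all(diff(multiplicative_null(g, 0.3)) >= 0))
  expect_error(multiplicative_null(1.2, 0), "proportions")
})

test_that("classification is invariant to rescaling all survivals", {
  set.seed(12)
  for (i in 1:20) {
    W0 <- runif(1, 40, 100)
    WX <- runif(1, 0, W0); WY <- runif(1, 0, W0); WXY <- runif(1, 0, W0)
    cc <- runif(1, 0.2, 1.2)
    r1 <- rescale_da(WX / W0, WY / W0, WXY / W0)
    r2 <- rescale_da(cc * WX / (cc * W0), cc * WY / (cc * W0),
                     cc * WXY / (cc * W0))
    expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-10)
  }
})

test_that("interaction table computes records and flags missing cells", {
  d <- make_design(replicates = 3)
  m <- preset_scenarios("null_flat")
  o <- simulate_experiment(d, m, seed = 5)
  # identical mortality everywhere -> DA = 0, additive
  o$mortality_pct <- 20
  it <- interaction_table(o)
  expect_true(all(abs(it$DA) < 1e-12))
  expect_true(all(it$label == "additive"))
  expect_equal(nrow(it), 12)

  # DA sign agrees with the multiplicative-null comparison
  o2 <- simulate_experiment(d, preset_scenarios("intrusion_double_threshold"),
                            seed = 6)
  it2 <- interaction_table(o2)
  ok <- !it2$undefined & abs(it2$DA) > 1e-12
  expect_true(all((it2$DA[ok] < 0) ==
                    (it2$observed_mortality_pct[ok] >
                       it2$null_mortality_pct[ok])))

  o3 <- o[!(o$nutrient_g == 40 & o$salinity == "stable"), ]
  expect_error(interaction_table(o3), "40")
})

test_that("DA is centred on zero when truth sits on the null surface", {
  d <- make_design()
  m <- null_surface_model()
  inside <- 0; total <- 0
  for (i in 1:60) {
    o <- simulate_experiment(d, m, bath_sd = 0, seed = 30000 + i)
    it <- interaction_table(o)
    se <- da_se(it$W0, it$WX, it$WY, it$WXY)
    inside <- inside + sum(abs(it$DA) < 2 * se)
    total <- total + nrow(it)
  }
  expect_gte(inside / total, 0.9)
})

test_that("forced synergy is labelled synergy along the gradient", {
  d <- make_design()
  m <- synergy_model()
  hit <- 0; nsim <- 60
  for (i in 1:nsim) {
    o <- simulate_experiment(d, m, bath_sd = 0, seed = 40000 + i)
    it <- interaction_table(o)
    low <- it$nutrient_g <= 40
    hit <- hit + all(it$label[low] == "synergy")
  }
  expect_gte(hit / nsim, 0.9)
})

test_that("two-way test has the design df and detects pure main effects", {
  d <- make_design()
  o <- simulate_experiment(d, additive_truth(), seed = 1)
  r <- two_way_interaction_test(o)
  expect_equal(r$df1, 12)   # (13 - 1) x (2 - 1)
  expect_equal(r$df2, 104)  # 130 - 26

  # constant within salinity (plus replicate noise orthogonal to the
  # design): interaction sum of squares is exactly zero
  o$mortality_pct <- 10 + 20 * (o$salinity == "intrusion") +
    rep(c(-1, 1), length.out = nrow(o))
  r2 <- two_way_interaction_test(o)
  expect_lt(r2$F, 1e-10)
  expect_gt(r2$p.value, 0.999)
})

test_that("bath variance component is detected when present", {
  d <- make_design()
  m <- additive_truth()
  o_big <- simulate_experiment(d, m, bath_sd = 0.08, seed = 3)
  r_big <- two_way_interaction_test(o_big)
  expect_lt(r_big$lrt_p, 0.05)
  o_nil <- simulate_experiment(d, m, bath_sd = 0, seed = 3)
  r_nil <- two_way_interaction_test(o_nil)
  expect_gt(r_nil$lrt_p, 0.05)
})
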