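test_that("design cardinalities match the closed-form products", {
  d <- make_design()
  expect_equal(nrow(d), 130)
  expect_equal(length(attr(d, "nutrient_levels")), 13)
  expect_equal(nrow(unique(d[c("nutrient_g", "salinity")])), 26)
  expect_equal(attr(d, "baths"), 6L)
  expect_equal(unique(d$n_initial), 15L)
  # bath assignment is a partition of the units
  expect_equal(sum(table(d$bath_id)), nrow(d))
  expect_true(all(d$bath_id %in% 1:6))

  # property: cardinalities for random design parameters
  set.seed(1)
  for (i in 1:20) {
    L <- sample(2:15, 1); S <- sample(1:3, 1); R <- sample(1:6, 1)
    B <- sample(1:8, 1)
    d <- make_design(nutrient_levels = seq(0, 10 * (L - 1), by = 10),
                     salinity_treatments = paste0("s", seq_len(S)),
                     replicates = R, baths = B)
    expect_equal(nrow(d), L * S * R)
    expect_equal(nrow(unique(d[c("nutrient_g", "salinity")])), L * S)
  }
})

test_that("degenerate and invalid designs are handled", {
  d <- make_design(nutrient_levels = c(0, 10), salinity_treatments = "only",
                   replicates = 1, baths = 1, individuals_per_tank = 1)
  expect_equal(nrow(d), 2)
  expect_error(make_design(nutrient_levels = 0), "2 distinct")
  expect_error(make_design(replicates = 0), "positive whole")
  expect_error(make_design(baths = -1), "positive whole")
})

test_that("preset scenarios carry the documented breakpoints", {
  expect_equal(preset_scenarios("stable_single_threshold")$
                 treatments$stable$psi, 70)
  expect_equal(preset_scenarios("intrusion_double_threshold")$
                 treatments$intrusion$psi, c(26.91, 84.13))
  expect_length(preset_scenarios("null_flat")$treatments$stable$psi, 0)
  # rise-fall-rise shape of the double-threshold scenario
  sl <- preset_scenarios("intrusion_double_threshold")$
    treatments$intrusion$slopes
  expect_true(sl[1] > 0 && sl[2] < 0 && sl[3] > 0)
  expect_error(preset_scenarios("bogus"), "null_flat")
})

test_that("simulation respects degenerate truths and is reproducible", {
  d <- make_design(replicates = 2)
  zero <- mean_model(list(stable = list(intercept = 0, psi = numeric(0),
                                        slopes = 0),
                          intrusion = list(intercept = 0, psi = numeric(0),
                                           slopes = 0)))
  o <- simulate_experiment(d, zero, bath_sd = 0, seed = 1)
  expect_true(all(o$n_dead == 0))
  one <- mean_model(list(stable = list(intercept = 1, psi = numeric(0),
                                       slopes = 0),
                         intrusion = list(intercept = 1, psi = numeric(0),
                                          slopes = 0)))
  o <- simulate_experiment(d, one, bath_sd = 0, seed = 1)
  expect_true(all(o$n_dead == o$n_initial))

  m <- preset_scenarios("stable_single_threshold")
  o1 <- simulate_experiment(d, m, seed = 7)
  o2 <- simulate_experiment(d, m, seed = 7)
  expect_identical(o1, o2)
  expect_equal(o1$mortality_pct, 100 * o1$n_dead / o1$n_initial)

  bad <- mean_model(list(stable = list(intercept = 0, psi = numeric(0),
                                       slopes = 0)))
  expect_error(simulate_experiment(d, bad), "lacks treatment")
  expect_warning(
    simulate_experiment(d, mean_model(list(
      stable = list(intercept = -0.5, psi = numeric(0), slopes = 0),
      intrusion = list(intercept = 0.1, psi = numeric(0), slopes = 0))),
      bath_sd = 0, seed = 1),
    "outside")
})

test_that("simulated means track the piecewise-linear truth", {
  d <- make_design()
  m <- preset_scenarios("stable_single_threshold")
  xs <- attr(d, "nutrient_levels")
  truth <- 100 * predict_mean_model(m, xs, "stable")
  acc <- matrix(0, 200, length(xs))
  for (i in 1:200) {
    o <- simulate_experiment(d, m, bath_sd = 0, seed = 8000 + i)
    st <- o[o$salinity == "stable", ]
    acc[i, ] <- tapply(st$mortality_pct, st$nutrient_g, mean)[as.character(xs)]
  }
  grand <- colMeans(acc)
  # Monte-Carlo SE of the grand mean: binomial tank variance / (200 sims x 5)
  se <- sqrt(truth / 100 * (1 - truth / 100) / 15) * 100 / sqrt(200 * 5)
  expect_true(all(abs(grand - truth) < 4 * pmax(se, 0.05)))
})

test_that("per-level variance converges to the binomial value", {
  d <- make_design(nutrient_levels = c(0, 60), salinity_treatments = "stable",
                   replicates = 10000, baths = 1)
  m <- mean_model(list(stable = list(intercept = 0.1, psi = numeric(0),
                                     slopes = 0.005)))
  o <- simulate_experiment(d, m, bath_sd = 0, seed = 3)
  for (lv in c(0, 60)) {
    p <- 0.1 + 0.005 * lv
    v_obs <- var(o$mortality_pct[o$nutrient_g == lv])
    v_theory <- p * (1 - p) / 15 * 1e4
    expect_lt(abs(v_obs - v_theory) / v_theory, 0.05)
  }
})

test_that("variance inflation acts only near the breakpoint", {
  d <- make_design(nutrient_levels = c(0, 70), salinity_treatments = "stable",
                   replicates = 2000, baths = 1)
  m1 <- preset_scenarios("stable_single_threshold", variance_inflation = TRUE)
  m0 <- preset_scenarios("stable_single_threshold")
  expect_gt(m1$inflation_sd, 0)
  expect_equal(m0$inflation_sd, 0)
  o1 <- simulate_experiment(d, m1, bath_sd = 0, seed = 5)
  o0 <- simulate_experiment(d, m0, bath_sd = 0, seed = 6)
  v <- function(o, lv) var(o$mortality_pct[o$nutrient_g == lv])
  # at the breakpoint the jitter inflates the variance well beyond binomial
  expect_gt(v(o1, 70), 2 * v(o0, 70))
  # 70 g away from the breakpoint the ramp is zero: variances agree
  expect_lt(abs(v(o1, 0) - v(o0, 0)) / v(o0, 0), 0.25)
})
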