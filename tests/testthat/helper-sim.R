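# Shared fixtures, built in code.

# additive truth on the probability scale: no nutrient x salinity interaction
additive_truth <- function() {
  mean_model(list(
    stable = list(intercept = 0.15, psi = numeric(0), slopes = 0.002),
    intrusion = list(intercept = 0.25, psi = numeric(0), slopes = 0.002)))
}

# combined-treatment mean placed exactly on the multiplicative-null surface:
# survival W_XY = W_0 * w_X * w_Y at every level (wY from a 0.2 salinity
# effect), so DA = 0 in truth
null_surface_model <- function() {
  xs <- seq(0, 120, by = 10)
  p0 <- 0.05
  pN <- pmin(pmax(p0 + 0.004 * xs, 0), 1)
  N <- (pN - p0) / (1 - p0)
  SV <- 0.2
  pXY <- p0 + (1 - p0) * ((N + SV) - N * SV)  # linear in x by construction
  mean_model(list(
    stable = list(intercept = p0, psi = numeric(0), slopes = 0.004),
    intrusion = list(intercept = pXY[1], psi = numeric(0),
                     slopes = (pXY[2] - pXY[1]) / (xs[2] - xs[1]))))
}

# combined survival forced to w_X * w_Y / 4 at all levels > 0: rescaled DA
# = -0.75 in truth, well inside the synergy bin. The salinity-only cell at
# 0 g keeps its own plain effect (mortality 0.25), so the intrusion curve
# needs a knee between 0 and the first positive level.
synergy_model <- function() {
  xs <- seq(0, 120, by = 10)
  p0 <- 0.05
  W0 <- 1 - p0
  wX <- (1 - pmin(pmax(p0 + 0.004 * xs, 0), 1)) / W0
  wY <- (1 - 0.25) / W0
  pXY <- 1 - W0 * wX * wY / 4       # linear in x (slope s2)
  s2 <- (pXY[2] - pXY[1]) / (xs[2] - xs[1])
  # knee at 5 g connecting the 0.25 salinity-only intercept to the synergy
  # line: value at 10 g must equal pXY[2]
  s1 <- (pXY[2] - 0.25 - 5 * s2) / 5
  mean_model(list(
    stable = list(intercept = p0, psi = numeric(0), slopes = 0.004),
    intrusion = list(intercept = 0.25, psi = 5, slopes = c(s1, s2))))
}

# delta-method standard error of DA from the four cell means (percent scale),
# using estimated binomial variances of each cell mean
da_se <- function(W0, WX, WY, WXY, n_tank = 15, reps = 5) {
  vW <- function(W) pmax(W / 100 * (1 - W / 100), 1e-4) / (n_tank * reps) * 1e4
  wX <- WX / W0; wY <- WY / W0; wXY <- WXY / W0
  g <- cbind(dW0 = (-WXY + 2 * wY * WX * wY * 0) / W0^2, # filled below
             dWX = -wY / W0,
             dWY = -wX / W0,
             dWXY = 1 / W0)
  # d(DA)/dW0 = (-WXY + 2 WX WY / W0) / W0^2
  g[, "dW0"] <- (-WXY + 2 * WX * WY / W0) / W0^2
  sqrt(g[, "dW0"]^2 * vW(W0) + g[, "dWX"]^2 * vW(WX) +
         g[, "dWY"]^2 * vW(WY) + g[, "dWXY"]^2 * vW(WXY))
}
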