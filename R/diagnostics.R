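# Tipping-point corroboration diagnostics: the variance-along-gradient
# early-warning profile and Hartigan's dip test for multimodality.

#' Variance-along-gradient profile
#'
#' Computes the unbiased sample variance of mortality across replicates at
#' every nutrient level of one salinity treatment and smooths it along the
#' gradient with a local-linear smoother (tricube weights). Rising variance
#' as the gradient approaches a threshold is a classic early-warning signal
#' of a tipping point.
#'
#' @param observations Tank observations for a single salinity treatment.
#' @param span Fraction of levels in each smoothing window (minimum 3
#'   levels).
#' @param grid_length Number of evaluation points of the smoothed curve.
#' @return Object of class `variance_profile`: `levels` (data frame with
#'   `nutrient_g`, `n`, `variance`), `curve` (data frame with `x`,
#'   `smoothed`), `span`.
#' @export
variance_profile <- function(observations, span = 0.75, grid_length = 101) {
  stopifnot(all(c("nutrient_g", "mortality_pct") %in% names(observations)))
  if ("salinity" %in% names(observations) &&
      length(unique(observations$salinity)) > 1)
    stop("variance_profile expects one salinity treatment at a time",
         call. = FALSE)
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]", call. = FALSE)
  sp <- split(observations$mortality_pct, observations$nutrient_g)
  n_rep <- lengths(sp)
  if (any(n_rep < 2)) {
    warning(sprintf("omitting %d level(s) with < 2 replicates",
                    sum(n_rep < 2)), call. = FALSE)
    sp <- sp[n_rep >= 2]
  }
  if (length(sp) < 3) stop("need variances at >= 3 levels", call. = FALSE)
  lev <- data.frame(nutrient_g = as.numeric(names(sp)),
                    n = lengths(sp),
                    variance = vapply(sp, var, numeric(1)),
                    row.names = NULL)
  lev <- lev[order(lev$nutrient_g), ]

  xs <- lev$nutrient_g; vs <- lev$variance
  L <- length(xs)
  window <- max(3, ceiling(span * L))
  grid <- seq(min(xs), max(xs), length.out = grid_length)
  smoothed <- vapply(grid, function(g) {
    d <- abs(xs - g)
    h <- sort(d)[min(window, L)]
    if (h == 0) h <- max(d[d > 0], 1)  # degenerate window
    w <- (1 - pmin(d / h, 1)^3)^3
    w[d >= h] <- 0
    use <- w > 0
    if (sum(use) < 2) return(vs[which.min(d)])
    # local linear fit at g, solved in closed form
    xw <- xs[use] - g
    W <- w[use]
    sw <- sum(W); swx <- sum(W * xw); swx2 <- sum(W * xw^2)
    swy <- sum(W * vs[use]); swxy <- sum(W * xw * vs[use])
    det <- sw * swx2 - swx^2
    if (abs(det) < 1e-12) return(swy / sw)
    (swx2 * swy - swx * swxy) / det
  }, numeric(1))

  structure(list(levels = lev,
                 curve = data.frame(x = grid, smoothed = smoothed),
                 span = span),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat("Variance profile over", nrow(x$levels), "levels (span", x$span, ")\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-distance between the empirical cdf and any
#' unimodal cdf, i.e. half the maximum distance between the empirical cdf
#' and the closest fit computed through the greatest-convex-minorant /
#' least-concave-majorant construction. It lies in `[1/(2n), 1/4]`; large
#' values indicate multimodality.
#'
#' @param sample Numeric vector, at least 4 finite values.
#' @return The dip statistic (a single number).
#' @examples
#' dip_statistic(c(rep(0, 30), rep(1, 30)))  # 0.25, the maximal dip
#' dip_statistic(1:10)                       # 1/20, the minimal dip
#' @export
dip_statistic <- function(sample) {
  sample <- as.numeric(sample)
  sample <- sample[is.finite(sample)]
  if (length(sample) < 4)
    stop("need at least 4 finite values", call. = FALSE)
  dip_cpp(sort(sample))
}

#' Dip test for multimodality
#'
#' Monte-Carlo dip test: the observed dip is compared with the dips of `B`
#' Uniform(0, 1) samples of the same size, the standard calibration null
#' (conservative for lighter-tailed unimodal data). The p-value is
#' `(1 + #\{D_b >= D_obs\}) / (B + 1)`.
#'
#' @param sample Numeric vector, at least 4 finite values.
#' @param B Number of Monte-Carlo null samples (>= 999 recommended).
#' @param seed Optional seed for reproducibility.
#' @return Object of class `dip_test`: `statistic` (D), `p.value`, `n`,
#'   `B`, `seed`.
#' @export
dip_test <- function(sample, B = 999, seed = NULL) {
  D <- dip_statistic(sample)
  n <- sum(is.finite(sample))
  if (B < 1) stop("'B' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null_dips <- dip_null_cpp(as.integer(n), as.integer(B))
  p <- (1 + sum(null_dips >= D)) / (B + 1)
  structure(list(statistic = D, p.value = p, n = n, B = as.integer(B),
                 seed = seed),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.4f (n = %d), p = %.4g (B = %d)\n",
              x$statistic, x$n, x$p.value, x$B))
  invisible(x)
}
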