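# Dixon's ratio test for a single outlier in a small sample.
#
# The ratio family follows standard practice: r10 for n <= 7, r11 for
# 8 <= n <= 10, r21 for 11 <= n <= 13, r22 for n >= 14. Critical values are
# the two-tailed tables of Rorabacher (1991, Anal. Chem. 63, 139-146), which
# correct the widely reproduced Dixon (1953) values; the test statistic is
# the ratio of the more extreme tail, so the two-tailed critical value gives
# an overall level-alpha test of "the most extreme point is an outlier".

.dixon_crit <- local({
  n <- 3:30
  q05 <- c(0.970, 0.829, 0.710, 0.625, 0.568,          # r10, n = 3..7
           0.608, 0.564, 0.530,                        # r11, n = 8..10
           0.619, 0.583, 0.557,                        # r21, n = 11..13
           0.586, 0.565, 0.546, 0.529, 0.514, 0.501,   # r22, n = 14..30
           0.489, 0.478, 0.468, 0.459, 0.451, 0.443,
           0.436, 0.429, 0.423, 0.417, 0.412)
  q01 <- c(0.994, 0.926, 0.821, 0.740, 0.680,
           0.717, 0.672, 0.635,
           0.709, 0.660, 0.638,
           0.670, 0.647, 0.627, 0.610, 0.594, 0.580,
           0.567, 0.555, 0.544, 0.535, 0.526, 0.517,
           0.510, 0.502, 0.495, 0.489, 0.483)
  data.frame(n = n, q05 = q05, q01 = q01)
})

dixon_ratio <- function(xs) {
  # xs sorted; returns Q for the low and high tail with the ratio type
  n <- length(xs)
  if (n <= 7) {
    type <- "r10"
    lo <- c(xs[2] - xs[1], xs[n] - xs[1])
    hi <- c(xs[n] - xs[n - 1], xs[n] - xs[1])
  } else if (n <= 10) {
    type <- "r11"
    lo <- c(xs[2] - xs[1], xs[n - 1] - xs[1])
    hi <- c(xs[n] - xs[n - 1], xs[n] - xs[2])
  } else if (n <= 13) {
    type <- "r21"
    lo <- c(xs[3] - xs[1], xs[n - 1] - xs[1])
    hi <- c(xs[n] - xs[n - 2], xs[n] - xs[2])
  } else {
    type <- "r22"
    lo <- c(xs[3] - xs[1], xs[n - 2] - xs[1])
    hi <- c(xs[n] - xs[n - 2], xs[n] - xs[3])
  }
  q_lo <- if (lo[2] > 0) lo[1] / lo[2] else 0
  q_hi <- if (hi[2] > 0) hi[1] / hi[2] else 0
  list(type = type, q_lo = q_lo, q_hi = q_hi)
}

#' Dixon's outlier test
#'
#' Tests whether the most extreme value of a small sample (3 to 30 points)
#' is an outlier, using the gap/range ratio appropriate for the sample size
#' and embedded two-tailed critical values. At most one point is flagged per
#' call; a zero-range sample flags nothing.
#'
#' @param values Numeric vector, 3 <= length <= 30.
#' @param alpha Significance level: 0.05 (default) or 0.01.
#' @return A list: `outlier` (logical flag), `Q` (statistic of the tested
#'   tail), `critical`, `side` ("low"/"high"), `index` (position of the
#'   flagged value in `values`, or `NA`), `ratio` (ratio family used), `n`.
#' @examples
#' dixon_outlier_test(c(1, 2, 3, 4, 100))  # Q = 96/99, flagged
#' @export
dixon_outlier_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  n <- length(values)
  if (n < 3 || n > 30)
    stop("Dixon's test is tabulated for 3 <= n <= 30", call. = FALSE)
  if (!alpha %in% c(0.05, 0.01))
    stop("'alpha' must be 0.05 or 0.01 (tabulated levels)", call. = FALSE)
  ord <- order(values)
  xs <- values[ord]
  crit <- .dixon_crit[[if (alpha == 0.05) "q05" else "q01"]][
    match(n, .dixon_crit$n)]
  if (xs[n] == xs[1])
    return(list(outlier = FALSE, Q = 0, critical = crit, side = NA_character_,
                index = NA_integer_, ratio = dixon_ratio(xs)$type, n = n))
  r <- dixon_ratio(xs)
  if (r$q_hi >= r$q_lo) {
    side <- "high"; Q <- r$q_hi; idx <- ord[n]
  } else {
    side <- "low"; Q <- r$q_lo; idx <- ord[1]
  }
  flag <- Q > crit
  list(outlier = flag, Q = Q, critical = crit, side = side,
       index = if (flag) idx else NA_integer_, ratio = r$type, n = n)
}

#' Screen replicate cells for outliers
#'
#' Applies [dixon_outlier_test()] within every treatment cell (nutrient
#' level x salinity) of a tank-observation table and marks at most one
#' outlying tank per cell. Cells outside the tabulated 3..30 size range are
#' left unscreened.
#'
#' @param observations Tank observation data frame (see
#'   [simulate_experiment()]).
#' @param alpha Significance level passed to [dixon_outlier_test()].
#' @return `observations` with a logical column `excluded`; attribute
#'   `excluded_tanks` lists the flagged tank ids.
#' @export
screen_outliers <- function(observations, alpha = 0.05) {
  stopifnot(all(c("nutrient_g", "salinity", "mortality_pct") %in%
                  names(observations)))
  excl <- logical(nrow(observations))
  for (cell in split(seq_len(nrow(observations)),
                     list(observations$nutrient_g, observations$salinity),
                     drop = TRUE)) {
    if (length(cell) < 3 || length(cell) > 30) next
    r <- dixon_outlier_test(observations$mortality_pct[cell], alpha)
    if (r$outlier) excl[cell[r$index]] <- TRUE
  }
  observations$excluded <- excl
  attr(observations, "excluded_tanks") <-
    if ("tank_id" %in% names(observations))
      observations$tank_id[excl] else which(excl)
  observations
}
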