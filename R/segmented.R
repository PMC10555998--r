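# Broken-line regression with unknown breakpoints.
#
# The mean is continuous piecewise linear:
#   E[y] = a + b0*x + sum_j bU_j * (x - psi_j)_+
# with the psi_j estimated by iterative linearization: at the current psi the
# model is augmented with V_j = -1[x > psi_j]; the coefficient gamma_j on V_j
# measures the "gap" left at psi_j and the update is
#   psi_j <- psi_j + gamma_j / bU_j
# (a first-order step towards the zero-gap solution), damped so that the
# residual sum of squares never increases.

seg_design <- function(x, psi) {
  X <- cbind(`(Intercept)` = 1, x = x)
  for (j in seq_along(psi)) X <- cbind(X, pmax(x - psi[j], 0))
  if (length(psi)) colnames(X)[2 + seq_along(psi)] <- paste0("U", seq_along(psi))
  X
}

seg_rss <- function(x, y, psi) {
  f <- .lm.fit(seg_design(x, psi), y)
  sum(f$residuals^2)
}

# interior midpoints between consecutive distinct x values
seg_midpoints <- function(x) {
  ux <- sort(unique(x))
  (ux[-1] + ux[-length(ux)]) / 2
}

# candidate breakpoint sets with >= 2 distinct x strictly inside each segment
seg_candidates <- function(x, n_breakpoints) {
  ux <- sort(unique(x))
  mids <- seg_midpoints(x)
  ok1 <- vapply(mids, function(m)
    sum(ux < m) >= 2 && sum(ux > m) >= 2, logical(1))
  if (n_breakpoints == 1) return(lapply(mids[ok1], identity))
  out <- list()
  m1 <- mids[ok1]
  for (a in m1) for (b in m1) if (a < b && sum(ux > a & ux < b) >= 2)
    out[[length(out) + 1]] <- c(a, b)
  out
}

#' Exhaustive-search broken-line fit (testing oracle)
#'
#' Fits the segmented model by exact least squares at every admissible
#' combination of candidate breakpoints (interior midpoints between
#' consecutive distinct `x`, with at least two distinct `x` per segment) and
#' returns the global minimum-RSS fit. Ties are broken in favour of the
#' smaller breakpoints. Intended as a brute-force oracle for
#' [fit_segmented()] on small data.
#'
#' @inheritParams fit_segmented
#' @return A `segmented_fit` (without standard errors for `psi`).
#' @export
brute_force_breakpoints <- function(x, y, n_breakpoints = 1) {
  stopifnot(length(x) == length(y), n_breakpoints %in% 1:2)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) > 2000) stop("brute force is for small data", call. = FALSE)
  cand <- seg_candidates(x, n_breakpoints)
  if (!length(cand))
    stop("too few distinct x values for ", n_breakpoints, " breakpoint(s)",
         call. = FALSE)
  best <- NULL; best_rss <- Inf
  for (ps in cand) {
    rss <- seg_rss(x, y, ps)
    if (rss < best_rss - 1e-12) { best <- ps; best_rss <- rss }
  }
  seg_finish(x, y, psi = best, converged = TRUE, iter = 0L,
             gap = rep(0, n_breakpoints), se_psi = rep(NA_real_, n_breakpoints))
}

# assemble a segmented_fit object from a final psi
seg_finish <- function(x, y, psi, converged, iter, gap, se_psi) {
  X <- seg_design(x, psi)
  f <- lm.fit(X, y)
  cf <- f$coefficients
  k <- length(psi)
  slopes <- cumsum(c(cf["x"], if (k) cf[paste0("U", seq_len(k))]))
  rss <- sum(f$residuals^2)
  df <- length(y) - ncol(X)
  ci <- if (k && all(is.finite(se_psi))) {
    tq <- qt(0.975, max(df, 1))
    cbind(lower = psi - tq * se_psi, upper = psi + tq * se_psi)
  } else matrix(NA_real_, k, 2, dimnames = list(NULL, c("lower", "upper")))
  structure(list(intercept = unname(cf[1]),
                 slopes = unname(slopes),
                 coef = cf,
                 psi = psi,
                 se_psi = se_psi,
                 ci = ci,
                 rss = rss,
                 fitted = f$fitted.values,
                 residuals = f$residuals,
                 df = df,
                 n = length(y),
                 n_breakpoints = k,
                 converged = converged,
                 iterations = iter,
                 gap = gap),
            class = "segmented_fit")
}

seg_iterate <- function(x, y, psi0, max_iter, tol) {
  rng <- range(x)
  mids <- seg_midpoints(x)
  k <- length(psi0)
  psi <- sort(psi0)
  rss_old <- seg_rss(x, y, psi)
  gap <- rep(NA_real_, k)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
    V <- vapply(psi, function(p) -as.numeric(x > p), numeric(length(x)))
    X <- cbind(1, x, U, V)
    f <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
    if (is.null(f) || any(is.na(f$coefficients)) ||
        f$rank < ncol(X)) break  # collinear working model
    bU <- f$coefficients[2 + seq_len(k)]
    gap <- f$coefficients[2 + k + seq_len(k)]
    if (any(abs(bU) < 1e-10)) break  # slope change vanished; psi unidentified
    if (max(abs(gap)) < tol) { converged <- TRUE; break }
    delta <- gap / bU
    step <- 1; improved <- FALSE
    while (step >= 1 / 64) {
      cand <- psi + step * delta
      # out-of-range updates are pulled back to the nearest interior midpoint
      out_lo <- cand <= rng[1]; out_hi <- cand >= rng[2]
      damp <- any(out_lo | out_hi)
      cand[out_lo] <- mids[1]
      cand[out_hi] <- mids[length(mids)]
      cand <- sort(cand)
      if (k == 2 && diff(cand) < 1e-8) { step <- step / 2; next }
      rss_new <- seg_rss(x, y, cand)
      if (rss_new <= rss_old + 1e-12) {
        psi <- cand; rss_old <- rss_new; improved <- TRUE
        if (damp) step <- step / 2  # damped after a range violation
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }  # no improving step left
  }
  list(psi = psi, rss = rss_old, converged = converged, iter = it, gap = gap)
}

#' Broken-line regression with unknown breakpoints
#'
#' Estimates a continuous piecewise-linear regression with 1 or 2 unknown
#' breakpoints by damped iterative linearization (see Details), restarted
#' from several initial values; the best (lowest-RSS) solution is returned.
#' `n_breakpoints = 0` fits an ordinary straight line in the same output
#' format.
#'
#' @details At the current estimate the working model
#'   `y ~ 1 + x + (x - psi_j)_+ + (-1[x > psi_j])` is fit by least squares;
#'   the coefficient `gamma_j` of the indicator column is the gap left in the
#'   fitted line at `psi_j` and `psi_j` is moved by `gamma_j / bU_j` (with
#'   `bU_j` the slope-change coefficient). Steps are halved until the RSS
#'   does not increase; updates leaving the observed `x` range are pulled
#'   back to the nearest interior midpoint and damped. Convergence is
#'   declared when `max |gamma_j| < tol`. The standard error of `psi_j` is
#'   the delta-method value `SE(gamma_j)/|bU_j|`.
#'
#'   Besides quantile-based initial values, a coarse grid search over
#'   candidate midpoints seeds one additional start, which makes the search
#'   robust to the local optima typical of breakpoint likelihoods.
#'
#' @param x Numeric gradient values.
#' @param y Numeric responses.
#' @param n_breakpoints 0, 1 or 2 breakpoints.
#' @param psi_init Optional numeric vector of starting breakpoints (length
#'   `n_breakpoints`, inside the range of `x`); default: quantile spread.
#' @param max_iter Maximum linearization iterations per start.
#' @param tol Convergence tolerance on the maximum absolute gap (response
#'   units).
#' @return An object of class `segmented_fit` with elements `intercept`,
#'   `slopes` (one per segment), `psi`, `se_psi`, `ci` (95%), `rss`,
#'   `fitted`, `df`, `converged`, `iterations`, `gap`.
#' @examples
#' x <- rep(seq(0, 120, 10), each = 3)
#' y <- pmax(x - 50, 0) * 0.5 + rnorm(length(x), sd = 2)
#' fit_segmented(x, y, 1)$psi
#' @export
fit_segmented <- function(x, y, n_breakpoints = 1, psi_init = NULL,
                          max_iter = 50, tol = 1e-4) {
  stopifnot(length(x) == length(y))
  if (!n_breakpoints %in% 0:2)
    stop("'n_breakpoints' must be 0, 1 or 2", call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  k <- n_breakpoints
  if (k == 0)
    return(seg_finish(x, y, numeric(0), TRUE, 0L, numeric(0), numeric(0)))
  ux <- sort(unique(x))
  if (length(ux) < 3 * (k + 1))
    stop("need at least 3 distinct x values per segment", call. = FALSE)

  starts <- list()
  if (!is.null(psi_init)) {
    psi_init <- sort(as.numeric(psi_init))
    if (length(psi_init) != k || any(psi_init <= min(x)) ||
        any(psi_init >= max(x)))
      stop("'psi_init' must be ", k, " value(s) strictly inside range(x)",
           call. = FALSE)
    starts[[1]] <- psi_init
    # one perturbed restart guards against a collinear working model
    span <- diff(range(x))
    starts[[2]] <- sort(pmin(pmax(psi_init + c(-1, 1)[seq_len(k)] *
                                    0.05 * span, min(ux) + 1e-8), max(ux) - 1e-8))
  } else {
    qs <- if (k == 1) c(0.25, 0.5, 0.75) else c(0.15, 0.35, 0.5, 0.65, 0.85)
    qv <- unname(quantile(x, qs, type = 7))
    if (k == 1) {
      starts <- as.list(unique(qv))
    } else {
      span <- diff(range(x))
      for (a in qv) for (b in qv)
        if (b - a >= 0.15 * span) starts[[length(starts) + 1]] <- c(a, b)
    }
    # coarse grid-search start (exact LS over admissible midpoints)
    cand <- seg_candidates(x, k)
    if (length(cand) && length(cand) <= 600) {
      rs <- vapply(cand, function(ps) seg_rss(x, y, ps), numeric(1))
      starts[[length(starts) + 1]] <- cand[[which.min(rs)]]
    }
  }

  best <- NULL
  for (s in starts) {
    r <- seg_iterate(x, y, s, max_iter, tol)
    if (is.null(best) || r$rss < best$rss - 1e-12 ||
        (r$rss < best$rss + 1e-12 && r$converged && !best$converged))
      best <- r
  }
  if (is.null(best))
    return(seg_finish(x, y, quantile(x, seq_len(k) / (k + 1)), FALSE, 0L,
                      rep(NA_real_, k), rep(NA_real_, k)))

  # delta-method SEs from the working model at the solution
  se_psi <- rep(NA_real_, k)
  U <- vapply(best$psi, function(p) pmax(x - p, 0), numeric(length(x)))
  V <- vapply(best$psi, function(p) -as.numeric(x > p), numeric(length(x)))
  colnames(U) <- paste0("U", seq_len(k))
  colnames(V) <- paste0("V", seq_len(k))
  dfw <- data.frame(y = y, x = x, U, V)
  wf <- tryCatch(lm(y ~ ., data = dfw), error = function(e) NULL)
  if (!is.null(wf) && !anyNA(coef(wf))) {
    sm <- suppressWarnings(summary(wf))$coefficients  # noiseless-fit chatter
    bU <- sm[paste0("U", seq_len(k)), "Estimate"]
    seg <- sm[paste0("V", seq_len(k)), "Std. Error"]
    se_psi <- unname(abs(seg / bU))
  }
  seg_finish(x, y, best$psi, best$converged, best$iter, best$gap, se_psi)
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Broken-line fit:", x$n_breakpoints, "breakpoint(s),",
      x$n, "observations\n")
  if (x$n_breakpoints) {
    for (j in seq_along(x$psi))
      cat(sprintf("  psi%d = %.3f (SE %.3f, 95%% CI %.3f..%.3f)\n", j,
                  x$psi[j], x$se_psi[j], x$ci[j, 1], x$ci[j, 2]))
  }
  cat("  slopes:", paste(sprintf("%.4g", x$slopes), collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g, converged: %s (%d iterations)\n",
              x$rss, x$converged, x$iterations))
  invisible(x)
}

#' Davies test for a breakpoint along a gradient
#'
#' Tests whether the regression of `y` on `x` changes slope somewhere along
#' the gradient, against the straight-line null. The breakpoint location is
#' a nuisance parameter that exists only under the alternative, so an
#' ordinary test at the best-fitting location would be anti-conservative;
#' instead the slope-change t statistic is evaluated on a grid of candidate
#' locations and the maximum `M` is referred to Davies' upper bound
#' `p = P(|Z| > M) + V * exp(-M^2/2) / sqrt(8 * pi)`, with `V` the total
#' variation of the signed statistics along the grid.
#'
#' @param x,y Numeric vectors (at least 6 points, more than one distinct x).
#' @param k_grid Number of candidate breakpoints (interior quantiles of x).
#' @return Object of class `davies_test`: `statistic` (M), `p.value`,
#'   `grid`, `stats` (signed t values), `K`.
#' @export
davies_test <- function(x, y, k_grid = 10) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6) stop("need at least 6 observations", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("x is degenerate (fewer than 3 distinct values)", call. = FALSE)
  if (k_grid < 2) stop("'k_grid' must be >= 2", call. = FALSE)
  grid <- unique(unname(quantile(x, (1:k_grid) / (k_grid + 1), type = 7)))
  grid <- grid[grid > min(x) & grid < max(x)]
  if (length(grid) < 2) stop("candidate grid collapsed; x too coarse",
                             call. = FALSE)
  y_scale <- max(sum((y - mean(y))^2), .Machine$double.eps)
  tstat <- vapply(grid, function(ps) {
    U <- pmax(x - ps, 0)
    f <- lm(y ~ x + U)
    if (sum(f$residuals^2) < 1e-10 * y_scale) return(0)  # perfect fit
    sm <- suppressWarnings(summary(f))$coefficients
    if (!"U" %in% rownames(sm)) return(0)
    tv <- sm["U", "t value"]
    if (!is.finite(tv)) 0 else tv
  }, numeric(1))
  M <- max(abs(tstat))
  V <- sum(abs(diff(tstat)))
  # first term on the t reference (finite-sample slope-change statistic);
  # the total-variation correction uses Davies' Gaussian bound
  p <- 2 * pt(-M, df = max(length(x) - 3, 1)) +
    V * exp(-M^2 / 2) / sqrt(8 * pi)
  p <- min(1, max(p, .Machine$double.xmin))
  structure(list(statistic = M, p.value = p, grid = grid, stats = tstat,
                 K = length(grid)),
            class = "davies_test")
}

#' @export
print.davies_test <- function(x, ...) {
  cat(sprintf("Davies test: M = %.3f over K = %d candidates, p = %.4g\n",
              x$statistic, x$K, x$p.value))
  invisible(x)
}
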