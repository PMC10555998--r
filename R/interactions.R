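# Stressor-interaction quantification on the rescaled Bliss-independence
# scale.
#
# Survival under each stressor is expressed relative to control,
# w = W / W_0. Under Bliss independence the combined relative survival is
# the product w_X * w_Y; the deviation from additivity DA = w_XY - w_X*w_Y
# measures the interaction, and its rescaled form maps interaction strength
# to [-1, 2]:
#   -1   combined stressor kills everything (extreme synergy)
#    0   exactly multiplicative (no interaction)
#    1   combined effect equals the strongest single stressor (buffering)
#    2   one stressor reverses the other (suppression)

#' Convert mortality to survival
#'
#' @param mortality_pct Mortality percentages in \[0, 100\].
#' @return `100 - mortality_pct`.
#' @export
to_survival <- function(mortality_pct) {
  if (any(!is.finite(mortality_pct)) ||
      any(mortality_pct < 0 | mortality_pct > 100))
    stop("mortality must be within [0, 100]", call. = FALSE)
  100 - mortality_pct
}

#' Deviation from additivity
#'
#' `DA = w_XY - w_X * w_Y` on the relative-survival scale. Negative values
#' mean the combination is more harmful than expected under independent
#' action (synergy), positive values less harmful (antagonism).
#'
#' @param w_x,w_y,w_xy Relative responses (survival / control survival),
#'   all >= 0. Vectorized.
#' @return Numeric DA values.
#' @export
deviation_from_additivity <- function(w_x, w_y, w_xy) {
  if (any(c(w_x, w_y, w_xy) < 0, na.rm = TRUE))
    stop("relative responses must be >= 0", call. = FALSE)
  w_xy - w_x * w_y
}

#' Rescaled deviation from additivity
#'
#' Maps DA to the interpretable \[-1, 2\] interaction scale. With
#' `E = w_X * w_Y` and `w_min = min(w_X, w_Y)`:
#' * `DA < 0`: `DA / E`, so that total mortality of the combination
#'   (`w_XY = 0`) gives -1;
#' * `DA > 0`: `DA / (w_min - E)`, so that a combined response equal to the
#'   strongest single stressor (`w_XY = w_min`) gives exactly 1;
#' * results are clipped to \[-1, 2\]; a near-zero denominator returns the
#'   clip boundary matching the sign of DA and is flagged degenerate.
#'
#' @inheritParams deviation_from_additivity
#' @param eps Numerical guard for zero DA and zero denominators.
#' @return Numeric vector in \[-1, 2\] with a logical attribute
#'   `degenerate`.
#' @examples
#' rescale_da(0.8, 0.8, 0)    # -1: combination kills everything
#' rescale_da(0.8, 0.5, 0.5)  #  1: combination = strongest stressor
#' @export
rescale_da <- function(w_x, w_y, w_xy, eps = 1e-9) {
  if (any(c(w_x, w_y, w_xy) < 0, na.rm = TRUE))
    stop("relative responses must be >= 0", call. = FALSE)
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  k <- max(length(w_x), length(w_y), length(w_xy))
  w_x <- rep_len(w_x, k); w_y <- rep_len(w_y, k); w_xy <- rep_len(w_xy, k)
  E <- w_x * w_y
  w_min <- pmin(w_x, w_y)
  DA <- w_xy - E
  out <- numeric(k)
  deg <- logical(k)
  neg <- DA < -eps
  pos <- DA > eps
  # synergy branch: scale by the expected response E
  bad <- neg & E < eps
  out[neg] <- pmax(DA[neg] / pmax(E[neg], eps), -1)
  out[bad] <- -1
  deg[bad] <- TRUE
  # antagonism branch: scale by the headroom to the strongest stressor
  den <- w_min - E
  badp <- pos & den < eps
  ok <- pos & !badp
  out[ok] <- pmin(DA[ok] / den[ok], 2)
  out[badp] <- 2
  deg[badp] <- TRUE
  out <- pmin(pmax(out, -1), 2)
  attr(out, "degenerate") <- deg
  out
}

#' Classify an interaction from its rescaled DA
#'
#' Bins (closed on the left, the last closed on both sides):
#' `[-1, -0.5)` synergy, `[-0.5, 0.5)` additive, `[0.5, 1.3)` antagonistic
#' buffering, `[1.3, 2]` suppression.
#'
#' @param rescaled_da Values in \[-1, 2\].
#' @return Factor with levels synergy, additive, buffering, suppression.
#' @export
classify_interaction <- function(rescaled_da) {
  v <- as.numeric(rescaled_da)
  if (any(!is.na(v) & (v < -1 | v > 2)))
    stop("rescaled DA must lie in [-1, 2]", call. = FALSE)
  cut(v, breaks = c(-1, -0.5, 0.5, 1.3, 2),
      labels = c("synergy", "additive", "buffering", "suppression"),
      right = FALSE, include.lowest = TRUE)
}

#' Multiplicative null model for combined mortality effects
#'
#' Combines two mortality effects under independent action:
#' `(N + SV) - N * SV`. Individuals killed by one factor cannot be killed by
#' the other, so the combined effect is capped at total mortality (1).
#'
#' @param N_effect,SV_effect Mortality proportions in \[0, 1\] (effects
#'   relative to control). Vectorized.
#' @return Predicted combined mortality proportion in \[0, 1\].
#' @export
multiplicative_null <- function(N_effect, SV_effect) {
  if (any(!is.finite(c(N_effect, SV_effect))) ||
      any(c(N_effect, SV_effect) < 0 | c(N_effect, SV_effect) > 1))
    stop("effects must be proportions in [0, 1]", call. = FALSE)
  (N_effect + SV_effect) - N_effect * SV_effect
}

#' Per-level interaction table
#'
#' Builds the full interaction record along the gradient from a
#' tank-observation table: cell mean mortalities, survival conversion,
#' relative responses, DA, rescaled DA with its class label, and the
#' multiplicative-null predicted combined mortality. The four cells used at
#' each nutrient level L are: control (0 g, first salinity level),
#' salinity-only (0 g, second level), nutrient-only (L, first level) and
#' combined (L, second level).
#'
#' @param observations Tank observations with both salinity treatments.
#' @param control_salinity,stress_salinity Labels of the baseline and
#'   stressor salinity treatments.
#' @param use `"raw"` cell means (default) or `"bath_adjusted"` means from
#'   an additive cell + bath linear model.
#' @return Data frame of class `interaction_table`, one row per nutrient
#'   level > 0.
#' @export
interaction_table <- function(observations,
                              control_salinity = "stable",
                              stress_salinity = "intrusion",
                              use = c("raw", "bath_adjusted")) {
  use <- match.arg(use)
  need <- c("nutrient_g", "salinity", "mortality_pct")
  stopifnot(all(need %in% names(observations)))
  obs <- observations
  if ("excluded" %in% names(obs)) obs <- obs[!obs$excluded, ]

  cell_means <- function(o) {
    if (use == "bath_adjusted" && "bath_id" %in% names(o)) {
      o$cell <- interaction(o$nutrient_g, o$salinity, drop = TRUE, sep = "|")
      f <- lm(mortality_pct ~ 0 + cell + factor(bath_id), data = o)
      baths <- unique(o$bath_id)
      grid <- expand.grid(cell = levels(o$cell), bath_id = baths)
      grid$pred <- predict(f, newdata = data.frame(
        cell = grid$cell, bath_id = factor(grid$bath_id)))
      agg <- aggregate(pred ~ cell, grid, mean)
      key <- do.call(rbind, strsplit(as.character(agg$cell), "|", fixed = TRUE))
      data.frame(nutrient_g = as.numeric(key[, 1]), salinity = key[, 2],
                 mean_mortality = agg$pred, stringsAsFactors = FALSE)
    } else {
      agg <- aggregate(mortality_pct ~ nutrient_g + salinity, o, mean)
      names(agg)[3] <- "mean_mortality"
      agg
    }
  }
  cm <- cell_means(obs)
  pick <- function(level, sal) {
    v <- cm$mean_mortality[cm$nutrient_g == level & cm$salinity == sal]
    if (!length(v))
      stop(sprintf("missing cell: %g g / %s", level, sal), call. = FALSE)
    v
  }
  lv0 <- min(cm$nutrient_g)
  levels_hi <- sort(setdiff(unique(cm$nutrient_g), lv0))
  if (!length(levels_hi)) stop("no nutrient levels above control", call. = FALSE)

  M0 <- pick(lv0, control_salinity)
  MY <- pick(lv0, stress_salinity)
  W0 <- 100 - M0
  WY <- 100 - MY

  rows <- lapply(levels_hi, function(L) {
    MX <- pick(L, control_salinity)
    MXY <- pick(L, stress_salinity)
    WX <- 100 - MX; WXY <- 100 - MXY
    if (W0 <= 0) {
      return(data.frame(nutrient_g = L, W0 = W0, WX = WX, WY = WY, WXY = WXY,
                        w_X = NA_real_, w_Y = NA_real_, w_XY = NA_real_,
                        DA = NA_real_, rescaled_DA = NA_real_,
                        degenerate = NA, label = NA_character_,
                        null_mortality_pct = NA_real_,
                        observed_mortality_pct = MXY, undefined = TRUE))
    }
    w_X <- WX / W0; w_Y <- WY / W0; w_XY <- WXY / W0
    DA <- deviation_from_additivity(w_X, w_Y, w_XY)
    rs <- rescale_da(w_X, w_Y, w_XY)
    # null prediction on the survival scale: W0 * w_X * w_Y, i.e. the
    # multiplicative model on mortality-effect proportions
    null_mort <- 100 - W0 * w_X * w_Y
    data.frame(nutrient_g = L, W0 = W0, WX = WX, WY = WY, WXY = WXY,
               w_X = w_X, w_Y = w_Y, w_XY = w_XY, DA = DA,
               rescaled_DA = as.numeric(rs),
               degenerate = attr(rs, "degenerate"),
               label = as.character(classify_interaction(as.numeric(rs))),
               null_mortality_pct = null_mort,
               observed_mortality_pct = MXY, undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Two-way interaction test with bath variance component
#'
#' Fits a two-way fixed-effects model (nutrient level x salinity) by
#' weighted least squares, with one-step cell-variance weights moderated
#' towards the pooled variance, and reports the F test of the interaction
#' term. The water-bath random intercept is tested by a likelihood-ratio
#' statistic referred to the 50:50 mixture of a point mass at zero and a
#' chi-square(1) (the boundary null for a variance component).
#'
#' @param observations Tank observations with >= 2 replicates per cell.
#' @param moderation Prior degrees of freedom pulling each cell variance
#'   towards the pooled variance before weighting (stabilizes the one-step
#'   weights estimated from few replicates).
#' @return Object of class `interaction_test`: `F`, `df1`, `df2`,
#'   `p.value`, `lrt_stat`, `lrt_p`, `bath_sd`.
#' @export
two_way_interaction_test <- function(observations, moderation = 24) {
  need <- c("nutrient_g", "salinity", "mortality_pct")
  stopifnot(all(need %in% names(observations)))
  obs <- observations
  if ("excluded" %in% names(obs)) obs <- obs[!obs$excluded, ]
  obs$nf <- factor(obs$nutrient_g)
  obs$sf <- factor(obs$salinity)
  if (nlevels(obs$nf) < 2 || nlevels(obs$sf) < 2)
    stop("need >= 2 levels of both factors", call. = FALSE)
  cellv <- tapply(obs$mortality_pct, interaction(obs$nf, obs$sf, drop = TRUE),
                  var)
  celln <- tapply(obs$mortality_pct, interaction(obs$nf, obs$sf, drop = TRUE),
                  length)
  if (any(celln < 2)) stop("need >= 2 replicates per cell", call. = FALSE)
  vbar <- mean(cellv, na.rm = TRUE)
  if (!is.finite(vbar) || vbar <= 0) vbar <- 1
  dfc <- celln - 1
  vsh <- (dfc * cellv + moderation * vbar) / (dfc + moderation)
  vsh[!is.finite(vsh) | vsh <= 0] <- vbar
  obs$w <- 1 / vsh[as.character(interaction(obs$nf, obs$sf, drop = TRUE))]

  fit <- lm(mortality_pct ~ nf * sf, data = obs, weights = w)
  an <- anova(fit)
  row <- "nf:sf"
  Fv <- an[row, "F value"]; df1 <- an[row, "Df"]; df2 <- an["Residuals", "Df"]
  pv <- an[row, "Pr(>F)"]

  lrt_stat <- NA_real_; lrt_p <- NA_real_; bath_sd <- NA_real_
  if ("bath_id" %in% names(obs) && length(unique(obs$bath_id)) > 1) {
    m1 <- tryCatch(
      suppressWarnings(
        lme4::lmer(mortality_pct ~ nf * sf + (1 | bath_id), data = obs,
                   weights = w, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.conv.grad = "ignore",
                     check.conv.hess = "ignore"))),
      error = function(e) NULL)
    if (!is.null(m1)) {
      m0 <- lm(mortality_pct ~ nf * sf, data = obs, weights = w)
      lrt_stat <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
      lrt_p <- if (lrt_stat <= 0) 1 else
        0.5 * pchisq(lrt_stat, df = 1, lower.tail = FALSE)
      vc <- lme4::VarCorr(m1)
      bath_sd <- attr(vc$bath_id, "stddev")[[1]]
    }
  }
  structure(list(F = Fv, df1 = df1, df2 = df2, p.value = pv,
                 lrt_stat = lrt_stat, lrt_p = lrt_p, bath_sd = bath_sd),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("Interaction F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p.value))
  if (is.finite(x$lrt_stat))
    cat(sprintf("Bath variance component: LRT = %.3f, p = %.4g (sd = %.3f)\n",
                x$lrt_stat, x$lrt_p, x$bath_sd))
  invisible(x)
}
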