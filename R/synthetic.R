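#' Build a full-factorial gradient design
#'
#' Lays out the experimental units of a two-stressor gradient experiment:
#' every nutrient level is crossed with every salinity treatment, each
#' combination replicated `replicates` times, and units are distributed over
#' `baths` blocking units (water baths). The default constants reproduce a
#' 13-level x 2-treatment x 5-replicate design: 26 treatments, 130 aquaria in
#' 6 water baths, 15 individuals per aquarium.
#'
#' @param nutrient_levels Ordered numeric vector of fertilizer masses (g).
#' @param salinity_treatments Character vector of salinity treatment labels.
#' @param replicates Replicates per treatment combination (>= 1).
#' @param baths Number of water baths (blocking units, >= 1).
#' @param individuals_per_tank Individuals placed in each aquarium (>= 1).
#' @param randomize_baths If `TRUE`, permute the bath assignment (requires
#'   `seed` for reproducibility); the default is a deterministic round-robin.
#' @param seed Optional seed used only when `randomize_baths = TRUE`.
#'
#' @return An object of class `gradient_design`: a data frame of units with
#'   columns `tank_id`, `bath_id`, `nutrient_g`, `salinity`, `n_initial`,
#'   plus attributes `nutrient_levels`, `salinity_treatments`, `replicates`,
#'   `baths`, `individuals_per_tank`.
#' @examples
#' d <- make_design()
#' nrow(d)                       # 130 experimental units
#' length(attr(d, "nutrient_levels")) * 2   # 26 treatments
#' @export
make_design <- function(nutrient_levels = seq(0, 120, by = 10),
                        salinity_treatments = c("stable", "intrusion"),
                        replicates = 5,
                        baths = 6,
                        individuals_per_tank = 15,
                        randomize_baths = FALSE,
                        seed = NULL) {
  nutrient_levels <- sort(unique(as.numeric(nutrient_levels)))
  if (length(nutrient_levels) < 2)
    stop("need at least 2 distinct nutrient levels", call. = FALSE)
  if (anyNA(nutrient_levels)) stop("nutrient levels must be finite", call. = FALSE)
  if (length(salinity_treatments) < 1 || anyDuplicated(salinity_treatments))
    stop("salinity treatments must be distinct labels", call. = FALSE)
  for (nm in c("replicates", "baths", "individuals_per_tank")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a positive whole number", nm), call. = FALSE)
  }

  units <- expand.grid(replicate = seq_len(replicates),
                       salinity = as.character(salinity_treatments),
                       nutrient_g = nutrient_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(units)
  bath_id <- rep_len(seq_len(baths), n)
  if (randomize_baths) {
    if (!is.null(seed)) set.seed(seed)
    bath_id <- sample(bath_id)
  }
  design <- data.frame(tank_id = seq_len(n),
                       bath_id = bath_id,
                       nutrient_g = units$nutrient_g,
                       salinity = units$salinity,
                       n_initial = as.integer(individuals_per_tank),
                       stringsAsFactors = FALSE)
  structure(design,
            nutrient_levels = nutrient_levels,
            salinity_treatments = as.character(salinity_treatments),
            replicates = as.integer(replicates),
            baths = as.integer(baths),
            individuals_per_tank = as.integer(individuals_per_tank),
            class = c("gradient_design", "data.frame"))
}

#' Construct a piecewise-linear mean-mortality model
#'
#' A mean model holds, for each salinity treatment, a piecewise-linear curve
#' for mean mortality (as a fraction in \[0, 1\]) along the nutrient
#' gradient: an intercept, breakpoint locations `psi` (g), and one slope per
#' segment (fraction per g). An optional variance-inflation profile adds
#' extra-binomial, logit-normal spread near the breakpoints, emulating the
#' flickering between alternative states expected close to a tipping point.
#'
#' @param treatments Named list; each element is a list with fields
#'   `intercept`, `psi` (possibly empty numeric) and `slopes`
#'   (length `length(psi) + 1`).
#' @param inflation_sd Maximum logit-scale standard deviation of the
#'   extra-binomial jitter, reached at a breakpoint (0 disables inflation).
#' @param inflation_window Half-width (g) of the linear inflation ramp
#'   around each breakpoint.
#' @return An object of class `mean_model`.
#' @seealso [preset_scenarios()] for ready-made scenarios.
#' @export
mean_model <- function(treatments, inflation_sd = 0, inflation_window = 25) {
  if (!is.list(treatments) || is.null(names(treatments)) ||
      any(!nzchar(names(treatments))))
    stop("'treatments' must be a named list", call. = FALSE)
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    psi <- as.numeric(tr$psi %||% numeric(0))
    if (length(psi) && (is.unsorted(psi, strictly = TRUE)))
      stop(sprintf("breakpoints for '%s' must be strictly increasing", nm),
           call. = FALSE)
    if (length(tr$slopes) != length(psi) + 1)
      stop(sprintf("'%s' needs one slope per segment (%d)", nm,
                   length(psi) + 1), call. = FALSE)
    treatments[[nm]] <- list(intercept = as.numeric(tr$intercept),
                             psi = psi, slopes = as.numeric(tr$slopes))
  }
  if (inflation_sd < 0 || inflation_window <= 0)
    stop("inflation parameters must be non-negative (window positive)",
         call. = FALSE)
  structure(list(treatments = treatments,
                 inflation_sd = inflation_sd,
                 inflation_window = inflation_window),
            class = "mean_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ready-made simulation scenarios
#'
#' Three scenarios with known piecewise-linear truth:
#' \describe{
#'   \item{`stable_single_threshold`}{flat low mortality up to a single
#'     breakpoint at 70 g, rising beyond it.}
#'   \item{`intrusion_double_threshold`}{rise-fall-rise shape with
#'     breakpoints at 26.91 g and 84.13 g.}
#'   \item{`null_flat`}{constant mortality, no breakpoint.}
#' }
#' Every salinity treatment in the design receives the same curve, so each
#' scenario isolates one mean structure for calibration and recovery studies.
#'
#' @param name Scenario name (see above).
#' @param salinity_treatments Treatment labels the model should cover.
#' @param variance_inflation If `TRUE`, switch on near-threshold
#'   variance inflation (logit-sd 1.5 within 25 g of a breakpoint); the
#'   default leaves the mortality noise purely binomial (plus bath effects).
#' @return A [mean_model()] object.
#' @examples
#' preset_scenarios("stable_single_threshold")$treatments$stable$psi  # 70
#' @export
preset_scenarios <- function(name,
                             salinity_treatments = c("stable", "intrusion"),
                             variance_inflation = FALSE) {
  curves <- list(
    stable_single_threshold = list(intercept = 0.05, psi = 70,
                                   slopes = c(0, 0.012)),
    intrusion_double_threshold = list(intercept = 0.08,
                                      psi = c(26.91, 84.13),
                                      slopes = c(0.015, -0.0045, 0.012)),
    null_flat = list(intercept = 0.15, psi = numeric(0), slopes = 0)
  )
  if (length(name) != 1 || !name %in% names(curves))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(curves), collapse = ", "),
         call. = FALSE)
  tr <- curves[[name]]
  treatments <- setNames(rep(list(tr), length(salinity_treatments)),
                         salinity_treatments)
  infl <- if (variance_inflation && length(tr$psi)) 1.5 else 0
  mean_model(treatments, inflation_sd = infl, inflation_window = 25)
}

#' Evaluate a mean model along the gradient
#'
#' @param model A [mean_model()].
#' @param x Nutrient levels (g).
#' @param treatment Treatment label to evaluate.
#' @param clip Clip the predicted mean to \[0, 1\] (the default).
#' @return Mean mortality fractions.
#' @export
predict_mean_model <- function(model, x, treatment, clip = TRUE) {
  tr <- model$treatments[[treatment]]
  if (is.null(tr)) stop("treatment '", treatment, "' not in model", call. = FALSE)
  p <- tr$intercept + tr$slopes[1] * x
  for (j in seq_along(tr$psi))
    p <- p + (tr$slopes[j + 1] - tr$slopes[j]) * pmax(x - tr$psi[j], 0)
  if (clip) pmin(pmax(p, 0), 1) else p
}

#' Simulate a gradient experiment with binomial mortality
#'
#' Draws tank-level mortality counts around the piecewise-linear mean
#' structure of `model`: `n_dead ~ Binomial(n_initial, p)` where
#' `p = clip(mean + bath effect, 0, 1)`, with one Normal(0, `bath_sd`) bath
#' effect per water bath. If the model carries a variance-inflation profile,
#' `p` additionally receives logit-normal jitter whose standard deviation
#' ramps linearly from 0 at `inflation_window` g away from a breakpoint to
#' `inflation_sd` at the breakpoint.
#'
#' @param design A [make_design()] object.
#' @param model A [mean_model()] covering every salinity treatment of the
#'   design.
#' @param bath_sd Standard deviation of the bath random effect on the
#'   probability scale (>= 0).
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return Data frame of tank observations: `tank_id`, `bath_id`,
#'   `nutrient_g`, `salinity`, `n_initial`, `n_dead`, `mortality_pct`.
#'   Attribute `n_clipped` counts units whose raw mean fell outside \[0, 1\].
#' @examples
#' obs <- simulate_experiment(make_design(),
#'                            preset_scenarios("stable_single_threshold"),
#'                            seed = 1)
#' head(obs)
#' @export
simulate_experiment <- function(design, model, bath_sd = 0.02, seed = NULL) {
  if (!inherits(design, "gradient_design"))
    stop("'design' must come from make_design()", call. = FALSE)
  if (!inherits(model, "mean_model"))
    stop("'model' must be a mean_model()", call. = FALSE)
  missing_tr <- setdiff(unique(design$salinity), names(model$treatments))
  if (length(missing_tr))
    stop("mean model lacks treatment(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  if (length(bath_sd) != 1 || !is.finite(bath_sd) || bath_sd < 0)
    stop("'bath_sd' must be a single non-negative number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(design)
  bath_eff <- rnorm(max(design$bath_id), 0, bath_sd)
  raw <- numeric(n)
  for (tr in unique(design$salinity)) {
    i <- design$salinity == tr
    raw[i] <- predict_mean_model(model, design$nutrient_g[i], tr, clip = FALSE)
  }
  n_clipped <- sum(raw < 0 | raw > 1)
  if (n_clipped > 0)
    warning(sprintf("%d unit(s) had a raw mean outside [0, 1]; clipped",
                    n_clipped), call. = FALSE)
  p <- pmin(pmax(raw + bath_eff[design$bath_id], 0), 1)

  if (model$inflation_sd > 0) {
    sd_i <- numeric(n)
    for (tr in unique(design$salinity)) {
      i <- design$salinity == tr
      psi <- model$treatments[[tr]]$psi
      if (length(psi)) {
        dmin <- do.call(pmin, lapply(psi, function(ps)
          abs(design$nutrient_g[i] - ps)))
        sd_i[i] <- model$inflation_sd *
          pmax(0, 1 - dmin / model$inflation_window)
      }
    }
    j <- sd_i > 0 & p > 0 & p < 1
    if (any(j))
      p[j] <- plogis(qlogis(p[j]) + rnorm(sum(j), 0, sd_i[j]))
  }

  n_dead <- rbinom(n, design$n_initial, p)
  out <- data.frame(tank_id = design$tank_id,
                    bath_id = design$bath_id,
                    nutrient_g = design$nutrient_g,
                    salinity = design$salinity,
                    n_initial = design$n_initial,
                    n_dead = n_dead,
                    mortality_pct = 100 * n_dead / design$n_initial,
                    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- n_clipped
  out
}
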