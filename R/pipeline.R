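# End-to-end analysis pipeline:
#   outlier screening -> broken-line fits + Davies test per salinity
#   treatment -> variance / dip diagnostics -> interaction classification.

#' Pipeline configuration
#'
#' @param input Path to a tidy CSV of tank observations (exclusive with
#'   `scenario`).
#' @param scenario Name of a [preset_scenarios()] scenario to simulate
#'   (exclusive with `input`).
#' @param seed Root seed; all stage-level randomness derives from it
#'   (stage seed = `seed * 1000 + stage index`).
#' @param davies_k Davies-test grid size.
#' @param breakpoints Breakpoint counts to try per treatment.
#' @param dip_B Monte-Carlo replicates of the dip test.
#' @param span Variance-profile smoother span.
#' @param outlier_alpha Level of the Dixon screening (NA skips screening).
#' @param variance_inflation Passed to [preset_scenarios()] when simulating.
#' @param use_means Cell means used by the interaction table: `"raw"` or
#'   `"bath_adjusted"`.
#' @param out_dir Optional output directory for the JSON report and CSV
#'   tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, seed = 1,
                            davies_k = 10, breakpoints = 0:2, dip_B = 999,
                            span = 0.75, outlier_alpha = 0.05,
                            variance_inflation = FALSE,
                            use_means = "raw", out_dir = NULL) {
  if (is.null(input) == is.null(scenario))
    stop("exactly one of 'input' and 'scenario' must be given", call. = FALSE)
  for (nm in c("seed", "davies_k", "dip_B", "span"))
    if (get(nm) <= 0) stop("'", nm, "' must be positive", call. = FALSE)
  if (!all(breakpoints %in% 0:2))
    stop("'breakpoints' must be a subset of 0:2", call. = FALSE)
  structure(list(input = input, scenario = scenario, seed = as.integer(seed),
                 davies_k = davies_k, breakpoints = sort(breakpoints),
                 dip_B = dip_B, span = span, outlier_alpha = outlier_alpha,
                 variance_inflation = variance_inflation,
                 use_means = use_means, out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(config, k) config$seed * 1000L + k

seg_bic <- function(fit) {
  # Gaussian BIC; +1 parameter for the residual variance
  n <- fit$n
  npar <- 2 + 2 * fit$n_breakpoints + 1
  n * log(fit$rss / n) + npar * log(n)
}

#' Run the full tipping-point analysis pipeline
#'
#' Stages, in order: (1) load or simulate the experiment; (2) Dixon outlier
#' screening per treatment cell; (3) per salinity treatment, broken-line
#' fits with 0/1/2 breakpoints, a Davies test gating breakpoint existence,
#' and BIC selection among the gated fits; (4) variance profile and dip
#' test per treatment; (5) interaction table and two-way interaction test
#' (skipped and logged when only one treatment is present). The report is
#' self-contained: re-running with the same config and seed reproduces it
#' bit for bit.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()", call. = FALSE)
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)

  # stage 1: data
  if (!is.null(config$input)) {
    obs <- read_experiment(config$input)
    note(paste("loaded", nrow(obs), "units from", config$input))
  } else {
    model <- preset_scenarios(config$scenario,
                              variance_inflation = config$variance_inflation)
    obs <- simulate_experiment(make_design(), model,
                               seed = stage_seed(config, 1L))
    note(paste("simulated scenario", config$scenario))
  }

  # stage 2: outlier screening
  if (!is.na(config$outlier_alpha)) {
    obs <- screen_outliers(obs, alpha = config$outlier_alpha)
    excl <- attr(obs, "excluded_tanks")
    note(paste("Dixon screening excluded", length(excl), "tank(s)",
               if (length(excl)) paste0("(ids: ",
                                        paste(excl, collapse = ", "), ")")
               else ""))
  } else {
    obs$excluded <- FALSE
    excl <- integer(0)
  }
  kept <- obs[!obs$excluded, ]

  # stage 3 + 4: per-treatment threshold analysis and diagnostics
  treatments <- list()
  for (tr in sort(unique(kept$salinity))) {
    oc <- kept[kept$salinity == tr, ]
    x <- oc$nutrient_g; y <- oc$mortality_pct
    fits <- list()
    for (k in config$breakpoints) {
      fits[[as.character(k)]] <- tryCatch(
        fit_segmented(x, y, n_breakpoints = k),
        error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
    dav <- tryCatch(davies_test(x, y, k_grid = config$davies_k),
                    error = function(e) NULL)
    gate_open <- !is.null(dav) && dav$p.value < 0.05
    cand <- if (gate_open) setdiff(names(fits), "0") else intersect(names(fits), "0")
    if (!length(cand)) cand <- names(fits)
    bics <- vapply(fits[cand], seg_bic, numeric(1))
    selected <- cand[which.min(bics)]

    vp <- tryCatch(variance_profile(oc, span = config$span),
                   error = function(e) NULL)
    dt <- tryCatch(dip_test(oc$mortality_pct, B = config$dip_B,
                            seed = stage_seed(config, 4L)),
                   error = function(e) NULL)
    treatments[[tr]] <- list(fits = fits, davies = dav,
                             selected = selected,
                             selected_fit = fits[[selected]],
                             variance = vp, dip = dt)
    note(sprintf("treatment %s: Davies p = %s, selected %s breakpoint(s)",
                 tr, if (is.null(dav)) "NA" else format(dav$p.value,
                                                        digits = 4),
                 selected))
  }

  # stage 5: interactions
  inter <- NULL; itest <- NULL
  if (length(unique(kept$salinity)) >= 2) {
    inter <- tryCatch(interaction_table(kept, use = config$use_means),
                      error = function(e) { note(paste("interaction stage:",
                                                       conditionMessage(e)))
                        NULL })
    itest <- tryCatch(two_way_interaction_test(kept),
                      error = function(e) NULL)
  } else {
    note("single-treatment data: interaction stage skipped")
  }

  report <- structure(list(observations = obs,
                           excluded_tanks = excl,
                           treatments = treatments,
                           interactions = inter,
                           interaction_test = itest,
                           log = log,
                           provenance = list(
                             seed = config$seed,
                             config = unclass(config),
                             package_version =
                               as.character(packageVersion("tipstress")))),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Produces `report.json` (the structured result), `observations.csv`, and
#' `interactions.csv` (when present) in `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    provenance = report$provenance,
    excluded_tanks = report$excluded_tanks,
    log = report$log,
    treatments = lapply(report$treatments, function(tr) list(
      selected = tr$selected,
      psi = tr$selected_fit$psi,
      se_psi = tr$selected_fit$se_psi,
      ci = tr$selected_fit$ci,
      slopes = tr$selected_fit$slopes,
      rss = tr$selected_fit$rss,
      converged = tr$selected_fit$converged,
      davies = if (!is.null(tr$davies))
        list(statistic = tr$davies$statistic, p = tr$davies$p.value,
             K = tr$davies$K),
      variance_levels = tr$variance$levels,
      dip = if (!is.null(tr$dip))
        list(D = tr$dip$statistic, p = tr$dip$p.value, n = tr$dip$n,
             B = tr$dip$B))),
    interaction_test = if (!is.null(report$interaction_test))
      unclass(report$interaction_test))
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = 12, pretty = TRUE, force = TRUE)
  write_experiment(report$observations, file.path(dir, "observations.csv"))
  if (!is.null(report$interactions))
    write.csv(report$interactions, file.path(dir, "interactions.csv"),
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Tipping-point pipeline report\n")
  cat("  units:", nrow(x$observations), " excluded:",
      length(x$excluded_tanks), "\n")
  for (tr in names(x$treatments)) {
    t <- x$treatments[[tr]]
    cat(sprintf("  %s: %s breakpoint(s)%s, Davies p = %s, dip p = %s\n", tr,
                t$selected,
                if (length(t$selected_fit$psi))
                  paste0(" at ", paste(sprintf("%.1f", t$selected_fit$psi),
                                       collapse = ", "), " g") else "",
                if (is.null(t$davies)) "NA" else
                  format(t$davies$p.value, digits = 3),
                if (is.null(t$dip)) "NA" else
                  format(t$dip$p.value, digits = 3)))
  }
  if (!is.null(x$interaction_test))
    print(x$interaction_test)
  invisible(x)
}
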