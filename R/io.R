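# Tidy CSV interface: one row per experimental unit (tank).

.exp_cols <- c("tank_id", "bath_id", "nutrient_g", "salinity",
               "n_initial", "n_dead", "mortality_pct")

#' Write a tank-observation table as tidy CSV
#'
#' @param observations Tank observation data frame.
#' @param path Output file.
#' @export
write_experiment <- function(observations, path) {
  cols <- intersect(.exp_cols, names(observations))
  write.csv(observations[cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the simulation-truth sidecar
#'
#' Records the generating mean model and seed next to a simulated data set
#' so parameter-recovery analyses can compare estimates against truth.
#'
#' @param model The generating [mean_model()].
#' @param seed Seed used in [simulate_experiment()].
#' @param path Output JSON file.
#' @export
write_truth <- function(model, seed, path) {
  jsonlite::write_json(list(treatments = model$treatments,
                            inflation_sd = model$inflation_sd,
                            inflation_window = model$inflation_window,
                            seed = seed),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tank-observation table from tidy CSV
#'
#' Validates the schema: required identifying columns, non-negative counts,
#' `n_dead <= n_initial`, and consistency of `mortality_pct` with the counts
#' (recomputed when both are present). Files carrying only `mortality_pct`
#' (no counts) are accepted; the count columns are then `NA` and the result
#' carries attribute `counts_present = FALSE`.
#'
#' @param path CSV file with header.
#' @return Validated tank observation data frame.
#' @export
read_experiment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("nutrient_g", "salinity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_counts <- all(c("n_initial", "n_dead") %in% names(d))
  if (!has_counts && !"mortality_pct" %in% names(d))
    stop("need either count columns (n_initial, n_dead) or mortality_pct",
         call. = FALSE)
  if (!"tank_id" %in% names(d)) d$tank_id <- seq_len(nrow(d))
  if (!"bath_id" %in% names(d)) d$bath_id <- NA_integer_
  if (!is.numeric(d$nutrient_g) || anyNA(d$nutrient_g))
    stop("column 'nutrient_g' must be numeric and complete", call. = FALSE)
  if (has_counts) {
    bad <- which(d$n_dead < 0 | d$n_initial <= 0)
    if (length(bad))
      stop("negative counts in row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    bad <- which(d$n_dead > d$n_initial)
    if (length(bad))
      stop("n_dead > n_initial in row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    mort <- 100 * d$n_dead / d$n_initial
    if ("mortality_pct" %in% names(d)) {
      bad <- which(abs(d$mortality_pct - mort) > 1e-6)
      if (length(bad))
        stop("mortality_pct inconsistent with counts in row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    d$mortality_pct <- mort
  } else {
    d$n_initial <- NA_integer_
    d$n_dead <- NA_integer_
  }
  bad <- which(d$mortality_pct < 0 | d$mortality_pct > 100)
  if (length(bad))
    stop("mortality_pct outside [0, 100] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- d[intersect(.exp_cols, names(d))]
  attr(out, "counts_present") <- has_counts
  out
}
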