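#' Shuffling-model predictions for all 16 subsets
#'
#' Computes the prediction table for every non-empty structured subset, or
#' for its time-/space-mixed counterpart, with subset metadata attached.
#'
#' @param subsets a [build_structured_subsets()] result.
#' @param mode `"structured"`, `"time"` (time-mixed) or `"space"`
#'   (space-mixed).
#' @param seed integer seed for mixed-dataset sampling.
#' @return data frame with columns `subset_key`, `combo`, `S`, `actual`, `k`,
#'   `space`, `time`.
#' @export
predictions_for_subsets <- function(subsets,
                                    mode = c("structured", "time", "space"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  out <- list()
  for (key in names(subsets$subsets)) {
    idx <- subsets$subsets[[key]]
    if (!length(idx)) next
    if (mode != "structured") {
      idx <- build_mixed(key, subsets, mode,
                         derive_seed(seed, match(key,
                                                 names(subsets$subsets))))
    }
    p <- strsplit(key, "-", fixed = TRUE)[[1L]]
    pred <- table_predictions(subsets$table, idx, as.integer(p[3L]))
    if (!nrow(pred)) next
    pred$subset_key <- key
    pred$space <- p[2L]
    pred$time <- p[1L]
    out[[key]] <- pred
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' End-to-end generative inference
#'
#' From an observed series of snapshots: estimates yearly turnover and the
#' zip distribution, builds a reference table of prior-drawn simulations from
#' the earliest snapshot, fits one random forest per parameter, and extracts
#' both posteriors for the observed summary vector.
#'
#' @param observed named list of [brand_population] snapshots (yearly).
#' @param n_sims reference-table size (desk default 5000; the full-scale
#'   setting is 500000).
#' @param n_trees trees per forest (desk default 500; full-scale 1000).
#' @param spec a [prior_spec].
#' @param snapshot_years years summarised for ABC (default
#'   [default_snapshot_years()] of the observed span).
#' @param seed integer root seed; every stage derives its own stream.
#' @param out_file optional path: write the posterior report as JSON.
#' @return list of class `inference_report` with `posterior_lambda`,
#'   `posterior_C`, `turnover`, `observed_stats`, and the fitted forests.
#' @export
run_generative_inference <- function(observed, n_sims = 5000, n_trees = 500,
                                     spec = prior_spec(),
                                     snapshot_years = NULL, seed = 1L,
                                     out_file = NULL) {
  years <- vapply(observed, function(p) p$year, integer(1))
  if (is.null(snapshot_years))
    snapshot_years <- default_snapshot_years(years)
  turn <- estimate_turnover(observed)
  base <- list(N_new = turn$N_new, N_old = turn$N_old,
               zip_probs = turn$zip_probs,
               years = seq(min(years), max(years)))
  observed_stats <- summarize_series(observed, snapshot_years,
                                     seed = derive_seed(seed, 1))
  table <- build_reference_table(n_sims, spec, observed[[1L]], base,
                                 snapshot_years,
                                 seed = derive_seed(seed, 2))
  fit_l <- fit_forest(table, "lambda", n_trees, seed = derive_seed(seed, 3))
  fit_C <- fit_forest(table, "C", n_trees, seed = derive_seed(seed, 4))
  report <- structure(list(
    posterior_lambda = posterior_abc(fit_l, observed_stats),
    posterior_C = posterior_abc(fit_C, observed_stats),
    turnover = turn, observed_stats = observed_stats,
    reference = list(table = table, fit_lambda = fit_l, fit_C = fit_C),
    config = list(n_sims = n_sims, n_trees = n_trees,
                  snapshot_years = snapshot_years, seed = seed)),
    class = "inference_report")
  if (!is.null(out_file)) write_inference_json(report, out_file)
  report
}

write_inference_json <- function(report, path) {
  out <- list(
    lambda = list(median = report$posterior_lambda$median,
                  ci95 = report$posterior_lambda$ci95,
                  samples = report$posterior_lambda$samples),
    C = list(median = report$posterior_C$median,
             ci95 = report$posterior_C$ci95,
             samples = report$posterior_C$samples),
    config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shuffle year and zip labels across brands
#'
#' Permutes, across the distinct brands of a series, which brand carries
#' which temporal trajectory (presence across snapshots) and which zip,
#' leaving the multiset of brand designs unchanged; then rebuilds the yearly
#' snapshots. This destroys temporal and spatial structure while preserving
#' marginal composition.
#'
#' @param observed named list of [brand_population] snapshots.
#' @param seed integer seed.
#' @return named list of snapshots with the same years.
#' @export
mix_population_labels <- function(observed, seed = 1L) {
  years <- vapply(observed, function(p) p$year, integer(1))
  comp <- do.call(rbind, lapply(observed, function(p) p$components))
  zip <- unlist(lapply(observed, function(p) p$zip), use.names = FALSE)
  fy <- unlist(lapply(observed, function(p) p$first_year), use.names = FALSE)
  snap <- rep.int(years, vapply(observed, n_brands, integer(1)))
  key <- paste(comp[, 1L], comp[, 2L], comp[, 3L], comp[, 4L], zip, fy,
               sep = "_")
  # identical codes can legitimately co-occur within a year; keep each
  # occurrence as its own brand so snapshot sizes are preserved exactly
  occ <- stats::ave(rep(1L, length(key)), key, snap, FUN = seq_along)
  key <- paste(key, occ, sep = "#")
  first <- !duplicated(key)
  ids <- match(key, unique(key))
  n_distinct <- max(ids)
  set.seed(seed)
  perm_year <- sample.int(n_distinct)   # trajectory reassignment
  perm_zip <- sample.int(n_distinct)
  u_rows <- which(first)
  traj <- split(snap, ids)
  zip_u <- zip[u_rows]
  fy_mixed <- vapply(traj[perm_year], min, integer(1))
  out <- lapply(years, function(y) {
    in_y <- which(vapply(traj[perm_year], function(tr) y %in% tr,
                         logical(1)))
    rows <- u_rows[in_y]
    brand_population(comp[rows, , drop = FALSE],
                     zip_u[perm_zip[in_y]],
                     fy_mixed[in_y], NA_integer_, y,
                     observed[[1L]]$symbols, observed[[1L]]$spatial)
  })
  names(out) <- as.character(years)
  out
}

#' Generative inference on time- and space-shuffled data
#'
#' Randomly permutes the years and locations of the observed brands (seeded)
#' and reruns [run_generative_inference()]; used to check that detected
#' signals of copying are robust to averaging.
#'
#' @inheritParams run_generative_inference
#' @return an `inference_report`.
#' @export
run_mixed_inference <- function(observed, n_sims = 5000, n_trees = 500,
                                spec = prior_spec(), snapshot_years = NULL,
                                seed = 1L, out_file = NULL) {
  mixed <- mix_population_labels(observed, derive_seed(seed, 99))
  run_generative_inference(mixed, n_sims, n_trees, spec, snapshot_years,
                           seed, out_file)
}

#' End-to-end averaging experiment
#'
#' Builds the 16 structured subsets, their time- and space-mixed
#' counterparts, computes shuffling-model predictions for all of them,
#' assembles both regression tables, and fits the full mixed model plus the
#' AIC ladder and ICCs for each comparison. Also returns the confusion
#' counts per structured subset.
#'
#' @param table a `brand_table` (see [pool_brands()] or
#'   [generate_wholesale_copy_table()]).
#' @param seed integer seed.
#' @return list of class `averaging_report`.
#' @export
run_averaging_experiment <- function(table, seed = 1L) {
  subsets <- build_structured_subsets(table)
  structured <- predictions_for_subsets(subsets, "structured")
  time_mixed <- predictions_for_subsets(subsets, "time",
                                        derive_seed(seed, 1))
  space_mixed <- predictions_for_subsets(subsets, "space",
                                         derive_seed(seed, 2))
  rows_time <- assemble_model_table(structured, time_mixed)
  rows_space <- assemble_model_table(structured, space_mixed)
  confusion <- t(vapply(split(structured, structured$subset_key),
                        classify_predictions, integer(4)))
  structure(list(
    subsets = subsets,
    fit_time = fit_lmm(rows_time, 3), fit_space = fit_lmm(rows_space, 3),
    ladder_time = aic_ladder(rows_time), ladder_space = aic_ladder(rows_space),
    icc_time = icc(rows_time), icc_space = icc(rows_space),
    confusion = confusion,
    rows_time = rows_time, rows_space = rows_space),
    class = "averaging_report")
}
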