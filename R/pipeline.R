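#' Forecast trajectories for every sampled parameter set
#'
#' Re-runs the forward model from the first fitted visit once per sampled
#' parameter set, returning fields at the requested days.
#'
#' @param result A [calibrate()] result.
#' @param dataset The [animal_dataset()] it was calibrated on.
#' @param output_days Days at which fields are needed (default: all visit
#'   days from the first fitted visit on).
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @return List of [simulate_growth()] trajectories, one per sampled set.
#' @export
forecast_ensemble <- function(result, dataset, output_days = NULL,
                              mech = mechanical_params(),
                              control = solver_control()) {
  grid <- dataset$grid
  first <- dataset$visits[[result$fitted_visits[1]]]
  if (is.null(output_days)) {
    days <- vapply(dataset$visits, function(v) v$day, numeric(1))
    output_days <- days[days >= first$day]
  }
  use_mech <- isTRUE(control$mechanics) && mech$lambda1 > 0
  op <- if (use_mech) cached_elasticity_operator(grid, mech) else NULL
  lapply(result$sampled_sets, function(ps)
    simulate_growth(grid, first$phi_T, first$phi_V, result$capacity, ps,
                    result$spec, t0 = first$day,
                    rt_events = dataset$rt_events,
                    output_days = output_days, mech = mech,
                    control = control, op = op))
}

# weighted per-sample combination of model trajectories: the j-th ensemble
# trajectory pairs the j-th parameter draw of every model
combine_trajectories <- function(traj_by_model, weights) {
  J <- length(traj_by_model[[1]])
  days <- traj_by_model[[1]][[1]]$days
  lapply(seq_len(J), function(j) {
    pT <- lapply(as.character(days), function(key) {
      Reduce(`+`, Map(function(trs, w) w * trs[[j]]$phi_T[[key]],
                      traj_by_model, weights))
    })
    pV <- lapply(as.character(days), function(key) {
      Reduce(`+`, Map(function(trs, w) w * trs[[j]]$phi_V[[key]],
                      traj_by_model, weights))
    })
    names(pT) <- names(pV) <- as.character(days)
    structure(list(days = days, phi_T = pT, phi_V = pV), class = "growth_trajectory")
  })
}

#' AIC table for a set of calibration results
#'
#' @param results List of [calibrate()] results.
#' @return Data frame with spec token, `k`, `n_obs`, `RSS`, `AIC`, `delta`
#'   and Akaike `weight`.
#' @export
aic_table <- function(results) {
  a <- vapply(results, function(r) r$AIC, numeric(1))
  w <- akaike_weights(a)
  data.frame(spec = vapply(results, function(r) spec_token(r$spec), character(1)),
             k = vapply(results, function(r) r$k, numeric(1)),
             n_obs = vapply(results, function(r) r$n_obs, numeric(1)),
             RSS = vapply(results, function(r) r$RSS, numeric(1)),
             AIC = a, delta = a - min(a[is.finite(a)]), weight = w)
}

#' Run the full analysis pipeline on one dataset
#'
#' Calibrates every requested family member, computes the AICc table and
#' Akaike weights, selects the lowest-AIC member, propagates the sampled
#' parameter sets into per-member forecast trajectories, forms the
#' Akaike-weighted ensemble, evaluates the global/local agreement metrics for
#' the selected member and the ensemble at the comparison visits (all fitted
#' visits after the first in scenario 1; the held-out visits in scenario 2),
#' and tests selected-vs-ensemble differences per metric. Optionally writes
#' CSV/JSON/NIfTI artifacts.
#'
#' @param dataset An [animal_dataset()].
#' @param specs List of [model_spec()]s (default: the full 18-member family).
#' @param scenario 1 or 2.
#' @param seed Root seed; per-member seeds are derived from it.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param sa A [sa_control()].
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @param n_samples Parameter draws per member (default 100).
#' @param bounds Calibration bounds (default [default_bounds()]).
#' @param fixed Named list of parameters held fixed in every calibration.
#' @return List of class `pipeline_result`: `results`, `aic_table`,
#'   `selected` (spec), `metrics_selected`, `metrics_ensemble`,
#'   `comparison_pvalues`, `comparison_days`, `seed`.
#' @export
run_pipeline <- function(dataset, specs = enumerate_models(), scenario = 1,
                         seed = 1L, outdir = NULL, sa = sa_control(),
                         mech = mechanical_params(),
                         control = solver_control(), n_samples = 100,
                         bounds = NULL, fixed = list()) {
  vis <- scenario_visits(dataset, scenario)
  days <- vapply(dataset$visits, function(v) v$day, numeric(1))
  comparison_days <- if (scenario == 1) days[vis$fitted][-1] else days[vis$held_out]
  if (length(comparison_days) == 0) stop("no comparison visits for this scenario")

  results <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    results[[i]] <- calibrate(dataset, specs[[i]], scenario = scenario,
                              bounds = bounds, seed = seed + 37L * i,
                              fixed = fixed, sa = sa, mech = mech,
                              control = control, n_samples = n_samples)
  }
  tab <- aic_table(results)
  selected_spec <- select_model(results)
  sel_idx <- which(vapply(results, function(r)
    identical(spec_token(r$spec), spec_token(selected_spec)), logical(1)))[1]

  out_days <- sort(unique(c(days[vis$fitted][1], comparison_days)))
  traj <- lapply(results, forecast_ensemble, dataset = dataset,
                 output_days = out_days, mech = mech, control = control)
  ens_traj <- combine_trajectories(traj, tab$weight)

  met_sel <- evaluate_forecast(traj[[sel_idx]], dataset, comparison_days)
  met_ens <- evaluate_forecast(ens_traj, dataset, comparison_days)
  metrics <- setdiff(names(met_sel$per_set), "sample")
  pvals <- vapply(metrics, function(m)
    compare_selected_vs_ensemble(met_sel$per_set[[m]], met_ens$per_set[[m]]),
    numeric(1))

  res <- structure(list(results = results, aic_table = tab,
                        selected = selected_spec,
                        metrics_selected = met_sel,
                        metrics_ensemble = met_ens,
                        comparison_pvalues = pvals,
                        comparison_days = comparison_days,
                        scenario = scenario, seed = seed),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_artifacts(res, dataset, traj, ens_traj, outdir)
  res
}

write_pipeline_artifacts <- function(res, dataset, traj, ens_traj, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$aic_table, file.path(outdir, "aic_table.csv"), row.names = FALSE)
  for (r in res$results) {
    token <- spec_token(r$spec)
    jsonlite::write_json(
      list(spec = token, theta_hat = as.list(r$theta_hat), RSS = r$RSS,
           k = r$k, n_obs = r$n_obs, AIC = r$AIC, seed = r$seed,
           scenario = r$scenario, ci95 = r$ci95),
      file.path(outdir, sprintf("calibration_%s.json", token)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  long <- function(rep, who) transform(rep$per_visit, model = who)
  metrics_long <- rbind(long(res$metrics_selected, "selected"),
                        long(res$metrics_ensemble, "ensemble"))
  utils::write.csv(metrics_long, file.path(outdir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(selected = spec_token(res$selected), scenario = res$scenario,
         seed = res$seed, comparison_days = res$comparison_days,
         comparison_pvalues = as.list(res$comparison_pvalues),
         metrics_selected = res$metrics_selected$summary,
         metrics_ensemble = res$metrics_ensemble$summary),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # ensemble mean field at the last comparison day
  key <- as.character(max(res$comparison_days))
  fields <- lapply(seq_along(traj), function(i) lapply(traj[[i]], function(tr) tr$phi_T[[key]]))
  ens <- ensemble_average(fields, res$aic_table$weight)
  write_field_nifti(ens, dataset$grid, file.path(outdir, sprintf("ensemble_phiT_day%s.nii.gz", key)))
  invisible(outdir)
}

#' @export
#' @method print pipeline_result
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: scenario %d, %d members, selected %s\n",
              x$scenario, nrow(x$aic_table), spec_token(x$selected)))
  print(x$aic_table[order(x$aic_table$AIC), c("spec", "k", "RSS", "AIC", "weight")],
        row.names = FALSE)
  invisible(x)
}
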