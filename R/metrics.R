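#' Percent error in predicted tumor volume
#'
#' The model tumor volume counts voxels whose tumor volume fraction meets the
#' tumor-extent threshold, times the voxel volume; the error is
#' `100 * (V_model - V_measured) / V_measured`.
#'
#' @param model_phi_T Model tumor volume-fraction field.
#' @param measured_mask Logical measured tumor mask.
#' @param threshold Tumor-extent threshold in `(0, 1)`.
#' @param grid A [grid3d()].
#' @return Signed percent error.
#' @export
percent_volume_error <- function(model_phi_T, measured_mask, threshold, grid) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  v_meas <- sum(measured_mask) * voxel_volume(grid)
  if (v_meas == 0) stop("measured tumor volume is zero")
  v_model <- sum(model_phi_T >= threshold & grid$brain_mask) * voxel_volume(grid)
  100 * (v_model - v_meas) / v_meas
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param mask_a,mask_b Logical arrays on a common grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("masks must share a grid")
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) return(1)
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return PCC in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) < 2) stop("at least 2 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Lin concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`: penalizes
#' departures of the x-y relationship from the identity line, so
#' `|CCC| <= |PCC|` with equality iff means and variances match.
#'
#' @inheritParams pcc
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  if (length(x) < 2) stop("at least 2 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  2 * stats::cov(x, y) / (stats::var(x) + stats::var(y) + (mean(x) - mean(y))^2)
}

per_visit_metrics <- function(phi_T_model, phi_V_model, visit, threshold, grid) {
  model_mask <- phi_T_model >= threshold & grid$brain_mask
  support <- (visit$tumor_mask | model_mask) & grid$brain_mask
  list(
    pct_vol_error = percent_volume_error(phi_T_model, visit$tumor_mask, threshold, grid),
    dice = dice(model_mask, visit$tumor_mask),
    pcc_T = pcc(phi_T_model[support], visit$phi_T[support]),
    ccc_T = ccc(phi_T_model[support], visit$phi_T[support]),
    pcc_V = pcc(phi_V_model[support], visit$phi_V[support]),
    ccc_V = ccc(phi_V_model[support], visit$phi_V[support]))
}

#' Evaluate forecast agreement across sampled parameter sets
#'
#' For each sampled trajectory, computes the global metrics (percent tumor
#' volume error, Dice of the thresholded model mask against the measured
#' mask) and the local metrics (PCC and CCC of tumor and blood volume
#' fractions over the union of measured and model masks) at every comparison
#' visit, then averages each metric across visits. One time-averaged value
#' per metric per parameter set is returned, with box-plot summaries.
#'
#' @param trajectories List of trajectories (one per sampled parameter set),
#'   each a [simulate_growth()] result whose output days cover the visits.
#' @param dataset An [animal_dataset()].
#' @param visit_days Days of the comparison visits.
#' @param threshold Tumor-extent threshold; default `0.5 * theta_min` of the
#'   dataset capacity.
#' @return Object of class `metric_report`: `per_set` (data frame, one row
#'   per parameter set), `per_visit` (long data frame of raw values),
#'   `summary` (median and quartiles per metric), `threshold`.
#' @export
evaluate_forecast <- function(trajectories, dataset, visit_days, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.5 * dataset$capacity$theta_min
  days <- vapply(dataset$visits, function(v) v$day, numeric(1))
  use <- which(days %in% visit_days)
  if (length(use) == 0) stop("no comparison visits overlap the dataset")
  grid <- dataset$grid
  rows <- list()
  per_set <- list()
  for (s in seq_along(trajectories)) {
    tr <- trajectories[[s]]
    vals <- NULL
    for (vi in use) {
      day <- days[vi]
      key <- as.character(day)
      if (is.null(tr$phi_T[[key]])) stop(sprintf("trajectory %d lacks day %s", s, key))
      m <- per_visit_metrics(tr$phi_T[[key]], tr$phi_V[[key]],
                             dataset$visits[[vi]], threshold, grid)
      rows[[length(rows) + 1L]] <- data.frame(sample = s, day = day,
                                              metric = names(m),
                                              value = unlist(m, use.names = FALSE))
      vals <- rbind(vals, unlist(m))
    }
    per_set[[s]] <- colMeans(vals, na.rm = TRUE)
  }
  per_set <- as.data.frame(do.call(rbind, per_set))
  per_set$sample <- seq_len(nrow(per_set))
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  metrics <- setdiff(names(per_set), "sample")
  summary <- do.call(rbind, lapply(metrics, function(m) {
    q <- qs(per_set[[m]])
    data.frame(metric = m, q25 = q[1], median = q[2], q75 = q[3])
  }))
  structure(list(per_set = per_set, per_visit = do.call(rbind, rows),
                 summary = summary, threshold = threshold),
            class = "metric_report")
}

#' Compare selected-model and ensemble metric samples
#'
#' Two-sided Wilcoxon rank-sum test between the two samples of per-parameter
#' set metric values (100 values each in the standard workflow). Identical
#' constant samples are defined to agree (p = 1).
#'
#' @param values_a,values_b Numeric metric samples.
#' @return The two-sided p-value.
#' @export
compare_selected_vs_ensemble <- function(values_a, values_b) {
  if (length(unique(c(values_a, values_b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(values_a, values_b)$p.value)
}
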