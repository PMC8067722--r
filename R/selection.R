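#' Corrected Akaike information criterion
#'
#' `AIC = 2k + n ln(RSS/n) + 2k(k+1)/(n-k-1)` for a least-squares fit with
#' `k` calibrated parameters and `n` observations (the small-sample
#' correction term requires `n > k + 1`).
#'
#' @param k Number of calibrated parameters.
#' @param n_obs Number of fitted observations.
#' @param RSS Residual sum of squares, positive.
#' @return The criterion value.
#' @export
aic <- function(k, n_obs, RSS) {
  if (n_obs <= k + 1) stop("n_obs must exceed k + 1 for the corrected AIC")
  if (!is.finite(RSS) || RSS <= 0) stop("RSS must be positive and finite")
  2 * k + n_obs * log(RSS / n_obs) + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Akaike ensemble weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`. Weights are invariant to common AIC shifts,
#' sum to 1 and are maximal at the minimum AIC. Non-finite AICs receive
#' weight 0.
#'
#' @param aics Numeric vector of AIC values (at least one finite).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  finite <- is.finite(aics)
  if (!any(finite)) stop("at least one finite AIC is required")
  delta <- aics - min(aics[finite])
  w <- ifelse(finite, exp(-delta / 2), 0)
  w / sum(w)
}

#' Select the model with the lowest AIC
#'
#' Ties are broken by fewer calibrated parameters, then by family order.
#'
#' @param records List of records, each with elements `spec`, `AIC` and `k`.
#' @return The winning record's `spec`.
#' @export
select_model <- function(records) {
  if (length(records) < 1) stop("at least one record required")
  a <- vapply(records, function(r) r$AIC, numeric(1))
  k <- vapply(records, function(r) r$k, numeric(1))
  ord <- order(a, k, seq_along(records))
  records[[ord[1]]]$spec
}

#' Akaike-weighted ensemble average of forecast fields
#'
#' `phi_ens = sum_i w_i * mean_j phi[i][j]`: the parameter-sample dimension is
#' averaged within each model, then models are combined with their Akaike
#' weights. Fields must share a grid; volume-fraction inputs yield a
#' volume-fraction output.
#'
#' @param fields List over models; each element a list over parameter samples
#'   of 3D arrays.
#' @param weights Akaike weights, one per model, summing to 1.
#' @return The ensemble-averaged field.
#' @export
ensemble_average <- function(fields, weights) {
  if (length(fields) != length(weights)) stop("one weight per model required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  dims <- dim(fields[[1]][[1]])
  out <- array(0, dims)
  for (i in seq_along(fields)) {
    samp <- fields[[i]]
    acc <- array(0, dims)
    for (j in seq_along(samp)) {
      if (!identical(dim(samp[[j]]), dims)) stop("fields must share a grid")
      acc <- acc + samp[[j]]
    }
    out <- out + weights[i] * acc / length(samp)
  }
  out
}
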