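#' Fit an inversion-recovery T1 relaxation curve
#'
#' Fits `S(TI) = A - B * exp(-TI / T1_star)` to one voxel's inversion-recovery
#' series by nonlinear least squares and recovers the longitudinal relaxation
#' time `T1 = T1_star * (B/A - 1)` and the inherent signal
#' `S0 = A * T1 / T1_star`. Magnitude data are polarity-restored before the
#' fit: samples at inversion times up to the minimum-magnitude sample are
#' negated.
#'
#' @param TI Inversion times (ms), at least 3 distinct values.
#' @param S Signal at each `TI` (magnitude or signed).
#' @param magnitude Logical; treat `S` as magnitude data needing polarity
#'   restoration (default `TRUE`).
#' @return List with `T1`, `T1_star`, `S0`, `A`, `B` (ms for times) or an
#'   error for degenerate input.
#' @export
fit_t1_ir <- function(TI, S, magnitude = TRUE) {
  if (length(unique(TI)) < 3) stop("at least 3 distinct inversion times required")
  if (length(TI) != length(S)) stop("TI and S must have equal length")
  if (stats::sd(S) == 0) stop("constant signal: T1 not identifiable")
  candidates <- list(S)
  if (magnitude) {
    # the sample nearest the null may lie on either side of zero; restore
    # polarity both ways and keep the better fit
    imin <- which.min(abs(S))
    s1 <- abs(S); s1[TI < TI[imin]] <- -s1[TI < TI[imin]]
    s2 <- abs(S); s2[TI <= TI[imin]] <- -s2[TI <= TI[imin]]
    candidates <- list(s1, s2)
  }
  fit <- NULL
  for (s in candidates) {
    A0 <- max(s)
    B0 <- A0 + max(abs(s))
    null_ti <- TI[which.min(abs(s))]
    T1s0 <- max(null_ti / log(max(B0 / A0, 1.01)), min(diff(sort(unique(TI)))))
    f <- tryCatch(
      minpack.lm::nlsLM(s ~ A - B * exp(-TI / T1s),
                        start = list(A = A0, B = B0, T1s = T1s0),
                        lower = c(1e-9, 1e-9, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || stats::deviance(f) < stats::deviance(fit)))
      fit <- f
  }
  if (is.null(fit)) stop("inversion-recovery fit did not converge")
  cf <- stats::coef(fit)
  A <- cf[["A"]]; B <- cf[["B"]]; T1s <- cf[["T1s"]]
  if (A <= 0) stop("non-physical fit (A <= 0)")
  T1 <- T1s * (B / A - 1)
  if (!is.finite(T1) || T1 <= 0) stop("non-physical fit (T1 <= 0)")
  list(T1 = T1, T1_star = T1s, S0 = A * T1 / T1s, A = A, B = B)
}

#' Fit an apparent diffusion coefficient
#'
#' Mono-exponential fit of diffusion-weighted signals: the slope of
#' `log(S)` against the b-value is `-ADC`. Negative fitted values are
#' clamped at 0; nonpositive signals flag the voxel.
#'
#' @param b b-values (s/mm^2), at least 2 distinct.
#' @param S Positive signals at each `b`.
#' @return ADC in mm^2/s.
#' @export
fit_adc <- function(b, S) {
  if (length(unique(b)) < 2) stop("at least 2 distinct b-values required")
  if (any(S <= 0)) stop("nonpositive signal: voxel flagged")
  slope <- stats::coef(stats::lm(log(S) ~ b))[["b"]]
  max(-slope, 0)
}

#' Map ADC to tumor cell volume fraction
#'
#' Linear, order-reversing map between free-water diffusion and maximal
#' cellularity: `phi_T = (ADC_w - ADC) / (ADC_w - ADC_min)`, clipped to
#' `[0, 1]`. `ADC_w` is the ADC of free water at 37 degrees C (default
#' 3.0e-3 mm^2/s); `ADC_min` the minimum tumor ADC observed across the
#' cohort.
#'
#' @param ADC ADC map (array or vector, mm^2/s).
#' @param ADC_w Free-water ADC (mm^2/s).
#' @param ADC_min Cohort-minimum tumor ADC (mm^2/s), `< ADC_w`.
#' @return Tumor volume fraction, same shape as `ADC`.
#' @export
adc_to_tumor_fraction <- function(ADC, ADC_w = 3.0e-3, ADC_min) {
  if (ADC_min >= ADC_w) stop("ADC_min must be smaller than ADC_w")
  pmin(pmax((ADC_w - ADC) / (ADC_w - ADC_min), 0), 1)
}

# trapezoid integral of a piecewise-linear curve over [t0, t0 + window],
# interpolating the endpoint exactly
trapz_window <- function(t, y, t0, window) {
  t1 <- min(t0 + window, max(t))
  if (t1 <= t0) return(0)
  yi <- stats::approx(t, y, xout = c(t0, t1))$y
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  yy <- c(yi[1], y[inside], yi[2])
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Blood volume fraction from DCE time courses
#'
#' Computes the relative blood volume fraction as the ratio of the area under
#' the tissue concentration curve to the area under the arterial input
#' function, both trapezoid-integrated over the first 60 s after bolus
#' arrival, and clips the result to `[0, 1]`. Bolus arrival is the first
#' sample at which the AIF exceeds its pre-injection baseline mean by 5
#' baseline standard deviations (baseline: the first `n_baseline` volumes).
#'
#' @param t Time base (s), common to tissue and AIF curves.
#' @param tissue Tissue curve (single voxel vector) or a matrix with one row
#'   per voxel.
#' @param aif Arterial input function on the same clock.
#' @param window Integration window after bolus arrival (s, default 60).
#' @param n_baseline Number of pre-injection baseline volumes (default 25).
#' @return Blood volume fraction(s) in `[0, 1]`.
#' @export
dce_blood_volume <- function(t, tissue, aif, window = 60, n_baseline = 25) {
  nb <- min(n_baseline, length(t) - 1)
  base <- aif[seq_len(nb)]
  thresh <- mean(base) + 5 * stats::sd(base)
  arr <- which(aif > thresh)
  arr <- arr[arr > nb]
  if (length(arr) == 0) {
    arr <- which(aif > mean(base) & seq_along(aif) > nb)
    if (length(arr) == 0) stop("no bolus arrival detected in the AIF")
  }
  t0 <- t[arr[1]]
  auc_aif <- trapz_window(t, aif, t0, window)
  if (auc_aif <= 0) stop("zero AIF area under the curve")
  one <- function(y) min(max(trapz_window(t, y, t0, window) / auc_aif, 0), 1)
  if (is.matrix(tissue)) apply(tissue, 1, one) else one(tissue)
}

#' Segment an enhancing lesion by intensity clustering
#'
#' Two-cluster k-means on the voxel intensities inside a bounding region of
#' interest (the stand-in for a manually drawn outline); the higher-mean
#' cluster is the lesion. Interior holes of the lesion are filled slice by
#' slice. Deterministic: cluster centres are initialized at the 10th and 90th
#' intensity percentiles.
#'
#' @param image 3D intensity array (e.g., post-contrast T1-weighted).
#' @param roi Logical 3D array bounding the lesion.
#' @param seed Integer seed (kept for interface stability; the clustering is
#'   deterministic by construction).
#' @return Logical 3D array: the lesion mask.
#' @export
segment_tumor <- function(image, roi, seed = 1L) {
  roi <- array(as.logical(roi), dim(image))
  vals <- image[roi]
  if (length(unique(vals)) < 2) stop("ROI intensity is uniform: no separable clusters")
  centers <- stats::quantile(vals, c(0.1, 0.9), names = FALSE)
  if (centers[1] == centers[2]) centers <- range(vals)
  km <- stats::kmeans(vals, centers = matrix(centers, ncol = 1), iter.max = 100)
  hi <- which.max(km$centers)
  mask <- array(FALSE, dim(image))
  mask[roi] <- km$cluster == hi
  filled <- array(0, dim(image))
  for (k in seq_len(dim(image)[3])) {
    sl <- mask[, , k] * 1
    if (any(sl > 0)) filled[, , k] <- EBImage::fillHull(sl) else filled[, , k] <- sl
  }
  filled > 0
}

#' Segmentation robustness under image noise
#'
#' Repeats the k-means lesion segmentation on noise-perturbed replicates of
#' one image (Gaussian noise at a given SNR, defined as mean in-ROI intensity
#' over noise SD) and reports the variability of the segmented volume and the
#' spatial overlap with the noiseless segmentation.
#'
#' @param image Noiseless 3D intensity array.
#' @param roi Logical bounding ROI.
#' @param grid A [grid3d()] (for voxel volume).
#' @param n Number of noise replicates (default 100).
#' @param snr Signal-to-noise ratio (default 20).
#' @param seed Integer seed.
#' @return List with `volume_se` (standard error of replicate volumes, mm^3),
#'   `dice` (vector of Dice coefficients vs the noiseless mask), `volumes`.
#' @export
segmentation_robustness <- function(image, roi, grid, n = 100, snr = 20, seed = 1L) {
  ref <- segment_tumor(image, roi)
  sigma <- mean(image[roi]) / snr
  set.seed(seed)
  vols <- numeric(n)
  dices <- numeric(n)
  for (r in seq_len(n)) {
    noisy <- image + array(stats::rnorm(length(image), 0, sigma), dim(image))
    m <- segment_tumor(noisy, roi)
    vols[r] <- sum(m) * voxel_volume(grid)
    dices[r] <- dice(m, ref)
  }
  list(volume_se = stats::sd(vols) / sqrt(n), dice = dices, volumes = vols)
}
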