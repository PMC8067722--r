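#' Imaging / treatment schedule presets
#'
#' The seven experimental timelines the framework targets: imaging days over
#' 0-21 days and daily RT fractions at 2 or 4 Gy on the stated day ranges.
#'
#' @param animal Preset name, `"animal1"` .. `"animal7"` (or 1..7).
#' @return List with `image_days`, `rt_days`, `dose` (Gy per fraction) and
#'   `rt_events` (data frame).
#' @export
rt_schedule_preset <- function(animal) {
  if (is.numeric(animal)) animal <- paste0("animal", animal)
  presets <- list(
    animal1 = list(image_days = c(0, 3, 5, 7, 10, 12, 17, 19, 21),
                   rt_days = c(3:7, 10:14), dose = 2),
    animal2 = list(image_days = c(0, 3, 5), rt_days = 3:5, dose = 4),
    animal3 = list(image_days = c(0, 3, 5, 7, 10, 12),
                   rt_days = c(3:7, 10:12), dose = 2),
    animal4 = list(image_days = c(0, 3, 5), rt_days = 3:6, dose = 2),
    animal5 = list(image_days = c(0, 3, 5, 7), rt_days = 3:6, dose = 2),
    animal6 = list(image_days = c(0, 2, 5, 7, 8, 12, 14, 16, 19),
                   rt_days = c(0:2, 6:9, 12, 13), dose = 4),
    animal7 = list(image_days = c(0, 3, 5, 7, 10, 12, 14, 17),
                   rt_days = c(3:7, 10:14), dose = 4))
  p <- presets[[animal]]
  if (is.null(p)) stop("unknown schedule preset: ", animal)
  p$rt_events <- data.frame(day = p$rt_days, dose = p$dose)
  p
}

#' Default brain-like study grid
#'
#' An ellipsoidal domain inscribed in the voxel box, gray matter throughout.
#'
#' @param nx,ny,nz Voxel counts (default 32 x 32 x 8).
#' @param dx,dy,dz Spacings in mm.
#' @return A [grid3d()].
#' @export
default_grid <- function(nx = 32, ny = 32, nz = 8,
                         dx = 0.25, dy = 0.25, dz = 1.0) {
  ci <- (nx + 1) / 2; cj <- (ny + 1) / 2; ck <- (nz + 1) / 2
  ii <- slice.index(array(0, c(nx, ny, nz)), 1)
  jj <- slice.index(array(0, c(nx, ny, nz)), 2)
  kk <- slice.index(array(0, c(nx, ny, nz)), 3)
  mask <- ((ii - ci) / (0.95 * nx / 2))^2 + ((jj - cj) / (0.95 * ny / 2))^2 +
          ((kk - ck) / (0.95 * nz / 2))^2 <= 1
  grid3d(nx, ny, nz, dx, dy, dz, brain_mask = mask)
}

#' Ground truth for a virtual animal
#'
#' Collects everything that defines a synthetic dataset: the generating
#' family member and its parameters, the schedule, the initial lesion
#' geometry, the capacity constants used by the generating run, and the
#' imaging noise level. Two identical truth objects with the same seed yield
#' identical datasets.
#'
#' Default parameters reflect image-based estimates for an intracranial
#' glioma model under 2 Gy/day fractions: proliferation 1.4/day, diffusion
#' 2.6e-2 mm^2/day, per-fraction survival 0.97 at 2 Gy (0.90 at 4 Gy).
#'
#' @param spec Generating [model_spec()] (default `global-C3-RTM3`).
#' @param params Generating [parameter_set()]; `NULL` for the dose-dependent
#'   defaults.
#' @param schedule A [rt_schedule_preset()] result or preset name (default
#'   `"animal3"`).
#' @param seed Integer seed for the imaging noise.
#' @param noise_snr Imaging SNR (mean in-tumor signal over noise SD); `Inf`
#'   for noiseless data. Default 20.
#' @param center Lesion centre in mm (default: domain centre).
#' @param radius Lesion e-folding radius in mm (default 1).
#' @param peak Peak initial tumor volume fraction (default 0.6).
#' @param theta_min,theta_V Capacity constants of the generating run.
#' @param mask_threshold Tumor-mask threshold on the noiseless fields.
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(spec = model_spec("RTM3", "C3", "global"),
                            params = NULL, schedule = "animal3", seed = 1L,
                            noise_snr = 20, center = NULL, radius = 1,
                            peak = 0.6, theta_min = 0.05, theta_V = 0.12,
                            mask_threshold = 0.05) {
  if (is.character(schedule) || is.numeric(schedule))
    schedule <- rt_schedule_preset(schedule)
  if (is.null(params)) {
    SF <- if (schedule$dose >= 4) 0.90 else 0.97
    params <- parameter_set(kp_T0 = 1.40, kd_T0 = 0.11,
                            D_T0 = 0.0258, D_V0 = 0.031,
                            phi_V_thresh = 0.03, theta_max = 0.94,
                            kp_V = 0.82, kd_V = 0.29, SF = SF, alpha1 = 4)
  }
  structure(list(spec = spec, params = params, schedule = schedule,
                 seed = seed, noise_snr = noise_snr, center = center,
                 radius = radius, peak = peak, theta_min = theta_min,
                 theta_V = theta_V, mask_threshold = mask_threshold),
            class = "synthetic_truth")
}

#' Add Gaussian imaging noise to a field
#'
#' Noise SD is `mean(field[mask]) / snr`; the result is clipped to `[0, 1]`.
#'
#' @param field Numeric array.
#' @param snr Signal-to-noise ratio (`Inf` returns the field unchanged).
#' @param mask Logical array defining the signal region for the SNR.
#' @param seed Integer seed.
#' @param where Optional logical array restricting which voxels receive
#'   noise (default: all). The virtual-animal generator perturbs only the
#'   measured region of interest, mirroring maps that are estimated
#'   voxelwise within the lesion.
#' @return Noisy field, same shape.
#' @export
add_noise <- function(field, snr, mask, seed = 1L, where = NULL) {
  if (snr <= 0) stop("snr must be positive")
  if (!any(mask)) stop("mask is empty")
  if (!is.finite(snr)) return(field)
  sigma <- mean(field[mask]) / snr
  set.seed(seed)
  noise <- array(stats::rnorm(length(field), 0, sigma), dim(field))
  if (!is.null(where)) noise[!where] <- 0
  pmin(pmax(field + noise, 0), 1)
}

initial_lesion <- function(grid, truth) {
  dims <- grid_dims(grid)
  sp <- grid_spacings(grid)
  x <- (slice.index(array(0, dims), 1) - 0.5) * sp[1]
  y <- (slice.index(array(0, dims), 2) - 0.5) * sp[2]
  z <- (slice.index(array(0, dims), 3) - 0.5) * sp[3]
  center <- truth$center
  if (is.null(center)) {
    idx <- which(grid$brain_mask)
    center <- c(mean(x[idx]), mean(y[idx]), mean(z[idx]))
  }
  r2 <- ((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2) / truth$radius^2
  phi_T <- truth$peak * exp(-r2)
  # peripherally elevated vasculature: a ring at the lesion edge on a perfused
  # background
  r <- sqrt(r2) * truth$radius
  phi_V <- 0.02 + 0.08 * exp(-((r - truth$radius) / 0.4)^2)
  phi_T[!grid$brain_mask] <- 0
  phi_V[!grid$brain_mask] <- 0
  list(phi_T = phi_T, phi_V = phi_V, center = center)
}

#' Generate a virtual animal dataset
#'
#' Seeds a Gaussian-profile lesion with peripherally elevated vasculature,
#' integrates the generating family member forward (applying RT fractions on
#' the schedule's treatment days), snapshots the fields at the imaging days,
#' adds Gaussian noise at the requested SNR, and derives tumor masks by
#' thresholding the noiseless truth. The returned dataset carries the
#' capacity constants the generating run actually used, so the synthetic
#' inverse problem is exactly self-consistent; the purely data-derived bounds
#' (as a measured-data workflow would assign them) are kept in the attached
#' truth record.
#'
#' @param truth A [synthetic_truth()].
#' @param grid A [grid3d()] (default [default_grid()]).
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @return An [animal_dataset()] with an extra element `truth`: the input
#'   truth augmented with the noiseless visits and the data-derived capacity
#'   bounds.
#' @export
generate_virtual_animal <- function(truth, grid = default_grid(),
                                    mech = mechanical_params(),
                                    control = solver_control()) {
  init <- initial_lesion(grid, truth)
  cap <- capacity_state(theta_min = truth$theta_min,
                        theta_max = truth$params$theta_max,
                        theta_V = truth$theta_V,
                        phi_V_thresh = truth$params$phi_V_thresh)
  sched <- truth$schedule
  tr <- simulate_growth(grid, init$phi_T, init$phi_V, cap, truth$params,
                        truth$spec, t0 = min(sched$image_days),
                        rt_events = sched$rt_events,
                        output_days = sched$image_days,
                        mech = mech, control = control)
  visits <- vector("list", length(sched$image_days))
  clean <- vector("list", length(sched$image_days))
  for (i in seq_along(sched$image_days)) {
    day <- sched$image_days[i]
    key <- as.character(day)
    pT <- tr$phi_T[[key]]
    pV <- tr$phi_V[[key]]
    mask <- pT >= truth$mask_threshold & grid$brain_mask
    if (!any(mask)) stop("lesion vanished below the mask threshold; unstable truth parameters?")
    clean[[i]] <- list(day = day, phi_T = pT, phi_V = pV, tumor_mask = mask)
    visits[[i]] <- list(
      day = day,
      phi_T = add_noise(pT, truth$noise_snr, mask, seed = truth$seed + 1000L * i,
                        where = mask),
      phi_V = add_noise(pV, truth$noise_snr, mask, seed = truth$seed + 1000L * i + 500L,
                        where = mask),
      tumor_mask = mask)
  }
  truth$noiseless_visits <- clean
  truth$derived_capacity <- assign_capacity_bounds(visits)
  truth$n_fractions <- tr$n_fractions
  ds <- animal_dataset(grid, visits, sched$rt_events, capacity = cap)
  ds$truth <- truth
  ds
}

#' MR acquisition protocol for the signal synthesizer
#'
#' @param TI Inversion times (ms); default 30 values from 125 to 3025 ms in
#'   100 ms steps.
#' @param b Diffusion b-values (s/mm^2); default 150, 350, 800.
#' @param ADC_w,ADC_min Free-water and minimum-cellularity ADC (mm^2/s).
#' @param T1_base,T1_slope Voxel T1 (ms) is `T1_base + T1_slope * phi_T`.
#' @param T1star_ratio Ratio `T1* / T1` of the readout-shortened relaxation.
#' @param S0 Inherent signal intensity.
#' @param dce_dt DCE sampling interval (s).
#' @param dce_n Number of DCE volumes.
#' @param n_baseline Pre-injection DCE volumes (default 25).
#' @return List of class `mr_protocol`.
#' @export
mr_protocol <- function(TI = seq(125, 3025, by = 100), b = c(150, 350, 800),
                        ADC_w = 3.0e-3, ADC_min = 0.8e-3,
                        T1_base = 2200, T1_slope = -600, T1star_ratio = 0.7,
                        S0 = 1, dce_dt = 1, dce_n = 150, n_baseline = 25) {
  structure(list(TI = TI, b = b, ADC_w = ADC_w, ADC_min = ADC_min,
                 T1_base = T1_base, T1_slope = T1_slope,
                 T1star_ratio = T1star_ratio, S0 = S0, dce_dt = dce_dt,
                 dce_n = dce_n, n_baseline = n_baseline),
            class = "mr_protocol")
}

#' Bi-exponential arterial input function
#'
#' A bolus arriving after the baseline volumes with a fast rise and slow
#' washout, normalized to unit peak. Only the area ratio matters for the
#' blood volume estimate, so the shape constants are conventional.
#'
#' @param t Time base (s).
#' @param t_arrival Bolus arrival time (s).
#' @param k_wash,k_rise Washout and rise rate constants (1/s).
#' @return AIF values on `t`.
#' @export
synthetic_aif <- function(t, t_arrival, k_wash = 0.02, k_rise = 0.35) {
  tau <- pmax(t - t_arrival, 0)
  a <- exp(-k_wash * tau) - exp(-k_rise * tau)
  a[t <= t_arrival] <- 0
  a / max(a)
}

#' Synthesize raw MR signal series from volume-fraction maps
#'
#' Emits, per voxel, an inversion-recovery series (from an assigned T1 map),
#' a diffusion-weighted series (inverting the linear ADC-cellularity map so
#' the ADC fit recovers `phi_T` exactly), and a DCE tissue time course
#' proportional to the AIF with proportionality `phi_V`. Round trips through
#' [fit_t1_ir()], [fit_adc()], [adc_to_tumor_fraction()] and
#' [dce_blood_volume()] recover the generating maps (exactly when noiseless).
#'
#' @param phi_T,phi_V Numeric vectors of voxel volume fractions.
#' @param protocol An [mr_protocol()].
#' @param snr Per-series SNR (`Inf` for noiseless signals).
#' @param seed Integer seed.
#' @return List with components `ir` (`TI`, signal matrix, `T1_true`), `dw`
#'   (`b`, signal matrix, `ADC_true`), `dce` (`t`, `aif`, tissue matrix).
#' @export
synthesize_mr_signals <- function(phi_T, phi_V, protocol = mr_protocol(),
                                  snr = Inf, seed = 1L) {
  phi_T <- as.numeric(phi_T); phi_V <- as.numeric(phi_V)
  p <- protocol
  set.seed(seed)
  noisy <- function(S) {
    if (!is.finite(snr)) return(S)
    S + matrix(stats::rnorm(length(S), 0, mean(abs(S)) / snr), nrow(S), ncol(S))
  }
  T1 <- p$T1_base + p$T1_slope * phi_T
  T1s <- p$T1star_ratio * T1
  A <- p$S0 * p$T1star_ratio
  B <- p$S0 * (1 + p$T1star_ratio)
  ir <- abs(outer(rep(A, length(phi_T)), rep(1, length(p$TI))) -
            B * exp(-outer(1 / T1s, p$TI)))
  ADC <- p$ADC_w - phi_T * (p$ADC_w - p$ADC_min)
  dw <- p$S0 * exp(-outer(ADC, p$b))
  t <- (seq_len(p$dce_n) - 1) * p$dce_dt
  aif <- synthetic_aif(t, t_arrival = p$n_baseline * p$dce_dt)
  tissue <- outer(phi_V, rep(1, length(t))) * matrix(aif, length(phi_V), length(t), byrow = TRUE)
  list(ir = list(TI = p$TI, S = noisy(ir), T1_true = T1),
       dw = list(b = p$b, S = noisy(dw), ADC_true = ADC),
       dce = list(t = t, aif = aif, tissue = noisy(tissue)))
}
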