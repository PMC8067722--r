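#' Model family member
#'
#' One member of the 18-model family of tumor/vasculature response to
#' fractionated radiotherapy: a radiotherapy response model (`RTM1`
#' instantaneous kill, `RTM2` kill plus cumulative proliferation slowdown,
#' `RTM3` proliferation slowdown plus rate-based delayed death), a spatial
#' efficacy coupling (`C1` packing density, `C2` vascularity, `C3` none) and
#' the proliferation-rate mode (`global` scalar or `local` voxelwise field).
#'
#' @param rtm One of `"RTM1"`, `"RTM2"`, `"RTM3"`.
#' @param coupling One of `"C1"`, `"C2"`, `"C3"`.
#' @param kp_mode One of `"global"`, `"local"`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(rtm, coupling, kp_mode) {
  rtm <- match.arg(rtm, c("RTM1", "RTM2", "RTM3"))
  coupling <- match.arg(coupling, c("C1", "C2", "C3"))
  kp_mode <- match.arg(kp_mode, c("global", "local"))
  structure(list(rtm = rtm, coupling = coupling, kp_mode = kp_mode),
            class = "model_spec")
}

#' @export
#' @method print model_spec
print.model_spec <- function(x, ...) {
  cat(spec_token(x), "\n")
  invisible(x)
}

#' Serialize / parse a model spec token
#'
#' Specs are written as 3-token strings such as `"local-C2-RTM3"`.
#'
#' @param spec A [model_spec()].
#' @return `spec_token` returns a character scalar; `parse_spec_token` the
#'   corresponding [model_spec()].
#' @export
spec_token <- function(spec) paste(spec$kp_mode, spec$coupling, spec$rtm, sep = "-")

#' @rdname spec_token
#' @param token Character scalar like `"global-C1-RTM2"`.
#' @export
parse_spec_token <- function(token) {
  parts <- strsplit(token, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("spec token must have three '-'-separated parts")
  model_spec(rtm = parts[3], coupling = parts[2], kp_mode = parts[1])
}

#' Enumerate the 18-member model family
#'
#' Ordering follows the family's numbering: the voxelwise proliferation
#' block first (models 1-9), then the global block (models 10-18); within a
#' block the response model varies slowest (models 1-3 are the instantaneous
#' kill members, 7-9 the death-rate members) and the coupling fastest
#' (C1, C2, C3).
#'
#' @return List of 18 [model_spec()] objects.
#' @export
enumerate_models <- function() {
  out <- list()
  for (kp_mode in c("local", "global"))
    for (rtm in c("RTM1", "RTM2", "RTM3"))
      for (coupling in c("C1", "C2", "C3"))
        out[[length(out) + 1L]] <- model_spec(rtm, coupling, kp_mode)
  out
}

#' Calibrated and assigned model constants
#'
#' @param kp_T0 Pre-treatment tumor proliferation rate (1/day); scalar, or a
#'   voxelwise field for `local` specs.
#' @param kd_T0 Tumor RT death rate (1/day), used by RTM3 only.
#' @param D_T0,D_V0 Unstressed tumor / vascular diffusion coefficients
#'   (mm^2/day).
#' @param phi_V_thresh Vascularity threshold of the carrying-capacity ramp.
#' @param theta_max Maximal tumor carrying capacity.
#' @param kp_V,kd_V Vasculature growth and death rates (1/day).
#' @param SF Per-fraction surviving fraction in `[0, 1]` (shared by tumor and
#'   vasculature).
#' @param alpha1 Vascularity coupling constant (C2 only).
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(kp_T0, kd_T0 = 0, D_T0, D_V0, phi_V_thresh,
                          theta_max, kp_V, kd_V, SF, alpha1 = 0) {
  rates <- c(kd_T0 = kd_T0, kp_V = kp_V, kd_V = kd_V)
  if (any(kp_T0 < 0) || any(rates < 0)) stop("rates must be nonnegative")
  if (D_T0 < 0 || D_V0 < 0) stop("diffusion coefficients must be nonnegative")
  if (SF < 0 || SF > 1) stop("SF must lie in [0, 1]")
  structure(list(kp_T0 = kp_T0, kd_T0 = kd_T0, D_T0 = D_T0, D_V0 = D_V0,
                 phi_V_thresh = phi_V_thresh, theta_max = theta_max,
                 kp_V = kp_V, kd_V = kd_V, SF = SF, alpha1 = alpha1),
            class = "parameter_set")
}

#' Spatial RT-efficacy coupling field
#'
#' Evaluates the coupling that modulates per-fraction survival: `C1` is the
#' packing fraction `phi / theta` (dense regions proliferate slowly and are
#' spared), `C2 = exp(-alpha1 * phi_V / theta_V)` (well-perfused, oxygenated
#' regions respond more), and `C3 = 1` (no spatial modulation). The vascular
#' analogue of `C1` uses `phi_V / theta_V`. Values are clamped to `[0, 1]`.
#'
#' @param spec A [model_spec()].
#' @param phi_T,phi_V Current volume-fraction fields.
#' @param theta_T Tumor carrying-capacity field.
#' @param theta_V Blood volume-fraction carrying capacity (scalar).
#' @param alpha1 Coupling constant (C2 only).
#' @param species `"tumor"` or `"vascular"`: which species the coupling
#'   applies to (affects `C1` only).
#' @return Field with values in `[0, 1]`.
#' @export
coupling_field <- function(spec, phi_T, theta_T, phi_V, theta_V, alpha1 = 0,
                           species = c("tumor", "vascular")) {
  species <- match.arg(species)
  C <- switch(spec$coupling,
    C1 = {
      if (species == "tumor") {
        if (any(theta_T <= 0)) stop("theta_T must be positive for C1 coupling")
        phi_T / theta_T
      } else {
        if (theta_V <= 0) stop("theta_V must be positive for C1 coupling")
        phi_V / theta_V
      }
    },
    C2 = exp(-alpha1 * phi_V / theta_V),
    C3 = {
      ones <- phi_T * 0 + 1
      ones
    })
  pmin(pmax(C, 0), 1)
}

#' Instantaneous RT kill
#'
#' Applies the per-fraction survival multiplier `C * SF` to a volume-fraction
#' field; used by RTM1 and RTM2 (for both tumor and vasculature) immediately
#' before the PDE step of a treatment time.
#'
#' @param phi Volume-fraction field immediately before the fraction.
#' @param C Coupling field from [coupling_field()].
#' @param SF Surviving fraction in `[0, 1]`.
#' @return Post-fraction field `phi * C * SF`.
#' @export
apply_rt_instantaneous <- function(phi, C, SF) {
  if (SF < 0 || SF > 1) stop("SF must lie in [0, 1]")
  phi * (C * SF)
}

#' Effective proliferation rate after n fractions
#'
#' `kp = kp0 * C * SF^n`: the proliferation rate decays multiplicatively with
#' each delivered fraction (RTM2 and RTM3). Before the first fraction the
#' pre-treatment rate applies unchanged.
#'
#' @param kp0 Pre-treatment rate (scalar or field).
#' @param C Coupling field.
#' @param SF Surviving fraction.
#' @param n Number of delivered fractions (`n >= 1`).
#' @return Effective rate field in `[0, kp0]`.
#' @export
effective_proliferation <- function(kp0, C, SF, n) {
  if (n < 1) stop("effective rates apply only after the first fraction (n >= 1)")
  kp0 * (C * SF^n)
}

#' Effective RT death rate after n fractions
#'
#' `kd = kd0 * (1 - C * SF^n)`, the death-rate form of RT response (RTM3):
#' the dying fraction grows toward 1 with the number of delivered fractions.
#'
#' @param kd0 Maximal RT death rate.
#' @inheritParams effective_proliferation
#' @return Effective death-rate field in `[0, kd0]`.
#' @export
effective_death <- function(kd0, C, SF, n) {
  if (n < 1) stop("effective rates apply only after the first fraction (n >= 1)")
  kd0 * (1 - C * SF^n)
}

# Conservative cross-diffusion flux divergence:
#   div( D [ (1 - phi_b/thTV) grad(phi_a/thTV) + (phi_a/thTV) grad(phi_b/thTV) ] )
# Face-centred D uses the harmonic mean, face fractions the arithmetic mean;
# faces on the mask boundary carry zero flux, so the summed divergence over
# the closed domain vanishes to round-off.
cross_diffusion_div <- function(phi_a, phi_b, theta_TV, D, grid) {
  dims <- grid_dims(grid)
  mask <- grid$brain_mask
  h <- grid_spacings(grid)
  a <- phi_a / theta_TV
  b <- phi_b / theta_TV
  D <- array(D, dims) + array(0, dims)  # force full array
  out <- array(0, dims)
  for (axis in 1:3) {
    nb <- shift_index(dims, axis, 1L)
    p <- which(mask & !is.na(nb))
    q <- nb[p]
    keep <- mask[q]
    p <- p[keep]; q <- q[keep]
    if (length(p) == 0) next
    Dsum <- D[p] + D[q]
    Df <- ifelse(Dsum > 0, 2 * D[p] * D[q] / Dsum, 0)
    af <- (a[p] + a[q]) / 2
    bf <- (b[p] + b[q]) / 2
    Fx <- Df * ((1 - bf) * (a[q] - a[p]) / h[axis] + af * (b[q] - b[p]) / h[axis])
    inc <- Fx / h[axis]
    out[p] <- out[p] + inc
    out[q] <- out[q] - inc
  }
  out
}

#' Tumor PDE right-hand side
#'
#' Evaluates the rate of change of the tumor volume fraction: a conservative
#' cross-diffusion term in which the spread of tumor cells is modulated by
#' the space occupied by vasculature, a logistic growth term limited by the
#' vascularity-driven carrying capacity, and (RTM3 only) an exponential RT
#' death term.
#'
#' @param phi_T,phi_V Volume-fraction fields (3D arrays).
#' @param cap A [capacity_state()]; the capacity field is re-derived from
#'   `phi_V` via [update_carrying_capacity()].
#' @param D_T Diffusion-coefficient field (mm^2/day), scalar or array.
#' @param kp_T Proliferation rate (1/day), scalar or field.
#' @param kd_T RT death rate (1/day), scalar or field (0 except RTM3).
#' @param grid A [grid3d()].
#' @return Field of time derivatives (1/day).
#' @export
rhs_tumor <- function(phi_T, phi_V, cap, D_T, kp_T, kd_T = 0, grid) {
  phi_T <- check_field(phi_T, grid, "phi_T")
  phi_V <- check_field(phi_V, grid, "phi_V")
  theta_T <- update_carrying_capacity(phi_V, cap)
  theta_TV <- theta_T + cap$theta_V
  div <- cross_diffusion_div(phi_T, phi_V, theta_TV, D_T, grid)
  growth <- kp_T * phi_T * (1 - phi_T / theta_T)
  out <- div + growth - kd_T * phi_T
  out[!grid$brain_mask] <- 0
  out
}

#' Vasculature PDE right-hand side
#'
#' Mirrors [rhs_tumor()] with the species' roles swapped in the
#' cross-diffusion term, plus logistic vascular growth weighted toward the
#' tumor periphery (`d`) and vascular death weighted toward the core
#' (`1 - d`).
#'
#' @inheritParams rhs_tumor
#' @param D_V Vascular diffusion-coefficient field (mm^2/day).
#' @param kp_V,kd_V Vascular growth / death rates (1/day), scalar or field.
#' @param d Normalized distance-to-periphery field (array, or a
#'   `distance_field` from [compute_distance_to_periphery()]).
#' @return Field of time derivatives (1/day).
#' @export
rhs_vasculature <- function(phi_V, phi_T, cap, D_V, kp_V, kd_V, d, grid) {
  phi_T <- check_field(phi_T, grid, "phi_T")
  phi_V <- check_field(phi_V, grid, "phi_V")
  if (inherits(d, "distance_field")) d <- d$d
  theta_T <- update_carrying_capacity(phi_V, cap)
  theta_TV <- theta_T + cap$theta_V
  div <- cross_diffusion_div(phi_V, phi_T, theta_TV, D_V, grid)
  growth <- kp_V * phi_V * (1 - phi_V / cap$theta_V) * d
  death <- kd_V * phi_V * (1 - d)
  out <- div + growth - death
  out[!grid$brain_mask] <- 0
  out
}
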