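#' Normalized distance to the tumor periphery
#'
#' Computes, inside a tumor mask, the Euclidean distance (in mm, honouring
#' anisotropic voxel spacings) from each tumor voxel to the tumor boundary,
#' and linearly rescales it so that boundary voxels carry the value 1 and the
#' deepest voxel(s) carry 0. The field localizes angiogenesis at the rim
#' (growth weighted by `d`) and vascular regression in the core (death
#' weighted by `1 - d`). Outside the mask the field is 0.
#'
#' A tumor voxel is a boundary voxel when at least one of its six face
#' neighbours is outside the tumor mask (voxels on the domain edge count as
#' boundary). If every tumor voxel is a boundary voxel the field is 1 over
#' the whole mask (growth-dominated periphery behaviour).
#'
#' @param tumor_mask Logical 3D array marking the tumor extent.
#' @param grid A [grid3d()].
#' @return A list of class `distance_field` with elements `d` (numeric 3D
#'   array in `[0, 1]`) and `tumor_mask`.
#' @export
compute_distance_to_periphery <- function(tumor_mask, grid) {
  dims <- grid_dims(grid)
  tumor_mask <- array(as.logical(tumor_mask), dims)
  if (!any(tumor_mask)) stop("tumor mask is empty")
  dist <- array(boundary_distance_cpp(tumor_mask, as.integer(dims),
                                      grid_spacings(grid)), dims)
  d <- array(0, dims)
  dmax <- max(dist)
  if (dmax == 0) {
    d[tumor_mask] <- 1  # all voxels are boundary voxels
  } else {
    d[tumor_mask] <- 1 - dist[tumor_mask] / dmax
  }
  structure(list(d = d, tumor_mask = tumor_mask), class = "distance_field")
}

#' Carrying-capacity state
#'
#' Bundles the tumor carrying-capacity field and its bounds. The tumor
#' capacity responds to local vascularity: voxels with blood volume fraction
#' at or above `phi_V_thresh` support the maximal packing fraction
#' `theta_max`; below the threshold the capacity ramps linearly from
#' `theta_min` at zero vascularity, continuously reaching `theta_max` at the
#' threshold.
#'
#' @param theta_min,theta_max Lower/upper tumor carrying-capacity bounds in
#'   `(0, 1]`, `theta_min <= theta_max`.
#' @param theta_V Blood volume-fraction carrying capacity (scalar).
#' @param phi_V_thresh Vascularity threshold, in `(0, theta_V)`.
#' @return An object of class `capacity_state` (without the `theta_T` field,
#'   which is derived from a blood volume map by [update_carrying_capacity()]).
#' @export
capacity_state <- function(theta_min, theta_max, theta_V, phi_V_thresh) {
  if (phi_V_thresh <= 0) stop("phi_V_thresh must be positive")
  stopifnot(theta_min > 0, theta_min <= theta_max, theta_max <= 1,
            theta_V > 0, phi_V_thresh < theta_V || isTRUE(all.equal(phi_V_thresh, theta_V)))
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 theta_V = theta_V, phi_V_thresh = phi_V_thresh),
            class = "capacity_state")
}

#' Vascularity-driven tumor carrying capacity
#'
#' Maps a blood volume-fraction field to the voxelwise tumor carrying
#' capacity: `theta_max` where `phi_V >= phi_V_thresh`, otherwise
#' `theta_min + phi_V * (theta_max - theta_min) / phi_V_thresh` (continuous
#' at the threshold).
#'
#' @param phi_V Blood volume-fraction field (3D array).
#' @param cap A [capacity_state()].
#' @return The capacity field `theta_T` (same shape as `phi_V`).
#' @export
update_carrying_capacity <- function(phi_V, cap) {
  if (cap$phi_V_thresh <= 0) stop("phi_V_thresh must be positive")
  ramp <- cap$theta_min + phi_V * (cap$theta_max - cap$theta_min) / cap$phi_V_thresh
  theta <- ifelse(phi_V >= cap$phi_V_thresh, cap$theta_max, ramp)
  array(theta, dim = dim(phi_V))
}

#' Measured carrying-capacity bounds
#'
#' Derives the assigned capacity constants from the imaging visits used for
#' calibration: `theta_min`/`theta_max` are the lowest and highest tumor
#' volume fractions observed over tumor voxels across those visits, and
#' `theta_V` is the maximum observed blood volume fraction (over the same
#' tumor voxels). The vascularity threshold is a calibrated parameter and is
#' set here to a placeholder of `theta_V / 2`.
#'
#' @param visits List of visits, each a list with elements `phi_T`, `phi_V`
#'   (3D arrays) and `tumor_mask` (logical 3D array).
#' @return A [capacity_state()].
#' @export
assign_capacity_bounds <- function(visits) {
  if (length(visits) < 1) stop("at least one visit is required")
  phiT <- unlist(lapply(visits, function(v) v$phi_T[v$tumor_mask]))
  phiV <- unlist(lapply(visits, function(v) v$phi_V[v$tumor_mask]))
  if (length(phiT) == 0 || all(phiT == 0))
    stop("no nonzero tumor volume fractions inside the tumor masks")
  theta_min <- max(min(phiT), 1e-3)  # noisy minima can clip to 0
  theta_max <- max(phiT)
  theta_V <- max(phiV)
  if (theta_V <= 0) stop("no nonzero blood volume fractions inside the tumor masks")
  capacity_state(theta_min = theta_min, theta_max = theta_max,
                 theta_V = theta_V, phi_V_thresh = theta_V / 2)
}

#' Assemble a per-animal dataset
#'
#' @param grid A [grid3d()].
#' @param visits List of visits; each a list with `day`, `phi_T`, `phi_V`,
#'   `tumor_mask`. Days must be strictly increasing.
#' @param rt_events Data frame (or list) with columns `day` and `dose` (Gy).
#' @param capacity A [capacity_state()]; if `NULL`, derived from all visits
#'   via [assign_capacity_bounds()].
#' @param phi_V_pretreatment_mean Mean pre-treatment blood volume fraction;
#'   if `NULL`, computed as the mean in-tumor `phi_V` over visits preceding
#'   the first RT event.
#' @return An object of class `animal_dataset`.
#' @export
animal_dataset <- function(grid, visits, rt_events, capacity = NULL,
                           phi_V_pretreatment_mean = NULL) {
  days <- vapply(visits, function(v) v$day, numeric(1))
  if (any(diff(days) <= 0)) stop("visit days must be strictly increasing")
  rt_events <- as.data.frame(rt_events)
  if (nrow(rt_events) > 0) {
    stopifnot(all(c("day", "dose") %in% names(rt_events)))
    rt_events <- rt_events[order(rt_events$day), , drop = FALSE]
  }
  if (is.null(capacity)) capacity <- assign_capacity_bounds(visits)
  if (is.null(phi_V_pretreatment_mean)) {
    first_rt <- if (nrow(rt_events) > 0) min(rt_events$day) else Inf
    pre <- visits[days < first_rt]
    if (length(pre) == 0) pre <- visits[1]
    phi_V_pretreatment_mean <- mean(unlist(lapply(pre, function(v) v$phi_V[v$tumor_mask])))
  }
  structure(list(grid = grid, visits = visits, rt_events = rt_events,
                 capacity = capacity,
                 phi_V_pretreatment_mean = phi_V_pretreatment_mean),
            class = "animal_dataset")
}

#' @export
#' @method print animal_dataset
print.animal_dataset <- function(x, ...) {
  cat(sprintf("animal_dataset: %d visits (days %s), %d RT fractions\n",
              length(x$visits),
              paste(vapply(x$visits, function(v) v$day, numeric(1)), collapse = ","),
              nrow(x$rt_events)))
  invisible(x)
}
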