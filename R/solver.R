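#' Solver configuration
#'
#' @param dt Time step in days (default 0.01).
#' @param d_refresh_steps Steps between refreshes of the distance-to-periphery
#'   field (default 25); the field is also refreshed at the start of every
#'   integration interval.
#' @param mech_interval_days Mechanics (displacement/stress) is re-solved at
#'   least this often in simulated days (default 1).
#' @param mech_dphi Additional mechanics refresh trigger: maximal voxel change
#'   of `phi_T` since the last solve (default 0.01).
#' @param mechanics Logical; solve the elasticity problem and damp diffusion
#'   with von Mises stress. When `FALSE` (or when `lambda1 = 0`) diffusion
#'   coefficients stay at their unstressed values.
#' @param extent_threshold Tumor-extent threshold on `phi_T` used to derive
#'   the model tumor mask for the distance field (default `0.5 * theta_min`).
#' @param overshoot_warn Warn if any update undershoots 0 by more than this.
#' @return List of class `solver_control`.
#' @export
solver_control <- function(dt = 0.01, d_refresh_steps = 25,
                           mech_interval_days = 1, mech_dphi = 0.01,
                           mechanics = TRUE, extent_threshold = NULL,
                           overshoot_warn = 1e-6) {
  structure(list(dt = dt, d_refresh_steps = d_refresh_steps,
                 mech_interval_days = mech_interval_days,
                 mech_dphi = mech_dphi, mechanics = mechanics,
                 extent_threshold = extent_threshold,
                 overshoot_warn = overshoot_warn),
            class = "solver_control")
}

#' Explicit-scheme stability check
#'
#' The fully explicit scheme is stable when
#' `2 * dt * D_max * (1/dx^2 + 1/dy^2 + 1/dz^2) <= 1`.
#'
#' @param D_max Largest diffusion coefficient in play (mm^2/day).
#' @param dt Time step (days).
#' @param grid A [grid3d()].
#' @return List with `pass` (logical) and `margin` (the criterion value;
#'   stable when `<= 1`).
#' @export
check_stability <- function(D_max, dt, grid) {
  h <- grid_spacings(grid)
  value <- 2 * dt * D_max * sum(1 / h^2)
  list(pass = value <= 1, margin = value)
}

expand_field <- function(x, dims) {
  if (length(x) == 1L) array(as.numeric(x), dims) else array(as.numeric(x), dims)
}

#' Single forward-Euler step of the coupled system
#'
#' Advances the tumor and vasculature fields by `nsteps` explicit steps with
#' all coefficient fields frozen (the carrying capacity still responds to the
#' evolving blood volume fraction at every step). This is the elementary
#' update used by [simulate_growth()]; exposed for testing and for custom
#' integration loops.
#'
#' @param phi_T,phi_V Current fields.
#' @param cap A [capacity_state()].
#' @param D_T,D_V Diffusion-coefficient fields (scalar or array).
#' @param kp_T,kd_T,kp_V,kd_V Rate fields (scalar or array, 1/day).
#' @param kd_V_rt Additional uniform vascular RT death-rate field.
#' @param d Distance-to-periphery field (array or `distance_field`).
#' @param dt Time step (days).
#' @param grid A [grid3d()].
#' @param nsteps Number of steps to take.
#' @return List with updated `phi_T`, `phi_V`, and the extreme pre-clip
#'   values seen (`min_value`, `max_value`).
#' @export
step_fields <- function(phi_T, phi_V, cap, D_T, D_V, kp_T, kd_T, kp_V, kd_V,
                        kd_V_rt = 0, d, dt, grid, nsteps = 1L) {
  dims <- grid_dims(grid)
  if (inherits(d, "distance_field")) d <- d$d
  res <- integrate_chunk_cpp(
    expand_field(phi_T, dims), expand_field(phi_V, dims), grid$brain_mask,
    expand_field(D_T, dims), expand_field(D_V, dims),
    expand_field(kp_T, dims), expand_field(kd_T, dims),
    expand_field(kp_V, dims), expand_field(kd_V, dims),
    expand_field(kd_V_rt, dims), expand_field(d, dims),
    cap$theta_min, cap$theta_max, cap$theta_V, cap$phi_V_thresh,
    as.integer(dims), grid_spacings(grid), dt, as.integer(nsteps))
  if (isTRUE(res$failed)) stop("non-finite value encountered during integration")
  res$phi_T <- array(res$phi_T, dims)
  res$phi_V <- array(res$phi_V, dims)
  res
}

# effective capacity for a trial parameter set: measured bounds with the
# calibrated theta_max / phi_V_thresh substituted
effective_capacity <- function(cap, params) {
  theta_max <- max(params$theta_max, cap$theta_min)
  capacity_state(theta_min = min(cap$theta_min, theta_max), theta_max = theta_max,
                 theta_V = cap$theta_V,
                 phi_V_thresh = min(max(params$phi_V_thresh, 1e-8), cap$theta_V))
}

#' Simulate tumor and vasculature growth under fractionated RT
#'
#' Integrates the coupled cross-diffusion system from an initial pair of
#' measured (or synthetic) maps with a fully explicit scheme (default
#' `dt = 0.01` days), no-flux boundaries at the brain-mask edge, and slip
#' boundary conditions for the mechanics. At each treatment day the RT event
#' is applied at the start of the day, before the first PDE step: the
#' fraction counter is incremented, instantaneous kill is applied for RTM1
#' and RTM2, and the effective proliferation/death rates are refreshed for
#' RTM2 and RTM3. When an output day coincides with a treatment day the
#' snapshot is taken before the fraction (pre-fraction morning imaging).
#'
#' @param grid A [grid3d()].
#' @param phi_T0,phi_V0 Initial fields at `t0`.
#' @param cap A [capacity_state()] carrying the measured bounds; the trial
#'   `theta_max` and `phi_V_thresh` are taken from `params`.
#' @param params A [parameter_set()].
#' @param spec A [model_spec()].
#' @param t0 Start day.
#' @param rt_events Data frame with columns `day`, `dose`; fractions outside
#'   `(t0, max(output_days)]` are ignored.
#' @param output_days Days at which fields are returned (must be `>= t0`).
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @param op Optional precomputed [elasticity_operator()].
#' @return List of class `growth_trajectory`: `days`, `phi_T` and `phi_V`
#'   (lists of arrays, one per output day), `n_fractions`, `dt`, `min_value`.
#' @export
simulate_growth <- function(grid, phi_T0, phi_V0, cap, params, spec, t0,
                            rt_events = NULL, output_days,
                            mech = mechanical_params(),
                            control = solver_control(), op = NULL) {
  dims <- grid_dims(grid)
  if (any(output_days < t0)) stop("output days must not precede the initial day")
  cap_eff <- effective_capacity(cap, params)
  tmax <- max(output_days)

  rt_days <- numeric(0)
  if (!is.null(rt_events) && NROW(rt_events) > 0) {
    rt_days <- sort(as.data.frame(rt_events)$day)
    rt_days <- rt_days[rt_days >= t0 & rt_days <= tmax]
  }

  dt <- control$dt
  D_cap <- max(params$D_T0, params$D_V0)
  nhalf <- 0
  while (!check_stability(D_cap, dt, grid)$pass) {
    dt <- dt / 2
    nhalf <- nhalf + 1
    if (nhalf > 30) stop("could not stabilize the explicit scheme")
  }
  if (nhalf > 0)
    warning(sprintf("time step halved %d times (dt = %.4g) to satisfy stability", nhalf, dt))

  phi_T <- check_field(phi_T0, grid, "phi_T0", fraction = TRUE)
  phi_V <- check_field(phi_V0, grid, "phi_V0", fraction = TRUE)

  thr <- control$extent_threshold
  if (is.null(thr)) thr <- 0.5 * cap_eff$theta_min
  last_d_mask <- NULL
  last_d <- NULL
  refresh_d <- function(pt) {
    m <- pt >= thr & grid$brain_mask
    if (!is.null(last_d_mask) && identical(m, last_d_mask)) return(last_d)
    last_d_mask <<- m
    last_d <<- if (!any(m)) array(0, dims) else compute_distance_to_periphery(m, grid)$d
    last_d
  }

  use_mech <- isTRUE(control$mechanics) && mech$lambda1 > 0
  if (use_mech && is.null(op)) op <- cached_elasticity_operator(grid, mech)
  D_T <- array(params$D_T0, dims)
  D_V <- array(params$D_V0, dims)
  phi_at_mech <- phi_T
  t_at_mech <- -Inf
  refresh_mech <- function(pt, now) {
    u <- solve_displacement(pt, mech, grid, op = op)
    vm <- von_mises(u, mech, grid, op = op)
    list(D_T = damp_diffusion(params$D_T0, mech$lambda1, vm),
         D_V = damp_diffusion(params$D_V0, mech$lambda1, vm))
  }
  if (use_mech) {
    Dl <- refresh_mech(phi_T, t0); D_T <- Dl$D_T; D_V <- Dl$D_V
    phi_at_mech <- phi_T; t_at_mech <- t0
  }

  kp_T0 <- if (length(params$kp_T0) == 1L) array(params$kp_T0, dims) else
    array(params$kp_T0, dims)
  kp_T_eff <- kp_T0
  kd_T_eff <- array(0, dims)
  kp_V_eff <- array(params$kp_V, dims)
  kd_V_rt <- array(0, dims)
  n_frac <- 0L
  min_seen <- 0

  apply_rt <- function() {
    n_frac <<- n_frac + 1L
    theta_T <- update_carrying_capacity(phi_V, cap_eff)
    C_t <- coupling_field(spec, phi_T, theta_T, phi_V, cap_eff$theta_V,
                          params$alpha1, species = "tumor")
    C_v <- coupling_field(spec, phi_T, theta_T, phi_V, cap_eff$theta_V,
                          params$alpha1, species = "vascular")
    if (spec$rtm %in% c("RTM1", "RTM2")) {
      phi_T <<- apply_rt_instantaneous(phi_T, C_t, params$SF)
      phi_V <<- apply_rt_instantaneous(phi_V, C_v, params$SF)
    }
    if (spec$rtm %in% c("RTM2", "RTM3")) {
      kp_T_eff <<- effective_proliferation(kp_T0, C_t, params$SF, n_frac)
      kp_V_eff <<- array(effective_proliferation(params$kp_V, C_v, params$SF, n_frac), dims)
    }
    if (spec$rtm == "RTM3") {
      kd_T_eff <<- effective_death(params$kd_T0, C_t, params$SF, n_frac)
      kd_V_rt <<- effective_death(params$kd_V, C_v, params$SF, n_frac)
    }
  }

  events <- sort(unique(c(output_days, rt_days)))
  events <- events[events >= t0]
  out_T <- vector("list", length(output_days))
  out_V <- vector("list", length(output_days))
  names(out_T) <- names(out_V) <- as.character(output_days)

  snapshot <- function(day) {
    key <- as.character(day)
    out_T[[key]] <<- phi_T
    out_V[[key]] <<- phi_V
  }

  cur <- t0
  d_field <- refresh_d(phi_T)
  if (events[1] == t0) {
    if (t0 %in% output_days) snapshot(t0)
    if (t0 %in% rt_days) apply_rt()
    events <- events[-1]
  }

  for (target in events) {
    nsteps <- round((target - cur) / dt)
    done <- 0L
    d_field <- refresh_d(phi_T)
    while (done < nsteps) {
      if (use_mech &&
          (cur + done * dt - t_at_mech >= control$mech_interval_days - 1e-9 ||
           max(abs(phi_T - phi_at_mech)) > control$mech_dphi)) {
        Dl <- refresh_mech(phi_T, cur + done * dt)
        D_T <- Dl$D_T; D_V <- Dl$D_V
        phi_at_mech <- phi_T; t_at_mech <- cur + done * dt
      }
      take <- min(control$d_refresh_steps, nsteps - done)
      res <- step_fields(phi_T, phi_V, cap_eff, D_T, D_V,
                         kp_T_eff, kd_T_eff, kp_V_eff, params$kd_V, kd_V_rt,
                         d_field, dt, grid, nsteps = take)
      phi_T <- res$phi_T
      phi_V <- res$phi_V
      min_seen <- min(min_seen, res$min_value)
      done <- done + take
      if (done < nsteps) d_field <- refresh_d(phi_T)
    }
    cur <- target
    if (target %in% output_days) snapshot(target)
    if (target %in% rt_days) apply_rt()
  }

  if (min_seen < -control$overshoot_warn)
    warning(sprintf("negative overshoot %.3g before clipping; explicit scheme near stability limit", min_seen))

  structure(list(days = output_days, phi_T = out_T, phi_V = out_V,
                 n_fractions = n_frac, dt = dt, min_value = min_seen),
            class = "growth_trajectory")
}
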