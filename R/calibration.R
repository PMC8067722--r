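#' Voxelwise proliferation-field parameterization
#'
#' Tiles the tumor bounding box of each axial slice into 3 x 3 in-plane
#' blocks; within each complete block the four corners and the centre are
#' calibration nodes, and every other tumor voxel (the block edge midpoints,
#' partial-block strips, and voxels outside all blocks) takes the value of
#' its nearest node (Euclidean distance in mm, ties broken by lowest linear
#' index). Calibrating only the nodes reduces the parameter count to roughly
#' 5/9 of the tumor voxels and spatially regularizes the field.
#'
#' @param tumor_union_mask Logical 3D array: union of measured tumor masks
#'   over the fitted visits.
#' @param grid A [grid3d()].
#' @return Object of class `kp_parameterization` with `node_indices` (linear
#'   voxel indices of the nodes), `assign` (for every brain-mask voxel, the
#'   node supplying its value) and `n_nodes`.
#' @export
build_kp_parameterization <- function(tumor_union_mask, grid) {
  dims <- grid_dims(grid)
  mask <- array(as.logical(tumor_union_mask), dims)
  if (!any(mask)) stop("tumor mask is empty")
  sp <- grid_spacings(grid)
  nodes <- integer(0)
  offs <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2), c(1, 1))
  for (k in seq_len(dims[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    ij <- which(sl, arr.ind = TRUE)
    i0 <- min(ij[, 1]); i1 <- max(ij[, 1])
    j0 <- min(ij[, 2]); j1 <- max(ij[, 2])
    bi <- seq(i0, i1 - 2, by = 3)
    bj <- seq(j0, j1 - 2, by = 3)
    for (oi in bi) for (oj in bj) for (r in seq_len(nrow(offs))) {
      i <- oi + offs[r, 1]; j <- oj + offs[r, 2]
      if (sl[i, j]) nodes <- c(nodes, vox_index(i, j, k, dims))
    }
  }
  nodes <- sort(unique(nodes))
  if (length(nodes) == 0) nodes <- which(mask)
  ijk <- function(lin) {
    kk <- (lin - 1L) %/% (dims[1] * dims[2])
    r <- (lin - 1L) %% (dims[1] * dims[2])
    cbind(r %% dims[1] + 1L, r %/% dims[1] + 1L, kk + 1L)
  }
  npos <- sweep(ijk(nodes), 2, sp, `*`)
  dom <- which(grid$brain_mask)
  dpos <- sweep(ijk(dom), 2, sp, `*`)
  assign_idx <- integer(length(dom))
  chunk <- max(1L, floor(2e6 / length(nodes)))
  for (start in seq(1L, length(dom), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(dom))
    d2 <- outer(dpos[sel, 1], npos[, 1], `-`)^2 +
          outer(dpos[sel, 2], npos[, 2], `-`)^2 +
          outer(dpos[sel, 3], npos[, 3], `-`)^2
    assign_idx[sel] <- apply(d2, 1, which.min)  # which.min takes the first (lowest index) on ties
  }
  structure(list(node_indices = nodes, domain_indices = dom,
                 assign = assign_idx, n_nodes = length(nodes),
                 tumor_mask = mask, dims = dims),
            class = "kp_parameterization")
}

#' Expand node values to a full proliferation field
#'
#' @param values Numeric vector, one value per node of `param`.
#' @param param A [build_kp_parameterization()] result.
#' @return Full-grid 3D array (nearest-node value everywhere in the brain
#'   mask, 0 outside).
#' @export
kp_field_from_nodes <- function(values, param) {
  if (length(values) != param$n_nodes) stop("one value per node required")
  out <- array(0, param$dims)
  out[param$domain_indices] <- values[param$assign]
  out
}

# in-plane dilation of a logical mask by `times` voxels
dilate_inplane <- function(mask, times = 2) {
  dims <- dim(mask)
  out <- mask
  for (t in seq_len(times)) {
    g <- out
    g[-1, , ] <- g[-1, , ] | out[-dims[1], , ]
    g[-dims[1], , ] <- g[-dims[1], , ] | out[-1, , ]
    g[, -1, ] <- g[, -1, ] | out[, -dims[2], ]
    g[, -dims[2], ] <- g[, -dims[2], ] | out[, -1, ]
    out <- g
  }
  out
}

#' Visits used for a calibration scenario
#'
#' Scenario 1 fits all imaging visits; scenario 2 fits the first half
#' (ceiling of V/2) and reserves the remainder for forecast validation.
#'
#' @param dataset An [animal_dataset()].
#' @param scenario 1 or 2.
#' @return List with integer vectors `fitted` and `held_out`.
#' @export
scenario_visits <- function(dataset, scenario = 1) {
  V <- length(dataset$visits)
  if (scenario == 1) return(list(fitted = seq_len(V), held_out = integer(0)))
  nf <- ceiling(V / 2)
  list(fitted = seq_len(nf), held_out = setdiff(seq_len(V), seq_len(nf)))
}

# ---- parameter vector plumbing --------------------------------------------

free_parameter_names <- function(spec, kp_param = NULL) {
  nm <- c("D_T0", "D_V0", "phi_V_thresh", "theta_max", "kp_V", "kd_V", "SF")
  if (spec$kp_mode == "global") nm <- c("kp_T0", nm)
  if (spec$rtm == "RTM3") nm <- c(nm, "kd_T0")
  if (spec$coupling == "C2") nm <- c(nm, "alpha1")
  if (spec$kp_mode == "local") {
    if (is.null(kp_param)) stop("local specs require a kp parameterization")
    nm <- c(nm, paste0("kp_node_", seq_len(kp_param$n_nodes)))
  }
  nm
}

#' Default calibration bounds
#'
#' Rates in `[1e-3, 10]` per day, diffusion coefficients in `[1e-4, 0.2]`
#' mm^2/day, `SF` in `[0.5, 1]`, `phi_V_thresh` in `[1e-3, theta_V]`,
#' `theta_max` in `[theta_min, 1]`, `alpha1` in `[0, 10]`; each bracket holds
#' plausible image-based estimates with ample margin.
#'
#' @param capacity A [capacity_state()] supplying `theta_min` and `theta_V`.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(capacity) {
  list(kp_T0 = c(1e-3, 10), kd_T0 = c(1e-3, 10),
       D_T0 = c(1e-4, 0.2), D_V0 = c(1e-4, 0.2),
       phi_V_thresh = c(1e-3, capacity$theta_V),
       theta_max = c(capacity$theta_min, 1),
       kp_V = c(1e-3, 10), kd_V = c(1e-3, 10),
       SF = c(0.5, 1), alpha1 = c(0, 10))
}

# Optimizer coordinates: rate-like parameters whose bounds span orders of
# magnitude are searched on the log scale; narrow parameters (SF, capacities,
# alpha1) stay linear. Estimates, intervals and sampling remain on the
# natural scale.
param_transforms <- function(lower, upper) {
  use_log <- lower > 0 & upper / pmax(lower, 1e-300) > 50
  list(
    use_log = use_log,
    fwd = function(x) ifelse(use_log, log(x), x),
    inv = function(z) ifelse(use_log, exp(z), z),
    lower = ifelse(use_log, log(lower), lower),
    upper = ifelse(use_log, log(upper), upper))
}

bounds_for <- function(names, bounds) {
  base <- function(nm) if (startsWith(nm, "kp_node_")) "kp_T0" else nm
  lower <- vapply(names, function(nm) bounds[[base(nm)]][1], numeric(1))
  upper <- vapply(names, function(nm) bounds[[base(nm)]][2], numeric(1))
  list(lower = lower, upper = upper)
}

theta_to_params <- function(theta, spec, fixed, kp_param = NULL) {
  get <- function(nm, default = NULL) {
    if (nm %in% names(theta)) return(unname(theta[[nm]]))
    if (nm %in% names(fixed)) return(fixed[[nm]])
    default
  }
  kp <- if (spec$kp_mode == "local") {
    nodes <- theta[startsWith(names(theta), "kp_node_")]
    kp_field_from_nodes(unname(nodes), kp_param)
  } else get("kp_T0")
  parameter_set(kp_T0 = kp,
                kd_T0 = if (spec$rtm == "RTM3") get("kd_T0") else 0,
                D_T0 = get("D_T0"), D_V0 = get("D_V0"),
                phi_V_thresh = get("phi_V_thresh"),
                theta_max = get("theta_max"),
                kp_V = get("kp_V"), kd_V = get("kd_V"),
                SF = get("SF"),
                alpha1 = if (spec$coupling == "C2") get("alpha1") else 0)
}

# ---- objective -------------------------------------------------------------

make_objective <- function(dataset, spec, fitted_idx, capacity = NULL,
                           mech = mechanical_params(),
                           control = solver_control(), kp_param = NULL,
                           support = NULL) {
  if (length(fitted_idx) < 2) stop("calibration needs at least 2 fitted visits")
  visits <- dataset$visits[fitted_idx]
  grid <- dataset$grid
  if (is.null(capacity)) capacity <- dataset$capacity
  if (is.null(support)) {
    union_mask <- Reduce(`|`, lapply(visits, function(v) v$tumor_mask))
    support <- dilate_inplane(union_mask, 2) & grid$brain_mask
  }
  t0 <- visits[[1]]$day
  later <- visits[-1]
  days <- vapply(later, function(v) v$day, numeric(1))
  n_obs <- 2L * sum(support) * length(later)
  use_mech <- isTRUE(control$mechanics) && mech$lambda1 > 0
  op <- if (use_mech) cached_elasticity_operator(grid, mech) else NULL
  meas <- unlist(lapply(later, function(v) c(v$phi_T[support], v$phi_V[support])))

  residual_fn <- function(params) {
    tr <- tryCatch(
      suppressWarnings(simulate_growth(grid, visits[[1]]$phi_T, visits[[1]]$phi_V,
                                       capacity, params, spec, t0,
                                       rt_events = dataset$rt_events,
                                       output_days = days, mech = mech,
                                       control = control, op = op)),
      error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    model <- unlist(lapply(as.character(days), function(k)
      c(tr$phi_T[[k]][support], tr$phi_V[[k]][support])))
    model - meas
  }
  list(residual_fn = residual_fn, n_obs = n_obs, support = support,
       capacity = capacity, t0 = t0, days = days, op = op, grid = grid,
       mech = mech, control = control)
}

#' Residual sum of squares of a parameter set
#'
#' Simulates the model forward from the first fitted visit and accumulates
#' squared residuals of both tumor and blood volume fractions against every
#' later fitted visit over the evaluation support (the union of measured
#' tumor masks over the fitted visits, dilated by 2 voxels in-plane).
#'
#' @param params A [parameter_set()].
#' @param spec A [model_spec()].
#' @param dataset An [animal_dataset()].
#' @param fitted_visits Integer indices of the fitted visits (default: all).
#' @param capacity Capacity bounds (defaults to `dataset$capacity`).
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @return List with `RSS`, `n_obs` and the residual vector (`RSS = Inf` with
#'   `residuals = NULL` if the forward solve fails).
#' @export
objective_rss <- function(params, spec, dataset,
                          fitted_visits = seq_along(dataset$visits),
                          capacity = NULL, mech = mechanical_params(),
                          control = solver_control()) {
  obj <- make_objective(dataset, spec, fitted_visits, capacity, mech, control)
  r <- obj$residual_fn(params)
  if (is.null(r)) return(list(RSS = Inf, n_obs = obj$n_obs, residuals = NULL))
  list(RSS = sum(r^2), n_obs = obj$n_obs, residuals = r)
}

# ---- Wald machinery (generic, reused by tests) -----------------------------

numeric_jacobian <- function(fn, par, r0 = NULL, rel_step = 1e-5) {
  if (is.null(r0)) r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1e-3)
    pj <- par; pj[j] <- pj[j] + h
    rj <- fn(pj)
    if (is.null(rj)) rj <- r0
    J[, j] <- (rj - r0) / h
  }
  J
}

wald_intervals <- function(fn, par, level = 0.95, r0 = NULL, J = NULL) {
  if (is.null(r0)) r0 <- fn(par)
  if (is.null(J)) J <- numeric_jacobian(fn, par, r0 = r0)
  n <- length(r0); k <- length(par)
  dof <- n - k
  if (dof < 1) stop("more parameters than observations")
  s2 <- sum(r0^2) / dof
  sv <- svd(J)
  tol <- max(sv$d) * 1e-10
  inv_d2 <- ifelse(sv$d > tol, 1 / sv$d^2, Inf)
  se <- sqrt(s2 * colSums(t(sv$v)^2 * inv_d2))
  tq <- stats::qt((1 + level) / 2, dof)
  data.frame(parameter = names(par), estimate = unname(par),
             se = unname(se),
             lower = unname(par - tq * se), upper = unname(par + tq * se),
             row.names = NULL)
}

# ---- simulated annealing ----------------------------------------------------

#' Annealing schedule for the global calibration phase
#'
#' Geometric cooling from `T0` by factor `cooling` with `iters_per_temp`
#' Metropolis proposals per temperature, stopping below `T_min`.
#'
#' @param T0 Initial temperature (relative to the starting RSS).
#' @param cooling Geometric cooling ratio.
#' @param iters_per_temp Proposals per temperature level.
#' @param T_min Stopping temperature.
#' @param step_frac Proposal SD as a fraction of each parameter's box width
#'   (scaled by `sqrt(T)`).
#' @return List of class `sa_control`.
#' @export
sa_control <- function(T0 = 1, cooling = 0.95, iters_per_temp = 50,
                       T_min = 1e-3, step_frac = 0.25) {
  structure(list(T0 = T0, cooling = cooling, iters_per_temp = iters_per_temp,
                 T_min = T_min, step_frac = step_frac), class = "sa_control")
}

anneal <- function(rss_fn, par0, lower, upper, sa = sa_control()) {
  par <- par0
  f <- rss_fn(par)
  tries <- 0
  while (!is.finite(f) && tries < 20) {
    par <- lower + stats::runif(length(par)) * (upper - lower)
    f <- rss_fn(par)
    tries <- tries + 1
  }
  if (!is.finite(f)) stop("no feasible starting point found for annealing")
  scale <- max(f, 1e-12)
  best <- par; fbest <- f
  width <- upper - lower
  archive <- list(list(par = par, rss = f))
  temp <- sa$T0
  while (temp > sa$T_min) {
    for (i in seq_len(sa$iters_per_temp)) {
      prop <- par + stats::rnorm(length(par), 0, sa$step_frac * sqrt(temp)) * width
      prop <- pmin(pmax(prop, lower), upper)
      fp <- rss_fn(prop)
      if (!is.finite(fp)) next
      archive[[length(archive) + 1L]] <- list(par = prop, rss = fp)
      if (fp < f || stats::runif(1) < exp(-(fp - f) / (temp * scale))) {
        par <- prop; f <- fp
        if (f < fbest) { best <- par; fbest <- f }
      }
    }
    temp <- temp * sa$cooling
  }
  # runner-up start for the local phase: best archived point well separated
  # from the optimum (at least 15% of the box diagonal away)
  diag2 <- sum(width^2)
  runner <- NULL; frunner <- Inf
  for (a in archive) {
    if (sum((a$par - best)^2) < 0.0225 * diag2) next
    if (a$rss < frunner) { runner <- a$par; frunner <- a$rss }
  }
  list(par = best, rss = fbest, runner = runner)
}

# ---- main calibration entry -------------------------------------------------

#' Calibrate a model-family member to imaging data
#'
#' Hybrid global/local optimization of a member's free parameters against the
#' tumor and blood volume-fraction maps of the fitted visits: a simulated
#' annealing pass over the bounded parameter box (geometric cooling) followed
#' by bounded Levenberg-Marquardt refinement from the best anneal point with
#' a numerical Jacobian (converged when the relative RSS change drops below
#' `1e-6`). Wald-type 95% confidence intervals are then derived from the
#' Jacobian at the optimum, and `n_samples` parameter sets are drawn
#' uniformly within the intervals (truncated to the hard bounds) for the
#' forecast ensembles. Deterministic given `seed`.
#'
#' @param dataset An [animal_dataset()].
#' @param spec A [model_spec()].
#' @param scenario 1 (fit all visits) or 2 (fit the first half).
#' @param bounds Named list of `c(lower, upper)` bounds; defaults to
#'   [default_bounds()].
#' @param seed Integer seed.
#' @param fixed Named list of parameter values to hold fixed (excluded from
#'   the optimizer, from `k` and from the intervals).
#' @param init Optional named starting values (otherwise the box midpoint).
#' @param sa A [sa_control()]; set `iters_per_temp` or the cooling ratio to
#'   trade global search effort for speed.
#' @param mech A [mechanical_params()].
#' @param control A [solver_control()].
#' @param n_samples Number of parameter sets drawn from the intervals.
#' @param lm_maxiter Maximum Levenberg-Marquardt iterations.
#' @param lm_from_init Also run a Levenberg-Marquardt polish from the
#'   starting point (box midpoint or `init`), guarding against an annealing
#'   phase that drifts onto a saturated plateau of the objective.
#' @return Object of class `calibration_result`: `spec`, `params_hat`
#'   (a [parameter_set()]), `theta_hat` (named vector of calibrated scalars),
#'   `RSS`, `k`, `n_obs`, `ci95` (data frame), `sampled_sets`, `AIC`, `seed`,
#'   plus the scenario bookkeeping.
#' @export
calibrate <- function(dataset, spec, scenario = 1, bounds = NULL, seed = 1L,
                      fixed = list(), init = NULL, sa = sa_control(),
                      mech = mechanical_params(), control = solver_control(),
                      n_samples = 100, lm_maxiter = 100, lm_from_init = FALSE) {
  vis <- scenario_visits(dataset, scenario)
  if (length(vis$fitted) < 2) stop("calibration needs at least 2 fitted visits")
  capacity <- dataset$capacity
  if (is.null(bounds)) bounds <- default_bounds(capacity)

  kp_param <- NULL
  if (spec$kp_mode == "local") {
    union_mask <- Reduce(`|`, lapply(dataset$visits[vis$fitted],
                                     function(v) v$tumor_mask))
    kp_param <- build_kp_parameterization(union_mask, dataset$grid)
  }
  free <- setdiff(free_parameter_names(spec, kp_param), names(fixed))
  if (length(free) == 0) stop("no free parameters")
  bb <- bounds_for(free, bounds)

  obj <- make_objective(dataset, spec, vis$fitted, capacity, mech, control,
                        kp_param = kp_param)
  if (obj$n_obs <= length(free) + 1)
    stop("too few observations for the number of calibrated parameters")

  resid_theta <- function(theta) {
    names(theta) <- free
    obj$residual_fn(theta_to_params(theta, spec, fixed, kp_param))
  }
  rss_theta <- function(theta) {
    r <- resid_theta(theta)
    if (is.null(r)) Inf else sum(r^2)
  }

  set.seed(seed)
  tf <- param_transforms(bb$lower, bb$upper)
  z0 <- (tf$lower + tf$upper) / 2
  if (!is.null(init)) {
    hit <- names(init)[names(init) %in% free]
    nat <- (bb$lower + bb$upper) / 2
    nat[match(hit, free)] <- unlist(init)[hit]
    z0 <- tf$fwd(nat)
  }
  names(z0) <- free
  rss_z <- function(z) rss_theta(tf$inv(z))
  ann <- anneal(rss_z, z0, tf$lower, tf$upper, sa)

  big <- sqrt(1e6 / obj$n_obs)
  lm_resid <- function(z) {
    r <- resid_theta(tf$inv(pmin(pmax(z, tf$lower), tf$upper)))
    if (is.null(r)) rep(big, obj$n_obs) else r
  }
  run_lm <- function(z_start) {
    lm <- minpack.lm::nls.lm(par = z_start, fn = lm_resid,
                             lower = tf$lower, upper = tf$upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = lm_maxiter, ftol = 1e-6, ptol = 1e-8,
                               factor = 0.5))
    z <- pmin(pmax(unlist(lm$par), tf$lower), tf$upper)
    list(z = z, rss = rss_z(z))
  }
  cand <- list(run_lm(ann$par))
  if (!is.null(ann$runner)) cand[[length(cand) + 1L]] <- run_lm(ann$runner)
  if (lm_from_init && sum((z0 - ann$par)^2) > 1e-12)
    cand[[length(cand) + 1L]] <- run_lm(z0)
  rss_cand <- vapply(cand, function(c) c$rss, numeric(1))
  rss_cand[!is.finite(rss_cand)] <- Inf
  theta_hat <- tf$inv(cand[[which.min(rss_cand)]]$z)
  names(theta_hat) <- free
  r_hat <- resid_theta(theta_hat)
  if (is.null(r_hat)) {
    theta_hat <- tf$inv(ann$par); names(theta_hat) <- free
    r_hat <- resid_theta(theta_hat)
  }
  if (is.null(r_hat)) stop("calibration failed: no feasible optimum")
  RSS <- sum(r_hat^2)
  if (RSS > ann$rss + 1e-12) { # LM must not worsen the anneal optimum
    theta_hat <- tf$inv(ann$par); names(theta_hat) <- free
    r_hat <- resid_theta(theta_hat); RSS <- sum(r_hat^2)
  }

  ci <- wald_intervals(function(th) { r <- resid_theta(th); if (is.null(r)) r_hat else r },
                       theta_hat, r0 = r_hat)
  k <- length(free)
  aicc <- if (RSS > 0) aic(k, obj$n_obs, RSS) else -Inf

  result <- structure(list(spec = spec, theta_hat = theta_hat,
                           params_hat = theta_to_params(theta_hat, spec, fixed, kp_param),
                           fixed = fixed, kp_param = kp_param,
                           RSS = RSS, k = k, n_obs = obj$n_obs,
                           ci95 = ci, AIC = aicc, seed = seed,
                           bounds = bb, free = free,
                           scenario = scenario, fitted_visits = vis$fitted,
                           held_out_visits = vis$held_out,
                           capacity = capacity, sa_rss = ann$rss),
                      class = "calibration_result")
  result$sampled_sets <- sample_parameters(result, count = n_samples,
                                           seed = seed + 1L)
  result
}

#' @export
#' @method print calibration_result
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %s  RSS = %.4g  k = %d  n = %d  AICc = %.4g\n",
              spec_token(x$spec), x$RSS, x$k, x$n_obs, x$AIC))
  invisible(x)
}

#' Wald 95% confidence intervals of a calibration
#'
#' Linearized intervals `estimate +/- t(0.975, n - k) * SE`, with standard
#' errors from the Jacobian-based covariance scaled by `RSS / (n - k)`.
#' Directions in which the Jacobian is rank deficient yield infinite
#' intervals.
#'
#' @param result A [calibrate()] result.
#' @return Data frame with columns `parameter`, `estimate`, `se`, `lower`,
#'   `upper`.
#' @export
confidence_intervals <- function(result) result$ci95

#' Sample parameter sets from the confidence intervals
#'
#' Independent uniform draws of each calibrated scalar within its 95%
#' interval, truncated to the hard bounds; degenerate (zero-width) intervals
#' reproduce the estimate. Used to propagate calibration uncertainty into
#' forecast ensembles.
#'
#' @param result A [calibrate()] result.
#' @param count Number of sets (default 100).
#' @param seed Integer seed.
#' @return List of `count` [parameter_set()] objects.
#' @export
sample_parameters <- function(result, count = 100, seed = 1L) {
  ci <- result$ci95
  lo <- pmax(ifelse(is.finite(ci$lower), ci$lower, result$bounds$lower),
             result$bounds$lower)
  hi <- pmin(ifelse(is.finite(ci$upper), ci$upper, result$bounds$upper),
             result$bounds$upper)
  bad <- lo > hi
  lo[bad] <- hi[bad] <- result$theta_hat[bad]
  set.seed(seed)
  lapply(seq_len(count), function(j) {
    theta <- stats::runif(length(lo), lo, hi)
    names(theta) <- result$free
    theta_to_params(theta, result$spec, result$fixed, result$kp_param)
  })
}
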