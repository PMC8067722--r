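test_that("the proliferation-field nodes tile 3x3 blocks with 5 nodes each", {
  g <- grid3d(9, 9, 1)
  m <- array(FALSE, c(9, 9, 1)); m[4:6, 4:6, 1] <- TRUE
  kp <- build_kp_parameterization(m, g)
  expect_equal(kp$n_nodes, 5)
  # constant node values reconstruct a constant field over the tumor
  f <- kp_field_from_nodes(rep(1.3, 5), kp)
  expect_true(all(f[m] == 1.3))
})

test_that("non-node voxels take their nearest node value (ties to lowest index)", {
  g <- grid3d(12, 12, 2)
  set.seed(4)
  m <- smooth_field(c(12, 12, 2), seed = 44, lo = 0, hi = 1) > 0.55
  m[, , ] <- m & array(TRUE, c(12, 12, 2))
  if (!any(m)) m[5:7, 5:7, 1] <- TRUE
  kp <- build_kp_parameterization(m, g)
  vals <- runif(kp$n_nodes, 0.5, 2)
  f <- kp_field_from_nodes(vals, kp)
  # brute-force nearest-node oracle
  dims <- c(12, 12, 2)
  sp <- c(g$dx, g$dy, g$dz)
  to_ijk <- function(lin) {
    k <- (lin - 1) %/% (dims[1] * dims[2])
    r <- (lin - 1) %% (dims[1] * dims[2])
    c(r %% dims[1] + 1, r %/% dims[1] + 1, k + 1)
  }
  npos <- t(vapply(kp$node_indices, to_ijk, numeric(3)))
  for (lin in which(m)) {
    p <- to_ijk(lin)
    dd <- sqrt(colSums((t(npos) - p)^2 * sp^2))
    expect_equal(f[lin], vals[which.min(dd)])
  }
})

test_that("the RSS objective is zero at truth and matches a naive double sum", {
  ds <- generate_virtual_animal(tiny_truth(seed = 2), tiny_grid(),
                                control = solver_control(mechanics = FALSE))
  spec <- ds$truth$spec
  r0 <- objective_rss(ds$truth$params, spec, ds,
                      control = solver_control(mechanics = FALSE))
  expect_equal(r0$RSS, 0)
  expect_equal(r0$n_obs, length(r0$residuals))

  # arbitrary (wrong) parameters: naive summation oracle over the support
  params <- parameter_set(kp_T0 = 0.5, kd_T0 = 0.1, D_T0 = 0.01, D_V0 = 0.01,
                          phi_V_thresh = 0.05, theta_max = 0.8, kp_V = 0.3,
                          kd_V = 0.1, SF = 0.95)
  r1 <- objective_rss(params, spec, ds, control = solver_control(mechanics = FALSE))
  grid <- ds$grid
  union_mask <- Reduce(`|`, lapply(ds$visits, function(v) v$tumor_mask))
  support <- rtforecast:::dilate_inplane(union_mask, 2) & grid$brain_mask
  days <- vapply(ds$visits, function(v) v$day, numeric(1))
  tr <- simulate_growth(grid, ds$visits[[1]]$phi_T, ds$visits[[1]]$phi_V,
                        ds$capacity, params, spec, days[1], ds$rt_events,
                        output_days = days[-1],
                        control = solver_control(mechanics = FALSE))
  acc <- 0
  for (vi in 2:length(ds$visits)) {
    key <- as.character(days[vi])
    for (lin in which(support)) {
      acc <- acc + (tr$phi_T[[key]][lin] - ds$visits[[vi]]$phi_T[lin])^2
      acc <- acc + (tr$phi_V[[key]][lin] - ds$visits[[vi]]$phi_V[lin])^2
    }
  }
  expect_equal(r1$RSS, acc, tolerance = 1e-10)
})

test_that("Wald intervals shrink to zero width at zero residual and match a
           bootstrap oracle on a toy exponential regression", {
  # toy model: y = exp(-theta * x) + noise
  set.seed(10)
  x <- seq(0.1, 3, length.out = 40)
  theta_true <- 0.8
  y <- exp(-theta_true * x) + rnorm(40, 0, 0.02)
  resid_fn <- function(par) exp(-par[["theta"]] * x) - y
  fit <- minpack.lm::nls.lm(par = c(theta = 0.3), fn = resid_fn)
  theta_hat <- unlist(fit$par)
  ci <- rtforecast:::wald_intervals(resid_fn, theta_hat)
  expect_equal(ci$estimate, mean(c(ci$lower, ci$upper)), tolerance = 1e-10)

  boot <- replicate(2000, {
    yb <- exp(-theta_hat * x) + sample(resid_fn(theta_hat), replace = TRUE)
    rb <- function(par) exp(-par * x) - yb
    unlist(minpack.lm::nls.lm(par = theta_hat, fn = rb)$par)
  })
  boot_ci <- quantile(boot, c(0.025, 0.975))
  expect_equal(ci$upper - ci$lower, unname(diff(boot_ci)), tolerance = 0.1)

  # zero residuals: interval width collapses
  y0 <- exp(-theta_true * x)
  rf0 <- function(par) exp(-par[["theta"]] * x) - y0
  ci0 <- rtforecast:::wald_intervals(rf0, c(theta = theta_true))
  expect_lt(ci0$upper - ci0$lower, 1e-10)
})

test_that("parameter sampling respects intervals, bounds and the seed", {
  ds <- generate_virtual_animal(tiny_truth(seed = 5, snr = 40), tiny_grid(),
                                control = solver_control(mechanics = FALSE))
  res <- calibrate(ds, ds$truth$spec, seed = 3,
                   fixed = list(kd_T0 = 0.2, D_T0 = 0.02, D_V0 = 0.02,
                                phi_V_thresh = 0.03, theta_max = 0.9,
                                kp_V = 0.6, kd_V = 0.25),
                   init = list(kp_T0 = 0.8, SF = 0.85),
                   sa = sa_control(T0 = 0.1, cooling = 0.5, iters_per_temp = 4,
                                   T_min = 0.01),
                   control = solver_control(mechanics = FALSE), n_samples = 20)
  expect_length(res$sampled_sets, 20)
  ci <- confidence_intervals(res)
  for (ps in res$sampled_sets) {
    expect_gte(ps$kp_T0, max(ci$lower[ci$parameter == "kp_T0"], res$bounds$lower[["kp_T0"]]))
    expect_lte(ps$SF, min(ci$upper[ci$parameter == "SF"], 1))
  }
  again <- sample_parameters(res, count = 20, seed = res$seed + 1L)
  expect_identical(vapply(again, function(p) p$SF, numeric(1)),
                   vapply(res$sampled_sets, function(p) p$SF, numeric(1)))
})

test_that("truth-initialized refinement sits at the zero-residual optimum and
           repeated calibration is deterministic", {
  ds <- generate_virtual_animal(tiny_truth(seed = 6), tiny_grid(),
                                control = solver_control(mechanics = FALSE))
  tp <- ds$truth$params
  fixed <- list(kd_T0 = tp$kd_T0, D_V0 = tp$D_V0, phi_V_thresh = tp$phi_V_thresh,
                theta_max = tp$theta_max, kp_V = tp$kp_V, kd_V = tp$kd_V)
  # annealing disabled (T0 below the stopping temperature): pure LM from truth
  res <- calibrate(ds, ds$truth$spec, seed = 2, fixed = fixed,
                   init = list(kp_T0 = tp$kp_T0, SF = tp$SF, D_T0 = tp$D_T0),
                   sa = sa_control(T0 = 1e-4, T_min = 1e-3),
                   control = solver_control(mechanics = FALSE), n_samples = 5)
  expect_lt(res$RSS, 1e-8)
  res2 <- calibrate(ds, ds$truth$spec, seed = 2, fixed = fixed,
                    init = list(kp_T0 = tp$kp_T0, SF = tp$SF, D_T0 = tp$D_T0),
                    sa = sa_control(T0 = 1e-4, T_min = 1e-3),
                    control = solver_control(mechanics = FALSE), n_samples = 5)
  expect_identical(res$theta_hat, res2$theta_hat)
  expect_identical(res$RSS, res2$RSS)
})

test_that("scenario 2 splits the visits at the ceiling of half", {
  ds <- generate_virtual_animal(tiny_truth(seed = 7), tiny_grid(),
                                control = solver_control(mechanics = FALSE))
  v <- scenario_visits(ds, 2)  # animal5 preset: 4 visits
  expect_equal(v$fitted, 1:2)
  expect_equal(v$held_out, 3:4)
  v1 <- scenario_visits(ds, 1)
  expect_equal(v1$fitted, 1:4)
})
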