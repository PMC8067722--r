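no_mech <- solver_control(mechanics = FALSE)

test_that("the stability criterion guards the explicit scheme", {
  g <- grid3d(8, 8, 4, 0.25, 0.25, 1.0)
  s <- check_stability(0.03, 0.01, g)
  expect_true(s$pass)
  expect_equal(s$margin, 2 * 0.01 * 0.03 * (2 / 0.25^2 + 1), tolerance = 1e-12)
  expect_true(check_stability(0, 100, g)$pass)
  expect_false(check_stability(0.03, 0.6, g)$pass)
})

test_that("an inert system stays exactly unchanged", {
  g <- grid3d(8, 8, 4)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(8, 8, 4), seed = 1, lo = 0, hi = 0.7)
  phi_V <- smooth_field(c(8, 8, 4), seed = 2, lo = 0, hi = 0.1)
  res <- step_fields(phi_T, phi_V, cap, 0, 0, 0, 0, 0, 0, 0,
                     array(0.5, c(8, 8, 4)), 0.01, g, nsteps = 200)
  expect_identical(res$phi_T, phi_T)
  expect_identical(res$phi_V, phi_V)
})

test_that("zero-diffusion untreated voxels follow the logistic closed form", {
  g <- grid3d(2, 2, 1)
  cap <- capacity_state(0.05, 0.90, 0.12, 0.03)
  params <- parameter_set(kp_T0 = 0.84, D_T0 = 0, D_V0 = 0,
                          phi_V_thresh = 0.03, theta_max = 0.90,
                          kp_V = 0, kd_V = 0, SF = 1)
  tr <- simulate_growth(g, array(0.1, c(2, 2, 1)), array(0.05, c(2, 2, 1)),
                        cap, params, model_spec("RTM1", "C3", "global"),
                        t0 = 0, output_days = c(4, 8, 12), control = no_mech)
  for (day in c(4, 8, 12)) {
    expect_equal(tr$phi_T[[as.character(day)]][1, 1, 1],
                 logistic_solution(day, 0.1, 0.84, 0.90), tolerance = 1.2e-3)
  }
})

test_that("total burden is conserved without growth or death", {
  g <- default_grid(16, 16, 4)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(16, 16, 4), seed = 3, lo = 0, hi = 0.7)
  phi_T[!g$brain_mask] <- 0
  phi_V <- smooth_field(c(16, 16, 4), seed = 4, lo = 0, hi = 0.1)
  phi_V[!g$brain_mask] <- 0
  res <- step_fields(phi_T, phi_V, cap, 0.025, 0.02, 0, 0, 0, 0, 0,
                     array(0.5, c(16, 16, 4)), 0.01, g, nsteps = 1000)
  expect_lt(abs(sum(res$phi_T) - sum(phi_T)) / sum(phi_T), 1e-6)
  expect_lt(abs(sum(res$phi_V) - sum(phi_V)) / sum(phi_V), 1e-6)
})

test_that("RTM1 with no spatial coupling jumps burden by exactly SF", {
  g <- grid3d(6, 6, 2)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(6, 6, 2), seed = 9, lo = 0.1, hi = 0.6)
  phi_V <- array(0.05, c(6, 6, 2))
  params <- parameter_set(kp_T0 = 0, D_T0 = 0, D_V0 = 0, phi_V_thresh = 0.04,
                          theta_max = 0.9, kp_V = 0, kd_V = 0, SF = 0.8)
  tr <- simulate_growth(g, phi_T, phi_V, cap, params,
                        model_spec("RTM1", "C3", "global"), t0 = 0,
                        rt_events = data.frame(day = 1, dose = 2),
                        output_days = c(0, 2), control = no_mech)
  expect_equal(sum(tr$phi_T[["2"]]), 0.8 * sum(phi_T), tolerance = 1e-12)
  expect_equal(tr$n_fractions, 1L)
})

test_that("fraction counting follows the treatment schedule", {
  g <- grid3d(4, 4, 2)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  params <- parameter_set(kp_T0 = 0, D_T0 = 0, D_V0 = 0, phi_V_thresh = 0.04,
                          theta_max = 0.9, kp_V = 0, kd_V = 0, SF = 0.95)
  sched <- rt_schedule_preset("animal1")
  tr <- simulate_growth(g, array(0.3, c(4, 4, 2)), array(0.05, c(4, 4, 2)),
                        cap, params, model_spec("RTM1", "C3", "global"),
                        t0 = 0, rt_events = sched$rt_events,
                        output_days = sched$image_days, control = no_mech)
  expect_equal(tr$n_fractions, 10L)
})

test_that("trajectories are reproducible and RT-free runs match plain integration", {
  g <- default_grid(12, 12, 4)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(12, 12, 4), seed = 11, lo = 0, hi = 0.5)
  phi_T[!g$brain_mask] <- 0
  phi_V <- array(0.05, c(12, 12, 4)); phi_V[!g$brain_mask] <- 0
  params <- parameter_set(kp_T0 = 0.8, D_T0 = 0.02, D_V0 = 0.02,
                          phi_V_thresh = 0.04, theta_max = 0.9,
                          kp_V = 0.5, kd_V = 0.2, SF = 0.9)
  run <- function(rt) simulate_growth(g, phi_T, phi_V, cap, params,
                                      model_spec("RTM2", "C1", "global"),
                                      t0 = 0, rt_events = rt,
                                      output_days = c(0, 2, 4),
                                      control = no_mech)
  a <- run(NULL)
  b <- run(NULL)
  expect_identical(a$phi_T, b$phi_T)
  empty_rt <- run(data.frame(day = numeric(0), dose = numeric(0)))
  expect_identical(a$phi_T, empty_rt$phi_T)
})

test_that("RTM3 with zero death rate and SF = 1 reduces to untreated growth", {
  g <- default_grid(12, 12, 4)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(12, 12, 4), seed = 21, lo = 0, hi = 0.5)
  phi_T[!g$brain_mask] <- 0
  phi_V <- array(0.05, c(12, 12, 4)); phi_V[!g$brain_mask] <- 0
  mk <- function(SF, kd) parameter_set(kp_T0 = 0.8, kd_T0 = kd, D_T0 = 0.02,
                                       D_V0 = 0.02, phi_V_thresh = 0.04,
                                       theta_max = 0.9, kp_V = 0.5, kd_V = 1e-9,
                                       SF = SF)
  rt <- data.frame(day = 1:3, dose = 2)
  treated <- simulate_growth(g, phi_T, phi_V, cap, mk(1, 0),
                             model_spec("RTM3", "C3", "global"), t0 = 0,
                             rt_events = rt, output_days = 4, control = no_mech)
  untreated <- simulate_growth(g, phi_T, phi_V, cap, mk(1, 0),
                               model_spec("RTM3", "C3", "global"), t0 = 0,
                               output_days = 4, control = no_mech)
  expect_equal(treated$phi_T[["4"]], untreated$phi_T[["4"]], tolerance = 1e-12)
})

test_that("halving the time step changes the solution at first order only", {
  g <- default_grid(12, 12, 4)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(12, 12, 4), seed = 31, lo = 0, hi = 0.5)
  phi_T[!g$brain_mask] <- 0
  phi_V <- array(0.05, c(12, 12, 4)); phi_V[!g$brain_mask] <- 0
  params <- parameter_set(kp_T0 = 1.0, D_T0 = 0.02, D_V0 = 0.02,
                          phi_V_thresh = 0.04, theta_max = 0.9,
                          kp_V = 0.5, kd_V = 0.2, SF = 0.9)
  run <- function(dt) simulate_growth(g, phi_T, phi_V, cap, params,
                                      model_spec("RTM1", "C3", "global"),
                                      t0 = 0, rt_events = data.frame(day = 2, dose = 2),
                                      output_days = 5,
                                      control = solver_control(dt = dt, mechanics = FALSE))
  coarse <- run(0.01)$phi_T[["5"]]
  fine <- run(0.005)$phi_T[["5"]]
  expect_lt(max(abs(coarse - fine)) / max(fine), 1e-3)
})
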