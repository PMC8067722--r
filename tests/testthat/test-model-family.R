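test_that("the model family enumerates 18 unique members in canonical order", {
  fam <- enumerate_models()
  expect_length(fam, 18)
  tokens <- vapply(fam, spec_token, character(1))
  expect_equal(anyDuplicated(tokens), 0L)
  # voxelwise-kp block first; members 7-9 of each block are the
  # death-rate (RTM3) members
  expect_true(all(vapply(fam[1:9], function(s) s$kp_mode, character(1)) == "local"))
  expect_equal(fam[[7]]$rtm, "RTM3")
  expect_equal(fam[[8]]$rtm, "RTM3")
  expect_equal(fam[[9]]$rtm, "RTM3")
  expect_equal(fam[[1]]$rtm, "RTM1")
  # tokens round-trip through the parser
  for (tok in tokens) expect_equal(spec_token(parse_spec_token(tok)), tok)
})

test_that("coupling fields evaluate their closed forms", {
  dims <- c(2, 2, 1)
  phi_T <- array(0.45, dims); theta_T <- array(0.9, dims)
  phi_V <- array(0, dims); theta_V <- 0.12
  c1 <- coupling_field(model_spec("RTM1", "C1", "global"), phi_T, theta_T,
                       phi_V, theta_V)
  expect_equal(c1[1], 0.5)
  c2a <- coupling_field(model_spec("RTM1", "C2", "global"), phi_T, theta_T,
                        phi_V, theta_V, alpha1 = 4)
  expect_equal(c2a[1], 1)
  c2b <- coupling_field(model_spec("RTM1", "C2", "global"), phi_T, theta_T,
                        array(theta_V, dims), theta_V, alpha1 = 4)
  expect_equal(c2b[1], exp(-4))
  c3 <- coupling_field(model_spec("RTM1", "C3", "global"), phi_T, theta_T,
                       phi_V, theta_V)
  expect_true(all(c3 == 1))
  # vascular analogue of C1 uses phi_V / theta_V
  c1v <- coupling_field(model_spec("RTM1", "C1", "global"), phi_T, theta_T,
                        array(0.06, dims), theta_V, species = "vascular")
  expect_equal(c1v[1], 0.5)
})

test_that("instantaneous kill and effective rates follow the survival law", {
  expect_equal(apply_rt_instantaneous(0.4, 1, 0.8), 0.32)
  expect_equal(apply_rt_instantaneous(0.7, 1, 1), 0.7)
  expect_equal(apply_rt_instantaneous(0.45, 0.45 / 0.9, 0.8), 0.18)

  expect_equal(effective_proliferation(1, 1, 0.9, 2), 0.81)
  expect_equal(effective_proliferation(2.5, 1, 1, 5), 2.5)
  expect_equal(effective_death(0.5, 1, 0.9, 1), 0.05)
  expect_equal(effective_death(0.5, 1, 1, 3), 0)
  expect_equal(effective_death(0.5, 1, 0.9, 500), 0.5, tolerance = 1e-10)
  # nonincreasing in n, bounded by the pre-treatment rates
  kp <- vapply(1:10, function(n) effective_proliferation(1.4, 0.8, 0.9, n), numeric(1))
  kd <- vapply(1:10, function(n) effective_death(0.3, 0.8, 0.9, n), numeric(1))
  expect_true(all(diff(kp) < 0) && all(kp <= 1.4) && all(kp >= 0))
  expect_true(all(diff(kd) > 0) && all(kd <= 0.3) && all(kd >= 0))
  expect_error(effective_proliferation(1, 1, 0.9, 0), "n >= 1")
})

test_that("tumor right-hand side reduces to its analytic limits", {
  g <- grid3d(5, 5, 3, 0.25, 0.25, 1)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  # uniform fields at capacity: diffusion and growth vanish
  phi_V <- array(0.05, c(5, 5, 3))  # above threshold -> theta_T = 0.9
  r0 <- rhs_tumor(array(0.9, c(5, 5, 3)), phi_V, cap, 0.02, 1.1, 0, g)
  expect_equal(max(abs(r0)), 0, tolerance = 1e-14)
  # uniform fields below capacity: pure logistic growth
  r1 <- rhs_tumor(array(0.4, c(5, 5, 3)), phi_V, cap, 0.02, 1.1, 0, g)
  expect_equal(r1, array(1.1 * 0.4 * (1 - 0.4 / 0.9), c(5, 5, 3)),
               tolerance = 1e-13)
})

test_that("PDE right-hand sides match the scalar-loop stencil oracle", {
  g <- grid3d(5, 5, 3, 0.25, 0.25, 1)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  d <- smooth_field(c(5, 5, 3), seed = 5, lo = 0, hi = 1)
  for (rep in 1:3) {
    phi_T <- smooth_field(c(5, 5, 3), seed = 10 + rep, lo = 0, hi = 0.8)
    phi_V <- smooth_field(c(5, 5, 3), seed = 20 + rep, lo = 0, hi = 0.1)
    D_T <- smooth_field(c(5, 5, 3), seed = 30 + rep, lo = 0.005, hi = 0.03)
    rt <- rhs_tumor(phi_T, phi_V, cap, D_T, 1.2, 0.1, g)
    expect_equal(rt, oracle_rhs_tumor(phi_T, phi_V, cap, D_T, 1.2, 0.1, g),
                 tolerance = 1e-10)
    rv <- rhs_vasculature(phi_V, phi_T, cap, 0.02, 0.8, 0.3, d, g)
    expect_equal(rv, oracle_rhs_vasc(phi_V, phi_T, cap, 0.02, 0.8, 0.3, d, g),
                 tolerance = 1e-10)
  }
})

test_that("vasculature right-hand side weights growth and death by depth", {
  g <- grid3d(4, 4, 2, 0.25, 0.25, 1)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  dims <- c(4, 4, 2)
  # at the periphery (d = 1) the death term vanishes
  r_per <- rhs_vasculature(array(0.05, dims), array(0.4, dims), cap,
                           0, 0, 0.5, array(1, dims), g)
  expect_equal(max(abs(r_per)), 0)
  # at capacity with uniform fields only core death remains
  d <- array(0.3, dims)
  r_cap <- rhs_vasculature(array(cap$theta_V, dims), array(0.4, dims), cap,
                           0, 0.8, 0.5, d, g)
  expect_equal(r_cap, array(-0.5 * cap$theta_V * 0.7, dims), tolerance = 1e-13)
})

test_that("the conservative flux form sums to zero over the closed domain", {
  g <- grid3d(6, 6, 4, 0.25, 0.25, 1)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(6, 6, 4), seed = 3, lo = 0, hi = 0.8)
  phi_V <- smooth_field(c(6, 6, 4), seed = 4, lo = 0, hi = 0.1)
  rt <- rhs_tumor(phi_T, phi_V, cap, 0.03, 0, 0, g)
  rv <- rhs_vasculature(phi_V, phi_T, cap, 0.03, 0, 0, array(0.5, c(6, 6, 4)), g)
  expect_lt(abs(sum(rt)) / max(abs(rt)), 1e-10)
  expect_lt(abs(sum(rv)) / max(abs(rv)), 1e-10)
})

test_that("a single explicit step agrees with the R right-hand sides", {
  g <- grid3d(6, 6, 4, 0.25, 0.25, 1)
  cap <- capacity_state(0.1, 0.9, 0.12, 0.04)
  phi_T <- smooth_field(c(6, 6, 4), seed = 13, lo = 0, hi = 0.7)
  phi_V <- smooth_field(c(6, 6, 4), seed = 14, lo = 0, hi = 0.1)
  d <- smooth_field(c(6, 6, 4), seed = 15, lo = 0, hi = 1)
  dt <- 0.01
  res <- step_fields(phi_T, phi_V, cap, 0.02, 0.015, 1.2, 0.1, 0.8, 0.3, 0.05,
                     d, dt, g, nsteps = 1)
  exp_T <- phi_T + dt * rhs_tumor(phi_T, phi_V, cap, 0.02, 1.2, 0.1, g)
  exp_V <- phi_V + dt * (rhs_vasculature(phi_V, phi_T, cap, 0.015, 0.8, 0.3, d, g) -
                         0.05 * phi_V)
  exp_V[!g$brain_mask] <- phi_V[!g$brain_mask]
  expect_equal(res$phi_T, pmin(pmax(exp_T, 0), 1), tolerance = 1e-13)
  expect_equal(res$phi_V, pmin(pmax(exp_V, 0), 1), tolerance = 1e-13)
})
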