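# Independent brute-force oracles used to validate the implementation's
# numerics, written as plain scalar loops.

# all-pairs distance-to-boundary oracle, rescaled like the implementation
oracle_distance <- function(tumor_mask, grid) {
  dims <- dim(tumor_mask)
  sp <- c(grid$dx, grid$dy, grid$dz)
  idx <- which(tumor_mask, arr.ind = TRUE)
  inside <- function(p) all(p >= 1) && p[1] <= dims[1] && p[2] <= dims[2] && p[3] <= dims[3]
  is_b <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                    c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
      if (!inside(nb) || !tumor_mask[nb[1], nb[2], nb[3]]) { is_b[r] <- TRUE; break }
    }
  }
  bpos <- idx[is_b, , drop = FALSE]
  dist <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    dd <- sqrt(((idx[r, 1] - bpos[, 1]) * sp[1])^2 +
               ((idx[r, 2] - bpos[, 2]) * sp[2])^2 +
               ((idx[r, 3] - bpos[, 3]) * sp[3])^2)
    dist[r] <- min(dd)
  }
  out <- array(0, dims)
  dmax <- max(dist)
  out[tumor_mask] <- if (dmax == 0) 1 else 1 - dist / dmax
  out
}

# scalar-loop face-flux divergence oracle for the cross-diffusion term
oracle_cross_div <- function(phi_a, phi_b, theta_TV, D, grid) {
  dims <- dim(phi_a)
  mask <- grid$brain_mask
  h <- c(grid$dx, grid$dy, grid$dz)
  a <- phi_a / theta_TV
  b <- phi_b / theta_TV
  if (length(D) == 1) D <- array(D, dims)
  out <- array(0, dims)
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (!mask[i, j, k]) next
    for (ax in 1:3) for (s in c(1, -1)) {
      q <- c(i, j, k) + s * offs[[ax]]
      if (any(q < 1) || q[1] > dims[1] || q[2] > dims[2] || q[3] > dims[3]) next
      if (!mask[q[1], q[2], q[3]]) next
      Dp <- D[i, j, k]; Dq <- D[q[1], q[2], q[3]]
      Df <- if (Dp + Dq > 0) 2 * Dp * Dq / (Dp + Dq) else 0
      ap <- a[i, j, k]; aq <- a[q[1], q[2], q[3]]
      bp <- b[i, j, k]; bq <- b[q[1], q[2], q[3]]
      af <- (ap + aq) / 2; bf <- (bp + bq) / 2
      Fx <- Df * ((1 - bf) * (aq - ap) / h[ax] + af * (bq - bp) / h[ax])
      out[i, j, k] <- out[i, j, k] + Fx / h[ax]
    }
  }
  out
}

oracle_rhs_tumor <- function(phi_T, phi_V, cap, D_T, kp_T, kd_T, grid) {
  theta_T <- update_carrying_capacity(phi_V, cap)
  out <- oracle_cross_div(phi_T, phi_V, theta_T + cap$theta_V, D_T, grid) +
    kp_T * phi_T * (1 - phi_T / theta_T) - kd_T * phi_T
  out[!grid$brain_mask] <- 0
  out
}

oracle_rhs_vasc <- function(phi_V, phi_T, cap, D_V, kp_V, kd_V, d, grid) {
  theta_T <- update_carrying_capacity(phi_V, cap)
  out <- oracle_cross_div(phi_V, phi_T, theta_T + cap$theta_V, D_V, grid) +
    kp_V * phi_V * (1 - phi_V / cap$theta_V) * d - kd_V * phi_V * (1 - d)
  out[!grid$brain_mask] <- 0
  out
}

# smooth random field in [lo, hi] (neighbour-averaged white noise)
smooth_field <- function(dims, seed, lo = 0, hi = 1, passes = 3) {
  set.seed(seed)
  f <- array(runif(prod(dims)), dims)
  for (p in seq_len(passes)) {
    g <- f
    g[-1, , ] <- g[-1, , ] + f[-dims[1], , ]
    g[-dims[1], , ] <- g[-dims[1], , ] + f[-1, , ]
    g[, -1, ] <- g[, -1, ] + f[, -dims[2], ]
    g[, -dims[2], ] <- g[, -dims[2], ] + f[, -1, ]
    f <- g / 5
  }
  lo + (hi - lo) * (f - min(f)) / (max(f) - min(f))
}

# closed-form logistic growth
logistic_solution <- function(t, phi0, kp, theta) {
  theta / (1 + (theta / phi0 - 1) * exp(-kp * t))
}

# a small, fast virtual animal for calibration-level tests
tiny_truth <- function(seed = 1, snr = Inf, spec = model_spec("RTM3", "C3", "global"),
                       schedule = "animal5", SF = 0.9) {
  synthetic_truth(spec = spec,
                  params = parameter_set(kp_T0 = 1.0, kd_T0 = 0.2, D_T0 = 0.02,
                                         D_V0 = 0.02, phi_V_thresh = 0.03,
                                         theta_max = 0.9, kp_V = 0.6, kd_V = 0.25,
                                         SF = SF, alpha1 = 2),
                  schedule = schedule, seed = seed, noise_snr = snr)
}

tiny_grid <- function() default_grid(16, 16, 4)

# exact two-sided rank-sum p-value by enumeration (no ties)
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  allranks <- seq_len(n + m)
  ws <- apply(combos, 2, function(ix) sum(allranks[ix]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
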