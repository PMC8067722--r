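test_that("inversion-recovery fitting recovers T1 from magnitude data", {
  TI <- seq(125, 3025, by = 100)
  T1 <- 1800; r <- 0.7
  T1s <- r * T1; A <- 0.7; B <- 1.7
  S <- abs(A - B * exp(-TI / T1s))
  fit <- fit_t1_ir(TI, S)
  expect_equal(fit$T1, T1s * (B / A - 1), tolerance = 1e-3)
  expect_lt(abs(fit$T1 - T1s * (B / A - 1)) / T1, 0.001)

  # B = 2A makes T1 equal the effective relaxation time
  S2 <- abs(1 - 2 * exp(-TI / 900))
  fit2 <- fit_t1_ir(TI, S2)
  expect_equal(fit2$T1, fit2$T1_star, tolerance = 1e-6)

  expect_error(fit_t1_ir(TI, rep(1, length(TI))), "constant")
  expect_error(fit_t1_ir(c(100, 200), c(1, 2)), "3 distinct")
})

test_that("ADC fitting is exact for mono-exponential decay", {
  b <- c(150, 350, 800)
  expect_equal(fit_adc(b, exp(-b * 1e-3)), 1e-3, tolerance = 1e-12)
  expect_equal(fit_adc(b, rep(0.7, 3)), 0)
  expect_error(fit_adc(b, c(1, 0, 1)), "flagged")
  # with multiplicative noise the LS fit matches a brute-force grid search
  set.seed(8)
  S <- exp(-b * 8e-4) * exp(rnorm(3, 0, 0.05))
  fitted <- fit_adc(b, S)
  adc_grid <- seq(0, 3e-3, by = 1e-7)
  sse <- vapply(adc_grid, function(a) {
    s0 <- exp(mean(log(S) + b * a))
    sum((log(S) - log(s0) + b * a)^2)
  }, numeric(1))
  expect_equal(fitted, adc_grid[which.min(sse)], tolerance = 2e-4)
})

test_that("the ADC-cellularity map is affine, order reversing and clipped", {
  expect_equal(adc_to_tumor_fraction(3e-3, 3e-3, 1e-3), 0)
  expect_equal(adc_to_tumor_fraction(1e-3, 3e-3, 1e-3), 1)
  expect_equal(adc_to_tumor_fraction(2e-3, 3e-3, 1e-3), 0.5)
  adc <- seq(0.5e-3, 3.5e-3, length.out = 11)
  phi <- adc_to_tumor_fraction(adc, 3e-3, 1e-3)
  expect_true(all(diff(phi) <= 0))
  expect_true(all(phi >= 0 & phi <= 1))
  expect_error(adc_to_tumor_fraction(1e-3, 1e-3, 2e-3), "smaller")
})

test_that("DCE blood volume is the windowed AUC ratio", {
  t <- 0:149
  aif <- synthetic_aif(t, t_arrival = 25)
  expect_equal(dce_blood_volume(t, aif, aif), 1)
  expect_equal(dce_blood_volume(t, 0.05 * aif, aif), 0.05, tolerance = 1e-12)
  # 60-s truncation matches a fine-grid trapezoid of the piecewise-linear curve
  base <- aif[1:25]
  t0 <- t[which(aif > mean(base) + 5 * sd(base) & seq_along(aif) > 25)[1]]
  fine <- seq(t0, t0 + 60, by = 1e-3)
  fine_trapz <- function(y) {
    yy <- approx(t, y, xout = fine)$y
    sum(diff(fine) * (head(yy, -1) + tail(yy, -1)) / 2)
  }
  tissue <- 0.07 * aif
  expect_equal(dce_blood_volume(t, tissue, aif),
               fine_trapz(tissue) / fine_trapz(aif), tolerance = 1e-9)
  expect_error(dce_blood_volume(t, aif, rep(0, length(t))), "arrival|AUC")
})

test_that("k-means lesion segmentation finds the enhancing region and fills holes", {
  dims <- c(20, 20, 3)
  img <- array(rnorm(prod(dims), 100, 2), dims)
  lesion <- array(FALSE, dims); lesion[6:14, 6:14, 2] <- TRUE
  cavity <- array(FALSE, dims); cavity[9:11, 9:11, 2] <- TRUE
  img[lesion & !cavity] <- rnorm(sum(lesion & !cavity), 200, 2)
  roi <- array(FALSE, dims); roi[3:17, 3:17, 1:3] <- TRUE
  mask <- segment_tumor(img, roi)
  expect_true(all(mask[lesion]))          # cavity filled
  expect_false(any(mask[!roi]))
  expect_gt(dice(mask, lesion), 0.98)
  expect_error(segment_tumor(array(5, dims), roi), "uniform")
})

test_that("segmentation is robust at the imaging noise level", {
  g <- grid3d(20, 20, 3)
  dims <- c(20, 20, 3)
  img <- array(100, dims)
  lesion <- array(FALSE, dims); lesion[6:14, 6:14, 2] <- TRUE
  img[lesion] <- 200
  roi <- array(FALSE, dims); roi[3:17, 3:17, 1:3] <- TRUE
  rob <- segmentation_robustness(img, roi, g, n = 25, snr = 20, seed = 2)
  expect_length(rob$dice, 25)
  expect_true(all(rob$dice > 0.9))
  expect_lt(rob$volume_se, 0.26)
})

test_that("synthesized MR signals round-trip through the measurement models", {
  set.seed(5)
  phi_T <- runif(30, 0, 0.9)
  phi_V <- runif(30, 0, 0.12)
  p <- mr_protocol()
  sig <- synthesize_mr_signals(phi_T, phi_V, p)
  # diffusion: exact inverse pair
  adc <- vapply(seq_along(phi_T), function(v) fit_adc(p$b, sig$dw$S[v, ]), numeric(1))
  expect_equal(adc_to_tumor_fraction(adc, p$ADC_w, p$ADC_min), phi_T,
               tolerance = 1e-10)
  # DCE: AUC ratio is exactly linear in phi_V
  pv <- dce_blood_volume(sig$dce$t, sig$dce$tissue, sig$dce$aif)
  expect_equal(unname(pv), phi_V, tolerance = 1e-12)
  # T1: nonlinear fit recovers the assigned map
  T1 <- vapply(1:5, function(v) fit_t1_ir(p$TI, sig$ir$S[v, ])$T1, numeric(1))
  expect_equal(T1, sig$ir$T1_true[1:5], tolerance = 1e-3)
})

test_that("noisy signal recovery is unbiased", {
  set.seed(6)
  n <- 3000
  phi_T <- runif(n, 0.2, 0.8)
  p <- mr_protocol()
  sig <- synthesize_mr_signals(phi_T, rep(0.05, n), p, snr = 20, seed = 7)
  adc <- vapply(seq_len(n), function(v) {
    S <- pmax(sig$dw$S[v, ], 1e-6)
    fit_adc(p$b, S)
  }, numeric(1))
  rec <- adc_to_tumor_fraction(adc, p$ADC_w, p$ADC_min)
  err <- rec - phi_T
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(n) + 0.01)
})
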