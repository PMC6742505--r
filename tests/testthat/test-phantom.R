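test_that("wrap_phase maps to (-pi, pi] with the +pi boundary convention", {
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(0.3), 0.3)
  # idempotence, congruence mod 2*pi, and periodicity on random values
  set.seed(1)
  x <- runif(5000, -30, 30)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_phase(w), w)
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
  n <- sample(-5:5, 5000, replace = TRUE)
  expect_equal(wrap_phase(x + 2 * pi * n), w, tolerance = 1e-9)
})

test_that("true phantom phase is zero for a null spec, spans > 2*pi by
           default, and is smooth inside the mask", {
  null_spec <- phantom_spec(background_poly_coeffs = numeric(0),
                            blob_params = list(), resection = NULL)
  expect_true(all(generate_true_phase(null_spec)$data == 0))

  spec <- phantom_spec(seed = 0)
  truth <- generate_true_phase(spec)
  expect_gt(diff(range(truth$data)), 2 * pi)
  # exhaustive 6-neighbour scan: no adjacent step reaches pi inside mask
  msk <- phantom_mask(spec)
  phi <- truth$data
  worst <- 0
  for (ax in 1:3) {
    n <- dim(phi)[ax]
    idx <- slice.index(phi, ax)
    lo <- idx <= n - 1
    d <- abs(phaseflow:::apply_along(phi, ax, function(v) c(diff(v), 0)))
    both <- msk & phaseflow:::apply_along(msk, ax,
                                          function(v) c(v[-1], FALSE))
    worst <- max(worst, max(d[both & lo]))
  }
  expect_lt(worst, pi)
  # determinism
  expect_identical(truth$data, generate_true_phase(spec)$data)
})

test_that("phantom magnitude has a plateau, a deep resection core and is
           nonnegative", {
  spec <- phantom_spec()
  mag <- generate_magnitude(spec)
  expect_true(all(mag$data >= 0))
  centre <- spec$resection$centre + 1
  plateau <- max(mag$data)
  expect_lt(mag$data[centre[1], centre[2], centre[3]], 0.1 * plateau)
  # mask covering the whole grid, no resection: exactly uniform
  full <- phantom_spec(mask_radius = c(1000, 1000, 1000), resection = NULL)
  mfull <- generate_magnitude(full)
  expect_true(all(mfull$data == mfull$data[1]))
})

test_that("phantom_spec validation names the offending field", {
  expect_error(phantom_spec(grid_shape = c(4, 64, 32)), "grid_shape")
  expect_error(phantom_spec(voxel_size = c(2.5, 0, 2.7)), "voxel_size")
  expect_error(phantom_spec(background_poly_coeffs = c(q = 1)),
               "background_poly_coeffs")
  expect_error(phantom_spec(mask_radius = c(0, 1, 1)), "mask_radius")
  expect_warning(phantom_spec(resection = list(centre = c(42, 22, 16),
                                               radii = c(9, 8, 6),
                                               rim_amplitude = 30,
                                               rim_width = 2.5)),
                 "rim_amplitude")
})

test_that("phase-domain Gaussian noise has the requested variance and a
           zero-variance identity", {
  spec <- phantom_spec()
  truth <- generate_true_phase(spec)
  expect_identical(add_phase_noise(truth, noise_spec("phase_gaussian",
                                                     variance = 0))$data,
                   truth$data)
  noisy <- add_phase_noise(truth, noise_spec("phase_gaussian",
                                             variance = 0.71, seed = 11))
  resid <- noisy$data - truth$data
  expect_gt(length(resid), 1e5)
  expect_equal(mean(resid^2), 0.71, tolerance = 0.05)
  # deterministic for a fixed seed
  noisy2 <- add_phase_noise(truth, noise_spec("phase_gaussian",
                                              variance = 0.71, seed = 11))
  expect_identical(noisy$data, noisy2$data)
})

test_that("complex-channel noise reproduces the exact phase-noise
           distribution in its two limits", {
  dims <- c(50, 50, 40)                 # 1e5 voxels
  phase <- phase_volume(array(0.4, dims), wrapped = FALSE)
  # high SNR: angle error approximately N(0, (sigma/A)^2)
  A <- 20; sig <- 1
  mag <- magnitude_volume(array(A, dims))
  noisy <- add_phase_noise(phase, noise_spec("complex_channel",
                                             sigma_channel = sig,
                                             seed = 3), mag)
  err <- wrap_phase(noisy$data - 0.4)
  expect_equal(sd(err), sig / A, tolerance = 0.1 * sig / A)
  expect_lt(abs(mean(err)), 3 * (sig / A) / sqrt(prod(dims)) * 5)
  # A = 0: uniform angles (chi-square goodness of fit over 20 bins)
  mag0 <- magnitude_volume(array(0, dims))
  unif <- add_phase_noise(phase, noise_spec("complex_channel",
                                            sigma_channel = 1, seed = 4),
                          mag0)
  expect_true(all(unif$data > -pi & unif$data <= pi))
  h <- table(cut(unif$data, breaks = seq(-pi, pi, length.out = 21)))
  p <- suppressWarnings(chisq.test(as.numeric(h)))$p.value
  expect_gt(p, 0.01)
  # magnitude is required in this mode
  expect_error(add_phase_noise(phase, noise_spec("complex_channel",
                                                 sigma_channel = 1)),
               "magnitude")
})

test_that("simulated echo pairs follow the off-resonance phase evolution", {
  dims <- c(8, 8, 4)
  zero <- simulate_echo_pair(array(0, dims), 0.008, 0.010)
  expect_true(all(zero$echo1$data == 0) && all(zero$echo2$data == 0))
  # 500 Hz over 2 ms: a full cycle; wrapped difference 0
  e500 <- simulate_echo_pair(array(500, dims), 0.008, 0.010)
  expect_equal(wrap_phase(e500$echo2$data - e500$echo1$data),
               array(0, dims), tolerance = 1e-9)
  # 100 Hz over 2 ms: 0.4*pi everywhere
  e100 <- simulate_echo_pair(array(100, dims), 0.008, 0.010)
  expect_equal(wrap_phase(e100$echo2$data - e100$echo1$data),
               array(0.4 * pi, dims), tolerance = 1e-9)
  expect_error(simulate_echo_pair(array(0, dims), 0.010, 0.008), "te2")
})

test_that("simulated EPI distortion translates, conserves mass and is the
           identity for zero displacement", {
  dims <- c(16, 24, 8)
  co <- phaseflow:::coord_arrays(dims)
  img <- 60 * exp(-((co$x - 7)^2 + (co$y - 11)^2 + (co$z - 3)^2) / (2 * 3^2))
  zero <- displacement_field(array(0, dims), pe_axis = 2)
  expect_equal(simulate_distorted_epi(img, zero), img, tolerance = 1e-9)
  # constant +2 voxel shift along PE
  two <- displacement_field(array(2, dims), pe_axis = 2)
  shifted <- simulate_distorted_epi(img, two)
  inner <- 4:24
  expect_equal(shifted[, inner, ], img[, inner - 2, ], tolerance = 1e-6)
  # linear ramp: mass conserved within 1% under Jacobian modulation
  ramp <- displacement_field(array(rep(seq(0, 3, length.out = dims[2]),
                                       each = dims[1]), dims), pe_axis = 2)
  dd <- simulate_distorted_epi(img, ramp, modulate_jacobian = TRUE)
  expect_lt(abs(sum(dd) - sum(img)) / sum(img), 0.01)
  expect_error(simulate_distorted_epi(img[1:8, , ], two), "shape")
})
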