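test_that("pair weights saturate, vanish on background and follow the
           geometric mean", {
  cfg <- unwrap_config()
  expect_equal(pair_weight(10, 12, cfg, norm_value = 10), 1)
  expect_equal(pair_weight(0, 5, cfg, norm_value = 5), 0)
  expect_equal(pair_weight(5, 10, cfg, norm_value = 10), sqrt(0.5),
               tolerance = 1e-12)
  # monotone nondecreasing in both arguments
  w <- pair_weight(seq(0.5, 10, by = 0.5), 8, cfg, norm_value = 10)
  expect_true(all(diff(w) >= 0))
})

test_that("unwrap energy matches hand arithmetic and is gauge invariant", {
  cfg <- unwrap_config(quality_weighting = "none")
  w3 <- phase_volume(array(c(0, 0.1, 0.2), c(3, 1, 1)), wrapped = TRUE)
  expect_equal(unwrap_energy(array(0, c(3, 1, 1)), w3, config = cfg), 0.02,
               tolerance = 1e-12)
  w2 <- phase_volume(array(c(3.0, -3.0), c(2, 1, 1)), wrapped = TRUE)
  expect_equal(unwrap_energy(array(c(0, 1), c(2, 1, 1)), w2, config = cfg),
               (2 * pi - 6)^2, tolerance = 1e-12)
  # adding a global constant to k leaves the energy unchanged
  set.seed(9)
  wr <- phase_volume(array(runif(60, -pi, pi), c(5, 4, 3)), wrapped = TRUE)
  k <- array(sample(-2:2, 60, replace = TRUE), c(5, 4, 3))
  for (const in c(-3, 1, 7))
    expect_equal(unwrap_energy(k + const, wr, config = cfg),
                 unwrap_energy(k, wr, config = cfg), tolerance = 1e-9)
})

test_that("squared potential makes every binary move submodular", {
  # V(2*pi + t) + V(-2*pi + t) - 2 V(t) = 8*pi^2 for all t
  t <- seq(-20, 20, length.out = 2001)
  gap <- (2 * pi + t)^2 + (-2 * pi + t)^2 - 2 * t^2
  expect_equal(gap, rep(8 * pi^2, length(t)), tolerance = 1e-9)
})

test_that("a single binary move resolves a wrapped pair and matches
           brute force on random small grids", {
  cfg <- unwrap_config(quality_weighting = "none")
  pairv <- phase_volume(array(c(-3, 3), c(2, 1, 1)), wrapped = TRUE)
  mv <- binary_move(array(0, c(2, 1, 1)), pairv, config = cfg)
  expect_equal(sum(mv$delta), 1)       # exactly one voxel incremented
  expect_equal(mv$energy_after, (2 * pi - 6)^2, tolerance = 1e-9)
  expect_lt(mv$energy_after, 36)
  # moves on random 2x2x2 instances equal the best of all 2^8 binary moves
  set.seed(10)
  for (rep in 1:20) {
    wr <- phase_volume(array(runif(8, -pi, pi), c(2, 2, 2)), wrapped = TRUE)
    k0 <- array(sample(-1:1, 8, replace = TRUE), c(2, 2, 2))
    mv <- binary_move(k0, wr, config = cfg)
    deltas <- all_labellings(8)
    best <- min(apply(deltas, 1, function(d)
      unwrap_energy(k0 + array(d, c(2, 2, 2)), wr, config = cfg)))
    expect_equal(mv$energy_after, best, tolerance = 1e-9)
  }
  # a fixed point returns the all-zero move
  flat <- phase_volume(array(0.2, c(3, 3, 1)), wrapped = TRUE)
  mv0 <- binary_move(array(0, c(3, 3, 1)), flat, config = cfg)
  expect_true(all(mv0$delta == 0))
})

test_that("iterated moves reach the enumerated global minimum on 3x3
           wrapped grids", {
  cfg <- unwrap_config(quality_weighting = "none")
  set.seed(12)
  for (rep in 1:5) {
    # smooth-ish 1D ramp folded into a 3x3 slab, plus noise
    base <- array(cumsum(runif(9, 0.4, 1.2)), c(3, 3, 1))
    wr <- wrap_phase(phase_volume(base + rnorm(9, sd = 0.3),
                                  wrapped = FALSE))
    uw <- unwrap(wr, config = cfg)
    want <- enum_unwrap_min(wr, counts_set = -1:1)
    expect_equal(uw$energy_trace[length(uw$energy_trace)], want,
                 tolerance = 1e-8)
  }
})

test_that("already-unwrapped input yields all-zero counts; energies
           decrease strictly; masked-out input errors", {
  cfg <- unwrap_config(quality_weighting = "none")
  wr <- phase_volume(array(runif(120, -2.8, 2.8), c(6, 5, 4)),
                     wrapped = TRUE)
  smooth <- phase_volume(array(seq(-2.5, 2.5, length.out = 120), c(6, 5, 4)),
                         wrapped = TRUE)
  uw <- unwrap(smooth, config = cfg)
  expect_true(all(uw$counts == 0))
  expect_true(uw$converged)

  spec <- small_spec()
  truth <- generate_true_phase(spec)
  noisy <- add_phase_noise(truth, noise_spec("phase_gaussian",
                                             variance = 0.4, seed = 5))
  uw2 <- unwrap(wrap_phase(noisy), generate_magnitude(spec))
  expect_true(all(diff(uw2$energy_trace) < 0))
  expect_true(uw2$converged)

  zero_mag <- magnitude_volume(array(0, spec$grid_shape))
  expect_error(unwrap(wrap_phase(truth), zero_mag),
               "masked|percentile")
})

test_that("noise-free phantom unwrapping is exact up to a global offset", {
  spec <- small_spec()
  truth <- generate_true_phase(spec)
  mag <- generate_magnitude(spec)
  uw <- unwrap(wrap_phase(truth), mag)
  rep <- mcr(uw$counts, true_counts(truth), uw$mask)
  expect_equal(rep$mcr, 0)
})
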