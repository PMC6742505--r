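test_that("cubic B-spline field reproduces constants exactly and single
           coefficients match the tabulated tensor basis", {
  g <- bspline_grid(c(20, 24, 12), 5, pe_axis = 2)
  expect_true(all(dense_field(g)$data == 0))
  g$coeffs[] <- 3
  expect_lt(max(abs(dense_field(g)$data - 3)), 1e-10)
  g$coeffs[] <- 0; g$coeffs[3, 3, 2] <- 1
  w <- outer(outer(g$basis[[1]][, 3], g$basis[[2]][, 3]), g$basis[[3]][, 2])
  expect_equal(dense_field(g)$data, w, tolerance = 1e-12)
  # partition of unity at every voxel
  for (a in 1:3)
    expect_equal(rowSums(g$basis[[a]]), rep(1, c(20, 24, 12)[a]),
                 tolerance = 1e-12)
})

test_that("local joint histograms have the right mass and degenerate to
           plain histograms for a flat kernel", {
  set.seed(30)
  dims <- c(16, 16, 8)
  ref <- array(runif(prod(dims), 0, 10), dims)
  g <- bspline_grid(dims, 4, pe_axis = 2)
  cfg <- reg_config(spacing = 4, bins = 16, gamma_sd = 3)
  h <- semi_histogram(ref, ref, c(3, 3, 2), g, cfg)
  expect_equal(sum(h$H), h$mass, tolerance = 1e-6)
  # identical images concentrate mass near the diagonal
  p <- h$H / sum(h$H)
  diag_mass <- sum(p[abs(row(p) - col(p)) <= 1])
  expect_gt(diag_mass, 0.95)
  # huge flat kernel + nearest Parzen = ordinary joint histogram
  cfgn <- reg_config(spacing = 4, bins = 8, gamma_sd = 1e4,
                     parzen = "nearest", intensity_quantiles = c(0, 1))
  hn <- semi_histogram(ref, ref, c(3, 3, 2), g, cfgn, gamma_sd = 1e4)
  expect_equal(sum(hn$H), prod(dims), tolerance = 1e-6)
  expect_equal(sum(diag(hn$H)), prod(dims), tolerance = 1e-6)
})

test_that("SEMI scores identity at 2, independence near 1, and peak at the
           true translation", {
  set.seed(31)
  dims <- c(24, 24, 12)
  ref <- array(runif(prod(dims), 0, 100), dims)
  g <- bspline_grid(dims, 6, pe_axis = 2)
  cfg <- reg_config(spacing = 6, bins = 16, parzen = "nearest",
                    intensity_quantiles = c(0, 1), label_range = 4)
  cp <- c(3, 3, 2)
  expect_equal(semi_data_term(ref, ref, g, 0, cfg, cp), 2, tolerance = 1e-9)
  # independent intensities: NMI near its lower bound of 1
  shuf <- array(sample(ref), dims)
  expect_lt(semi_data_term(ref, shuf, g, 0, cfg, cp), 1.1)
  # translated floating image scores best at the matching label
  co <- phaseflow:::coord_arrays(dims)
  tex <- 50 + 40 * sin(co$x / 2) * cos(co$y / 1.7) + 20 * sin(co$z)
  flt3 <- simulate_distorted_epi(tex, displacement_field(array(3, dims),
                                                         pe_axis = 2))
  s3 <- semi_data_term(tex, flt3, g, 3, cfg, cp)
  s0 <- semi_data_term(tex, flt3, g, 0, cfg, cp)
  expect_gt(s3, s0)
})

test_that("pairwise regularisation is the absolute total-displacement
           difference", {
  expect_equal(pairwise_cost(0, 0, 2, 2), 0)
  expect_equal(pairwise_cost(0, 1.5, 2, 2), 1.5)
  expect_equal(pairwise_cost(1, 2, 1.0, 3.5), abs((1 + 1) - (3.5 + 2)))
  expect_equal(pairwise_cost(2, 1, 3.5, 1.0), pairwise_cost(1, 2, 1.0, 3.5))
})

test_that("confidence projection is a convex combination of voxel values", {
  dims <- c(20, 20, 10)
  g <- bspline_grid(dims, 5, pe_axis = 2)
  u <- project_confidence(array(0.7, dims), g)
  act <- phaseflow:::project_to_grid(array(1, dims), g)$active
  expect_true(all(abs(u[act] - 0.7) < 1e-9))
  # checkerboard: all interior projections strictly between 0 and 1
  co <- phaseflow:::coord_arrays(dims)
  cb <- (co$x + co$y + co$z) %% 2
  v <- project_confidence(cb, g)
  inner <- array(FALSE, dim(v)); inner[3:4, 3:4, 2:3] <- TRUE
  expect_true(all(v[inner] > 0 & v[inner] < 1))
})

test_that("registration recovers a smooth synthetic distortion and the
           objective trace is monotone", {
  p <- registration_problem(seed = 1)
  flt <- simulate_distorted_epi(p$img, p$truth)
  expect_warning(
    out <- register(p$img, flt, init = NULL, conf = NULL,
                    config = fast_reg_config(), pe_axis = 2),
    "confidence")
  err <- abs(out$data - p$truth$data)
  expect_lt(mean(err[p$mask]), 0.5)
  for (tr in attr(out, "energy_trace"))
    expect_true(all(diff(tr) <= 1e-9))
})

test_that("full confidence freezes the fieldmap initialisation and an
           identity problem stays put", {
  p <- registration_problem(seed = 2)
  flt <- simulate_distorted_epi(p$img, p$truth)
  cfg <- fast_reg_config(levels = 1, lambda_global = 1, max_cycles = 3)
  out <- register(p$img, flt, init = p$truth,
                  conf = array(1, p$dims), config = cfg)
  expect_lt(max(abs(out$data - p$truth$data)), 0.1)
  # identical images, zero init, sigma = 1: nothing should move
  out0 <- register(p$img, p$img, init = NULL, conf = array(1, p$dims),
                   config = cfg)
  expect_true(all(out0$data == 0))
})

test_that("stronger uniform confidence pulls the solution monotonically
           toward the initialisation", {
  p <- registration_problem(seed = 3)
  flt <- simulate_distorted_epi(p$img, p$truth)
  cfg <- fast_reg_config(levels = 1, lambda_global = 1, max_cycles = 2)
  dev <- sapply(c(0, 0.5, 1), function(s) {
    out <- register(p$img, flt, init = p$truth,
                    conf = array(s, p$dims), config = cfg)
    mean(abs(out$data - p$truth$data))
  })
  expect_true(all(diff(dev) <= 1e-9))
})
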