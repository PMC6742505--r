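# Shared fixtures, built in code at test time.

# compact phantom used by module tests (same structure as the default
# 64x64x32 spec, scaled to keep per-test runtime low)
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 16),
               blob_params = list(
                 list(centre = c(12, 20, 6), sd = 4, amplitude = 2.5),
                 list(centre = c(22, 12, 10), sd = 5, amplitude = -3)),
               resection = list(centre = c(21, 11, 8), radii = c(5, 4, 3),
                                rim_amplitude = 2, rim_width = 2),
               mask_radius = c(14, 14, 7), ...)
}

# wrap counts implied by an unwrapped phase volume (the ground truth the
# unwrapper should recover, up to a global offset)
true_counts <- function(phase) {
  round((phase$data - wrap_phase(phase$data)) / (2 * pi))
}

# textured structural image + smooth sub-3-voxel PE displacement field used
# by the registration recovery experiments
registration_problem <- function(seed = 1, dims = c(32, 32, 16)) {
  set.seed(seed)
  co <- phaseflow:::coord_arrays(dims)
  img <- 50 * exp(-((co$x - 15)^2 + (co$y - 15)^2 + (co$z - 7)^2) / (2 * 8^2)) +
    30 * exp(-((co$x - 8)^2 + (co$y - 22)^2 + (co$z - 9)^2) / (2 * 4^2)) +
    25 * sin(co$x / 3) * cos(co$y / 4) + 20
  noise <- array(rnorm(prod(dims)), dims)
  sm <- noise
  for (ax in 1:3)
    sm <- (sm +
             phaseflow:::apply_along(sm, ax, function(v) c(v[-1], v[length(v)])) +
             phaseflow:::apply_along(sm, ax, function(v) c(v[1], v[-length(v)]))) / 3
  img <- img + 10 * sm
  tru <- 3 * exp(-((co$x - 16)^2 + (co$y - 16)^2) / (2 * 10^2)) *
    exp(-(co$z - 8)^2 / (2 * 6^2))
  list(img = img, truth = displacement_field(tru, pe_axis = 2),
       mask = img > 25, dims = dims)
}

fast_reg_config <- function(...) {
  args <- list(spacing = 4, levels = 2, label_step = 1, label_range = 4,
               bins = 32, max_cycles = 4)
  do.call(reg_config, utils::modifyList(args, list(...)))
}
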