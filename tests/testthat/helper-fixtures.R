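# Shared fixtures, built in code at test time.

# Noise-free scene of a bare dendrite tube.
tube_scene <- function(path, image_shape, pixel_size = 0.07,
                       psf_sigma = 0.1, background = 5) {
  cfg <- scene_config(list(), pixel_size = pixel_size,
                      image_shape = image_shape, dendrite_path = path,
                      psf_sigma = psf_sigma, poisson_noise = FALSE,
                      read_noise_sd = 0, background_level = background)
  render_scene(cfg)
}

# Standard two-object NOR arena used across behavior tests.
nor_objects <- function() {
  list(object_spec("A", c(10, 10), 2.5, role = "familiar"),
       object_spec("B", c(23, 23), 2.5, role = "novel"))
}

# Independent brute-force oracle for the exact two-sample KS p-value:
# enumerate every subset of the pooled sample by bitmask and take D from
# stats::ks.test (suppressing its tie warnings).
brute_force_ks_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  d_obs <- suppressWarnings(stats::ks.test(a, b)$statistic)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(inset) != n1) next
    total <- total + 1L
    d <- suppressWarnings(stats::ks.test(pooled[inset], pooled[!inset])$statistic)
    if (d >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}
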