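# Shared fixture builders. All scenes are generated in code; no files.

# A textured two-population scene with a silk ring: intensity structure
# (disc / rect / silk / dark background) gives the channels the spatial
# texture registration needs, while the mixture SD provides redox spread.
texturedScene <- function(seed, shift = c(0L, 0L), noise = FALSE,
                          size = 64L, background_counts = 0,
                          sd_redox = 0.08, silk = TRUE) {
  p1 <- populationSpec("core",
                       data.frame(mean = 0.35, sd = sd_redox, weight = 1),
                       intensity_mean = 120, lifetime_ns = 1.0)
  p2 <- populationSpec("edge",
                       data.frame(mean = 0.65, sd = sd_redox, weight = 1),
                       intensity_mean = 80, lifetime_ns = 1.5)
  c0 <- size / 2
  sceneSpec(size, size,
            populations = list(
              list(spec = p1, footprint = discFootprint(c0 - 10, c0, 9)),
              list(spec = p2,
                   footprint = rectFootprint(c0 + 4, 6, size - c0 - 6, 22))),
            silk = if (silk) ringFootprint(c0, c0, c0 - 7, c0 - 3) else NULL,
            silk_lifetime_ns = 2.8, silk_intensity_mean = 150,
            channel_shift = shift, max_shift = 20L, noise = noise,
            background_counts = background_counts, seed = seed)
}

# Registration fixture: every pixel carries >= 50 expected counts per
# channel and the cell/silk structure sits well above the background, the
# way real fields correlate across channels through shared morphology
# (shot noise, not texture, is then the only obstacle to registration).
registrationScene <- function(seed, shift = c(0L, 0L), noise = FALSE,
                              size = 64L) {
  p1 <- populationSpec("core",
                       data.frame(mean = 0.40, sd = 0.05, weight = 1),
                       intensity_mean = 600, lifetime_ns = 1.0)
  p2 <- populationSpec("edge",
                       data.frame(mean = 0.60, sd = 0.05, weight = 1),
                       intensity_mean = 300, lifetime_ns = 1.5)
  c0 <- size / 2
  sceneSpec(size, size,
            populations = list(
              list(spec = p1, footprint = discFootprint(c0 - 10, c0, 9)),
              list(spec = p2,
                   footprint = rectFootprint(c0 + 4, 6, size - c0 - 6, 22))),
            silk = ringFootprint(c0, c0, c0 - 7, c0 - 3),
            silk_intensity_mean = 1000, channel_shift = shift,
            max_shift = 20L, noise = noise, background_counts = 50,
            seed = seed)
}

# A flat single-population scene covering the whole frame.
uniformScene <- function(seed, mean_redox = 0.5, sd_redox = 0,
                         size = 32L, noise = FALSE, intensity = 100,
                         shift = c(0L, 0L), lifetime_ns = 1.2) {
  pop <- populationSpec("cells",
                        data.frame(mean = mean_redox, sd = sd_redox,
                                   weight = 1),
                        intensity_mean = intensity,
                        lifetime_ns = lifetime_ns)
  sceneSpec(size, size,
            populations = list(list(
              spec = pop, footprint = rectFootprint(0, 0, size, size))),
            silk = NULL, channel_shift = shift, noise = noise, seed = seed)
}

# Scene whose two channels are exactly proportional (constant redox,
# varying intensity): correlation at the true shift is exactly 1.
proportionalScene <- function(seed, shift = c(0L, 0L)) {
  pA <- populationSpec("bright", data.frame(mean = 0.5, sd = 0, weight = 1),
                       intensity_mean = 200, lifetime_ns = 1.0)
  pB <- populationSpec("dim", data.frame(mean = 0.5, sd = 0, weight = 1),
                       intensity_mean = 60, lifetime_ns = 1.0)
  sceneSpec(48, 48,
            populations = list(
              list(spec = pA, footprint = discFootprint(20, 24, 10)),
              list(spec = pB, footprint = rectFootprint(32, 4, 12, 40))),
            silk = NULL, silk_redox = 0.5, channel_shift = shift,
            noise = FALSE, seed = seed)
}

# Analytic mono-exponential phasor at angular frequency omega.
phasorClosedForm <- function(tau, omega) {
  wt <- omega * tau
  c(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

# A noiseless DecayStack with a single lifetime everywhere.
monoExpStack <- function(tau, n_bins = 512L, window_ns = 12.5,
                         npx = 4L, intensity = 1000) {
  pop <- populationSpec("cells", data.frame(mean = 0.5, sd = 0, weight = 1),
                        intensity_mean = intensity, lifetime_ns = tau)
  spec <- sceneSpec(npx, npx,
                    populations = list(list(
                      spec = pop, footprint = rectFootprint(0, 0, npx, npx))),
                    silk = NULL, noise = FALSE, seed = 1)
  renderDecays(makeScene(spec),
               acquisitionSpec(n_time_bins = n_bins,
                               time_window_ns = window_ns))
}
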