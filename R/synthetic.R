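#' Describe a cell population for scene synthesis
#'
#' A population is a metabolically distinct group of cells whose per-pixel
#' redox ratios are drawn i.i.d. from a Gaussian mixture on \[0, 1\] — the
#' generative twin of the Gaussian components that the histogram
#' decomposition later recovers. Draws falling outside \[0, 1\] are clipped
#' (and the clipped mass reported on the scene), not redrawn.
#'
#' @param name population label.
#' @param mixture data frame (or coercible) with columns `mean`, `sd`,
#'   `weight`: component means in \[0, 1\], positive SDs (redox units) and
#'   weights summing to 1. An `sd` of 0 gives a degenerate point mass.
#' @param intensity_mean expected total photons per pixel (> 0).
#' @param lifetime_ns fluorescence lifetime of the population's NAD(P)H
#'   signal in ns (> 0); cellular values are typically 0.8–1.5 ns.
#' @return a `PopulationSpec` (validated list).
#' @examples
#' populationSpec("tumor", data.frame(mean = c(0.3, 0.6), sd = 0.05,
#'                                    weight = c(0.7, 0.3)),
#'                intensity_mean = 100, lifetime_ns = 1.2)
#' @export
populationSpec <- function(name, mixture, intensity_mean, lifetime_ns = 1.2) {
  mixture <- as.data.frame(mixture)
  if (!all(c("mean", "sd", "weight") %in% names(mixture)))
    stop("mixture needs columns mean, sd, weight")
  if (abs(sum(mixture$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1 (got ", sum(mixture$weight), ")")
  if (any(mixture$mean < 0 | mixture$mean > 1))
    stop("mixture means must lie in [0, 1]")
  if (any(mixture$sd < 0))
    stop("mixture sds must be >= 0")
  .assertScalar(intensity_mean, "intensity_mean")
  .assertScalar(lifetime_ns, "lifetime_ns")
  structure(list(name = as.character(name), mixture = mixture,
                 intensity_mean = intensity_mean, lifetime_ns = lifetime_ns),
            class = "PopulationSpec")
}

#' Footprint descriptors for scene geometry
#'
#' Footprints place a population inside the field; silk geometry places the
#' scaffold. Coordinates are 0-based pixel centers (x = column, y = row).
#'
#' @param x0,y0 top-left corner of a rectangle.
#' @param w,h rectangle width and height in pixels.
#' @param cx,cy disc / ring center.
#' @param r disc radius in pixels.
#' @param r_inner,r_outer ring radii (silk scaffolds are donut-shaped).
#' @return a footprint descriptor list.
#' @name footprints
#' @export
rectFootprint <- function(x0, y0, w, h)
  list(type = "rect", x0 = x0, y0 = y0, w = w, h = h)

#' @rdname footprints
#' @export
discFootprint <- function(cx, cy, r)
  list(type = "disc", cx = cx, cy = cy, r = r)

#' @rdname footprints
#' @export
ringFootprint <- function(cx, cy, r_inner, r_outer)
  list(type = "ring", cx = cx, cy = cy, r_inner = r_inner, r_outer = r_outer)

.footprintMask <- function(fp, width, height) {
  g <- .pixelGrid(width, height)
  m <- switch(fp$type,
    rect = {
      if (fp$x0 < 0 || fp$y0 < 0 || fp$x0 + fp$w > width ||
          fp$y0 + fp$h > height)
        stop("rect footprint exceeds image bounds")
      g$x >= fp$x0 & g$x < fp$x0 + fp$w & g$y >= fp$y0 & g$y < fp$y0 + fp$h
    },
    disc = {
      if (fp$cx - fp$r < -0.5 || fp$cy - fp$r < -0.5 ||
          fp$cx + fp$r > width - 0.5 || fp$cy + fp$r > height - 0.5)
        stop("disc footprint exceeds image bounds")
      (g$x - fp$cx)^2 + (g$y - fp$cy)^2 <= fp$r^2
    },
    ring = {
      if (fp$cx + fp$r_outer > width - 0.5 || fp$cx - fp$r_outer < -0.5 ||
          fp$cy + fp$r_outer > height - 0.5 || fp$cy - fp$r_outer < -0.5)
        stop("ring footprint exceeds image bounds")
      d2 <- (g$x - fp$cx)^2 + (g$y - fp$cy)^2
      d2 >= fp$r_inner^2 & d2 <= fp$r_outer^2
    },
    stop("unknown footprint type: ", fp$type)
  )
  m
}

#' Describe a synthetic scene
#'
#' Declares everything [makeScene()] needs: field size, the silk-scaffold
#' geometry and its (long) autofluorescence lifetime, the cell populations
#' and their spatial footprints, the integer misregistration applied to the
#' FAD channel at render time, and whether Poisson shot noise is applied.
#'
#' @param width,height field size in pixels.
#' @param populations list of `list(spec = populationSpec(...), footprint =
#'   ...)` entries (see [rectFootprint()] and friends).
#' @param silk `NULL` for no scaffold, or a footprint (typically
#'   [ringFootprint()], the donut shape of the construct).
#' @param silk_lifetime_ns silk autofluorescence lifetime in ns; silk is
#'   longer-lived than cellular NAD(P)H, which is what the lifetime filter
#'   exploits. Default 2.8 ns (a test fixture, not a measured value).
#' @param silk_intensity_mean expected silk photons/pixel.
#' @param silk_redox effective FAD fraction of silk autofluorescence used
#'   when rendering the two channels (fixture value).
#' @param channel_shift integer `(dx, dy)` applied to the FAD channel when
#'   rendering, emulating chromatic misregistration.
#' @param max_shift declared bound on `|dx|, |dy|` (default 20 px).
#' @param noise `TRUE` to apply Poisson shot noise when rendering.
#' @param background_counts expected dark counts per background pixel and
#'   channel (default 0; set > 0 to exercise zero-denominator handling).
#' @param seed integer seed making the scene and its renders reproducible.
#' @return a `SceneSpec` (validated list).
#' @export
sceneSpec <- function(width, height, populations, silk = NULL,
                      silk_lifetime_ns = 2.8, silk_intensity_mean = 150,
                      silk_redox = 0.3, channel_shift = c(0L, 0L),
                      max_shift = 20L, noise = TRUE, background_counts = 0,
                      seed = 1L) {
  .assertScalar(width, "width"); .assertScalar(height, "height")
  if (!length(populations))
    stop("at least one population is required")
  for (p in populations) {
    if (!inherits(p$spec, "PopulationSpec"))
      stop("each population entry needs a $spec built by populationSpec()")
    if (is.null(p$footprint$type))
      stop("each population entry needs a $footprint")
  }
  channel_shift <- as.integer(round(channel_shift))
  if (length(channel_shift) != 2L)
    stop("channel_shift must be (dx, dy)")
  if (any(abs(channel_shift) > max_shift))
    stop("|channel_shift| must not exceed max_shift = ", max_shift)
  if (background_counts < 0) stop("background_counts must be >= 0")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    populations = populations, silk = silk,
    silk_lifetime_ns = silk_lifetime_ns,
    silk_intensity_mean = silk_intensity_mean, silk_redox = silk_redox,
    channel_shift = channel_shift, max_shift = as.integer(max_shift),
    noise = isTRUE(noise), background_counts = background_counts,
    seed = as.integer(seed)), class = "SceneSpec")
}

#' Acquisition settings
#'
#' Laser powers at the two excitation wavelengths (755 nm for NADH, 860 nm
#' for FAD), detector gains, and the TCSPC timing parameters. The decay time
#' window must fit inside one excitation period (1 / repetition rate).
#'
#' @param power_nadh,power_fad excitation power in mW (about 20 mW at the
#'   focal plane on the real instrument).
#' @param gain_nadh,gain_fad dimensionless detector gain factors.
#' @param n_time_bins number of TCSPC time bins (>= 16 for decay rendering).
#' @param rep_rate_MHz laser repetition rate; 80 MHz for a Ti:Sapphire.
#' @param time_window_ns decay window in ns; defaults to the full excitation
#'   period 1e3 / rep_rate_MHz.
#' @return an `AcquisitionSpec` (validated list).
#' @export
acquisitionSpec <- function(power_nadh = 20, power_fad = 20, gain_nadh = 1,
                            gain_fad = 1, n_time_bins = 256L,
                            rep_rate_MHz = 80,
                            time_window_ns = 1e3 / rep_rate_MHz) {
  for (nm in c("power_nadh", "power_fad", "gain_nadh", "gain_fad",
               "n_time_bins", "rep_rate_MHz", "time_window_ns"))
    .assertScalar(get(nm), nm)
  if (time_window_ns > 1e3 / rep_rate_MHz + 1e-9)
    stop("time_window_ns must not exceed one excitation period (",
         format(1e3 / rep_rate_MHz), " ns)")
  structure(list(power_nadh = power_nadh, power_fad = power_fad,
                 gain_nadh = gain_nadh, gain_fad = gain_fad,
                 n_time_bins = as.integer(n_time_bins),
                 rep_rate_MHz = rep_rate_MHz,
                 time_window_ns = time_window_ns),
            class = "AcquisitionSpec")
}

#' Build a ground-truth scene from a scene specification
#'
#' Paints silk and population footprints into a label image, then draws each
#' cell pixel's true redox ratio i.i.d. from its population's Gaussian
#' mixture (clipped to \[0, 1\]; the clipped mass is recorded), and assigns
#' expected intensities and lifetimes. Populations may grow over the silk
#' scaffold (cells seeded on silk), but two populations claiming the same
#' pixel is an error naming the pair.
#'
#' @param spec a [sceneSpec()].
#' @return a [SyntheticScene-class].
#' @export
makeScene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  w <- spec$width; h <- spec$height
  labels <- matrix(.LABEL_BACKGROUND, h, w)
  lifetimes <- matrix(NA_real_, h, w)
  intensity <- matrix(spec$background_counts * 2, h, w)
  if (!is.null(spec$silk)) {
    sm <- .footprintMask(spec$silk, w, h)
    labels[sm] <- .LABEL_SILK
    lifetimes[sm] <- spec$silk_lifetime_ns
    intensity[sm] <- spec$silk_intensity_mean
  }
  npop <- length(spec$populations)
  popNames <- vapply(spec$populations, function(p) p$spec$name, character(1))
  masks <- vector("list", npop)
  for (i in seq_len(npop)) {
    m <- .footprintMask(spec$populations[[i]]$footprint, w, h)
    clash <- which(m & labels > 0L)
    if (length(clash)) {
      other <- labels[clash[1]]
      stop(sprintf(
        "populations '%s' and '%s' overlap at %d pixel(s), e.g. (x=%d, y=%d)",
        popNames[other], popNames[i], length(clash),
        (clash[1] - 1L) %/% h, (clash[1] - 1L) %% h))
    }
    labels[m] <- i
    masks[[i]] <- m
  }
  trueRedox <- matrix(NA_real_, h, w)
  nClipped <- 0L; nDrawn <- 0L
  .withSeed(spec$seed, {
    for (i in seq_len(npop)) {
      p <- spec$populations[[i]]$spec
      m <- masks[[i]]
      n <- sum(m)
      if (!n) next
      comp <- sample.int(nrow(p$mixture), n, replace = TRUE,
                         prob = p$mixture$weight)
      r <- stats::rnorm(n, p$mixture$mean[comp], p$mixture$sd[comp])
      nClipped <- nClipped + sum(r < 0 | r > 1)
      nDrawn <- nDrawn + n
      trueRedox[m] <- pmin(1, pmax(0, r))
      lifetimes[m] <- p$lifetime_ns
      intensity[m] <- p$intensity_mean
    }
  })
  new("SyntheticScene",
      trueRedox = trueRedox, labels = labels, populationNames = popNames,
      silkMask = labels == .LABEL_SILK, totalIntensity = intensity,
      lifetimes = lifetimes, appliedShift = spec$channel_shift,
      seed = spec$seed, clipFraction = if (nDrawn) nClipped / nDrawn else 0,
      spec = unclass(spec))
}

# Expected per-channel photon rates before power/gain scaling: FAD = r * T,
# NADH = (1 - r) * T on cells, split by silk_redox on silk, 50/50 on the
# (dark-count) background. Conservation: NADH + FAD == totalIntensity.
.expectedChannels <- function(scene) {
  r <- scene@trueRedox
  sp <- scene@spec
  fadFrac <- ifelse(scene@labels > 0L, r,
                    ifelse(scene@silkMask, sp$silk_redox, 0.5))
  T <- scene@totalIntensity
  list(nadh = (1 - fadFrac) * T, fad = fadFrac * T)
}

#' Render the two intensity channels of a scene
#'
#' Inverts the redox definition: a cell pixel with true ratio \eqn{r} and
#' expected total intensity \eqn{T} emits \eqn{rT} expected FAD photons and
#' \eqn{(1-r)T} expected NADH photons. Expected counts are then scaled by
#' the two-photon excitation factor power^exponent x gain per channel
#' (exponent 2 by default — TPEF signal is quadratic in excitation power),
#' the FAD channel is translated by the scene's applied shift (pixels
#' shifted in from outside the frame carry background signal), and Poisson
#' shot noise is applied if the scene requests it.
#'
#' @param scene a [SyntheticScene-class].
#' @param acq an [acquisitionSpec()].
#' @param exponent power-scaling exponent (default 2).
#' @param seed RNG seed for the shot noise; defaults to a sub-seed derived
#'   from the scene seed so renders are reproducible.
#' @param condition,sample_id,field_id metadata stamped on the field.
#' @return a raw (unnormalized) [TPEFField-class].
#' @export
renderChannels <- function(scene, acq, exponent = 2,
                           seed = .subSeed(scene@seed, 1),
                           condition = "synthetic", sample_id = "s1",
                           field_id = "f1") {
  stopifnot(is(scene, "SyntheticScene"), inherits(acq, "AcquisitionSpec"))
  ch <- .expectedChannels(scene)
  sp <- scene@spec
  nadh <- ch$nadh * acq$power_nadh^exponent * acq$gain_nadh
  fadUnshifted <- ch$fad * acq$power_fad^exponent * acq$gain_fad
  bgFad <- sp$background_counts * acq$power_fad^exponent * acq$gain_fad
  sh <- .translate(fadUnshifted, scene@appliedShift)
  fad <- sh$image
  fad[!sh$valid] <- bgFad
  if (sp$noise) {
    .withSeed(seed, {
      nadh[] <- stats::rpois(length(nadh), nadh)
      fad[] <- stats::rpois(length(fad), fad)
    })
  }
  new("TPEFField", nadh = nadh, fad = fad,
      acq = acq[c("power_nadh", "power_fad", "gain_nadh", "gain_fad")],
      meta = list(condition = condition, sample_id = sample_id,
                  field_id = field_id),
      normalized = FALSE, divisors = c(nadh = NA_real_, fad = NA_real_))
}

#' Render the TCSPC photon-decay stack of a scene
#'
#' Each pixel's expected decay is a binned mono-exponential with the pixel's
#' lifetime, normalized over the acquisition window so the total expected
#' count equals the pixel's total intensity (the mono-exponential truncated
#' to one excitation period is proportional to the periodic steady-state
#' decay, so its phasor at the laser harmonic is exact). Background pixels
#' without a lifetime receive no photons. Poisson noise per (pixel, bin) if
#' the scene requests noise.
#'
#' @inheritParams renderChannels
#' @return a [DecayStack-class].
#' @export
renderDecays <- function(scene, acq, seed = .subSeed(scene@seed, 2)) {
  stopifnot(is(scene, "SyntheticScene"), inherits(acq, "AcquisitionSpec"))
  nt <- acq$n_time_bins
  if (nt < 16L) stop("n_time_bins must be >= 16")
  dt <- acq$time_window_ns / nt
  edges <- seq(0, acq$time_window_ns, length.out = nt + 1L)
  h <- nrow(scene@labels); w <- ncol(scene@labels)
  tau <- scene@lifetimes
  hasTau <- !is.na(tau) & tau > 0
  counts <- array(0, c(h, w, nt))
  if (any(hasTau)) {
    # bin probabilities per distinct lifetime (scenes use few lifetimes)
    for (tv in unique(tau[hasTau])) {
      p <- (exp(-edges[-(nt + 1L)] / tv) - exp(-edges[-1L] / tv)) /
        (1 - exp(-acq$time_window_ns / tv))
      idx <- which(hasTau & tau == tv)
      expected <- outer(scene@totalIntensity[idx], p)
      for (b in seq_len(nt)) counts[idx + (b - 1L) * h * w] <- expected[, b]
    }
  }
  if (scene@spec$noise)
    .withSeed(seed, counts[] <- stats::rpois(length(counts), counts))
  new("DecayStack", counts = counts, binWidthNs = dt, t0OffsetNs = 0)
}
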