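#' First-harmonic phasor transform of a decay stack
#'
#' Projects each pixel's photon decay onto sine and cosine at angular
#' frequency `omega`, with time taken at bin centers:
#' \deqn{g = \sum_t I(t)\cos(\omega t) / \sum_t I(t), \qquad
#'       s = \sum_t I(t)\sin(\omega t) / \sum_t I(t).}
#' For any non-negative decay the phasor lies inside the unit circle;
#' noise-free mono-exponential decays lie on the universal semicircle
#' \eqn{(g - 1/2)^2 + s^2 = 1/4}. Pixels with fewer than `min_counts` total
#' photons are marked undefined rather than propagating unstable ratios.
#'
#' @param stack a [DecayStack-class].
#' @param omega angular frequency in rad/ns; defaults to the first harmonic
#'   of an 80 MHz Ti:Sapphire, `2 * pi * 0.080`.
#' @param min_counts minimum total photons for a defined phasor.
#' @return a [PhasorField-class].
#' @export
phasorTransform <- function(stack, omega = 2 * pi * 0.080, min_counts = 1) {
  stopifnot(is(stack, "DecayStack"))
  .assertScalar(omega, "omega")
  d <- dim(stack@counts)
  nt <- d[3]
  tc <- stack@t0OffsetNs + (seq_len(nt) - 0.5) * stack@binWidthNs
  flat <- stack@counts
  dim(flat) <- c(d[1] * d[2], nt)
  tot <- rowSums(flat)
  defined <- tot >= min_counts & tot > 0
  g <- s <- rep(NA_real_, length(tot))
  g[defined] <- (flat[defined, , drop = FALSE] %*% cos(omega * tc)) /
    tot[defined]
  s[defined] <- (flat[defined, , drop = FALSE] %*% sin(omega * tc)) /
    tot[defined]
  new("PhasorField",
      g = matrix(g, d[1], d[2]), s = matrix(s, d[1], d[2]),
      defined = matrix(defined, d[1], d[2]), omega = omega,
      totalCounts = matrix(tot, d[1], d[2]))
}

#' Apparent (phase) lifetime from a phasor field
#'
#' The single-number lifetime statistic used for silk masking:
#' \eqn{\tau = s / (\omega g)}, exact for mono-exponential decays at the
#' laser harmonic. Pixels with `g <= 0` (or undefined phasors) yield `NA`.
#'
#' @param phasor a [PhasorField-class].
#' @return numeric matrix of lifetimes in ns, `NA` where undefined.
#' @export
apparentLifetime <- function(phasor) {
  stopifnot(is(phasor, "PhasorField"))
  tau <- matrix(NA_real_, nrow(phasor@g), ncol(phasor@g))
  ok <- phasor@defined & !is.na(phasor@g) & phasor@g > 0
  tau[ok] <- phasor@s[ok] / (phasor@omega * phasor@g[ok])
  tau
}

#' Lifetime-threshold silk filter
#'
#' Silk-scaffold autofluorescence at 755 nm excitation has a longer lifetime
#' than cellular NAD(P)H, so scaffold regions are removed by masking out
#' pixels whose apparent lifetime exceeds a cutoff, keeping cellular signal.
#' Raising the cutoff never removes more pixels (monotone masking). Pixels
#' with no defined lifetime (too few photons) are kept here — they are
#' excluded downstream by the intensity floor of [computeRedoxMap()] — and
#' do not enter `fractionRemoved`.
#'
#' @param lifetimes numeric matrix of lifetimes in ns ([apparentLifetime()]),
#'   `NA` where undefined.
#' @param cutoff_ns lifetime cutoff in ns (> 0). The default 2.0 ns sits
#'   between silk (about 2.8 ns) and cellular NAD(P)H (at or below about
#'   1.5 ns) so that silk is removed with minimal loss of cellular signal.
#' @return a [SilkMask-class] (`TRUE` = keep).
#' @export
silkFilter <- function(lifetimes, cutoff_ns = 2.0) {
  .assertScalar(cutoff_ns, "cutoff_ns")
  defined <- !is.na(lifetimes)
  keep <- !(defined & lifetimes > cutoff_ns)
  frac <- if (any(defined)) sum(!keep[defined]) / sum(defined) else 0
  new("SilkMask", mask = keep, cutoffNs = cutoff_ns, fractionRemoved = frac)
}

#' Intensity-threshold fallback mask
#'
#' When no decay stack was acquired the lifetime-based silk filter cannot
#' run; this fallback removes pixels whose summed channel intensity exceeds
#' a quantile threshold (silk autofluorescence is typically bright). It is a
#' coarser surrogate — the principled filter is [silkFilter()] — and is
#' labeled as such in its output.
#'
#' @param nadh,fad normalized channel matrices.
#' @param quantile upper intensity quantile removed (default 0.99, i.e. keep
#'   everything; lower it to actually mask).
#' @return list with `mask` (logical, `TRUE` = keep), `threshold`, and
#'   `method = "intensity-fallback"`.
#' @export
intensityFallbackMask <- function(nadh, fad, quantile = 0.99) {
  tot <- nadh + fad
  thr <- stats::quantile(tot, quantile, names = FALSE)
  list(mask = tot <= thr, threshold = thr, method = "intensity-fallback")
}
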