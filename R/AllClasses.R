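#' @import methods
NULL

# Label codes used in SyntheticScene@labels. Populations are 1..P.
.LABEL_BACKGROUND <- 0L
.LABEL_SILK <- -1L

#' Two-photon excited fluorescence field
#'
#' A single imaged plane: the NADH channel (755 nm excitation, 460 nm
#' emission) and the FAD channel (860 nm excitation, 525 nm emission) as
#' equally shaped non-negative matrices, together with the acquisition
#' settings needed for power/gain normalization and the metadata that places
#' the field inside a cohort.
#'
#' The coordinate convention throughout the package is row-major with the
#' origin at the top-left: a pixel is \code{(x, y)} with \code{x} the 0-based
#' column and \code{y} the 0-based row, i.e. matrix element \code{[y + 1,
#' x + 1]}. Channel shifts \code{(dx, dy)} are applied to the FAD channel.
#'
#' @slot nadh,fad numeric matrices of photon counts (raw) or normalized
#'   intensities, same shape, all values non-negative.
#' @slot acq named list with entries \code{power_nadh}, \code{power_fad}
#'   (mW), \code{gain_nadh}, \code{gain_fad} (dimensionless), all positive.
#' @slot meta named list with at least \code{condition}, \code{sample_id},
#'   \code{field_id}; optionally \code{depth_um}.
#' @slot normalized logical; \code{TRUE} after [normalizeField()].
#' @slot divisors named numeric; the divisor applied per channel
#'   (\code{NA_real_} while raw) so normalization is exactly invertible.
#' @seealso [TPEFField()], [normalizeField()], [renderChannels()]
#' @export
setClass("TPEFField",
  representation(
    nadh = "matrix", fad = "matrix",
    acq = "list", meta = "list",
    normalized = "logical", divisors = "numeric"
  ),
  prototype(
    normalized = FALSE,
    divisors = c(nadh = NA_real_, fad = NA_real_)
  )
)

setValidity("TPEFField", function(object) {
  msg <- character()
  if (!identical(dim(object@nadh), dim(object@fad)))
    msg <- c(msg, "nadh and fad must have identical dimensions")
  if (anyNA(object@nadh) || anyNA(object@fad))
    msg <- c(msg, "channel images must not contain NA")
  else if (min(object@nadh) < 0 || min(object@fad) < 0)
    msg <- c(msg, "channel images must be non-negative")
  need <- c("power_nadh", "power_fad", "gain_nadh", "gain_fad")
  miss <- setdiff(need, names(object@acq))
  if (length(miss))
    msg <- c(msg, paste0("acq is missing: ", paste(miss, collapse = ", ")))
  else {
    vals <- unlist(object@acq[need])
    if (any(!is.finite(vals)) || any(vals <= 0))
      msg <- c(msg, "acquisition powers and gains must be finite and > 0")
  }
  needm <- c("condition", "sample_id", "field_id")
  missm <- setdiff(needm, names(object@meta))
  if (length(missm))
    msg <- c(msg, paste0("meta is missing: ", paste(missm, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-pixel time-binned photon decay stack
#'
#' Time-correlated single-photon counting (TCSPC) histograms for every pixel
#' of a field at 755 nm excitation, stored as an array with dimensions
#' \code{(y, x, time_bin)}. Bin \code{i} covers
#' \code{t0_offset_ns + (i-1)*bin_width_ns} to
#' \code{t0_offset_ns + i*bin_width_ns}.
#'
#' @slot counts non-negative numeric array \code{(ny, nx, nt)}.
#' @slot binWidthNs positive bin width in ns.
#' @slot t0OffsetNs offset of the first bin edge in ns (usually 0).
#' @seealso [phasorTransform()], [renderDecays()]
#' @export
setClass("DecayStack",
  representation(counts = "array", binWidthNs = "numeric",
                 t0OffsetNs = "numeric"),
  prototype(t0OffsetNs = 0)
)

setValidity("DecayStack", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-D array (y, x, time_bin)")
  if (anyNA(object@counts) || min(object@counts) < 0)
    msg <- c(msg, "counts must be non-negative and NA-free")
  if (length(object@binWidthNs) != 1L || object@binWidthNs <= 0)
    msg <- c(msg, "binWidthNs must be a single positive number")
  if (length(object@t0OffsetNs) != 1L || object@t0OffsetNs < 0)
    msg <- c(msg, "t0OffsetNs must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Phasor-space representation of a decay stack
#'
#' Per-pixel first-harmonic phasor coordinates \eqn{g} (cosine moment) and
#' \eqn{s} (sine moment) at angular frequency \eqn{\omega}. Noise-free
#' mono-exponential decays fall on the universal semicircle
#' \eqn{(g - 1/2)^2 + s^2 = 1/4}. Pixels with fewer than the minimum photon
#' count are undefined (\code{FALSE} in \code{defined}; \code{NA} in
#' \code{g}/\code{s}).
#'
#' @slot g,s numeric matrices, dimensionless, \code{NA} where undefined.
#' @slot defined logical matrix of pixels with enough photons.
#' @slot omega angular frequency in rad/ns.
#' @slot totalCounts per-pixel total photons.
#' @seealso [phasorTransform()], [apparentLifetime()]
#' @export
setClass("PhasorField",
  representation(g = "matrix", s = "matrix", defined = "matrix",
                 omega = "numeric", totalCounts = "matrix")
)

setValidity("PhasorField", function(object) {
  msg <- character()
  dims <- dim(object@g)
  if (!identical(dims, dim(object@s)) || !identical(dims, dim(object@defined)))
    msg <- c(msg, "g, s and defined must have identical dimensions")
  if (length(object@omega) != 1L || object@omega <= 0)
    msg <- c(msg, "omega must be a single positive number (rad/ns)")
  if (any(is.na(object@g[object@defined])))
    msg <- c(msg, "g must be defined wherever defined is TRUE")
  if (length(msg)) msg else TRUE
})

#' Silk-scaffold mask from the lifetime filter
#'
#' Result of thresholding a per-pixel lifetime map: \code{TRUE} pixels are
#' kept (cellular), \code{FALSE} pixels are removed as silk scaffold whose
#' autofluorescence lifetime exceeds the cutoff. \code{fractionRemoved} is
#' computed over pixels with a defined lifetime.
#'
#' @slot mask logical matrix, \code{TRUE} = keep.
#' @slot cutoffNs the lifetime cutoff in ns.
#' @slot fractionRemoved fraction of defined pixels removed, in \[0, 1\].
#' @seealso [silkFilter()]
#' @export
setClass("SilkMask",
  representation(mask = "matrix", cutoffNs = "numeric",
                 fractionRemoved = "numeric")
)

setValidity("SilkMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (object@cutoffNs <= 0)
    msg <- c(msg, "cutoffNs must be positive")
  fr <- object@fractionRemoved
  if (length(fr) != 1L || is.na(fr) || fr < 0 || fr > 1)
    msg <- c(msg, "fractionRemoved must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-pixel optical redox ratio map
#'
#' The optical redox ratio FAD/(FAD + NADH) per pixel, with an explicit
#' validity mask. A pixel is valid when it survives the silk mask, lies in
#' the registration overlap, and its summed intensity exceeds the epsilon
#' floor; invalid pixels hold \code{NA} in \code{values}. On disk the mask is
#' encoded as NaN in a float TIFF ([writeRedoxMap()]); in memory no NaN
#' arithmetic is performed.
#'
#' @slot values numeric matrix in \[0, 1\] on valid pixels, \code{NA}
#'   elsewhere.
#' @slot valid logical matrix.
#' @slot meta field metadata passthrough.
#' @seealso [computeRedoxMap()], [fieldRedox()], [smoothRedoxMap()]
#' @export
setClass("RedoxMap",
  representation(values = "matrix", valid = "matrix", meta = "list")
)

setValidity("RedoxMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@valid)))
    msg <- c(msg, "values and valid must have identical dimensions")
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be logical")
  v <- object@values[object@valid]
  if (anyNA(v))
    msg <- c(msg, "values must be defined on valid pixels")
  else if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "valid redox values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pixel-wise redox ratio histogram
#'
#' Valid redox values binned into 50 equal bins on \[0, 1\] (51 edges). Bins
#' are half-open \code{[a, b)} except the last, which is closed so the value
#' 1.0 is counted. \code{density} is the fraction of valid pixels per bin and
#' sums to 1.
#'
#' @slot edges numeric vector of 51 strictly increasing edges, 0 to 1.
#' @slot density numeric vector of 50 non-negative bin fractions.
#' @slot nPixels number of valid pixels binned.
#' @slot meta image metadata passthrough.
#' @seealso [makeRedoxHistogram()], [fitBasis()], [fitWeights()]
#' @export
setClass("RedoxHistogram",
  representation(edges = "numeric", density = "numeric",
                 nPixels = "numeric", meta = "list")
)

setValidity("RedoxHistogram", function(object) {
  msg <- character()
  ne <- length(object@edges)
  if (length(object@density) != ne - 1L)
    msg <- c(msg, "density must have one entry per bin (length(edges) - 1)")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (object@edges[1] != 0 || object@edges[ne] != 1)
    msg <- c(msg, "edges must span exactly [0, 1]")
  if (min(object@density) < 0)
    msg <- c(msg, "density must be non-negative")
  if (abs(sum(object@density) - 1) > 1e-9)
    msg <- c(msg, "density must sum to 1 within 1e-9")
  if (object@nPixels <= 0)
    msg <- c(msg, "nPixels must be positive")
  if (length(msg)) msg else TRUE
})

#' Shared Gaussian basis for histogram decomposition
#'
#' The K Gaussian components (means and standard deviations on the redox
#' scale) fitted to the aggregate histogram pooled across all groups.
#' Components are labeled by ascending mean, so Component 1 is centered at
#' the lowest redox ratio (the glycolysis-associated component) and
#' Component K at the highest. The basis is the element-wise average of the
#' sorted per-iteration fits across \code{nIterations} independent random
#' initializations.
#'
#' @slot means,sds numeric length-K vectors; means sorted ascending, sds > 0.
#' @slot nIterations number of EM initializations averaged.
#' @slot seeds the sub-seed used per iteration (provenance).
#' @slot bic Bayesian information criterion of the averaged basis refitted
#'   to the pooled histogram (informational; K is user-chosen).
#' @seealso [fitBasis()], [fitWeights()]
#' @export
setClass("GaussianBasis",
  representation(means = "numeric", sds = "numeric",
                 nIterations = "numeric", seeds = "numeric", bic = "numeric"),
  prototype(bic = NA_real_)
)

setValidity("GaussianBasis", function(object) {
  msg <- character()
  k <- length(object@means)
  if (k < 1L) msg <- c(msg, "basis needs at least one component")
  if (length(object@sds) != k)
    msg <- c(msg, "means and sds must have equal length")
  if (is.unsorted(object@means))
    msg <- c(msg, "means must be sorted ascending")
  if (any(object@sds <= 0))
    msg <- c(msg, "sds must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic ground-truth scene
#'
#' Full ground truth for one synthetic field: per-pixel true redox ratio
#' (defined exactly on cell-population pixels), a label image (0 background,
#' -1 silk, 1..P the populations), the true silk mask, the expected total
#' photon intensity, per-pixel fluorescence lifetimes, the integer channel
#' shift applied to the FAD channel at render time, and the seed that makes
#' the scene reproducible. \code{clipFraction} reports the mass of mixture
#' draws clipped into \[0, 1\].
#'
#' @slot trueRedox numeric matrix, \code{NA} off cell pixels.
#' @slot labels integer matrix of label codes.
#' @slot populationNames names of labels 1..P.
#' @slot silkMask logical matrix, \code{TRUE} on silk.
#' @slot totalIntensity expected photons/pixel before channel scaling.
#' @slot lifetimes per-pixel lifetime in ns (\code{NA} on background).
#' @slot appliedShift integer \code{(dx, dy)} applied to FAD when rendering.
#' @slot seed integer seed.
#' @slot clipFraction fraction of redox draws clipped to \[0, 1\].
#' @slot spec the [sceneSpec()] the scene was built from.
#' @seealso [makeScene()], [renderChannels()], [renderDecays()]
#' @export
setClass("SyntheticScene",
  representation(
    trueRedox = "matrix", labels = "matrix", populationNames = "character",
    silkMask = "matrix", totalIntensity = "matrix", lifetimes = "matrix",
    appliedShift = "integer", seed = "integer", clipFraction = "numeric",
    spec = "list"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  dims <- dim(object@labels)
  for (sl in c("trueRedox", "silkMask", "totalIntensity", "lifetimes"))
    if (!identical(dim(slot(object, sl)), dims))
      msg <- c(msg, paste0(sl, " must match the label image shape"))
  cell <- object@labels > 0L
  if (any(is.na(object@trueRedox[cell])))
    msg <- c(msg, "trueRedox must be defined on every cell pixel")
  if (any(!is.na(object@trueRedox[!cell])))
    msg <- c(msg, "trueRedox must be undefined off cell pixels")
  if (!identical(unname(object@silkMask), unname(object@labels == .LABEL_SILK)))
    msg <- c(msg, "silkMask must agree with the silk label")
  if (length(object@appliedShift) != 2L)
    msg <- c(msg, "appliedShift must be (dx, dy)")
  if (length(msg)) msg else TRUE
})

#' Channel registration result
#'
#' The integer shift \code{(dx, dy)} that, applied to the FAD channel,
#' maximizes the Pearson correlation with the NADH channel over the overlap
#' region, the correlation at the optimum, and the joint-validity mask of
#' pixels both channels cover after shifting.
#'
#' @slot shift integer \code{(dx, dy)}.
#' @slot score Pearson correlation at the optimum, in \[-1, 1\] (0 reported
#'   for zero-variance overlaps).
#' @slot overlapMask logical matrix of jointly valid pixels.
#' @seealso [registerChannels()], [applyShift()]
#' @export
setClass("RegistrationResult",
  representation(shift = "integer", score = "numeric", overlapMask = "matrix")
)

setValidity("RegistrationResult", function(object) {
  msg <- character()
  if (length(object@shift) != 2L)
    msg <- c(msg, "shift must be (dx, dy)")
  if (length(object@score) != 1L || is.na(object@score) ||
      object@score < -1 - 1e-12 || object@score > 1 + 1e-12)
    msg <- c(msg, "score must be a single correlation in [-1, 1]")
  if (length(msg)) msg else TRUE
})
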