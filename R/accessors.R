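#' @rdname TPEFField-class
#' @export
setMethod("nadh", "TPEFField", function(x) x@nadh)

#' @rdname TPEFField-class
#' @export
setMethod("fad", "TPEFField", function(x) x@fad)

#' @rdname TPEFField-class
#' @export
setMethod("acqParams", "TPEFField", function(x) x@acq)

#' @rdname TPEFField-class
#' @export
setMethod("fieldMeta", "TPEFField", function(x) x@meta)

#' @rdname TPEFField-class
#' @export
setMethod("isNormalized", "TPEFField", function(x) x@normalized)

#' @rdname RedoxMap-class
#' @export
setMethod("redoxValues", "RedoxMap", function(x) x@values)

#' @rdname RedoxMap-class
#' @export
setMethod("validMask", "RedoxMap", function(x) x@valid)

#' @rdname SilkMask-class
#' @export
setMethod("validMask", "SilkMask", function(x) x@mask)

#' @rdname DecayStack-class
#' @export
setMethod("decayCounts", "DecayStack", function(x) x@counts)

#' @rdname DecayStack-class
#' @export
setMethod("binWidthNs", "DecayStack", function(x) x@binWidthNs)

#' @rdname GaussianBasis-class
#' @export
setMethod("componentMeans", "GaussianBasis", function(x) x@means)

#' @rdname GaussianBasis-class
#' @export
setMethod("componentSds", "GaussianBasis", function(x) x@sds)

#' @rdname GaussianBasis-class
#' @export
setMethod("nComponents", "GaussianBasis", function(x) length(x@means))

setMethod("show", "TPEFField", function(object) {
  d <- dim(object@nadh)
  cat(sprintf("TPEFField %d x %d [%s]\n", d[2], d[1],
              if (object@normalized) "normalized" else "raw"))
  m <- object@meta
  cat(sprintf("  condition=%s sample=%s field=%s\n",
              m$condition, m$sample_id, m$field_id))
  a <- object@acq
  cat(sprintf("  power (mW): NADH %.3g, FAD %.3g; gain: NADH %.3g, FAD %.3g\n",
              a$power_nadh, a$power_fad, a$gain_nadh, a$gain_fad))
  invisible(NULL)
})

setMethod("show", "DecayStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "DecayStack %d x %d pixels, %d time bins of %.4g ns (window %.4g ns)\n",
    d[2], d[1], d[3], object@binWidthNs, d[3] * object@binWidthNs))
  invisible(NULL)
})

setMethod("show", "PhasorField", function(object) {
  cat(sprintf("PhasorField %d x %d, omega = %.4g rad/ns, %d defined pixels\n",
              ncol(object@g), nrow(object@g), object@omega,
              sum(object@defined)))
  invisible(NULL)
})

setMethod("show", "SilkMask", function(object) {
  cat(sprintf("SilkMask: cutoff %.3g ns, %.2f%% of defined pixels removed\n",
              object@cutoffNs, 100 * object@fractionRemoved))
  invisible(NULL)
})

setMethod("show", "RedoxMap", function(object) {
  n <- sum(object@valid)
  cat(sprintf("RedoxMap %d x %d, %d valid pixels", ncol(object@values),
              nrow(object@values), n))
  if (n > 0)
    cat(sprintf(", mean %.4f", mean(object@values[object@valid])))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "RedoxHistogram", function(object) {
  cat(sprintf("RedoxHistogram: %d bins on [0, 1], %g pixels\n",
              length(object@density), object@nPixels))
  invisible(NULL)
})

setMethod("show", "GaussianBasis", function(object) {
  k <- length(object@means)
  cat(sprintf("GaussianBasis with %d component%s (average of %g EM runs):\n",
              k, if (k == 1) "" else "s", object@nIterations))
  for (i in seq_len(k))
    cat(sprintf("  Component %d: mean %.4f, sd %.4f\n",
                i, object@means[i], object@sds[i]))
  if (!is.na(object@bic)) cat(sprintf("  BIC (informational): %.2f\n", object@bic))
  invisible(NULL)
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SyntheticScene %d x %d, seed %d\n", d[2], d[1], object@seed))
  cat(sprintf("  populations: %s\n",
              paste(object@populationNames, collapse = ", ")))
  cat(sprintf("  silk pixels: %d; applied FAD shift (dx=%d, dy=%d)\n",
              sum(object@silkMask), object@appliedShift[1],
              object@appliedShift[2]))
  invisible(NULL)
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: shift (dx=%d, dy=%d), score %.4f, %d overlap pixels\n",
              object@shift[1], object@shift[2], object@score,
              sum(object@overlapMask)))
  invisible(NULL)
})
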