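# Integer translation: out[y + dy, x + dx] = in[y, x] (0-based x = column,
# y = row). Returns the shifted image and the validity mask of pixels that
# received a value.
.translate <- function(image, shift) {
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  h <- nrow(image); w <- ncol(image)
  out <- matrix(NA_real_, h, w)
  valid <- matrix(FALSE, h, w)
  srcRows <- seq_len(h)[seq_len(h) + dy >= 1L & seq_len(h) + dy <= h]
  srcCols <- seq_len(w)[seq_len(w) + dx >= 1L & seq_len(w) + dx <= w]
  if (length(srcRows) && length(srcCols)) {
    out[srcRows + dy, srcCols + dx] <- image[srcRows, srcCols]
    valid[srcRows + dy, srcCols + dx] <- TRUE
  }
  list(image = out, valid = valid)
}

#' Translate an image by an integer pixel shift
#'
#' Pure translation, no interpolation: the pixel at `(x, y)` moves to
#' `(x + dx, y + dy)`. Pixels shifted in from outside the frame are invalid
#' (`NA` in the image, `FALSE` in the mask).
#'
#' @param image a numeric matrix.
#' @param shift integer `(dx, dy)`.
#' @return list with `image` (shifted matrix) and `valid` (logical mask).
#' @examples
#' applyShift(matrix(1:9, 3, 3), c(1, 0))
#' @export
applyShift <- function(image, shift) {
  if (any(shift != round(shift))) stop("shift must be integer pixels")
  .translate(image, shift)
}

#' Normalize a field for excitation power and detector gain
#'
#' Each channel is divided by power^exponent x gain for that channel, making
#' intensities comparable across acquisitions. The exponent defaults to 2
#' because two-photon excited fluorescence scales with the square of the
#' excitation power; the divisors are recorded on the result so the
#' operation is exactly invertible (raw = normalized x divisor).
#'
#' @param field a raw [TPEFField-class].
#' @param exponent power exponent (default 2).
#' @return a normalized [TPEFField-class].
#' @export
normalizeField <- function(field, exponent = 2) {
  stopifnot(is(field, "TPEFField"))
  if (field@normalized) stop("field is already normalized")
  a <- field@acq
  div <- c(nadh = a$power_nadh^exponent * a$gain_nadh,
           fad = a$power_fad^exponent * a$gain_fad)
  if (any(!is.finite(div)) || any(div <= 0))
    stop("powers and gains must be positive and finite")
  initialize(field, nadh = field@nadh / div[["nadh"]],
             fad = field@fad / div[["fad"]],
             normalized = TRUE, divisors = div)
}

#' Co-register the FAD channel onto the NADH channel
#'
#' Exhaustive search over all integer shifts `(dx, dy)` with
#' `|dx|, |dy| <= max_shift`, scoring each by the Pearson correlation of the
#' two channels on the overlap region; the NADH channel is held fixed and
#' the FAD channel is moved. Ties (including the all-degenerate case of a
#' zero-variance overlap, whose correlation is defined as 0) are broken by
#' the smallest Euclidean shift norm, then lexicographically by `(dx, dy)`,
#' so a featureless pair deterministically returns the zero shift.
#'
#' @param nadh,fad numeric matrices of identical shape.
#' @param max_shift search radius in pixels (default 20).
#' @param min_overlap minimum admissible overlap pixel count; shifts whose
#'   overlap is smaller are not considered, and if no shift is admissible an
#'   error is raised rather than a silent result.
#' @return a [RegistrationResult-class]; apply its `shift` to the FAD
#'   channel with [applyShift()] to align it.
#' @export
registerChannels <- function(nadh, fad, max_shift = 20L, min_overlap = 32L) {
  if (!identical(dim(nadh), dim(fad)))
    stop("channels must have identical shape")
  if (max_shift < 0) stop("max_shift must be >= 0")
  h <- nrow(nadh); w <- ncol(nadh)
  cand <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dx, cand$dy), ]
  best <- NULL; bestScore <- -Inf
  for (i in seq_len(nrow(cand))) {
    dx <- cand$dx[i]; dy <- cand$dy[i]
    # overlap in fixed-frame coordinates after moving FAD by (dx, dy):
    # fixed pixel (r, c) pairs with fad[r - dy, c - dx]
    r0 <- max(1L, 1L + dy); r1 <- min(h, h + dy)
    c0 <- max(1L, 1L + dx); c1 <- min(w, w + dx)
    if (r1 < r0 || c1 < c0) next
    if ((r1 - r0 + 1L) * (c1 - c0 + 1L) < min_overlap) next
    a <- nadh[r0:r1, c0:c1]
    b <- fad[(r0:r1) - dy, (c0:c1) - dx]
    score <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
             else stats::cor(as.vector(a), as.vector(b))
    if (score > bestScore) {
      bestScore <- score
      best <- c(dx, dy)
    }
  }
  if (is.null(best))
    stop("no candidate shift leaves an overlap of at least ", min_overlap,
         " pixels; reduce max_shift or min_overlap")
  ov <- .translate(matrix(1, h, w), best)$valid
  new("RegistrationResult", shift = as.integer(best),
      score = bestScore, overlapMask = ov)
}

#' Normalize and register a field in one step
#'
#' Convenience wrapper: [normalizeField()] then [registerChannels()], with
#' the registered FAD channel substituted and the overlap recorded. Because
#' normalization is a per-channel scalar division, it commutes with the
#' integer-shift registration.
#'
#' @inheritParams normalizeField
#' @inheritParams registerChannels
#' @return list with `field` (normalized [TPEFField-class] whose FAD channel
#'   is aligned; out-of-frame pixels hold 0) and `registration`
#'   (the [RegistrationResult-class]).
#' @export
preprocessField <- function(field, exponent = 2, max_shift = 20L,
                            min_overlap = 32L) {
  nf <- normalizeField(field, exponent)
  reg <- registerChannels(nf@nadh, nf@fad, max_shift, min_overlap)
  sh <- .translate(nf@fad, reg@shift)
  aligned <- sh$image
  aligned[!sh$valid] <- 0
  list(field = initialize(nf, fad = aligned), registration = reg)
}
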