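#' Per-pixel optical redox ratio map
#'
#' Computes FAD / (FAD + NADH) per pixel on normalized, registered channels.
#' A pixel is valid when it is allowed by `valid_mask` (silk mask intersected
#' with the registration overlap) and its summed intensity exceeds `epsilon`
#' — the floor excludes dark background pixels without touching dim cells.
#' An empty valid set is an error that names which constraint emptied it.
#'
#' @param nadh,fad normalized channel matrices of identical shape.
#' @param valid_mask logical matrix of admissible pixels (default all).
#' @param epsilon denominator floor in normalized intensity units
#'   (default 1e-6).
#' @param meta metadata list carried onto the map.
#' @return a [RedoxMap-class].
#' @examples
#' m <- matrix(1, 4, 4)
#' redoxValues(computeRedoxMap(m, m))[1, 1]  # 0.5
#' @export
computeRedoxMap <- function(nadh, fad, valid_mask = NULL, epsilon = 1e-6,
                            meta = list()) {
  if (!identical(dim(nadh), dim(fad)))
    stop("channels must have identical shape")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(nadh), ncol(nadh))
  if (!identical(dim(valid_mask), dim(nadh)))
    stop("valid_mask must match the channel shape")
  denom <- nadh + fad
  bright <- denom > epsilon
  valid <- valid_mask & bright
  if (!any(valid)) {
    why <- c(
      if (!any(valid_mask)) "the input mask (silk/overlap) excludes every pixel",
      if (!any(bright)) sprintf("no pixel has NADH + FAD > epsilon = %g", epsilon),
      if (any(valid_mask) && any(bright))
        "the mask and the intensity floor jointly exclude every pixel")
    stop("empty valid set: ", paste(why, collapse = "; "))
  }
  values <- matrix(NA_real_, nrow(nadh), ncol(nadh))
  values[valid] <- fad[valid] / denom[valid]
  new("RedoxMap", values = values, valid = valid, meta = meta)
}

#' Per-field redox summary
#'
#' The mean redox value of one field of view. The default
#' `intensity_weighted` mode reports the normalized FAD intensity
#' contribution over the summed NADH + FAD contributions,
#' \eqn{\sum F / \sum (F + N)} over valid pixels; `pixel_mean` averages the
#' per-pixel ratios instead. The two agree on uniform fields and differ when
#' bright and dim pixels have different ratios.
#'
#' @inheritParams computeRedoxMap
#' @param mode `"intensity_weighted"` (default) or `"pixel_mean"`.
#' @return one-row data.frame with `field_mean`, `mode`, `n_valid_pixels`,
#'   and any `condition`/`sample_id`/`field_id` present in `meta`.
#' @examples
#' n <- matrix(c(9, 0), 1); f <- matrix(c(1, 1), 1)
#' fieldRedox(n, f, mode = "pixel_mean")$field_mean          # 0.55
#' fieldRedox(n, f, mode = "intensity_weighted")$field_mean  # 2/11
#' @export
fieldRedox <- function(nadh, fad, valid_mask = NULL,
                       mode = c("intensity_weighted", "pixel_mean"),
                       epsilon = 1e-6, meta = list()) {
  mode <- match.arg(mode)
  map <- computeRedoxMap(nadh, fad, valid_mask, epsilon, meta)
  v <- map@valid
  fm <- if (mode == "intensity_weighted")
    sum(fad[v]) / sum(fad[v] + nadh[v])
  else mean(map@values[v])
  out <- data.frame(field_mean = fm, mode = mode, n_valid_pixels = sum(v),
                    stringsAsFactors = FALSE)
  for (k in c("condition", "sample_id", "field_id", "depth_um"))
    if (!is.null(meta[[k]])) out[[k]] <- meta[[k]]
  out
}

#' Per-sample redox means from field summaries
#'
#' Fields are averaged (unweighted) within each sample: the sample — a whole
#' 3D construct — is the unit of statistical inference, which is what makes
#' a two-group comparison with n = 3 samples per condition carry 4 degrees
#' of freedom.
#'
#' @param fields data.frame of field summaries ([fieldRedox()] rows) with
#'   columns `field_mean`, `sample_id` and optionally `condition`.
#' @return data.frame with one row per sample: `condition` (if present),
#'   `sample_id`, `sample_mean`, `n_fields`.
#' @export
sampleRedox <- function(fields) {
  stopifnot(is.data.frame(fields), nrow(fields) >= 1L,
            all(c("field_mean", "sample_id") %in% names(fields)))
  keyCols <- intersect(c("condition", "sample_id"), names(fields))
  key <- interaction(fields[keyCols], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(fields, key), function(d) {
    row <- d[1, keyCols, drop = FALSE]
    row$sample_mean <- mean(d$field_mean)
    row$n_fields <- nrow(d)
    row
  })
  out <- do.call(rbind, agg)  # split() yields deterministic level order
  rownames(out) <- NULL
  out
}
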