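#' Describe one experimental condition of a synthetic cohort
#'
#' Convenience wrapper producing a full-frame single-population condition:
#' every cell pixel's redox ratio is drawn from `N(mean_redox, sd_redox)`
#' (clipped to \[0, 1\]). For structured conditions (several populations,
#' silk geometry) pass `populations` built by hand to [cohortDesign()].
#'
#' @param mean_redox condition-level true mean redox ratio.
#' @param sd_redox per-pixel redox SD (default 0.05).
#' @param intensity_mean expected photons/pixel (default 100).
#' @param lifetime_ns cellular lifetime in ns (default 1.2).
#' @return a condition descriptor for [cohortDesign()].
#' @export
uniformCondition <- function(mean_redox, sd_redox = 0.05,
                             intensity_mean = 100, lifetime_ns = 1.2) {
  list(mean_redox = mean_redox, sd_redox = sd_redox,
       intensity_mean = intensity_mean, lifetime_ns = lifetime_ns)
}

#' Describe a multi-condition synthetic imaging cohort
#'
#' Mirrors the study design: a small number of constructs (samples) per
#' condition, several fields imaged per sample, with a treatment effect
#' expressed as a redox offset. Between-field biological variability is
#' modeled as a Gaussian offset of each field's population means with SD
#' `field_sd` (shared by every population in the field).
#'
#' @param conditions named list of condition descriptors
#'   ([uniformCondition()]), each optionally carrying a `redox_offset`
#'   (treatment effect added to all its population means).
#' @param n_samples samples (constructs) per condition; the study images
#'   n = 3 per condition.
#' @param fields_per_sample fields imaged per sample (3–8 in the study;
#'   default 4).
#' @param width,height field size in pixels.
#' @param field_sd SD of the per-field redox offset (default 0.03).
#' @param acq an [acquisitionSpec()].
#' @param noise apply Poisson shot noise (default `TRUE`).
#' @param channel_shift_max if > 0, each field's FAD channel is shifted by
#'   integers drawn uniformly from `[-max, max]^2` (tests registration
#'   end-to-end); 0 keeps channels aligned.
#' @param include_decays render a TCSPC decay stack per field (needed for
#'   the silk filter; costly, off by default).
#' @param silk optional silk footprint (e.g. [ringFootprint()]) painted in
#'   every field, plus `silk_lifetime_ns`/`silk_intensity_mean` fixtures.
#' @param silk_lifetime_ns,silk_intensity_mean silk fixture parameters.
#' @return a `CohortDesign` list.
#' @export
cohortDesign <- function(conditions, n_samples = 3L, fields_per_sample = 4L,
                         width = 64L, height = 64L, field_sd = 0.03,
                         acq = acquisitionSpec(), noise = TRUE,
                         channel_shift_max = 0L, include_decays = FALSE,
                         silk = NULL, silk_lifetime_ns = 2.8,
                         silk_intensity_mean = 150) {
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list")
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (fields_per_sample < 1L) stop("fields_per_sample must be >= 1")
  structure(list(conditions = conditions, n_samples = as.integer(n_samples),
                 fields_per_sample = as.integer(fields_per_sample),
                 width = as.integer(width), height = as.integer(height),
                 field_sd = field_sd, acq = acq, noise = isTRUE(noise),
                 channel_shift_max = as.integer(channel_shift_max),
                 include_decays = isTRUE(include_decays), silk = silk,
                 silk_lifetime_ns = silk_lifetime_ns,
                 silk_intensity_mean = silk_intensity_mean),
            class = "CohortDesign")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministically expands a [cohortDesign()] into rendered fields (and
#' optionally decay stacks) with per-field metadata and a ground-truth
#' manifest recording each field's generating mean redox, so downstream
#' recovery and inference can be checked against truth.
#'
#' @param design a [cohortDesign()].
#' @param seed integer master seed; every field derives its own sub-seed.
#' @return list with `entries` (one per field: `field` [TPEFField-class],
#'   `decay` or `NULL`, `truth` list) and `truth` (data.frame: condition,
#'   sample_id, field_id, true_mean_redox, field_offset, shift_dx,
#'   shift_dy), plus the design and seed.
#' @export
makeCohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "CohortDesign"))
  entries <- list()
  truthRows <- list()
  idx <- 0L
  for (cn in names(design$conditions)) {
    cond <- design$conditions[[cn]]
    offset <- if (is.null(cond$redox_offset)) 0 else cond$redox_offset
    for (si in seq_len(design$n_samples)) {
      sid <- sprintf("%s_s%d", cn, si)
      for (fi in seq_len(design$fields_per_sample)) {
        idx <- idx + 1L
        sub <- .subSeed(seed, idx)
        draws <- .withSeed(sub, list(
          fieldOffset = stats::rnorm(1, 0, design$field_sd),
          shift = if (design$channel_shift_max > 0)
            sample(seq(-design$channel_shift_max, design$channel_shift_max),
                   2L, replace = TRUE)
          else c(0L, 0L)))
        mu <- min(1, max(0, cond$mean_redox + offset + draws$fieldOffset))
        pop <- populationSpec(
          cn, data.frame(mean = mu, sd = cond$sd_redox, weight = 1),
          intensity_mean = cond$intensity_mean,
          lifetime_ns = cond$lifetime_ns)
        spec <- sceneSpec(
          design$width, design$height,
          populations = list(list(
            spec = pop,
            footprint = rectFootprint(0, 0, design$width, design$height))),
          silk = design$silk, silk_lifetime_ns = design$silk_lifetime_ns,
          silk_intensity_mean = design$silk_intensity_mean,
          channel_shift = draws$shift,
          max_shift = max(1L, design$channel_shift_max),
          noise = design$noise, seed = .subSeed(sub, 1))
        scene <- makeScene(spec)
        fid <- sprintf("%s_f%d", sid, fi)
        field <- renderChannels(scene, design$acq, condition = cn,
                                sample_id = sid, field_id = fid)
        decay <- if (design$include_decays) renderDecays(scene, design$acq)
                 else NULL
        entries[[idx]] <- list(field = field, decay = decay,
                               truth = list(true_mean_redox = mu,
                                            shift = draws$shift))
        truthRows[[idx]] <- data.frame(
          condition = cn, sample_id = sid, field_id = fid,
          true_mean_redox = mu, field_offset = draws$fieldOffset,
          shift_dx = draws$shift[1], shift_dy = draws$shift[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  list(entries = entries, truth = truth, design = design, seed = seed)
}

#' Run the redox pipeline over a generated cohort
#'
#' For every field: power/gain normalization, channel co-registration,
#' optional lifetime-based silk masking (when decay stacks are present),
#' per-pixel redox map and per-field summary; then fields are averaged into
#' per-sample means, the unit of inference.
#'
#' @param cohort output of [makeCohort()].
#' @param exponent power-normalization exponent (default 2).
#' @param max_shift registration search radius; defaults to the design's
#'   `channel_shift_max` plus a 2 px margin.
#' @param cutoff_ns silk-filter lifetime cutoff in ns.
#' @param epsilon redox denominator floor.
#' @param mode field summary mode, see [fieldRedox()].
#' @param keep_maps also return the per-field [RedoxMap-class] objects
#'   (needed for histogram decomposition).
#' @return list with `fields` (per-field summary data.frame joined to the
#'   ground truth), `samples` ([sampleRedox()] output) and, if requested,
#'   `maps`.
#' @export
analyzeCohort <- function(cohort, exponent = 2, max_shift = NULL,
                          cutoff_ns = 2.0, epsilon = 1e-6,
                          mode = "intensity_weighted", keep_maps = FALSE) {
  if (is.null(max_shift))
    max_shift <- cohort$design$channel_shift_max + 2L
  maps <- if (keep_maps) vector("list", length(cohort$entries)) else NULL
  rows <- vector("list", length(cohort$entries))
  for (i in seq_along(cohort$entries)) {
    e <- cohort$entries[[i]]
    pp <- preprocessField(e$field, exponent, max_shift)
    mask <- pp$registration@overlapMask
    if (!is.null(e$decay)) {
      tau <- apparentLifetime(phasorTransform(e$decay))
      mask <- mask & validMask(silkFilter(tau, cutoff_ns))
    }
    f <- pp$field
    rows[[i]] <- fieldRedox(f@nadh, f@fad, mask, mode, epsilon, f@meta)
    if (keep_maps)
      maps[[i]] <- computeRedoxMap(f@nadh, f@fad, mask, epsilon, f@meta)
  }
  fields <- do.call(rbind, rows)
  rownames(fields) <- NULL
  out <- list(fields = fields, samples = sampleRedox(fields))
  if (keep_maps) out$maps <- maps
  out
}
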