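# --- minimal 32-bit float TIFF writer -------------------------------------
#
# The CRAN tiff package reads IEEE-float TIFFs (including NaN) but only
# writes [0,1]-scaled unsigned integers, so the float dialect is written
# here directly: little-endian baseline TIFF, one grayscale sample per
# pixel, SampleFormat = IEEE float, one strip per image, multi-page via a
# chained IFD per page. Values are stored as float32 (integers up to 2^24
# round-trip exactly; doubles are truncated to float precision).

.tiffEntry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in the 4-byte slot
  c(.le16(tag), .le16(type), .le32(count),
    if (type == 3L) c(.le16(value), as.raw(c(0, 0))) else .le32(value))
}
.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.writeFloatTiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)  # "II", magic 42
  # layout per page: [pixel strip][IFD]; first IFD offset follows header
  nTags <- 10L
  ifdSize <- 2L + nTags * 12L + 4L
  offset <- 8L
  dataOff <- integer(length(images)); ifdOff <- integer(length(images))
  for (i in seq_along(images)) {
    nbytes <- 4L * length(images[[i]])
    dataOff[i] <- offset + ifdSize
    ifdOff[i] <- offset
    offset <- offset + ifdSize + nbytes
  }
  writeBin(.le32(ifdOff[1]), con)
  for (i in seq_along(images)) {
    m <- images[[i]]
    h <- nrow(m); w <- ncol(m)
    nextIfd <- if (i < length(images)) ifdOff[i + 1L] else 0L
    ifd <- c(
      .le16(nTags),
      .tiffEntry(256L, 4L, 1L, w),                 # ImageWidth
      .tiffEntry(257L, 4L, 1L, h),                 # ImageLength
      .tiffEntry(258L, 3L, 1L, 32L),               # BitsPerSample
      .tiffEntry(259L, 3L, 1L, 1L),                # Compression: none
      .tiffEntry(262L, 3L, 1L, 1L),                # Photometric: min-is-black
      .tiffEntry(273L, 4L, 1L, dataOff[i]),        # StripOffsets
      .tiffEntry(277L, 3L, 1L, 1L),                # SamplesPerPixel
      .tiffEntry(278L, 4L, 1L, h),                 # RowsPerStrip
      .tiffEntry(279L, 4L, 1L, 4L * h * w),        # StripByteCounts
      .tiffEntry(339L, 3L, 1L, 3L),                # SampleFormat: IEEE float
      .le32(nextIfd))
    writeBin(ifd, con)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
  }
  invisible(path)
}

# readTIFF returns float samples as-is and integer samples scaled to [0,1];
# integer dialects are rescaled by the caller using the sidecar's dialect.
.readTiffImage <- function(path, page = 1L) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (page > length(imgs)) stop("TIFF has only ", length(imgs), " page(s)")
  img <- imgs[[page]]
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

# --- fields ---------------------------------------------------------------

.SIDEcar_FIELD_KEYS <- c("power_nadh", "power_fad", "gain_nadh", "gain_fad",
                         "condition", "sample_id", "field_id")

#' Save a field to TIFF + YAML sidecar
#'
#' Writes the two channels as single-page grayscale TIFFs and the
#' acquisition metadata as a YAML sidecar with a fixed key order, so
#' identical inputs produce byte-identical files. The `float32` dialect
#' stores intensities as IEEE floats (photon counts round-trip exactly);
#' `uint16` stores integers up to 65535 via the tiff package.
#'
#' @param field a [TPEFField-class].
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>_nadh.tif`, `<stem>_fad.tif`,
#'   `<stem>.yaml`.
#' @param dialect `"float32"` (default) or `"uint16"`.
#' @return invisibly, the named list of written paths.
#' @seealso [loadField()]
#' @export
saveField <- function(field, dir, stem = field@meta$field_id,
                      dialect = c("float32", "uint16")) {
  stopifnot(is(field, "TPEFField"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(nadh = file.path(dir, paste0(stem, "_nadh.tif")),
                fad = file.path(dir, paste0(stem, "_fad.tif")),
                sidecar = file.path(dir, paste0(stem, ".yaml")))
  for (ch in c("nadh", "fad")) {
    m <- slot(field, ch)
    if (dialect == "float32") .writeFloatTiff(m, paths[[ch]])
    else {
      if (max(m) > 65535 || any(m != round(m)))
        stop("uint16 dialect requires integer counts <= 65535")
      tiff::writeTIFF(m / 65535, paths[[ch]], bits.per.sample = 16L,
                      compression = "none")
    }
  }
  side <- c(field@acq[c("power_nadh", "power_fad", "gain_nadh", "gain_fad")],
            field@meta[intersect(c("condition", "sample_id", "field_id",
                                   "depth_um"), names(field@meta))],
            list(normalized = field@normalized, dialect = dialect))
  writeLines(yaml::as.yaml(side), paths$sidecar)
  invisible(paths)
}

#' Load a field from TIFF + YAML sidecar
#'
#' Reads the two channel TIFFs (either dialect; equal contents load to
#' equal values) and validates the sidecar, raising an error that names any
#' missing metadata key. Shape mismatches between the channels and negative
#' pixel values are errors.
#'
#' @param nadh_path,fad_path channel TIFF paths.
#' @param sidecar_path YAML sidecar path.
#' @return a [TPEFField-class].
#' @export
loadField <- function(nadh_path, fad_path, sidecar_path) {
  side <- yaml::read_yaml(sidecar_path)
  miss <- setdiff(.SIDEcar_FIELD_KEYS, names(side))
  if (length(miss))
    stop("sidecar is missing required key(s): ", paste(miss, collapse = ", "))
  readCh <- function(p) {
    m <- .readTiffImage(p)
    if (identical(side$dialect, "uint16")) m <- round(m * 65535)
    m
  }
  nadh <- readCh(nadh_path)
  fad <- readCh(fad_path)
  if (!identical(dim(nadh), dim(fad)))
    stop("channel shape mismatch: NADH ", paste(dim(nadh), collapse = "x"),
         " vs FAD ", paste(dim(fad), collapse = "x"))
  if (min(nadh) < 0 || min(fad) < 0)
    stop("negative pixel values in channel image")
  norm <- isTRUE(side$normalized)
  new("TPEFField", nadh = nadh, fad = fad,
      acq = side[c("power_nadh", "power_fad", "gain_nadh", "gain_fad")],
      meta = side[intersect(c("condition", "sample_id", "field_id",
                              "depth_um"), names(side))],
      normalized = norm, divisors = c(nadh = NA_real_, fad = NA_real_))
}

# --- redox maps -----------------------------------------------------------

#' Write / read a redox map as float TIFF
#'
#' Masked (invalid) pixels are encoded as NaN on disk; in memory the mask is
#' the explicit `valid` slot and no NaN arithmetic occurs in the pipeline.
#'
#' @param map a [RedoxMap-class].
#' @param path output TIFF path.
#' @return `writeRedoxMap()`: invisibly, the path. `loadRedoxMap()`: a
#'   [RedoxMap-class] whose validity mask is the non-NaN pixels.
#' @export
writeRedoxMap <- function(map, path) {
  stopifnot(is(map, "RedoxMap"))
  m <- map@values
  m[!map@valid] <- NaN
  .writeFloatTiff(m, path)
  invisible(path)
}

#' @rdname writeRedoxMap
#' @export
loadRedoxMap <- function(path) {
  m <- .readTiffImage(path)
  valid <- is.finite(m)
  m[!valid] <- NA_real_
  new("RedoxMap", values = m, valid = valid, meta = list())
}

# --- decay stacks ---------------------------------------------------------

#' Write / read a TCSPC decay stack (multi-page float TIFF + YAML sidecar)
#'
#' One TIFF page per time bin; the sidecar records `bin_width_ns`,
#' `t0_offset_ns` and `n_time_bins`. Counts round-trip losslessly (they are
#' integers well below float32's 2^24 exact-integer limit).
#'
#' @param stack a [DecayStack-class].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @return `saveDecayStack()`: invisibly, the path; `loadDecayStack()`: a
#'   [DecayStack-class].
#' @export
saveDecayStack <- function(stack, path) {
  stopifnot(is(stack, "DecayStack"))
  d <- dim(stack@counts)
  pages <- lapply(seq_len(d[3]), function(b) stack@counts[, , b])
  .writeFloatTiff(pages, path)
  writeLines(yaml::as.yaml(list(bin_width_ns = stack@binWidthNs,
                                t0_offset_ns = stack@t0OffsetNs,
                                n_time_bins = d[3])),
             paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname saveDecayStack
#' @param sidecar_path the YAML sidecar (defaults to `<path>.yaml`).
#' @export
loadDecayStack <- function(path, sidecar_path = paste0(path, ".yaml")) {
  side <- yaml::read_yaml(sidecar_path)
  miss <- setdiff(c("bin_width_ns", "t0_offset_ns"), names(side))
  if (length(miss))
    stop("sidecar is missing required key(s): ", paste(miss, collapse = ", "))
  imgs <- tiff::readTIFF(path, all = TRUE)
  counts <- array(0, c(dim(imgs[[1]])[1:2], length(imgs)))
  for (b in seq_along(imgs)) {
    pg <- imgs[[b]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    counts[, , b] <- pg
  }
  new("DecayStack", counts = counts, binWidthNs = side$bin_width_ns,
      t0OffsetNs = side$t0_offset_ns)
}

# --- tables and manifests -------------------------------------------------

#' Write a results table as deterministic CSV
#'
#' UTF-8, '.' decimal separator, mandatory header row, LF line endings, no
#' row names and no quoting of numerics — identical inputs give
#' byte-identical files. An empty table writes the header only. NaN/NA in a
#' numeric column is an error unless `allow_na = TRUE`, so half-computed
#' results cannot be written silently.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @param allow_na permit missing values in numeric columns.
#' @return invisibly, the path.
#' @export
writeTable <- function(rows, path, allow_na = FALSE) {
  stopifnot(is.data.frame(rows))
  if (!allow_na)
    for (cn in names(rows))
      if (is.numeric(rows[[cn]]) && anyNA(rows[[cn]]))
        stop("column '", cn, "' contains NA/NaN where a number is required")
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a table written by [writeTable()]
#' @param path CSV path.
#' @return a data.frame.
#' @export
readTable <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")

#' Write / read a cohort manifest
#'
#' The manifest lists every field's identity and file locations; the
#' `(condition, sample_id, field_id)` triple must be unique within a
#' cohort.
#'
#' @param manifest data.frame with at least `condition`, `sample_id`,
#'   `field_id` columns (typically also the channel and sidecar paths).
#' @param path CSV path.
#' @return as [writeTable()] / [readTable()].
#' @export
writeManifest <- function(manifest, path) {
  need <- c("condition", "sample_id", "field_id")
  stopifnot(all(need %in% names(manifest)))
  key <- do.call(paste, c(manifest[need], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (condition, sample_id, field_id) in manifest")
  writeTable(manifest, path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- readTable(path)
  need <- c("condition", "sample_id", "field_id")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(m[need], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (condition, sample_id, field_id) in manifest")
  m
}
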