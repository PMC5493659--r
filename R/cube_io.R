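# Ingestion and calibration of raw hyperspectral streams.
#
# A pushbroom line-scan camera emits one frame per scan line; each frame
# holds all spectral bands for the pixels across the line. Concatenated
# over lines this is the band-interleaved-by-line (BIL) layout. The
# instrument this package targets records 250 bands over 400--1000 nm with
# 1,004 pixels across the line and 900 scan lines, so a full acquisition is
# a 1,004 x 250 x 900 sample block.

#' Number of spectral bands of the reference instrument
#' @export
HP_N_BANDS <- 250L

#' Spectral range of the reference instrument (nm)
#' @export
HP_WL_RANGE <- c(400, 1000)

#' Construct a raw hyperspectral stream
#'
#' Wraps a payload of unsigned integer samples together with its dimension
#' triple and interleave tag. The payload may be given either as a `raw`
#' byte vector (decoded according to `sample_type`) or as an already
#' decoded numeric/integer vector of samples.
#'
#' @param payload raw vector of bytes, or numeric vector of decoded samples.
#' @param dims integer triple `(spatial_width, n_bands, n_lines)`.
#' @param interleave one of `"bil"`, `"bsq"`, `"bip"`.
#' @param sample_type sample encoding for raw payloads; only
#'   `"uint16le"` (16-bit unsigned little-endian, the instrument default)
#'   and `"uint8"` are supported.
#' @return an object of class `raw_stream`.
#' @export
raw_stream <- function(payload, dims, interleave = c("bil", "bsq", "bip"),
                       sample_type = c("uint16le", "uint8")) {
  interleave <- match.arg(interleave)
  sample_type <- match.arg(sample_type)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L))
    stop("`dims` must be a positive integer triple (width, bands, lines)")
  n_samples <- prod(as.double(dims))
  if (is.raw(payload)) {
    bps <- if (sample_type == "uint16le") 2L else 1L
    expected <- n_samples * bps
    if (length(payload) != expected)
      stop(sprintf(
        "payload size mismatch: expected %.0f bytes (%d x %d x %d samples x %d bytes), got %d",
        expected, dims[1], dims[2], dims[3], bps, length(payload)))
  } else {
    if (!is.numeric(payload)) stop("payload must be a raw or numeric vector")
    if (length(payload) != n_samples)
      stop(sprintf(
        "payload size mismatch: expected %.0f samples (%d x %d x %d), got %d",
        n_samples, dims[1], dims[2], dims[3], length(payload)))
  }
  structure(list(payload = payload, dims = dims, interleave = interleave,
                 sample_type = sample_type),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> %d x %d x %d (%s, %s), %s payload\n",
              x$dims[1], x$dims[2], x$dims[3], x$interleave, x$sample_type,
              if (is.raw(x$payload)) "byte" else "decoded"))
  invisible(x)
}

decode_samples <- function(stream) {
  if (!is.raw(stream$payload)) return(stream$payload)
  n <- prod(as.double(stream$dims))
  if (stream$sample_type == "uint16le")
    readBin(stream$payload, "integer", n = n, size = 2L,
            signed = FALSE, endian = "little")
  else
    as.integer(stream$payload)
}

#' Reorganize a raw stream into per-band images
#'
#' Decodes the sample payload and reshapes it into one image per spectral
#' band following the stream's interleave. For BIL the fastest-varying
#' index is the pixel across the scan line, then the band, then the line.
#'
#' @param stream a [raw_stream()].
#' @return numeric array `spatial_width x n_lines x n_bands`; element
#'   `[p, l, b]` is the sample for pixel `p` of line `l` at band `b`.
#' @export
reorganize_stream <- function(stream) {
  stopifnot(inherits(stream, "raw_stream"))
  samples <- decode_samples(stream)
  w <- stream$dims[1]; nb <- stream$dims[2]; nl <- stream$dims[3]
  out <- switch(stream$interleave,
    bil = aperm(array(samples, dim = c(w, nb, nl)), c(1L, 3L, 2L)),
    bsq = array(samples, dim = c(w, nl, nb)),
    bip = aperm(array(samples, dim = c(nb, w, nl)), c(2L, 3L, 1L)))
  out
}

#' Flatten a band stack back into a payload (inverse of reorganize_stream)
#' @param bands array `width x lines x bands`.
#' @param interleave layout of the output sample order.
#' @return numeric sample vector.
#' @export
flatten_bands <- function(bands, interleave = c("bil", "bsq", "bip")) {
  interleave <- match.arg(interleave)
  switch(interleave,
    bil = as.vector(aperm(bands, c(1L, 3L, 2L))),
    bsq = as.vector(bands),
    bip = as.vector(aperm(bands, c(3L, 1L, 2L))))
}

#' Calibrate a raw band image to reflectance
#'
#' Applies the standard two-point radiometric calibration
#' `r = (I - I_dark) / (I_ref - I_dark)` elementwise, where `I_dark` is the
#' dark-current frame and `I_ref` the white reference (whiteboard) frame.
#' Pixels where the reference equals the dark frame carry no calibration
#' information and are set to `NA`. Small negative reflectances (sensor
#' noise around the dark level) are clipped at 0 by default; values above
#' `flag_above` are counted in the `"n_flagged"` attribute.
#'
#' @param raw_img,dark_img,white_img numeric matrices of identical shape.
#' @param clip_negative clip negative reflectance at 0 (default TRUE).
#' @param flag_above reflectances above this are tallied as suspect.
#' @return reflectance matrix with attribute `n_flagged`.
#' @export
calibrate_reflectance <- function(raw_img, dark_img, white_img,
                                  clip_negative = TRUE, flag_above = 1.2) {
  if (!all(dim(raw_img) == dim(dark_img)) || !all(dim(raw_img) == dim(white_img)))
    stop("raw, dark and white images must have identical dimensions")
  denom <- white_img - dark_img
  r <- (raw_img - dark_img) / denom
  r[denom == 0] <- NA_real_
  n_flagged <- sum(r > flag_above, na.rm = TRUE)
  if (clip_negative) r[!is.na(r) & r < 0] <- 0
  attr(r, "n_flagged") <- n_flagged
  r
}

#' Band index to wavelength mapping
#'
#' The instrument samples 400--1000 nm with 250 bands on a uniform grid, so
#' band `i` (1-based) sits at `400 + (i - 1) * 600 / 249` nm (step
#' ~2.41 nm). Band labels round to the nearest nanometre.
#'
#' @param i 1-based band index (vectorized).
#' @param n_bands number of bands (default 250).
#' @param range wavelength range in nm (default `c(400, 1000)`).
#' @param rounded round to nearest nm for labelling (default FALSE).
#' @return wavelength(s) in nm.
#' @export
band_wavelength <- function(i, n_bands = HP_N_BANDS, range = HP_WL_RANGE,
                            rounded = FALSE) {
  if (any(i < 1L | i > n_bands) || any(i != as.integer(i)))
    stop(sprintf("band index out of range [1, %d]", n_bands))
  wl <- range[1] + (i - 1) * diff(range) / (n_bands - 1)
  if (rounded) round(wl) else wl
}

#' Construct a calibrated spectral cube
#'
#' @param reflectance numeric array `bands x rows x cols`.
#' @param wavelengths strictly increasing wavelength vector (nm), one per band.
#' @param stage_label growth-stage label (free text).
#' @param view_angle imaging view angle in degrees (0 or 90).
#' @param accession accession identifier.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(reflectance, wavelengths, stage_label = NA_character_,
                          view_angle = 0, accession = NA_character_) {
  stopifnot(length(dim(reflectance)) == 3L)
  if (dim(reflectance)[1] != length(wavelengths))
    stop("length(wavelengths) must equal the number of bands")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(reflectance = reflectance, wavelengths = as.numeric(wavelengths),
                 stage_label = stage_label, view_angle = view_angle,
                 accession = accession),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<spectral_cube> %d bands x %d x %d px, %.0f-%.0f nm",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(x$accession)) cat(sprintf(", accession %s", x$accession))
  if (!is.na(x$stage_label)) cat(sprintf(" (%s, view %g)", x$stage_label, x$view_angle))
  cat("\n")
  invisible(x)
}

#' Build a calibrated cube from a raw stream and calibration frames
#'
#' Convenience wrapper: reorganizes the stream, calibrates each band with
#' the matching dark/white band images, and attaches the wavelength grid.
#' If `streams` is a list of three repeated scans they are averaged sample
#' by sample before calibration, which improves the signal-to-noise ratio.
#'
#' @param streams a [raw_stream()] or a list of them (repeated scans).
#' @param dark,white calibration arrays `width x lines x bands` (per-band
#'   images), or matrices `width x lines` reused for all bands.
#' @param wavelengths wavelength vector; default the instrument grid.
#' @param ... passed to [spectral_cube()].
#' @return a `spectral_cube` (reflectance `bands x width x lines`).
#' @export
build_cube <- function(streams, dark, white, wavelengths = NULL, ...) {
  if (inherits(streams, "raw_stream")) streams <- list(streams)
  stacks <- lapply(streams, reorganize_stream)
  bands <- Reduce(`+`, stacks) / length(stacks)
  nb <- dim(bands)[3]
  if (is.null(wavelengths)) wavelengths <- band_wavelength(seq_len(nb), n_bands = nb)
  get_frame <- function(frames, b) if (length(dim(frames)) == 3L) frames[, , b] else frames
  refl <- array(NA_real_, dim = c(nb, dim(bands)[1], dim(bands)[2]))
  for (b in seq_len(nb))
    refl[b, , ] <- calibrate_reflectance(bands[, , b], get_frame(dark, b),
                                         get_frame(white, b))
  spectral_cube(refl, wavelengths, ...)
}

# --- ENVI-style container -------------------------------------------------
#
# Cubes are stored as an ENVI header/data pair: a plain-text `.hdr` with
# the dimensions, interleave, data type and full-precision wavelength list,
# next to a headerless binary file of little-endian doubles (ENVI data
# type 5) in BSQ order. Double storage keeps the round trip lossless.

#' Write a spectral cube as an ENVI header/data pair
#'
#' @param cube a `spectral_cube`.
#' @param path data-file path; the header is written at `<path>.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$reflectance)   # bands, rows, cols
  hdr <- c(
    "ENVI",
    "description = {hyperphen reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[3]),
    sprintf("bands = %d", d[1]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("stage label = %s", cube$stage_label),
    sprintf("view angle = %g", cube$view_angle),
    sprintf("accession = %s", cube$accession),
    sprintf("wavelength = {%s}",
            paste(formatC(cube$wavelengths, digits = 17, format = "g"),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major; reflectance is already bands x rows x cols, so emit
  # each band's rows-major image in sequence
  writeBin(as.vector(aperm(cube$reflectance, c(2L, 3L, 1L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[1]))
    stop("malformed ENVI header: missing ENVI magic line")
  fields <- list()
  # split on newlines that start a `key =` pair; brace values may span lines
  keyre <- "^[[:space:]]*([^=]+?)[[:space:]]*=[[:space:]]*(.*)$"
  i <- 1L
  lns <- lines[-1]
  while (i <= length(lns)) {
    ln <- lns[i]
    if (grepl(keyre, ln)) {
      key <- tolower(sub(keyre, "\\1", ln))
      val <- sub(keyre, "\\2", ln)
      while (grepl("\\{", val) && !grepl("\\}", val) && i < length(lns)) {
        i <- i + 1L
        val <- paste(val, lns[i])
      }
      fields[[key]] <- gsub("[{}]", "", val)
    }
    i <- i + 1L
  }
  fields
}

#' Read a spectral cube from an ENVI header/data pair
#'
#' @param path data-file path written by [write_cube()] (header at
#'   `<path>.hdr`).
#' @return a `spectral_cube`.
#' @export
read_cube <- function(path) {
  f <- parse_envi_header(paste0(path, ".hdr"))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("malformed ENVI header: missing ", paste(miss, collapse = ", "))
  rows <- as.integer(f$samples); cols <- as.integer(f$lines)
  nb <- as.integer(f$bands)
  if (as.integer(f[["data type"]]) != 5L)
    stop("unsupported ENVI data type (only 5 = float64 is written by this package)")
  if (tolower(trimws(f$interleave)) != "bsq")
    stop("unsupported interleave in header (expected bsq)")
  n <- as.double(rows) * cols * nb
  sz <- file.info(path)$size
  if (is.na(sz) || sz != n * 8)
    stop(sprintf("cube data size mismatch: header implies %.0f bytes, file has %.0f",
                 n * 8, sz))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  refl <- aperm(array(vals, dim = c(rows, cols, nb)), c(3L, 1L, 2L))
  wl <- as.numeric(strsplit(f$wavelength, ",")[[1]])
  if (length(wl) != nb) stop("malformed ENVI header: wavelength count != bands")
  spectral_cube(refl, wl,
                stage_label = if (is.null(f[["stage label"]])) NA_character_ else f[["stage label"]],
                view_angle = if (is.null(f[["view angle"]])) NA_real_ else as.numeric(f[["view angle"]]),
                accession = if (is.null(f$accession)) NA_character_ else f$accession)
}
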