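# Plant/background separation in calibrated cubes.
#
# Vegetation contrast is maximal across the red edge: plant pixels have a
# deep chlorophyll absorption near 670 nm and a high NIR plateau near
# 800 nm, while soil, pot and background are spectrally flat. A simple
# normalized-difference ratio of the two bands therefore separates plant
# from non-plant robustly and independently of the illumination gain.

#' Construct a plant mask
#' @param mask logical matrix, TRUE for plant pixels.
#' @return object of class `plant_mask` with fields `mask` and `s_pixels`
#'   (the projected area S in pixels).
#' @export
plant_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, s_pixels = sum(mask)), class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d px, S = %d plant pixels\n",
              nrow(x$mask), ncol(x$mask), x$s_pixels))
  invisible(x)
}

nearest_band <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

#' Segment the plant from a calibrated cube
#'
#' Computes an NDVI-like ratio `(NIR - red) / (NIR + red)` from the bands
#' nearest `nir_nm` and `red_nm`, thresholds it with Otsu's method,
#' cleans the mask with a 3x3 morphological opening and drops connected
#' components smaller than `min_size` pixels. Multiple plant blobs are
#' retained as long as each passes the size filter. Because the ratio is
#' invariant to a common illumination gain, the projected area S does not
#' depend on absolute reflectance scaling.
#'
#' @param cube a [spectral_cube()].
#' @param red_nm,nir_nm wavelengths (nm) of the red absorption and NIR
#'   plateau bands used for the ratio. Defaults 670 and 800.
#' @param min_size smallest connected component kept, in pixels.
#' @param opening_size side of the square opening kernel (default 3).
#' @param ndvi_min hard floor on the ratio: healthy vegetation sits well
#'   above 0.2, flat backgrounds near 0, so pixels below the floor are
#'   never plant regardless of the Otsu split (which would otherwise
#'   bisect a plant-free scene).
#' @return a `plant_mask`. If no plant pixels survive, a warning is issued
#'   and S = 0.
#' @export
segment_plant <- function(cube, red_nm = 670, nir_nm = 800, min_size = 50L,
                          opening_size = 3L, ndvi_min = 0.2) {
  stopifnot(inherits(cube, "spectral_cube"))
  red <- cube$reflectance[nearest_band(cube$wavelengths, red_nm), , ]
  nir <- cube$reflectance[nearest_band(cube$wavelengths, nir_nm), , ]
  denom <- nir + red
  ndvi <- (nir - red) / denom
  ndvi[!is.finite(ndvi)] <- 0
  # Otsu needs [0, 1]; NDVI lives in [-1, 1]
  scaled <- (ndvi + 1) / 2
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > th & ndvi > ndvi_min
  if (opening_size > 1L && any(mask)) {
    # opening by reconstruction: the plain opening erases noise specks but
    # also clips thin leaf tips; restoring the full connected components
    # that survive the opening keeps the plant silhouette intact
    kern <- EBImage::makeBrush(opening_size, shape = "box")
    marker <- EBImage::opening(EBImage::Image(mask * 1), kern) > 0.5
    labm <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                   nrow(ndvi), ncol(ndvi))
    survivors <- setdiff(unique(labm[as.logical(marker)]), 0L)
    mask <- matrix(labm %in% survivors, nrow(ndvi), ncol(ndvi))
  }
  if (min_size > 0L && any(mask)) {
    labm <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                   nrow(ndvi), ncol(ndvi))
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= min_size)
    mask <- matrix(labm %in% keep, nrow(ndvi), ncol(ndvi))
  }
  pm <- plant_mask(mask)
  if (pm$s_pixels == 0L) warning("no plant pixels found; returning empty mask (S = 0)")
  pm
}

#' Apply a plant mask to a cube
#'
#' Excludes non-plant pixels from all bands: masked-out pixels are set to
#' `NA` so they drop out of downstream statistics.
#'
#' @param cube a `spectral_cube`.
#' @param mask a `plant_mask` or logical matrix matching the cube's
#'   spatial dimensions.
#' @return a `spectral_cube` with background pixels set to `NA`.
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  d <- dim(cube$reflectance)
  if (!all(dim(m) == d[2:3]))
    stop("mask shape does not match cube spatial dimensions")
  refl <- cube$reflectance
  drop_idx <- which(!m)
  if (length(drop_idx)) {
    nb <- d[1]
    # pixel (r, c) of band b sits at b + (idx - 1) * nb in the flat array
    flat <- rep(drop_idx - 1L, each = nb) * nb + seq_len(nb)
    refl[flat] <- NA_real_
  }
  out <- cube
  out$reflectance <- refl
  out
}

#' Jaccard index between two masks
#' @param a,b logical matrices of identical shape.
#' @return intersection over union (1 if both empty).
#' @export
mask_jaccard <- function(a, b) {
  if (inherits(a, "plant_mask")) a <- a$mask
  if (inherits(b, "plant_mask")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
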