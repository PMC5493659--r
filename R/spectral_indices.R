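# The per-plant hyperspectral index catalog.
#
# Eight families are computed from a segmented cube:
#   T  (250)  total reflectance per band, summed over plant pixels
#   A  (250)  average reflectance per band, A_i = T_i / S
#   dT, dA    first derivatives of T and A w.r.t. wavelength (per nm)
#   ddT, ddA  second derivatives
#   CPT, CPA  20 characteristic spectral features each, from T and A
# for 6 x 250 + 2 x 20 = 1,540 named indices; the projected area S makes
# 1,541 independent variables per plant. Derivatives keep full length via
# one-sided stencils at the two spectral ends.

# --- finite differences ---------------------------------------------------

lagrange3_d1 <- function(x0, x1, x2, at) {
  # weights of f(x0), f(x1), f(x2) for f'(at)
  c((2 * at - x1 - x2) / ((x0 - x1) * (x0 - x2)),
    (2 * at - x0 - x2) / ((x1 - x0) * (x1 - x2)),
    (2 * at - x0 - x1) / ((x2 - x0) * (x2 - x1)))
}

lagrange3_d2 <- function(x0, x1, x2) {
  2 * c(1 / ((x0 - x1) * (x0 - x2)),
        1 / ((x1 - x0) * (x1 - x2)),
        1 / ((x2 - x0) * (x2 - x1)))
}

#' First and second derivative of a spectrum with respect to wavelength
#'
#' Three-point stencils: central differences at interior bands, one-sided
#' at the two ends, so the output keeps the input length. Derivatives are
#' per nanometre, which makes values comparable across spectral
#' resolutions. Exact for quadratics (first derivative) and cubics on a
#' uniform grid (second derivative, interior).
#'
#' @param values numeric spectrum, one value per band.
#' @param wavelengths strictly increasing wavelengths (nm).
#' @return list with components `d1` and `d2`, each `length(values)`.
#' @export
derivative_spectrum <- function(values, wavelengths) {
  n <- length(values)
  stopifnot(length(wavelengths) == n, n >= 3L)
  if (any(!is.finite(values))) stop("spectrum contains non-finite values")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  d1 <- d2 <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i == 1L) 1L else if (i == n) n - 2L else i - 1L
    idx <- j:(j + 2L)
    w1 <- lagrange3_d1(wavelengths[idx[1]], wavelengths[idx[2]],
                       wavelengths[idx[3]], wavelengths[i])
    w2 <- lagrange3_d2(wavelengths[idx[1]], wavelengths[idx[2]], wavelengths[idx[3]])
    d1[i] <- sum(w1 * values[idx])
    d2[i] <- sum(w2 * values[idx])
  }
  list(d1 = d1, d2 = d2)
}

# --- band statistics ------------------------------------------------------

#' Per-band total and average reflectance over the plant mask
#'
#' `T_i` is the sum of reflectance over all plant pixels at band `i`;
#' `A_i = T_i / S` where S is the projected area in pixels, so
#' `A_i * S = T_i` always.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [plant_mask()] or logical matrix.
#' @return list with `total` (T), `average` (A), both length `n_bands`,
#'   and `s_pixels`.
#' @export
band_stats <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  d <- dim(cube$reflectance)
  if (!all(dim(m) == d[2:3])) stop("mask shape does not match cube")
  s <- sum(m)
  if (s == 0L) stop("empty mask: projected area S = 0, band statistics undefined")
  flat <- matrix(cube$reflectance, nrow = d[1])   # bands x pixels
  total <- rowSums(flat[, as.vector(m), drop = FALSE], na.rm = TRUE)
  list(total = total, average = total / s, s_pixels = s)
}

# --- characteristic indices ----------------------------------------------

# Registry of the 20 characteristic features computed from one spectrum.
# Slots 1-9 are the three classical edges (blue 490-530, yellow 560-640,
# red 680-760): position of the first-derivative extremum, its amplitude,
# and the trapezoid integral of the first derivative over the window
# (the "edge area"). Slot 9 is the red-edge area. Slots 10-15 are the
# green peak (510-560), red valley (640-700), NIR plateau mean (780-1000)
# and visible mean (400-760); 16-20 are ratio / normalized-difference
# combinations. `center_nm` is the nominal wavelength at which each slot
# is tallied in wavelength-frequency summaries.
characteristic_registry <- function() {
  data.frame(
    slot = 1:20,
    name = c("blue_edge_position", "blue_edge_amplitude", "blue_edge_area",
             "yellow_edge_position", "yellow_edge_amplitude", "yellow_edge_area",
             "red_edge_position", "red_edge_amplitude", "red_edge_area",
             "green_peak_position", "green_peak_height",
             "red_valley_position", "red_valley_depth",
             "nir_plateau_mean", "visible_mean",
             "green_red_ratio", "nd_nir_red_valley",
             "red_blue_edge_area_ratio", "nd_red_yellow_edge_area",
             "nir_visible_ratio"),
    center_nm = c(510, 510, 510, 600, 600, 600, 720, 720, 720,
                  535, 535, 670, 670, 890, 580, 535, 890, 720, 720, 890),
    stringsAsFactors = FALSE)
}

window_idx <- function(wavelengths, lo, hi) {
  if (lo < min(wavelengths) || hi > max(wavelengths))
    stop(sprintf("feature window [%g, %g] nm outside wavelength range [%g, %g]",
                 lo, hi, min(wavelengths), max(wavelengths)))
  which(wavelengths >= lo & wavelengths <= hi)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

edge_features <- function(d1, wl, lo, hi, signed_max = TRUE) {
  idx <- window_idx(wl, lo, hi)
  seg <- d1[idx]
  k <- if (signed_max) which.max(seg) else which.max(abs(seg))
  list(position = wl[idx][k],
       amplitude = seg[k],
       area = trapz(wl[idx], seg))
}

#' Characteristic spectral features of one spectrum
#'
#' Computes the 20-slot characteristic feature vector (edge positions,
#' amplitudes and areas; green peak; red valley; plateau means; ratio and
#' normalized-difference combinations) from a single spectrum. Applied to
#' the total-reflectance spectrum this yields the CPT family, to the
#' average-reflectance spectrum the CPA family; the formulas are
#' identical. Slot 9 is the red-edge area: the integral of the first
#' derivative over 680--760 nm.
#'
#' @param values spectrum (T or A), one value per band.
#' @param wavelengths wavelengths (nm).
#' @return named numeric vector of length 20.
#' @export
characteristic_indices <- function(values, wavelengths) {
  d1 <- derivative_spectrum(values, wavelengths)$d1
  blue <- edge_features(d1, wavelengths, 490, 530)
  yellow <- edge_features(d1, wavelengths, 560, 640, signed_max = FALSE)
  red <- edge_features(d1, wavelengths, 680, 760)
  gp_idx <- window_idx(wavelengths, 510, 560)
  gk <- which.max(values[gp_idx])
  green_pos <- wavelengths[gp_idx][gk]; green_height <- values[gp_idx][gk]
  rv_idx <- window_idx(wavelengths, 640, 700)
  rk <- which.min(values[rv_idx])
  red_pos <- wavelengths[rv_idx][rk]; red_depth <- values[rv_idx][rk]
  nir_mean <- mean(values[window_idx(wavelengths, 780, 1000)])
  vis_mean <- mean(values[window_idx(wavelengths, 400, 760)])
  nd <- function(a, b) if (a + b == 0) NA_real_ else (a - b) / (a + b)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  out <- c(blue$position, blue$amplitude, blue$area,
           yellow$position, yellow$amplitude, yellow$area,
           red$position, red$amplitude, red$area,
           green_pos, green_height, red_pos, red_depth,
           nir_mean, vis_mean,
           ratio(green_height, red_depth),
           nd(nir_mean, red_depth),
           ratio(red$area, blue$area),
           nd(red$area, yellow$area),
           ratio(nir_mean, vis_mean))
  names(out) <- characteristic_registry()$name
  out
}

# --- catalog assembly -----------------------------------------------------

#' The index catalog layout
#'
#' One row per index: name (`T_1` ... `CPA_20`), family, band number (NA
#' for characteristic slots) and the wavelength at which the index is
#' tallied in wavelength-frequency summaries (the band wavelength, or the
#' characteristic slot's window centre).
#'
#' @param n_bands number of spectral bands (default 250).
#' @param wavelengths optional wavelength grid (default instrument grid).
#' @return data.frame with 6 * n_bands + 40 rows.
#' @export
index_catalog <- function(n_bands = HP_N_BANDS, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- band_wavelength(seq_len(n_bands), n_bands)
  reg <- characteristic_registry()
  band_fams <- c("T", "A", "dT", "dA", "ddT", "ddA")
  rows <- do.call(rbind, lapply(band_fams, function(f)
    data.frame(name = paste0(f, "_", seq_len(n_bands)), family = f,
               band = seq_len(n_bands), wavelength_nm = wavelengths,
               stringsAsFactors = FALSE)))
  cp <- do.call(rbind, lapply(c("CPT", "CPA"), function(f)
    data.frame(name = paste0(f, "_", reg$slot), family = f,
               band = NA_integer_, wavelength_nm = reg$center_nm,
               stringsAsFactors = FALSE)))
  rbind(rows, cp)
}

#' Assemble the full index vector for one plant view
#'
#' Computes all eight families from a calibrated cube and its plant mask:
#' per-band totals T and averages A, first and second derivatives dT, dA,
#' ddT, ddA, and the characteristic features CPT (from T) and CPA (from
#' A) -- 1,540 named indices. The projected area S is attached as an
#' attribute; with S the plant is described by 1,541 variables.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [plant_mask()]; segmented with [segment_plant()] if
#'   missing.
#' @return object of class `index_vector`: a named numeric vector of
#'   length 1,540 with attributes `s_pixels`, `stage_label`, `accession`,
#'   `view_angle`.
#' @export
assemble_index_vector <- function(cube, mask = NULL) {
  if (is.null(mask)) mask <- segment_plant(cube)
  bs <- band_stats(cube, mask)
  wl <- cube$wavelengths
  n_bands <- length(wl)
  dT <- derivative_spectrum(bs$total, wl)
  dA <- derivative_spectrum(bs$average, wl)
  fams <- list(T = bs$total, A = bs$average,
               dT = dT$d1, dA = dA$d1, ddT = dT$d2, ddA = dA$d2)
  expected_band <- rep(n_bands, 6)
  if (!all(vapply(fams, length, 1L) == expected_band))
    stop("index assembly error: a band family has the wrong length")
  cpt <- characteristic_indices(bs$total, wl)
  cpa <- characteristic_indices(bs$average, wl)
  if (length(cpt) != 20L || length(cpa) != 20L)
    stop("index assembly error: characteristic family has the wrong length")
  vals <- c(unlist(fams, use.names = FALSE), cpt, cpa)
  names(vals) <- index_catalog(n_bands, wl)$name
  structure(vals, s_pixels = bs$s_pixels, stage_label = cube$stage_label,
            accession = cube$accession, view_angle = cube$view_angle,
            class = "index_vector")
}

#' @export
print.index_vector <- function(x, ...) {
  cat(sprintf("<index_vector> %d indices + S = %d px", length(x),
              attr(x, "s_pixels")))
  if (!is.na(attr(x, "accession"))) cat(", accession", attr(x, "accession"))
  cat("\n")
  invisible(x)
}

#' Average the index vectors of the two imaging views
#'
#' Plants are imaged from two angles (0 and 90 degrees); the per-plant
#' index vector is the arithmetic mean of the two views' vectors and S the
#' mean of the two projected areas.
#'
#' @param vectors list of `index_vector`s of one plant.
#' @return a combined `index_vector` (view_angle `NA`).
#' @export
combine_views <- function(vectors) {
  stopifnot(length(vectors) >= 1L,
            all(vapply(vectors, inherits, TRUE, "index_vector")))
  vals <- Reduce(`+`, lapply(vectors, as.numeric)) / length(vectors)
  names(vals) <- names(vectors[[1]])
  structure(vals,
            s_pixels = mean(vapply(vectors, attr, 1, "s_pixels")),
            stage_label = attr(vectors[[1]], "stage_label"),
            accession = attr(vectors[[1]], "accession"),
            view_angle = NA_real_,
            class = "index_vector")
}

#' One-row data frame of an index vector (wide CSV layout)
#' @param x an `index_vector`.
#' @param ... unused.
#' @return data.frame with metadata columns, S, and 1,540 index columns.
#' @export
as.data.frame.index_vector <- function(x, ...) {
  out <- data.frame(accession = attr(x, "accession"),
                    stage_label = attr(x, "stage_label"),
                    view_angle = attr(x, "view_angle"),
                    S = attr(x, "s_pixels"), stringsAsFactors = FALSE)
  vals <- as.list(as.numeric(x))
  names(vals) <- names(x)
  cbind(out, as.data.frame(vals, check.names = FALSE))
}
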