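# Synthetic inputs with stored ground truth.
#
# The cube generator emulates what the imaging pipeline assumes about
# vegetation: a plant-shaped mask on a dark background, spectra with a
# green reflectance peak near 550 nm, a chlorophyll absorption trough
# near 680 nm, a steep red edge between 680 and 760 nm whose inflection
# shifts with chlorophyll, and a NIR plateau scaled by biomass. The
# population generator draws biallelic SNP panels (optionally with AR(1)
# linkage disequilibrium along each chromosome) and bivariate phenotypes
# with specified heritabilities and genetic correlation under the
# additive model the REML machinery assumes.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Image parameters
#' control the spectral shape and the sensor model; genetics parameters
#' control the SNP panel and the phenotype architecture.
#'
#' @param seed default RNG seed for the generators.
#' @param dims image dimensions `(spatial_width, n_bands, n_lines)`.
#' @param noise_sd additive reflectance noise SD per pixel and band.
#' @param pixel_gain_sd SD of the per-pixel multiplicative gain (leaf
#'   angle / self-shading variation).
#' @param green_peak_height green-peak amplitude above the visible base.
#' @param absorption_depth_range 680-nm absorption depth at latent
#'   chlorophyll 0 and 1.
#' @param red_edge_inflection_range red-edge inflection (nm) at latent
#'   chlorophyll 0 and 1.
#' @param nir_base,nir_biomass_gain NIR plateau height at latent biomass
#'   0, and its gain with biomass.
#' @param background_refl flat background reflectance.
#' @param dark_level,white_gain sensor dark level and white dynamic range
#'   in counts.
#' @param n_accessions,n_snps,n_chromosomes panel dimensions.
#' @param maf_range minor-allele-frequency range for simulated SNPs.
#' @param ld_rho AR(1) correlation of adjacent SNPs' latent haplotype
#'   field (0 = linkage equilibrium).
#' @param n_qtl,qtl_frac number of planted QTLs and the fraction of
#'   genetic variance they carry.
#' @param h2 length-2 vector of trait heritabilities.
#' @param r_g genetic correlation between the two traits.
#' @param r_e residual correlation between the two traits.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       dims = c(80L, 250L, 80L),
                       noise_sd = 0.01,
                       pixel_gain_sd = 0.03,
                       green_peak_height = 0.08,
                       absorption_depth_range = c(0.02, 0.08),
                       red_edge_inflection_range = c(700, 720),
                       nir_base = 0.35,
                       nir_biomass_gain = 0.3,
                       background_refl = 0.05,
                       dark_level = 500,
                       white_gain = 40000,
                       n_accessions = 200L,
                       n_snps = 2000L,
                       n_chromosomes = 2L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0,
                       n_qtl = 0L,
                       qtl_frac = 0.2,
                       h2 = c(0.5, 0.5),
                       r_g = 0.6,
                       r_e = 0) {
  stopifnot(length(dims) == 3L, all(dims > 0),
            noise_sd >= 0, pixel_gain_sd >= 0,
            all(h2 >= 0), all(h2 <= 1), length(h2) == 2L,
            abs(r_g) <= 1, abs(r_e) <= 1,
            ld_rho >= 0, ld_rho < 1,
            n_qtl <= n_snps, qtl_frac >= 0, qtl_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

gauss <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))

#' Parametric vegetation reflectance spectrum
#'
#' Sum of a logistic red edge / NIR plateau, a Gaussian green peak and a
#' Gaussian chlorophyll absorption at 680 nm, over a small visible base.
#' Higher latent chlorophyll deepens the absorption and shifts the
#' red-edge inflection to longer wavelengths; higher latent biomass
#' raises the NIR plateau.
#'
#' @param wavelengths wavelengths (nm).
#' @param chl,biomass latent variables in `[0, 1]`.
#' @param config a [sim_config()].
#' @return reflectance spectrum (values floored at 0.005).
#' @export
plant_spectrum <- function(wavelengths, chl, biomass, config = sim_config()) {
  infl <- config$red_edge_inflection_range[1] +
    diff(config$red_edge_inflection_range) * chl
  depth <- config$absorption_depth_range[1] +
    diff(config$absorption_depth_range) * chl
  nir <- config$nir_base + config$nir_biomass_gain * biomass
  r <- 0.08 +
    config$green_peak_height * gauss(wavelengths, 550, 25) +
    nir * stats::plogis((wavelengths - infl) / 10) -
    depth * gauss(wavelengths, 680, 18)
  pmax(r, 0.005)
}

draw_plant_mask <- function(width, lines, n_leaves = 8L) {
  # rosette of tapering elliptical strokes around the image centre
  if (width < 32L || lines < 32L)
    stop("image dimensions too small for the plant shape (need >= 32 px)")
  mask <- matrix(FALSE, width, lines)
  cx <- width / 2; cy <- lines / 2
  len <- 0.42 * min(width, lines)
  for (k in seq_len(n_leaves)) {
    theta <- 2 * pi * (k - 1) / n_leaves + runif(1, -0.2, 0.2)
    llen <- len * runif(1, 0.7, 1)
    for (t in seq(0.05, 1, length.out = 80)) {
      px <- cx + t * llen * cos(theta)
      py <- cy + t * llen * sin(theta)
      wd <- max(2.5, 5 * (1 - 0.6 * t))
      xs <- max(1, floor(px - wd)):min(width, ceiling(px + wd))
      ys <- max(1, floor(py - wd)):min(lines, ceiling(py + wd))
      for (xx in xs) for (yy in ys)
        if ((xx - px)^2 + (yy - py)^2 <= wd^2) mask[xx, yy] <- TRUE
    }
  }
  mask
}

#' Simulate a raw hyperspectral acquisition with ground truth
#'
#' Draws a plant mask, builds per-pixel plant spectra (the parametric
#' spectrum times a per-pixel gain, plus additive noise), adds a flat
#' background and a spectrally flat "pot" region, and inverts the
#' two-point calibration to emit an integer raw stream plus consistent
#' dark and white frames. Calibrating the emitted stream therefore
#' recovers the simulated reflectance up to sensor quantization.
#'
#' @param config a [sim_config()].
#' @param chl,biomass latent chlorophyll and biomass in `[0, 1]`.
#' @param seed RNG seed (default `config$seed`).
#' @return list: `stream` (a [raw_stream()]), `dark`, `white`
#'   (calibration arrays `width x lines x bands`), `wavelengths`, and
#'   `truth` (`mask`, `spectrum`, `reflectance` array, `chl`, `biomass`).
#' @export
simulate_cube <- function(config = sim_config(), chl = 0.5, biomass = 0.5,
                          seed = config$seed) {
  width <- config$dims[1]; nb <- config$dims[2]; lines <- config$dims[3]
  wl <- band_wavelength(seq_len(nb), n_bands = nb)
  with_seed(seed, {
    mask <- draw_plant_mask(width, lines)
    spec <- plant_spectrum(wl, chl, biomass, config)
    refl <- array(config$background_refl, dim = c(nb, width, lines))
    # spectrally flat pot below the plant: excluded by the red-edge ratio
    pot_rows <- max(1, round(width * 0.4)):min(width, round(width * 0.6))
    pot_cols <- max(1, lines - round(lines * 0.12)):lines
    refl[, pot_rows, pot_cols] <- 0.15
    plant_idx <- which(mask)
    n_plant <- length(plant_idx)
    gain <- 1 + rnorm(n_plant, 0, config$pixel_gain_sd)
    px_spec <- outer(spec, gain)                       # bands x plant pixels
    if (config$noise_sd > 0)
      px_spec <- px_spec + rnorm(length(px_spec), 0, config$noise_sd)
    px_spec <- pmax(px_spec, 0)
    flat <- matrix(refl, nrow = nb)
    flat[, plant_idx] <- px_spec
    refl <- array(flat, dim = c(nb, width, lines))
    # sensor model: dark level with a mild spatial pattern, halogen-shaped
    # lamp spectrum with a quadratic vignette across the scan line
    lamp <- 0.5 + 0.5 * gauss(wl, 800, 220)
    vignette <- 1 - 0.1 * ((seq_len(width) - width / 2) / width)^2
    dark <- array(config$dark_level, dim = c(width, lines, nb))
    white <- dark + config$white_gain *
      rep(outer(vignette, rep(1, lines)), nb) *
      rep(lamp, each = width * lines)
    raw <- dark + aperm(refl, c(2L, 3L, 1L)) * (white - dark)
    raw <- round(pmin(pmax(raw, 0), 65535))
    stream <- raw_stream(flatten_bands(raw, "bil"),
                         dims = c(width, nb, lines), interleave = "bil")
    list(stream = stream, dark = dark, white = white, wavelengths = wl,
         truth = list(mask = mask, spectrum = spec, reflectance = refl,
                      chl = chl, biomass = biomass),
         config = config)
  })
}

#' Polygenic values from standardized dosages
#'
#' `u = Z w / sqrt(m)` with `Z` the column-standardized dosage matrix:
#' the additive genetic value implied by per-SNP weights `w`. Accessions
#' with identical genotypes receive identical values by construction.
#'
#' @param geno a [genotype_matrix()].
#' @param weights SNPs x traits weight matrix (or vector).
#' @return accessions x traits matrix of genetic values.
#' @export
polygenic_values <- function(geno, weights) {
  weights <- as.matrix(weights)
  Z <- scale(geno$dosage)
  Z[, apply(geno$dosage, 2, sd) == 0] <- 0
  (Z %*% weights) / sqrt(nrow(weights))
}

std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0

#' Simulate a genotype panel with bivariate phenotypes
#'
#' Draws a biallelic SNP panel (uniform MAF; optional AR(1) LD along each
#' chromosome via a latent Gaussian haplotype field) and two phenotypes
#' built from a shared genetic architecture: an optional set of planted
#' QTLs carrying `qtl_frac` of the genetic variance plus a polygenic
#' term over all SNPs, with per-trait weights correlated at `r_g`. The
#' genetic and residual components are standardized empirically and the
#' residual is orthogonalized against the genetic values, so the
#' realized variance fractions match the requested `h2` closely.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return list: `geno` (a [genotype_matrix()]), `traits` (data.frame
#'   `accession, y1, y2`), `truth` (`h2`, `r_g`, `genetic_values`
#'   (n x 2, on the phenotype scale), `weights`, `qtl` data.frame).
#' @export
simulate_population <- function(config = sim_config(), seed = config$seed) {
  n <- config$n_accessions; m <- config$n_snps
  nchr <- config$n_chromosomes
  with_seed(seed, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    per_chr <- rep(m %/% nchr, nchr)
    per_chr[seq_len(m %% nchr)] <- per_chr[seq_len(m %% nchr)] + 1L
    chrom <- rep(paste0("chr", seq_len(nchr)), per_chr)
    pos <- unlist(lapply(per_chr, function(k) sort(sample.int(3e7, k))))
    dosage <- matrix(0L, n, m)
    if (config$ld_rho > 0) {
      for (hap in 1:2) {
        off <- 0L
        for (k in per_chr) {
          z <- matrix(rnorm(n * k), n, k)
          for (j in 2:k)
            z[, j] <- config$ld_rho * z[, j - 1] +
              sqrt(1 - config$ld_rho^2) * z[, j]
          thr <- qnorm(maf[(off + 1):(off + k)])
          dosage[, (off + 1):(off + k)] <-
            dosage[, (off + 1):(off + k)] + (z < rep(thr, each = n))
          off <- off + k
        }
      }
    } else {
      dosage[] <- rbinom(n * m, 2L, rep(maf, each = n))
    }
    map <- data.frame(snp = sprintf("snp_%s_%09d", chrom, pos),
                      chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    rownames(dosage) <- sprintf("acc%04d", seq_len(n))
    geno <- genotype_matrix(dosage, map, orient_minor = TRUE)
    m_eff <- ncol(geno$dosage)
    # per-SNP weights correlated at r_g across the two traits
    a <- rnorm(m_eff); b <- rnorm(m_eff)
    w <- cbind(a, config$r_g * a + sqrt(1 - config$r_g^2) * b)
    qtl <- data.frame(snp = character(0), beta1 = numeric(0), beta2 = numeric(0))
    u <- polygenic_values(geno, w)
    if (config$n_qtl > 0L && config$qtl_frac > 0) {
      qtl_idx <- sort(sample.int(m_eff, config$n_qtl))
      aq <- rnorm(config$n_qtl); bq <- rnorm(config$n_qtl)
      wq <- cbind(aq, config$r_g * aq + sqrt(1 - config$r_g^2) * bq)
      Zq <- scale(geno$dosage[, qtl_idx, drop = FALSE])
      uq <- (Zq %*% wq) / sqrt(config$n_qtl)
      u <- sqrt(1 - config$qtl_frac) * apply(u, 2, std) +
        sqrt(config$qtl_frac) * apply(uq, 2, std)
      qtl <- data.frame(snp = geno$map$snp[qtl_idx],
                        beta1 = wq[, 1], beta2 = wq[, 2],
                        stringsAsFactors = FALSE)
    }
    g <- apply(u, 2, std)
    e0 <- rnorm(n); e1 <- config$r_e * e0 + sqrt(1 - config$r_e^2) * rnorm(n)
    E <- cbind(e0, e1)
    # orthogonalize residuals against both genetic values, then restandardize
    E <- apply(E, 2, function(v) std(lm.fit(cbind(1, g), v)$residuals))
    gv <- sweep(g, 2, sqrt(config$h2), `*`)
    y <- gv + sweep(E, 2, sqrt(1 - config$h2), `*`)
    traits <- data.frame(accession = rownames(geno$dosage),
                         y1 = y[, 1], y2 = y[, 2], stringsAsFactors = FALSE)
    list(geno = geno, traits = traits,
         truth = list(h2 = config$h2, r_g = config$r_g,
                      genetic_values = gv, weights = w, qtl = qtl))
  })
}
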