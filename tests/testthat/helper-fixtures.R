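# Shared fixtures: tiny cubes and panels built in code at test time.

# small calibrated cube with a known rectangular "plant" patch
tiny_cube <- function(n_bands = 5L, rows = 6L, cols = 4L, value = 0.5,
                      wavelengths = NULL) {
  if (is.null(wavelengths))
    wavelengths <- seq(400, 1000, length.out = n_bands)
  spectral_cube(array(value, dim = c(n_bands, rows, cols)), wavelengths)
}

rect_mask <- function(rows, cols, r = 1:2, c = 1:2) {
  m <- matrix(FALSE, rows, cols)
  m[r, c] <- TRUE
  m
}

# independent brute-force BIL decoder: triple loop over (line, band, pixel)
bil_oracle <- function(payload, width, n_bands, n_lines) {
  out <- array(NA_real_, dim = c(width, n_lines, n_bands))
  k <- 1L
  for (l in seq_len(n_lines))
    for (b in seq_len(n_bands))
      for (p in seq_len(width)) {
        out[p, l, b] <- payload[k]
        k <- k + 1L
      }
  out
}

# independent per-pixel accumulation of band totals
band_total_oracle <- function(cube, mask) {
  d <- dim(cube$reflectance)
  tot <- numeric(d[1])
  for (b in seq_len(d[1]))
    for (r in seq_len(d[2]))
      for (cc in seq_len(d[3]))
        if (mask[r, cc]) tot[b] <- tot[b] + cube$reflectance[b, r, cc]
  tot
}

# small random genotype panel (no classes, plain matrices) for oracles
random_panel <- function(n, m, seed, maf_lo = 0.05, maf_hi = 0.5) {
  set.seed(seed)
  maf <- runif(m, maf_lo, maf_hi)
  dos <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  map <- data.frame(snp = paste0("s", seq_len(m)),
                    chrom = rep("chr1", m),
                    pos = sort(sample.int(5e7, m)),
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

# greedy clumping re-derived from scratch (explicit loops, its own r2)
clump_oracle <- function(assoc, dosage, suggestive, r2_max = 0.25,
                         support_p = 1e-4, min_support = 5L) {
  r2_pair <- function(a, b) {
    va <- dosage[, a]; vb <- dosage[, b]
    cv <- sum((va - mean(va)) * (vb - mean(vb)))
    den <- sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
    if (den == 0) return(0)
    (cv / den)^2
  }
  cand <- assoc[assoc$p < suggestive, , drop = FALSE]
  leads <- character(0)
  removed <- character(0)
  repeat {
    pool <- cand[!(cand$snp %in% c(leads, removed)), , drop = FALSE]
    if (!nrow(pool)) break
    pool <- pool[order(pool$p, pool$chrom, pool$pos), , drop = FALSE]
    top <- pool$snp[1]
    leads <- c(leads, top)
    for (s in pool$snp[-1])
      if (r2_pair(top, s) > r2_max) removed <- c(removed, s)
  }
  keep <- vapply(leads, function(s) {
    others <- assoc$snp[assoc$p < support_p & assoc$snp != s]
    sum(vapply(others, function(o) r2_pair(s, o) > r2_max, TRUE)) >= min_support
  }, TRUE)
  sort(leads[keep])
}

# single-linkage locus merge via union-find (quadratic, independent of
# the sorted-gap logic in define_loci)
loci_oracle <- function(chrom, pos, gap_bp = 3e5) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (i != j && chrom[i] == chrom[j] && abs(pos[i] - pos[j]) < gap_bp) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) { parent[ri] <- rj; changed <- TRUE }
        }
  }
  vapply(seq_len(n), find, 1L)
}
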