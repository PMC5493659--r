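# Quantitative-genetic analyses on top of the index catalog:
# SNP filtering, genomic relationship matrix, bivariate REML for
# heritability and genetic correlation, hyper-trait selection, a per-SNP
# association scan, and GWAS post-processing (thresholds, LD clumping,
# locus merging, candidate windows, haplotype contrasts).

#' Construct a genotype matrix
#'
#' @param dosage accessions x SNPs matrix of minor-allele dosages in
#'   {0, 1, 2} (missing allowed as NA). Column names are SNP ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   one row per SNP in column order.
#' @param orient_minor flip columns whose allele frequency exceeds 0.5 so
#'   that dosage counts the minor allele (default TRUE).
#' @return object of class `genotype_matrix` with fields `dosage`, `map`,
#'   `maf`.
#' @export
genotype_matrix <- function(dosage, map, orient_minor = TRUE) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(map),
            all(c("snp", "chrom", "pos") %in% names(map)))
  colnames(dosage) <- map$snp
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  p <- colMeans(dosage, na.rm = TRUE) / 2
  if (orient_minor) {
    flip <- which(p > 0.5)
    if (length(flip)) {
      dosage[, flip] <- 2 - dosage[, flip]
      p[flip] <- 1 - p[flip]
    }
  }
  ord <- order(map$chrom, map$pos)
  structure(list(dosage = dosage[, ord, drop = FALSE],
                 map = map[ord, , drop = FALSE],
                 maf = pmin(p, 1 - p)[ord]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Dosages are taken from the GT field (count of ALT alleles, then
#' oriented to the minor allele); multi-allelic records are dropped.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[g %in% c("1/1", "1|1")] <- 2
    out
  }
  dos <- t(apply(gt[biallelic, , drop = FALSE], 1, count_alt))
  dos <- t(dos)  # accessions x SNPs
  ids <- fix$ID[biallelic]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[biallelic][noid], "_", fix$POS[biallelic][noid])
  map <- data.frame(snp = ids, chrom = fix$CHROM[biallelic],
                    pos = as.integer(fix$POS[biallelic]), stringsAsFactors = FALSE)
  colnames(dos) <- ids
  rownames(dos) <- colnames(gt)
  genotype_matrix(dos, map)
}

#' Filter SNPs on minor allele frequency and carrier count
#'
#' Keeps SNPs with minor allele frequency at least `maf_min` and with at
#' least `mac_min` accessions carrying the minor allele.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param mac_min minimum number of accessions carrying the minor allele
#'   (default 6).
#' @return filtered `genotype_matrix`.
#' @export
filter_snps <- function(geno, maf_min = 0.05, mac_min = 6L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  carriers <- colSums(geno$dosage > 0, na.rm = TRUE)
  keep <- geno$maf >= maf_min & carriers >= mac_min
  if (!any(keep)) warning("no SNPs pass the MAF/carrier filter")
  structure(list(dosage = geno$dosage[, keep, drop = FALSE],
                 map = geno$map[keep, , drop = FALSE],
                 maf = geno$maf[keep]),
            class = "genotype_matrix")
}

#' Genomic relationship matrix
#'
#' Standardizes each SNP's dosage column (mean 0, variance 1) and forms
#' `Z Z' / m` over the `m` polymorphic SNPs: the standard marker-based
#' relationship matrix whose diagonal averages about 1. Monomorphic SNPs
#' carry no information and are excluded.
#'
#' @param geno a [genotype_matrix()] (ideally after [filter_snps()]).
#' @return symmetric positive semi-definite accessions x accessions matrix.
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosage
  sds <- apply(dos, 2, sd)
  poly <- which(!is.na(sds) & sds > 0)
  if (!length(poly)) stop("no polymorphic SNPs")
  Z <- scale(dos[, poly, drop = FALSE])
  tcrossprod(Z) / length(poly)
}

#' Eigendecomposition of a GRM, cached for repeated REML fits
#' @param grm relationship matrix.
#' @return object of class `grm_eigen` (`values`, `vectors`).
#' @export
grm_eigen <- function(grm) {
  if (inherits(grm, "grm_eigen")) return(grm)
  e <- eigen(grm, symmetric = TRUE)
  structure(list(values = pmax(e$values, 0), vectors = e$vectors),
            class = "grm_eigen")
}

chol_from_par <- function(p) {
  L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
  tcrossprod(L)
}

#' Bivariate REML: heritabilities and genetic correlation
#'
#' Fits the two-trait variance-component model `y_t = mu_t + u_t + e_t`
#' with `Var(u) = G (x) K` structured by the genomic relationship matrix
#' `K` and diagonal residuals `Var(e) = E (x) I`, and maximizes the
#' restricted likelihood over the 2x2 genetic and residual covariance
#' matrices. The GRM is eigendecomposed once, both traits are rotated
#' into its eigenbasis where observations decouple into independent 2x2
#' blocks, and the exact restricted likelihood is maximized by
#' quasi-Newton iteration on a log-Cholesky parameterization (which keeps
#' both covariance matrices positive definite throughout). Traits are
#' standardized internally. Heritability is the genetic variance as a
#' proportion of total variance; the genetic correlation `r_g` is read
#' off the genetic covariance matrix and clipped to [-1, 1] (estimates
#' within 0.001 of the boundary are reported as exactly +/-1 with
#' `boundary = TRUE`).
#'
#' @param y1,y2 numeric trait vectors (one value per accession).
#' @param grm relationship matrix or a cached [grm_eigen()].
#' @param max_iter maximum optimizer iterations (default 200).
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood (default 1e-8).
#' @return object of class `bivariate_estimate`: `h2_1`, `h2_2`, `r_g`,
#'   standard errors (`se_h2_1`, `se_h2_2`, `se_r_g`), `converged`,
#'   `boundary`, `loglik`, and the variance-component matrices `G`, `E`.
#' @export
reml_bivariate <- function(y1, y2, grm, max_iter = 200L, tol = 1e-8) {
  y1 <- as.numeric(scale(y1)); y2 <- as.numeric(scale(y2))
  n <- length(y1)
  stopifnot(length(y2) == n)
  if (anyNA(y1) || anyNA(y2)) stop("traits must be complete (no NA)")
  eg <- grm_eigen(grm)
  stopifnot(nrow(eg$vectors) == n)
  d <- eg$values
  z1 <- drop(crossprod(eg$vectors, y1))
  z2 <- drop(crossprod(eg$vectors, y2))
  x <- drop(crossprod(eg$vectors, rep(1, n)))
  x2 <- x * x
  negll <- function(par) {
    G <- chol_from_par(par[1:3]); E <- chol_from_par(par[4:6])
    a <- d * G[1, 1] + E[1, 1]
    b <- d * G[1, 2] + E[1, 2]
    cc <- d * G[2, 2] + E[2, 2]
    det_i <- a * cc - b * b
    if (any(det_i <= 1e-300)) return(1e10)
    i11 <- cc / det_i; i22 <- a / det_i; i12 <- -b / det_i
    M11 <- sum(x2 * i11); M12 <- sum(x2 * i12); M22 <- sum(x2 * i22)
    detM <- M11 * M22 - M12 * M12
    if (detM <= 1e-300) return(1e10)
    v1 <- sum(x * (i11 * z1 + i12 * z2))
    v2 <- sum(x * (i12 * z1 + i22 * z2))
    b1 <- (M22 * v1 - M12 * v2) / detM
    b2 <- (M11 * v2 - M12 * v1) / detM
    r1 <- z1 - x * b1; r2 <- z2 - x * b2
    quad <- sum(r1 * (i11 * r1 + i12 * r2) + r2 * (i12 * r1 + i22 * r2))
    0.5 * (sum(log(det_i)) + log(detM) + quad)
  }
  S <- cov(cbind(y1, y2))
  start_from <- function(M) {
    L <- t(chol(M + diag(1e-6, 2)))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  par0 <- c(start_from(S / 2), start_from(S / 2))
  lb <- rep(c(log(1e-4), -20, log(1e-4)), 2)
  ub <- rep(c(log(20), 20, log(20)), 2)
  opt <- optim(par0, negll, method = "L-BFGS-B", lower = lb, upper = ub,
               control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  G <- chol_from_par(opt$par[1:3]); E <- chol_from_par(opt$par[4:6])
  clip <- function(v) pmax(v, 1e-8)
  h2 <- c(G[1, 1] / (G[1, 1] + E[1, 1]), G[2, 2] / (G[2, 2] + E[2, 2]))
  h2 <- pmin(pmax(h2, 0), 1)
  rg <- G[1, 2] / sqrt(clip(G[1, 1]) * clip(G[2, 2]))
  boundary <- abs(rg) > 1 - 1e-3
  rg <- if (boundary) sign(rg) else max(-1, min(1, rg))
  ses <- rep(NA_real_, 3)
  if (!boundary && opt$convergence == 0) {
    est_fun <- function(par) {
      Gp <- chol_from_par(par[1:3]); Ep <- chol_from_par(par[4:6])
      c(Gp[1, 1] / (Gp[1, 1] + Ep[1, 1]), Gp[2, 2] / (Gp[2, 2] + Ep[2, 2]),
        Gp[1, 2] / sqrt(clip(Gp[1, 1]) * clip(Gp[2, 2])))
    }
    hess <- try(optimHess(opt$par, negll), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      cov_par <- try(solve(hess), silent = TRUE)
      if (!inherits(cov_par, "try-error")) {
        eps <- 1e-5
        J <- sapply(seq_along(opt$par), function(j) {
          pp <- opt$par; pp[j] <- pp[j] + eps
          pm <- opt$par; pm[j] <- pm[j] - eps
          (est_fun(pp) - est_fun(pm)) / (2 * eps)
        })
        vv <- diag(J %*% cov_par %*% t(J))
        ses <- sqrt(pmax(vv, 0))
      }
    }
  }
  structure(list(h2_1 = h2[1], h2_2 = h2[2], r_g = rg,
                 se_h2_1 = ses[1], se_h2_2 = ses[2], se_r_g = ses[3],
                 converged = opt$convergence == 0, boundary = boundary,
                 loglik = -opt$value, G = G, E = E, n = n),
            class = "bivariate_estimate")
}

#' @export
print.bivariate_estimate <- function(x, ...) {
  cat(sprintf("<bivariate_estimate> h2 = %.3f / %.3f, r_g = %.3f%s (n = %d%s)\n",
              x$h2_1, x$h2_2, x$r_g, if (x$boundary) " [boundary]" else "",
              x$n, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Univariate REML heritability
#'
#' Single-trait restriction of [reml_bivariate()]: one genetic and one
#' residual variance component on the GRM eigenbasis.
#'
#' @inheritParams reml_bivariate
#' @param y trait vector.
#' @return list with `h2`, `converged`, `loglik`.
#' @export
reml_univariate <- function(y, grm, max_iter = 200L) {
  y <- as.numeric(scale(y))
  eg <- grm_eigen(grm)
  d <- eg$values
  z <- drop(crossprod(eg$vectors, y))
  x <- drop(crossprod(eg$vectors, rep(1, length(y))))
  x2 <- x * x
  negll <- function(par) {
    vg <- exp(par[1]); ve <- exp(par[2])
    s <- d * vg + ve
    M <- sum(x2 / s)
    bhat <- sum(x * z / s) / M
    r <- z - x * bhat
    0.5 * (sum(log(s)) + log(M) + sum(r * r / s))
  }
  opt <- optim(c(log(0.5), log(0.5)), negll, method = "L-BFGS-B",
               lower = log(1e-6), upper = log(20),
               control = list(maxit = max_iter))
  vg <- exp(opt$par[1]); ve <- exp(opt$par[2])
  list(h2 = vg / (vg + ve), converged = opt$convergence == 0, loglik = -opt$value)
}

#' Select hyper-traits
#'
#' An index qualifies as a hyper-trait when it is phenotypically and
#' genetically tied to an agronomic trait and highly heritable:
#' `|r_p| >= 0.5`, `|r_g| >= 0.5` and `h2 >= 0.5`. Correlations enter in
#' absolute value, so strongly negatively correlated indices qualify too.
#'
#' @param stats data.frame with columns `index`, `r_p`, `r_g`, `h2`.
#' @param r_p_min,r_g_min,h2_min selection thresholds (all default 0.5).
#' @return the input with a logical `pass` column; rows with missing
#'   estimates are flagged `NA` and a warning is issued.
#' @export
select_hyper_traits <- function(stats, r_p_min = 0.5, r_g_min = 0.5,
                                h2_min = 0.5) {
  stopifnot(all(c("r_p", "r_g", "h2") %in% names(stats)))
  miss <- !complete.cases(stats[, c("r_p", "r_g", "h2")])
  if (any(miss))
    warning(sum(miss), " index(es) skipped: missing estimates")
  stats$pass <- abs(stats$r_p) >= r_p_min & abs(stats$r_g) >= r_g_min &
    stats$h2 >= h2_min
  stats$pass[miss] <- NA
  stats
}

#' Hyper-trait scan over an index table
#'
#' For every index column: Pearson correlation `r_p` with the agronomic
#' trait, and `h2` / `r_g` from a bivariate REML of the index against the
#' trait on the GRM. The result feeds [select_hyper_traits()].
#'
#' @param index_table matrix/data.frame, rows = accessions.
#' @param trait agronomic trait vector.
#' @param grm relationship matrix or [grm_eigen()].
#' @param ... thresholds passed to [select_hyper_traits()].
#' @return data.frame `index, r_p, r_g, h2, pass`.
#' @export
hyper_trait_scan <- function(index_table, trait, grm, ...) {
  X <- as_feature_matrix(index_table)
  eg <- grm_eigen(grm)
  rows <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    if (sd(v) == 0) return(data.frame(index = nm, r_p = NA_real_,
                                      r_g = NA_real_, h2 = NA_real_))
    est <- reml_bivariate(v, trait, eg)
    data.frame(index = nm, r_p = cor(v, trait), r_g = est$r_g, h2 = est$h2_1,
               stringsAsFactors = FALSE)
  })
  select_hyper_traits(do.call(rbind, rows), ...)
}

#' Per-SNP linear association scan
#'
#' Simple single-marker regression of the phenotype on each SNP's dosage;
#' the slope t-test gives the P-value. This is deliberately plain plumbing
#' so the post-processing chain can run end-to-end; it does not correct
#' for population structure or kinship the way a mixed-model scan would.
#'
#' @param geno a [genotype_matrix()] (filtered).
#' @param phenotype numeric vector, one value per accession.
#' @param trait_id label stored in the output (default "trait").
#' @return data.frame `snp, chrom, pos, p, trait` (monomorphic SNPs are
#'   absent).
#' @export
association_scan <- function(geno, phenotype, trait_id = "trait") {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(nrow(geno$dosage) == n)
  if (sd(y) == 0) stop("phenotype has zero variance")
  sds <- apply(geno$dosage, 2, sd)
  keep <- which(!is.na(sds) & sds > 0)
  r <- suppressWarnings(drop(cor(geno$dosage[, keep, drop = FALSE], y,
                                 use = "pairwise.complete.obs")))
  r2 <- pmin(r * r, 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(snp = geno$map$snp[keep], chrom = geno$map$chrom[keep],
             pos = geno$map$pos[keep], p = p, trait = trait_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-wide P-value thresholds from the effective SNP number
#'
#' Multiple-testing thresholds based on the effective number of
#' independent SNPs `N` (estimated externally): suggestive `1/N` and
#' significant `0.05/N`, so the significant threshold is always exactly
#' 0.05 times the suggestive one.
#'
#' @param n_effective effective number of independent SNPs (> 0).
#' @return named numeric vector `c(suggestive, significant)`.
#' @export
thresholds_from_N <- function(n_effective) {
  if (!is.numeric(n_effective) || length(n_effective) != 1L || n_effective <= 0)
    stop("the effective SNP number must be a single positive value")
  c(suggestive = 1 / n_effective, significant = 0.05 / n_effective)
}

ld_r2_with <- function(dosage, lead_col, other_cols) {
  # composite r^2 on dosages: squared Pearson correlation
  drop(suppressWarnings(cor(dosage[, lead_col], dosage[, other_cols, drop = FALSE],
                            use = "pairwise.complete.obs")))^2
}

#' LD clumping of association results into lead SNPs
#'
#' Greedy clumping by ascending P-value among SNPs below the suggestive
#' threshold: the best remaining SNP becomes a lead and every remaining
#' candidate in LD with it (`r^2 > r2_max`) is removed. Afterwards, leads
#' supported by fewer than `min_support` SNPs at `P < support_p` in LD
#' with them (`r^2 > r2_max`) are dropped -- an isolated significant SNP
#' with no associated neighborhood is likely an artifact. The LD `r^2` is
#' the squared Pearson correlation of dosages. The result does not depend
#' on the row order of `assoc`.
#'
#' @param assoc association table (`snp, chrom, pos, p`).
#' @param geno a [genotype_matrix()] holding the same SNPs.
#' @param suggestive P-value threshold for candidate leads.
#' @param r2_max LD ceiling between independent leads (default 0.25).
#' @param support_p P-value bound for supporting SNPs (default 1e-4).
#' @param min_support minimum number of supporting SNPs (default 5).
#' @return data.frame of leads: `snp, chrom, pos, p, n_support`.
#' @export
clump_leads <- function(assoc, geno, suggestive, r2_max = 0.25,
                        support_p = 1e-4, min_support = 5L) {
  stopifnot(inherits(geno, "genotype_matrix"),
            all(c("snp", "chrom", "pos", "p") %in% names(assoc)))
  known <- assoc$snp %in% colnames(geno$dosage)
  if (any(!known)) {
    warning(sum(!known), " SNP(s) without genotypes excluded from clumping")
    assoc <- assoc[known, , drop = FALSE]
  }
  cand <- assoc[assoc$p < suggestive, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  leads <- integer(0)
  while (any(alive)) {
    i <- which(alive)[1]
    leads <- c(leads, i)
    live <- which(alive)
    r2 <- ld_r2_with(geno$dosage, cand$snp[i], cand$snp[live])
    alive[live[r2 > r2_max]] <- FALSE
    alive[i] <- FALSE
  }
  out <- cand[leads, , drop = FALSE]
  support <- assoc[assoc$p < support_p, , drop = FALSE]
  n_support <- vapply(out$snp, function(s) {
    others <- support$snp[support$snp != s]
    if (!length(others)) return(0L)
    sum(ld_r2_with(geno$dosage, s, others) > r2_max)
  }, 1L)
  out$n_support <- n_support
  out <- out[n_support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge associated SNPs into loci
#'
#' Single-linkage merge along each chromosome: SNPs whose adjacent
#' distance is less than `gap_kb` kilobases fall into the same locus, so
#' the gap between two distinct loci on a chromosome is at least
#' `gap_kb`. Each locus is represented by its lead SNP, the member with
#' the lowest P-value (ties broken by the smaller position).
#'
#' @param assoc data.frame `snp, chrom, pos` and optionally `p` (needed
#'   for lead selection; defaults to 1 when absent).
#' @param gap_kb merge distance in kb (default 300).
#' @return object of class `locus_set`: `loci` (one row per locus:
#'   `locus, chrom, start, end, n_snps, lead_snp, lead_pos, lead_p`) and
#'   `members` (the input plus a `locus` column).
#' @export
define_loci <- function(assoc, gap_kb = 300) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(assoc)))
  if (is.null(assoc$p)) assoc$p <- 1
  members <- assoc[order(assoc$chrom, assoc$pos), , drop = FALSE]
  members$locus <- NA_integer_
  gap_bp <- gap_kb * 1000
  locus_id <- 0L
  for (ch in unique(members$chrom)) {
    idx <- which(members$chrom == ch)
    pos <- members$pos[idx]
    new_block <- c(TRUE, diff(pos) >= gap_bp)
    members$locus[idx] <- locus_id + cumsum(new_block)
    locus_id <- locus_id + sum(new_block)
  }
  loci <- do.call(rbind, lapply(split(members, members$locus), function(m) {
    lead <- m[order(m$p, m$pos), ][1, ]
    data.frame(locus = m$locus[1], chrom = m$chrom[1],
               start = min(m$pos), end = max(m$pos), n_snps = nrow(m),
               lead_snp = lead$snp, lead_pos = lead$pos, lead_p = lead$p,
               stringsAsFactors = FALSE)
  }))
  loci <- loci[order(loci$locus), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, members = members, gap_kb = gap_kb),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci from %d SNPs (merge gap %g kb)\n",
              nrow(x$loci), nrow(x$members), x$gap_kb))
  invisible(x)
}

#' Read gene annotations from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature_type annotation rows to keep (default "gene").
#' @return `GRanges` of genes with a `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  if (!is.null(gr$Name)) {
    use <- !is.na(gr$Name)
    ids[use] <- gr$Name[use]
  }
  gr$gene_id <- ids
  gr
}

#' Candidate genes around a lead SNP
#'
#' Returns the genes overlapping the window `flank_kb` upstream and
#' downstream of the lead SNP position.
#'
#' @param chrom,pos chromosome and 1-based position of the lead SNP.
#' @param genes `GRanges` from [read_gene_annotation()] or a data.frame
#'   with columns `gene_id, chrom, start, end`.
#' @param flank_kb window half-width in kb (default 100).
#' @return data.frame `gene_id, chrom, start, end, distance` (distance 0
#'   when the SNP lies inside the gene). Empty with a warning when the
#'   chromosome is absent from the annotation.
#' @export
candidate_window <- function(chrom, pos, genes, flank_kb = 100) {
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(genes$start, genes$end),
      gene_id = genes$gene_id)
  }
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (!chrom %in% as.character(GenomeInfoDb::seqnames(genes))) {
    warning("chromosome ", chrom, " absent from the annotation")
    return(empty)
  }
  win <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(max(1, pos - flank_kb * 1000), pos + flank_kb * 1000))
  hits <- IRanges::subsetByOverlaps(genes, win)
  if (!length(hits)) return(empty)
  st <- GenomicRanges::start(hits); en <- GenomicRanges::end(hits)
  dist <- pmax(0, pmax(st - pos, pos - en))
  out <- data.frame(gene_id = hits$gene_id,
                    chrom = as.character(GenomeInfoDb::seqnames(hits)),
                    start = st, end = en, distance = dist,
                    stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Haplotype groups at significant SNPs and their phenotype contrast
#'
#' Accessions are grouped by their identical multi-SNP genotype string
#' over the supplied significant SNPs; groups smaller than `min_group`
#' are set aside, and the phenotype of the two largest remaining groups
#' is compared with a Welch two-sample t-test.
#'
#' @param dosages accessions x SNPs dosage matrix restricted to the
#'   significant SNPs (e.g. `geno$dosage[, snps]`).
#' @param phenotype numeric vector, one value per accession.
#' @param min_group smallest group size retained (default 30).
#' @return list: `groups` (haplotype string, n, mean phenotype for every
#'   retained group, largest first), `test` (the `htest`), `p_value`.
#' @export
haplotype_compare <- function(dosages, phenotype, min_group = 30L) {
  dosages <- as.matrix(dosages)
  phenotype <- as.numeric(phenotype)
  stopifnot(nrow(dosages) == length(phenotype))
  hap <- apply(dosages, 1, paste, collapse = "")
  sizes <- sort(table(hap), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_group]
  if (length(keep) < 2L)
    stop("fewer than two haplotype groups of size >= ", min_group)
  groups <- data.frame(
    haplotype = keep,
    n = as.integer(sizes[keep]),
    mean = vapply(keep, function(h) mean(phenotype[hap == h]), 1),
    stringsAsFactors = FALSE, row.names = NULL)
  tt <- t.test(phenotype[hap == keep[1]], phenotype[hap == keep[2]])
  list(groups = groups, test = tt, p_value = tt$p.value)
}
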