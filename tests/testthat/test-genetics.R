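# SNP filtering, GRM, REML, hyper-trait selection and GWAS post-processing.

test_that("SNP filter applies the MAF and carrier-count rules", {
  # 100 accessions: MAF 0.04 SNP removed, 5-carrier SNP removed
  n <- 100
  dos <- cbind(
    rare = c(rep(1, 8), rep(0, 92)),          # MAF 0.04
    few = c(2, 2, 1, 1, 1, rep(0, 95)),       # MAF 0.035, 5 carriers
    ok = c(rep(1, 30), rep(0, 70)))           # MAF 0.15, 30 carriers
  map <- data.frame(snp = colnames(dos), chrom = "chr1", pos = c(100, 200, 300))
  g <- genotype_matrix(dos, map)
  f <- filter_snps(g)
  expect_equal(f$map$snp, "ok")
  # carrier threshold alone: MAF 0.05 but < 6 carriers
  dos2 <- cbind(border = c(2, 2, 2, 2, 2, rep(0, 95)))  # MAF 0.05, 5 carriers
  g2 <- genotype_matrix(dos2, data.frame(snp = "border", chrom = "chr1", pos = 1))
  expect_warning(f2 <- filter_snps(g2), "no SNPs")
  expect_equal(ncol(f2$dosage), 0L)
})

test_that("SNP filter matches a brute-force per-SNP count oracle", {
  g <- random_panel(80, 150, seed = 30, maf_lo = 0.01, maf_hi = 0.5)
  f <- filter_snps(g, maf_min = 0.05, mac_min = 6)
  keep_oracle <- vapply(seq_len(ncol(g$dosage)), function(j) {
    v <- g$dosage[, j]
    p <- sum(v) / (2 * length(v))
    maf <- min(p, 1 - p)
    maf >= 0.05 && sum(v > 0) >= 6
  }, TRUE)
  expect_equal(f$map$snp, g$map$snp[keep_oracle])
})

test_that("the GRM is symmetric PSD with unit mean diagonal", {
  g <- random_panel(60, 400, seed = 31)
  K <- compute_grm(g)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  # identical genotype rows relate as strongly as an accession to itself
  dos <- g$dosage; dos[2, ] <- dos[1, ]
  g2 <- genotype_matrix(dos, g$map)
  K2 <- compute_grm(g2)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-10)
})

test_that("the GRM matches an explicit double-loop oracle on a small panel", {
  g <- random_panel(12, 40, seed = 32)
  K <- compute_grm(g)
  Z <- scale(g$dosage[, apply(g$dosage, 2, sd) > 0])
  m <- ncol(Z)
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12)
    oracle[i, j] <- sum(Z[i, ] * Z[j, ]) / m
  expect_equal(unname(K), oracle)
})

test_that("bivariate REML hits the r_g = 1 boundary for a duplicated trait", {
  pop <- simulate_population(sim_config(seed = 41, n_accessions = 200L,
                                        n_snps = 600L))
  K <- compute_grm(pop$geno)
  est <- reml_bivariate(pop$traits$y1, pop$traits$y1, K)
  expect_equal(est$r_g, 1)
  expect_true(est$boundary)
  expect_lte(abs(est$h2_1 - est$h2_2), 0.01)
})

test_that("bivariate REML recovers simulated h2 and r_g", {
  cfg <- sim_config(n_accessions = 300L, n_snps = 1200L,
                    h2 = c(0.5, 0.5), r_g = 0.6)
  res <- sapply(1:6, function(s) {
    pop <- simulate_population(cfg, seed = 500 + s)
    est <- reml_bivariate(pop$traits$y1, pop$traits$y2, compute_grm(pop$geno))
    c(est$h2_1, est$h2_2, est$r_g)
  })
  mean_est <- rowMeans(res)
  expect_lt(abs(mean_est[1] - 0.5), 0.15)
  expect_lt(abs(mean_est[2] - 0.5), 0.15)
  expect_lt(abs(mean_est[3] - 0.6), 0.15)
})

test_that("REML heritability is centred near zero when none was simulated", {
  # under h2 = 0 the estimate is a boundary-truncated half-normal whose
  # sampling SD at this panel size is about sqrt(2 m) / n ~ 0.1, so single
  # seeds can exceed 0.1; the location over seeds must stay near zero
  cfg <- sim_config(n_accessions = 300L, n_snps = 1000L, h2 = c(0, 0), r_g = 0)
  h2s <- vapply(1:10, function(s) {
    pop <- simulate_population(cfg, seed = 600 + s)
    est <- reml_bivariate(pop$traits$y1, pop$traits$y2, compute_grm(pop$geno))
    est$h2_1
  }, 1)
  expect_lt(mean(h2s), 0.1)
  expect_lt(median(h2s), 0.08)
})

test_that("bivariate REML with a noise second trait reduces to the univariate fit", {
  pop <- simulate_population(sim_config(seed = 43, n_accessions = 300L,
                                        n_snps = 1200L, h2 = c(0.5, 0.5)))
  K <- compute_grm(pop$geno)
  eg <- grm_eigen(K)
  uni <- reml_univariate(pop$traits$y1, eg)
  set.seed(99)
  noise <- rnorm(300)
  biv <- reml_bivariate(pop$traits$y1, noise, eg)
  expect_lt(abs(biv$h2_1 - uni$h2), 0.05)
})

test_that("hyper-trait selection applies the 0.5/0.5/0.5 rule on absolute r", {
  stats <- data.frame(
    index = c("ddT_124", "CPT_3", "weak", "strong_neg"),
    r_p = c(0.68, -0.60, 0.4, -0.9),
    r_g = c(0.67, -0.55, 0.9, -0.8),
    h2 = c(0.75, 0.68, 0.9, 0.9))
  out <- select_hyper_traits(stats)
  expect_equal(out$pass, c(TRUE, TRUE, FALSE, TRUE))
  stats$h2[1] <- NA
  expect_warning(out2 <- select_hyper_traits(stats), "skipped")
  expect_true(is.na(out2$pass[1]))
})

test_that("hyper-trait scan computes r_p, r_g and h2 per index", {
  cfg <- sim_config(seed = 44, n_accessions = 250L, n_snps = 800L,
                    h2 = c(0.6, 0.6), r_g = 0.8)
  pop <- simulate_population(cfg)
  K <- compute_grm(pop$geno)
  idx <- cbind(proxy = pop$traits$y2, noise = rnorm(250))
  res <- hyper_trait_scan(idx, pop$traits$y1, K)
  expect_equal(res$index, c("proxy", "noise"))
  expect_gt(abs(res$r_p[1]), abs(res$r_p[2]))
  expect_true(is.logical(res$pass))
})

test_that("association P-values are uniform under the null", {
  g <- random_panel(300, 5000, seed = 50)
  set.seed(51)
  y <- rnorm(300)
  assoc <- association_scan(g, y)
  ks <- suppressWarnings(ks.test(assoc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted QTL is the study-wide minimum P in most seeds", {
  hits <- vapply(1:20, function(s) {
    g <- random_panel(500, 200, seed = 700 + s)
    set.seed(800 + s)
    q <- 117
    z <- scale(g$dosage[, q])
    y <- sqrt(0.2) * z + sqrt(0.8) * rnorm(500)   # QTL explains 20%
    assoc <- association_scan(g, y)
    assoc$snp[which.min(assoc$p)] == g$map$snp[q]
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("monomorphic SNPs are absent from the scan output", {
  g <- random_panel(50, 20, seed = 52)
  g$dosage[, 3] <- 0
  set.seed(53)
  assoc <- association_scan(g, rnorm(50))
  expect_false(g$map$snp[3] %in% assoc$snp)
  expect_equal(nrow(assoc), 19)
  expect_error(association_scan(g, rep(1, 50)), "zero variance")
})

test_that("thresholds derive from the effective SNP number exactly", {
  th <- thresholds_from_N(1e6)
  expect_equal(unname(th), c(1e-6, 5e-8))
  # printed threshold pairs: significant = 0.05 x suggestive
  th_ind <- thresholds_from_N(1 / 1.66e-6)
  expect_equal(unname(th_ind["significant"]), 8.30e-8)
  th_jap <- thresholds_from_N(1 / 3.81e-6)
  expect_equal(unname(th_jap["significant"]), 1.91e-7, tolerance = 0.005 / 1.91)
  for (N in c(3, 1e4, 7.7e6))
    expect_equal(unname(thresholds_from_N(N)["significant"]),
                 0.05 * unname(thresholds_from_N(N)["suggestive"]))
  expect_error(thresholds_from_N(0), "positive")
  expect_error(thresholds_from_N(-5), "positive")
})

test_that("clumping keeps the lower-P member of an LD pair and enforces support", {
  # two significant SNPs in near-perfect LD plus a supporting neighborhood
  set.seed(60)
  n <- 400
  base <- rbinom(n, 2, 0.3)
  flip <- function(v, rate) { i <- runif(n) < rate; w <- v; w[i] <- 2 - v[i]; w }
  dos <- cbind(lead = base, dep = flip(base, 0.02),
               sapply(1:6, function(i) flip(base, 0.12)))
  colnames(dos) <- c("lead", "dep", paste0("sup", 1:6))
  map <- data.frame(snp = colnames(dos), chrom = "chr1",
                    pos = seq(1e6, by = 1e4, length.out = 8))
  g <- genotype_matrix(dos, map, orient_minor = FALSE)
  assoc <- data.frame(snp = colnames(dos), chrom = "chr1", pos = map$pos,
                      p = c(1e-9, 5e-8, rep(5e-5, 6)))
  leads <- clump_leads(assoc, g, suggestive = 1e-6)
  expect_equal(leads$snp, "lead")
  expect_gte(leads$n_support, 5)
  # with most of the neighborhood above support_p the lead is dropped
  assoc2 <- assoc; assoc2$p[4:8] <- 0.5   # only 1 supporting SNP left
  leads2 <- clump_leads(assoc2, g, suggestive = 1e-6)
  expect_equal(nrow(leads2), 0L)
})

test_that("clumping matches a from-scratch oracle on random 200-SNP panels", {
  for (seed in 1:4) {
    pop <- simulate_population(sim_config(seed = seed, n_accessions = 250L,
                                          n_snps = 200L, ld_rho = 0.9,
                                          n_qtl = 2L, qtl_frac = 0.7,
                                          h2 = c(0.7, 0.7)))
    assoc <- association_scan(pop$geno, pop$traits$y1)
    leads <- clump_leads(assoc, pop$geno, suggestive = 1e-4,
                         support_p = 1e-2, min_support = 3L)
    oracle <- clump_oracle(assoc, pop$geno$dosage, suggestive = 1e-4,
                           support_p = 1e-2, min_support = 3L)
    expect_equal(sort(leads$snp), oracle)
  }
})

test_that("clumping is invariant to association row order", {
  pop <- simulate_population(sim_config(seed = 61, n_accessions = 250L,
                                        n_snps = 150L, ld_rho = 0.9,
                                        n_qtl = 2L, qtl_frac = 0.7,
                                        h2 = c(0.7, 0.7)))
  assoc <- association_scan(pop$geno, pop$traits$y1)
  l1 <- clump_leads(assoc, pop$geno, suggestive = 1e-3,
                    support_p = 1e-2, min_support = 2L)
  set.seed(62)
  l2 <- clump_leads(assoc[sample.int(nrow(assoc)), ], pop$geno,
                    suggestive = 1e-3, support_p = 1e-2, min_support = 2L)
  expect_equal(l1[order(l1$snp), ], l2[order(l2$snp), ], ignore_attr = TRUE)
})

test_that("locus merging follows the 300-kb single-linkage rule", {
  assoc <- data.frame(snp = c("a", "b", "c"), chrom = "chr1",
                      pos = c(1000000, 1200000, 1900000),
                      p = c(1e-8, 1e-7, 1e-9))
  ls <- define_loci(assoc)
  expect_equal(nrow(ls$loci), 2L)
  expect_equal(ls$loci$start, c(1000000, 1900000))
  expect_equal(ls$loci$end, c(1200000, 1900000))
  expect_equal(ls$loci$lead_snp, c("a", "c"))
  # single SNP: a singleton locus
  ls1 <- define_loci(data.frame(snp = "x", chrom = "chr5", pos = 42, p = 1e-6))
  expect_equal(nrow(ls1$loci), 1L)
  expect_equal(ls1$loci$n_snps, 1L)
})

test_that("locus sets match a union-find oracle and keep their invariants", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
    pos <- sample.int(2e7, n)
    assoc <- data.frame(snp = paste0("s", 1:n), chrom = chrom, pos = pos,
                        p = runif(n))
    ls <- define_loci(assoc)
    comp <- loci_oracle(assoc$chrom, assoc$pos)
    # identical partitions
    got <- ls$members$locus[match(assoc$snp, ls$members$snp)]
    expect_equal(length(unique(got)), length(unique(comp)))
    expect_true(all(tapply(comp, got, function(v) length(unique(v))) == 1))
    # invariants: disjoint loci, >= 300 kb gaps, full coverage
    expect_false(any(is.na(ls$members$locus)))
    for (ch in unique(ls$loci$chrom)) {
      l <- ls$loci[ls$loci$chrom == ch, ]
      l <- l[order(l$start), ]
      if (nrow(l) > 1) {
        expect_true(all(l$start[-1] - l$end[-nrow(l)] >= 3e5))
        expect_true(all(l$start[-1] > l$end[-nrow(l)]))
      }
    }
  }
})

test_that("candidate windows select genes within 100 kb of the lead", {
  genes <- data.frame(gene_id = c("near", "far", "inside"),
                      chrom = c("chr9", "chr9", "chr9"),
                      start = c(20798000, 20941000, 20780000),
                      end = c(20800000, 20943000, 20795000))
  # gene 7 kb upstream of the lead: included
  hits <- candidate_window("chr9", 20791791, genes)
  expect_setequal(hits$gene_id, c("near", "inside"))
  expect_equal(hits$distance[hits$gene_id == "near"], 20798000 - 20791791)
  expect_equal(hits$distance[hits$gene_id == "inside"], 0)
  # 150 kb away: excluded (far gene sits ~149 kb from this lead)
  expect_false("far" %in% candidate_window("chr9", 20792000, genes)$gene_id)
  expect_warning(none <- candidate_window("chr1", 100, genes), "absent")
  expect_equal(nrow(none), 0L)
})

test_that("candidate windows match a brute-force overlap oracle", {
  set.seed(70)
  for (rep in 1:5) {
    genes <- data.frame(gene_id = paste0("g", 1:50), chrom = "chr2",
                        start = st <- sample.int(5e6, 50))
    genes$end <- genes$start + sample.int(2e4, 50)
    pos <- sample.int(5e6, 1)
    got <- candidate_window("chr2", pos, genes)$gene_id
    lo <- pos - 1e5; hi <- pos + 1e5
    oracle <- genes$gene_id[genes$end >= lo & genes$start <= hi]
    expect_setequal(got, oracle)
  }
})

test_that("haplotype groups contrast phenotypes with a Welch test", {
  # two haplotype groups 1 SD apart, n = 200 each: strong detection
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    dos <- rbind(matrix(0, 200, 2), matrix(2, 200, 2))
    y <- c(rnorm(200, 0), rnorm(200, 1))
    haplotype_compare(dos, y, min_group = 30)$p_value < 0.01
  }, TRUE)
  expect_gte(sum(hits), 19)
  # identical distributions: P uniform over seeds
  ps <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    dos <- rbind(matrix(0, 100, 2), matrix(2, 100, 2))
    haplotype_compare(dos, rnorm(200), min_group = 30)$p_value
  }, 1)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("small haplotype groups are excluded and singletons error", {
  set.seed(71)
  dos <- rbind(matrix(0, 100, 2), matrix(2, 80, 2),
               cbind(rep(0, 10), rep(2, 10)))   # third group of 10
  y <- rnorm(190)
  res <- haplotype_compare(dos, y, min_group = 30)
  expect_equal(nrow(res$groups), 2L)
  expect_equal(res$groups$n, c(100L, 80L))
  expect_error(haplotype_compare(matrix(0, 50, 2), rnorm(50), min_group = 30),
               "fewer than two")
})
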