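test_that("haplotype panels are deterministic and phase-consistent", {
  a <- simulate_haplotype_pool(seed = 301)
  b <- simulate_haplotype_pool(seed = 301)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$geno$haplotypes, b$geno$haplotypes)
  odd <- seq(1, nrow(a$geno$haplotypes), 2)
  expect_equal(a$geno$haplotypes[odd, ] + a$geno$haplotypes[odd + 1, ],
               unname(a$geno$dosages), ignore_attr = TRUE)
  maf <- pmin(colMeans(a$geno$dosages) / 2, 1 - colMeans(a$geno$dosages) / 2)
  expect_true(all(maf >= 0.05))
  # SNPs map into the generated interval
  asg <- assign_snps_to_intervals(a$geno$snps, a$interval)
  expect_true(all(!is.na(asg$interval_id)))
})

test_that("switch rate controls the LD extent of the panel", {
  lo <- simulate_haplotype_pool(n_founders = 4, switch_rate = 0.001, seed = 311)
  hi <- simulate_haplotype_pool(n_founders = 8, switch_rate = 0.9, seed = 311)
  m_lo <- interval_median_r2(lo$geno, lo$geno$snps$snp_id)$median_r2
  m_hi <- interval_median_r2(hi$geno, hi$geno$snps$snp_id)$median_r2
  expect_gt(m_lo, 5 * m_hi)
  expect_lt(m_hi, 0.05)
  # near-zero switching leaves many perfectly correlated pairs
  cm <- suppressWarnings(stats::cor(lo$geno$dosages))^2
  expect_gt(mean(cm[upper.tri(cm)] > 0.999, na.rm = TRUE), 0.02)
})

test_that("simulated expression follows the additive model and the seed", {
  panel <- simulate_haplotype_pool(seed = 321)
  snp <- panel$geno$snps$snp_id[4]
  y1 <- simulate_expression(panel$geno, snp, beta = 1, noise_sd = 1, seed = 5)
  y2 <- simulate_expression(panel$geno, snp, beta = 1, noise_sd = 1, seed = 5)
  expect_identical(y1, y2)
  y0 <- simulate_expression(panel$geno, snp, beta = 2, noise_sd = 1e-12, seed = 5)
  # vanishing noise: phenotype is an exact affine function of dosage
  expect_equal(stats::cor(dosage_of(panel$geno, snp), y0), 1)
  expect_gt(spearman_assoc(dosage_of(panel$geno, snp), y0)$rho, 0.9)
  expect_error(simulate_expression(panel$geno, snp, noise_sd = -1), "negative")
})

test_that("null expression keeps the eQTL caller at its nominal rate", {
  # beta = 0: significant fraction over genes is near the permutation tail
  panel <- simulate_haplotype_pool(n_snps = 12, seed = 331)
  geno <- panel$geno
  n_genes <- 60
  set.seed(332)
  vals <- matrix(rnorm(n_samples(geno) * n_genes), nrow = n_samples(geno),
                 dimnames = list(geno$sample_ids, paste0("g", 1:n_genes)))
  expr <- expression_matrix(
    vals, data.frame(gene_id = paste0("g", 1:n_genes), chrom = geno$snps$chrom[1],
                     tss = 5000L, strand = "+"), normalized = TRUE)
  calls <- call_cis_eqtls(geno, expr, n_perm = 100, tail = 0.05, seed = 333)
  frac <- mean(calls$significant)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})

test_that("H0 quartets keep causal SNPs distinct, masked and MAF-matched", {
  n_bad <- 0
  for (k in 1:20) {
    panel <- simulate_haplotype_pool(n_founders = 5, switch_rate = 0.01,
                                     seed = 340 + k)
    scen <- build_h0_quartets(panel, seed = 350 + k)
    if (nrow(scen) == 0) next
    expect_true(all(scen$c_eqtl != scen$c_dsnp))
    expect_true(all(scen$proxy_eqtl != scen$proxy_dsnp))
    expect_lte(nrow(scen), 5L)
    for (i in seq_len(nrow(scen))) {
      expect_setequal(scen$masked[[i]], c(scen$c_eqtl[1], scen$c_dsnp[1]))
      expect_false(scen$proxy_eqtl[i] %in% scen$masked[[i]])
      expect_false(scen$proxy_dsnp[i] %in% scen$masked[[i]])
    }
  }
})

test_that("H0 proxies are the top-correlated SNPs with their causal SNPs", {
  panel <- simulate_haplotype_pool(n_founders = 4, switch_rate = 0.01, seed = 361)
  scen <- build_h0_quartets(panel, seed = 362)
  expect_gt(nrow(scen), 0)
  d <- panel$geno$dosages
  pool <- setdiff(colnames(d), c(scen$c_eqtl[1], scen$c_dsnp[1]))
  r2e <- suppressWarnings(as.vector(cor(d[, pool], d[, scen$c_eqtl[1]]))^2)
  best <- pool[order(-r2e)][1]
  expect_equal(scen$proxy_eqtl[1], best)
})

test_that("H1 trios respect the r2 window and the exclusion rules", {
  found <- 0
  for (k in 1:25) {
    panel <- simulate_haplotype_pool(n_founders = sample(3:6, 1),
                                     switch_rate = 0.01, seed = 370 + k)
    ids <- panel$geno$snps$snp_id
    set.seed(380 + k)
    csnp <- sample(ids, 1)
    y <- simulate_expression(panel$geno, csnp, seed = 380 + k)
    scen <- build_h1_trios(panel, y, csnp, seed = 390 + k)
    if (nrow(scen) == 0) next
    found <- found + nrow(scen)
    expect_lte(nrow(scen), 5L)
    d <- panel$geno$dosages
    for (i in seq_len(nrow(scen))) {
      expect_false(scen$proxy_dsnp[i] == csnp)
      expect_false(scen$proxy_dsnp[i] %in% scen$proxy_eqtl[seq_len(i)])
      r2 <- stats::cor(d[, scen$proxy_dsnp[i]], d[, csnp])^2
      expect_gte(r2, 0.5); expect_lte(r2, 0.9)
      expect_identical(scen$masked[[i]], csnp)
    }
  }
  expect_gt(found, 10)
})

test_that("masked causal SNPs never enter the scored sweep", {
  sim <- run_rtc_simulation("h1", n_intervals = 8, seed = 401)
  expect_false(any(sim$eqtl_snp == sim$c_eqtl))
  expect_false(any(sim$gwas_snp == sim$c_eqtl))
  sim0 <- run_rtc_simulation("h0", n_intervals = 8, seed = 402)
  expect_false(any(sim0$eqtl_snp == sim0$c_eqtl | sim0$eqtl_snp == sim0$c_dsnp))
  expect_false(any(sim0$gwas_snp == sim0$c_eqtl | sim0$gwas_snp == sim0$c_dsnp))
  # score bookkeeping holds end to end
  expect_true(all(sim$rtc > 0 & sim$rtc <= 1))
  expect_true(all(sim$rtc == (sim$n_snps - sim$rank) / sim$n_snps))
  g <- glance(sim)
  expect_equal(g$n_scenarios, nrow(sim))
})
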