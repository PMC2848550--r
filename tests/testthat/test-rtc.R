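test_that("correcting for the eQTL SNP itself removes the association", {
  panel <- simulate_haplotype_pool(n_snps = 20, seed = 101)
  geno <- panel$geno
  causal <- geno$snps$snp_id[5]
  y <- simulate_expression(geno, causal, beta = 1, noise_sd = 0.5, seed = 102)
  g <- dosage_of(geno, causal)
  uncorrected <- spearman_assoc(g, y)$p_nominal
  expect_lt(uncorrected, 1e-8)
  expect_gt(corrected_pvalue(y, g, g)$p_adjusted, 1e-3)
  # orthogonal correction leaves the association essentially untouched
  set.seed(103)
  indep <- rbinom(length(y), 2, 0.4)
  adj <- corrected_pvalue(y, g, indep)$p_adjusted
  expect_lt(abs(log10(adj) - log10(uncorrected)), 2)
  expect_error(corrected_pvalue(y, g, rep(1, length(y))), "constant")
})

test_that("the score is (n_snps - rank)/n_snps with rank-0 at concordance", {
  panel <- simulate_haplotype_pool(n_snps = 50, switch_rate = 0.05, seed = 111)
  geno <- panel$geno
  maf <- pmin(colMeans(geno$dosages) / 2, 1 - colMeans(geno$dosages) / 2)
  causal <- geno$snps$snp_id[which.max(maf)]
  y <- simulate_expression(geno, causal, beta = 1, noise_sd = 0.5, seed = 112)
  r <- rtc_score(geno, geno$snps$snp_id, causal, causal, y)
  expect_equal(r$rank, 0L)
  expect_equal(r$rtc, 1)
  expect_equal(r$rtc, (r$n_snps - r$rank) / r$n_snps)
  expect_equal(r$r2_eqtl_dsnp, 1)
  # a perfect proxy (duplicate dosage column) also scores 1
  dup <- genotype_matrix(
    cbind(geno$dosages, twin = dosage_of(geno, causal)),
    rbind(geno$snps, tibble::tibble(snp_id = "twin", chrom = geno$snps$chrom[1],
                                    pos = max(geno$snps$pos) + 1000L,
                                    ref = "A", alt = "G")))
  r2 <- rtc_score(dup, dup$snps$snp_id, causal, "twin", y)
  expect_equal(r2$rtc, 1)
})

test_that("scoring agrees with an independent brute-force sweep", {
  set.seed(121)
  for (k in 1:10) {
    panel <- simulate_haplotype_pool(
      n_founders = sample(2:8, 1), n_snps = 25,
      switch_rate = exp(runif(1, log(0.002), log(0.1))), seed = 1200 + k)
    geno <- panel$geno
    ids <- geno$snps$snp_id
    if (length(ids) < 6) next
    causal <- sample(ids, 1)
    y <- simulate_expression(geno, causal, beta = 1, noise_sd = 1,
                             seed = 1300 + k)
    eqtl <- sample(ids, 1); gwas <- sample(ids, 1)
    got <- rtc_score(geno, ids, eqtl, gwas, y)
    ora <- oracle_rtc(geno, ids, eqtl, gwas, y)
    expect_identical(got$rank, as.integer(ora$rank))
    expect_equal(got$rtc, ora$rtc)
    expect_identical(got$n_snps, ora$n_snps)
  }
})

test_that("the score ignores SNP input order and affine phenotype changes", {
  panel <- simulate_haplotype_pool(n_snps = 20, seed = 131)
  geno <- panel$geno
  ids <- geno$snps$snp_id
  causal <- ids[3]
  y <- simulate_expression(geno, causal, beta = 1, noise_sd = 1, seed = 132)
  base <- rtc_score(geno, ids, causal, ids[7], y)
  set.seed(133)
  perm <- rtc_score(geno, sample(ids), causal, ids[7], y)
  expect_equal(perm$rtc, base$rtc)
  expect_equal(perm$rank, base$rank)
  aff <- rtc_score(geno, ids, causal, ids[7], 3.5 * y - 11)
  expect_equal(aff$rtc, base$rtc)
  expect_equal(aff$rank, base$rank)
  expect_error(rtc_score(geno, ids[1:5], causal, ids[7], y), "not in the interval")
})

make_scan_fixture <- function(shared = TRUE, seed = 141) {
  # two hotspot intervals on different chromosomes; causal structure in each
  p1 <- simulate_haplotype_pool(n_snps = 25, switch_rate = 0.02, seed = seed,
                                chrom = "chr1")
  p2 <- simulate_haplotype_pool(n_snps = 25, switch_rate = 0.02, seed = seed + 1,
                                chrom = "chr2")
  geno <- genotype_matrix(
    cbind(p1$geno$dosages,
          `colnames<-`(p2$geno$dosages,
                       sub("sim", "two", colnames(p2$geno$dosages)))),
    dplyr::bind_rows(p1$geno$snps,
                     dplyr::mutate(p2$geno$snps,
                                   snp_id = sub("sim", "two", snp_id))))
  ints <- hotspot_intervals(tibble::tibble(
    interval_id = c("int1", "int2"), chrom = c("chr1", "chr2"),
    start = 1L, end = 60000L))
  causal1 <- p1$geno$snps$snp_id[10]
  y1 <- simulate_expression(p1$geno, causal1, beta = 1.2, noise_sd = 0.5,
                            seed = seed + 2)
  set.seed(seed + 3)
  y2 <- rnorm(n_samples(geno))  # second gene: pure noise
  expr <- expression_matrix(
    cbind(geneA = y1, geneB = y2),
    data.frame(gene_id = c("geneA", "geneB"), chrom = c("chr1", "chr2"),
               tss = c(10000L, 10000L), strand = "+"), normalized = TRUE)
  list(geno = geno, ints = ints, expr = expr, causal1 = causal1)
}

test_that("the cis scan scores only intervals with GWAS SNP and significant eQTL", {
  fx <- make_scan_fixture()
  calls <- call_cis_eqtls(fx$geno, fx$expr, n_perm = 200, tail = 0.05, seed = 9)
  expect_true(calls$significant[calls$gene_id == "geneA"])
  gwas <- tibble::tibble(
    snp_id = c(fx$geno$snps$snp_id[5], "two005"),
    trait = c("Crohn's disease", "Height"),
    immunity_related = c(TRUE, FALSE))
  res <- rtc_cis_scan(fx$geno, fx$expr, fx$ints, gwas, calls)
  # int2 has a GWAS SNP but no significant eQTL: no row emitted
  expect_false("int2" %in% res$interval_id)
  expect_true(all(res$interval_id == "int1"))
  expect_true(all(res$gene_id == "geneA"))
  expect_equal(res$rtc, (res$n_snps - res$rank) / res$n_snps)
  # two GWAS SNPs in one interval give two rows for the same gene
  gwas2 <- tibble::tibble(
    snp_id = fx$geno$snps$snp_id[c(5, 6)],
    trait = c("Crohn's disease", "Crohn's disease"),
    immunity_related = TRUE)
  res2 <- rtc_cis_scan(fx$geno, fx$expr, fx$ints, gwas2, calls)
  expect_equal(nrow(res2), 2L)
  expect_equal(unique(res2$gene_id), "geneA")
  expect_setequal(res2$gwas_snp, gwas2$snp_id)
})

test_that("the trans scan keeps top intervals and filters genes by trans P", {
  # distal gene (different chromosome) driven by an interval SNP
  panel <- simulate_haplotype_pool(n_snps = 25, switch_rate = 0.02,
                                   seed = 151, chrom = "chr1")
  geno <- panel$geno
  causal <- geno$snps$snp_id[12]
  y <- simulate_expression(geno, causal, beta = 1.2, noise_sd = 0.5, seed = 152)
  expr <- expression_matrix(
    matrix(y, ncol = 1, dimnames = list(geno$sample_ids, "distal")),
    data.frame(gene_id = "distal", chrom = "chr9", tss = 5e6L, strand = "+"),
    normalized = TRUE)
  ints <- hotspot_intervals(tibble::tibble(
    interval_id = "int1", chrom = "chr1", start = 1L, end = 60000L))
  gwas <- tibble::tibble(snp_id = causal, trait = "T1D",
                         immunity_related = TRUE)
  expect_warning(
    res <- rtc_trans_scan(geno, expr, ints, gwas, top_k = 50, p_trans_max = 1e-5),
    "top_k")
  expect_equal(nrow(res), 1L)
  expect_lt(res$p_trans, 1e-5)
  expect_gt(res$rtc, 0.9)  # GWAS SNP is the causal trans SNP itself
})

test_that("uniform-null expectations and density adjustments are exact", {
  expect_equal(expected_high_rtc_count(130, 0.9), 13)
  expect_equal(density_adjusted_count(33, 3), 99)
  expect_error(expected_high_rtc_count(10, 0))
})
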