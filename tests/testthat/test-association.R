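make_replicates <- function(vals1, vals2, genes = NULL) {
  n_genes <- nrow(vals1)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)), chrom = "1",
                        tss = seq_len(n_genes) * 1000L, strand = "+")
  }
  ints <- cbind(vals1, vals2)[, rep(seq_len(ncol(vals1)), each = 2) +
                                c(0, ncol(vals1))]
  colnames(ints) <- paste0(rep(paste0("S", seq_len(ncol(vals1))), each = 2),
                           c("_1", "_2"))
  structure(list(genes = genes, intensities = ints,
                 samples = paste0("S", seq_len(ncol(vals1))),
                 normalized = FALSE),
            class = "expression_replicates")
}

test_that("normalization equalizes per-sample medians in log2 space", {
  set.seed(11)
  raw1 <- matrix(2^rnorm(500, 8), nrow = 50)   # 50 genes x 10 samples
  raw2 <- raw1 * 2^matrix(rnorm(500, 0, 0.1), nrow = 50)
  e <- normalize_expression(make_replicates(raw1, raw2))
  med <- apply(e$values, 1, median)
  expect_lt(max(med) - min(med), 1e-12)
  # reference is the median of the per-sample medians before centering
  collapsed <- vapply(seq_len(10), function(i) {
    rowMeans(limma::normalizeQuantiles(log2(cbind(raw1[, i], raw2[, i]))))
  }, numeric(50))
  expect_equal(unname(med[1]), median(apply(collapsed, 2, median)))
})

test_that("identical replicates normalize to the single-replicate path", {
  set.seed(12)
  raw <- matrix(2^rnorm(200, 8), nrow = 20)
  e2 <- normalize_expression(make_replicates(raw, raw))
  single <- expression_matrix(
    t(raw), data.frame(gene_id = paste0("g", 1:20), chrom = "1",
                       tss = 1:20 * 1000L, strand = "+"))
  e1 <- normalize_expression(single)
  expect_equal(unname(e2$values), unname(e1$values))
})

test_that("constant log2 offsets between samples vanish after normalization", {
  set.seed(13)
  base <- 2^rnorm(40, 8)
  raw <- cbind(base, base * 4)  # sample 2 shifted by 2 in log2
  e <- normalize_expression(make_replicates(raw, raw))
  # median normalization removes the constant shift entirely
  expect_equal(unname(e$values[1, ]), unname(e$values[2, ]))
  expect_equal(median(e$values[1, ]), median(e$values[2, ]))
})

test_that("non-positive intensities are rejected with the offending cell", {
  raw <- matrix(c(1, 2, 0, 4), nrow = 2)
  expect_error(normalize_expression(make_replicates(raw, raw)), "g2")
})

test_that("spearman association matches the midrank-Pearson oracle", {
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.2, 0.8, 2.0, 1.5, 3.1, 2.7)
  got <- spearman_assoc(g, y, min_samples = 3)
  ora <- oracle_spearman(g, y)
  expect_equal(got$rho, ora$rho)
  expect_equal(got$p_nominal, ora$p)

  set.seed(31)
  for (k in 1:20) {
    gg <- rbinom(40, 2, runif(1, 0.1, 0.5))
    if (stats::var(gg) == 0) next
    yy <- rnorm(40) + 0.3 * gg
    got <- spearman_assoc(gg, yy)
    ora <- oracle_spearman(gg, yy)
    expect_equal(got$rho, ora$rho)
    expect_equal(got$p_nominal, ora$p)
  }
})

test_that("perfect concordance saturates rho with a positive minimal P", {
  g <- c(0, 0, 1, 1, 2, 2)
  up <- spearman_assoc(g, c(1.1, 1.1, 2.4, 2.4, 3.9, 3.9), min_samples = 3)
  expect_equal(up$rho, 1)
  expect_identical(up$p_nominal, .Machine$double.xmin)
  dn <- spearman_assoc(g, -g, min_samples = 3)
  expect_equal(dn$rho, -1)
  expect_identical(dn$p_nominal, .Machine$double.xmin)
  expect_error(spearman_assoc(g, rep(1, 6), min_samples = 3), "constant")
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(41)
  g <- rbinom(60, 2, 0.4)
  y <- rnorm(60) + 0.5 * g
  base <- spearman_assoc(g, y)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 2, function(x) atan(x))) {
    tr <- spearman_assoc(g, f(y))
    expect_equal(tr$rho, base$rho, tolerance = 1e-12)
    expect_equal(tr$p_nominal, base$p_nominal, tolerance = 1e-12)
  }
})

test_that("cis/trans windows follow the inclusive 1Mb / 5Mb boundaries", {
  expect_equal(assign_relation("1", 2e6, "1", 1e6), "cis")        # exactly 1Mb
  expect_equal(assign_relation("1", 4e6, "1", 1e6), "excluded")   # 3Mb apart
  expect_equal(assign_relation("1", 6e6, "1", 1e6), "trans")      # exactly 5Mb
  expect_equal(assign_relation("2", 1e6, "1", 1e6), "trans")      # other chrom
  expect_equal(assign_relation("1", 1e6 + 1, "1", 2e6 + 2), "excluded")
})

test_that("permutation threshold is the tail-order statistic of the minima", {
  set.seed(51)
  G <- matrix(rbinom(50 * 8, 2, 0.3), nrow = 50)
  y <- rnorm(50)
  thr <- permutation_threshold(y, G, n_perm = 100, tail = 0.05, seed = 3)
  # independent recomputation of the same permutation stream
  zg <- apply(G, 2, rank)
  set.seed(3)
  P <- replicate(100, sample.int(50))
  minima <- apply(P, 2, function(idx) {
    min(vapply(seq_len(ncol(G)), function(j) {
      oracle_spearman(G[, j], y[idx])$p
    }, numeric(1)))
  })
  expect_equal(thr$perm_threshold, sort(minima)[5])
  # more stringent tail -> lower threshold
  thr01 <- permutation_threshold(y, G, n_perm = 100, tail = 0.01, seed = 3)
  expect_lt(thr01$perm_threshold, thr$perm_threshold)
  # single candidate SNP: minima are that SNP's permuted P-values
  thr1 <- permutation_threshold(y, G[, 1, drop = FALSE], n_perm = 100,
                                tail = 0.05, seed = 3)
  minima1 <- apply(P, 2, function(idx) oracle_spearman(G[, 1], y[idx])$p)
  expect_equal(thr1$perm_threshold, sort(minima1)[5])
})

test_that("a strongly causal cis SNP is called significant", {
  panel <- simulate_haplotype_pool(n_snps = 20, seed = 61)
  geno <- panel$geno
  causal <- geno$snps$snp_id[10]
  y <- simulate_expression(geno, causal, beta = 1, noise_sd = 0.5, seed = 62)
  expr <- expression_matrix(
    matrix(y, ncol = 1, dimnames = list(geno$sample_ids, "gene1")),
    data.frame(gene_id = "gene1", chrom = geno$snps$chrom[1],
               tss = geno$snps$pos[10], strand = "+"), normalized = TRUE)
  calls <- call_cis_eqtls(geno, expr, n_perm = 200, tail = 0.05, seed = 63)
  expect_true(calls$significant)
  best <- dosage_of(geno, calls$best_snp_id)
  expect_gt(stats::cor(best, dosage_of(geno, causal))^2, 0.8)
})

test_that("best-SNP ties break deterministically by genomic position", {
  g <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  dup <- make_geno(cbind(a = g, b = g), pos = c(500L, 100L))
  y <- as.numeric(g) + rnorm(10, 0, 0.1)
  expr <- expression_matrix(
    matrix(y, ncol = 1, dimnames = list(dup$sample_ids, "gene1")),
    data.frame(gene_id = "gene1", chrom = "1", tss = 300L, strand = "+"),
    normalized = TRUE)
  calls <- call_cis_eqtls(dup, expr, n_perm = 100, seed = 1, min_samples = 5)
  expect_equal(calls$best_snp_id, "b")  # pos 100 < 500
})

test_that("residualization matches the closed-form two-parameter OLS", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  expect_equal(residualize(2 + 3 * g, g), rep(0, 8), tolerance = 1e-12)
  set.seed(71)
  y <- rnorm(8)
  res <- residualize(y, g)
  b <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  a <- mean(y) - b * mean(g)
  expect_equal(res, y - a - b * g)
  expect_lt(abs(stats::cor(res, g)), 1e-10)
  # independent phenotype: residuals approach the centered phenotype
  set.seed(72)
  y2 <- rnorm(5000); g2 <- rbinom(5000, 2, 0.5)
  expect_gt(stats::cor(residualize(y2, g2), y2 - mean(y2)), 0.999)
  expect_error(residualize(y, rep(2, 8)), "constant")
})

test_that("variance ratio contrasts adjusted R2 after vs before correction", {
  panel <- simulate_haplotype_pool(n_snps = 20, seed = 81)
  geno <- panel$geno
  causal <- geno$snps$snp_id[8]
  y <- simulate_expression(geno, causal, beta = 1, noise_sd = 0.7, seed = 82)
  g <- dosage_of(geno, causal)
  # correcting for the eQTL itself leaves nothing
  expect_lt(variance_ratio(y, g, g)$variance_ratio, 0.05)
  # an independent SNP removes nothing
  set.seed(83)
  indep <- rbinom(length(y), 2, 0.4)
  gi <- make_geno(cbind(e = g, i = indep))
  expect_gt(variance_ratio(y, g, indep)$variance_ratio, 0.8)
  # intermediate case matches direct recomputation from two regressions
  other <- geno$snps$snp_id[9]
  vr <- variance_ratio(y, g, dosage_of(geno, other))
  before <- summary(stats::lm(y ~ g))$adj.r.squared
  after <- summary(stats::lm(stats::residuals(
    stats::lm(y ~ dosage_of(geno, other))) ~ g))$adj.r.squared
  expect_equal(vr$variance_ratio, max(0, after) / max(0, before))
})
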