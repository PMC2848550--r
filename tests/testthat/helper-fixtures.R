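# Fixtures are built in code; file-based ones are written to tempfiles.

options(rtcscore.verbose = FALSE)

# tiny unphased genotype object from a dosage matrix (SNPs in columns)
make_geno <- function(dos, chrom = "1", pos = NULL, haplotypes = NULL) {
  dos <- as.matrix(dos)
  if (is.null(colnames(dos))) colnames(dos) <- paste0("rs", seq_len(ncol(dos)))
  if (is.null(rownames(dos))) rownames(dos) <- paste0("s", seq_len(nrow(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 100L
  genotype_matrix(
    dos,
    snps = data.frame(snp_id = colnames(dos), chrom = chrom, pos = pos,
                      ref = "A", alt = "G"),
    haplotypes = haplotypes)
}

# diploid genotypes drawn from explicit haplotype frequencies
# p = c(pAB, pAb, paB, pab); returns list(g1, g2, h1, h2)
sample_from_hap_freqs <- function(p, n, seed = 1) {
  set.seed(seed)
  haps <- sample.int(4, 2 * n, replace = TRUE, prob = p)
  a1 <- as.integer(haps %in% c(1, 2))  # allele at locus 1
  a2 <- as.integer(haps %in% c(1, 3))  # allele at locus 2
  odd <- seq(1, 2 * n, 2)
  list(g1 = a1[odd] + a1[odd + 1], g2 = a2[odd] + a2[odd + 1],
       h1 = a1, h2 = a2)
}

write_test_vcf <- function(path, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  gt <- function(a, b) paste0(a, sep, b)
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    paste("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
          gt(0, 0), gt(0, 1), gt(1, 1), sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", ".", ".", "GT",
          gt(0, 1), gt(0, 1), gt(0, 0), sep = "\t"),
    paste("1", "300", "rs3", "G", "GA,T", ".", ".", ".", "GT",
          gt(0, 0), gt(0, 1), gt(1, 1), sep = "\t"))
  writeLines(lines, path)
  path
}

# deterministic spearman oracle: midranks then explicit pearson + t
oracle_spearman <- function(g, y) {
  rg <- rank(g); ry <- rank(y)
  r <- sum((rg - mean(rg)) * (ry - mean(ry))) /
    sqrt(sum((rg - mean(rg))^2) * sum((ry - mean(ry))^2))
  n <- length(g)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# independent RTC sweep: lm() residuals + cor.test per interval SNP,
# explicit counting of higher-impact corrections
oracle_rtc <- function(geno, snp_ids, eqtl, gwas, y) {
  ge <- dosage_of(geno, eqtl)
  usable <- snp_ids[vapply(snp_ids, function(s) {
    stats::var(dosage_of(geno, s)) > 0
  }, logical(1))]
  p_adj <- vapply(usable, function(s) {
    gs <- dosage_of(geno, s)
    res <- stats::residuals(stats::lm(y ~ gs))
    suppressWarnings(stats::cor.test(ge, res, method = "spearman",
                                     exact = FALSE)$p.value)
  }, numeric(1))
  rank_g <- sum(p_adj[names(p_adj) != gwas] > p_adj[[gwas]])
  list(n_snps = length(usable), rank = rank_g,
       rtc = (length(usable) - rank_g) / length(usable), p_adj = p_adj)
}
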