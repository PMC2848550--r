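#' Allele frequency and MAF from dosages
#'
#' @param dosages numeric vector of 0/1/2 alternate-allele dosages, `NA`
#'   allowed.
#' @return One-row tibble with `alt_freq`, `maf`, `n_used`.
#' @examples
#' allele_freq(c(0, 1, 2, 1))  # alt_freq 0.5
#' @export
allele_freq <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) abort("allele frequency undefined: all dosages missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  tibble(alt_freq = f, maf = min(f, 1 - f), n_used = sum(ok))
}

# Haplotype frequencies (pAB, pAb, paB, pab) from two phased binary columns.
hap_freqs_phased <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  n <- length(h1)
  if (n == 0) abort("no complete haplotypes")
  c(pAB = sum(h1 == 1 & h2 == 1), pAb = sum(h1 == 1 & h2 == 0),
    paB = sum(h1 == 0 & h2 == 1), pab = sum(h1 == 0 & h2 == 0)) / n
}

#' Maximum-likelihood 2-SNP haplotype frequencies from unphased genotypes
#'
#' Standard EM for the two-locus phase problem: only double heterozygotes
#' are phase-ambiguous. Initialized at linkage equilibrium; iterates until
#' the log-likelihood changes by less than `tol`.
#'
#' @param g1,g2 dosage vectors (0/1/2, `NA` allowed; pairwise-complete
#'   samples used).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter iteration cap (default 5000, generous because boundary
#'   solutions with a haplotype frequency at 0 converge sublinearly);
#'   non-convergence is an error reporting the iteration count and last
#'   log-likelihood change.
#' @return List with `freqs` (named `pAB`, `pAb`, `paB`, `pab`, where `A`/`B`
#'   denote the alternate alleles), `loglik`, `iterations`, `n_used`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 5000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) abort("no pairwise-complete samples")
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1, g2[i] + 1] <- cnt[g1[i] + 1, g2[i] + 1] + 1
  pA <- sum(g1) / (2 * n); pB <- sum(g2) / (2 * n)
  p <- c(pAB = pA * pB, pAb = pA * (1 - pB), paB = (1 - pA) * pB,
         pab = (1 - pA) * (1 - pB))
  genoprob <- function(p) {
    m <- matrix(0, 3, 3)
    m[3, 3] <- p["pAB"]^2;             m[3, 2] <- 2 * p["pAB"] * p["pAb"]
    m[3, 1] <- p["pAb"]^2;             m[2, 3] <- 2 * p["pAB"] * p["paB"]
    m[2, 2] <- 2 * (p["pAB"] * p["pab"] + p["pAb"] * p["paB"])
    m[2, 1] <- 2 * p["pAb"] * p["pab"]; m[1, 3] <- p["paB"]^2
    m[1, 2] <- 2 * p["paB"] * p["pab"]; m[1, 1] <- p["pab"]^2
    m
  }
  ll <- function(p) {
    m <- genoprob(p)
    sum(cnt[cnt > 0] * log(m[cnt > 0]))
  }
  ll_old <- ll(p)
  for (it in seq_len(max_iter)) {
    denom <- p[["pAB"]] * p[["pab"]] + p[["pAb"]] * p[["paB"]]
    q <- if (denom > 0) p[["pAB"]] * p[["pab"]] / denom else 0.5
    nAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3] + cnt[2, 2] * q
    nAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1] + cnt[2, 2] * (1 - q)
    naB <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3] + cnt[2, 2] * (1 - q)
    nab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1] + cnt[2, 2] * q
    p <- c(pAB = nAB, pAb = nAb, paB = naB, pab = nab) / (2 * n)
    ll_new <- ll(p)
    delta <- abs(ll_new - ll_old)
    if (delta < tol) {
      return(list(freqs = p, loglik = ll_new, iterations = it, n_used = n))
    }
    ll_old <- ll_new
  }
  abort(sprintf("haplotype EM did not converge in %d iterations (last log-likelihood change %.3e)",
                max_iter, delta))
}

# r2, dprime and D from a haplotype-frequency vector; NA when a locus is
# monomorphic (denominator zero).
ld_from_hap_freqs <- function(p) {
  pA <- p["pAB"] + p["pAb"]; pB <- p["pAB"] + p["paB"]
  pa <- 1 - pA; pb <- 1 - pB
  D <- unname(p["pAB"] - pA * pB)
  denom <- pA * pa * pB * pb
  if (denom <= 0) return(list(r2 = NA_real_, dprime = NA_real_, D = D))
  dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  dprime <- if (D == 0) 0 else abs(D) / dmax
  list(r2 = unname(D^2 / denom), dprime = unname(min(dprime, 1)), D = D)
}

check_pairwise <- function(g1, g2, min_samples) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_samples) {
    abort(sprintf("only %d pairwise-complete samples (< %d required)",
                  sum(ok), min_samples))
  }
  ok
}

#' Pairwise r-squared between two SNPs
#'
#' Without phase, the squared Pearson correlation of the dosage vectors
#' (composite genotype r-squared). With phased haplotypes supplied, the
#' haplotype-frequency definition `D^2 / (pA pa pB pb)`.
#'
#' @param g1,g2 dosage vectors (0/1/2, `NA` allowed).
#' @param haps optional list of two phased binary haplotype vectors (two
#'   entries per sample) for the haplotype-based estimate.
#' @param min_samples minimum pairwise-complete samples (default 30).
#' @param on_monomorphic `"error"` (default) or `"na"`: r-squared is
#'   undefined when either SNP is monomorphic in the used samples; `"na"`
#'   returns the explicit `NA` marker so callers such as
#'   [interval_median_r2()] can exclude and count these pairs.
#' @return r-squared in `[0, 1]`, or `NA` under `on_monomorphic = "na"`.
#' @export
pairwise_r2 <- function(g1, g2, haps = NULL, min_samples = 30,
                        on_monomorphic = c("error", "na")) {
  on_monomorphic <- match.arg(on_monomorphic)
  if (!is.null(haps)) {
    res <- ld_from_hap_freqs(hap_freqs_phased(haps[[1]], haps[[2]]))$r2
    if (is.na(res) && on_monomorphic == "error") {
      abort("r-squared undefined: a SNP is monomorphic in the haplotype panel")
    }
    return(res)
  }
  ok <- check_pairwise(g1, g2, min_samples)
  v1 <- stats::var(g1[ok]); v2 <- stats::var(g2[ok])
  if (v1 == 0 || v2 == 0) {
    if (on_monomorphic == "error") {
      abort("r-squared undefined: monomorphic SNP in the used samples")
    }
    return(NA_real_)
  }
  cor(g1[ok], g2[ok])^2
}

#' Pairwise D-prime between two SNPs
#'
#' `|D| / Dmax` from haplotype frequencies: counted directly when phased
#' haplotypes are supplied, otherwise maximum-likelihood frequencies from
#' the unphased genotypes via [em_haplotype_freqs()].
#'
#' @inheritParams pairwise_r2
#' @return D-prime in `[0, 1]`, or `NA` under `on_monomorphic = "na"`.
#' @export
pairwise_dprime <- function(g1, g2, haps = NULL, min_samples = 30,
                            on_monomorphic = c("error", "na")) {
  on_monomorphic <- match.arg(on_monomorphic)
  if (!is.null(haps)) {
    p <- hap_freqs_phased(haps[[1]], haps[[2]])
  } else {
    ok <- check_pairwise(g1, g2, min_samples)
    p <- em_haplotype_freqs(g1[ok], g2[ok])$freqs
  }
  res <- ld_from_hap_freqs(p)$dprime
  if (is.na(res) && on_monomorphic == "error") {
    abort("D-prime undefined: monomorphic SNP in the used samples")
  }
  res
}

#' LD statistics for one SNP pair of a genotype matrix
#'
#' Convenience wrapper computing r-squared and D-prime for two SNPs of a
#' [genotype_matrix()], preferring phased haplotypes when the object
#' carries them.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @param min_samples minimum pairwise-complete samples (default 30).
#' @return One-row tibble `snp_a, snp_b, r2, dprime, n_used, method`;
#'   statistics are symmetric in the two SNPs.
#' @export
ld_pair <- function(geno, snp_a, snp_b, min_samples = 30) {
  g1 <- dosage_of(geno, snp_a); g2 <- dosage_of(geno, snp_b)
  haps <- NULL
  method <- "em_genotype"
  if (!is.null(geno$haplotypes)) {
    haps <- list(geno$haplotypes[, snp_a], geno$haplotypes[, snp_b])
    method <- "phased_counts"
  }
  n_used <- sum(!is.na(g1) & !is.na(g2))
  r2 <- if (is.null(haps)) {
    pairwise_r2(g1, g2, min_samples = min_samples)
  } else {
    pairwise_r2(g1, g2, haps = haps, min_samples = min_samples)
  }
  tibble(snp_a = snp_a, snp_b = snp_b, r2 = r2,
         dprime = pairwise_dprime(g1, g2, haps = haps, min_samples = min_samples),
         n_used = n_used, method = method)
}

#' Median pairwise r-squared of an interval
#'
#' Summary of the LD extent of a hotspot interval: the median over all
#' C(n, 2) pairwise genotype r-squared values among the interval's SNPs.
#' Pairs with undefined r-squared (monomorphic members) are excluded and
#' counted.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids ids of the interval's SNPs (at least 2 usable).
#' @param min_samples minimum pairwise-complete samples per pair.
#' @return One-row tibble `median_r2, n_snps, n_pairs_used, n_pairs_undefined`.
#' @export
interval_median_r2 <- function(geno, snp_ids, min_samples = 30) {
  if (length(snp_ids) < 2) abort("interval needs at least 2 SNPs for median r-squared")
  d <- dosage_of(geno, snp_ids, drop = FALSE)
  cc <- sum(complete.cases(d))
  if (cc < min_samples) {
    abort(sprintf("only %d complete samples (< %d required)", cc, min_samples))
  }
  suppressWarnings(cm <- cor(d, use = "pairwise.complete.obs"))
  r2 <- cm[upper.tri(cm)]^2
  n_undef <- sum(is.na(r2))
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0) abort("no SNP pair with defined r-squared in interval")
  tibble(median_r2 = median(r2), n_snps = length(snp_ids),
         n_pairs_used = length(r2), n_pairs_undefined = n_undef)
}
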