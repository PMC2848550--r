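# Midranks, Pearson-on-ranks Spearman, and the t approximation used for
# nominal P-values throughout the package.
spearman_rho_p <- function(gr, yr, n) {
  r <- suppressWarnings(cor(gr, yr))
  if (is.na(r)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(r) >= 1 - 1e-15) {
    return(c(rho = sign(r), p = .Machine$double.xmin))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(rho = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Spearman rank-correlation association of dosage and phenotype
#'
#' Rank correlation is the package's association statistic: it is robust
#' to outliers in expression values. Both vectors receive midranks for
#' ties; rho is the Pearson correlation of the ranks and the two-sided
#' nominal P-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. A perfect correlation
#' (`|rho| = 1`) gets the smallest positive double rather than zero. For
#' tiny samples an exact permutation P-value is available via
#' `exact = TRUE` (delegated to [stats::cor.test()]).
#'
#' @param dosages dosage vector (0/1/2, `NA` allowed).
#' @param phenotype numeric phenotype vector, same length.
#' @param min_samples minimum pairwise-complete samples (default 30).
#' @param exact use the exact null distribution instead of the t
#'   approximation (small n, no ties).
#' @return One-row tibble `rho, p_nominal, n_used`.
#' @export
spearman_assoc <- function(dosages, phenotype, min_samples = 30, exact = FALSE) {
  ok <- check_pairwise(dosages, phenotype, min_samples)
  g <- dosages[ok]; y <- phenotype[ok]
  if (stats::var(g) == 0) abort("dosage vector is monomorphic in the used samples")
  if (stats::var(y) == 0) abort("phenotype is constant in the used samples")
  n <- length(g)
  if (exact) {
    ct <- suppressWarnings(stats::cor.test(g, y, method = "spearman", exact = TRUE))
    return(tibble(rho = unname(ct$estimate),
                  p_nominal = max(ct$p.value, .Machine$double.xmin),
                  n_used = n))
  }
  rp <- spearman_rho_p(rank(g), rank(y), n)
  tibble(rho = rp[["rho"]], p_nominal = rp[["p"]], n_used = n)
}

#' Classify a SNP-gene pair as cis, trans, or excluded
#'
#' A SNP acts in cis on a gene when it lies within 1 Mb on either side of
#' the gene's transcription start site (boundary inclusive); in trans when
#' it lies on a different chromosome or at least 5 Mb from the TSS
#' (boundary inclusive). Same-chromosome pairs between the two windows are
#' excluded from both analyses.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle).
#' @param gene_chrom,gene_tss gene coordinates.
#' @param cis_window cis distance cutoff in bp (default 1e6).
#' @param trans_window trans distance cutoff in bp (default 5e6).
#' @return Character vector in `{"cis", "trans", "excluded"}`.
#' @export
assign_relation <- function(snp_chrom, snp_pos, gene_chrom, gene_tss,
                            cis_window = 1e6, trans_window = 5e6) {
  d <- abs(as.numeric(snp_pos) - as.numeric(gene_tss))
  same <- snp_chrom == gene_chrom
  dplyr::case_when(
    !same ~ "trans",
    d <= cis_window ~ "cis",
    d >= trans_window ~ "trans",
    TRUE ~ "excluded")
}

# Standardized midrank columns: each column of m ranked then scaled to
# zero mean / unit norm, so crossprod gives Spearman rho.
std_rank_cols <- function(m) {
  r <- apply(m, 2, rank)
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(m))
  r <- sweep(r, 2, colMeans(r))
  norms <- sqrt(colSums(r^2))
  norms[norms == 0] <- NA_real_
  sweep(r, 2, norms, "/")
}

# Spearman rho and P of one phenotype against every column of a complete
# dosage matrix (no NAs), vectorized.
spearman_vec <- function(G, y) {
  n <- length(y)
  zg <- std_rank_cols(G)
  zy <- std_rank_cols(matrix(y, ncol = 1))
  rho <- as.vector(crossprod(zg, zy))
  p <- ifelse(abs(rho) >= 1 - 1e-15, .Machine$double.xmin,
              2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
  list(rho = rho, p = p)
}

#' All SNP-gene associations in a relation mode
#'
#' Computes Spearman associations for every SNP-gene pair in the requested
#' relation (cis, trans, or both), returning a long tibble. Intended for
#' the synthetic-scale panels this package analyses and simulates.
#'
#' @param geno a [genotype_matrix()].
#' @param expr a normalized [expression_matrix()] on the same samples
#'   (intersected automatically).
#' @param mode `"cis"`, `"trans"`, or `"all"` (both, excluded pairs
#'   dropped).
#' @param min_samples minimum pairwise-complete samples per test.
#' @inheritParams assign_relation
#' @return Tibble `snp_id, gene_id, relation, rho, p_nominal, n_used`.
#' @export
map_associations <- function(geno, expr, mode = c("cis", "trans", "all"),
                             min_samples = 30, cis_window = 1e6,
                             trans_window = 5e6) {
  mode <- match.arg(mode)
  m <- match_samples(geno, expr)
  geno <- m$geno; expr <- m$expr
  pairs <- tidyr::crossing(snp_id = geno$snps$snp_id,
                           gene_id = expr$genes$gene_id) |>
    left_join(geno$snps |> select("snp_id", snp_chrom = "chrom", pos = "pos"),
              by = "snp_id") |>
    left_join(expr$genes |> select("gene_id", gene_chrom = "chrom", tss = "tss"),
              by = "gene_id") |>
    mutate(relation = assign_relation(.data$snp_chrom, .data$pos,
                                      .data$gene_chrom, .data$tss,
                                      cis_window, trans_window))
  keep <- if (mode == "all") c("cis", "trans") else mode
  pairs <- filter(pairs, .data$relation %in% keep)
  if (nrow(pairs) == 0) {
    return(tibble(snp_id = character(), gene_id = character(),
                  relation = character(), rho = double(),
                  p_nominal = double(), n_used = integer()))
  }
  res <- pairs |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      y <- expr$values[, key$gene_id]
      purrr::map(df$snp_id, function(s) {
        a <- spearman_assoc(dosage_of(geno, s), y, min_samples = min_samples)
        mutate(a, snp_id = s)
      }) |>
        list_rbind() |>
        left_join(df |> select("snp_id", "relation"), by = "snp_id")
    }) |>
    ungroup() |>
    select("snp_id", "gene_id", "relation", "rho", "p_nominal", "n_used")
  res
}

#' Permutation threshold for a gene's minimum association P-value
#'
#' Null distribution of the gene's best nominal P-value: in each
#' permutation round the phenotype values are shuffled across samples (the
#' same shuffle applied against every candidate SNP, preserving inter-SNP
#' LD) and the minimal Spearman P over the candidate set is recorded. The
#' threshold is the lower `tail` quantile of the permutation minima by
#' order statistic: the `ceiling(tail * n_perm)`-th smallest minimum.
#'
#' @param phenotype numeric phenotype vector.
#' @param dosages samples x SNPs dosage matrix of the gene's candidate
#'   SNPs (complete cases used).
#' @param n_perm number of permutations (>= 100; the reference analysis
#'   used 10,000).
#' @param tail tail probability of the minimum-P null (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param min_samples minimum complete samples.
#' @return One-row tibble `perm_threshold, n_permutations, tail, n_snps`.
#' @export
permutation_threshold <- function(phenotype, dosages, n_perm = 10000L,
                                  tail = 0.05, seed = 1L, min_samples = 30) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, ncol = 1)
  if (ncol(dosages) < 1) abort("at least one candidate SNP required")
  stopifnot(n_perm >= 100, tail > 0, tail < 1)
  ok <- complete.cases(dosages) & !is.na(phenotype)
  if (sum(ok) < min_samples) {
    abort(sprintf("only %d complete samples (< %d required)", sum(ok), min_samples))
  }
  G <- dosages[ok, , drop = FALSE]
  y <- phenotype[ok]
  n <- length(y)
  zg <- std_rank_cols(G)
  poly <- !is.na(colSums(zg))
  if (!any(poly)) abort("all candidate SNPs monomorphic")
  zg <- zg[, poly, drop = FALSE]
  yr <- rank(y)
  yr <- (yr - mean(yr)) / sqrt(sum((yr - mean(yr))^2))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  P <- withr_seed(replicate(n_perm, sample.int(n)))
  ZY <- matrix(yr[P], nrow = n)  # each column a permuted standardized rank vector
  rho <- crossprod(zg, ZY)
  rho <- pmin(pmax(rho, -1), 1)
  pmat <- ifelse(abs(rho) >= 1 - 1e-15, .Machine$double.xmin,
                 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
  minima <- apply(pmat, 2, min)
  k <- ceiling(tail * n_perm)
  tibble(perm_threshold = sort(minima)[k], n_permutations = as.integer(n_perm),
         tail = tail, n_snps = sum(poly))
}

#' Per-gene cis eQTL calls with permutation significance
#'
#' For every gene: take its cis-window SNPs, pick the best SNP by minimal
#' nominal Spearman P (ties broken deterministically by smallest genomic
#' position), compute the gene's permutation threshold, and flag the gene
#' significant when the best nominal P is at or below the threshold. Genes
#' without cis SNPs are emitted unscored and non-significant.
#'
#' @inheritParams map_associations
#' @param n_perm,tail,seed see [permutation_threshold()]; per-gene
#'   permutation seeds are derived deterministically from `seed`.
#' @return Tibble of class `eqtl_calls`: `gene_id, best_snp_id, rho,
#'   p_nominal, perm_threshold, n_permutations, tail, n_cis_snps,
#'   significant`.
#' @export
call_cis_eqtls <- function(geno, expr, n_perm = 10000L, tail = 0.05,
                           seed = 1L, min_samples = 30, cis_window = 1e6) {
  m <- match_samples(geno, expr)
  geno <- m$geno; expr <- m$expr
  out <- purrr::imap(setNames(expr$genes$gene_id, expr$genes$gene_id), function(gid, nm) {
    i <- match(gid, expr$genes$gene_id)
    rel <- assign_relation(geno$snps$chrom, geno$snps$pos,
                           expr$genes$chrom[i], expr$genes$tss[i],
                           cis_window = cis_window)
    cis_ids <- geno$snps$snp_id[rel == "cis"]
    empty <- tibble(gene_id = gid, best_snp_id = NA_character_,
                    rho = NA_real_, p_nominal = NA_real_,
                    perm_threshold = NA_real_,
                    n_permutations = as.integer(n_perm), tail = tail,
                    n_cis_snps = length(cis_ids), significant = FALSE)
    if (length(cis_ids) == 0) return(empty)
    y <- expr$values[, gid]
    G <- dosage_of(geno, cis_ids, drop = FALSE)
    ok <- complete.cases(G) & !is.na(y)
    if (sum(ok) < min_samples) return(empty)
    sv <- spearman_vec(G[ok, , drop = FALSE], y[ok])
    usable <- !is.na(sv$p)
    if (!any(usable)) return(empty)
    pos <- geno$snps$pos[match(cis_ids, geno$snps$snp_id)]
    cand <- which(usable & sv$p == min(sv$p[usable]))
    best <- cand[which.min(pos[cand])]
    gene_seed <- (as.integer(seed) + i * 7919L) %% .Machine$integer.max
    thr <- permutation_threshold(y[ok], G[ok, usable, drop = FALSE],
                                 n_perm = n_perm, tail = tail,
                                 seed = gene_seed, min_samples = min_samples)
    tibble(gene_id = gid, best_snp_id = cis_ids[best], rho = sv$rho[best],
           p_nominal = sv$p[best], perm_threshold = thr$perm_threshold,
           n_permutations = as.integer(n_perm), tail = tail,
           n_cis_snps = length(cis_ids),
           significant = sv$p[best] <= thr$perm_threshold)
  })
  res <- list_rbind(out)
  class(res) <- c("eqtl_calls", class(res))
  res
}

#' Residualize a phenotype on a correcting SNP
#'
#' Ordinary least squares of the phenotype on the correcting dosage with
#' intercept; returns the residuals, the "corrected phenotype" used by the
#' concordance score. Residuals have zero Pearson correlation with the
#' correcting dosage by construction.
#'
#' @param phenotype numeric phenotype vector.
#' @param dosages correcting SNP's dosage vector (must be polymorphic).
#' @return Numeric residual vector aligned to the input (NA where either
#'   input was missing).
#' @export
residualize <- function(phenotype, dosages) {
  ok <- !is.na(phenotype) & !is.na(dosages)
  if (stats::var(dosages[ok]) == 0) {
    abort("correcting SNP is constant in the used samples (collinear with intercept)")
  }
  fit <- lm.fit(cbind(1, dosages[ok]), phenotype[ok])
  out <- rep(NA_real_, length(phenotype))
  out[ok] <- fit$residuals
  names(out) <- names(phenotype)
  out
}

# adjusted R^2 of a simple linear regression y ~ g
adj_r2 <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  fit <- lm.fit(cbind(1, g), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  1 - (rss / (n - 2)) / (tss / (n - 1))
}

#' Ratio of eQTL variance explained after vs before dSNP correction
#'
#' Diagnostic contrasting the adjusted R-squared of the eQTL regression on
#' the original phenotype ("before") with the same regression on the
#' phenotype residualized for the disease SNP ("after"). A ratio near 0
#' means the disease SNP explains away the eQTL signal (shared effect); a
#' ratio near 1 means the correction removed nothing. Negative adjusted
#' R-squared values are floored at 0 before forming the ratio; a zero
#' "before" yields the undefined marker `NA`.
#'
#' @param phenotype numeric phenotype vector.
#' @param eqtl_dosages eQTL SNP dosages.
#' @param dsnp_dosages disease (GWAS) SNP dosages.
#' @return One-row tibble `r2_before, r2_after, variance_ratio`.
#' @export
variance_ratio <- function(phenotype, eqtl_dosages, dsnp_dosages) {
  before <- max(0, adj_r2(phenotype, eqtl_dosages))
  resid <- residualize(phenotype, dsnp_dosages)
  after <- max(0, adj_r2(resid, eqtl_dosages))
  tibble(r2_before = before, r2_after = after,
         variance_ratio = if (before == 0) NA_real_ else after / before)
}
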