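#' Best association P-value per SNP
#'
#' Reduces a long association table to one minimal nominal P-value per
#' SNP within the requested relation mode; SNPs with no tested gene in
#' that mode are omitted (count logged).
#'
#' @param assoc tibble from [map_associations()].
#' @param mode `"cis"` or `"trans"`.
#' @return Tibble `snp_id, best_p, n_genes_tested`.
#' @export
best_p_per_snp <- function(assoc, mode = c("cis", "trans")) {
  mode <- match.arg(mode)
  all_snps <- unique(assoc$snp_id)
  out <- assoc |>
    filter(.data$relation == mode) |>
    group_by(.data$snp_id) |>
    summarise(best_p = min(.data$p_nominal), n_genes_tested = n(),
              .groups = "drop")
  omitted <- length(all_snps) - nrow(out)
  if (omitted > 0) {
    rtc_log(sprintf("best_p_per_snp: %d SNP(s) with no %s test omitted",
                    omitted, mode))
  }
  out
}

maf_bin <- function(maf, bin_width) {
  # bins over (0, 0.5]; bin k covers ((k-1)*w, k*w]
  pmax(ceiling(maf / bin_width), 1L)
}

#' MAF-matched random SNP sets
#'
#' Draws `n_sets` random SNP sets from a pool such that each set
#' reproduces the target set's minor-allele-frequency histogram exactly
#' (bins of width `bin_width` over (0, 0.5]): for every occupied target
#' bin, as many pool SNPs as targets are sampled, with replacement.
#'
#' @param targets tibble with columns `snp_id`, `maf` (the GWAS SNPs).
#' @param pool tibble with columns `snp_id`, `maf`, disjoint from the
#'   targets.
#' @param n_sets number of sets (default 1000).
#' @param bin_width MAF bin width (default 0.01).
#' @param seed RNG seed.
#' @return List of `n_sets` character vectors, each of length
#'   `nrow(targets)`.
#' @export
sample_maf_matched_sets <- function(targets, pool, n_sets = 1000L,
                                    bin_width = 0.01, seed = 1L) {
  stopifnot(all(c("snp_id", "maf") %in% names(targets)),
            all(c("snp_id", "maf") %in% names(pool)), n_sets >= 1)
  overlap <- intersect(targets$snp_id, pool$snp_id)
  if (length(overlap) > 0) {
    abort(paste0("pool must be disjoint from targets; shared: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  tb <- maf_bin(targets$maf, bin_width)
  pb <- maf_bin(pool$maf, bin_width)
  need <- table(tb)
  empty <- setdiff(names(need), unique(as.character(pb)))
  if (length(empty) > 0) {
    lo <- (as.integer(empty) - 1) * bin_width
    abort(sprintf("no pool SNP in occupied MAF bin(s): %s",
                  paste(sprintf("(%.3g, %.3g]", lo, lo + bin_width),
                        collapse = ", ")))
  }
  pool_by_bin <- split(pool$snp_id, pb)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    unlist(lapply(names(need), function(b) {
      sample(pool_by_bin[[b]], need[[b]], replace = TRUE)
    }), use.names = FALSE)
  })
}

#' Median QQ curves with an upper confidence band
#'
#' Builds the observed-versus-null QQ comparison for best-P sets: the
#' observed curve is the sorted `-log10` P of the target set; the expected
#' curve is the pointwise median across the null sets' sorted curves; the
#' confidence bound is the pointwise `ci_level` quantile across
#' `n_ci_pairs` null curves (resampled with replacement from the provided
#' null sets when more pairs are requested than sets supplied). P-values
#' are floored at the smallest positive double before the log transform.
#'
#' @param observed_p numeric vector of the target SNPs' best P-values.
#' @param null_p list of numeric vectors, one per null set.
#' @param ci_level confidence level of the upper bound (default 0.95).
#' @param n_ci_pairs number of null curves behind the bound (default
#'   10000).
#' @param seed RNG seed for the resampling.
#' @return Tibble of class `qq_curves`: `quantile_index, observed,
#'   null_median, ci_upper` (all `-log10` scale, ascending), with
#'   attributes `n_sets` and `n_snps_per_set`.
#' @export
qq_median_ci <- function(observed_p, null_p, ci_level = 0.95,
                         n_ci_pairs = 10000L, seed = 1L) {
  if (length(null_p) < 2) abort("at least 2 null sets required")
  len <- min(length(observed_p), vapply(null_p, length, integer(1)))
  if (len < 1) abort("empty P-value set")
  top_neglog <- function(p) {
    x <- sort(-log10(pmax(p, .Machine$double.xmin)), decreasing = TRUE)
    sort(x[seq_len(len)])  # most significant `len` values, ascending
  }
  obs <- top_neglog(observed_p)
  null_mat <- vapply(null_p, top_neglog, numeric(len))  # len x n_sets
  null_median <- apply(null_mat, 1, median)
  set.seed(seed)
  idx <- if (n_ci_pairs <= ncol(null_mat)) seq_len(n_ci_pairs) else
    sample.int(ncol(null_mat), n_ci_pairs, replace = TRUE)
  ci_upper <- apply(null_mat[, idx, drop = FALSE], 1, quantile,
                    probs = ci_level, names = FALSE)
  out <- tibble(quantile_index = seq_len(len), observed = obs,
                null_median = null_median,
                ci_upper = pmax(ci_upper, null_median))
  attr(out, "n_sets") <- length(null_p)
  attr(out, "n_snps_per_set") <- len
  class(out) <- c("qq_curves", class(out))
  out
}

#' Fisher test for immunity-stratified enrichment of high scores
#'
#' Two-sided Fisher exact test on the 2x2 table of best RTC score per GWAS
#' SNP (at or above `rtc_threshold` versus below) against the
#' immunity-relatedness of the SNP's trait.
#'
#' @param scores tibble with one row per GWAS SNP, columns `best_rtc` and
#'   `immunity_related` (logical); e.g. derived from [rtc_cis_scan()]
#'   output.
#' @param rtc_threshold score cutoff (default 0.9).
#' @return One-row tibble `odds_ratio, p_value, n_immunity, n_other,
#'   n_high_immunity, n_high_other`.
#' @export
immunity_enrichment_test <- function(scores, rtc_threshold = 0.9) {
  stopifnot(all(c("best_rtc", "immunity_related") %in% names(scores)))
  imm <- as.logical(scores$immunity_related)
  if (!any(imm) || all(imm)) abort("both immunity strata must be non-empty")
  high <- scores$best_rtc >= rtc_threshold
  tab <- table(factor(imm, levels = c(TRUE, FALSE)),
               factor(high, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         n_immunity = sum(imm), n_other = sum(!imm),
         n_high_immunity = sum(imm & high), n_high_other = sum(!imm & high))
}
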