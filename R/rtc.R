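#' Adjusted eQTL association P-value after correcting for a SNP
#'
#' The phenotype is residualized on the correcting SNP (ordinary least
#' squares with intercept) and the Spearman association of the eQTL dosage
#' with the corrected phenotype is recomputed; the adjusted P-value
#' quantifies how much eQTL signal the correction leaves behind.
#'
#' @param phenotype numeric phenotype vector.
#' @param eqtl_dosages eQTL SNP dosage vector.
#' @param correcting_dosages dosage vector of the SNP corrected for.
#' @param min_samples minimum pairwise-complete samples.
#' @return One-row tibble `rho_adjusted, p_adjusted, n_used`.
#' @export
corrected_pvalue <- function(phenotype, eqtl_dosages, correcting_dosages,
                             min_samples = 30) {
  res <- residualize(phenotype, correcting_dosages)
  a <- spearman_assoc(eqtl_dosages, res, min_samples = min_samples)
  tibble(rho_adjusted = a$rho, p_adjusted = a$p_nominal, n_used = a$n_used)
}

# Adjusted P for the eQTL against corrections by every column of G.
# Complete-case fast path (no NAs) vectorizes the residual regressions and
# the rank correlations; otherwise falls back to corrected_pvalue per SNP.
rtc_sweep_padj <- function(y, g_eqtl, G, min_samples) {
  if (anyNA(y) || anyNA(g_eqtl) || anyNA(G)) {
    return(vapply(seq_len(ncol(G)), function(j) {
      corrected_pvalue(y, g_eqtl, G[, j], min_samples = min_samples)$p_adjusted
    }, numeric(1)))
  }
  n <- length(y)
  if (n < min_samples) abort(sprintf("only %d samples (< %d required)", n, min_samples))
  yc <- y - mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  ss <- colSums(Gc^2)
  beta <- colSums(Gc * yc) / ss
  R <- yc - sweep(Gc, 2, beta, "*")  # residual per correcting SNP, by column
  zr <- std_rank_cols(R)
  ge <- rank(g_eqtl)
  ge <- (ge - mean(ge)) / sqrt(sum((ge - mean(ge))^2))
  rho <- as.vector(crossprod(zr, ge))
  ifelse(abs(rho) >= 1 - 1e-15, .Machine$double.xmin,
         2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
}

#' Regulatory Trait Concordance score for one eQTL / GWAS SNP pair
#'
#' Core scoring scheme. Every usable SNP in the hotspot interval
#' (including the eQTL SNP and the GWAS SNP themselves) is used in turn to
#' correct the phenotype, and the eQTL association is re-tested on each
#' corrected phenotype. A larger adjusted P-value means the correction
#' removed more of the eQTL signal, i.e. a higher correction impact. The
#' GWAS SNP's rank is the number of other interval SNPs with strictly
#' higher impact (ties do not increase the rank), and
#' `RTC = (N_SNPs - Rank) / N_SNPs`, in `(0, 1]`, with values near 1
#' indicating that the GWAS SNP and the eQTL tag the same functional
#' variant. SNPs whose correction fails (constant dosage) are excluded
#' from both the sweep and `N_SNPs` and logged.
#'
#' @param geno a [genotype_matrix()].
#' @param interval_snps character vector of SNP ids belonging to the
#'   hotspot interval (must contain `eqtl_snp` and `gwas_snp`; at least 2
#'   usable SNPs).
#' @param eqtl_snp id of the eQTL SNP.
#' @param gwas_snp id of the GWAS (disease) SNP.
#' @param phenotype normalized expression vector for the eQTL gene,
#'   aligned to `geno` samples.
#' @param min_samples minimum complete samples.
#' @param interval_id,gene_id optional labels carried into the result.
#' @param dump_sweep attach the full per-SNP sweep (`attr(x, "sweep")`).
#' @return One-row tibble of class `rtc_result`: `interval_id, gene_id,
#'   eqtl_snp, gwas_snp, n_snps, rank, rtc, p_adjusted_gwas, r2_eqtl_dsnp,
#'   dprime_eqtl_dsnp, variance_ratio`.
#' @export
rtc_score <- function(geno, interval_snps, eqtl_snp, gwas_snp, phenotype,
                      min_samples = 30, interval_id = NA_character_,
                      gene_id = NA_character_, dump_sweep = FALSE) {
  interval_snps <- unique(interval_snps)
  if (!eqtl_snp %in% interval_snps) abort("eqtl_snp is not in the interval SNP set")
  if (!gwas_snp %in% interval_snps) abort("gwas_snp is not in the interval SNP set")
  G <- dosage_of(geno, interval_snps, drop = FALSE)
  y <- phenotype
  g_eqtl <- dosage_of(geno, eqtl_snp)
  # usable = polymorphic among samples complete for (y, eqtl); correction
  # for a constant dosage is collinear with the intercept and fails
  ok <- !is.na(y) & !is.na(g_eqtl)
  usable <- vapply(seq_len(ncol(G)), function(j) {
    v <- G[ok & !is.na(G[, j]), j]
    length(v) >= min_samples && stats::var(v) > 0
  }, logical(1))
  dropped <- interval_snps[!usable]
  if (length(dropped) > 0) {
    rtc_log(sprintf("rtc_score: excluded %d unusable SNP(s) from the sweep: %s",
                    length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  sweep_ids <- interval_snps[usable]
  if (!gwas_snp %in% sweep_ids) abort("gwas_snp correction failed (unusable dosages)")
  if (length(sweep_ids) < 2) abort("fewer than 2 usable SNPs in interval")
  cc <- ok & complete.cases(G[, sweep_ids, drop = FALSE])
  p_adj <- rtc_sweep_padj(y[cc], g_eqtl[cc], G[cc, sweep_ids, drop = FALSE],
                          min_samples)
  names(p_adj) <- sweep_ids
  n_snps <- length(sweep_ids)
  rank_gwas <- sum(p_adj[sweep_ids != gwas_snp] > p_adj[[gwas_snp]])
  g_dsnp <- dosage_of(geno, gwas_snp)
  ld <- ld_pair(geno, eqtl_snp, gwas_snp, min_samples = min_samples)
  vr <- variance_ratio(y, g_eqtl, g_dsnp)
  out <- tibble(
    interval_id = interval_id, gene_id = gene_id,
    eqtl_snp = eqtl_snp, gwas_snp = gwas_snp,
    n_snps = n_snps, rank = as.integer(rank_gwas),
    rtc = (n_snps - rank_gwas) / n_snps,
    p_adjusted_gwas = unname(p_adj[[gwas_snp]]),
    r2_eqtl_dsnp = ld$r2, dprime_eqtl_dsnp = ld$dprime,
    variance_ratio = vr$variance_ratio)
  class(out) <- c("rtc_result", class(out))
  if (dump_sweep) {
    attr(out, "sweep") <- tibble(snp_id = sweep_ids, p_adjusted = unname(p_adj)) |>
      arrange(desc(.data$p_adjusted))
  }
  out
}

#' Genome scan: RTC scores for cis-colocalized GWAS SNPs and eQTLs
#'
#' For every hotspot interval containing at least one catalog GWAS SNP and
#' at least one significant cis eQTL (its best SNP mapping into the same
#' interval), scores every (GWAS SNP, eQTL gene) combination. Multiple
#' GWAS SNPs in one interval and multiple eQTL genes per interval each get
#' their own rows.
#'
#' @param geno a [genotype_matrix()].
#' @param expr a normalized [expression_matrix()].
#' @param intervals a [hotspot_intervals()] set.
#' @param gwas_catalog tibble from [read_gwas_catalog()].
#' @param eqtl_calls tibble from [call_cis_eqtls()].
#' @param min_samples minimum complete samples.
#' @param rtc_min report filter on the score (default 0, everything; 0.9
#'   is the stringent discovery cutoff).
#' @return Tibble of `rtc_result` rows sorted by descending score, plus
#'   `trait`, `immunity_related` (any trait of the SNP) and
#'   `best_rtc_for_gwas`, the per-GWAS-SNP best score across genes.
#' @export
rtc_cis_scan <- function(geno, expr, intervals, gwas_catalog, eqtl_calls,
                         min_samples = 30, rtc_min = 0) {
  m <- match_samples(geno, expr)
  geno <- m$geno; expr <- m$expr
  assignment <- assign_snps_to_intervals(geno$snps, intervals)
  snp_int <- setNames(assignment$interval_id, assignment$snp_id)
  gwas_in <- gwas_catalog |>
    dplyr::distinct(.data$snp_id) |>
    filter(.data$snp_id %in% names(snp_int)) |>
    mutate(interval_id = unname(snp_int[.data$snp_id])) |>
    filter(!is.na(.data$interval_id))
  sig <- eqtl_calls |>
    filter(.data$significant, !is.na(.data$best_snp_id)) |>
    mutate(interval_id = unname(snp_int[.data$best_snp_id])) |>
    filter(!is.na(.data$interval_id))
  shared <- intersect(gwas_in$interval_id, sig$interval_id)
  rows <- purrr::map(shared, function(iid) {
    snps_here <- assignment$snp_id[!is.na(assignment$interval_id) &
                                     assignment$interval_id == iid]
    combos <- tidyr::crossing(
      gwas_snp = gwas_in$snp_id[gwas_in$interval_id == iid],
      gene_id = sig$gene_id[sig$interval_id == iid])
    purrr::pmap(combos, function(gwas_snp, gene_id) {
      eqtl <- sig$best_snp_id[sig$gene_id == gene_id][1]
      rtc_score(geno, snps_here, eqtl, gwas_snp,
                expr$values[, gene_id], min_samples = min_samples,
                interval_id = iid, gene_id = gene_id)
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(interval_id = character(), gene_id = character(),
                  eqtl_snp = character(), gwas_snp = character(),
                  n_snps = integer(), rank = integer(), rtc = double(),
                  p_adjusted_gwas = double(), r2_eqtl_dsnp = double(),
                  dprime_eqtl_dsnp = double(), variance_ratio = double(),
                  trait = character(), immunity_related = logical(),
                  best_rtc_for_gwas = double()))
  }
  traits <- gwas_catalog |>
    group_by(.data$snp_id) |>
    summarise(trait = paste(sort(unique(.data$trait)), collapse = ";"),
              immunity_related = any(.data$immunity_related), .groups = "drop")
  rows |>
    left_join(traits, by = c(gwas_snp = "snp_id")) |>
    group_by(.data$gwas_snp) |>
    mutate(best_rtc_for_gwas = max(.data$rtc)) |>
    ungroup() |>
    filter(.data$rtc >= rtc_min) |>
    arrange(desc(.data$rtc))
}

#' Genome scan: RTC scores for trans eQTLs in top GWAS intervals
#'
#' All intervals containing a catalog GWAS SNP are ranked by their most
#' significant trans association (any interval SNP against any gene
#' genome-wide); the `top_k` intervals are retained and, within each,
#' every gene whose best trans P-value in the interval is below
#' `p_trans_max` is scored against each GWAS SNP of the interval, using
#' the gene's best interval SNP as the eQTL.
#'
#' @inheritParams rtc_cis_scan
#' @param top_k number of top intervals to keep (default 50).
#' @param p_trans_max nominal trans P-value filter for scored genes
#'   (default 1e-5).
#' @return As [rtc_cis_scan()], with an extra `p_trans` column.
#' @export
rtc_trans_scan <- function(geno, expr, intervals, gwas_catalog,
                           top_k = 50L, p_trans_max = 1e-5,
                           min_samples = 30, rtc_min = 0) {
  stopifnot(top_k >= 1, p_trans_max > 0, p_trans_max < 1)
  m <- match_samples(geno, expr)
  geno <- m$geno; expr <- m$expr
  assignment <- assign_snps_to_intervals(geno$snps, intervals)
  snp_int <- setNames(assignment$interval_id, assignment$snp_id)
  gwas_in <- gwas_catalog |>
    dplyr::distinct(.data$snp_id) |>
    filter(.data$snp_id %in% names(snp_int)) |>
    mutate(interval_id = unname(snp_int[.data$snp_id])) |>
    filter(!is.na(.data$interval_id))
  if (nrow(gwas_in) == 0) return(tibble())
  gwas_int_ids <- unique(gwas_in$interval_id)
  scan_snps <- assignment$snp_id[assignment$interval_id %in% gwas_int_ids &
                                   !is.na(assignment$interval_id)]
  assoc <- map_associations(subset_genotypes(geno, snp_ids = scan_snps),
                            expr, mode = "trans", min_samples = min_samples) |>
    mutate(interval_id = unname(snp_int[.data$snp_id]))
  if (nrow(assoc) == 0) return(tibble())
  int_rank <- assoc |>
    group_by(.data$interval_id) |>
    summarise(min_p = min(.data$p_nominal), .groups = "drop") |>
    arrange(.data$min_p)
  if (top_k > nrow(int_rank)) {
    warn(sprintf("top_k = %d exceeds the %d intervals with trans tests; using all",
                 top_k, nrow(int_rank)))
    top_k <- nrow(int_rank)
  }
  keep_int <- int_rank$interval_id[seq_len(top_k)]
  rows <- purrr::map(keep_int, function(iid) {
    snps_here <- assignment$snp_id[!is.na(assignment$interval_id) &
                                     assignment$interval_id == iid]
    best_by_gene <- assoc |>
      filter(.data$interval_id == iid) |>
      group_by(.data$gene_id) |>
      slice_min(.data$p_nominal, n = 1, with_ties = FALSE) |>
      ungroup() |>
      filter(.data$p_nominal < p_trans_max)
    if (nrow(best_by_gene) == 0) return(NULL)
    combos <- tidyr::crossing(
      gwas_snp = gwas_in$snp_id[gwas_in$interval_id == iid],
      gene_id = best_by_gene$gene_id)
    purrr::pmap(combos, function(gwas_snp, gene_id) {
      row <- best_by_gene[best_by_gene$gene_id == gene_id, ]
      rtc_score(geno, snps_here, row$snp_id, gwas_snp,
                expr$values[, gene_id], min_samples = min_samples,
                interval_id = iid, gene_id = gene_id) |>
        mutate(p_trans = row$p_nominal)
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) return(tibble())
  traits <- gwas_catalog |>
    group_by(.data$snp_id) |>
    summarise(trait = paste(sort(unique(.data$trait)), collapse = ";"),
              immunity_related = any(.data$immunity_related), .groups = "drop")
  rows |>
    left_join(traits, by = c(gwas_snp = "snp_id")) |>
    group_by(.data$gwas_snp) |>
    mutate(best_rtc_for_gwas = max(.data$rtc)) |>
    ungroup() |>
    filter(.data$rtc >= rtc_min) |>
    arrange(desc(.data$rtc))
}

#' Expected number of high-scoring intervals under a uniform score null
#'
#' Under the null of no shared functional variants the score is uniform on
#' (0, 1], so among `n_intervals` tested intervals one expects
#' `n_intervals * (1 - rtc_min)` to score at or above `rtc_min` by chance.
#' Used to calibrate how many reported discoveries exceed chance.
#'
#' @param n_intervals number of scored intervals.
#' @param rtc_min score cutoff (default 0.9, the top decile).
#' @return Expected chance count (numeric).
#' @export
expected_high_rtc_count <- function(n_intervals, rtc_min = 0.9) {
  stopifnot(n_intervals >= 0, rtc_min > 0, rtc_min <= 1)
  n_intervals * (1 - rtc_min)
}

#' Adjust a perfect-score count for genotyping-density imbalance
#'
#' When the GWAS-side panel is genotyped `density_ratio` times less
#' densely than the eQTL panel, perfect concordance (both proxies being
#' the identical typed SNP) is underobserved by about that factor; the
#' expected count under equal density is the observed count scaled up.
#'
#' @param n_observed observed count of perfect-scoring pairs.
#' @param density_ratio ratio of the denser to the sparser SNP panel
#'   (e.g. ~3 for 1.2M vs 0.4M typed SNPs).
#' @return Density-adjusted expected count.
#' @export
density_adjusted_count <- function(n_observed, density_ratio) {
  stopifnot(n_observed >= 0, density_ratio > 0)
  n_observed * density_ratio
}
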