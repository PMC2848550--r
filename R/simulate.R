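#' Simulate an LD-structured phased haplotype panel for one interval
#'
#' Founder-mosaic model: a small pool of founder haplotypes is drawn as
#' independent binary sequences (per-SNP allele frequencies uniform on
#' (0.1, 0.9)), and each panel haplotype copies a founder, switching to a
#' random founder between adjacent SNPs with probability `switch_rate`.
#' Few founders and low switch rates give long shared blocks (high LD);
#' many founders or rates near 1 give near-independent SNPs. SNPs whose
#' panel MAF falls below `maf_min` are dropped. Fully deterministic under
#' `seed`.
#'
#' @param n_founders number of founder haplotypes (>= 2; default 5,
#'   matching the low common-haplotype diversity of hotspot-delimited
#'   blocks).
#' @param n_haplotypes panel haplotypes, two per diploid sample (default
#'   218, i.e. 109 diploids).
#' @param n_snps SNPs before the MAF filter (default 50).
#' @param switch_rate per-adjacent-SNP founder switch probability, in
#'   (0, 1) (default 0.05).
#' @param maf_min panel MAF cutoff (default 0.05).
#' @param seed RNG seed.
#' @param chrom chromosome label (default `"sim1"`).
#' @param spacing bp between adjacent SNPs (default 1000).
#' @return List with `geno` (a phased [genotype_matrix()]) and `interval`
#'   (a one-row [hotspot_intervals()] spanning all simulated positions).
#' @export
simulate_haplotype_pool <- function(n_founders = 5L, n_haplotypes = 218L,
                                    n_snps = 50L, switch_rate = 0.05,
                                    maf_min = 0.05, seed = 1L,
                                    chrom = "sim1", spacing = 1000L) {
  stopifnot(n_founders >= 2, switch_rate > 0, switch_rate < 1,
            n_haplotypes >= 2, n_haplotypes %% 2 == 0, n_snps >= 2)
  set.seed(seed)
  freqs <- runif(n_snps, 0.1, 0.9)
  founders <- matrix(rbinom(n_founders * n_snps, 1L, rep(freqs, each = n_founders)),
                     nrow = n_founders)
  fid <- matrix(0L, nrow = n_haplotypes, ncol = n_snps)
  fid[, 1] <- sample.int(n_founders, n_haplotypes, replace = TRUE)
  for (j in 2:n_snps) {
    switch <- runif(n_haplotypes) < switch_rate
    fid[, j] <- ifelse(switch, sample.int(n_founders, n_haplotypes, replace = TRUE),
                       fid[, j - 1])
  }
  hap <- matrix(founders[cbind(as.vector(fid), rep(seq_len(n_snps), each = n_haplotypes))],
                nrow = n_haplotypes)
  dos <- hap[seq(1, n_haplotypes, 2), , drop = FALSE] +
    hap[seq(2, n_haplotypes, 2), , drop = FALSE]
  maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  keep <- which(maf >= maf_min)
  if (length(keep) == 0) abort("all simulated SNPs fell below the MAF cutoff")
  snps <- tibble(snp_id = sprintf("sim%03d", keep), chrom = chrom,
                 pos = keep * spacing, ref = "A", alt = "G")
  rownames(dos) <- sprintf("ind%03d", seq_len(n_haplotypes / 2))
  geno <- genotype_matrix(dos[, keep, drop = FALSE], snps,
                          haplotypes = hap[, keep, drop = FALSE])
  interval <- hotspot_intervals(tibble(
    interval_id = paste0("hs_", chrom), chrom = chrom, start = 1L,
    end = n_snps * spacing + 1L))
  list(geno = geno, interval = interval)
}

#' Simulate an expression phenotype from a causal SNP
#'
#' Additive single-SNP model: `y = beta * dosage + Normal(0, noise_sd)`.
#'
#' @param geno a [genotype_matrix()].
#' @param causal_snp id of the causal SNP (must be polymorphic).
#' @param beta additive effect per alternate allele (default 1).
#' @param noise_sd residual standard deviation (>= 0; default 1).
#' @param seed RNG seed.
#' @return Named numeric phenotype vector aligned to the samples.
#' @export
simulate_expression <- function(geno, causal_snp, beta = 1, noise_sd = 1,
                                seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  g <- dosage_of(geno, causal_snp)
  if (stats::var(g, na.rm = TRUE) == 0) abort("causal SNP is monomorphic")
  set.seed(seed)
  y <- beta * g + rnorm(length(g), 0, noise_sd)
  names(y) <- geno$sample_ids
  y
}

# r2 of every SNP against one reference SNP (genotype based, complete panel)
r2_with <- function(geno, ref_snp) {
  d <- geno$dosages
  suppressWarnings(r <- as.vector(cor(d, d[, ref_snp])))
  setNames(r^2, colnames(d))
}

#' Sample two-causal-variant (H0) scenario quartets for one interval
#'
#' Null-hypothesis generator: a causal eQTL SNP (c-eQTL) drives
#' expression; a distinct causal disease SNP (c-dSNP) is sampled from the
#' same interval with its MAF drawn to match a reference MAF distribution
#' (binned as in [sample_maf_matched_sets()]). Up to `max_pairs` observed
#' proxy pairs are then formed: the i-th pair takes the i-th most
#' r-squared-correlated SNP with the c-eQTL as the eQTL and with the
#' c-dSNP as the dSNP (both causals excluded, since they are masked before
#' scoring); pairs whose eQTL and dSNP coincide are excluded as they
#' contradict the null.
#'
#' @param panel list from [simulate_haplotype_pool()].
#' @param c_eqtl id of the causal expression SNP; sampled uniformly when
#'   `NULL`.
#' @param gwas_maf_reference numeric vector of reference MAFs for the
#'   c-dSNP draw (e.g. a GWAS catalog's MAFs); `NULL` means a uniform MAF
#'   target over (0.05, 0.5].
#' @param max_pairs maximum proxy pairs per interval (default 5).
#' @param bin_width MAF bin width for the matching (default 0.01).
#' @param seed RNG seed.
#' @return Tibble of class `sim_scenarios`, one row per emitted scenario:
#'   `hypothesis, interval_id, c_eqtl, c_dsnp, proxy_eqtl, proxy_dsnp,
#'   pair_index`; masked SNP ids in the `masked` list-column. Possibly
#'   zero rows (skips are logged).
#' @export
build_h0_quartets <- function(panel, c_eqtl = NULL, gwas_maf_reference = NULL,
                              max_pairs = 5L, bin_width = 0.01, seed = 1L) {
  geno <- panel$geno
  ids <- geno$snps$snp_id
  if (length(ids) < 4) abort("interval too small to sample distinct quartets")
  set.seed(seed)
  if (is.null(c_eqtl)) c_eqtl <- sample(ids, 1)
  maf <- pmin(colMeans(geno$dosages) / 2, 1 - colMeans(geno$dosages) / 2)
  cand <- setdiff(ids, c_eqtl)
  cand_bin <- maf_bin(maf[cand], bin_width)
  ref_w <- if (is.null(gwas_maf_reference)) {
    # uniform MAF target over (0.05, 0.5]: equal weight per occupied bin
    w <- 1 / table(cand_bin)[as.character(cand_bin)]
    w[maf[cand] < 0.05] <- 0
    as.numeric(w)
  } else {
    ref_tab <- table(maf_bin(gwas_maf_reference, bin_width))
    w <- ref_tab[as.character(cand_bin)] / table(cand_bin)[as.character(cand_bin)]
    as.numeric(ifelse(is.na(w), 0, w))
  }
  if (all(ref_w == 0)) {
    rtc_log("build_h0_quartets: no candidate c-dSNP matches the reference MAF distribution; interval skipped")
    return(empty_scenarios())
  }
  c_dsnp <- sample(cand, 1, prob = ref_w)
  pool <- setdiff(ids, c(c_eqtl, c_dsnp))
  r2_e <- r2_with(geno, c_eqtl)[pool]
  r2_d <- r2_with(geno, c_dsnp)[pool]
  ord_e <- pool[order(-r2_e)]
  ord_d <- pool[order(-r2_d)]
  k <- min(max_pairs, length(pool))
  out <- tibble(hypothesis = "H0",
                interval_id = panel$interval$interval_id[1],
                c_eqtl = c_eqtl, c_dsnp = c_dsnp,
                proxy_eqtl = ord_e[seq_len(k)], proxy_dsnp = ord_d[seq_len(k)],
                pair_index = seq_len(k)) |>
    filter(.data$proxy_eqtl != .data$proxy_dsnp)
  if (nrow(out) < k) {
    rtc_log(sprintf("build_h0_quartets: excluded %d pair(s) with identical eQTL and dSNP",
                    k - nrow(out)))
  }
  out$masked <- purrr::map(seq_len(nrow(out)), ~c(c_eqtl, c_dsnp))
  class(out) <- c("sim_scenarios", class(out))
  out
}

empty_scenarios <- function() {
  out <- tibble(hypothesis = character(), interval_id = character(),
                c_eqtl = character(), c_dsnp = character(),
                proxy_eqtl = character(), proxy_dsnp = character(),
                pair_index = integer(), masked = list())
  class(out) <- c("sim_scenarios", class(out))
  out
}

#' Sample shared-causal-variant (H1) scenario trios for one interval
#'
#' Alternative-hypothesis generator: a single causal SNP (cSNP) drives
#' expression and is tagged by both proxies. Per iteration i (up to
#' `max_pairs`): the eQTL is the i-th most significant SNP for the
#' phenotype excluding the cSNP; the dSNP is sampled uniformly among SNPs
#' whose r-squared with the cSNP lies in `[r2_lo, r2_hi]`, excluding the
#' cSNP and every eQTL chosen so far. The cSNP is masked before scoring.
#'
#' @param panel list from [simulate_haplotype_pool()].
#' @param phenotype expression vector (simulated from the cSNP).
#' @param csnp id of the causal SNP.
#' @param r2_lo,r2_hi r-squared window for dSNP sampling (defaults 0.5 and
#'   0.9).
#' @param max_pairs maximum trios (default 5).
#' @param seed RNG seed.
#' @param min_samples minimum complete samples for the association ranking.
#' @return Tibble of class `sim_scenarios` (columns as
#'   [build_h0_quartets()], with `c_eqtl = c_dsnp = csnp`); steps without
#'   an eligible dSNP are skipped and logged.
#' @export
build_h1_trios <- function(panel, phenotype, csnp, r2_lo = 0.5, r2_hi = 0.9,
                           max_pairs = 5L, seed = 1L, min_samples = 30) {
  stopifnot(r2_lo < r2_hi)
  geno <- panel$geno
  ids <- geno$snps$snp_id
  if (!csnp %in% ids) abort("csnp not in panel")
  others <- setdiff(ids, csnp)
  if (length(others) < 2) abort("interval too small to sample trios")
  sv <- spearman_vec(dosage_of(geno, others, drop = FALSE), phenotype)
  ord <- order(sv$p, geno$snps$pos[match(others, geno$snps$snp_id)])
  eqtl_order <- others[ord]
  r2_c <- r2_with(geno, csnp)[others]
  window <- others[!is.na(r2_c) & r2_c >= r2_lo & r2_c <= r2_hi]
  set.seed(seed)
  rows <- list()
  chosen_eqtls <- character()
  for (i in seq_len(min(max_pairs, length(eqtl_order)))) {
    eqtl <- eqtl_order[i]
    chosen_eqtls <- c(chosen_eqtls, eqtl)
    elig <- setdiff(window, c(csnp, chosen_eqtls))
    if (length(elig) == 0) {
      rtc_log(sprintf("build_h1_trios: no eligible dSNP in r2 window at step %d; skipped", i))
      next
    }
    dsnp <- if (length(elig) == 1) elig else sample(elig, 1)
    rows[[length(rows) + 1]] <- tibble(
      hypothesis = "H1", interval_id = panel$interval$interval_id[1],
      c_eqtl = csnp, c_dsnp = csnp, proxy_eqtl = eqtl, proxy_dsnp = dsnp,
      pair_index = i)
  }
  if (length(rows) == 0) return(empty_scenarios())
  out <- list_rbind(rows)
  out$masked <- purrr::map(seq_len(nrow(out)), ~csnp)
  class(out) <- c("sim_scenarios", class(out))
  out
}

#' Full simulation study of the concordance score
#'
#' End-to-end benchmark: per interval, simulate a haplotype panel (switch
#' rate drawn log-uniformly over `switch_rate_range` so intervals span
#' high- to low-LD regimes), simulate expression from the causal SNP,
#' sample H0 quartets or H1 trios, mask the causal SNP(s), and score every
#' scenario with [rtc_score()]. Defaults mirror the benchmark conditions:
#' 287 intervals under H0, 290 under H1, 109 diploid samples, beta 1,
#' noise SD 1.
#'
#' @param hypothesis `"h0"` (two causal variants) or `"h1"` (one causal
#'   variant).
#' @param n_intervals number of simulated intervals; default 287 for H0
#'   and 290 for H1.
#' @param n_samples diploid sample count (default 109).
#' @param n_snps,maf_min panel parameters, see
#'   [simulate_haplotype_pool()].
#' @param n_founders_range integer range of founder-pool sizes; each
#'   interval draws its founder count uniformly from it (default
#'   `c(2, 8)`: 2 founders give near-complete LD blocks, 8 give diverse,
#'   low-LD intervals).
#' @param switch_rate_range range of per-interval founder switch rates
#'   (log-uniform draw; default `c(0.002, 0.1)`). Together with
#'   `n_founders_range` this spans interval median r-squared from near 0
#'   to near 1.
#' @param beta,noise_sd expression model, see [simulate_expression()].
#' @param gwas_maf_reference optional reference MAF vector for H0 c-dSNP
#'   sampling.
#' @param r2_lo,r2_hi H1 dSNP sampling window.
#' @param max_pairs scenarios per interval cap (default 5).
#' @param seed master seed; all per-interval seeds derive from it.
#' @param min_samples minimum complete samples for associations.
#' @return Tibble of class `rtc_simulation`, one row per scored scenario:
#'   scenario descriptors plus `rtc, rank, n_snps, r2_eqtl_dsnp,
#'   dprime_eqtl_dsnp, variance_ratio, interval_median_r2, switch_rate`.
#'   Use [glance()] for the summary block (H0 uniformity KS test, H1
#'   high-score fraction).
#' @export
run_rtc_simulation <- function(hypothesis = c("h0", "h1"),
                               n_intervals = NULL, n_samples = 109L,
                               n_snps = 50L, n_founders_range = c(2L, 8L),
                               maf_min = 0.05,
                               switch_rate_range = c(0.002, 0.1),
                               beta = 1, noise_sd = 1,
                               gwas_maf_reference = NULL,
                               r2_lo = 0.5, r2_hi = 0.9, max_pairs = 5L,
                               seed = 1L, min_samples = 30) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(n_intervals)) n_intervals <- if (hypothesis == "h0") 287L else 290L
  stopifnot(n_intervals >= 1)
  set.seed(seed)
  rates <- exp(runif(n_intervals, log(switch_rate_range[1]),
                     log(switch_rate_range[2])))
  founder_counts <- sample(seq(n_founders_range[1], n_founders_range[2]),
                           n_intervals, replace = TRUE)
  iseeds <- sample.int(2147483000L, n_intervals)
  rows <- purrr::map(seq_len(n_intervals), function(i) {
    panel <- simulate_haplotype_pool(
      n_founders = founder_counts[i], n_haplotypes = 2L * n_samples,
      n_snps = n_snps, switch_rate = rates[i], maf_min = maf_min,
      seed = iseeds[i], chrom = sprintf("sim%04d", i))
    ids <- panel$geno$snps$snp_id
    if (length(ids) < 6) return(NULL)
    set.seed((iseeds[i] + 1L) %% 2147483647L)
    causal <- sample(ids, 1)
    y <- simulate_expression(panel$geno, causal, beta = beta,
                             noise_sd = noise_sd,
                             seed = (iseeds[i] + 2L) %% 2147483647L)
    scen_seed <- (iseeds[i] + 3L) %% 2147483647L
    scen <- if (hypothesis == "h0") {
      build_h0_quartets(panel, c_eqtl = causal,
                        gwas_maf_reference = gwas_maf_reference,
                        max_pairs = max_pairs, seed = scen_seed)
    } else {
      build_h1_trios(panel, y, causal, r2_lo = r2_lo, r2_hi = r2_hi,
                     max_pairs = max_pairs, seed = scen_seed,
                     min_samples = min_samples)
    }
    if (nrow(scen) == 0) return(NULL)
    masked_ids <- unique(unlist(scen$masked))
    visible <- setdiff(ids, masked_ids)
    masked_geno <- subset_genotypes(panel$geno, snp_ids = visible)
    med <- interval_median_r2(masked_geno, visible, min_samples = min_samples)
    scored <- purrr::pmap(
      scen[, c("proxy_eqtl", "proxy_dsnp", "pair_index")],
      function(proxy_eqtl, proxy_dsnp, pair_index) {
        rtc_score(masked_geno, visible, proxy_eqtl, proxy_dsnp, y,
                  min_samples = min_samples,
                  interval_id = panel$interval$interval_id[1]) |>
          mutate(pair_index = pair_index)
      }) |> list_rbind()
    scored |>
      mutate(hypothesis = toupper(hypothesis), interval_index = i,
             c_eqtl = scen$c_eqtl[1], c_dsnp = scen$c_dsnp[1],
             interval_median_r2 = med$median_r2, switch_rate = rates[i],
             n_founders = founder_counts[i])
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) abort("simulation produced no scored scenario")
  rows <- select(rows, "hypothesis", "interval_index", "interval_id",
                 "pair_index", "c_eqtl", "c_dsnp",
                 eqtl_snp = "eqtl_snp", gwas_snp = "gwas_snp",
                 "n_snps", "rank", "rtc", "p_adjusted_gwas",
                 "r2_eqtl_dsnp", "dprime_eqtl_dsnp", "variance_ratio",
                 "interval_median_r2", "switch_rate", "n_founders")
  attr(rows, "hypothesis") <- toupper(hypothesis)
  attr(rows, "seed") <- seed
  class(rows) <- c("rtc_simulation", class(rows))
  rows
}

#' @exportS3Method generics::glance
glance.rtc_simulation <- function(x, ...) {
  ks <- suppressWarnings(ks.test(x$rtc, "punif"))
  tibble(hypothesis = attr(x, "hypothesis"),
         n_scenarios = nrow(x),
         n_intervals = dplyr::n_distinct(x$interval_index),
         mean_rtc = mean(x$rtc),
         frac_rtc_ge_0.9 = mean(x$rtc >= 0.9),
         ks_stat_uniform = unname(ks$statistic),
         ks_p_uniform = ks$p.value)
}

#' @exportS3Method generics::tidy
tidy.rtc_simulation <- function(x, ...) {
  as_tibble(x)
}
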