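# rtcscore

Many GWAS hits sit on top of expression QTLs, but the genome's linkage
disequilibrium (LD) structure means a lot of those overlaps are
coincidental: the disease SNP and the eQTL can tag two different
functional variants that merely live in the same haplotype block.
`rtcscore` implements the **Regulatory Trait Concordance (RTC)** score, a
conditional-analysis statistic that asks whether a GWAS SNP and a
colocalizing eQTL in the same recombination-hotspot interval are tagging
the *same* functional variant — together with everything needed to run
and validate it: Spearman-based eQTL mapping with permutation
thresholds, pairwise LD metrics (r² and D′, phased or EM-based),
MAF-matched QQ enrichment curves, an immunity-stratified Fisher test,
and an LD-structured genotype simulator for benchmarking.

It is written for statistical geneticists and regulatory-genomics
analysts who have genotypes (VCF or dosage tables), normalized
expression, hotspot interval coordinates (BED) and a GWAS SNP list, and
want a ranked list of candidate disease genes whose regulation the GWAS
signal plausibly perturbs.

## The score

For a gene with an eQTL and a GWAS SNP in the same hotspot interval,
every SNP *s* of the interval is used in turn to "correct" the
expression phenotype: the phenotype is residualized on *s* by linear
regression, and the eQTL association is re-tested on the residuals with
Spearman rank correlation, giving an adjusted P-value. A correction
that removes more of the eQTL signal leaves a *larger* adjusted P. The
GWAS SNP's rank counts the interval SNPs that beat it:

```
Rank_GWAS = #{ s != GWAS SNP : P_adj(s) > P_adj(GWAS SNP) }
RTC       = (N_SNPs - Rank_GWAS) / N_SNPs
```

RTC lies in (0, 1]. When the GWAS SNP is the eQTL SNP itself (or a
perfect proxy), no SNP corrects better, the rank is 0 and RTC = 1.
Because the sweep spans the whole interval, the score is comparable
across intervals with very different LD; under two distinct causal
variants it is uniformly distributed, so `RTC >= 0.9` discoveries can be
calibrated against a chance expectation of `0.1 * N_intervals`.

## Worked example

Simulate one hotspot interval (109 diploids, 50 SNPs before the MAF
filter), drive expression from a causal SNP, and score an observed
eQTL-proxy / disease-SNP pair that both tag it:

```r
library(rtcscore)

panel <- simulate_haplotype_pool(n_snps = 50, switch_rate = 0.02, seed = 7)
ids    <- panel$geno$snps$snp_id          # 34 SNPs survive the MAF filter
causal <- ids[15]                         # "sim026", the (later masked) truth
y <- simulate_expression(panel$geno, causal, beta = 1, noise_sd = 0.5, seed = 8)

rtc_score(panel$geno, ids,
          eqtl_snp = "sim036",            # best correlate of the causal SNP
          gwas_snp = "sim014",            # r2 with the causal SNP ~ 0.65
          phenotype = y)
#>   eqtl_snp gwas_snp n_snps rank   rtc r2_eqtl_dsnp dprime_eqtl_dsnp variance_ratio
#> 1   sim036   sim014     34    2 0.941        0.331            0.627          0.299
```

Only 2 of 34 interval SNPs remove the eQTL signal more completely than
the disease SNP, so RTC = 32/34 = 0.94 — strong evidence for a shared
functional variant even though the pairwise r² between the two observed
SNPs is a modest 0.33 (this is exactly the situation where raw LD
metrics mislead).

The full benchmark reproduces the score's two signature distributions:

```r
sim_h1 <- run_rtc_simulation("h1", n_intervals = 60, seed = 42)  # one causal SNP
glance(sim_h1)[, c("n_scenarios", "frac_rtc_ge_0.9")]
#>   n_scenarios frac_rtc_ge_0.9
#> 1         102           0.294        # ~3x the chance rate of 0.10

sim_h0 <- run_rtc_simulation("h0", n_intervals = 60, seed = 42)  # two causal SNPs
glance(sim_h0)[, c("n_scenarios", "ks_stat_uniform", "ks_p_uniform")]
#>   n_scenarios ks_stat_uniform ks_p_uniform
#> 1         291          0.0438        0.632  # uniform under the null
autoplot(sim_h0)
```

Real-data scans follow the same grammar: `read_genotypes()`,
`read_expression()`, `read_intervals()`, `read_gwas_catalog()` feed
`call_cis_eqtls()` and then `rtc_cis_scan()` / `rtc_trans_scan()`, which
return one tibble row per scored (interval, gene, eQTL, GWAS SNP)
combination, sorted by score. `best_p_per_snp()`,
`sample_maf_matched_sets()` and `qq_median_ci()` build the
regulatory-signal enrichment QQ curves, and
`immunity_enrichment_test()` runs the trait-class Fisher test. A thin
command-line front end over the same functions lives in
`inst/cli/rtc.R` (subcommands `eqtl-map`, `rtc-cis`, `rtc-trans`,
`enrich-qq`, `simulate`, `ld`).

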