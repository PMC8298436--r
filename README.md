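# mprastat

Statistical machinery for massively parallel reporter assay (MPRA)
screens of regulatory variants, built for barcode-level analyses of
allelic effects and allele-by-drug interactions — the setting of an MPRA
that screens GWAS-prioritized SNPs in a retinoid-responsive cell model
with and without all-*trans* retinoic acid (ATRA).

In an MPRA, each candidate regulatory sequence (an *element*; one SNP
contributes a reference-allele and an alternate-allele element) is tagged
with several unique barcodes, and activity is read out as the log2 ratio
of depth-normalized RNA barcode counts to depth-normalized input-DNA
barcode counts. A pool of promoter-only *basal* barcodes carries no
candidate sequence, so randomized pseudo-allelic comparisons among basal
barcodes measure exactly the barcode-driven expression variability that a
real allelic comparison must beat. `mprastat` implements that empirical
null machinery end to end:

- **quantify** — barcode activity `log2((rna+pc)/N_rna) − log2((dna+pc)/N_dna)`,
  depth/representation filtering, and per-sample element means.
- **allelic tests** — per SNP, the composite log2 fold change (mean over
  samples of alt − ref element expression), a two-sided t-test across
  replicates, and an empirical p-value
  `P_emp = (1 + #{|t_null| ≥ |t_obs|}) / (1 + n_sims)` against simulated
  allelic comparisons between random disjoint subsets of basal barcodes;
  Shapiro–Wilk normality gating with a recorded Mann–Whitney fallback,
  Benjamini–Hochberg FDR, and a Monte-Carlo power analysis of the design.
- **interaction model** — per SNP, the linear mixed model
  `expression ~ allele + drug + allele:drug + (1 | replicate)` on
  barcode-level measurements (fitted with lme4; minimum 40% of possible
  measurements), per-coefficient Wald F statistics ranked against
  20,000 randomized basal-only F statistics, a likelihood-ratio test of
  the interaction (ML interaction model vs ML additive model, χ²₁), and
  classification of SNPs into allele-only / interaction-only / both /
  none using the combined single-condition direction rules.
- **motifs** — PWM scanning of element sequences (log2-odds, both
  strands, relative score rescaled to [0, 1] between the matrix's
  attainable extremes), restricted to windows overlapping the SNP, with
  strong/weak allelic perturbation calls.
- **enrichment** — resampling enrichment of motif perturbations among
  functional vs analyzed SNPs (10,000 random draws of `n` SNPs), the
  motif–expression concordance statistic, and ChIP-peak overlap counting
  on 0-based half-open intervals.
- **synthetic data** — a generator with known ground truth (planted
  allelic, drug and interaction effects; barcode and replicate random
  effects; Poisson-lognormal counts) emulating the study design of up to
  ~1454 SNPs × 2 alleles × 10 barcodes, 110 basal barcodes and 6
  replicates per condition, so every stage is testable without external
  data.

## Worked example

```r
library(mprastat)

design <- generate_library(n_snps = 40, seed = 1)
truth  <- make_ground_truth(design,
                            beta_allele = rep(c(0, 0.6), 20),
                            beta_inter  = rep(c(0, 0, 0.8, 0), 10),
                            seed = 2)
counts <- simulate_counts(design, truth, depth = 2e6, seed = 3)
expr   <- filter_table(compute_expression(counts), design,
                       rna_counts = counts$rna)$expr

# single-condition allelic tests against a basal-barcode t null
vehicle <- subset_samples(expr, "vehicle")
tnull   <- build_basal_null(vehicle, design, n_sims = 5000, seed = 4)
allelic <- run_allelic_tests(element_means(vehicle, design), null = tnull)
head(allelic[order(allelic$p_emp),
             c("snp_id", "composite_log2fc", "t_stat", "p_emp", "fdr_q")], 5)
#>     snp_id composite_log2fc t_stat p_emp    fdr_q
#> 2  snp0002            0.590   33.8 2e-04 2.97e-10
#> 4  snp0004            0.609   36.2 2e-04 1.42e-10
#> 6  snp0006            0.589   34.5 2e-04 1.42e-10
#> 8  snp0008            0.626   25.0 2e-04 1.24e-09
#> 10 snp0010            0.582   32.5 2e-04 2.47e-08

# allele x drug mixed models against a basal F null
fnull <- basal_F_null(expr, design, n_sims = 5000, seed = 5)
lmm   <- run_interaction_analysis(expr, design, nulls = fnull)
head(lmm[order(lmm$p_emp_inter),
         c("snp_id", "beta_allele", "beta_inter",
           "p_emp_allele", "p_emp_inter", "lrt_p")], 5)
#>     snp_id beta_allele beta_inter p_emp_allele p_emp_inter    lrt_p
#> 3  snp0003      0.0288      0.774        0.391       2e-04 8.03e-58
#> 7  snp0007      0.0424      0.782        0.211       2e-04 1.36e-58
#> 11 snp0011      0.0137      0.747        0.675       2e-04 4.97e-57
#> 15 snp0015     -0.0377      0.794        0.217       2e-04 8.93e-67
#> 19 snp0019      0.0457      0.774        0.159       2e-04 9.76e-61
```

The SNPs planted with a 0.6 log2-unit allelic effect are recovered with
composite log2FC ≈ 0.6 at the empirical p floor `1/(n_sims + 1)`; the
SNPs planted with a 0.8 interaction coefficient are recovered with
`beta_inter ≈ 0.8`, interaction `P_emp` at the floor, and decisive
likelihood-ratio support, while their allele main effects remain null.

```r
pw <- power_analysis(effect_log2fc = 1.1, n_sims = 2000, seed = 6)
pw$power
#> [1] 1
```

Under the design's noise level (barcode SD 0.12, 10 barcodes per allele,
6 replicates), an allelic effect of |log2FC| = 1.1 is detected at
Bonferroni-corrected α = 0.1/1013 in essentially every simulation — the
design is comfortably past the 80% power target.

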