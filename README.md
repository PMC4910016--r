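# famsel — two-timescale selection analysis of gene families

Large gene families — chemoreceptors (Or, Gr, Ir) and odorant-binding
proteins (Obp) are the canonical case — are often presented as token
examples of rapid adaptive evolution, but testing that claim requires
putting them in a genome-wide, family-wide context at more than one
timescale. `famsel` is an R package for doing exactly that on a
multi-population panel of inbred lines (five populations, 84 lines, with
the African sample representing the ancestral range):

* **Between species** — McDonald–Kreitman tables per gene
  (P_R, P_S, D_R, D_S; African polymorphism only; marginals > 6 required),
  Fisher's exact test, the direction of selection
  DoS = D_R/(D_R+D_S) − P_R/(P_R+P_S), and a family-level
  maximum-likelihood estimate of the adaptive substitution fraction α
  (per-gene Poisson rates profiled out; shared neutral replacement
  fraction f; 2-log-likelihood-unit profile CIs; 1-df LRT against α = 0),
  scaled to ω_a by the relative synonymous rate.
* **Within species** — per-SNP Weir–Cockerham F_st (haploid
  variance-components form) over all 10 population pairs, empirical 1%/5%
  tail outliers per chromosome class, family tail enrichment,
  standing-variation and divergent-selection candidate calls; unfolded
  site-frequency spectra and Fay & Wu's H = θ_π − θ_H per gene and
  population, family bootstrap CIs, and significance from neutral
  coalescent simulations conditioned on the observed number of segregating
  sites (demography × recombination grid).
* **Relaxed constraint** — per-site P_R/P_S diversity ratios with
  Kruskal–Wallis family comparisons; CNV-derived gene structures (complete
  duplications, chimeras, tandem same-strand fusions, coding deletions);
  polymorphic null-allele summaries under the single-class ≥ 10% rule;
  deletion:duplication ratios.
* **Receptor function** — lifetime kurtosis
  K_L = (1/M) Σ ((r_i − r̄)/σ_r)^4 − 3 of odorant response profiles and its
  correlation with gene-level mean F_st.

A built-in coalescent engine (Hudson ancestral recombination graph in
Rcpp: multi-population demography with polytomy merges, growth, migration,
recombination, fixed-S and θ-mode mutation dropping, ms-style scaling)
supplies every null distribution, and a synthetic-data generator emulates
the full panel — genome annotation with codon degeneracy, SNPs with
residual heterozygosity/missingness/ancestral posteriors, divergence
counts, CNV/indel tables, response matrices — with every planted signal
recorded in a truth sidecar, so the entire pipeline is testable offline.

## Worked example

```r
library(famsel)

cfg <- scenario_config(
  n_background = 120,                                   # background genes for the empirical tails
  fst_inflation = list(family = "Or", intensity = 0.5,  # plant local adaptation in Or
                       graded = TRUE),
  sweeps = data.frame(family = "Gr", gene_index = 1,    # plant one sweep in Gr (Ithaca)
                      pop = "I", intensity = 1),
  kl_coupling = -0.8)                                   # broad tuning <-> high differentiation

ds <- generate_dataset(cfg, seed = 42)
report <- run_pipeline(ds, seed = 1)
print(report)
```

```
famsel pipeline report
  MK:  201 of 202 genes tested; 1 Bonferroni-significant
  alpha[Or] = 0.534 (CI 0.448:0.605), omega_a = 0.865
  alpha[Gr] = 0.295 (CI 0.140:0.419), omega_a = 0.383
  alpha[Ir] = 0.028 (CI -0.142:0.171), omega_a = 0.028
  alpha[Obp] = 0.107 (CI -0.214:0.336), omega_a = 0.113
  alpha[background] = 0.079 (CI 0.005:0.146), omega_a = 0.080
  Fst tail: top family Or (fraction 0.120)
  standing variation fraction: 0.160
  H[Or] = -1.676 (CI -2.306:-1.064) *
  H[Gr] = -0.174 (CI -1.266:0.532)
  H[Ir] = -0.497 (CI -1.287:0.221)
  H[Obp] = -0.382 (CI -0.772:-0.024) *
  H[background] = -0.551 (CI -0.822:-0.287) *
  K_L ~ Fst: r = -0.352 (p = 0.108, n = 22)
```

Reading the output against the planted truth: the generated α values per
family were Or 0.4, Gr 0.2, Ir 0, Obp 0.1 — the family ML estimates
recover that ordering, with the Or estimate pushed up slightly because the
planted differentiation removes some African replacement polymorphism.
The differentiation-inflated family (Or) tops the replacement-SNP tail
enrichment (12.0% of its records in the genome-wide 1% tail, versus ~2%
for the others):

```r
head(report$enrichment, 5)
#>       family outliers total   fraction rank
#> 1         Or      819  6830 0.11991215    1
#> 2         Gr      129  5118 0.02520516    2
#> 3        Obp       45  2266 0.01985878    3
#> 4         Ir      143  7345 0.01946903    4
#> 5 background    668  34833 0.01917722    5
```

The swept and inflated Or family also shows strongly negative Fay & Wu's H
(derived alleles driven to high frequency), and the response matrix built
with negative tuning-breadth coupling yields a negative K_L–F_st
correlation. Individual stages are available as plain functions
(`wc_fst_site`, `fst_tail_outliers`, `fay_wu_h`, `h_significance_sim`,
`alpha_family_ml`, `classify_cnv_gene_events`, `null_allele_summary`,
`lifetime_kurtosis`, ...), readers/writers for VCF/BED/TSV are in
`read_snp_vcf` / `read_gene_bed` / `write_dataset`, and a thin CLI lives
at `inst/cli/famsel` (`famsel simulate|pipeline --out DIR --seed N`).

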