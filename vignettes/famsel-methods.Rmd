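---
title: "Methods: two-timescale selection analysis of gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-timescale selection analysis of gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsel)
```

# Scope and data model

`famsel` measures natural selection acting on large gene families — the
chemoreceptor repertoires (odorant receptors, gustatory receptors,
ionotropic receptors) and odorant-binding proteins of *Drosophila* are the
motivating case — at two timescales:

* **between species** (millions of years): adaptive protein divergence from
  McDonald–Kreitman (MK) contingency tables;
* **within species** (thousands of years): local adaptation from
  allele-frequency differentiation (Weir–Cockerham $F_{st}$) and selective
  sweep footprints in the site-frequency spectrum (Fay & Wu's $H$), plus
  relaxed constraint from diversity ratios and gene-disrupting variation.

The data model is a panel of inbred lines from five world populations
(Beijing 15, Ithaca 19, Netherlands 19, Tasmania 18, Zimbabwe 13 lines; the
Zimbabwe sample represents the ancestral range). Lines are mostly
homozygous, with residual heterozygous blocks and missing calls, so
genotype tables carry calls in $\{0, \tfrac12, 1, \mathrm{NA}\}$ per line
and site. All coordinates are 0-based half-open internally (BED
convention); VCF positions are converted on read and write. Because the
study data themselves are not redistributable at package scale, a
first-class synthetic-data generator (section *Synthetic data*) reproduces
the panel design with known ground truth; every statistical claim in the
test suite is made against that ground truth or an independent oracle.

# Between-species stage: MK tables, DoS, $\alpha$, $\omega_a$

Per gene we assemble $(P_R, P_S, D_R, D_S)$: replacement and silent
polymorphism counted in the ancestral-range (Zimbabwe) sample only, and
replacement and silent substitutions to the outgroup. Genes with any
marginal sum of the $2\times2$ table $\le 6$ are flagged excluded — tests on
nearly empty tables are uninformative. The per-gene tests are Fisher's
exact test (two-sided by summing all tables with probability not exceeding
the observed one — conventions differ between implementations, so this one
is pinned and oracle-tested) and the direction of selection
$$\mathrm{DoS} = \frac{D_R}{D_R + D_S} - \frac{P_R}{P_R + P_S},$$
which is robust for sparse tables. The per-gene point estimate is
$\alpha = 1 - (D_S P_R)/(D_R P_S)$.

**Family-level likelihood.** To combine genes within a family we use an
explicit Poisson factorization with per-gene nuisance rates
$\theta_i$ (polymorphism) and $t_i$ (divergence), a shared
effectively-neutral replacement fraction $f$, and a shared adaptive
fraction $\alpha$:
$$P_{S,i} \sim \mathrm{Pois}(\theta_i L_{s,i}),\quad
  P_{R,i} \sim \mathrm{Pois}(f\,\theta_i L_{n,i}),\quad
  D_{S,i} \sim \mathrm{Pois}(t_i L_{s,i}),\quad
  D_{R,i} \sim \mathrm{Pois}\!\left(\frac{f\,t_i L_{n,i}}{1-\alpha}\right).$$
The nuisance rates profile out in closed form, leaving a two-parameter
surface in $(\alpha, \log f)$ maximised by Nelder–Mead. Confidence
intervals are profile-likelihood regions within 2 log-likelihood units of
the maximum (an MCMC posterior is the obvious alternative; profiling is
implemented and labelled as such), and the test against $\alpha = 0$ is a
1-df likelihood-ratio test. Parameter-recovery simulation (200 genes,
$\alpha = 0.4$, $f = 0.2$) and type-I calibration (500 null fits,
rejection rate within $5\% \pm 2\%$) are part of the acceptance suite.
With identical genes the MLE collapses to the pooled point estimate, which
the tests check numerically. $\omega_a$ scales $\alpha$ by the relative
synonymous rate using pooled counts:
$\omega_a = \alpha\,(\sum D_R / \sum L_n)/(\sum D_S / \sum L_s)$.

**Site lengths.** Effective synonymous/nonsynonymous site counts come from
codon degeneracy: with $L_x$ the number of $x$-fold degenerate coding
positions, $L_n = L_1 + \tfrac23 L_2 + \tfrac13 L_3$ and
$L_s = L_4 + \tfrac13 L_2 + \tfrac23 L_3$, so $L_n + L_s$ equals the coding
length exactly. One canonical transcript per gene; the terminal stop codon
is excluded from the gene model entirely (the natural reading when lengths
must sum to coding length). Degeneracy is enumerated from the standard
genetic code, which is also how the effect classifier (synonymous /
replacement / nonsense) is exhaustively validated over all
$64 \times 9$ single-base codon changes.

**Polarization.** Ancestral states are probabilistic; a site is polarized
when the posterior for one allele being ancestral is at least 0.85, *with
the boundary inclusive* — "at least 85%" reads naturally as $\ge$. Sites
below the threshold are excluded from polarized analyses rather than
guessed.

# Within-species stage 1: $F_{st}$ differentiation

Per-SNP $F_{st}$ uses the Weir–Cockerham variance-components estimator in
its haploid (allele-count) form, appropriate because inbred lines are
haploidized before frequency-based analyses: with $r$ populations, sizes
$n_i$ and frequencies $p_i$,
$\mathrm{MSP} = \sum n_i (p_i - \bar p)^2/(r-1)$,
$\mathrm{MSG} = \sum n_i p_i (1 - p_i)/(N - r)$,
$n_c = (N - \sum n_i^2/N)/(r-1)$, $a = (\mathrm{MSP}-\mathrm{MSG})/n_c$,
$b = \mathrm{MSG}$ and $\theta = a/(a+b)$. Negative estimates are reported
as computed; sites monomorphic over all populations are flagged undefined
and excluded from tails. The implementation is validated to $10^{-12}$
against an independently coded ANOVA on expanded allele vectors, and
reciprocally fixed sites give exactly 1 at any sample sizes.

Empirical outlier calling takes, per population pair and chromosome class
(X and autosomes separately, since their effective sizes differ; X-linked
null models scale sizes by 3/4, configurable), the genome-wide distribution
of defined $\theta$ for the chosen effect class and marks values at or
above the value at ascending rank $\lceil (1-q) N \rceil$. Ties at the
threshold count as outliers — the inclusive rule is pinned because rank
conventions silently differ between tools. All 10 population pairs are
used; family enrichment is the fraction of a family's replacement-SNP
records falling in the tail, ranked across families. Simulation-based
thresholds from the coalescent engine provide the neutral comparison, and a
report marks pairs whose empirical thresholds exceed the neutral ones.
Divergent-selection candidates are genes with two or more distinct
replacement outlier SNPs whose outlier status arises in different
population pairs; the standing-variation summary is the fraction of
polarized candidate SNPs whose derived allele segregates (frequency
strictly inside $(0,1)$) in the Zimbabwe sample. A model-based outlier list
(e.g. from an external Bayesian $F_{st}$ scan) can be supplied as a TSV and
intersected with the empirical tail; the scan itself is out of scope here.

# Within-species stage 2: SFS and sweeps

The unfolded spectrum $\xi_i$ counts polarized derived alleles at frequency
$i/n$; sites fixed derived are not segregating and are excluded. Fay & Wu's
$$H = \theta_\pi - \theta_H,\qquad
  \theta_\pi = \binom{n}{2}^{-1}\!\sum i (n-i)\,\xi_i,\qquad
  \theta_H = \binom{n}{2}^{-1}\!\sum i^2 \xi_i,$$
is negative when high-frequency derived alleles are in excess — the
footprint of a recent sweep. The algebraically identical collapsed form
$H = \binom{n}{2}^{-1}\sum i(n-2i)\,\xi_i$ is used as a cross-check to
$10^{-12}$. $H$ is computed per population (with a pooled option), because
sweep signals are population-specific; family summaries use a gene-level
percentile bootstrap (default $B = 10{,}000$; the percentile variant is the
design choice since nothing pins a different one) and a family is
"significantly negative" when the 95% interval's upper bound is below 0.

Significance for individual genes comes from neutral coalescent nulls
conditioned on the gene's observed number of segregating sites, over a grid
of demographic models and scaled recombination rates
$\rho \in \{1, 50, 250\}$, with locus lengths set to family medians
(Or/Gr 1500 bp, Ir 2000 bp, Obp 600 bp). The p-value per cell is the
fraction of replicates with $H$ at or below the observed value; zero
counts are reported at the resolution bound $1/n_{\mathrm{reps}}$. A gene
is a sweep candidate when it stays significant at the 5% tier under every
demographic model for at least the two higher recombination rates — the
low-$\rho$ null is the most variable and is deliberately not allowed to
veto.

# The coalescent engine

The null distributions come from a from-scratch structured-coalescent
simulator with recombination (Hudson's ancestral recombination graph),
written in C++ for speed and exposed through R wrappers. Conventions are
ms-style throughout: time in units of $4N_0$ generations, sizes relative to
$N_0$, $\rho = 4N_0 r L$, per-lineage backward migration rate
$M_{ij} = 4N_0 m_{ij}$, mutations at rate $\theta$ per unit of
span-weighted branch length. Under these conventions the expected pairwise
TMRCA is $0.5$ (i.e. $2N_0$ generations), $E[S] = \theta \sum_{i<n} 1/i$,
$E[\pi] = \theta$ and $E[\xi_i] = \theta/i$ — all verified at $10^4$
replicates within 3 standard errors, and the two-deme island model
reproduces $E[T_{\mathrm{between}}] = 1 + 1/(2M)$ and is checked
distributionally against an independent simulator (msprime) by a
Kolmogorov–Smirnov test on segregating-site counts.

Demographic events (backward in time) support multi-way merges at one event
time (the forced polytomy of the three short terminal out-of-Africa
branches is expressed this way, applied in deterministic label order), size
and exponential-growth changes, and migration-matrix changes (including
Africa–ancestral-out-of-Africa migration). Fixed-$S$ conditioning places
exactly $S$ mutations with probability proportional to branch length
(Hudson's method, matching `ms -s`), rather than rejection sampling.

One distributional subtlety is documented rather than hidden: under
fixed-$S$ conditioning the expectation of $H$ is *not* exactly zero (the
mutation count no longer co-varies with tree length, which tilts
$E[\xi_i]$ slightly toward high-frequency classes). The zero-mean
calibration is therefore asserted in $\theta$-mode, where it holds
unconditionally; fixed-$S$ nulls are used exactly as the empirical pipeline
uses them, so the slight conditional skew cancels between observed and null
replicates.

Three editable demographic presets ship with the package (constant-size;
out-of-Africa bottleneck; bottleneck plus growth with ancestral migration).
Their parameter values — polytomy at $t_1 = 0.02$, out-of-Africa split at
$t_2 = 0.06$ with a 10× bottleneck, African origin at $t_3 = 0.15$, derived
growth from 0.5 to 2, migration $M = 0.5$ on the out-of-Africa stem — are
package defaults chosen to produce out-of-Africa-like differentiation and
SFS skews at the right order of magnitude; they are containers to be
overridden with fitted values for any particular dataset, not estimates.

# Relaxed constraint and gene loss

$P_R/P_S$ is the ratio of per-site replacement to per-site silent
diversity, $(\pi_R/L_n)/(\pi_S/L_s)$, undefined when silent diversity is
zero. Family heterogeneity is tested with Kruskal–Wallis plus pairwise
Wilcoxon follow-ups under Holm correction (base `stats` implementations).

CNV-derived gene structures are classified exhaustively and mutually
exclusively per event: *complete duplication* (duplication spans the whole
gene), *chimera* (duplication partially covers two genes), *fusion*
(deletion removes the facing ends of two tandem genes, joining the rest;
strand concordance is recorded because observed fusions are same-strand),
*gene deletion* (deletion removes coding sequence without fusing), with
non-coding and intergenic events kept but never counted as nulls. A gene
carries a high-frequency null allele in a population when **one single
class** of disruptive mutation (nonsense SNP, frameshift indel — exonic and
length $\not\equiv 0 \bmod 3$ — or coding CNV deletion) segregates at
$\ge 10\%$ of that population's lines; classes are never summed, and the
threshold is a within-population fraction with an inclusive boundary.
Deletion:duplication ratios are reported overall and above a 10% frequency
floor, gcd-reduced only when both sides are positive (so "19:0" prints as
counted).

# Receptor tuning breadth

Lifetime kurtosis of a receptor's response profile over $M$ odorants uses
population moments:
$$K_L = \frac1M \sum_{i=1}^M \left(\frac{r_i - \bar r}{\sigma_r}\right)^4 - 3 .$$
The $-3$ excess term is a display convention only — $K_L$ enters the
analysis through correlation and regression, both invariant to constant
shifts — and can be disabled. $K_L$ requires $\sigma_r > 0$ and at least 4
responses, and is invariant to affine rescaling of the profile (tested
exactly). The tuning-breadth analysis regresses gene-level mean $F_{st}$
(averaged over SNPs and the 10 population pairs) on $K_L$, reporting the
product-moment correlation with its p-value and the regression slope; a
rank-correlation option is available since response scales are heterogeneous.

# Synthetic data

The generator emulates the panel, not any particular genome: arms 2L, 2R,
3L, 3R, X; four large families ($\ge 20$ genes, enforced) plus a background
gene set; random sense-codon sequences giving real degeneracy structure;
per-gene neutral genealogies from the configured demographic preset
(X-linked genes at 3/4 size); SNP effects classified from actual codon
context; residual heterozygosity (default 1%), missingness (default 2%)
and a configured fraction of sites left unpolarizable (default 10%).
Default per-site $\theta$ is 0.008 and divergence generation uses per-site
polymorphism/divergence rates of 0.03 and 0.12 — the order observed for
African *D. melanogaster* silent diversity and *D. simulans* silent
divergence, which also keeps MK tables comfortably past the marginal
filter. The default background of 500 × 1.5 kb genes yields roughly
$4\times10^4$ SNPs so empirical 1% tails rest on $>10^4$ records.

Planted signals, all recorded in a truth sidecar: family-level
differentiation inflation (replacement SNPs pushed toward fixation of the
derived allele in a random population, optionally graded per gene),
selective sweeps (a fraction of a gene's derived alleles pushed to
frequency $(n-1)/n$ in one population — a deterministic frequency
transformation, not forward simulation, because the nulls are neutral and
the tests need controllable effect sizes), complete duplications, chimeras,
tandem same-strand fusions, $\ge 10\%$ null alleles of each class, known
per-family $\alpha$, and a tuning-breadth coupling. Generation is
byte-identical under a fixed seed and configuration.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linked selection and background selection,
realistic recombination maps and inversions (the real heterozygous blocks
are inversion-associated; here heterozygosity is sprinkled independently),
sequencing error structure, gene conversion, alignment/callability masks,
and real codon usage. Conclusions about method calibration transfer;
conclusions about *D. melanogaster* biology require the real panel.

# Numerical choices and degenerate inputs

* Polarization boundary inclusive at 0.85; posterior outside $[0,1]$ is an
  error.
* Heterozygote resolution is per-site independent; imputation happens
  *after* heterozygote resolution, from the population-specific frequency
  of the resolved calls (the alternative order is not distinguishable from
  published descriptions; this one is pinned and documented). A site with
  all calls missing in a population is an error naming site and population.
* $F_{st}$ tail ties count as outliers; thresholds use ascending rank
  $\lceil (1-q)N\rceil$; at least 100 defined values are required.
* Fisher two-sided p sums tables with $\Pr \le \Pr_{\mathrm{obs}}$ (with a
  $1+10^{-7}$ tolerance factor in the oracle, as in common
  implementations).
* $\alpha$ search space is $(-10, 0.999)$; $f$ is optimised on the log
  scale in $(-12, 6)$; non-convergence raises an error carrying the
  optimizer state.
* $S = 0$ replicates are valid: $\pi = 0$, $H$ undefined (NA), spectra
  empty.
* Zero-denominator ratios: $P_R/P_S$ undefined at zero silent diversity;
  deletion:duplication "$d{:}0$" reported with ratio $+\infty$; "0:0" with
  ratio NA.

# Problem sizes used by the shipped validation

The test and acceptance runs size their simulations to hold statistical
guarantees while staying desk-scale: $10^4$ replicates for coalescent
calibration and the $F_{st}$ oracle; the full enumeration of Fisher tables
with margins $\le 30$ (implementation evaluated on symmetry-canonical
representatives, with the symmetry itself verified on random tables); 500
trials for LRT type-I calibration; 3000-replicate null grids and 100
injected sweeps for power; 100 pipeline replicates on a 140-gene genome for
enrichment ranking; and one full default-scale (582-gene) pipeline run.
These sizes are the package's validation design; all are driven by a single
seed argument.

# Known limitations

* The family $\alpha$ model shares one $f$ across genes; a full
  distribution of fitness effects is out of scope.
* No haplotype statistics (iHS/XP-EHH), no composite-likelihood scan, no
  normalized $H$; the SFS machinery is $H$ plus simulation nulls.
* The simulator is neutral by design; selection enters only through the
  injection operators.
* BayeScan-style model-based outlier detection is consumed, not
  reimplemented.
* Splice isoforms, UTR/splice-site effect classes and multi-nucleotide
  variant normalization are not modelled; one transcript per gene.
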