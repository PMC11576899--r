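---
title: "Ancestry-component covariance analysis: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-component covariance analysis: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ancestra)
```

## The problem

Present-day European genomes are a mosaic of three deeply diverged
ancestral components — Western Hunter-Gatherer (WHG), Early European
Farmer (EEF) and Steppe Bronze Age (SBA) — brought together by admixture
between roughly 8000 and 1000 BCE. If these source populations carried
different mean genetic values for a polygenic trait, that history leaves
a signature in today's cohorts: individuals relatively more similar to
one component should, on average, deviate in the trait. `ancestra`
implements a statistic for that similarity (covA), the regression
machinery to test trait–ancestry associations while controlling for
environmental and genome-wide stratification, and a simulator used to
calibrate what such associations can and cannot show.

## The covA statistic

For individual $i$ and ancestry $p$, over a locus set $S$,

$$\mathrm{covA}(i,p) = \frac{1}{|S|}\sum_{l \in S}
  \left(x_{il} - \bar f_l\right)\left(f_{pl} - \bar g_l\right),$$

where $x_{il}$ is the individual's haploid-scale dosage (diploid
dosage / 2), $\bar f_l$ the contemporary cohort mean of $x_{\cdot l}$,
$f_{pl}$ the ancestry-$p$ reference-panel frequency, and $\bar g_l$ the
unweighted mean of $f_{\cdot l}$ over the ancestries. Centring the panel
term by $\bar g_l$ makes covA a *relative* similarity:
$\sum_p \mathrm{covA}(i,p) = 0$ for every individual, so three
ancestries span two degrees of freedom, and any two of the three
genome-wide covA values capture all genome-wide covA variability. The
statistic is computed either over all variants ("GW-covA") or restricted
to trait-associated genomic regions ("TAGR-covA"): merged 20 kb windows
centred on published GWAS hits for the trait.

This closed form is a reconstruction: the statistic is defined verbally
in the literature it comes from (a covariance between individual dosage
and ancestral frequency, with respect to contemporary and ancient
means), and the specific centring above is the one that yields the
stated sum-to-zero / two-degrees-of-freedom property. Because every
model standardizes covA across individuals before regression, the
$1/|S|$ normalization (chosen so genome-wide and TAGR covA live on one
scale) has no effect on test statistics. Missing modern dosages are
skipped with per-individual renormalization rather than imputed; panel
frequencies are masked wherever any ancestry has fewer than `min_calls
= 10` non-missing calls, so all ancestries are always contrasted on the
same loci.

## Association models

Each trait is regressed on one ancestry's standardized covA plus
covariates:

$$t_i = \beta_0 + \beta_{\mathrm{covA}(p)}\,\mathrm{covA}(i,p)
  + \boldsymbol\beta_c' \mathbf c_i + \varepsilon_i.$$

Continuous traits use least squares (after preprocessing: optional log
transform, optional residualization on an adjustment covariate such as
BMI, removal of values more than 4 IQRs beyond the quartiles, then
standardization); categorical {0,1} traits use logistic regression and
ordinal traits a proportional-odds logistic regression, both reporting
odds ratios with two-sided Wald p-values. When covA is TAGR-restricted,
the genome-wide covA of two ancestries (default WHG and EEF — any pair
spans the 2-dof space, the choice merely relabels control coefficients)
enters as covariates to absorb genome-wide structure. Trait-wise
significance is controlled at Benjamini–Hochberg FDR 0.05.

The within-sibship design decomposes covA into the sibship mean and the
individual's deviation, $\mathrm{covA} = \mathrm{covA}_{sib} +
\mathrm{covA}'$, and fits both terms; the coefficient on
$\mathrm{covA}'$ is immune to environmental confounders shared within a
family and correlated with between-family ancestry, because siblings'
deviations from their family mean arise from Mendelian segregation.
Sibships are built from a kinship table by keeping pairs with kinship in
[0.177, 0.354] flagged as full siblings, taking connected components,
and dropping entirely any component that is not a pairwise-complete
full-sibling clique.

## The simulator

`run_scenario()` implements a hybrid scheme:

1. **Founder phase.** For each of `n_loci` unlinked intervals, founder
   haplotypes are drawn from a neutral Kingman coalescent at
   mutation–drift equilibrium in the ancestral population
   (infinite-sites mutation at rate $\mu$ per bp). Intervals are
   non-recombining in this phase; recombination is handled forward in
   time.
2. **Forward phase.** From the deepest split a diploid Wright–Fisher
   simulation takes over: the WHG-like branch splits first, the
   remaining branch later splits into EEF- and SBA-like branches. Each
   generation, parents are sampled with probability proportional to
   Gaussian fitness $w_i = \exp(-(t_i - \theta)^2 / 2\omega^2)$ of the
   trait value around the branch optimum $\theta$ (neutral when
   $\omega = \infty$). Gametes assort independently across intervals and
   recombine within an interval with probability $rL$ per meiosis.
3. **Trait.** One causal SNP per causal interval (a segregating founder
   site with MAF ≥ 0.01, so that the "trait-affecting SNP" of an
   interval is actually polymorphic) receives an effect
   $\beta_l \sim N(0,1)$; effects are rescaled once, at the start of the
   forward phase, so the initial Var(GV) equals $h^2$ and the initial
   trait SD is 1 — the unit in which $\omega$ and the optima are
   expressed. Environmental noise with variance $\mathrm{Var(GV)}(1 -
   h^2)/h^2$ is added each generation (for selection) and to the final
   cohort (for analysis).
4. **Admixture and labels.** The present-day lineage is the WHG
   substratum receiving two pulses: EEF at 250 generations ago
   (proportion 0.782) and SBA at 150 (proportion 0.45), so the expected
   final fractions are WHG 12%, EEF 43%, SBA 45% — the WHG value matches
   estimates for Britain and the split depth (800 generations ≈ 23 ky at
   29 y/generation) matches the divergence time of these components.
   From the first pulse onward every allele copy carries a source-
   ancestry label; a recombinant haplotype takes the label of the parent
   haplotype covering the causal site (interval midpoint for non-causal
   intervals).
5. **Sampling.** Reference panels of 100 individuals are drawn from each
   branch one generation before the first pulse affecting it — they play
   the role of the ancient genomes. The cohort is drawn from the final
   generation together with a two-generation pedigree, so that
   `filter_relatives()` can enforce "no shared parent or grandparent".

GWAS-like discovery is mimicked by `ascertain_causal()`: causal SNP $l$
is retained iff its explained variance fraction $2 f_l (1 - f_l)
\beta_l^2 / \mathrm{Var}(t) \ge \tau$. The default $\tau =
1.5\times10^{-4}$ was calibrated once from the closed-form neutral
frequency spectrum (before any simulation was run) so that the default
full-scale architecture (1000 causal loci, $h^2 = 0.5$) retains roughly
45–50% of causal loci, the middle of the plausible discovery range;
smaller polygenicity mechanically increases the retained fraction, as
in real GWAS.

### Scales

The full-scale profile (`scenario_profile("full")`) uses 1000 × 20 kb
intervals, $\mu = 1.25\times10^{-8}$, $r = 10^{-8}$, branch Ne 10,000
and a 10,000-strong cohort. All analyses in the test suite and the
reproduction script use the desk-scale profile
(`scenario_profile("test")`): populations, times and cohort divided by
10 and intervals shortened to 5 kb, with $\mu$ and $r$ multiplied by 40
so that the population-scaled compound parameters — per-interval
$\theta = 4N_e\mu L$, $\rho = 4N_e r L$ and drift time $t/2N_e$ — all
match their full-scale values. The desk cohort is 2000 rather than 1000:
the sampling SE of a regression slope on standardized covA is
$\approx 1/\sqrt n$ in trait-SD units, and at $n = 1000$ that noise
(0.032) would be comparable to the drift-induced slope spread whose
97.5th percentile (≈ 0.05) is one of the quantities of interest; at $n =
2000$ it is subdominant. This was fixed from the SE algebra before any
simulation output was inspected.

One quantity needs an explicit scale correction. Under equal optima the
replicate spread of $\beta_{\mathrm{covA}(1)}$ combines the
drift-induced *chance covariance* between genetic value and ancestry
similarity — whose variance scales as $1/n_{causal}$, an
effective-number-of-loci effect — with regression sampling noise of
variance $\approx 1/n_{cohort}$. A 97.5th percentile measured with 100
causal loci is therefore inflated by roughly $\sqrt{10}$ relative to the
1000-locus architecture. `project_threshold()` removes this by rescaling
the empirical percentile by the implied total-SD ratio; the
$1/n_{causal}$ scaling was checked by simulation at an intermediate
locus count (replicate SD 0.053 at 100 loci, 0.035 observed at 400
versus 0.033 predicted). Equal-optimum thresholds quoted by the package
are the projected values.

Desk-scale grid sizes used by the tests and the reproduction script:
the optimum-shift family runs 10 scenarios (5 shift magnitudes × 2
shifted ancestries) × 5 replicates, the equal-optimum family 4 scenarios
(ω ∈ {1,2} × h² ∈ {0.3,0.8}) × 9 replicates, plus 5 neutral replicates;
the ascertainment check runs once with 1000 causal intervals at the
desk-scale population profile, which preserves the causal frequency
spectrum and the varexp distribution the retained count depends on.

### What the generator emulates, and what it does not

It reproduces: three-population divergence under stabilizing selection
with optional optimum shifts, pulse admixture with realistic
proportions, equilibrium standing variation with realistic per-interval
diversity, heritability-controlled phenotypes, per-copy local ancestry,
pedigree structure in the final generations, and pre-admixture ancient
reference sampling. It does not model: new mutations during the forward
phase (the forward epoch, 800 generations, is short against $4N_e$, so
their contribution to common variation is negligible — but very recent
rare variation is absent), chromosome-scale linkage (intervals are
unlinked by design, as are the real TAGRs to a first approximation),
dominance or epistasis, mate choice, reference-panel missingness or
damage, and any environmental stratification. Passing tests therefore
show that the statistic and models behave as intended under the stated
genetic architecture, not that real-biobank confounding is fully
represented; the within-sibship machinery is exercised with synthetic
family-level confounders instead.

## Numerical and design choices

* **Coordinates.** VCF input is 1-based; all internal intervals are
  0-based half-open (BED convention). TAGR windows are `pos − 1 ±
  window/2`, clipped at 0, merged when overlapping or adjacent.
* **Ties.** Ancestry rankings break ties by input label order and set a
  `tie` attribute. Quantiles use linear interpolation between order
  statistics (R type 7).
* **Degenerate inputs.** h² outside (0,1], zero genetic variance with
  h² < 1, non-positive ω, empty ancestry groups, all-masked frequency
  panels, sibships with no within variation, and perfect collinearity
  (reported with the offending column names) are all hard errors rather
  than silent results.
* **Fitness underflow.** If every individual's Gaussian fitness
  underflows to zero (a fully maladapted population under an extreme
  shift), parent sampling falls back to uniform for that generation.
* **Selection timing.** `selection_mode = "pre_admixture"` (the default
  with finite ω) applies selection in the ancestral branches and leaves
  the admixed lineage neutral; `"post_admixture"` does the reverse with
  optimum 0. The shifted-optimum grids alternate which ancestry is
  shifted between EEF and SBA so no label is privileged.
* **Determinism.** A scenario plus a seed reproduces a run bit for bit;
  grid replicates derive their seeds from the master seed by a fixed
  affine map kept below $2^{31}$.
* **Within-sibship controls.** The genome-wide covA covariates enter the
  sibling model as totals (not themselves decomposed); the within
  coefficient of interest is unaffected by this choice because the
  decomposition of the tested covA is exact.

## Known limitations

The covA closed form is one member of the family of statistics
compatible with its verbal definition (per-locus weighting and variance
scaling could differ); the sum-to-zero and standardization contracts,
which the tests pin down, are the binding properties. The equal-optimum
97.5th-percentile threshold is sensitive to the assumed demography
(split times and Ne are literature-informed defaults, not fitted), so at
desk scale it should be read as an order-of-magnitude calibration.
Local-ancestry true-positive rates are intrinsically lower for the
minor (WHG-like, 12%) component, whose local frequencies drift most
after admixture.
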