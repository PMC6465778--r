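---
title: "Reference-powered association testing: model, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-powered association testing: model, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrpat)
```

## The problem

A case-control GWAS with a few hundred cases is underpowered: real
susceptibility alleles sit just above the genome-wide significance threshold
and are reported as negative. Public population panels such as the gnomAD
non-Finnish European allele counts offer tens of thousands of extra
chromosomes that could serve as auxiliary controls — but pooling them naively
with the study controls is dangerous, because any allele-frequency
differentiation between the study's control group and the panel (population
stratification, genotyping-platform differences) is read by the pooled test
as a case signal and inflates the type-I error.

`rrpat` implements a per-SNP statistic that takes the reference's power while
charging a price for control-reference differentiation.

## The statistic

At one biallelic SNP, write allele-count tables for case (ca), control (co)
and reference (re). Two Fisher exact tests are computed:

* $p_1 = P(\mathrm{ca} - (\mathrm{co}+\mathrm{re}))$: case versus the pooled
  control + reference counts — the powerful but fragile comparison;
* $p_2 = P(\mathrm{co} - \mathrm{re})$: control versus reference — a pure
  measure of how much the panel disagrees with the study's own controls.

The test statistic is the difference of their logs:

$$T = \ln p_1 - \ln p_2 .$$

Under the null hypothesis that all three groups share one allele frequency,
$p_1$ and $p_2$ are independent and (treating them as continuous) uniform on
$(0,1)$, so $-\ln p_1$ and $-\ln p_2$ are Exponential(1) and their difference
$-T$ — hence $T$ — follows a standard Laplace(0,1) distribution. The
lower-tail probability of $T$ has a closed form directly in the two
p-values:

$$
P(T) \;=\;
\begin{cases}
 \dfrac{p_1}{2\,p_2}, & p_1 \le p_2,\\[1ex]
 1 - \dfrac{p_2}{2\,p_1}, & p_1 > p_2.
\end{cases}
$$

Both branches give $1/2$ at $p_1 = p_2$; $P(T)$ increases in $p_1$ and
decreases in $p_2$, so control-reference differentiation always *weakens* the
claimed significance — $p_2$ acts as a penalizer of the pooled comparison.

```{r}
p_of_t(0.01, 0.5)    # pooled signal strong, panel compatible
p_of_t(0.01, 0.05)   # same signal, but the panel disagrees with the controls
```

### The compatibility gate

The penalty is proportional, not absolute: under *severe* stratification or a
platform artifact the correction is no longer trustworthy. The package
therefore flags every SNP with $p_2 <$ `gate` (default 0.01) as
`reference_compatible = FALSE`. `run_rrpat()` exposes both policies a user
might want — keep such SNPs visible but flagged (`gate_action = "flag"`, the
default, so artifacts can be inspected) or remove them
(`gate_action = "filter"`). A flagged SNP can never be classified as
`rescued`.

### Assumptions and their failure modes

* **Independence of $p_1$ and $p_2$.** Exact only asymptotically — the
  control counts enter both tables. At the group sizes the method targets
  (controls a small fraction of the pooled group) the dependence is weak; the
  simulation suite measures the residual miscalibration directly.
* **Continuity.** Fisher p-values are discrete and stochastically larger than
  uniform, so $P(T)$ computed from them is *conservative* under the null
  rather than exactly Laplace. The exact Laplace calibration is verified on
  continuous uniforms; the simulated type-I error of the discrete pipeline is
  verified to stay at or below the nominal level.
* **Allele-level testing.** Counts of allele copies, not genotypes, are
  compared; there is no covariate adjustment, no imputation, and no
  genotype-model (dominance) flexibility. This mirrors the Fisher-exact GWAS
  tradition the statistic extends.
* **Sidedness.** The component Fisher tests are two-sided
  (minimum-likelihood rule), the GWAS convention; a one-sided variant that
  penalizes only same-direction control-reference drift would be
  conceivable, but it is not what the closed form above models, and the
  package keeps direction handling in the component tests (configurable via
  `alternative`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gate` | 0.01 | compatibility threshold on $p_2$; below it the reference-powered result is not trusted |
| `threshold` / `m`, `family_alpha` | `family_alpha / m` | per-SNP significance cutoff; `m` defaults to the number of SNPs tested after QC, and published genome-wide cutoffs (e.g. $1.2\times10^{-7}$, $7.14\times10^{-8}$) can be set directly |
| HWE `threshold` | 0.001 | exact-test p-value below which a SNP is removed |
| HWE `population` | `"control"` | genotypes tested; HWE departures in cases can be genuine signal, and the reference carries no genotypes, so controls are the default (``"both"`` pools case + control) |
| rejection rule | strict `p < alpha` | the conservative reading; `strict = FALSE` uses `<=` |
| `alternative` | `"two.sided"` | sidedness of all component Fisher tests |

## Numerical implementation

The statistic lives on log p-values end to end:

* The Fisher tests are computed with a vectorized log-space enumeration of
  the hypergeometric support (`stats::dhyper(log = TRUE)` plus a sorted
  cumulative log-sum-exp whose deep-tail entries are recomputed against a
  local maximum). Pooling a study against $10^5$ reference chromosomes
  routinely produces $p_1 \sim 10^{-300}$ or smaller; ratios are formed in
  log space and exponentiated last, and results expose `neg_log10_p_t`,
  which stays exact even where `p_t` itself underflows double precision.
* Ties in the minimum-likelihood rule use the same $1 + 10^{-7}$ relative
  tolerance as `stats::fisher.test`, with which the implementation agrees to
  $10^{-12}$ (it exists separately because a simulation needs ~$10^5$ exact
  tests per scenario and log-scale output).
* The branch condition of $P(T)$ is implemented as $p_1 \le p_2$ exactly;
  both branches agree at the tie.
* A table with a zero margin (e.g. both groups monomorphic) admits one
  outcome and returns $p = 1$; zero or out-of-range p-values and empty
  groups are errors, never silent values.
* The exact Hardy-Weinberg test enumerates all heterozygote counts of
  matching parity with log-gamma closed forms and the same tie rule.

## The simulation study

`run_scenario()` draws, per replicate, one alt-allele count per group from
$\mathrm{Binomial}(2N, q)$ and records rejection proportions of the four
tests (pooled, control-reference, plain case-control, and $P(T)$) at each
significance level, with Monte-Carlo standard errors
$\sqrt{\hat r(1-\hat r)/R}$. Design points:

* **Monomorphic replicates** (common at $q = 0.001$ with small groups) give
  all Fisher p-values 1 and $P(T) = 0.5$; they count as non-rejections and
  are never dropped — dropping them would bias the type-I error upward.
* **Reproducibility.** Each scenario runs under its own seed through
  `withr::with_seed()`; identical seeds give bitwise-identical results, and
  `build_grid()` derives one stream seed per cell from a master seed so any
  subset of the grid reproduces identically.
* **The factorial grid.** `build_grid()` spans case sizes
  100/500/1000/3000, control multipliers 0.5/1/2/5, reference sizes
  $10^4/10^5$, reference frequencies 0.001–0.3, control frequency
  multipliers 1/1.1 and case multipliers 1/1.1/1.5/3 — 1,280 parameter
  cells, each simulated with a configurable replicate count (default
  100,000).

The representative scenarios bundled into the test suite show the method's
three headline behaviours: under the full null every test holds its level
(with the expected slight conservativeness); under control-reference drift
($q_{ca} = q_{co} = 1.1\,q_{re}$) the naive pooled test's false-positive
rate explodes while $P(T)$'s stays far lower and *falls* as controls
outnumber cases; and under genuine case effects $P(T)$'s power dominates the
plain case-control test's, dramatically so for rare alleles.

The test suite runs these checks at 20,000 replicates per scenario and
compares against reference rates estimated at 100,000 replicates, so
tolerances are 3 standard errors of the *difference* of the two estimates;
`scripts/acceptance.R` uses 100,000 replicates for the full-null scenario
(needed to resolve the $\alpha = 0.001$ tail) and 20,000 elsewhere. These
sizes were chosen so the whole battery runs in minutes on one core while
keeping every comparison's Monte-Carlo error well under the effect sizes
being verified.

## The synthetic cohort generator

`generate_cohort()` produces study genotypes, a reference table and a truth
table from a `cohort_spec()`. It emulates exactly the statistical structure
the statistic assumes — independent SNPs; per-group binomial allele
frequencies; genotypes in Hardy-Weinberg proportions ($p^2, 2pq, q^2$)
within each group, a refinement over allele-count-only simulation needed to
exercise the HWE filter and the VCF path; multiplicative control+case versus
reference stratification; planted case-effect SNPs; and planted HWE
violations via a heterozygote-deficit factor (weights
$p^2, 2pq\cdot d, q^2$, renormalized). Ref/alt alleles are drawn avoiding
A/T and C/G pairs so every generated SNP is strand-unambiguous and joinable.

It deliberately does **not** emulate linkage disequilibrium, realistic
site-frequency spectra, genotyping error, call-rate artifacts or platform
batch effects. Tests passing on generated cohorts therefore demonstrate
calibration and power *under the idealized sampling model* — they do not
certify behaviour on real array data, where the compatibility gate and HWE
filter carry the burden the generator does not model.

## Pipeline conventions

* **Reference joining** matches by (chromosome, position) with `chr`
  prefixes normalized, then reconciles alleles: exact, swapped
  (alt count becomes $AN - AC$), strand-complemented, and
  complemented+swapped, in that priority; A/T and C/G study SNPs are
  dropped as strand-ambiguous, and every drop is logged with a reason.
  A site-match rate below 50% warns about a probable genome-build mismatch.
  Multi-allelic reference records are split into biallelic rows before
  joining ($AN$ shared, one $AC$ per alternate).
* **Genomic inflation** is the median-based $\lambda$: the median of
  $\chi^2_1$ quantile transforms of the p-values divided by
  $\mathrm{qchisq}(0.5, 1) \approx 0.4549$.
* **Classification.** At the chosen threshold each SNP is `positive_both`,
  `rescued` (significant only by $P(T)$, gate passed — the variants the
  reference recovers), `lost` (significant only by the plain test) or
  `negative`; a gate-failed SNP whose only significant result is $P(T)$ is
  classified `negative` because that result is untrusted.
* **Counts, not frequencies,** are the internal currency; a
  frequency-only reference must be converted (lossily, by rounding
  `frequency * chrom_total`) before entering the pipeline.
* Missing genotypes are excluded from that SNP's counts only; positions are
  1-based as in VCF; build agreement between study and reference is the
  caller's responsibility beyond the match-rate warning.

## A worked example

```{r example}
spec <- cohort_spec(
  n_case = 300, n_control = 300, n_ref = 5000, n_snps = 400,
  effect_snps = data.frame(index = 1, multiplier = 1.5, q_ref = 0.15),
  seed = 7
)
cohort <- generate_cohort(spec)
joined <- join_reference(cohort$snps, cohort$reference)
kept <- hwe_filter(joined)$kept
result <- run_rrpat(kept, m = nrow(kept))
glance(result)
tidy(result) |>
  dplyr::filter(rescue_class != "negative") |>
  dplyr::select(rsid, p_ca_co, p_co_re, p_t, rescue_class)
```

## Known limitations

* The statistic treats component p-values as continuous; at very small
  counts (rare alleles, tiny cohorts) the discreteness makes $P(T)$
  conservative, costing some power rather than validity.
* One reference at a time; combining multiple panels is the caller's
  problem (run the pipeline once per panel and compare).
* No covariate adjustment or PCA-based stratification correction — the
  gate rejects strongly stratified SNPs rather than modelling the
  stratification.
* Linear-scan file handling only; inputs of a few million SNPs are fine,
  but there is no indexed random access.
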