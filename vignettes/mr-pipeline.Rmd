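---
title: "Methods: two-sample MR screening, mediation and GRS replication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening, mediation and GRS replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem mrflow addresses

Microbiome-wide causal screens ask whether the abundance of individual
gut microbial taxa affects a disease outcome — here prototypically
atrial fibrillation — using only GWAS summary statistics. Each taxon is
treated as an exposure instrumented by the handful of SNPs that reach
suggestive significance in a metagenomic GWAS of several thousand
participants, while the outcome association for the same SNPs comes
from a disease meta-GWAS of around a million. Because hundreds of taxa
are screened at once, discoveries are controlled by the false discovery
rate; because instruments may be pleiotropic, a battery of estimators
with different identifying assumptions is run alongside the primary
one; and because a causal taxon may act through known risk factors,
mediation is quantified by two-step MR. A final, independent line of
evidence associates per-individual weighted genetic risk scores with
incident disease in a prospective cohort.

## Statistical model

For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its per-allele
effect on the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its
effect on the outcome (log odds for binary outcomes). Under the
instrumental-variable assumptions the per-SNP Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect $\theta$, and the estimators combine the ratios:

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ through the origin with weights
  $w_j = 1/\sigma_{Yj}^2$, algebraically the $w_j\hat\beta_{Xj}^2$-
  weighted mean of the ratios. The default multiplicative
  random-effects SE multiplies the fixed-effect SE by
  $\max\{1, \sqrt{Q/(J-1)}\}$, where $Q$ is Cochran's statistic, so
  heterogeneity can widen but never narrow the interval.
* **MR-Egger** — the same regression with an intercept, after
  orienting every $\hat\beta_{Xj} \ge 0$; the intercept estimates
  directional pleiotropy (valid under InSIDE), and the slope remains a
  causal estimate when the intercept is genuinely non-zero. SEs use
  the residual scale floored at one and t-tests on $J-2$ df.
* **Weighted median** — the ratio at cumulative weight one half with
  weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ and the interpolation
  convention $p_j = (S_j - w_j/2)/S_J$; consistent while valid
  instruments carry a majority of the weight.
* **Modes** — the argmax of a gaussian kernel density over the
  ratios (bandwidth $0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$ times
  a user factor), weighted by inverse ratio variance or not;
  consistent when the largest cluster of agreeing ratios is valid.
* **MR-PRESSO** — a parametric-simulation test of the leave-one-out
  weighted residual sum of squares, with per-SNP outlier flags
  (Bonferroni-corrected empirical p-values) and a distortion test that
  compares the outlier-corrected IVW shift against random removals of
  the same size.

Median and mode SEs come from a parametric bootstrap that redraws both
$\hat\beta_{Xj}^*$ and $\hat\beta_{Yj}^*$ from their sampling
distributions; this is why those estimators carry exposure-side
uncertainty that the analytic IVW/Egger SEs do not (see *Limitations*).

Dispatch follows instrument count: one SNP gives the Wald ratio, two
give IVW only, three or more add Egger/median/modes, four or more add
MR-PRESSO. Screening adjusts the primary (IVW or Wald) p-values by
Benjamini–Hochberg with the denominator equal to the number of
exposures *attempted* — a taxon whose instruments all failed selection
still counts toward the correction, mirroring a screen corrected for
all 207 taxa.

Mediation uses the product-of-coefficients decomposition: with
$\beta_1$ the taxon→risk-factor effect, $\beta_2$ the
risk-factor→outcome effect and $\beta_3$ the taxon's total effect, the
proportion mediated is $\beta_1\beta_2/\beta_3$, with a percentile CI
from a parametric bootstrap that treats the three coefficients as
independent normals (they come from non-overlapping two-sample fits).
Multivariable MR — weighted least squares of outcome effects on the
matrix of exposure effects without intercept — validates the mediator
by estimating each exposure's direct effect conditional on the others;
with a single exposure column it reduces to IVW exactly, which is also
how it is tested.

The cohort stage computes per-individual weighted genetic risk scores
$s_i = \sum_k w_k d_{ik}$ (weights are the exposure-GWAS instrument
betas, dosages mean-imputed when missing), excludes prevalent cases
(event on or before recruitment), and fits a Cox proportional-hazards
model of incident events on the score with Efron tie handling via the
`survival` package, reporting the hazard ratio per score unit, Wald CI
and the global Schoenfeld-residual test on the event-time rank scale.
Competing deaths are censored in this primary fit; subdistribution
(Fine–Gray) modelling is deliberately out of scope.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `p_threshold` | 1e-5 | instrument inclusion p-value (suggestive, as used for taxon GWAS) |
| `eaf_floor` | 0.01 | minor-allele-frequency floor, applied to `min(eaf, 1-eaf)` |
| `clump_r2`, `clump_kb` | 0.001, 10000 | greedy clump threshold and half-window (kb) |
| `proxy_r2` | 0.8 | minimum r² for outcome-side proxy substitution |
| `palindrome_eaf_window` | 0.08 | ambiguous-frequency zone 0.42–0.58 for A/T, C/G SNPs |
| `alpha` | 0.05 | FDR significance level of the screen |
| `riskfactor_p` | 0.005 | significance screen for mediator→outcome effects before mediation |
| `reverse_p` | 5e-8 | instrument threshold for reverse-direction MR |
| `n_boot` | 1000–2000 | bootstrap draws (median/mode SEs; mediation CI) |
| `n_sim` | 1000 | MR-PRESSO simulations; the global p is floored at 1/(n_sim+1) |

The EAF filter is read as a minor-allele-frequency floor because a
literal `eaf > 0.01` would retain near-monomorphic variants with
`eaf ≈ 1`, which cannot serve as instruments. The palindrome window
0.08 is the de-facto community default; the analysis that motivated
this package used frequency inference without printing a cut-off, so
the window is exposed as a parameter and setting it large effectively
drops all palindromes.

## What the synthetic generator emulates

`sim_sumstats()` draws, per SNP, a minor-allele frequency from
`maf_range`, a true exposure effect $\gamma_j \sim N(0,
\texttt{gamma\_sd}^2)$, and observed effects around the truth with the
analytic GWAS standard error $1/\sqrt{2f(1-f)n}$. Outcome effects are
$\Gamma_j = \theta\gamma_j + \alpha_j$ with $\alpha_j$ zero, balanced
or directional. The defaults encode the study conditions this package
is built around: an exposure GWAS of $n = 7{,}738$, an outcome
meta-GWAS of $n \approx 1.03$M, and `gamma_sd = 0.15`, the effect
scale at which essentially every selected instrument clears the
$F > 19$ strength bar reported for such screens. Instruments are
simulated LD-independent (a post-clumping world); an optional block-LD
mode generates correlated candidates plus the matching LD matrix
purely to exercise the clumping code.

`sim_triangle()` builds a mediation triangle with defaults
$\beta_1 = 0.05$, $\beta_2 = 0.336$, $\delta = 0.123$, i.e. a total
effect $\beta_3 = \ln 1.15$ and a true proportion mediated of 12.0% —
the regime of a taxon acting partly through body-mass index. The
observed taxon-exposure effects are shared between the taxon–mediator
and taxon–outcome pairs, as happens when both fits reuse one exposure
GWAS; the bootstrap nevertheless treats the coefficients as
independent, which makes its CIs mildly conservative.

`sim_cohort()` produces dosages $\sim$ Binomial(2, maf), covariates
(age, sex, four PCs, batch, centre) with modest hazard effects, a true
hazard ratio of 1.14 per score unit, a 0.5%/year baseline hazard and
exponential loss/death processes tuned to give roughly 5–7% incident
events over ~11.5 years of mean follow-up, plus a configurable
prevalent fraction. Default cohort size is 50,000 — large enough for
stable Cox estimates, small enough that replicate calibration studies
run in minutes.

What the generator does **not** emulate: LD between instruments and
non-instruments (beyond the block mode), winner's-curse selection of
instruments in the discovery GWAS, population stratification,
liability-scale binary traits (binary outcomes are simulated directly
on the log-odds scale), genotype–covariate correlation, and
administrative censoring calendars. Passing calibration tests on this
generator therefore demonstrates internal statistical correctness
under the stated model, not robustness to those real-data features.

## Numerical choices

* P-values printed as zero are floored at 1e-300 so $-\log_{10}p$
  stays finite.
* Clumping ranks by ascending p-value with lexicographic `variant_id`
  tie-breaks, making the greedy result fully deterministic; pairs
  absent from the LD table count as unlinked.
* All CIs are Wald-type $\hat\beta \pm 1.96\,\mathrm{se}$; odds-ratio
  columns are $\exp(\cdot)$ transforms of the same interval.
* Empirical p-values (MR-PRESSO global, outlier and distortion tests)
  use the $(1 + \#\{\text{exceedances}\})/(n+1)$ convention, so they
  are never zero.
* If all per-SNP ratios coincide, the kernel bandwidth degenerates;
  the mode estimators then return the common ratio directly.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; `mr_run_study()` derives all stage seeds from
  one master seed, so a study run is reproducible byte-for-byte in its
  manifest.

## Design decisions that were genuinely open

* **F-statistics** use the single-SNP approximation $(\beta/se)^2$;
  per-SNP $R^2$ and exact per-variant sample sizes are not uniformly
  available across source GWAS, and the two agree to first order.
* **Egger calibration**: the intercept test is calibrated under its
  own null — balanced pleiotropy around zero. Under exactly zero
  pleiotropy the $\max(1,\sigma)$ residual floor makes the test
  conservative by construction; the package documents rather than
  "fixes" this, since removing the floor would allow intervals
  narrower than fixed-effects.
* **Directional pleiotropy is orientation-relative**: with exposure
  effects of both signs, adding a constant to every outcome effect
  becomes balanced after Egger's sign orientation. The recovery tests
  therefore inject pleiotropy after orientation.
* **Proxy substitution** swaps in the proxy variant on *both* the
  exposure and outcome side (the proxy's own exposure association is
  available in the full exposure GWAS), which avoids guessing allele
  phase from r² alone; proxies are restricted to the same chromosome
  when positions are known.
* **Mediation bootstrap** resamples coefficients, not instruments —
  the instrument-level data needed for the latter are not part of the
  published mediation summaries this mirrors.
* **Overlap bias** uses the first-order approximation
  `overlap × confounded_assoc / F̄`; the web tool it stands in for
  does not print its formula, so the approximation is documented as
  such.

## Known limitations

The analytic IVW and Egger standard errors condition on the observed
exposure effects. When the outcome GWAS is two orders of magnitude
larger than the exposure GWAS — precisely the microbiome-screen
regime — the neglected exposure-side error produces a regression
dilution of order $\sigma_X^2/E[\beta_X^2]$ (about 1–2% here) that can
rival the IVW SE itself once many instruments are combined. In the
package's own calibration runs this shows up as under-coverage of the
IVW/Egger intervals at larger true effects, while the
bootstrap-based weighted median and mode retain nominal coverage; the
acceptance script reports all four coverages so the effect is visible
rather than hidden. Screens should therefore read the IVW point
estimate as mildly attenuated toward zero at this sample-size
asymmetry. Other limitations: no Steiger directionality filtering, no
correlated-instrument IVW (instruments are clumped upstream), no
Fine–Gray competing-risks stage, and no real-genotype handling (VCF /
BGEN parsing is out of scope).

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- study_config(
  n_taxa = 20,
  signal_taxa = list(list(id = "taxon_A", theta = log(1.4), n_snps = 10)),
  sim = sim_config(cohort_n = 5000, seed = 7),
  methods = "primary", seed = 7
)
res <- mr_run_study(cfg, "study_out")
res$screen[res$screen$significant, ]
```

The per-stage TSVs, the JSON manifest (seeds, thresholds, stage
status) and the run log land in `study_out/`.
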