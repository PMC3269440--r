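---
title: "Quantifying and correcting systematic noise in nested microarray experiments"
author: "batchscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting systematic noise in nested microarray experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchscope)
```

## The problem

Microarray expression measurements carry systematic noise introduced by the
processing hierarchy: arrays sit on chips, chips are hybridised in runs
(typically one run per day), runs belong to experiments that may be separated
by months and by fresh rounds of amplification and labelling. Samples that
share a unit at any of these levels share a component of error. When the
grouping of biological interest is confounded with this hierarchy, batch
noise masquerades as biology; when it is merely crossed with it, batch noise
inflates within-group variance and costs power. batchscope quantifies the
noise level by level, removes it probe-wise, and evaluates how well control
samples (a generic reference RNA versus pools mixed from the study's own
samples) track the batch shifts that clinical samples actually experience.

## The nested variance model

For each probe $g$ the log2 expression of sample $j$ is modelled as

$$y_{gj} = \mu_g + x_j^\top\beta_g + \sum_{l} b_{u_l(j),g} + \varepsilon_{gj},$$

where $x_j$ codes optional fixed biological effects (cell line, treatment
group), $u_l(j)$ is the unit of nesting level $l$ (experiment, run, chip)
that sample $j$ belongs to, $b_{u,g} \sim N(0, \sigma_{l,g}^2)$ are
independent random batch effects and
$\varepsilon_{gj} \sim N(0, \sigma_{e,g}^2)$ is the residual
(between-arrays-within-chip) error. All modelling is on the log2 scale, so
the Gaussian components correspond to log-normal multiplicative noise on the
intensity scale.

Two estimators are provided.

* `fit_nested_mom()` — classical balanced nested ANOVA. Mean squares are
  formed at every stratum and the triangular expected-mean-squares (EMS)
  system is solved; negative solutions are truncated at zero (the signed
  solutions are also kept, see below). It requires equal children counts at
  every level and, when a fixed factor is present, balance of that factor
  within every innermost unit; anything else raises an error that points to
  the REML path.
* `fit_nested_reml()` — restricted maximum likelihood for arbitrary nested
  designs. The restricted log-likelihood is maximised over log-variances
  with analytic gradients (L-BFGS-B, change tolerance $10^{-8}$, cap 200
  iterations); a box bound 32 log-units below the total variance acts as the
  zero boundary and a final polish snaps any component there whenever doing
  so costs less than the tolerance, because the restricted likelihood is
  flat in log-variance as a component vanishes. Fixed effects are estimated
  by generalised least squares inside each evaluation. On balanced designs
  with interior solutions the optimum coincides with the EMS solution (the
  fit is warm-started there), which is also the package's agreement test.
  Levels represented by a single unit are inestimable and reported `NA`;
  zero-variance probes are flagged and skipped.

`decompose_variance()` applies either fit probe-wise and reports, per level,
the cross-probe mean SD, the pooled RMS SD $\sqrt{\overline{\hat\sigma^2}}$,
and the percent contribution $100\,\overline{SD}_l / \sum_k \overline{SD}_k$
computed on the SD scale. Two summaries are kept deliberately. The mean SD
is the conventional basis for percent contributions, but as an estimate of a
common level SD it is biased low at small unit counts: with three
experiments the between-experiment mean square has two degrees of freedom
and Jensen's inequality on the square root costs roughly 20% of the SD. The
pooled RMS (equivalently, averaging the variance estimates before taking the
root) is the natural aggregate when probes share the level SD and is the
quantity used in recovery checks. Conversely, truncation at zero biases
per-probe components upward under the null, which is why the raw signed EMS
solutions (`variance_raw`) back all pooled and unbiasedness checks.

## Empirical-Bayes batch correction

`combat_fit()`/`combat_apply()` implement the parametric empirical-Bayes
location/scale adjustment in three stages.

1. **Standardisation.** Per probe, a location model with intercept, optional
   covariates and batch terms under the batch-size-weighted zero-sum
   constraint ($\sum_i n_i \hat\gamma_{ig} = 0$) is fitted by least squares;
   the pooled residual SD $\hat\sigma_g$ yields the standardised grid
   $z_{gj}$. Standardising first stops high-expressed, high-variance probes
   from dominating the prior estimates.
2. **Hyperpriors by the method of moments.** Per batch $i$ and probe $g$,
   the sample mean $\hat\gamma_{ig}$ and variance $\hat\delta^2_{ig}$ of
   $z$ are computed. A normal prior for the additive effects takes the
   cross-probe mean and variance of $\hat\gamma_{ig}$; an inverse-gamma
   prior for the scale effects is matched through its mean
   $\theta/(\lambda-1)$ and variance $\theta^2/((\lambda-1)^2(\lambda-2))$.
3. **Posterior expectations.** The conditional posterior means
   $\gamma^*_{ig}$ and $\delta^{*2}_{ig}$ are iterated from
   $(\hat\gamma, \hat\delta^2)$ to convergence (max absolute change below
   $10^{-6}$, cap 100) and the adjusted value is
   $\hat\sigma_g(z_{gj} - \gamma^*_{ig})/\delta^*_{ig} + \hat\alpha_g +
   x_j^\top\hat\beta_g$.

Design choices worth knowing:

* Known biological covariates are included in the location model by default
  (`covariates = "group"` in the pipeline), so the correction does not eat
  the biology; samples without a covariate value (control replicates) form
  their own level. Full confounding of covariates with batch is an error,
  never a silent fit — correcting a fully confounded design would remove
  the effect under study along with the batch.
* Correction at two nested levels (by experiment, then by run) is performed
  sequentially outermost-first via `combat_correct()`.
* With a single batch the adjustment is unidentifiable and the model
  degenerates to the identity.
* The scale estimates centre at $N/(N-n_\text{batches})$ rather than 1
  because the pooled variance divides by $N$ while the per-batch sample
  variances divide by $n_i - 1$; this matches the reference implementation
  and is asserted in the tests.
* Empirical-Bayes correction shrinks, but cannot annihilate, the sampling
  noise of per-probe batch means; a second correction pass therefore still
  moves values by roughly $\sigma/(2\sqrt{n_i})$. The meaningful target is
  the systematic between-batch variance component, which the tests show is
  driven to zero while planted fold changes are preserved.

`mean_center()` provides the per-probe mean-centring baseline; with
shrinkage and scale adjustment disabled the empirical-Bayes correction
reduces to it exactly.

## Inter-batch calibrators

The same source RNA hybridised in two batches isolates the batch shift:
`batch_shifts()` collects, for every duplicate clinical pair and every pair
of control replicates spanning the same two units of a batch level, the
per-probe difference $\Delta_g$ oriented by lexicographic batch label order
(the same orientation for samples and controls, so signs cancel in
correlations). `calibrator_fidelity()` correlates a control pair's shift
with a sample pair's shift, overall and restricted to probes whose absolute
sample shift exceeds cumulative thresholds (0, 0.5, 1.0, 1.5 log2 units by
default) — how faithfully a calibrator tracks the batch effect grows with
the magnitude of the shift. `compare_calibrators()` runs the one-sample,
two-tailed t-test on per-pair fidelity differences, and
`count_batch_regulated()` counts probes shifted more than a fold threshold
(strictly) in at least a given number of duplicate pairs.

The generator gives this comparison teeth through the expression-coupling
weight: a probe's realised batch shift in a sample is scaled by
$w_{gj} = (1-\kappa) + \kappa\, s_{gj}$, where $s_{gj}$ is the probe's
within-sample expression rank mapped to $[0,1]$. A pooled control shares the
member samples' expression ranks, so its shifts co-vary with theirs; a
generic control has an independent profile and cannot. At $\kappa = 0$ the
two calibrator types are exchangeable by construction — the package's null
check. The rank-based monotone map is a deliberate minimal mechanism: batch
response must depend on the sample's expression profile for pooled
calibrators to win, and the exact physical mechanism is not modelled.

## Probe properties

GC-dependent vulnerability is modelled as a step function: probes with GC
fraction below a cutoff (default 0.55) have their level SDs multiplied by a
configurable factor, optionally only at selected levels. `gc_sd_enrichment()`
cross-tabulates (GC below cutoff) × (SD above cutoff) and applies the
Pearson chi-squared test without continuity correction; the SD cutoff
defaults to the 90th percentile of the SD vector, which adapts to each
level's magnitude and makes the result invariant to monotone transforms of
the SDs. Results with any expected cell below 5 are flagged, not suppressed.
`gc_distribution_shift()` contrasts a probe subset's GC density (Gaussian
kernel) against the probe universe with a goodness-of-fit chi-squared on
0.05-wide bins, and `position_sd_association()` checks for 3'/5' positional
trends with a Spearman correlation and a seeded permutation p-value
(1,000 permutations); probe position fractions are expected already
normalised to the sense strand (antisense probes flipped as
$1 - \text{fraction}$), and `N` bases are excluded from both numerator and
denominator of the GC fraction.

## Differential expression

`de_test()` applies plain Welch or paired t-tests per probe with
Benjamini–Hochberg adjustment, calling a probe significant when it passes
both the adjusted-p cutoff and a natural-scale fold-change floor
($|2^{\Delta}| \ge 1.5$ by default, symmetric for down-regulation). Plain
t-tests stand in for moderated-t and permutation-FDR machinery on purpose:
the quantity of interest downstream — the concordance of significant-probe
lists across replicate experiments and correction regimes, via
`list_concordance()` — is method-agnostic at simulation scale. Technical
duplicates are collapsed to one array per source RNA so they never
pseudo-replicate. A pooled-variance floor is deliberately not applied by
default.

## What the generator emulates, and what it does not

`design_spec()`/`simulate_experiment()` produce an expression matrix,
sample sheet, probe sheet (with synthetic 50-mer sequences) and the full
realised truth. Defaults were fixed once, before any test outcomes, to a
scaled-down image of a combined BeadChip study:

* nesting `c(experiment = 3, run = 2, chip = 2, array = 4)` with level SDs
  0.30 / 0.15 / 0.10 and residual 0.20 log2 units — the ordering
  (outer levels noisiest) and magnitudes follow the observation that
  earlier sample-preparation stages contribute the most variation;
* per-probe baselines $N(7, 2^2)$; two groups with 10% truly differential
  probes and $N(0,1)$ log2 effects;
* one generic-control and one pooled-control replicate per chip (the
  generic control mirrors a commercial reference RNA hybridised to every
  chip; the pool averages all biological source profiles on the log2
  scale, a well-mixed approximation of physical pooling);
* duplicate clinical samples split across runs (14 pairs in the calibrator
  analyses, matching the duplicate design that motivated the method);
* expression coupling $\kappa = 0.5$ — strong enough that pooled
  calibrators measurably outperform generic ones, as observed on real
  data, while keeping batch shifts mostly shared across probes;
* probe GC targets from Beta(6, 4) (median ≈ 0.61), matching the
  deliberate high-GC bias of commercial probe designs, with the
  vulnerability multiplier defaulting to 1 (off) so that noise levels mean
  what they say unless vulnerability is the object of study;
* detection confidences from a logistic map of true expression (midpoint 4,
  scale 0.7, logit noise 0.5), giving realistic 20–40% filter losses at the
  default baseline; the confidence score itself is treated as an opaque
  quantity in [0, 1], larger is better;
* an optional `outlier_chip` multiplier can inflate one chip's SD to mimic
  a single aberrant chip, without claiming anything about the cause of
  such outliers in real data.

The generator does not model dye or scanner physics, spatial artefacts
within a chip, bead-level replication, background correction, or
probe-sequence-specific hybridisation thermodynamics. Passing tests
therefore demonstrate correctness of the estimators and the internal
consistency of the analysis chain under the stated noise model — not
fidelity to any particular real data set.

## Numerical choices and problem sizes

Quantile normalisation delegates to the standard rank-wise-mean
implementation; ties receive the mean of the reference values at their tied
ranks, which keeps the operation exactly idempotent. The pipeline
(`run_pipeline()`) derives per-stage seeds from one global seed so stages
are individually reproducible, validates its configuration against a closed
key schema, writes all artifacts as TSV/FASTA with MD5 digests logged, and
aborts on the first failing stage by name. Stage-wise resumption from cached
artifacts is not implemented; determinism is provided by the seeding scheme
instead.

Test and acceptance runs use deliberately modest sizes — 1,000–5,000 probes,
24–48 arrays, 15–100 replicate simulations per property — chosen so the
whole suite exercises every claim in a few minutes while keeping Monte-Carlo
error far from each assertion's margin. Empirical checks quoted in the
tests (estimator bias of mean-of-SD summaries, the $N/(N-n_b)$ centring of
scale estimates, boundary rates of null components near 50%) were measured
under exactly these conditions.

## Known limitations

* Only strictly nested random designs are supported — no crossed random
  effects, no covariances between levels, no heavy-tailed error models.
* The correction implements the parametric empirical-Bayes variant only.
* Balanced-design EMS requires fixed-factor balance within innermost units;
  everything else must go through REML.
* Percent contributions inherit the biases of per-probe SD summaries
  discussed above; compare the `rms_sd` column when absolute recovery
  matters.
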