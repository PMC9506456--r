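---
title: "Cumulative dietary risk assessment with cumrisk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative dietary risk assessment with cumrisk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumrisk)
library(dplyr)
```

## The assessment problem

Metalaxyl-M and azoxystrobin are systemic fungicides co-formulated against
*Peronosporales* on scallion and registered on many other crops. Both
target the mammalian liver, so a consumer's exposure to the two should be
assessed jointly, not compound by compound. `cumrisk` implements the
relative potency factor (RPF) approach to that problem: all residues are
converted into equivalents of a single *index compound* before exposure is
simulated, and the resulting cumulative exposure is compared with the
index compound's health-based reference dose.

The pipeline has five stages, each usable on its own:

1. residue-trial summarization (STMR/HR, MRL screening),
2. dissipation kinetics,
3. RPF cumulation per food category,
4. nested two-dimensional Monte Carlo exposure simulation with risk
   characterization,
5. contribution analysis.

## Residue summarization and censoring

A supervised trial reports, per analyte, site and pre-harvest interval, a
small number of residue concentrations, some of which are below the limit
of quantification (LOQ, here 0.001 mg/kg). The package summarizes each
analyte × interval cell by the **supervised trial median residue**
(STMR — the sample median, averaging the two central order statistics for
even `n`) and the **highest residue** (HR — the maximum). Replicate
samples from one site are treated as independent observations; for the
packaged study this is the reading (n = 8 per cell: 4 sites × 2
replicates) that reproduces the published medians.

Censored entries (`"<0.001"`) are substituted at the **full LOQ** by
default. This is deliberately conservative (it can only raise exposure),
and the packaged data are insensitive to it: the two censored values per
cell are the two smallest of eight, so the median does not move whichever
of the LOQ, LOQ/2 or 0 rules is chosen. No distributional non-detect
model (Kaplan–Meier, censored MLE) is attempted — with 2 censored points
in 8 there is nothing to estimate.

MRL compliance is strict: a highest residue exactly at the limit fails.
An analyte with no MRL on record produces an explicit "no standard" row;
silence would look like compliance.

## Dissipation kinetics

Post-application decay is modelled as single first-order:

$$C(t) = C_0 e^{-kt}, \qquad t_{1/2} = \ln 2 / k .$$

The default fit is ordinary least squares of $\ln C$ on $t$ (`k` = −slope,
`C0` = exp(intercept)) — the convention in dissipation studies, where
multiplicative measurement error makes the log scale natural. A nonlinear
refinement (`stats::nls`, initialized from the log-linear solution) is
available; on noiseless data the two coincide exactly, on noisy data they
weight early large residues differently. $R^2$ is reported on the fitted
scale (log for log-linear, original for nonlinear). A fitted $k \le 0$ is
flagged non-decaying; its half-life is undefined and decay predictions
refuse to evaluate rather than returning negative-rate extrapolations.

Censored observations are **excluded** from kinetic regressions
(`fit_dissipation()`): a value known only to be below LOQ carries no
usable information about the decay rate, and imputing it at the LOQ
flattens the tail and biases $k$ downward — on a series decaying from
2 mg/kg with $k = 0.6\,\mathrm{d}^{-1}$, the day-14 sample sits an order
of magnitude below LOQ and its imputation alone costs about 8% of $k$.
Fits are per analyte × site; pooled fits across sites would mix climates
and initial deposits. At least three distinct quantified time points are
required. Published half-lives for the packaged study (1.15/1.06 d for
metalaxyl-M, 2.28/3.89 d for azoxystrobin at two sites) ship as reference
metadata in `reference_tables()$kinetics_reference`; the underlying full
time series are not public, so they are context, not test targets.

## Method validation statistics

Matrix effect is the relative slope change between matrix-matched and
solvent calibration:
$\mathrm{ME}(\%) = 100\,(b_\mathrm{matrix} - b_\mathrm{solvent}) / b_\mathrm{solvent}$,
negative for ion suppression. It is invariant to rescaling both slopes,
so the instrument's absolute response level does not matter. Recovery
sets are summarized by the arithmetic mean and the relative standard
deviation with the $n-1$ denominator, the residue-method convention; an
RSD from a single replicate is reported as `NA` rather than 0.

## RPF cumulation

With azoxystrobin as index compound (chosen in the source study for its
richer residue base, despite being the *less* toxic of the pair), the RPF
of compound $i$ is $\mathrm{RPF}_i = \mathrm{NOAEL_{index}} /
\mathrm{NOAEL}_i$; from the liver-toxicity NOAELs of 18.2 and
8 mg/kg bw/day, metalaxyl-M gets 18.2/8 = 2.275 and the index compound
exactly 1. Within food category $j$,

$$C_{\mathrm{index},j} = \sum_i C_{i,j}\,\mathrm{RPF}_i ,$$

with missing residue entries as structural zeros. The STMR is the default
basis (central-tendency chronic assessment); the HR basis gives a
worst-case run. `cumulate_residues()` also returns each compound's share
of $C_{\mathrm{index},j}$ — the pre-cumulation attribution that the
contribution analysis reuses, and the only decomposition consistent with
the sum's linearity.

One packaged discrepancy is worth knowing: the dark-vegetables category
recomputes to $0.920 + 0.034 \times 2.275 = 0.99735$ mg/kg, while the
source table prints 0.996. The inputs printed to 3 decimals cannot
produce 0.996, so the published figure was most likely computed from
pre-rounded intermediates; the package reports the recomputed value.

## The two-dimensional Monte Carlo engine

Chronic cumulative exposure of an individual in group $g$ is

$$E = \sum_j \frac{\mathrm{CONS}_j \, C_{\mathrm{index},j}}{bw},$$

with consumption in g/day converted to kg/day, residues in mg/kg, body
weight in kg, so $E$ is in mg/kg bw/day. Risk is characterized as

$$R(\%) = 100 \cdot \frac{E}{\mathrm{NOAEL_{index}} / \mathrm{UF}},$$

with a total uncertainty factor of 100 (10 interspecies × 10
intraspecies); $R < 100\%$ is deemed acceptable.

**Inner loop (variability).** Each of `n_inner` iterations (default 2000)
draws one body weight, one consumption amount per category, and one
residue concentration per category, and evaluates $E$. Body weight and
consumption are lognormal, matched to the supplied arithmetic mean and CV
(`cv = 0` collapses to a point mass); lognormal is the standard choice
for these positive, right-skewed quantities and guarantees positive body
weights without truncation. Residues default to the **fixed**
index-equivalent value per category. An empirical mode is available: give
a category a `samples` vector (e.g. per-trial index-equivalent residues)
and each iteration draws from it. Fixed mode is the default because the
packaged per-category table carries only STMR/HR — there is no per-trial
sample set to resample for most categories.

**Outer loop (uncertainty).** Each of `n_outer` replicates (default 500)
re-realizes uncertain parameters, then runs one inner loop. The default
nonparametric model re-draws every group's per-category consumption mean
as the mean of a pseudo-sample of `pseudo_n` (default 100) consumption
records, and bootstrap-resamples any empirical residue sets; fixed
residue values carry no sampling uncertainty and stay fixed. The
`"none"` mode repeats the inner loop unperturbed, isolating pure Monte
Carlo noise — that is the configuration under which the P97.5 estimator
can be checked against the closed-form lognormal quantile
$\exp(\mu + 1.95996\,\sigma)$.

**Summaries.** Within each inner loop the requested percentiles (default
P50, P97.5, P99.9) of the risk distribution are computed with the
linear-interpolation empirical quantile (R type 7). Across outer
replicates, the reported estimate is the median and the band the
2.5th/97.5th percentiles (two-sided 95%, the default) or 5th/95th
(one-sided option) — the published convention ("upper limit of the 95%
confidence interval") does not say which was used, so both exist and the
choice is a flag.

**Reproducibility.** Every RNG stream is seeded as a deterministic
function of (master seed, group label, outer-replicate index) via a small
string hash, so repeated runs are bit-identical, results do not depend on
the order groups are listed in, and the same applies if groups were ever
processed in parallel. Because lognormal draws scale exactly with their
mean at fixed CV, common seeds also make monotonicity exact: raising a
consumption mean cannot lower any percentile, and doubling body weight
exactly halves every risk percentile.

## Contribution analysis

Contributions are ratios of means over the inner-loop samples:
compound $i$ (or category $j$) contributes
$100 \cdot \overline{E_i} / \overline{E}$ percent. Ratios of means are a
stable, well-defined population quantity; a per-percentile option
(samples in a small window around a chosen quantile of total exposure)
exists for sensitivity analysis. Both decompositions sum to 100% whenever
total exposure is positive, and an all-zero diet raises an explicit
"undefined" error instead of returning NaNs.

## The synthetic population

The consumption survey behind the original 40-group assessment (2 regions
× 2 sexes × 10 age classes) is not public, so `generate_population()`
emulates its *structure* with known ground truth, and is explicit about
being synthetic:

* body-weight means ramp monotonically from 14 kg (2–3 y) to 65 kg
  (adult male), females slightly lighter, rural groups 5% lighter;
  within-group CV 0.12;
* adult consumption means follow a staple-heavy East Asian diet pattern
  (e.g. rice 230 g/day, vegetables ~275 g/day combined, soy sauce
  9 g/day) with CVs 0.4–0.8, scaled by $(bw/65)^{0.75}$ so that smaller
  bodies eat less in absolute terms but more per kg — the structural
  reason children carry higher risk;
* urban groups eat more fruit, rural groups slightly more staples;
* an optional seed applies a small (CV 5%) lognormal jitter so groups are
  not exact scalings of one another.

What the generator does *not* emulate: true dietary survey marginals,
correlations between food groups within an individual, regional residue
differences, or seasonal/acute consumption patterns. Consequently, tests
passing on synthetic data show that the *engine* is correct (its
distributional, scaling and determinism properties), not that any
absolute risk number describes a real population. The published headline
risks (P97.5 upper-CI range 13.94–41.25%, maximum 90.68% at P99.9)
depended on the unpublished survey and are deliberately not reproduction
targets; what the package does reproduce qualitatively is the
demographic pattern — child groups' percentiles exceed adult groups'
roughly in proportion to the body-weight ratio, and azoxystrobin
dominates the cumulative exposure.

## Numerical choices and problem sizes

* Full floating precision throughout; rounding only at presentation.
* Quantiles: type-7 linear interpolation everywhere (inner percentiles
  and outer bands), so degenerate inputs collapse exactly to the
  deterministic value.
* `n_inner ≥ 100` and `n_outer ≥ 2` are enforced as floor preconditions;
  defaults are 2000 × 500. The test suite exercises the engine at
  reduced sizes (inner 100–2000, outer 2–50) chosen so the whole suite
  runs in well under a minute, with one 40-group 2000 × 50 end-to-end
  pass as the largest case; the full 2000 × 500 default completes in a
  few minutes on a single CPU.
* Seeds are 31-bit; the substream hash stays below 2^31 − 1.
* Non-finite exposures abort the run with a diagnostic rather than
  propagating into percentiles.

## Known limitations

* Chronic exposure only; no acute (single-day) assessment.
* Substitution-based censoring only (by design; see above).
* Single first-order kinetics; no biphasic (DFOP/FOMC) models.
* The RPF method assumes dose additivity on a common endpoint; no
  interaction (synergy/antagonism) modelling.
* Residue uncertainty enters only through empirical sample sets; no
  parametric distribution fitting to residues is attempted, so a
  category summarized by a single STMR has no residue-side uncertainty
  in the outer loop.
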