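---
title: "Methods: growth-anchored dose response, combination-index synergy, and efficacy statistics"
author: "panelscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-anchored dose response, combination-index synergy, and efficacy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscreen)
```

panelscreen analyzes multi-dose proliferation screens that anchor every
reading to the cell count at the time of dosing (T0). This vignette is the
package's account of the models it fits, the conventions it adopts where the
underlying assay protocols are ambiguous, and what its synthetic-data checks
do and do not establish.

## The dose-response model and the growth window

Raw well signals are normalized to percent of the mean T0 anchor signal, so
100 always means "as many cells as at dosing time" and the mean DMSO well
level records untreated growth over the assay (typically 150–400 %T0 for a
6-day assay). Each line × agent titration is fit with the four-parameter
logistic

$$f(c) = b + \frac{t - b}{1 + (c/I)^{s}},$$

with bottom $b$, top $t$ (both %T0), inflection $I$ (nM) and Hill slope $s$;
$s > 0$ encodes a response decreasing with dose and parameters are
canonicalized so $t \ge b$. Fitting is nonlinear least squares
(`minpack.lm::nlsLM`) in a log-inflection parameterization, initialized from
data quantiles (top = max response, bottom = min response, inflection = the
concentration nearest mid-response, slope = 1) with a fixed schedule of up to
five jittered restarts; the schedule is deterministic so fits never consume
random numbers. A restart loop stops as soon as a converged fit explains at
least 95% of the response variance. Data with no measurable dose effect, or a
fitted span below 1 %T0, yield a flagged *degenerate* result instead of an
error.

The potency metrics are defined on the fitted curve relative to the growth
window between T0 (100) and the DMSO level $u$:

* **gIC50** — concentration at the window midpoint $(u + 100)/2$;
* **gIC100** — concentration of complete growth stasis (response 100);
* **dEC50** — concentration of 50% net cell death (response 50);
* **Ymin − T0** — minimum of the fitted curve over the *tested* range minus
  100; positive values mean net growth, negative net death. The tested-range
  restriction matters: the asymptote is never reported as an achieved effect.

Each concentration metric carries an explicit censoring state: `gt_max` when
the level is attained only beyond the highest tested concentration (the
value slot then holds that concentration as a bound, matching the "> 29.3 µM"
reporting convention), `unreachable` when the level lies outside the fitted
asymptotes, `degenerate` after a failed fit (all three metrics, with
Ymin − T0 set to $u - 100$). Extrapolated metrics are never reported as
attained values — a choice we make deliberately where assay write-ups are
silent.

Biological replicates are averaged on the log10 scale (geometric mean) for
concentration metrics — "average potency" for lognormally distributed
concentrations — and arithmetically for Ymin − T0. A metric is censored in
the aggregate only when censored in every replicate; mixed aggregates are
flagged `partial`.

```{r metrics-example}
cv <- fourpl_curve(bottom = 0, top = 300, inflection = 1000, slope = 1)
concs <- 30000 / 3^(9:0)
dat <- normalized_curve_data(concs, fourpl_response(cv, concs), dmso_level = 300)
growth_metrics(fit_fourpl(dat), dat)
```

On this reference curve the closed forms give gIC50 = 500 nM, gIC100 =
2000 nM and dEC50 = 5000 nM, which the fitted pipeline reproduces to well
under 0.1%.

## Combination index and the three-tier call

Fixed-ratio titrations dilute both agents together at constant parts (e.g.
4:1), so the mixture traces a single total-dose axis. The mixture and both
single agents are fit with the same 4PL machinery, and at each effect level
$\ell$ the mixture attains within its tested range (the three metric-defined
levels above), the mutually non-exclusive combination index is

$$CI_\ell = \frac{D_1}{Dx_1} + \frac{D_2}{Dx_2} + \frac{D_1 D_2}{Dx_1 Dx_2},$$

with $D_i$ the component doses inside the mixture at level $\ell$ and $Dx_i$
the single-agent doses producing the same level. A sham (an agent combined
with itself 1:1) scores exactly $0.5 + 0.5 + 0.25 = 1.25$ under this form;
more generally a sham at fractions $(f_A, f_B)$ scores $1 + f_A f_B$, and an
exactly Loewe-additive mixture scores in $(1, 1.25]$ at every level.

Conventions where the underlying protocol leaves room, each switchable where
noted:

* **Effect levels.** CI is evaluated at all three metric levels and
  classified on the *minimum* available CI, mirroring the parameter list the
  fold-shift rule names.
* **Fold shifts** compare like for like: an agent's own potency metric
  divided by its *per-component* concentration in the mixture at the matching
  parameter (not the total dose). They are computed only where both
  quantities are uncensored.
* **Same-parameter policy.** The fold-shift requirement is read as: one
  common parameter at which *both* agents shift by the threshold
  (`synergy_rules(same_parameter = TRUE)`); the per-agent reading is
  available behind the flag.
* **Monotherapy-incapable levels.** If a single agent's asymptotes exclude
  the level, its $Dx$ is infinite, its CI terms contribute 0 (the formula's
  limit), and the result is flagged rather than dropped — a combination
  achieving an effect no monotherapy achieves is maximal synergy evidence
  and stays auditable.
* **Dx lookups may extrapolate** beyond an agent's tested range (they are
  model quantities); only asymptote-unreachability censors them.
* **CI above 1** is reported numerically but called additive; no antagonism
  tier is defined.

The call is then: **strongly synergistic** iff summary CI < 0.44 and both
fold shifts ≥ 5 at some common parameter; **synergistic** iff summary
CI < 0.78 with both fold shifts ≥ 3; **additive** otherwise.

## What the synthetic generator emulates

The generator exists so every downstream stage can be tested against known
ground truth without any external data. Its defaults are fixed study
conditions, chosen once:

* 230 lines across 8 tumor-type strata; per-line untreated growth
  $t \sim U(150, 400)$ %T0, maximal-effect floor $b \sim U(0, 120)$ %T0,
  Hill slope $s \sim U(0.9, 1.3)$, T0 raw level lognormal around 1000
  arbitrary units.
* Baseline log10 inflection $\sim N(\log_{10} 550, 0.8)$ nM — centred on a
  550 nM wild-type median potency with a realistic 13 nM–30 µM span — and
  a 3× multiplicative inflection shift in KRAS-mutant lines, yielding
  mutant/WT median potencies near 1650/550 nM.
* Mutations sampled independently per gene per line at panel-typical
  frequencies, with hotspot protein changes for KRAS/NRAS/HRAS/BRAF/PIK3CA
  and random missense (plus ~12% frameshift/splice strings, which must fall
  back to gene-level markers) elsewhere.
* Multiplicative lognormal measurement noise with unit mean (default CV 5%;
  viability readouts are positive and heteroscedastic), applied to anchor
  wells (6 each of T0 and DMSO) and to 2 replicate treated wells over
  10-point 3-fold dilutions from 30 µM.

Combination plates are built from the single-agent ground truth by **Loewe
dose equivalence**: the mixture response at total dose $D$ solves

$$\frac{f_A D}{Dx_A(E)} + \frac{f_B D}{Dx_B(E)} = \psi$$

by bisection on the effect level (monotone one-to-one with the equivalent
dose; the bracket is shrunk to 1e-12 relative width). $\psi = 1$ is exactly
additive; $\psi < 1$ inflates the equivalent dose by $1/\psi$, and because
$1/\text{fold}_A + 1/\text{fold}_B = \psi$ at every level, a planted
$\psi = 0.1$ forces both fold shifts to at least 10 wherever the single-agent
metrics are measurable.

One structural choice deserves emphasis: the generator draws the bottom and
slope per *line* (shared by both agents) rather than per agent. Under shared
$b$, $t$, $s$ the 4PL family is closed under Loewe mixing — the additive
mixture is again an exact 4PL with inflection
$\left(f_A/I_A + f_B/I_B\right)^{-1}\!\psi$ — so when the pipeline's CI
deviates from the additive band $(1, 1 + f_A f_B]$ it measures synergy, not
4PL model misfit. With per-agent bottoms the Loewe mixture acquires a plateau
kink that no 4PL can represent, and CI estimates through any 4PL-based
pipeline absorb that model error; the solver handles such curves (and is
tested on them), but the default study conditions avoid conflating the two
effects. Real screens do not enjoy this closure — a caveat on what passing
checks show about real data.

The xenograft generator grows tumors exponentially from a 100–200 mm³
randomization volume with per-measurement lognormal noise, measuring twice
weekly until the endpoint volume is crossed (the crossing measurement is
kept) or the final day censors the animal.

## Biomarker statistics

Censored gIC50 values enter ranking after substitution with the maximum
tested concentration — a conservative lower bound that matches ranking
printed "> max" values — and are flagged. The marker screen runs a two-sided
Wilcoxon rank-sum test of mutant vs wild-type log10 gIC50 for every gene and
residue marker (residues parsed from missense strings such as G12D → G12),
reporting medians on both scales, a direction (resistance when the mutant
median is higher), the unadjusted p < 0.05 significance column, and
Benjamini–Hochberg q-values alongside. The exact rank-sum distribution is
used for combined n ≤ 20 without ties, the tie-corrected normal
approximation with continuity correction otherwise; 2×2 enrichment tests
(net-death depletion, synergy association) use Fisher's exact test with a
Haldane-corrected sample odds ratio when a cell is empty. The minimum mutant
count per tested marker defaults to 1 and is configurable. These standard
tests are delegated to `stats::wilcox.test` and `stats::fisher.test`; the
test suite verifies both against from-scratch enumeration oracles (all
mutant/WT partitions to n = 10; all 2×2 tables to N = 30).

## In-vivo efficacy

Time to endpoint interpolates the crossing log-linearly between bracketing
measurements, $t_1 + (t_2 - t_1)\ln(E/V_1)/\ln(V_2/V_1)$ — exact under
exponential growth — falling back to linear interpolation (with a warning)
around nonpositive volumes. Animals that never cross are censored at the
final study day. %TGD is the percent increase in median TTE over control;
censored animals contribute their censoring day to the medians, which biases
%TGD toward zero, so any such median is flagged. Arm comparisons use the
standard two-group log-rank (Mantel–Cox) test via `survival::survdiff`.
Day-fixed TGI is $100(1 - \Delta T/\Delta C)$ on mean volume changes from
baseline — one of several formulas in circulation, so it is the documented
default rather than a claim of protocol fidelity — with a two-sided
Mann–Whitney test on the day-d volumes.

## Numerical choices and calibration experiments

* Loewe bisection bracket: 1e-12 relative; 4PL fitter tolerances 1e-15
  (ftol/ptol), 200 iterations; degenerate-span threshold 1 %T0; restart
  acceptance at 95% variance explained.
* The Loewe-bound check uses 50 noise-free ψ = 1 pairs and allows 1e-3 of
  fit slack on the CI band; the sham check requires |CI − 1.25| < 1e-3.
* Planted-marker recovery uses the spec of a screen worth recovering: 200
  lines, mutant frequency 0.25, 3× multiplier, 2% noise, 100 seeded screens,
  top-5 rank by p with direction "resistance" in ≥ 95%.
* Null calibration permutes potency labels on an effect-free 200-line panel
  and evaluates the p < 0.05 rate over gene-level markers, where mutant
  counts (≈ 4–100) put the rank test in its calibrated regime; singleton
  residue markers have discrete p-value support bounded away from 0.05 and
  are covered instead by the stochastic-dominance (one-sided KS) property.
  Log-rank size is checked on 500 equal-hazard two-arm studies of 10 animals
  each. Both rates are required to sit inside the 99% binomial band around
  0.05.

## Known limitations

* The generator's mutations are independent across genes; co-occurrence and
  mutual-exclusivity structure of real panels is not emulated.
* Synthetic realism is calibrated only to printed potency ranges; raw-signal
  distributions of real readers (spatial plate effects, edge wells, outlier
  wells) are not modeled, and no outlier-well rejection is implemented.
* Bell-shaped/biphasic responses are out of scope; such data will fit badly
  and should be caught by the RSS diagnostics.
* %TGD's treatment of censored medians understates large effects; prefer the
  log-rank p and the censoring flag when many animals are censored.
* The association screen is univariate by design — no lineage, copy-number
  or expression covariates.
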