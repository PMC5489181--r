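---
title: "Methods: robust-design capture-recapture for long-term camera-trap monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust-design capture-recapture for long-term camera-trap monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapRD)
```

# The problem and the data

Camera-trap studies of individually identifiable animals (jaguars here,
recognised by their spot patterns) produce *detection events*: one
time-stamped identification of one individual at one station. Over a
multi-year program the events carry information about far more than a
single season's abundance — apparent survival, temporary movement off the
sampled grid, detectability differences between sexes and camera
technologies, residency and turnover. The robust design makes these
estimable by nesting short, closed sampling occasions (weeks) inside open
annual seasons.

The package's calibration target is a 14-year monitoring program: twelve
annual dry-season surveys 2002–2008 and 2011–2015 (none in 2009–2010),
19 stations, film cameras through 2008 and digital cameras from 2011, with
one year-long survey (2013) entering through a 100-day dry-season
subsample.

# Ingestion rules

* **Independence.** Consecutive events of one individual less than 24 hours
  apart are one sighting: a greedy forward scan keeps an event only if it is
  ≥ 24 h after the last *kept* event of that individual
  (`filterIndependent()`). Greedy keep-first is the standard field rule and
  is deterministic and idempotent; a global maximum-independent-set would
  keep more events but is not what practitioners compute.
* **Secondary windows.** Each primary is cut into consecutive 7-day blocks
  from its start date; a final remainder shorter than a week is merged into
  the last full week, so a 100-day survey yields 14 weekly occasions (the
  last 9 days long). Week membership is binary — any number of independent
  events in a window is one detection.
* **Exclusions.** Cubs are excluded by default (the models describe the
  adult population; `age_class` defaults to adult when absent). Unknown-sex
  individuals are retained in pooled counts but excluded automatically from
  any fit whose structure involves sex.
* Timestamps are naive local time; the 24-h rule is a duration, so day
  boundaries are irrelevant.

# The likelihood

Let individual *i* of sex *s* have per-primary detection counts
$d_{it}$ over $K_t$ weekly occasions, with first detection in primary $f$.
States are on-grid $A$, off-grid $O$, dead $D$ (absorbing; "dead" is
*apparent* death — mortality confounded with permanent emigration). The
one-year transition matrix is built from annual apparent survival $\varphi$
and emigration probabilities $\gamma''$ (leave the grid) and $\gamma'$
(stay off the grid), and is raised to the $\Delta t$-th power across the
survey gap, applying the annual rates in each unobserved year. On-grid
emission in primary $t$ is $p_t^{d}(1-p_t)^{K_t-d}$ with $p = c$ (no
behavioural response); off-grid and dead states emit only all-zero
histories.

The likelihood is conditional on first capture (Huggins form): the
first-primary emission is divided by $p^*_f = 1-(1-p_f)^{K_f}$, and
primaries after $f$ are handled by a three-state forward recursion.
Abundance never enters the likelihood; it is derived as
$\hat N_{st} = n_{st}/\hat p^*_{st}$ with a delta-method standard error
combining the binomial component $n(1-p^*)/p^{*2}$ with the detection
parameter uncertainty through the observed information. This conditional
form was chosen because the study treats abundance explicitly as a derived
parameter; it also keeps the parameter space small and the objective
smooth. Cells with $n_{st}=0$ (e.g. a sex undetected in a year) are
reported as not estimable rather than zero.

`historyLoglik()` is the readable scalar reference implementation;
`fitModel()` uses an algebraically identical vectorised engine (unique
history patterns collapsed with multiplicities, one matrix product per
primary). Tests pin the two to each other and to an independent state-path
enumeration, and verify that history probabilities sum to one by exhaustive
enumeration at $T = 3$, $K = 2$.

## Model structures

Structures mirror the field's notation: survival `"."`, `"sex"`, `"time"`,
`"sex*time"`, or one-sex time dependence `"sex(time/.)"` / `"sex(./time)"`;
emigration random ($\gamma'=\gamma''$), Markovian (both free) or none
($\gamma''=0$, $\gamma'=1$ fixed — the fixed $\gamma'$ is unreachable and
inert); detection over sex × camera era, with `era(./time)` keeping
detection constant across film-era primaries and year-specific across
digital-era primaries. Each real parameter cell maps to exactly one
logit-scale coefficient; sexes are groups sharing one likelihood.

## Optimisation and uncertainty

Quasi-Newton (`nlminb`) from one heuristic start plus dispersed random
starts drawn logit-uniform on (0.05, 0.95) — Markovian emigration can make
the surface multimodal; 10 starts is the default, and the replicated
validation experiments use 2 starts with the heuristic start first, which
was sufficient for the unimodal random-emigration structure. Convergence
tolerance is 1e-10 (relative) on the objective; non-finite objectives
return a large penalty so the optimiser backs off. The covariance is the
inverse of the numerically differentiated observed information
(`optimHess`); real-scale standard errors follow by the delta method.
Coefficients with $|\hat\beta| > 10$ (boundary: perfect or zero detection)
are flagged and their standard errors marked unreliable.

AICc uses $-2\ell + 2K + 2K(K+1)/(n_{\mathrm{eff}}-K-1)$ with
$n_{\mathrm{eff}} = \sum_i (T - f_i + 1)$, the number of primaries each
individual is at risk of modelling after first capture. Conventions for
conditional-likelihood effective sample size differ between
implementations and the original analysis software does not document its
choice, so `neffRule = "individuals"` is available as a switch; AICc
*differences* within a candidate set, which are all that weights use, are
barely affected. Model averaging is done on the real scale with
Burnham–Anderson unconditional standard errors, over the top six models by
default in the worked reproduction (the study's reporting convention).

# Derived demography

* $\lambda_t = \hat N_{t+1}/\hat N_t$ across consecutive surveyed years
  only; the 2008→2011 gap yields no entry. Totals sum the sexes, treating
  an inestimable sex as 0 with an annotation (the convention the published
  summary table uses for its first year); per-sex entries stay undefined
  instead.
* Recruitment $B_t = \hat N_{t+1} - \hat N_t\hat\varphi_t$, floored at 0
  (the unfloored value is kept for diagnostics); totals are sums of the
  per-sex floored values, and a year with inestimable $\hat N_t$
  contributes 0, flagged — both conventions read off the published table.
* The geometric-mean rate of change is summarised with the plain variance
  of the $\lambda$ values. The analysis this mirrors cites a variance
  estimator whose formula it does not reproduce; rather than guess, both
  divisor conventions (n and n−1) are emitted and labelled. The published
  male variance is consistent with divisor n, the recruit variances with
  n−1.
* Minimum age is (last − first detection year) + 2, from the assumption
  that adults are at least two years old at first solo detection. Cohorts
  are labelled by first-detection year; a first detection in the first
  surveyed year after a gap is ambiguous and gets a merged label
  ("2009/2011").

# Population structure

Residents are individuals detected in ≥ 3 consecutive *surveyed* years;
unsurveyed years are skipped, not counted as absences, so 2008→2011 counts
as consecutive — absence of data is not absence of the animal. The default
evaluation window is 2003–2007 (the longest uninterrupted run of surveys)
with one buffer year either side so that 2002/2008 detections can secure
residency status, exactly as the study restricted its analysis. Group
comparisons use a two-sided Monte-Carlo permutation test
($p = (1 + \#\{|T^*| \ge |T|\})/(B+1)$, seed-controlled), paired Wilcoxon
and Mann-Whitney tests (exact null distributions for small tie-free
samples), and ordinary least squares for the detection-span regression
`span ~ years detected` per sex. The published regressions report
intercepts, so OLS *with* intercept is the implemented reading of the
"y = m x" description; the sexes' slopes are compared through the
interaction term of the pooled model. Reported proportions are rounded to
whole percent, mirroring the published presentation.

# The synthetic-data generator

`simulatePopulation()` generates what the analysis assumes, plus a truth
ledger for validation. The study-scale preset (`jaguarPreset()`) fixes the
generative values at the program's model-averaged estimates: φ = 0.78,
random temporary emigration γ = 0.20, per-occasion detection 0.36 (males)
and 0.07 (females) in the film era and the published year-specific values
in the digital era; 19 stations; Poisson recruitment at per-capita rate
0.22 per year (the stationary replacement rate 1 − φ, which at the preset's
scale of ≈ 36 adults also matches the published mean of about six
recruits/year); 18 initial adults per sex. The true sex ratio is balanced —
the strongly male-biased *detected* ratio is an emergent artifact of
sex-specific detectability, as in the study.

Design choices worth calling out:

* **Transients.** The observed male dichotomy — consistently detected
  residents versus sporadic transients — is generated as detection
  heterogeneity: a fraction (0.3) of entrants carry a detection multiplier
  of 0.6, the ratio of the observed transient/resident
  detections-per-location medians. Transients share φ and γ: permanent
  departures of true transients are already part of *apparent* mortality,
  so giving transients an additional forced departure would change the
  meaning of φ and make the generative value unrecoverable by the very
  model the data are meant to validate. A `transientLeaves` switch restores
  literal dwell-then-leave behaviour (1–2 years) for users who want to
  study that misspecification; it is off in the preset.
* **Event placement.** Each per-occasion detection spawns
  1 + Poisson(0.5) raw events within a 6-hour cluster at one uniformly
  chosen station, with the cluster placed more than 24 h + cluster-width
  inside its weekly window. The 24-h filter therefore collapses every
  cluster to one event but never erases a detected occasion, making the
  truth ledger exactly recoverable — the simulator-truth oracle tests rely
  on this. Real data can lose occasions to cross-boundary filtering;
  the generator deliberately does not emulate that edge case.
* **What is not emulated.** No spatial structure (station choice is
  uniform; no home ranges or trap-shyness), no individual heterogeneity
  beyond the resident/transient dichotomy, no cub dynamics, no
  misidentification. Passing recovery tests on these data therefore
  validates the estimator and pipeline under the model's own assumptions;
  it does not certify robustness to spatial or behavioural structure in
  real data.
* The population process is a critical branching process (mean growth 1),
  so individual realisations drift — sex totals can differ noticeably
  between replicates. That is realistic for a small population and is why
  validation statements are about means over replicates.

# Validation problem sizes

The test suite checks exhaustive-enumeration identities at $T \le 3$,
$K \le 2$ (where the full history space is tractable), closed-M0 and CJS
reductions against independent oracles, and small parameter-recovery runs.
The headline experiment — also re-run from scratch by
`scripts/acceptance.R` — uses 200 replicate datasets at the study's scale
(12 primaries, weekly occasions, the 2009–2010 gap) fitted with the
top-ranked structure `phi(.) gamma(random,.) p(sex*era(./time))`,
summarising the mean of $\hat\varphi$ and $\hat\gamma$ and the coverage of
95% Wald intervals (computed on the logit scale, which respects the (0,1)
range). Two hundred replicates put the Monte-Carlo standard error of the
means near 0.002, comfortably below the 0.03 bias band the recovery check
uses.

# Known limitations

* The likelihood conditions on first capture: entry (recruitment into the
  detectable population) is not modelled, so per-capita recruitment is
  recovered only demographically, not as a likelihood parameter.
* Abundance SEs use the Huggins delta form; with strong unmodelled
  detection heterogeneity they understate uncertainty (visible in the
  preset, where female detection is near the boundary in sparse years).
* Multi-year gaps assume the annual rates applied each unobserved year;
  whether the original analysis applied per-year or per-interval
  transitions across its gap is not documented, and the two differ for
  Markovian structures.
* The full 20-model candidate set of the original analysis is only
  partially published; `jaguarModelSet(extended = TRUE)` appends plausible
  fill-ins, clearly flagged non-canonical.
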