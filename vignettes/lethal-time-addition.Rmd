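---
title: "Predicting mixture toxicity from lethal times: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mixture toxicity from lethal times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethaltime)
```

## The model chain

`lethaltime` predicts the lethal effect of a chemical mixture on aquatic
organisms from single-chemical acute-toxicity summaries. Four pieces are
chained together.

**Quantal probit estimation.** Dead-out-of-exposed counts at a series of
levels (concentrations, or observation times within one concentration
group) are fitted by maximum likelihood to

$$\Phi^{-1}(p) = \beta_0 + \beta_1 \log_{10}(\text{level}),$$

the implicit assumption being a log-normal tolerance distribution across
organisms. Median effective levels (LC50 on the concentration axis, LT50
on the time axis) come from inverting the line; 95% limits come from
Fieller's theorem on the fitted line's covariance (`effective_level()`).
Time-axis fits use the cumulative mortality series of one concentration
group. Those counts are not independent across times — the same fish stay
dead — but the mean structure at every grid time is exactly the probit
curve, so the working-independence fit remains consistent; its
time-axis intervals should be read as approximate.

**The lethal-time law.** Per chemical, `ln(LT50) = a + b ln(C)` is fitted
by ordinary least squares on both natural-log axes (`fit_loglog()`). The
slope `b` is negative for ordinary toxicants (higher concentration kills
faster). The law is deliberately used for extrapolation — computing lethal
times at mixture component concentrations far below any tested level —
so predictions carry an `extrapolated` flag rather than being refused.

**Lethal-time addition.** A mixture at total concentration $C$ is split
into components $C_i$ in exact ratio proportions; each component's lethal
time $LT_i$ comes from its law; and

$$LT_{50,\text{mix}} = \frac{1}{\sum_i C_i / LT_i}.$$

Each term $C_i/LT_i$ behaves as a killing-rate contribution, which gives
the rule its two structural properties (tested as invariants): the result
never exceeds $\min_i(LT_i/C_i)$, and adding a component strictly
decreases it. Applied to a single component the rule returns $LT/C$,
which equals the chemical's own LT50 only at $C = 1$ mg/L — the rule is
meant for true mixtures, and the degenerate case is documented rather
than special-cased.

**Hyperbolic mortality and predicted LC50.** Mortality over time follows
$P = P_{100}\, t/(LT_{50} + t)$ (`hyperbolic_mortality()`), with
$P(LT_{50}) = P_{100}/2$ exactly (the implementation evaluates
$P_{100}/(LT_{50}/t + 1)$ so this identity holds in floating point too).
The predicted fixed-time mixture LC50 (`hm_predicted_lc50()`) is, by
default, a probit fit of the predicted percentage mortalities at that
time against total concentration, treating each percentage as the quantal
response of a nominal group of 10 — mirroring how an observed bioassay
would be analysed, and how the case study's published predictions were
evidently produced. Direct inversion of $LT_{50,\text{mix}}(C) = t$ by
root solving is exposed as `method = "invert"`; on the case-study
series the two agree within a few percent, and on any series whose
mortalities are probit-symmetric around 50% they coincide exactly (a
property the tests exercise).

**Reference model and scoring.** Concentration addition combines
component lethal concentrations at a common effect level $x$ as the
proportion-weighted harmonic mean $LC_{x,\text{mix}} = 1/\sum_i (p_i /
LC_{x,i})$ over the grid $x \in \{5, 15, 35, 60, 90\}\%$, and a probit
fit through those five rows gives the CA-predicted LC50. The model
deviation ratio `MDR = predicted/observed` classifies the mixture as
synergistic (> 2), additive ([0.5, 2], boundaries inclusive) or
antagonistic (< 0.5). Toxicity categories use the conventional decade
scheme on half-open intervals: [0.1, 1) highly, [1, 10) moderately,
[10, 100) slightly toxic, anything else out of scheme. Both boundary
conventions are deterministic choices where prose definitions
("between 1 and 10") are ambiguous.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `p100` | percent | 100 | mortality ceiling of the hyperbolic curve; <100 models partial susceptibility |
| time grid | h | 24, 48, 72, 96 | standard acute-test reporting grid |
| `t_lc50` | h | 96 | standard acute endpoint; any time works |
| effect grid | percent | 5, 15, 35, 60, 90 | spans the response range with the tails a 10-fish design can resolve |
| `n_nominal` | count | 10 | group size a predicted percentage stands for when refitted by probit |
| convergence | — | 1e-10, ≤100 iter | IRLS tolerance of the probit fit |

## Numerical choices

* **log10 metameter, no +5 probit offset.** Median-effect estimates are
  invariant to the offset; the modern parameterisation matches mainstream
  statistical software.
* **Groups at 0% or 100% stay in the likelihood.** Only complete
  separation (no partial group and non-interleaved extremes) is refused,
  with an error advising interval-only statements.
* **Heterogeneity.** When Pearson $\chi^2/\mathrm{df} > 1$ the parameter
  covariance is inflated by it and a $t_{\mathrm{df}}$ critical value
  replaces the normal one — Finney's convention. When Fieller's $g \ge 1$
  the limits are undefined and reported as absent rather than fabricated.
* **No natural-response parameter.** Control mortality is assumed zero,
  as in the bundled case study.
* **Exact ratios, not printed proportions.** Component concentrations and
  CA proportions always come from the ratio weights at full precision;
  two-decimal printed proportions are treated as display rounding. This
  is what makes the published cells reproducible.
* **Display rounding is half-up** (`round_half_up()`), matching printed
  tables; all internal arithmetic is full precision.

## The synthetic bioassay generator

`simulate_time_to_death()` draws per-organism death times from the exact
tolerance model the estimators assume: $\log_{10} T$ normal with median
$\exp(a + b\ln C)$ and spread $1/\text{slope}$. Deaths after the study
end (default 96 h) are censored as survivors; cumulative counts are
emitted on an hourly grid. Defaults mirror the standard fingerling
design: 20 fish per concentration (duplicate aquaria of 10, pooled),
hourly counts, 96 h. Each scenario owns a private seeded RNG stream, so
identical seeds give identical tables and simulation never perturbs the
caller's random state.

Because generator and estimator share one model, recovery tests validate
the estimation chain, not the model's realism. Real bioassays differ in
ways the generator deliberately omits: toxicokinetic/toxicodynamic
interactions between components (the generator is additive by
construction), control mortality, between-aquarium variation, and
observation ties from counting only once per hour. Passing recovery
tests therefore show the estimators are consistent and well calibrated
under the model's own assumptions — not that any particular mixture in
nature is additive.

Simulation problem sizes used by the tests and the acceptance script:
interval coverage uses 500 replicates of a 5-level, 10-fish design with
true probit slope 3; study-size recovery uses 200 replicates of the same
design against the criterion $r^2 \ge 0.75$; the large-sample check uses
4 concentrations at 2000 fish each, with concentrations chosen so the
true LT50s (8–65 h) fall informatively inside the 96-h window — a group
whose true LT50 lies far beyond the study end contributes almost no
deaths and only noise.

## Design decisions in the bundled case study

The case-study tables were transcribed from a published pesticide-mixture
study and carry that source's internal inconsistencies. The package's
policy is to surface them, never to absorb them:

* Of 70 published mixture-LT50 cells, 56 regenerate within 0.5% from the
  coefficient table and ratio weights; the remainder (one whole tilapia
  mixture with a uniform ~10% offset, and scattered single rows) are
  flagged `consistent = FALSE` in the bundle and reported by
  `reproduce_mixture_lt50()`.
* The catfish atrazine–mancozeb composition is stored as 1.39:1
  (atrazine:mancozeb). The source prints "1:1.39" — the equitoxic-ratio
  convention — but its own lethal-time, mortality and
  concentration-addition tables all cohere only with the reverse order,
  so the corrected order is used and noted here.
* The catfish quaternary weights are the species' own equitoxic LC50
  ratio (17.463 : 24.383 : 0.515 : 0.000434), which reproduces the
  published rows; the ratio printed for both species is exactly the
  tilapia equitoxic ratio.
* The single-pesticide concentration–LT50 table is bundled only for the
  seven chemical × species blocks whose pairing could be verified by
  refitting (the recovered coefficients match the published ones to
  ~0.01); the eighth block is omitted and the published coefficient
  table is authoritative downstream.
* Observed mixture LC50s are taken from the published comparison table as
  given. They are not exactly recoverable from the observed mortality
  counts by standard probit (several observed series reach 100%
  mortality below the stated LC50), so recomputed observed values are
  never substituted for the published ones in MDR scoring.

## Known limitations

* Additivity is assumed throughout; interacting mixtures will deviate,
  and the MDR is the diagnostic, not a correction.
* The lethal-time law is linear in log–log space; strong departures from
  linearity (e.g. thresholds near no-effect concentrations) make
  long-range extrapolation unreliable, which is why extrapolation is
  flagged.
* Time-axis probit intervals ignore the serial dependence of cumulative
  counts; treat LT50 confidence limits as approximate.
* The CA comparison needs component lethal concentrations at the chosen
  effect grid; with very shallow or very steep slopes the 5% and 90%
  entries are themselves long extrapolations.
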