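---
title: "Ensemble modelling of the arachidonic acid cascade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modelling of the arachidonic acid cascade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `aacascade`, the
assumptions behind it, the tunable parameters and their defaults, the
numerical choices, and the limits of what the synthetic-data tests can
demonstrate.

## The model

The arachidonic acid (AA) cascade is simulated as a deterministic ODE
system over two well-mixed compartments: an intracellular compartment of
1 pL and an extracellular compartment of 1 nL, approximating a cultured
cell and its share of medium. The shipped catalogue
(`build_aa_cascade()`, also on disk under `inst/extdata/aa_cascade/`)
contains 113 numbered reactions over 49 metabolites, 18 enzymes, 2
transporters and 2 source pools. Reaction numbering is stable and used in
every error message and log, so a problem can always be traced to a
catalogue row.

Reaction classes and rate laws:

* **Enzymatic** reactions use a reversible uni–uni Michaelis–Menten law
  with competitive occupancy terms for substrates sharing the enzyme
  (e.g. PGE₂ and PGF₂α at 15-PGDH, the three HPETEs at PHGPx):
  $v = k_{cat} E \,(S/K_{ms} - P/(K_{ms}K_{eq}))\,/\,(1 + S/K_{ms} +
  P/K_{mp} + \sum_j C_j/K_{m,j})$.
  The same elementary kinetics are assumed for every enzyme; nothing in
  the available data justifies more complex (allosteric, multi-substrate)
  forms.
* **Non-enzymatic** conversions (PGI₂ and TXA₂ hydrolysis, PGD₂ → PGJ₂
  dehydration, extracellular HPETE reduction) are reversible mass action,
  $v = k_f S - k_r P$.
* **Transport** is carrier-mediated efflux with competition between all
  cargo of the same transporter:
  $v = k_{cat} T (S/K_m) / (1 + S/K_m + \sum_j S_j/K_{m,j})$, evaluated
  on the donor-compartment concentration basis and scaled by the
  donor/acceptor volume ratio on the acceptor side so the transported
  amount is conserved. The prostaglandin transporter (PGT) carries the
  prostanoids; the ABC transporter carries AA, the HETE/HPETE species and
  leukotrienes, plus five prostanoids as a second export route.
* **Degradation** is first order, $v = k_{deg} S$, for every metabolite
  in both compartments.
* **Substrate release** (reaction 95) injects AA into the intracellular
  pool following a programmable availability curve (below). Two
  alternative entry routes — enzymatic release from a membrane pool
  (reaction 1) and non-enzymatic membrane release (reaction 113) — are in
  the catalogue but disabled by default; any reaction can be switched
  on/off via its `enabled` flag.

Enzyme and transporter concentrations are parameters, not state: they are
constant over a simulation unless a protein-induction schedule overrides
them (piecewise-constant, right-continuous steps, matching the
"concentration raised at fixed time points" semantics of induction
experiments such as UVR-driven COX-2 upregulation). Transcription and
translation are deliberately outside the model's timescale, as are
CYP450 metabolism, esterified-HETE hydrolysis and cysteinyl-leukotriene
feedback.

### The release profile

AA availability after a stimulus is described by four parameters: the
maximum 6 h concentration $M$ (mM), the doubling time $t_d$ (h), the
half-life $t_h$ (h) and a Boolean decay switch (with a peak time at which
decay engages). Within a segment the available concentration rises as
$A(t) = M - (M - A_0)\,2^{-t/t_d}$ and, once the decay switch engages,
falls as $A_0\,2^{-t/t_h}$. Scheduled re-assignments change any of these
parameters at fixed times; $A(t)$ is kept continuous across every event
by re-basing the segment on the current level. The text names these
parameters without a closed form; the exponential-approach/exponential-
decay form above is the package's choice — it is the simplest law with
the right half-time semantics. The ODE system receives the *increase* of
$A$ as the release flux; decay phases inject nothing (released AA then
declines through its own consumption and degradation).

`make_release_scenarios()` returns the four canonical dynamics (single
pulse, constant, decaying, delayed) plus the "minimal + delayed" schedule
that releases 10% of the total AA over 0–3 h and 90% over 3–6 h.

## Parameterisation

Every parameter is log-normal. `fit_weighted_lognormal()` turns weighted
literature values into a prior: $\mu$ and $\sigma$ are the weighted mean
and SD of $\ln v$ with weights normalised internally, and $\sigma$ is
floored at $\sigma_{min} = 0.25$ so a single literature value still
yields a sampleable prior. The full scoring rubric that would produce
those weights from experimental-condition metadata is out of scope here;
weights default to 1.

Thermodynamic consistency is enforced at sampling time, not after the
fact: within each enzymatic quadruplet $(k_{cat}, K_{ms}, K_{mp},
K_{eq})$ only three members are sampled and $K_{mp} = K_{eq} K_{ms}$ is
derived (the Haldane relation of the implemented rate law under the
single-turnover-number convention); within each non-enzymatic triplet,
$k_r = k_f / K_{eq}$. Sampling is otherwise independent across
parameters — no cross-reaction correlations are imposed. The residual
$|K_{mp}/(K_{eq}K_{ms}) - 1|$ (and its triplet analogue) is checked to
below $10^{-9}$ across every sampled variant in the test suite.

Default prior baselines for the shipped network (ln-space mean, SD), with
units:

| kind | default | rationale |
|------|---------|-----------|
| $k_{cat}$ | ln 5 s⁻¹, 0.8 | eicosanoid-pathway turnover numbers cluster at a few per second and are comparatively well characterised |
| $K_{ms}$, transport $K_m$ | ln 5 µM, 1.0 | low-micromolar substrate affinities typical of COX/LOX and lipid carriers |
| $K_{eq}$ | ln 10⁶, 1.0 | oxygenations and hydrolyses are strongly exergonic; reactions are reversible in form but far from equilibrium in practice |
| $k_f$ | ln 2·10⁻³ s⁻¹, 1.0 | minutes-to-hours non-enzymatic conversion half-lives |
| $k_{deg}$ | ln 10⁻⁵ s⁻¹, 1.0 | slow first-order loss (many-hour stability) |
| $[E]_0$ | ln 10⁻⁵ mM, 1.7 | proteomics-derived abundances span orders of magnitude |

The COX isoform abundances are overridden to ln 10⁻³ mM (SD 1.15,
spanning roughly 10⁻⁴–10⁻² mM) and the 12-/15-LOX abundances to
ln 10⁻⁵·⁵ mM (SD 1.7, spanning roughly 10⁻⁷–10⁻⁴ mM), matching the
ranges over which these enzymes have been reported. 184 parameters of the
shipped network are independently sampled: 3 per enabled enzymatic
reaction (21), 2 per non-enzymatic reaction (11), one affinity per
transport reaction (29), one rate per degradation reaction (49), 17
enzyme and 2 transporter concentrations, and 2 transporter turnover
numbers. That count doubles as the Bonferroni hypothesis count during
adaptation and is recomputed automatically for reduced networks.

The default stimulus magnitude (10 mM maximum releasable AA) corresponds
to a cellular AA content of roughly 3 µg per million cells in a 1 pL
cell volume.

## Simulation protocol and numerics

A simulation covers 7 h: 1 h of equilibration from the 10⁻²⁸ mM
metabolite floor with release off, then the stimulus event activates the
release profile at $t = 0$ and the response is recorded for 6 h, with
report times at 0.5, 1, 3 and 6 h. Internal time is seconds (all rate
constants are s⁻¹); interfaces use hours.

* Solver: `deSolve::lsoda` (stiff-capable, automatic method switching).
* Tolerances: rtol 10⁻⁸, atol 10⁻³⁰ mM — the absolute tolerance must sit
  below the 10⁻²⁸ mM initial floor, 26 orders below typical outputs.
  Solutions at the report times change by well under 0.1% when both
  tolerances are tightened tenfold (checked in the test suite).
* Events (stimulus activation, release-schedule re-assignments, decay
  switch-on, induction steps) are implemented by stopping and restarting
  the integration at the event times, so the right-hand side is smooth
  within every segment — much kinder to a stiff solver than a
  discontinuous RHS.
* Negative concentrations within a few atol of zero are numerical zeros
  and floored in the stored trajectory; anything beyond that margin would
  fail the non-negativity test.
* A variant whose integration fails is returned with
  `status = "failed"`, counted, and excluded from summaries, scoring and
  adaptation — an ensemble must survive pathological parameter draws.
* Reproducibility: the ensemble seed fully determines the sampled
  matrix, and execution is serial, so re-running a configuration yields
  byte-identical outputs.

## Scoring and adaptation

The quality score of one data point is
$\ln \mathcal N(\ln C_{exp};\, \ln C_{sim}, \sigma)$ with $\sigma = 1$
by default. The width is a design choice: with $\sigma = 1$ the
per-point pass threshold of −10 corresponds to a ±4.3 ln-unit band, and
the standard thresholds (point > −10, metabolite series > −40, total >
−500) are used as given. Simulated values below 10⁻³⁰ mM are floored
before the log so a numerically-zero prediction scores very badly rather
than −∞; below-LOQ measurements are excluded from scoring (not imputed),
with the excluded count logged. Scores are invariant to the concentration
unit as long as experiment and simulation share it. Unit conversion from
assay units (pg per million cells) to mM requires cell counts and volumes
the model does not know, so the dataset format carries an explicit
`conversion_factor` with no silent default.

Adaptation selects the top decile of variants by total cumulative score
(ties broken by variant index, deterministic), then runs a one-sample,
two-sided Kolmogorov–Smirnov test of each sampled parameter's
ln-values against its Normal($\mu$, $\sigma$) prior, with Bonferroni
control of the family-wise error rate at 1% over the 184 sampled
parameters. A significant prior is refitted by maximum likelihood to the
top-decile values (σ floored at $\sigma_{min}$). Refitting — rather than
truncation or reweighting — is the package's mechanism for "adjusting the
distribution toward enriched values": it is simple, keeps the prior
log-normal so adaptation rounds can be chained, and the per-bin
enrichment profile (log observed/expected ratio over the prior's central
99.9% mass, pseudocount 0.5) is retained for inspection. Dependent
parameters ($K_{mp}$, $k_r$) are never tested — they are functions of
sampled ones.

## What the synthetic data does and does not show

`generate_pseudo_experiment()` emulates the statistical structure the
scoring stage assumes: extracellular concentrations of an observable
panel (six eicosanoids for the keratinocyte-like case, three for the
fibroblast-like case) at 0.5/1/3/6 h, with multiplicative log-normal
noise (default σ = 0.3 ln-units, a plausible lipidomics replicate
spread) and a limit-of-quantification flag. It does **not** emulate raw
mass-spectrometry signals, extraction recovery, internal-standard
normalisation, or systematic (non-multiplicative) measurement error, and
the generating model is by construction the same family as the fitted
model — so passing tests demonstrate internal consistency of the
pipeline, not accuracy on real cells.

`parameter_recovery_harness()` runs the full loop with a known ground
truth: a +2 ln-unit shift of the 12-LOX concentration off its prior
mode. The test suite runs it at 300 variants (sized so the whole suite
stays in minutes on one CPU; larger studies would use 1000). At that
scale the behaviour splits cleanly:

* the *selection* stage works — the top decile's 12-LOX values are
  visibly enriched toward the truth (median shifted by about +1 ln-unit
  from the prior centre), and the enrichment profile shows the same
  shift; but
* the *significance* stage does not reach the Bonferroni-corrected
  threshold: with only 30 top variants, the corrected KS test needs a
  statistic of about 0.42, while the achievable enrichment yields about
  0.28. Two effects cap the statistic: KS sensitivity scales with the
  top-set size (a top-100-of-1000 selection has nearly twice the
  effective sample), and the data constrain the *product* of 12-LOX
  concentration with its turnover number (plus export and degradation
  factors), not the concentration alone, so the marginal shift is
  bounded by the concentration's variance share of that product.

Consequently the adapted prior is left unchanged at this scale — the
correct behaviour for a non-significant test, and a deliberate
illustration that the scaled-down study is underpowered for
Bonferroni-corrected enrichment detection, while the direction of the
enrichment is already informative. The KS machinery itself is verified
separately: under the null its corrected type-I error stays below 1%,
and a one-ln-unit shift at 100 selected values is detected with power
above 0.9.

## Known limitations

* The catalogue is a reconstruction of the canonical AA-cascade topology
  at the documented scale; it is validated structurally (counts,
  compartment pairing, parameter references) but individual kinetic
  constants are prior ranges, not curated per-reaction literature fits.
* Uni–uni kinetics only; no allosteric regulation, no feedback loops.
* The release profile replaces PLA₂ mechanism with phenomenological
  dynamics — intentional, but it means stimulus strength and shape are
  inputs, not predictions.
* Serial execution only; a 1000-variant ensemble takes on the order of
  15 minutes on one CPU.
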