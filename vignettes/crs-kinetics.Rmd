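---
title: "Modeling cellular self-repair kinetics under ionizing radiation with crsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cellular self-repair kinetics under ionizing radiation with crsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsim)
```

## The model

`crsim` simulates the repair system of a single cell under acute
ionizing radiation (IR) as a population-balance model of interacting
"active particles" in two sub-populations: DNA damage (DNA, free
double-strand breaks, correctly repaired and misrepaired DSB–protein
complexes) and repair enzymes (repair gene, repair mRNA, repair
protein). The scheme is hybrid: DSB generation is a stochastic Poisson
process, while every other flux is a continuous mass-action rate. Time
is an abstract discrete grid of *time-scales*; the model deliberately
assigns no physical duration to one time-scale and no molar units to
abundances, so all rates are "per time-scale" and all pools are counts.

Each time-scale applies four stages in a fixed operator-splitting
order:

1. **Damage.** A Poisson draw with mean `k_t * a_ir * dose` adds free
   DSBs, routed at generation into a fast cohort (fraction `f_fast`)
   and a slow cohort. DNA and repair gene shrink by survival fractions
   `1 - exp(-gamma * mu * dose)`; destroyed gene is gone for good (the
   model has no gene synthesis). Each DSB is simultaneously counted as
   a new DNA on the DNA ledger.
2. **Enzymes.** Transcription flux
   `k_mrna_basal * G + eta_gene_dsb * G * B * g(B)` and translation
   flux `k_rp_basal * M + eta_mrna_dsb * M * B * h(B)` feed the mRNA
   and RP pools against first-order self-degradation.
3. **Complex synthesis.** Four channels — {fast, slow} x {first-order,
   second-order} — convert DSB + RP into complexes; a per-channel
   fraction `p_misrepair_ij` of the flux is misrepaired (mDSBC), the
   rest correctly repaired (rDSBC); complexes dis-synthesize back into
   one DSB plus one RP at rates `delta_r`, `delta_m`.
4. **Toxins and stability.** Toxins are the instantaneous burden
   `mdsbc + dsb`; genome stability decays multiplicatively by the
   excess over the tolerable burden,
   `S <- S * exp(-lambda_tox * max(0, toxins - theta_tox))`.

Three derived indicators summarize a run: RP available (repair
capability), the per-time-scale rDSBC synthesis flux (cellular activity
in relaying the damage signal downstream), and toxins/stability (genome
integrity).

## Modelling assumptions

* Particles are homogeneously distributed; all interactions are binary
  encounters with mass-action (bilinear) rates.
* 70% of newly generated DSBs are handled by the fast repair kinetics,
  and each fast-channel rate is exactly 10 times its slow counterpart.
  Both facts are structural: cohort membership is assigned at
  generation time, and the fast rates are derived from the slow ones,
  so `channelRates()` can never violate the ratio.
* The same repair enzyme pool serves both repair kinetics (no separate
  HR/NHEJ enzyme species).
* One RP binds per DSB in a complex and dis-synthesis releases exactly
  one of each. This makes two conservation ledgers exact to float
  precision at every step: DSB pairing
  (`generated + dis-synthesized = free + synthesized`) and the RP
  balance (`produced - degraded - bound = pool change`). The test
  suite checks both at every recorded step.
* Toxins are not degraded; no downstream signalling (P53 etc.) is
  modelled — the rDSBC flux is reported as the signal the cell *would*
  relay.

## Parameters

`defaultParameters()` returns the reference set. Four values are
anchored to the radiobiological literature:

| field | default | meaning |
|---|---|---|
| `a_ir` | 35 | mean DSBs per Gy per time-scale (measured range 30–40) |
| `f_fast` | 0.70 | fraction of DSBs handled by the fast kinetics |
| `rate_ratio_fast_slow` | 10 | fast/slow channel rate ratio |
| `gamma_dna`, `gamma_gene` | 0.8 | reference cell-type IR sensitivity |

Every remaining rate constant is a **surrogate** value: no published
numeric table was available for this parameterization, so the free
constants were calibrated once, against the canonical qualitative
behaviour of an irradiated cell at constant 8 Gy over 2500 time-scales,
and then frozen:

* repair mRNA rises steeply, passes one major climax, and collapses
  toward zero late in the run;
* RP builds to a single climax and later collapses sharply, settling
  at a small dynamic equilibrium;
* the free-DSB pool spikes in the first few time-scales (before the
  enzyme pools have ramped up), is then held on a long plateau where
  repair matches induction, and finally explodes when RP runs out;
* the rDSBC synthesis flux keeps rising through the plateau (recycling
  via dis-synthesis adds to the fresh influx) and turns over after the
  RP climax;
* genome stability is flat or slowly decaying through the plateau and
  collapses after the DSB explosion;
* over 10, 15, 20 Gy, every collapse time moves earlier with dose.

The calibration logic, in terms a maintainer can re-derive: the
gene-destruction rate `mu_gene_rate` sets the collapse clock (the gene
pool decays as `exp(-gamma * mu * dose * t)`, dragging mRNA and hence
RP production down with it); `eta_mrna_dsb` sets the production margin
over the 280 DSBs/time-scale influx at 8 Gy and so the plateau level of
the free-DSB pool; `beta_slow_1` must be large enough that the slow
cohort's equilibrium stays below the saturation thresholds
(`theta_mrna`, `theta_rp`), which in turn must sit above the initial
DSB spike at the strongest dose of interest (20 Gy), or the cell dies
in the ramp-up phase instead of through gene exhaustion; `theta_tox`
sits above the plateau toxin burden so stability decay concentrates in
the post-collapse phase; `lambda_tox` scales how fast stability falls
once the pool explodes. The shipped configuration is written by
`writeConfig()` and documented as surrogate here; replacing it with a
measured table is a drop-in config change.

## Numerical choices

**Integration.** One time-scale is one step (`dt = 1`); stages use
per-process exponential updates rather than raw Euler so no pool can go
negative at any rate:

* pure decay (DNA, gene, dis-synthesis) uses survival fractions
  `pool * (1 - exp(-rate))`;
* production + decay (mRNA, RP) uses the exact linear-system step
  `x' = x e^{-d} + (P/d)(1 - e^{-d})` with the production rate `P`
  frozen at its start-of-step value. The discrete zero-IR fixed point
  therefore coincides exactly with the continuous balance
  `mrna* = k_mrna_basal G / d_mrna`, `rp* = k_rp_basal mrna* / d_rp`,
  which the tests verify to 1e-6 after a cold-start burn-in.

**Saturation.** The threshold factors are
`g(B) = (theta / (theta + max(0, B - theta)))^2`: exactly 1 up to the
threshold, smoothly decreasing beyond it. The square makes the
interaction flux `B * g(B)` *peak at the threshold and decay toward
zero* under damage overload; a first-power factor would only plateau,
and production would never collapse however large the damage — the
collapse phenomenology requires the stronger form. It also gives the
strict inequality `flux(2 theta) < flux(theta)` (the first-power form
ties exactly at `2 theta`).

**RP limitation.** Raw channel demand is
`beta_i1 * B_i + beta_i2 * B_i^2` (times the global encounter
coefficient `eta_rp_dsb`, default 1, kept so the configuration surface
exposes all three binary-interaction coefficients). The realized share
is `rp / (rp + demand)`, then fluxes are proportionally capped so no
cohort and no more RP than available is consumed. In the unconstrained
regime the channel fluxes remain exactly linear/quadratic in cohort
size — the quadratic ratio test (factor 4 at doubled cohort) holds to
1e-6.

**Stochasticity.** A single RNG stream, seeded per run, drives the
Poisson draws; the caller's RNG state is saved and restored.
Mean-field mode replaces each draw by its mean and is seed-independent.
The misrepair split is applied as a deterministic per-channel fraction
in both modes: synthesis fluxes are real-valued even in stochastic runs
(only DSB generation is discrete), so a binomial draw has no integer
trial count to act on.

**Degenerate inputs.** Zero dose is an exact no-op for the damage
stage; `rp = 0` suppresses all synthesis while dis-synthesis continues;
a zero-length dose profile returns just the initial state; sub-1e-12
negative drift from float cancellation is clamped to zero, and any
larger negativity or non-finite value aborts the run with the time
index attached (a bug trap, unreachable in normal operation).

## Design decisions at genuinely open points

* **New DNA and the breakable substrate.** Each DSB is counted as a new
  DNA. By default this credits only the displayed DNA ledger, not the
  substrate from which further DNA is destroyed — feeding it back would
  create an unbounded positive feedback with no described counterpart.
  The feedback variant is available via `new_dna_feedback = TRUE`.
* **Dis-synthesized complexes return as intact DSBs** (plus a free RP),
  re-routed fast/slow at `f_fast` like any newly appearing free DSB —
  consistent with cohort assignment at (re)generation time.
* **Misrepair fractions** default to higher misrepair in the
  second-order channels (0.03/0.06 second-order vs 0.01/0.03
  first-order), reflecting that rejoining ends from two different DSBs
  is the error-prone route.
* **Stability is a state, activity a derived indicator.** Genome
  stability `S(t)` is integrated as part of the cell state (bounded in
  `[0, s0]`, non-increasing by construction); "cellular activity of
  transferring DNA damage" is reported as the per-step rDSBC synthesis
  flux track rather than as a separate state variable.
* **Turning-point detection** (`indicatorReport`) anchors the rDSBC
  sign-change search at the climax of the 25-step-smoothed flux, so the
  ramp-up transient in the first few time-scales is not mistaken for
  the decline. The near-zero threshold for the mRNA collapse defaults
  to 1% of the track maximum, detected at or after the mRNA peak.
* **The bolus routing experiment** (`repairBolus`, used to demonstrate
  the 70% fast share) disables dis-synthesis for its duration;
  otherwise the complex pools leak DSBs back forever and the free pool
  never reaches exhaustion. Channel rates stay at their defaults.

## What a simulation does and does not show

Runs emulate: Poisson damage statistics with dose-linear mean,
threshold-limited enzyme production, fast/slow and first/second-order
repair-channel structure, misrepair, reversibility, and
toxin-threshold-driven viability loss — enough to study orderings,
collapse existence, and dose monotonicity.

They do not emulate: physical time (one time-scale has no assigned
duration, so detected times are comparable only within a
parameterization); track-structure or microdosimetric DSB spectra;
dose-rate effects beyond the linear mean; cell-cycle dependence;
downstream P53 signalling; or toxin degradation. Because the free rate
constants are surrogate-calibrated to qualitative shapes, the absolute
collapse times the package prints characterize this parameterization,
not a measured cell line; only the structural claims (35 DSBs/Gy mean,
70% fast share, 10x rate ratio, conservation, orderings, dose
monotonicity) are asserted by the test suite.

## Problem sizes

The shipped tests and the acceptance script use: 100,000 draws for
damage-mean recovery; a 1,000-DSB bolus for channel routing; 2500
time-scales for collapse-phenomenology runs at 8–20 Gy; 50 stochastic
trajectories of 300 time-scales for the ensemble-vs-mean-field
comparison (checked at five checkpoints within three standard errors);
and 1,000 random series for the detection-oracle equivalence. A
2500-step run takes well under a second on commodity hardware.

```{r example}
res <- runSimulation(doseProfile(8, 2500), seed = 1)
detectedTimes(indicatorReport(res))
```
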