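---
title: "Estimating rare-event release kinetics with flooding biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rare-event release kinetics with flooding biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodkin)
```

## The problem

A guest molecule bound inside a layered host — the motivating case is a
poorly soluble drug intercalated in a clay excipient — escapes to solution
on timescales far beyond what direct simulation of the bound dynamics can
reach. The release time `tau` and rate `k = 1/tau` are nonetheless the
quantities a formulator needs. `floodkin` implements the standard
rare-event answer in a fully controllable one-dimensional setting: add a
*flooding* bias `V` that fills the bound basin but vanishes at the
transition state, run an ensemble of accelerated escapes, and rescale each
apparent escape time back to physical time by the mean exponentiated bias,

  `tau_i = < exp(V/kT) >_run * t_MD,i .`

The rescaling is exact in the rare-event (memoryless) limit provided the
bias is null where the committor is decided. Its validity is therefore
*testable*: physical exit times must be exponentially distributed, which
the package checks with a one-sample Kolmogorov–Smirnov test, and in 1D
the true mean first-passage time (MFPT) is available exactly by
quadrature, so every estimate here is validated against ground truth
rather than against another simulation.

## Model and assumptions

Dynamics are overdamped Langevin (Euler–Maruyama, reflecting domain
boundaries, escape = first touch of `|y| >= threshold`, no persistence
window). The choice of overdamped dynamics is deliberate: the rescaling
formalism is dynamics-agnostic, and the overdamped limit is the one in
which the MFPT double-integral oracle is exact, making oracle/simulation
comparisons clean. All internal units are reduced — `kT = 1`, `D0 = 1`,
dimensionless lengths; `kT_in_kcal_mol()` and friends convert to
kcal/mol at 310 K (kT ≈ 0.616 kcal/mol) for physically worded configs,
and conversion happens only at the config boundary.

The landscapes are stand-ins, not fits to any atomistic system:

- `make_double_well(B, 2a)` — the canonical validation surface,
  `U = B(1-(y/a)^2)^2`.
- `make_interlayer_surrogate()` — even in `y`; a periodic corrugation
  `depth * sin^2(pi y/period)` models the succession of binding sites a
  guest hops between while diffusing along the gallery, and past
  `edge_position` the energy descends smoothly by `solvation_drop` to a
  flat solvent plateau. Defaults (depth 4 kT, period 1, edge 6, drop
  2 kT) keep all barriers low enough that the exact oracle and even
  brute-force unbiased simulation remain affordable, while preserving the
  qualitative ordering: release slows sharply with placement depth.
- `make_single_well(3)` — fast surface desorption, no enhanced sampling
  needed.

Shipped scenarios place the guest at the gallery centre (`y = 0`),
mid-way (`y = 3`) and near the edge (`y = 5.8`), plus the desorption
case. Their oracle MFPTs (123.7, 100.3 and 30.8 reduced time units)
decrease monotonically with depth. The compression of these ratios
relative to a real intercalation system (where centre-to-edge can span
five orders of magnitude) is a conscious scale choice; the *ordering* and
the estimator machinery are what the surrogate exercises.

A scenario also carries a `bound_region` — the interval the bound-state
samplers confine to (reflecting walls at its edges). For the double well
this ends at the barrier top; for the interlayer it is the gallery
`[-6, 6]`.

## The two bias constructions

**Static mixture bias.** Unbiased bound-state samples (default: 2e5
steps, subsampled every 10) are fitted with a Gaussian mixture by
expectation–maximization (5 seeded restarts, tolerance 1e-8, best
log-likelihood kept; the winning run's log-likelihood trace is stored and
is non-decreasing by construction). The bias is
`V(d) = kT log((P(d)+eps)/eps)`: the mixture-density bias shifted so
`V = 0` wherever `P = 0`. The shift matters — an unshifted constant
offset would contaminate `<exp(V/kT)>` — and the smoothing parameter is
tied to the cutoff by `eps = P_max exp(-E_cut/kT)`, so the bias ceiling
at the density peak equals `E_cut` (never exceeding `E_cut + kT log 2`
anywhere). `n_components` defaults to 3 and is a config choice, not
selected automatically.

**On-the-fly kernel bias.** Every `pace` steps a Gaussian kernel (fixed
bandwidth `sigma` = half the standard deviation of a short bound-state
run) is deposited at the current CV value with weight
`w_k = exp(V_{k-1}(s_k)/kT)` — the bias in force just before the update —
and the probability estimate is the weighted kernel density. The bias is
the well-tempered flooding form
`V_n(s) = (1-1/gamma) kT log((P_n/Z_n + eps)/eps)` with
`eps = exp(-E_cut/((1-1/gamma) kT))` and `gamma = 10`; `Z_n` is the mean
of `P_n` over the deposited kernel centres, recomputed each update
(quadratic in kernel count — irrelevant at the kernel counts reached
here). Two hard rules complete the construction:

- **Excluded region.** No kernel is ever deposited at `|s| > excluded`;
  the bias is still *evaluated* (and exerts force) everywhere — only
  deposition is excluded. This is what keeps the transition state
  bias-free.
- **Ceiling.** `V` is capped at `E_cut` (zero force on the capped
  plateau). With the centre-averaged `Z_n`, the raw formula can exceed
  the cutoff where `P_n/Z_n > 1`; the cap restores the "energy cutoff"
  semantics and keeps the basin from being overfilled past the intended
  level.

## Why the deposition defaults look the way they do

Two defaults were set by a validity study on the barrier-8 double well
with `E_cut = 6`, where the exact answer is known:

- **`excluded` = half the distance from the basin centre to the nearest
  bound-region edge** (0.5 for the double well, 3 for the interlayer).
  Allowing deposition closer to the barrier produced systematically
  inflated `tau` (ensemble means ~1.4x the oracle): escapes then happen
  while the bias under the escape path is still being assembled, and the
  accumulated `exp(V/kT)` no longer reflects a quasi-static boost. A wide
  bias-free buffer — several kernel bandwidths plus the entire barrier
  approach — removes the effect. (Broadening the kernels instead makes
  matters far worse: bandwidths comparable to the buffer leak bias onto
  the transition state itself and inflate `tau` by up to an order of
  magnitude, which is why the bandwidth stays at half the bound-state
  standard deviation.)
- **`pace` = 100 steps**, about three basin relaxation times at the
  default timestep. The growing bias must be quasi-static on the scale of
  basin relaxation, but it must also *finish growing* well before the
  typical escape; at desk scale an escape happens after tens of
  depositions, so a slower pace leaves the ensemble mid-transient. A
  matched experiment makes the point sharply: ensembles run live during
  deposition overestimated the oracle by ~30%, while re-running fresh
  trajectories under each run's own *frozen* final bias recovered the
  oracle exactly. With the two defaults above, live ensembles recover the
  oracle within Monte-Carlo error across seeds (ratios 0.93–1.18,
  mean 1.03, n = 25 per ensemble).

These are the package's own calibration of the method's validity
conditions, not fits to any external number — the quantity being
recovered is the package's own exact oracle.

## Exit-time statistics

`fit_release_kinetics()` (the central model object) reports:

- `tau_fit`: least-squares fit of the ECDF (plotting positions `i/n`) to
  `1 - exp(-t/tau)`. Reported as `tau`, alongside `mu ± sigma` (sample
  moments, `n-1` denominator) because the two legitimately differ in
  finite ensembles.
- one-sample KS statistic and asymptotic p-value against the fitted
  exponential. Testing against a self-fitted `tau` is mildly
  anti-conservative; a parametric-bootstrap p-value (`n_boot`, default
  200 replicates when enabled) is available behind a flag. At the
  package's standard ensemble size (n = 25) the plain asymptotic test is
  in fact well calibrated: 4.9% rejection at nominal 5% over 2000 null
  replicates.
- censoring: runs that do not escape within `max_steps` are excluded and
  counted (never imputed), with a warning above 20% censoring.

Degenerate inputs are defined, not errors: identical exit times give
`sigma = 0` and a finite `tau_fit`; fewer than 5 times refuse the KS
test with advice to run more simulations.

The acceleration average uses the *instantaneous* bias at the visited
point — the bias in force when the point was visited, not re-evaluated
under the final bias. For the static mixture bias the two conventions
coincide; for the on-the-fly bias the instantaneous convention is the one
that pairs with quasi-static growth.

## Numerical choices

- Engine: Euler–Maruyama, default `dt = 1e-3`. Stability was verified
  against the harmonic Boltzmann-variance test; the stiffest shipped
  forces (corrugation curvature ~80 kT/length²) keep `dt` an order of
  magnitude inside the stability limit.
- Seeding: one RNG stream per run, seed = `base_seed + run index`;
  identical inputs give bit-identical trajectories, and fixture files are
  byte-identical under their manifest seeds.
- Oracle: composite trapezoid on 20001 points with midrange energy
  shifting (the shifts cancel exactly in the integrand product) and a
  Richardson half-grid error estimate; relative error < 1e-6 on all
  shipped scenarios. Second-order convergence is tested. A symmetric
  two-exit scenario started at the symmetry point equals the
  reflect-at-centre problem exactly (verified to 6e-10); asymmetric
  starts use the two-absorbing-boundary closed form instead, since a
  reflect/absorb geometry is not the true escape problem there.
- Arrhenius check: for the quartic well the Kramers prefactor is itself
  proportional to the barrier, so the test asserts linearity of
  `log(T*B)` in `B` (slope 0.99 over B = 6, 8, 10) rather than of
  `log T`, whose bare slope (~0.87) would misleadingly fail a 1/kT
  comparison.

## What the synthetic fixtures do and do not show

`generate_fixture()` writes COLVAR-dialect run files whose *rescaled*
exit times are exponential with a known mean by construction (zero,
constant, or deposition-like ramp bias profiles). They encode exactly the
null hypothesis the analysis assumes, so a failure on fixtures isolates a
statistics bug from a dynamics bug. They do not emulate trajectories of
any molecular system: no solvent, no counterions, no multidimensional
committor. Likewise, passing the double-well and surrogate tests shows
the estimator machinery is correct, not that a one-dimensional descriptor
suffices for a particular real host–guest complex — descriptor quality is
the user's modelling responsibility, and the KS p-value is the built-in
alarm that tends to trip when it is poor.

## Problem sizes

The shipped validation sizes are chosen so the full suite runs on a
laptop-class single core in well under a minute of simulation time:
unbiased/oracle comparison at barrier 4 kT with 100 runs; flooding
recovery at barrier 8 kT with 25 runs per method (the conventional
ensemble size for this kind of study); KS calibration with 1000
replicates of 25 draws; bound-state sampling 2e5 steps. Larger barriers
are validated through the oracle alone, where cost is independent of
barrier height.

## Known limitations

- One descriptor only; the mixture and kernel machinery are written for
  1D, and multivariate generalization is out of scope.
- Fixed kernel bandwidth (no adaptive shrinking, no kernel merging); at
  the kernel counts reached here compression would buy nothing and would
  obscure the estimator.
- `Z_n` as the kernel-centre average is one of several reasonable
  normalizations; it is transparent and cheap, and the `E_cut` cap
  removes its main artefact, but it is not the integral-over-explored-
  volume definition used elsewhere.
- The two-depth diffusion estimate is dimensional analysis, not a
  rigorous Einstein relation — useful as an order-of-magnitude summary
  when in-host diffusion limits release, nothing more.
- Escape is defined as first touch of the absorbing threshold. Without a
  commitment window, a scenario whose threshold sits in a recrossing
  region would overcount escapes; the shipped thresholds are placed past
  the solvation drop where recrossing is negligible.
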