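---
title: "Model and methods: simulating macrophage-T cell-tumor interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating macrophage-T cell-tumor interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tmesim` is a hybrid agent-based model of early tumor growth in a
two-dimensional tissue slice, built to ask one question: how do
macrophage-directed immunotherapies change the ability of T cells to
eliminate a tumor? This vignette describes the model, its assumptions, the
calibration of its defaults, and the numerical choices a user should know
about before trusting — or extending — the results.

## The model in one page

The tissue is a single-occupancy lattice (default 100 x 100 sites of
15 um, a 1.5 x 1.5 mm slice; one cell per site). Three agent types live on
it:

* **Cancer cells** advance a proliferation clock (period = 24 h /
  `proliferation_rate_day`; 30 h at the default 0.8/day) and divide into a
  uniformly random empty neighboring site. A surrounded cell becomes
  quiescent — its clock freezes — and re-checks for space every step. Cells
  die at an age limit (300 h default) or, configurably, after a fixed
  number of divisions. Every live, unengaged cancer cell secretes IL-4 and
  a macrophage activation factor (representing alarmins such as HMG-B1).
* **Macrophages** are seeded sparsely at initialization (2e-3 cells/site)
  and recruited at a constant rate. They enter naive (M0). Once the local
  activation factor passes a licensing threshold and their 24-h
  redifferentiation clock has elapsed, they read local IL-4 and IFN-gamma
  (plus the systemic PI3K activity) and commit to M1 or M2 through the
  differentiation model below; they re-evaluate every 24 h indefinitely.
  M2 macrophages secrete IL-4.
* **T cells** are recruited in proportion to a saturating function of
  recent cancer-cell deaths (antigen release): the recruitment rate is
  `ka * N_death * r1 / (ki + N_death)`, where `N_death` sums the death log
  over a closed 1-day window centered `t_delay` days in the past. A naive
  T cell adjacent to antigen (a cancer cell or an M1 macrophage) becomes
  fully active with probability
  `antigen * sigmoid(k * ((antigen - numM2/(numM1 + 1)) - s))` —
  M1 neighbors promote activation, M2 neighbors suppress it. Active cells
  secrete IFN-gamma, proliferate into empty neighbors, and kill: killing
  locks the T cell and its target into a mutual engagement for
  `engage_duration_h`; at expiry the cancer cell dies and the T cell spends
  one unit of its kill budget, exhausting when the budget reaches zero.

Three diffusible factors (activation factor, IL-4, IFN-gamma) obey
reaction-diffusion equations solved by operator splitting each step:
point-source secretion, then an explicit 5-point finite-difference pass
with zero-flux boundaries, sub-cycled to the stability bound
`D*dt/h^2 <= 1/4`. A first-order decay term is included (the pure
diffusion+secretion form grows without bound); setting decay to zero
recovers the undamped equations exactly, which is also how the
mass-conservation tests are made exact.

One engine step (default 1 h) executes: (1) secretion and diffusion;
(2) macrophage recruitment; (3) macrophages in random order; (4) T-cell
recruitment, then T cells in random order (engagements resolve first);
(5) cancer cells in random order; (6) removal of dead agents;
(7) treatment events; (8) recording. A run stops at elimination (0 cancer
cells), at the 5,000-cell cap (space saturation), or at 200 days.

## The differentiation model and its neural surrogate

Macrophage commitment is decided by a mechanistic model read through a
product-ratio score. The mechanistic component shipped here is an
algebraic stand-in with the input/output contract of an intracellular
signaling ODE model: five M1 marker channels (standing in for iNOS,
TNF-alpha, CXCL9, CXCL10 and IL-12) respond as
`1 + alpha_j * H(ifng; K_ifng)` and three M2 channels (IL-10, Arg-1,
VEGF) as `1 + beta_j * pi3k * H(il4; K_il4)`, with `H(x; K) = x/(x + K)`.
All channels are baseline-normalized to 1. The score is the product of the
M1 channels over the product of the M2 channels, averaged over a 24-h
window (for the steady-state stand-in the average equals the instantaneous
value; the plug-in interface accepts time-course-returning models and
averages numerically). A score strictly above 1 labels M1; ties fall to
M2, the microenvironment's default attractor. The stand-in is monotone by
construction: more IFN-gamma never flips M1 to M2, and lowering PI3K
activity only enlarges the M1 region — the mechanism PI3K-inhibition
therapy exploits.

Inside the engine this decision is made by a neural surrogate: a network
with one hidden layer of four sigmoid neurons (inputs IL-4, IFN-gamma,
PI3K activity; one sigmoid output). It is trained on 100,000 Monte-Carlo
samples drawn uniformly over the input ranges and labeled by the
mechanistic oracle, using binary cross-entropy with weight decay
(`nnet`). Because the optimizer occasionally stalls in a poor local
optimum, training restarts from several random initializations and keeps
the fit with the lowest final penalized training deviance — a selection
that never touches the held-out data. Held-out accuracy is recorded on a
random 20% split and is consistently above 99%. Inputs are min-max
normalized; out-of-range queries are clamped to the training edges rather
than extrapolated. The default input ranges (IL-4 0–60, IFN-gamma 0–120
molecules/site) cover the field extrema observed in baseline and treated
lattice runs with headroom.

`nnet` provides no early-stopping callback, so the iteration cap plus
weight decay plays that regularizing role; with 21 weights and 80,000
training rows, overfitting is not a practical concern.

## Treatments

* **Depletion** — while on, every macrophage (any phenotype) is removed
  with probability `strength` per step (continuous), or an exact
  `round(strength * N)` macrophages (nearest, ties up) are removed at each
  cycle start (cycled).
* **Recruitment inhibition** — the macrophage recruitment rate is scaled
  by `1 - strength` while on.
* **PI3K inhibition (reeducation)** — every differentiation query uses
  PI3K activity `1 - strength` while on. Nothing else is touched: not
  survival, not recruitment.

Schedules are pure functions of time: off before `start_day` (default
100), continuous thereafter, or cycled with
`(t - start_day) mod cycle_duration < days_on`. Setting any strength to 0
reproduces the untreated trajectory bit for bit under the same seed.

## Chemotaxis and movement

Cells migrate one site per step by steepest ascent on the
activation-factor field among empty neighbors (Moore neighborhood by
default; ties uniform at random, so a flat field gives an unbiased random
walk; a fully blocked cell stays). Two receptor-level features bound the
sensing range:

* a **sensing floor** (`chemo_floor`, default 1 molecule/site): field
  values below it are indistinguishable from zero. Without it, the
  exponentially small far tail of the field would give every immune cell
  on the lattice a beeline to the tumor from the first step.
* a **saturation ceiling** (`act_sat`, default 30): values above it
  compare equal, so cells deep inside the saturated zone near the tumor
  lose directional information and churn locally.

Together with perpetual motility (a cell whose uphill side is occupied
steps to the best reachable site instead of freezing), these keep the
peritumoral immune crowd loose. This matters for a structural property of
the model: tumor control must be cytotoxic, not mechanical. With T-cell
activation disabled, growth with the full immune population present is
statistically indistinguishable from growth with no immune cells at all —
a property the test suite checks explicitly. Under an absorbing
steepest-ascent rule (cells freeze at local maxima), macrophages pile into
a static shell at the tumor boundary and suppress growth by crowding
alone, which both violates that property and confounds every treatment
comparison.

## Initialization

25 cancer cells start in a compact centered block. Founders get uniformly
random cell-cycle phases and ages, and resident macrophages uniformly
random ages. With identical clocks the founding population divides and
dies in synchronized waves that persist for weeks of simulated time,
producing artificial oscillations and artificially tiny between-replicate
variance at wave-aligned sampling times; random phases restore the
desynchronized steady state a real lesion would have.

## Calibration of defaults

The parameters a practitioner would look up in a supplement are config
entries here; the shipped values were set once, as follows, and the same
values are used by every test and example:

* **Geometry and physics**: 15-um sites; diffusivity 3 um^2/s for all
  three factors (hindered interstitial diffusion of ~15-25 kDa proteins);
  decay 1e-4/s for the cytokines (~2 h half-life) and 5e-4/s for the
  activation factor, giving a decay length of ~5 sites so the chemotactic
  field is tumor-localized. Secretion rates (0.02 molecules/s for tumor
  IL-4 and 0.05 for the activation factor, 0.01 for M2 IL-4, 0.05 for
  T-cell IFN-gamma) put the realized fields in the tens of molecules per
  site — the same scale as the differentiation half-saturations
  (`K_il4 = K_ifng = 10`), so the M1/M2 boundary is a nontrivial surface
  across the simulator's operating range.
* **Activation sigmoid**: `k = 4.4`, `s = 0.5`, so activation is ~0.9 per
  step with no macrophage neighbors, ~0.1 with one net M2 neighbor, and
  negligible at `numM2/(numM1+1) >= 3`. All per-step probabilities are
  step-length-dependent and documented as such.
* **Population balance**: macrophage recruitment 6 cells/day (lifespan
  240 h), T-cell basal recruitment 30 cells/day saturating with
  half-saturation `ki = 50` deaths, 3-day priming delay, kill budget 3
  with 6-h engagements. These were calibrated jointly — once — so that the
  untreated system reproduces the qualitative reference behavior: the
  tumor is held at a sub-saturation equilibrium by T-cell killing, nearly
  all runs persist for 100+ days, macrophages are overwhelmingly M2, no
  M1 cells appear without treatment, and full-strength PI3K inhibition
  started at equilibrium eliminates the tumor through an M1/T-cell
  positive feedback (M1 appearance -> more activation -> more IFN-gamma ->
  more M1). Depletion and recruitment inhibition at high strengths are
  also curative, at lower active-T levels than reeducation — the expected
  ordering among the three strategies.

## What the tests do and do not show

The packaged experiments run at desk scale: a 50 x 50 lattice (a quarter
of the reference tissue), 10–20 replicates per arm, and 30–100 day
horizons, with treatment started at day 50 once equilibrium is
established. The acceptance suite checks: surrogate fidelity (>= 98%
held-out accuracy at the full 100,000-sample scale); exact conservation
and stencil correctness of the diffusion solver; closed forms of the
recruitment and activation laws; the binomial survival law of continuous
depletion; bit-level run reproducibility; the cytotoxic-not-spatial
control property; and dose-monotonicity of tumor removal under PI3K
inhibition. Full-scale sweeps (100 x 100, 100 replicates, ten strengths,
cycling grids, 500-set Latin hypercube designs) use the same code paths
through `treatment_sweep()`, `run_lhs()` and `lhs_sample()` and are a
matter of compute budget, not code.

The synthetic environment emulates cell-scale interaction logic, not any
specific tumor type. It omits — deliberately — angiogenesis, hypoxia,
nutrient competition, stroma, checkpoint-ligand dynamics, Treg/Th
subpopulations, continuous macrophage phenotype spectra, and off-lattice
mechanics. Passing tests therefore certify the implementation and the
internal logic of the interaction network, not quantitative predictions
for real tissue.

## Numerical notes and edge cases

* **Determinism**: one RNG stream per run, seeded once; compiled phases
  draw from R's generator, so `(seed, params, treatment)` determine every
  output byte. Replicates use distinct logged seeds.
* **Stability**: the diffusion macro step sub-cycles to
  `D*dt/h^2 <= 1/4`; decay is applied per sub-step as an exact
  exponential factor, which preserves non-negativity unconditionally.
* **Ties**: migration ties break uniformly at random; the differentiation
  score tie (exactly 1) falls to M2; cycled-depletion rounding is nearest
  with ties up.
* **Degenerate inputs**: empty lattices are fixed points of the step;
  single-class surrogate training records a warning state and a constant
  model; a full lattice records a recruitment shortfall instead of
  failing; fractional recruitment uses a deterministic carry accumulator,
  so long-run arrivals equal rate x time exactly.
* **Engagement integrity**: engaged pairs are mutual by construction and
  audited in tests; engaged cells are frozen (no aging, secretion,
  movement, or division) until resolution.
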