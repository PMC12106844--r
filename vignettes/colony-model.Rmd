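---
title: "A hybrid agent-based / reaction-diffusion model of bacterial colony development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid agent-based / reaction-diffusion model of bacterial colony development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonysim)
```

## The model

`colonysim` simulates an *E. coli* colony developing on a glucose minimal-medium
agar surface, coupling three components:

1. **Agents.** Each cell is a rod (spherocylinder) of radius `r0` confined to
   the x–z cross-sectional plane — one lateral dimension along the agar surface
   and one vertical. This (1+1)-dimensional geometry keeps large populations
   tractable while still expressing both radial and vertical expansion. Cells
   elongate exponentially at their local growth rate — the full spherocylinder
   extent (rod plus caps, proportional to biomass) is multiplied by
   `exp(lambda dt)`, and a daughter inherits exactly half the parent's extent,
   so total biomass and cell count track `exp(lambda t)` through divisions —
   divide at a noisy threshold length, and move by overdamped mechanics under
   four forces:
   Hertz-like elastic repulsion between overlapping rods, the same law against
   the agar half-space, a surface-tension spring that pulls protruding cell
   poles back to the smoothed colony outline, and a weak settling force.

2. **Metabolism.** The local biomass growth rate combines three growth modes
   weighted by Monod factors,
   $$\lambda = \lambda_1\,\theta_o + \lambda_2\,(1-\theta_o)
             + \lambda_3\,(1-\theta_g)\,\theta_o,
   \qquad \theta_s = \frac{C_s}{C_s + K_s},$$
   for aerobic growth on glucose ($\lambda_1$), anaerobic growth on glucose
   ($\lambda_2$) and aerobic growth on acetate ($\lambda_3$). The
   $(1-\theta_g)$ gate encodes the hierarchical preference of glucose over
   acetate; $\theta_o$ switches between the aerobic and anaerobic branches.
   Each mode rate uses a *maintenance-shifted* Monod form: growth is zero at or
   below the concentration $C^* = K\,m/(q_{\max}-m)$ at which maximal uptake
   just covers the maintenance requirement, and follows
   $\lambda_{\max}(C-C^*)/((C-C^*)+K)$ above it. This particular shifted form
   is the one genuinely free functional choice in the growth law: it is
   continuous at $C^*$, reduces to plain Monod when $C^*=0$, and keeps the
   correct saturation value.

3. **Metabolite fields.** Glucose, oxygen and acetate concentrations obey
   reaction-diffusion equations
   $$\partial_t C = D_+\Delta C + \rho P - \rho Q \ \text{(colony)},\qquad
     \partial_t C = D_-\Delta C \ \text{(agar)},$$
   with concentration and flux continuity across the agar–colony interface.
   Uptake and excretion rates per biomass follow the growth-coupled forms
   (e.g. $Q_g = q_{g,\mathrm{aer}}\lambda_1\theta_o +
   q_{g,\mathrm{ana}}\lambda_2(1-\theta_o) + Q_{g,\mathrm{maint}}$; glucose and
   oxygen are never excreted). Glucose and acetate see no-flux conditions on
   every outer boundary; oxygen is held at ambient concentration on all
   air-facing surfaces and no-flux on the side walls and agar bottom.

**Maintenance, starvation and death.** Maintenance is a carbon flux
(`m_carbon`, mmol C gdw⁻¹ h⁻¹; glucose counts 6 C per molecule, acetate 2).
Achievable carbon uptake at the local concentrations is allocated to
maintenance first — glucose before acetate, mirroring the hierarchical
preference — and a cell whose achievable uptake falls below `m_carbon` is
*starving*. Starvation time accumulates on an aerobic or anaerobic clock
according to the local oxygen state (anoxia: $C_o < K_o$), and converts to a
death probability
$$p = 1-\exp\!\big(-\delta_{\mathrm{aer}}\tau_{\mathrm{aer}}
                   -\delta_{\mathrm{ana}}\tau_{\mathrm{ana}}\big),$$
with $\delta_{\mathrm{aer}} = 0.2$/day and $\delta_{\mathrm{ana}} = 2$/day, the
rates measured for glucose-starved batch cultures. Maintenance glucose consumed
anaerobically is fermented, excreting two acetate per glucose; this same 2:1
stoichiometry bounds the acetate a colony can ever excrete at twice the initial
glucose concentration (40 mM for a 20 mM plate).

**Clock semantics.** Whether starvation clocks reset when nutrients return is
not determined by the biology we encode; we default to *cumulative* clocks (the
death hazard acts on total accumulated exposure, and in colonies starvation
durations grow monotonically anyway), with `reset_on_feed = TRUE` available.

## Numerical scheme

Each macro step of `dt_macro` (default 2 min) iterates four stages: (1) cells
are rasterised into a coarse-grained colony mask (morphological closing of the
occupied grid cells) with a biomass density field
$\rho = \rho_{\mathrm{cell}} \times$ occupied-area fraction; (2) the metabolite
fields advance; (3) growth rates and maintenance states are sampled at each
cell centre by bilinear interpolation restricted to non-air grid cells; (4)
cells elongate, divide, update their starvation clocks and death probabilities,
and the contact mechanics relax through adaptive explicit substeps, each
bounded by the stability limit of the currently stiffest contact
(`mech_safety` × drag × length / max force gradient).

The field solver uses cell-centred five-point finite differences with
harmonic-mean face diffusivities, the standard flux-continuous treatment of the
diffusivity jump at the agar–colony interface. Oxygen kinetics relax within
seconds, far below the macro step, so oxygen is solved to quasi-steady state by
fixed-point iteration on the Monod-linearised uptake. Glucose and acetate,
whose domain is closed (a *steady* state with uptake would spuriously drain the
finite reservoir instantaneously), are instead integrated in time by subcycled
backward-Euler steps. Uptake is linearised implicitly as
$\kappa C_{\mathrm{new}}$ with $\kappa = \rho Q(C_{\mathrm{old}})/C_{\mathrm{old}}$,
which keeps the system an M-matrix and guarantees nonnegative concentrations
while conserving mass (the uptake actually applied is the one reported to the
bookkeeping). Grid cells that newly join the colony inherit the mean
concentration of their active neighbours.

Numerical parameters that matter, with defaults: grid spacing `grid_h` (5 µm;
scaled demonstration runs use 8 µm), `dt_macro` (2 min; scaled runs 6 min),
`n_subcycle` (3 implicit substeps per macro step for glucose/acetate),
oxygen fixed-point tolerance `1e-4` relative, mechanics substep cap `dt_mech`
(3.6 s) with safety factor 0.4.

## Parameters

All defaults are listed with units and provenance in `param_registry()`.
Measured quantities for this organism/medium (death rates, the ~5 mM acetate
Monod constant, initial glucose) are marked `measured`; standard *E. coli*
physiology values from the literature (maximal growth rates ~1.0/0.6/0.4 h⁻¹
for the three modes, yields expressed as uptake-per-growth coefficients,
diffusivities, ambient oxygen 0.25 mM air-saturated, biomass density
200 gdw L⁻¹ at full packing) are marked `literature-default`; the remaining
choices of this model (overflow acetate at ~10% of the fermentative excretion
coefficient, mechanical stiffnesses, the anoxia cutoff at $K_o$) are marked
`model-default`. Every value can be overridden from a YAML configuration; units
are fixed (µm, h, mM, gdw) rather than inferred, to avoid silent conversion
errors.

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` builds cell tables, cross-sectional profiles and
viability decay series with analytically known ground truth: an all-monolayer
colony, a stacked block with a single-layer skirt of configurable width, a
parabolic dome profile whose disk-sum volume is computed in closed form, and
exponential CFU decay series with optional lognormal noise. These exercise the
observables and the decay fitter exactly. They do *not* emulate segmentation
noise, uneven illumination, or the 3-D geometry of real confocal stacks, so
passing these tests validates the estimators' arithmetic, not image analysis.

The simulator itself is run at desk scale: our canonical demonstration window
is 0.8 mm of agar surface over a 1.2 mm-deep agar column, 15 h of development,
a few thousand agents — against the several-millimetre, multi-day,
~10⁶–10⁹-agent colonies of the laboratory system. Three consequences are worth
keeping in mind.

First, glucose diffuses across such a window in well under an hour, so the
*total* pool — not only the local gradient — limits growth: the 20 mM pool
here sustains colony-wide growth to about 10.5 h (10 mM to about 9 h), after
which the colony spreads only by mechanical relaxation. Radial speed and
linearity are therefore quantified on the *expansion phase*, from
establishment to growth arrest (the first time the growing fraction drops
below 5%) — the scaled analogue of fitting the experimental radius over its
linear window. The full-run fit, bent by the pool-exhaustion knee, is reported
alongside for transparency. In the laboratory system the plate holds a
reservoir several orders of magnitude larger and only about half of it is
consumed after two days, so no such knee occurs there.

Second, the peripheral monolayer width (and hence the radial speed) depends on
mechanical parameters that are only semi-quantitative in any agent-based rod
model; the surface-tension and settling coefficients were calibrated once, on
nutrient-replete runs, to reproduce the qualitative morphology (a flat colony,
aspect ratio well above one, with a persistent single-cell peripheral skirt
and a verticalized interior). The monolayer's *constancy in time* and its
*insensitivity to glucose* are the meaningful outputs, not its absolute
magnitude (~5–15 µm here, ~20 µm in experiments, ~60 µm in full-scale
(1+1)-dimensional simulations).

Third, the interior death zone is attenuated by scale. A mid-height death
maximum requires a thick core that is simultaneously anoxic and
carbon-starved. In a ~35 µm-tall scaled colony the glucose-fed bottom and the
oxygen-fed top nearly tile the height, so that overlap is thin and brief;
moreover, once the pool is exhausted, carbon-coupled maintenance respiration
ceases, the colony re-aerates, and further starvation accrues on the slow
aerobic clock almost uniformly. Expected death therefore concentrates away
from the surfaces only around its onset; at late times the cell-dense bottom
band dominates the 4 µm death grid. Millimetre-tall colonies, with their
persistent anoxic core, do not share this limitation.

## Degenerate inputs and tie rules

Orientation classification uses a strict cutoff (`|angle| > pi/4` is vertical;
exactly pi/4 counts horizontal), matching the strict `> 0.01 h⁻¹` growing-cell
rule. A colony that is a monolayer throughout reports half its footprint per
side. A flux partition with zero total flux is undefined and returned as `NA`
rather than 0. Cells at exactly the division threshold do not divide (strict
inequality); a division that would produce nonpositive rod length (parent
shorter than two cap radii) is suppressed. The empty cell table is a valid
value for constructors and classifiers but an error for profile/monolayer
observables, which have no meaningful answer.

## Known limitations

Rod mechanics omit rolling friction, adhesion and agar deformation; dead cells
remain as inert mechanical objects (no lysis or necromass recycling); nitrate
respiration, pH/buffer chemistry and other fermentation products (ethanol,
formate) are out of scope; fields and agents live strictly in the x–z plane, so
absolute radial speeds and monolayer widths overestimate their 3-D
counterparts. The maintenance requirement is a single carbon flux shared by all
modes; mode-specific maintenance would need measurements we do not encode.

## A worked example

```{r example, eval = FALSE}
p <- colony_params(C_g_init = 20, domain_width = 720, agar_depth = 480,
                   air_height = 36, grid_h = 6, dt_macro = 0.05, t_end = 12)
sim <- run_simulation(p, seed = 1)
summary(sim)
plot(sim)                     # final cross-section, cells coloured by angle
k <- kinetics(sim)            # one row per macro step
expansion_kinetics(k[, c("time", "radius", "height")], window = c(4, 12))
```

The decay fitter works directly on two-column viability tables:

```{r decay}
fx <- generate_fixtures("decay-series",
                        params = list(a = 1e9, delta = 2, noise = 0))
fit <- fit_exponential_decay(fx$data$time_days, fx$data$cfu_per_ml)
fit
```
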