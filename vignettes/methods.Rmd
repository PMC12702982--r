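---
title: "Modeling trabecular bone remodeling under denosumab with osteosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trabecular bone remodeling under denosumab with osteosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`osteosim` is a micro-multiphysics agent-based (micro-MPA) simulator of
trabecular bone remodeling. Three physical processes are coupled on one
isotropic voxel lattice (14 µm voxels by default):

1. **Tissue mechanics.** Each bone voxel is one 8-node trilinear hexahedral
   finite element with Young's modulus proportional to its mineral fraction
   (`E = E_max · mineral`, default `E_max` 10 GPa, ν = 0.3). Uniaxial
   compression along z (bottom face held, top face displaced, lateral faces
   traction-free) gives the per-element *effective strain*
   ε_eff = √(2U/E), the strain-energy-density equivalent strain. The applied
   load is scaled once so the strain histogram of the bone phase peaks at
   2500 µε, and from then on the *force* is held constant: as the structure
   loses bone the surviving struts strain harder, which is the negative
   feedback arm of the mechanostat.
2. **Cytokine reaction–diffusion–decay.** Eight species (free RANKL, OPG,
   RANKL–OPG, sclerostin, TGF-β, estrogen, denosumab, RANKL–denosumab) live
   on the same lattice. Diffusion uses an explicit 7-point stencil with
   zero-flux boundaries; decay is applied exactly as `exp(-λ dt)`; the two
   reversible complexation reactions advance by an implicit
   (backward-Euler) reaction extent per voxel, which is unconditionally
   stable for stiff on-rates and conserves the three bound+free totals to
   machine precision. The complexes carry no signaling activity; they are
   reversible buffers of free RANKL.
3. **Cell behavior.** Osteoblast-lineage (MSC, osteoblast, lining cell,
   osteocyte) and osteoclast-lineage (HSC, surface preosteoclast,
   osteoclast, osteomorph) agents occupy marrow, surface and bone voxels.
   Transitions are per-agent Bernoulli draws with exponential waiting-time
   probabilities `1 − exp(−rate·dt)`; each rate is a baseline differentiation,
   proliferation or apoptosis constant times normalized Hill effect terms
   evaluated at the *marrow-average* signal levels, mirroring the averaged
   effect terms of the population balance equations. Osteoclasts resorb the
   voxel under them (releasing TGF-β in proportion to the mineral removed);
   osteoblasts deposit osteoid into an adjacent marrow voxel; mineral then
   follows osteoid with the exponential primary-mineralization law, reaching
   70 % of the gap in one week (k = ln(10/3)/7 ≈ 0.172 /day).

### The four mechanistic toggles

Each hypothesis for post-denosumab bone loss is independently switchable;
"off" replaces the modulation with the neutral constant 1:

* **Gate-blocking** (`P_A`): HSC → preosteoclast differentiation scales with
  a Hill curve of RANK occupancy. Under treatment occupancy collapses, the
  gate closes and HSCs accumulate; after drug clearance the reservoir
  differentiates en masse.
* **Osteomorph recycling** (`P_B`): osteoclasts fission into one marrow
  osteomorph per nucleus with probability rate
  `min(p_max, k_fiss (1 − occupancy))`, calibrated so a surface tiled with
  osteoclasts at 100 ng/mL RANKL (= 5000 pM at the default 20 kDa) fissions
  at 0.6 osteoclasts/hour per (100 µm)². Osteomorphs chemotax up the RANKL
  gradient at 14.4 µm/day, survive with a 6-month half-life, and re-fuse
  onto the surface with probability rate ∝ occupancy. With the toggle off
  the cell type does not exist and osteoclasts only apoptose.
* **Clast–blast coupling** (`P_C`): the TGF-β released by resorption
  stimulates MSC → osteoblast differentiation through an activating Hill
  term. During treatment resorption stops, TGF-β falls and formation follows
  it down; during the rebound the released TGF-β drives the recovery of
  formation.
* **Mechanostat** (`P_D`): osteocytes produce RANKL and sclerostin in
  proportion to a decreasing Hill response of local effective strain
  (midpoint 2500 µε, between the 200 µε disuse-resorption and 4000 µε
  overload thresholds) and OPG with the complementary response. Off,
  production is frozen at the midpoint level.

### Occupancy: local and serum-like

Every osteoclast-lineage agent integrates `do/dt = k_on L (1−o) − k_off o`
against the free RANKL at its own voxel. This *local* occupancy drives the
spatial mechanisms (fission, fusion). The *population-level* effect terms
(gate, preosteoclast fusion, drug-accelerated apoptosis) instead use the
equilibrium occupancy at the marrow-mean free RANKL — a serum-like scalar.
This separation is deliberate: agents sort themselves toward RANKL hotspots
over time, so a population rate driven by the mean of convex Hill responses
of local occupancies would drift with the spatial configuration rather than
with the drug state.

## Homeostasis by construction

The biopsy-scale system has two near-integrator pools (the osteomorph pool,
half-life 6 months, and the HSC pool) and several positive feedback paths
(disuse → RANKL → resorption; consumer-pool depletion → free ligand).
Long-horizon stability therefore cannot be left to parameter luck; it is
built in:

* **Balance calibration.** After seeding, every lineage rate that the
  stationarity of the balance equations determines (`Γ_MSC→OB`, `Γ_lc→OB`,
  `Γ_OB→OCY`, `Γ_HSC→pre`, `Γ_pre→OCL`, the fusion constant and the stem
  sources) is solved so the seeded population is an expectation fixed point,
  on the realized per-day event-probability scale (`1 − exp(−rate)`), with
  the fusion budget restricted to surface-adjacent osteomorphs.
* **Production calibration.** Per-osteocyte RANKL, OPG and sclerostin
  production rates are set so the tabulated initial concentrations are
  stationary under decay, complex drain and receptor-mediated consumption;
  the TGF-β release constant is set the same way against the expected
  resorption flux. Receptor-mediated RANKL internalization (an exponential
  sink proportional to the binding flux `L·(1−o)` of osteoclasts and
  osteomorphs) takes a configurable share (default one half) of the
  production budget and is the fast negative feedback that makes the surface
  osteoclast pool self-limiting.
* **Finite surface niches.** Osteoclast formation (preosteoclast conversion
  and osteomorph fusion) scales with `1 − N/(2 N₀)`, where `N` is the
  current osteoclast nuclei mass and `N₀` its baseline: recruitment stops at
  twice the baseline mass and doubles when the pool is depleted. This caps
  the resorptive burst and speeds the post-discontinuation rebound.
* **Niche-regulated stem pools.** MSC and HSC sources relax toward the
  seeded pool sizes with rate `k_niche` (0.05/day), so gate-blocking
  accumulation saturates instead of growing without bound.
* **Spin-up and burn-in.** Before time zero the engine first equilibrates
  fields, receptor occupancies and marrow cell positions for `spin_up_days`
  (30) without cell transitions, then runs `burn_in_days` (270) of full
  drug-free dynamics. At the end of burn-in the formation rate is pinned to
  the *measured* resorption flux minus the configured placebo imbalance
  (default 0.6 %/year of bone volume, inside the 0.5–5 %-per-4-years
  placebo-drift calibration constraint), the mean-field baselines are
  re-normalized at the realized operating point, and baseline BMC is taken
  there. This two-stage calibration is what makes the placebo arm drift
  slowly and the treatment contrasts interpretable.

## Parameters

Numeric binding constants, diffusivities and Hill parameters are not fixed
by any published table at this lattice scale; the defaults are the package's
own calibration, chosen once and documented here:

| Parameter | Default | Why |
|---|---|---|
| `k_min` | ln(10/3)/7 ≈ 0.172 /day | 70 % primary mineralization in 1 week |
| λ(denosumab) | ln 2 / 26 /day | 26-day drug half-life |
| osteomorph half-life | 182.5 days | 6-month survival |
| chemotactic speed | 14.4 µm/day | reported osteomorph motility |
| Kd(RANKL–OPG) | 0.6·12.3/400 pM | the initial concentration table is a chemical equilibrium |
| Kd(RANKL–denosumab) | 10 pM (k_off 0.2/day) | deliberately high off-rate so free RANKL recovers 6–9 months after the final injection as the antibody decays |
| Kd(RANK receptor) | 50 pM | occupancy responsive at near-surface RANKL levels |
| dose pulse | 40 000 pM per 60 mg | suppresses free RANKL > 95 % within days |
| diffusivities | 30 µm²/day | effective (binding-retarded) marrow diffusivity; one stable explicit step per day at 14 µm |
| `p_fiss_max` | 0.28 /day | the fission law is capped at the reference rate itself |
| effect curves | e_max 2 (n 2); occupancy e_max 3 (n 2); apoptosis e_max 10 (n 2) | bounded, normalized to 1 at baseline; the occupancy amplitude also calibrates the reported ~2:1 split between marrow-precursor and osteomorph-reservoir contributions to the post-discontinuation osteoclast surge |
| `E_max`, ν | 10 GPa, 0.3 | linear density-modulus law; config-exposed and logged |
| `rho_cal` | 1.2 g/cm³ | cancels in %ΔBMC |

Initial concentrations and cell densities follow the clinical initialization
table (RANKL 0.6 pM, OPG 12.3 pM, RANKL–OPG 400 pM, sclerostin 50 pM, TGF-β
200 pM, estrogen 27.5 pM; osteocytes 18 500/mm³ BV, MSC 8000 and HSC
6000/mm³ marrow, osteoblasts 6.6/mm² and osteoclasts 0.65/mm² with mean 5
nuclei on histology). Estrogen is held at its postmenopausal value; only its
effect term on osteoblast apoptosis is active.

## Seeding

Two strain-driven seeding modes exist. *Modelling* mode uses the absolute
thresholds (osteoblasts above 4000 µε, osteoclasts below 200 µε).
*Remodelling* mode (the engine default) divides the volume into 1000
near-cubic subregions, seeds osteoblasts above and osteoclasts below the
subregion's mean surface strain, and accepts only subregions where this
yields 6–40 osteoblasts and 4–40 osteoclasts — basic multicellular units.
The published description assigns osteoclasts to both sides of the mean;
this is read as a typographical slip and osteoblasts take the high-strain
side, consistent with the modelling thresholds. Because the acceptance rule
flips between sparse and dense seeding depending on how block size compares
with the surface density, the engine keeps at most `bmu_per_mm2` accepted
subregions per mm² of bone surface (default 20) — active remodeling units
are sparse — and calibrates the per-nucleus resorption rate so total
turnover is `annual_turnover` (default 15 %) of the bone volume per year,
making bone-mass dynamics independent of the seeded-count accident.
Preosteoclasts seed at parity with osteoclasts and osteomorphs at nuclei
parity — the standing reservoir the recycling loop turns over.

## Synthetic phantoms

Real biopsies are not redistributable, so every pipeline stage runs on
synthetic rod/plate phantoms: jittered lattices of vertical rods, lateral
ties and vertical plates (all sharing coordinate pools, so the skeleton is
one connected component), dilated via the Euclidean distance transform to an
exact voxel budget matching the target BV/TV (cohort default 13.1 %). The
`archetype_mix` weight moves the structure model index between plate-like
and rod-like. Phantoms reproduce BV/TV, connectivity along the loading axis,
and the rod/plate SMI contrast; they do not reproduce biopsy-specific
anisotropy, cortical remnants, or scanner noise — conclusions about
individual-biopsy response heterogeneity are outside what phantom runs can
show.

## Morphometry

BV/TV by voxel count; bone surface by the smoothed-gradient integral of the
indicator (exact on flat faces, a few percent low on curved ones); Tb.Th and
Tb.Sp by Hildebrand maximal-sphere filling on the distance transform; SMI by
the differential construction `6·V·S′/S²` with `S′` a central difference of
the surface area under a 1.5-voxel dilation/erosion. On ideal primitives
this yields SMI ≈ 0 (plate), 3 (rod), 4 (sphere) within voxelization error.
Dynamic parameters (BFR, BRR, MAR, MRR) come from voxel-wise osteoid gains
and losses normalized per bone surface and time. BMC is the mineral-weighted
voxel sum (binary counting is a config option); only %ΔBMC is ever compared.

## Numerical choices

* Daily cell timestep; diffusion sub-stepped to the explicit stability bound
  `dt ≤ h²/(6D)`; binding implicit; occupancy and decay exact exponentials.
* Micro-FE: element-by-element Jacobi-preconditioned conjugate gradients
  (rtol 1e-8 by default, 1e-5 inside the engine loop with warm starts);
  the solution is refreshed on a 7-day cadence only when more than 0.2 % of
  bone voxels changed. In-plane rigid modes are removed by two point
  constraints that leave a uniform uniaxial stress state exactly
  representable, so the solid-block closed form (ε_eff = applied strain)
  holds to solver tolerance.
* Voxels eroded below the bone threshold (osteoid 0.5) are cleared outright
  — the osteoclast finishes the voxel — so resorption and formation move
  whole voxels symmetrically; the effective volumetric rates account for
  this.
* Degenerate inputs: empty bone errors in morphometry and seeding; no load
  path errors in mechanics; all-equal strain histograms fall back to
  mean-based load scaling with a warning.
* Reproducibility: one master seed per run; phantom, seeding and engine
  draw from deterministically derived child streams; identical config and
  seed give bit-identical run tables.

## Problem sizes

Desk-scale defaults keep every stage tractable on one CPU: parameter-level
checks run on 24³–32³ phantoms in seconds; the seeding targets use 64³; the
healthy-baseline (90-day) and 4-year placebo runs use 48³. The full-scale
biopsy format (282×282×264 at 14 µm) is accepted by the I/O layer and dims
validation but is not simulated by default.

## Known limitations

* No mineralization lag time and no secondary-mineralization heterogeneity;
  a voxel's mineral always relaxes exponentially toward its osteoid.
* The fission law cannot be linear in (1 − occupancy) across five orders of
  magnitude of RANKL; it is capped at the reference rate, so the measured
  calibration point is honored but extrapolation to very low occupancy is
  flat.
* The inter-patient variability the factorial analysis models comes, at
  desk scale, from phantom-to-phantom structural variation only.
* Systemic pharmacokinetics are reduced to a uniform marrow pulse per
  injection; no whole-body compartments.
* BTM-like outputs (BFR/BRR) are noisier than BMC and, as in vivo, harder
  to match than densitometric trends.
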