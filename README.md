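# osteosim

Agent-based multiphysics simulation of trabecular bone remodeling under
denosumab treatment and discontinuation.

Denosumab, a RANKL antibody injected every 6 months, steadily builds bone —
but stopping it triggers a rapid rebound of resorption that erases the gains
within about 18 months. `osteosim` implements a micro-multiphysics
agent-based (micro-MPA) model to probe the four mechanistic hypotheses
proposed for this rebound: it couples, on one isotropic voxel lattice,

* a voxel hexahedral **micro-finite-element** solver producing the effective
  strain ε_eff = √(2U/E) that drives mechanotransduction,
* **reaction–diffusion–decay** of the RANK/RANKL/OPG signaling system
  (free RANKL, OPG, sclerostin, TGF-β, estrogen, denosumab and the
  RANKL–OPG / RANKL–denosumab complexes as reversible buffers), and
* stochastic **bone-cell agents** — osteoblast lineage (MSC → osteoblast →
  lining cell/osteocyte) and osteoclast lineage (HSC → preosteoclast →
  osteoclast ⇄ osteomorph) — that resorb and form tissue voxel by voxel,
  with mineral following osteoid by first-order kinetics (70 % in one week).

Four mechanism toggles (`P_A` gate-blocking, `P_B` osteomorph recycling,
`P_C` clast–blast coupling via TGF-β, `P_D` mechanostat) can be switched
independently; `run_factorial()` executes the canonical 16-configuration
grid (runs α…π) and `fit_factorial_mixed_model()` fits
`BMC ~ P_A*P_B*P_C*P_D + BL + (1 | phantom)` by REML with Wald tests, the
evaluation layer the mechanism attribution rests on. Comparison metrics
(MAAPE in degrees, windowed R²) score simulated %ΔBMC against a
user-supplied clinical %ΔBMD series.

Because real biopsy scans are not redistributable, the package generates
synthetic rod/plate trabecular phantoms with controllable bone volume
fraction (cohort default BV/TV 13.1 %) and structure model index, so every
stage is testable end to end.

## Worked example

```r
library(osteosim)

# a 64^3 phantom at the cohort bone volume fraction
ph <- generate_phantom(phantom_spec(dims = 64, target_bvtv = 0.131, seed = 1))
static_morphometry(ph)[, c("BV_TV", "Tb_Th", "SMI")]
#>       BV_TV      Tb_Th      SMI
#> 1 0.1310005 0.06270169 1.982495

# two years of 6-monthly injections, then two years off treatment
# (a 32^3 phantom keeps the run short)
ph32 <- generate_phantom(phantom_spec(dims = 32, seed = 1))
cfg <- simulation_config(treatment_months = 24, followup_months = 24, seed = 1)
res <- run_simulation(cfg, ph32)
res$table[res$table$time_months %in% c(1, 6, 12, 24, 30, 36, 42, 48),
          c("time_months", "pct_BMC", "BFR", "BRR")]
```

The `pct_BMC` column rises through the treatment phase (resorption is
suppressed while formation continues), peaks near month 24–30, drops
rapidly as the drug clears and the precursor reservoir plus osteomorph pool
re-form osteoclasts, and stabilizes over months 36–48. `BRR` (the bone
resorption rate, the in-silico analogue of serum CTX) collapses after each
injection and rebounds above its old level before `BFR` (the analogue of
P1NP) follows — the resorption-led imbalance that drives the loss.

A placebo arm is `treatment_months = 0`; its 4-year drift is calibrated to
lie between 0.5 % and 5 % of baseline BMC.

## Command line

A thin CLI wraps the exported functions:

```sh
osteosim phantom   --out phantom.nii.gz --seed 1
osteosim simulate  --config cfg.yaml --phantom phantom.nii.gz --out run/
osteosim factorial --config cfg.yaml --phantoms phantoms/ --out table.csv
osteosim morpho    --in phantom.nii.gz --out morpho.csv
osteosim analyze   --table table.csv --clinical clinical.csv --out report.json
```

Configuration is YAML over full defaults (`validate_config()`); unknown keys
are rejected, and the four flags map to the Greek run label (e.g.
`P_A=1 P_B=1 P_C=0 P_D=0` is run ζ).

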