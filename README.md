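# litterGDM

Guild-based simulation of early plant-litter decomposition in soil, for
soil ecologists and biogeochemical modellers studying how litter chemistry
and microbial activity jointly control carbon mineralization during the
first weeks to months of decay.

## The model

Litter carbon from proximate (Van Soest) analysis is split into four pools:
a decomposable soluble fraction C1D, a persistent soluble fraction C1T, the
acid-hydrolysable holocellulose pool C2 and the acid non-hydrolysable
Klason-lignin pool C3 (all mgC per kg soil). Three microbial guilds —
opportunists (C1D only), cellulolytic (C1D, C2) and lignolytic (C1D, C2,
C3) — consume them with **reverse Michaelis–Menten** kinetics, saturating
in decomposer biomass *B* rather than substrate *C*:

    dC_i/dt = − Σ_j  k_i · C_i · B_j / (K_Bji + B_j)

A fraction `e_i` of each decay flux is assimilated (e1 = 0.4, e2 = 0.3,
e3 = 0), the rest is growth respiration; guilds also pay maintenance
respiration `g·B_j`. The **lignocellulose index** LCI = C3/(C2+C3) feeds
back on the kinetics: k2 declines linearly with LCI and reaches zero at
LCI = 0.7; lignin decay switches on only above a genotype-specific
threshold `lci_t`. Total biomass is capped at `bc_max` = 5% of system
organic C; the excess becomes necromass. Cumulative **microbial
production** is carbon released minus carbon respired — equivalently,
biomass growth plus necromass.

The package bundles the full parameterization of four maize (*Zea mays*)
root genotypes (F2, F2bm1, F292, F292bm3) from a 112-day incubation study,
and provides

* `gdm_simulate()` — compiled fixed-step simulator returning a trajectory
  with respiration rate, cumulative CO2, LCI, realized carbon use
  efficiency, production and necromass series;
* `gdm_calibrate()` — bounded multi-start calibration of (`lci_t`,
  `k_b22`) against observation sets, minimizing the sum of four normalized
  RMSEs; returns a fitted-model object with `coef`, `summary`, `predict`,
  `residuals`, `plot` and `simulate` methods;
* `gdm_sensitivity()` / `partition_variance()` — ±10% Monte-Carlo parameter
  perturbation experiment with type-II sum-of-squares variance partitioning;
* chemistry utilities (`derive_indices()`, `decay_coefficient()`,
  `estimate_k2max()`, `transfer_*()`, `gdm_extrapolate()`) mapping litter
  cell-wall chemistry (Klason lignin, arabinan:xylan ratio, cell-wall
  sugars) to model parameters;
* `generate_observations()` / `generate_genotype()` — synthetic incubation
  observation sets with the study's sampling days and a multiplicative
  noise model;
* a command-line interface (`inst/cli/gdm.R`) with `simulate`, `calibrate`,
  `sensitivity`, `extrapolate` and `synth` subcommands.

## Worked example

```r
library(litterGDM)

p <- gdm_genotype("F2")
tr <- gdm_simulate(p)          # 112 days, dt = 0.1 d
print(tr)
#> Guild decomposition model trajectory (genotype F2)
#>   113 output days over 112 d (dt = 0.1 d)
#>   day 112: cumulative CO2 = 738.5, production = 326.8, LCI = 0.558, biomass = 49.1 mgC/kg
#>   mass balance error: 2.05e-12 mgC; clipping events: 0
```

By day 112 the F2 simulation has mineralized 738.5 mgC/kg soil as CO2 (37%
of the initial 2000 mgC/kg of litter C), the LCI of the remaining litter
has risen from 0.24 to 0.56 as holocellulose decayed while lignin
persisted, and 326.8 mgC/kg has passed through microbial biomass
(production), most of it now in the necromass account.

Calibration against a synthetic observation set with 2% measurement noise:

```r
obs <- generate_observations(p, noise_cv = 0.02, seed = 7)
fit <- gdm_calibrate(obs, update_params(p, lci_t = 0.55, k_b22 = 60),
                     n_starts = 3, seed = 1)
print(fit)
#> Calibrated guild decomposition model
#>   best-fit: lci_t = 0.2528, k_b22 = 28.66
#>   objective (sum of normalized RMSEs): 0.081937
#>   convergence code: 0 (0 = converged); 3 start(s)
```

`k_b22` (guild 2's half-saturation for holocellulose, true value 29) is
recovered to ~1%. `lci_t` drifts to its bound: the lignin decay it gates is
bounded by k3max = 0.001/d and is invisible at this noise level — see the
vignette (`vignettes/guild-decomposition-model.Rmd`) for the
identifiability discussion.

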