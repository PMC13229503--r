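# bindmech

Does a flytrap-type substrate-binding protein bind its ligand by
**induced fit** (bind first, close second) or **conformational
selection** (close first, bind second)? Equilibrium affinities and
structures cannot tell the two apart; kinetics can. `bindmech` is an R
package plus a scripted analysis that implements the full quantitative
chain for this discrimination, exercised end-to-end on synthetic data:

* **Relaxation kinetics** of the linearized three-state schemes. With
  `S = k_e + k_r + k_+[L] + k_-`, the dominant relaxation rate is
  `k_obs = (S - sqrt(S^2 - 4c))/2` with
  `c = k_e(k_+[L] + k_-) + k_r k_-` (CS) or
  `c = k_+[L](k_e + k_r) + k_e k_-` (IF), cross-checked against the
  generator-matrix eigenvalues to rtol 1e-9, together with the
  effective two-state rates, e.g. CS
  `k_on = k_e k_+ / (k_r + k_+[L])`, IF
  `k_off = k_- k_e / (k_- + k_r)` (which forces `k_off < k_e`).
* **SPR fitting under mass-transport limitation**: the two-compartment
  ODE `dr/dt = k_on L_surf (r_max - r) - k_off r`,
  `dL_surf/dt = k_t(L_bulk - L_surf) - alpha dr/dt`, with exponential
  drift correction, fixed-`k_on` association/dissociation fits, and the
  rescaled sum-of-squared-residuals profile whose plateau-above-knee
  shape yields a *lower bound* on the effective on-rate constant.
* **smFRET burst analysis** for µsALEX photon streams: all-photon and
  dual-channel (AND-gate) burst searches, proximity ratio
  `E* = F_DA/(F_DD + F_DA)` and stoichiometry
  `S* = (F_DD + F_DA)/(F_DD + F_DA + F_AA)`, accurate-FRET and
  lifetime-FRET corrections, Gaussian population fits, the
  outside-the-main-population fraction, burst variance analysis against
  the shot-noise semicircle `sqrt(E*(1-E*)/n)`, and Hill (n = 1)
  titration fits.
* **Censored dwell-time estimation**: exponential MLE
  `mean = (sum(t_obs) + n_cens * T)/n_obs` with profile-likelihood
  confidence intervals.
* **Mechanism verdict**: propagation of experimental bounds (K_d range,
  on-rate bounds, closed-population ceiling, exchange-rate ceiling)
  through the pathway inequalities into a compatibility report with a
  replayable equation trail.
* **Synthetic-data generators** for every input — photon streams with
  two-state CTMC FRET dynamics, transport-limited sensorgram cycles,
  binding titrations, censored dwell trajectories — each embedding its
  truth parameters and seed.

## Worked example

The headline inference takes the experimental constraint set of the
glutamine-binding protein study — K_d 10–20 nM, effective on-rate
3e7–1e8 M⁻¹s⁻¹, highest tested ligand concentration 500 nM, a 10%
ceiling on the closed-state population of the ligand-free protein, and
a 100 s⁻¹ ceiling on detectable conformational exchange — and asks
which pathway survives:

```r
library(bindmech)
v <- discriminate(glnbp_constraints())
print(v)
#> Mechanism compatibility verdict
#>   CS: k_e > 15.3 s-1, k_r > 138 s-1 (timescale < 7.26 ms) -> INCOMPATIBLE (escape: exchange faster than 1e-07 s)
#>   IF: 0.3 < k_off < 2 s-1, P_OL > 0.299% -> compatible
```

Reading the numbers: at 500 nM the conformational-selection relaxation
rate would have to exceed `3e7 * 500e-9 + 0.3 = 15.3` s⁻¹, whose
large-concentration limit is the excitation rate `k_e`; the 10%
population ceiling then forces the relaxation rate
`k_r >= 9 * k_e > 137.7` s⁻¹, i.e. open/closed exchange faster than
7.26 ms — excluded by the single-molecule screens unless exchange is
faster than the 100 ns detection floor. Induced fit only needs
`k_off < k_e < k_r < 100` s⁻¹, which the derived
`k_off` range 0.3–2 s⁻¹ leaves ample room for, with at least
~0.3% of the liganded protein in the open conformation.

The standard binding free energy for the calorimetric affinity:

```r
binding_free_energy(35e-9, 298.15)
#> [1] -42.55616   # kJ/mol
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_relaxation_landscape.R` | exact vs approximate `k_obs` for both pathways across ligand concentration |
| `02_spr_fits.R` | sensorgram cycles at the 7.8–1000 nM ladder: drift correction, quality screen, fixed-`k_on` fits, SSR profile, equilibrium K_d |
| `03_smfret_bursts.R` | apo/holo burst populations, outside fraction, burst variance analysis, Hill titration |
| `04_dwell_times.R` | censored dwell MLE and interval coverage |
| `05_mechanism_verdict.R` | the constraint propagation and verdict (prints the block quoted above) |

Run any of them from the repository root, e.g.
`Rscript analysis/05_mechanism_verdict.R`.

## Package layout

* `R/kinetics.R` — pathway rates, generator matrices, exact/approximate
  relaxation rates, effective rates, thermodynamics
* `R/spr.R` — sensorgram container, transport-limited ODE, drift
  correction, fits, SSR profiling, quality screen, equilibrium fit
* `R/smfret.R` — burst searches, E*/S*, FRET corrections, population
  fits, BVA, titration fit
* `R/simulate.R` — the synthetic-data generators
* `R/mechanism.R` — constraint sets, bound propagation, verdict,
  censored dwell MLE
* `vignettes/mechanism-discrimination.Rmd` — the models, their
  assumptions, parameter choices and limitations
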