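# bsabkin

Mechanistic mass-action modeling of monospecific and bispecific antibody
binding to the interleukin-6 and interleukin-8 receptors.

## The problem

IL-6 and IL-8 signaling synergistically drives cancer metastasis, and the
bispecific antibody BS1 — one anti-IL-6R arm (from tocilizumab) and one
anti-IL-8R arm (from 10H2) — blocks both receptors on the same cell.
Whether a bivalent binder ends up in binary (Ab·R) or ternary (R·Ab·R)
complexes determines how stably it occupies its targets, and that balance
depends on arm affinity, cross-linking efficiency, antibody dose, and
receptor expression. `bsabkin` is for modelers and antibody engineers who
want to simulate, fit, and interrogate that balance quantitatively.

## The model

Mass-action ODEs over {Ab, R1, R2, Ab·R1, Ab·R2, R1·Ab·R2} (per-cell counts
for surface species, nM for free antibody, coupled by α = 8.3×10⁻⁷
nM/(#/cell)):

    d[Ab·R1]/dt = kon,R1[Ab][R1] + koff,R2[R1·Ab·R2]
                  − kon,R2*[R2][Ab·R1] − koff,R1[Ab·R1]
    d[R1·Ab·R2]/dt = kon,R1*[R1][Ab·R2] + kon,R2*[R2][Ab·R1]
                     − (koff,R1 + koff,R2)[R1·Ab·R2]

plus the free-species balances. Detailed balance around the closed binding
cycle forces K₁K₄/(K₂K₃) = 1, so kon,8R* = kon,8R·kon,6R*/kon,6R is always
derived and only five rate constants are free. The cross-arm binding
efficiency χ = (α⁻¹kon,R*)/kon,R measures the avidity advantage of the
tethered second arm. Homobivalent antibodies get a statistical factor of 2
on first association and on ternary dissociation (configurable). A stiff
Rosenbrock (RODAS3) integrator with analytic Jacobians is built in.

The package covers: assay simulation with washout, occupancy summaries,
dose × receptor grids, monoclonal-combination comparisons, monovalent
restriction, multi-start bounded least-squares fitting (log₁₀ space, Latin
hypercube starts, four normalization schemes), a synthetic MFI-like data
generator, and local (+10% AUC) / global (±2 decade occupancy) univariate
sensitivity analyses.

## Worked example

```r
library(bsabkin)
rc <- best_fit_rates()       # constants fitted to HEK 293T binding assays
signif(equilibrium_constants(rc), 2)
#>      KD_6R      KD_8R KD_6R_star KD_8R_star
#>    9.5e+00    7.1e+00    5.7e-04    4.3e-04
signif(cross_arm_efficiency(rc), 3)
#> [1] 16500

sim <- simulate_assay("BS1", "IL6R+IL8R+", dose = 100, rc, fitting_protocol())
summarize_occupancy(sim)
#>   bound_binary bound_ternary bound_total frac_binary frac_ternary frac_total
#> 1     277083.9      620432.6    897516.5   0.2966637    0.6642747  0.9609384
#>    occ_il6r occ_il8r zero_receptor
#> 1 0.9974716 0.942258         FALSE
```

After a 2 h incubation of 100 nM BS1 on the double-positive line (3.16×10⁵
IL-6R, 6.18×10⁵ IL-8R per cell), washout, and 15 min detection: 96% of all
receptors are occupied, two-thirds of them in ternary complexes, and the
scarcer IL-6R is nearly saturated (99.7%) — the avidity-driven enrichment
on the limiting receptor that distinguishes the bispecific from a
monoclonal combination.

End-to-end parameter recovery on synthetic data:

```r
dat  <- generate_dataset(default_design(), rc, noise_model(sigma = 0.05), seed = 1)
fits <- run_multistart(normalize_dataset(dat), lhs_initial_guesses(n = 50, seed = 2))
filter_and_select(fits)$summary
```

A command-line front end is installed as `exec/bsabkin`
(`bsabkin reproduce --out-dir out --seed 1` regenerates all derived
tables); see `?run_cli`.

## Layout

- `R/`, `src/` — implementation (rates/registries, simulator + integrator,
  grids, fitting, synthetic data, sensitivity, CLI)
- `tests/testthat/` — unit, property, and acceptance tests
- `vignettes/binding-model.Rmd` — the model, assumptions, numerical
  choices, and known limitations
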