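---
title: "Mechanistic modeling of bivalent antibody binding to IL-6R and IL-8R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic modeling of bivalent antibody binding to IL-6R and IL-8R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsabkin)
```

## The model

`bsabkin` simulates the cell-surface binding of three bivalent antibodies to
the interleukin-6 receptor alpha (IL-6R) and the interleukin-8 receptor B
(IL-8R/CXCR2): the monoclonals tocilizumab (two anti-IL-6R arms) and 10H2
(two anti-IL-8R arms), and the bispecific BS1 (one arm of each). Binding is
described by mass-action ordinary differential equations over the species

* free antibody `Ab` (nM in the well),
* free receptors `R1` (IL-6R) and `R2` (IL-8R) (#/cell),
* binary complexes `Ab.R1`, `Ab.R2` (#/cell),
* the ternary complex `R1.Ab.R2` (#/cell), in which one antibody bridges two
  receptors on the same cell.

First-arm association (rate constants `kon_6R`, `kon_8R`, nM^-1 s^-1) brings
the antibody onto the surface; cross-linking (`kon_6R*`, `kon_8R*`,
(#/cell)^-1 s^-1) converts a binary complex plus a free receptor into the
ternary complex. Dissociation from binary and ternary complexes shares the
same `koff` per receptor (similarity of binding sites). Free antibody is a
bulk concentration while surface species are per-cell counts; the constant
`alpha = 8.3e-7` nM/(#/cell) converts between the two and corresponds to
1e5 cells in about 200 uL (`alpha_from_geometry()` recomputes it for other
geometries).

### The thermodynamic cycle constraint

The four reactions (Ab+R1, Ab+R2, Ab.R2+R1, Ab.R1+R2) form a closed cycle,
so detailed balance forces the product of their equilibrium constants to
unity. With the shared-`koff` assumption this reduces to

```
kon_6R* / kon_6R = kon_8R* / kon_8R  (common units via alpha)
```

so only five rate constants are free; `kon_8R*` is always derived
(`apply_cycle_constraint()`, checked by `cycle_product()`). The common ratio,
expressed in nM^-1 s^-1, is the cross-arm binding efficiency `chi`
(`cross_arm_efficiency()`); for the bundled best-fit constants
`chi = 1.65e4`, i.e. the tethered second arm binds about four orders of
magnitude faster than the first.

### Homobivalent statistical factors

The monoclonals carry two identical arms. By default the first association
runs at `2*kon*[Ab][R]` (either arm can make first contact) and
ternary-to-binary dissociation at `2*koff*[R.Ab.R]` (either arm can
release); binary-to-ternary cross-linking uses the single-arm `kon*`. The
factor of two is a structural choice, not a measured quantity, so
`model_options(stat_factor = 1)` disables it for sensitivity of conclusions
to this choice. With the factor enabled, x nM of a monoclonal presents the
same arm concentration as 2x nM of the bispecific, which is what makes the
1:1 monoclonal combination comparable to the bispecific at equal total dose.

## Numerical integration

The rate scales span roughly ten orders of magnitude (cross-linking
equilibrium constants are sub-picomolar while first-step binding is at nM
scale), so the system is integrated with an L-stable Rosenbrock method
(RODAS3, order 3 with an embedded order-2 error estimate) with analytic
Jacobians, implemented in C++ inside the package because no stiff ODE solver
package is available in the target environment. Defaults: relative
tolerance `1e-8`, absolute tolerance `1e-12` of each species' typical scale
(the dose for antibody, the larger receptor count for surface species).
Linear conservation laws (receptor totals; antibody total before washout)
are preserved to machine precision by construction of the method; the test
suite verifies drift below `1e-6` relative and detailed-balance equilibrium
ratios to `1e-4`. Integrator outputs are clipped at zero for reporting only;
an excursion below `-100 x atol` raises an error instead of being silently
clipped.

## Assay protocols

Two protocols mirror the wet-lab designs:

* **fitting protocol** — antibody added at t = 0; 2 h association at 4 C
  with receptor synthesis/internalization/degradation suppressed;
  instantaneous washout (free antibody set to 0) at 2 h; 15 min detection
  incubation; the terminal *total bound antibody per cell* is the model
  analogue of the flow-cytometry mean fluorescent intensity (MFI).
* **analysis protocol** — 24 h, no washout, occupancy summaries at the end.

Washout semantics: the default is a single reset of the free-antibody pool
to zero, after which dissociated antibody re-enters the free pool and may
rebind; `clamp_washout = TRUE` instead holds free antibody at zero
(perfusion-like). The published description does not distinguish the two;
both are provided and the default is the reset. After washout the ternary
complex count *increases* while total bound antibody decays: freed receptors
cross-link with existing binary complexes — the avidity signature this model
exists to capture.

## Parameter estimation

The five free constants are fitted to normalized dose-response tables by
bounded nonlinear least squares in log10 space (log-uniform initial-guess
ranges and order-of-magnitude bounds justify the log parameterization,
which the source description leaves implicit). The data normalization
divides every MFI value, per cell line, by the mean BS1 signal at its
saturation doses — doses where BS1 binding is within 5% of its dose-grid
maximum, falling back to the top two doses — making fits invariant to the
arbitrary MFI scale. Four schemes normalize the *simulation* side
(`norm_scheme()`): basis BS1 or per-antibody, reference saturation doses or
maximum dose; the default (BS1/saturation) is the scheme under which the
published constants were selected. The experimental side is always
BS1/saturation-normalized, so only the default scheme can reach zero cost
on noise-free synthetic data; the per-antibody schemes are retained as the
alternatives that were evaluated and rejected.

Multistart machinery: `lhs_initial_guesses()` draws stratified log-uniform
Latin hypercube samples (exactly one per stratum per margin);
`run_multistart()` solves one bounded least-squares problem per start using
a bound-projected Levenberg-Marquardt on the residual vector (finite
difference Jacobian; `stats::nlminb` is available as an alternative);
`filter_and_select()` discards starts that did not converge or did not move
from their guess (operationalized as max per-parameter displacement below
1e-6 log10 units), then selects the minimum-cost fit with ties broken by
start index. A failed integration at any design point contributes a large
penalty residual rather than aborting the start. The observed discard rate
is optimizer-dependent and is reported, not targeted.

## Synthetic data

Raw MFI values for the original experiment are unpublished (the study
deposits no accession; values appear only in figures), so `generate_dataset()`
stands in for them: it forward-simulates the fitting protocol over the
default design — 11 log-spaced doses from 0.01 to 1000 nM; the seven
binding-competent antibody x cell-line combinations (77 points); receptor
expressions 5.08e5 (IL-6R+ line), 1.30e6 (IL-8R+ line), and 3.16e5/6.18e5
(double-positive line) — multiplies by an arbitrary MFI scale (default 1e3
per bound antibody per cell), and applies multiplicative Gaussian noise per
replicate (3 replicates, CV 5% truncated at zero, a plausible magnitude for
flow-cytometry technical replicates; the true replicate noise is not
recoverable from the published error bars and remains a free knob). What a
green test establishes: the pipeline recovers known ground truth from data
with this structure. What it does not establish: agreement with the original
instrument's MFI values, autofluorescence, or gating artifacts — none of
which are modeled.

## Sensitivity analyses

* **Local**: BS1 at 10 nM on 5e4 + 5e4 receptors/cell, 2 h, no washout;
  each rate constant and each initial concentration is raised 10% in a
  separate run; outputs are trapezoid AUCs of ternary-bound and total bound
  receptor; sensitivity = %dAUC / %dparameter.
* **Global**: same receptor levels (treated as initial values, not clamped
  — the published wording "constant receptor concentrations" is ambiguous
  and no turnover process exists in this model, so the two readings
  coincide), 24 h horizon, each rate constant varied over +/-2 decades on a
  41-point log grid, dose panel {1, 10, 100} nM by default (the published
  panels are not enumerated).

When a parent of the derived `kon_8R*` is perturbed, the default
(`constraint = "propagate"`) re-derives it so the cycle stays valid; a
`"frozen"` mode holds it fixed since the published choice is not stated.
Propagation is asymmetric under an IL-6R/IL-8R role swap (the derived
element stays `kon_8R*` on both sides), so exact swap symmetry of
sensitivities holds only in frozen mode.

## Design choices and known limitations

* **BsAb vs monoclonal combination at 1:1 receptors.** The two agree to
  about 7e-3 absolute occupancy fraction at 24 h (1.6e-3 at full
  equilibrium) with the bundled constants. Exact identity is impossible:
  the cycle constraint forces `kon_6R* != kon_8R*` whenever
  `kon_6R != kon_8R`. Tests assert figure-resolution identity (1e-2).
* **Total occupancy is not globally monotone in `kon_6R`.** Speeding the
  first binding step past its optimum converts stable ternary complexes
  into binary ones and can lower total bound receptor at high dose; only
  the directional claim (slowing the first step two decades below baseline
  costs binding) is asserted.
* **mAb combination decouples.** Tocilizumab and 10H2 bind disjoint
  receptors, so the joint system is simulated exactly as two independent
  homobivalent networks and summarized together.
* Receptor synthesis, internalization and degradation are out of scope
  (suppressed at 4 C in the source experiments), as are IL-6/IL-8 ligand
  competition, downstream JAK/STAT signaling, diffusion-limited
  cross-linking, and in-vivo pharmacokinetics.

## A worked example

```{r example, eval = FALSE}
rc <- best_fit_rates()
signif(equilibrium_constants(rc), 2)
#>      KD_6R      KD_8R KD_6R_star KD_8R_star
#>    9.5e+00    7.1e+00    5.7e-04    4.3e-04

sim <- simulate_assay("BS1", "IL6R+IL8R+", 100, rc, fitting_protocol())
summarize_occupancy(sim)

# end-to-end synthetic recovery
dat <- generate_dataset(default_design(), rc, noise_model(sigma = 0.05),
                        seed = 1)
fits <- run_multistart(normalize_dataset(dat),
                       lhs_initial_guesses(n = 50, seed = 2))
filter_and_select(fits)$summary
```
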