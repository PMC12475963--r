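---
title: "Estimating free-energy barriers of diffusion-controlled reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating free-energy barriers of diffusion-controlled reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrierless)
```

## The problem

Many elementary steps in chemistry — ligand dissociation from a metal
complex, fragmentation of an encounter complex, homolytic bond cleavage —
are *electronically barrierless*: the electronic energy rises monotonically
as the two fragments separate, and no saddle point exists on the potential
energy surface. Experimentally these steps are diffusion controlled, and
they still have a barrier in the *Gibbs free energy*, because the entropy
gained as the fragments start translating and rotating independently
eventually overwhelms the electronic attraction. Static quantum chemistry
with the rigid-rotor harmonic-oscillator (RRHO) model cannot see this
barrier: RRHO entropy is defined at stationary points and knows nothing
about the gradual onset of fragment translation and rotation along the
path. Rigorous alternatives (variable-reaction-coordinate variational
transition-state theory, ab initio molecular dynamics with entropic path
sampling) exist but are orders of magnitude more expensive.

`barrierless` implements a cost-efficient composite model that needs only
three expensive quantities — the RRHO entropies of the bound complex and of
the two isolated fragments — plus two cheap series along the relaxed scan:
the electronic energies and a quantum-chemical bond descriptor (a bond
order such as IBSI, MBO or LBO, or an atoms-in-molecules index evaluated at
the bond critical point).

## The model

Energies are referenced so that the separated fragments sit at exactly
0 kJ/mol. Four pieces are composed:

1. **Electronic energy.** A Morse curve is fitted to the scan,
   $\Delta E_\mathrm{fit}(r) = \Delta E_\mathrm{eq}\,
   (e^{-2a(r - r_\mathrm{eq})} - 2 e^{-a(r - r_\mathrm{eq})})$,
   so that $\Delta E(r_\mathrm{eq}) = -\Delta E_\mathrm{eq}$ and
   $\Delta E \to 0$ as $r \to \infty$ (`fit_morse()`).

2. **Bond cleavage.** The descriptor series is min–max normalized to
   $[0, 1]$ and fitted with $D_\mathrm{fit}(r) = D_0 e^{-k_\mathrm{desc} r}$
   (`normalize_descriptor()`, `fit_descriptor()`). The bond is declared
   broken where the fitted slope magnitude first drops to a cutoff
   $\gamma_\mathrm{cleave}$, which has the closed form
   $r_\mathrm{cleave} = \ln(k_\mathrm{desc} D_0 / \gamma_\mathrm{cleave}) /
   k_\mathrm{desc}$ (`cleavage_distance()`). A larger cutoff breaks the
   bond earlier and lowers the final barrier.

3. **Entropy onset.** The total dissociation entropy is
   $\Delta S_\mathrm{diss} = S_A + S_B - S_{AB}$ from the RRHO engine
   (`species_entropy()`, `entropy_amplitude()`); its free-energy amplitude
   $-T\Delta S_\mathrm{diss}$ is typically a few tens of kJ/mol and
   negative. Its onset along the path is modelled by a sigmoid
   $-T\Delta S_\mathrm{fit}(r) = \dfrac{-T\Delta S_\mathrm{diss}}
   {1 + e^{-k_\mathrm{sig}(r - r_\mathrm{cleave})}}$,
   anchored so that **exactly half** of the total entropy is recovered at
   the cleavage distance — $r_\mathrm{cleave}$ is the inflection point.
   This anchoring removes the ambiguity that plagues free sigmoid fits to
   scattered pointwise entropies.

4. **Assembly and tuning.** The free energy is the pointwise sum
   $\Delta G_\mathrm{fit}(r) = \Delta E_\mathrm{fit}(r) - T\Delta
   S_\mathrm{fit}(r)$ (`assemble_gibbs()`). Its interior maximum is the
   transition state; the dissociation barrier is taken relative to the
   curve at $r_\mathrm{eq}$ and the association barrier relative to the
   separated-fragment asymptote (`find_barrier()`). A steepness that is too
   high leaves an unphysical minimum between the transition state and the
   products, so $k_\mathrm{sig}$ is lowered geometrically from its starting
   value until no post-TS minimum deeper than a tolerance survives
   (`tune_steepness()`); the first (largest) passing steepness is kept.

`run_pipeline()` chains all stages and records every intermediate
parameter.

```{r pipeline}
case <- synthetic_case(seed = 42)
res <- run_pipeline(gen_scan(case), gen_descriptor(case),
                    amplitude = case$amplitude, gamma_cleave = 0.02)
glance(res)
```

## Parameters that matter

| parameter | unit | default | meaning |
|---|---|---|---|
| `gamma_cleave` | 1/Å (normalized) | 0.02 | slope cutoff defining bond cleavage; 0.02 works well in the gas phase, 0.01 in solution |
| `k_start` | 1/Å | 10 | initial sigmoid steepness |
| `shrink` | – | 0.9 | geometric factor per tuning step |
| `k_floor` | 1/Å | 0.1 | tuning failure threshold |
| `tol_min` | kJ/mol | 0.01 | depth at which a post-TS dip counts as a minimum |
| `tol_barrier` | kJ/mol | 0.01 | height at which an interior maximum counts as a barrier |
| `grid_step` | Å | 1e-3 | curve resolution for TS location and dip detection |
| `raising_cutoff` | cm⁻¹ | 100 | low-frequency raising in the vibrational entropy |
| temperature, pressure | K, Pa | 298.15, 101325 | thermodynamic state of the RRHO entropies |

The cutoff `gamma_cleave` is the one genuinely physical tunable: sweeping
it over the conventional ladder shows the barrier decreasing monotonically
as the cutoff grows, because cleavage — and with it the entropy onset —
moves inward:

```{r sweep}
sweep <- gamma_sweep(gen_scan(case), gen_descriptor(case), case$amplitude,
                     c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1))
sweep[, c("gamma_cleave", "r_cleave", "k_sig_final", "barrier_dissociation")]
```

## The RRHO entropy engine

`species_entropy()` evaluates the standard closed-form factorization:
Sackur–Tetrode translational entropy, classical rigid-rotor rotational
entropy from the principal moments of inertia (with a user-supplied
symmetry number — point-group perception is deliberately out of scope),
harmonic vibrational entropy, and $R\ln(2S{+}1)$ electronic entropy.
Design choices:

* **Low-mode raising.** Harmonic frequencies below 100 cm⁻¹ are unreliable
  and their entropy term diverges as $\nu \to 0$; every mode below the
  cutoff is raised to the cutoff before evaluation (the quasi-harmonic
  treatment applied by GoodVibes-style workflows), rather than switched to
  a free-rotor interpolation. The cutoff is configurable; 0 recovers the
  plain harmonic result.
* **Masses** are standard (abundance-weighted) atomic weights, matching
  common thermochemistry codes, not single-isotope masses.
* **Linearity** is decided by the smallest principal moment of inertia
  (below 10⁻³ amu Å² the species is treated as a linear rotor), which is
  robust for near-linear geometries.
* **Standard state** is the ideal gas at the given pressure with no
  concentration correction.

## What the synthetic generator emulates — and what it does not

`synthetic_case()` produces fully specified dissociations with known ground
truth: a Morse electronic curve sampled on the scan grid, an exponentially
decaying descriptor on the normalized scale, an entropy amplitude, and
optional i.i.d. Gaussian noise (the minimal model for the scatter seen in
pointwise entropy estimates). The defaults mirror a hydrogen-bonded
complex: a 20 kJ/mol well at 1.95 Å scanned to 6 Å in 0.05 Å steps, a
descriptor decay of 1.3 Å⁻¹, and a −35 kJ/mol amplitude at room
temperature — the canonical entropy gain of splitting one molecule in two.

`analytic_barrier()` is the oracle: it composes the free-energy curve from
the *true* parameters — including the exact min–max transform the pipeline
applies to the descriptor — and maximizes it by brute force on a 10⁻⁴ Å
grid, with no fitting and no refinement.

Two deliberate validation-design points:

* **Fast-decaying descriptors for tight agreement.** Min–max normalization
  subtracts the smallest descriptor value on the grid, which leaves a
  constant offset of order $e^{-k_\mathrm{desc}\cdot\mathrm{span}}$ under
  the exponential fit. For slow decays over short spans this offset biases
  $r_\mathrm{cleave}$ by up to ~5·10⁻⁴ Å and the barrier by a few times
  10⁻³ kJ/mol. The randomized validation suite therefore uses
  covalent-bond-order-like decays ($k_\mathrm{desc} \in [2.2, 3.2]$ Å⁻¹)
  over a 6 Å span, where the offset is below 2·10⁻⁶ and pipeline and
  oracle agree to better than 10⁻³ kJ/mol. The slow-decay default case is
  used for qualitative behaviour (sweeps, noise robustness).
* **What passing does not show.** The generator draws from the same model
  families the pipeline fits, so these tests demonstrate correctness of
  the machinery, not of the model for real scans: real electronic curves
  are only approximately Morse, real descriptors only approximately
  exponential, and real pointwise entropies scatter non-Gaussianly. The
  problem sizes (82–121 scan points, 25 random cases, 50 noise seeds) are
  the package's chosen validation scale.

## Numerical choices and degenerate inputs

* Nonlinear least squares uses Levenberg–Marquardt with tight tolerances;
  starting values come from the data (well minimum and curvature for the
  Morse fit, a log-linear regression for the descriptor decay).
* The transition state is located on a `grid_step` scan and refined with a
  three-point parabola, then re-evaluated through the analytic models, so
  the reported barrier does not depend on grid registration; doubling the
  density moves it by less than 10⁻⁴ kJ/mol.
* Post-TS dip detection appends the $r \to \infty$ asymptote to the
  scanned window, so a minimum whose rise completes only beyond the window
  edge is still seen. The window always extends to
  $r_\mathrm{cleave} + 10 / k_\mathrm{sig}$, where the sigmoid is
  saturated to ~5·10⁻⁵ of its amplitude.
* The sigmoid is evaluated *literally* at $r_\mathrm{eq}$, where it is
  slightly nonzero; that residual is reported (`residual_at_req`) and can
  be subtracted with `offset_at_req = TRUE`. The literal form is the
  default because the half-anchored sigmoid, not its offset variant, is
  the model's definition; the two differ by well under 1 kJ/mol whenever
  $k_\mathrm{sig}(r_\mathrm{cleave} - r_\mathrm{eq}) \gtrsim 5$.
* Whether $r_\mathrm{eq}$ is fitted or fixed from the optimized geometry
  is an open modelling choice; both are supported (`fix_r_eq`), with the
  free fit as default since it uses the same objective as the rest of the
  curve.
* Degenerate inputs fail loudly with the stage name attached: constant
  descriptors, non-decaying descriptors, scans without a bound well, a
  cutoff larger than the initial descriptor slope ("bond already broken at
  equilibrium"), and steepness tuning that reaches its floor.

## Known limitations

* The entropy model interpolates between two RRHO endpoints; everything
  RRHO misses (hindered rotations, vibrational anharmonicity,
  conformational entropy, ro-vibrational coupling) is missed here too. At
  high temperatures (upwards of ~1200 K) the RRHO endpoints themselves
  become unreliable and the composite model inherits that breakdown.
* One bond, one reaction coordinate; no multi-dimensional coordinates, no
  tunnelling, no variational flux minimization.
* The cleavage cutoff is a convention, not an observable: reported
  barriers should state it, and comparisons across reactions must hold it
  fixed.
* Descriptor values must come from an external wavefunction-analysis tool;
  the package consumes tables, it does not compute electronic structure.
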