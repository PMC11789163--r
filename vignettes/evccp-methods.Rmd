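---
title: "Extended-variable coupled polymorph sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-variable coupled polymorph sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evccp)
```

## The sampling problem

Crystal structure prediction for a rigid molecule asks: given the molecule,
a space group and the number Z' of independent molecules in the asymmetric
unit, which periodic packings are low in lattice energy, and how easily does
a search generate each of them?  The classic baseline is pseudo-random (PR)
search: draw cell parameters and molecular placements at random, locally
minimize the lattice energy, repeat N times, and de-duplicate.  PR search is
robust but spends most of its effort rediscovering wide basins; polymorphs
with narrow basins of attraction are generated rarely.

This package implements an enhanced-sampling layer over that baseline.  A
set of *extended variables* (EVs) `S` — one center-of-mass triple plus one
set of intrinsic ZYZ Euler angles per molecule of the cluster, living in a
large orthogonal reference box with no self-interaction — is tethered to the
packing coordinates `X` of the crystal by a harmonic spring:

    U(X, H, S) = U(X, H) + k_com/2 * sum_i |com_i - s_com,i|^2
                         + k_euler/2 * sum_i wrap(euler_i - s_euler,i)^2

where `H` is the unit cell and `U(X, H)` the lattice energy per molecule.
At every Monte Carlo step the EVs are held fixed while a *mini-batch* of M
structures is generated: each member draws a fresh random cell within the
sampler bounds, seeds its packing coordinates at `X0 = S`, is pre-screened
against an energy threshold, and is then locally minimized on the biased
surface.  The batch minimum of the biased energy is the step's conditional
energy `U(X, H | S)`, and `S` itself is propagated by a Metropolis update at
bath temperature T with uniform component-wise proposals.  Strong coupling
concentrates the generated structures around the packing the EVs currently
describe — the generator samples the *conditional* distribution
P(X, H | S) rather than the marginal P(X, H) — while the Metropolis walk
moves `S` between basins.

Replica exchange ("MRE") runs several such chains at a temperature ladder
and periodically swaps **only the EV vector** (and its cached conditional
energy) between neighboring baths with the usual
min(1, exp[(β_i − β_j)(U_i − U_j)]) rule.  Three variant moves are
implemented on top of the plain ladder (MRE0): a history-dependent Gaussian
repulsion on visited EV states (MRE1, metadynamics-style), a per-bath reset
to the best basin seen so far at the start of each cycle (MRE2,
"forced relaxation"), and a global restart from the fully re-minimized
unbiased minimum of everything archived (MRE3, "relaxation restart").

Because the EVs are ergodic ordinary coordinates, ensembles of polymorphs
generated under two different generator settings (for example Z' = 2 versus
Z' = 1) can be compared thermodynamically: the EV path of the base ensemble
is re-fed to the target generator, energy differences are re-weighted per
molecule, and a free-energy difference follows from Zwanzig exponential
averaging with a line fit against temperature.

## The energy backend

The method is potential-agnostic; this package ships a documented site-site
Lennard-Jones (12-6, Lorentz–Berthelot mixing) plus real-space Coulomb
rigid-body lattice energy in place of a production force field.  Key
choices:

* **Per-molecule normalization.** The pair sum runs over asymmetric-unit
  sites against every symmetry/periodic image inside the cutoff, is halved
  for double counting and divided by Z'.  Intramolecular pairs are excluded
  (rigid bodies make them constant).
* **Force-shifted truncation** (default `shift = TRUE`,
  `cutoff = 8` Å): each pair term is shifted so that both the energy and its
  derivative vanish at the cutoff.  A plain truncated potential leaves a
  discontinuity that finite-difference gradients sample as spurious
  ~10^3 kJ/mol/Å spikes, which destroys quasi-Newton convergence
  diagnostics.  Tests that assert textbook pair values use
  `shift = FALSE` with a large cutoff, where the difference is below their
  tolerances.
* **No Ewald summation.**  Shipped fixtures carry zero or small charges, so
  real-space truncation suffices; this is a documented limitation of the
  backend, not of the sampling layer.
* **Units and constants**: kJ/mol, Å, degrees, K;
  kB = 0.0083144621 kJ/mol/K; Coulomb prefactor 1389.35458 kJ mol⁻¹ Å e⁻².
  Harmonic constants carry inverse-square units (kJ mol⁻¹ Å⁻²,
  kJ mol⁻¹ deg⁻²): a harmonic energy requires them, even though spring
  constants for this method are sometimes quoted per-Å/per-degree.

Local minimization is L-BFGS-B over the centers, Euler angles and the free
cell parameters of the crystal system, with central finite-difference
gradients evaluated in compiled code and box constraints that keep the cell
non-degenerate (lengths bounded away from zero, angles in [40°, 140°]).
The projected-gradient stopping target defaults to 1e-2 kJ/mol per
coordinate: with FD gradients, tightening to 1e-4 multiplies the iteration
count several-fold while moving energies by far less than the duplicate
tolerance of 0.1 kJ/mol.  Reference fixtures and MRE3 restarts re-polish at
1e-3 with a raised iteration cap.  Records that stop at the iteration cap
or with a large residual gradient are flagged `converged = FALSE` and kept.

## Duplicate detection and post-processing

Two records are duplicates when (i) unbiased energies agree within
0.1 kJ/mol, (ii) their **Niggli-reduced** cells agree within 0.1 Å / 0.5°,
and (iii) when the raw settings coincide, the best center RMSD over
symmetry images, molecule permutations, an aligning origin shift and
minimum-image wrapping is below 0.3 Å.  Comparing reduced cells is
essential: the same lattice re-described in another basis (a monoclinic
shear, an axis relabeling) otherwise counts as a new "polymorph", which
splits N_distinct and deflates every probability estimate.  The reduction
follows Krivy–Gruber with numerical tolerances and is property-tested
against random unimodular basis changes.

Sampler archives store structures minimized *under the bias*; they are
slightly strained copies of the underlying minima.  All landscape
statistics and hit counts therefore run through `postprocess_records()`,
which re-minimizes each archived record on the unbiased surface — the
analogue of the usual post-processing stage of enhanced-sampling searches,
which do not fully converge structures on the fly.

## Synthetic fixtures: what they emulate, and what they do not

The fixture module generates every input the tests need:

* **Molecules** — a single LJ site ("atom", ε = 1 kJ/mol, σ = 3.4 Å), a
  bent triatomic (bond 1.5 Å, angle 105°), a charged variant (±0.2 e) and a
  planar 5-site ring.  Values favor numerical robustness over chemistry.
* **Reference polymorphs** — the global minimum of a seeded 200-trial PR
  search, polished to a fixed point and cached per session.  The bent/P2₁
  system is the workhorse: ~40+ distinct minima at desk scale, with a global
  minimum whose basin captures only ~5 % of random starts — a deep *and*
  rare target, the situation the enhanced sampler is designed for.
* **Analytic EV surrogates** — quadratic (exact Gaussian stationary law),
  double-well (exact 1-D Boltzmann marginal and swap-acceptance integrals),
  a seeded rough quadratic (enumerable local minima), and a displaced
  harmonic pair with closed-form ΔF(T).  Surrogates bypass the crystal
  generator entirely, so sampler correctness is tested against exact
  statistical mechanics with no force-field noise.

What passing these tests does **not** show: behavior under a realistic
force field (dispersion anisotropy, electrostatics-dominated packings,
torsional flexibility), Z' > 2 cluster effects at production scale, or any
of the published benchmark numbers for real compounds, which depend on
their force field and 8000-structure searches.  The package's claims are
about the *method's* statistical behavior, which the surrogates pin down
exactly.

## Numerical and statistical choices

* **RNG streams.** Every stochastic component draws from its own saved
  `.Random.seed` stream, so replica baths are independent and an
  exchange-off ladder reproduces independent chains *bit-exactly* — that
  reduction is a test, not an aspiration.  Child seeds stay below 2^31.
* **Proposal steps.** For the quadratic surrogate the test uses steps of
  1.2 × the target thermal width (acceptance ≈ 0.4); crystal-mode defaults
  are 0.5 Å / 10°.  `run_fed_study` scales steps by sqrt(T/300) across its
  ladder and warns when a run's acceptance leaves [0.3, 0.7], mirroring the
  usual acceptance-ratio guidance.
* **Mini-batch energy.**  The step energy is the hard argmin of the batch's
  biased energies.  A log-sum-exp smoothing over the batch at the bath
  temperature is available behind `smoothing = TRUE`; the published
  description's exact conditional-probability smoothing appears only in an
  appendix that is not printed in the available text, so the argmin form is
  the default.
* **Adaptive pre-rejection.**  The threshold defaults to 1000 kJ/mol above
  the best unbiased energy seen in the run (configurable, or a fixed
  value); prefilter rejections redraw the member's cell up to a retry cap,
  and a fully infeasible batch raises a step-infeasible error that the
  Metropolis layer logs as a rejection.
* **Autocorrelation-aware errors.**  FEP standard errors from chain samples
  are inflated by the integrated autocorrelation time of the Boltzmann
  weights (initial-positive-sequence truncation); iid delta-method errors
  alone overstate precision several-fold at these step sizes.
* **Exchange bookkeeping.**  Swaps move cached conditional energies by
  default; `re_evaluate_on_swap = TRUE` re-runs mini-batches at the swapped
  EVs for the strict interpretation.  Nearest-neighbor pairs alternate
  parity every sweep (default every 5 steps).
* **Ties and degenerate inputs.**  Group comparisons use strict `<` for
  R_g (ties count as "not lower"); percentiles are nearest-rank;
  `top20_gap` truncates its window below 20 samples; gimbal-locked Euler
  extraction returns γ = 0.

## The vibrational free-energy line

The harmonic vibrational free energy per mode is
F = ħω/2 + kB·T·ln(1 − e^(−ħω/kBT)), summed over the spectrum
(`vib_free_energy`; the T = 0 limit is the zero-point sum).  A subtlety
matters for interpreting line fits of ΔF_vib(T): expanding
ln(1 − e^(−x)) = ln x − x/2 + x²/24 − …, the −x/2 term **cancels the
zero-point energy exactly**, so the exact high-temperature line has slope
kB Σ ln(ω_b/ω_a) and an intercept that estimates the ħ²ω² quantum
correction — *not* the ZPE difference.  The customary straight-line model
(`fed_vib(..., approx = "high_T")`) drops that cancellation, giving
ΔF(T) = ΔZPE + kB Σ ln(ω_b/ω_a) · T, whose intercept is the ZPE difference
by construction.  The package exposes both; the consistency tests assert
linearity and the classical slope for the exact form, and intercept = ΔZPE
for the model form.  A positive fitted intercept with a negative slope
yields the usual entropic crossing temperature, reported by
`fit_fed_line()`.

## Problem sizes used by the shipped tests

Chosen once, as the package's own desk-scale study conditions: Boltzmann
check 50 000 surrogate steps (5 000 burn-in, thin 20); reduction check
2 000 PR trials vs a 2 000-structure zero-coupling chain; coupling-bias
check 100 mini-batches (M = 5) at each k in {0, 10, 100, 1000};
enrichment check 5 000 PR trials vs 500 mini-batches (M = 5); two-bath
double-well ladders of 30 000 steps against an 80 000-step single-T run,
with both chains thinned by the measured integrated autocorrelation time
of the well indicator before the marginal chi-square (the raw chains are
far from independent, which would make the test anti-conservative);
FEP surrogate ladders of 10 000 steps with 2 000 discarded (the published
protocol's shape) at five temperatures; and the rare-minimum comparison at
a 600-structure budget per search over 6 seeds with the 263/370/574/1142 K
ladder, k = 1000 and M = 10.  The variant comparison is the one place the
published scale (8 000 structures per search) is reduced; the compared
quantity — ordering of generation counts — is scale-free, and the ordering
is unchanged at the larger scales we ran during development.

## Known limitations

* The energy backend is a toy potential; absolute energies, densities and
  landscape shapes do not transfer to real compounds.
* Duplicate matching is lattice-plus-energy based; enantiomorphic pairs and
  accidentally isoenergetic packings with identical reduced cells merge.
* No torsional degrees of freedom; the rigid-body approximation is baked
  into the coordinate model.
* Exchange of non-ordinal EVs (space group, Z') is out of scope here, as in
  the method's original description.
* Coulomb interactions are cut off in real space; strongly charged systems
  would need an Ewald-capable backend behind the same interface.
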