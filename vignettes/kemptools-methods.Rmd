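---
title: "Models and methods in kemptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kemptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

kemptools bundles the quantitative machinery used to study how directed
evolution improves a designed Kemp eliminase: kinetic decomposition of
isotope effects, a two-state empirical valence bond (EVB) free-energy
engine, conformational-substate classification, and one-dimensional
tunneling corrections. This vignette records the models, the defaults and
the reasoning behind the design choices, so that results produced with the
package can be interpreted — and criticized — precisely.

## Kinetics

Rates are turnover numbers (s⁻¹). `fit_michaelis_menten()` subtracts the
uncatalyzed background from every velocity before fitting
`v = kcat·S/(KM + S)` by Levenberg–Marquardt least squares on
log-parameterized `(kcat, KM)`, which enforces positivity without
constraints; start values come from a double-reciprocal linearization.
Fewer than five distinct substrate concentrations are refused — with four
or fewer points a two-parameter saturation fit is too poorly determined to
report standard errors honestly. If all velocities fall at or below
background, the fit is refused rather than returned as a degenerate zero.

`fit_arrhenius()` is ordinary least squares of `ln k` on `1/T` (the
conventional Arrhenius plot), with `Ea = −slope·R`, `ln A = intercept`, and
`R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹` fixed package-wide so every energy in the
package is in kcal/mol. Weighted regression is available but not the
default: replicate-level variance estimates are rarely stable enough at
three replicates to justify them. The KIE decomposition reports, at a
caller-chosen temperature defaulting to 303 K (the temperature of the
saturation-kinetics constants),

* `ΔEa = Ea(D) − Ea(H)`,
* `A_H/A_D = exp(lnA_H − lnA_D)`,
* `KIE = (A_H/A_D)·exp(ΔEa/RT)`,

the last identity holding exactly by construction. Standard errors are
first-order (delta-method) propagations using the full per-isotope fit
covariance, including the strongly negative `cov(Ea, lnA)` of an Arrhenius
fit; the test suite checks them against a 1000-resample parametric
bootstrap. Reconstructing the published table's KIE column from its printed
(rounded) `ΔEa` and `A_H/A_D` values reproduces the printed KIEs to within
about 7.5%, which is the expected amplification of input rounding through
the exponential — this, not a fitting claim, is what the consistency checks
in the acceptance battery assert.

## The EVB engine

The engine implements a textbook two-state EVB: each diabatic state is a
classical force field (Morse bond for the forming/breaking X–H bond,
harmonic bonds and angles for spectator coordinates, Lennard-Jones plus
Coulomb with state-specific charges, Coulomb constant 332.06
kcal Å mol⁻¹ e⁻²), the second state carries a constant gas-phase shift α,
and the ground state is the lower eigenvalue of the 2×2 Hamiltonian with
off-diagonal coupling H₁₂. The coupling is constant by default; a
distance-dependent `A·exp(−μr)` form is available. A constant H₁₂ is the
simplest form that the two-target calibration (barrier and reaction free
energy) determines uniquely together with α.

Dynamics run on the mapping potential `Em = (1−λ)ε₁ + λε₂′` with a leapfrog
integrator, Berendsen thermostat (coupling time 100 fs by default), and
SHAKE (absolute tolerance 10⁻⁸ Å, 500 iteration cap) constraining water
geometry only — the transferring hydrogen is never constrained, and the
system constructor refuses constraint lists that touch it. Units are
kcal/mol, Å, fs, amu; the droplet boundary is a half-harmonic radial wall.
All randomness (initial Maxwell–Boltzmann velocities, water placement)
flows through R's RNG, so a `set.seed()` call makes trajectories
bit-reproducible.

The free-energy machinery follows the standard FEP/umbrella-sampling
construction: Zwanzig exponential averages between adjacent λ frames
(forward-only by default; bidirectional averaging available — which of the
two a reference implementation uses is rarely stated, and forward-only is
the more conservative default), then per-frame gap histograms reweighted by
`exp(−β(Eg − Em))` and offset by `ΔG(λ)`, combined across frames with
count weights. Default gap bins are 2 kcal/mol wide with a 10-sample
minimum count; the transition-state bin is the maximum of Δg between the
two basin minima, and a profile with no interior maximum is flagged rather
than silently reported. On exhaustively enumerable two-parabola systems the
profile reproduces the Marcus closed forms `ΔG‡ = λr/4` and
`(λr+ΔG0)²/4λr` to better than 0.1 kcal/mol at 0.25 kcal/mol bins, which
is how the test suite validates the whole chain.

### The toy solution reference and its calibration

The packaged reference system (`gen_toy_evb_system()`) is a deliberately
minimal stand-in for the aqueous background reaction: a united-atom C–H
donor, a carboxylate-like acceptor modeling a propionate base, and ~40
flexible-charge TIP3P-like waters in an 8 Å droplet with a 10 kcal/mol/Å²
wall. State 1 Morse-bonds the hydrogen to carbon with carboxylate charges;
state 2 Morse-bonds it to the acceptor oxygen with a carbanion-like charge
pattern. Weak (1 kcal/mol/Å²) position restraints on the solute heavy atoms
and a donor–acceptor distance restraint play the role that reacting-atom
restraints play in a solution reference simulation: they stop the triad
from drifting and reorienting, which would otherwise dominate run-to-run
variance. This system exercises the EVB/FEP/US machinery faithfully;
force-field realism (a full OPLS-AA/AMBER treatment, polarizable boundary
solvent, long-range electrostatics beyond a plain cutoff) is explicitly out
of scope, so no packaged system claims to reproduce enzyme-variant
barriers.

Calibration exploits a structural property of the mapping Hamiltonian: the
forces `∇Em` contain neither H₁₂ (which never enters Em) nor α (which
enters only as a per-frame constant). Trajectories are therefore *exactly*
independent of both parameters, and stored samples can be re-evaluated
under any candidate `(H₁₂, α)` without importance-sampling error.
`calibrate_reference()` runs a few independent mapping series (default 3,
mirroring the practice of running replicate EVB trajectories), pools them,
and solves the two-target problem — activation free energy 21.2 kcal/mol
for the aqueous Kemp elimination, and a reaction free energy that is a
required configuration input — by Nelder–Mead on the re-evaluated profile.
Because the solve is exact given the samples, calibration converges in one
outer iteration, and restarting from a converged coupling terminates
immediately; additional outer iterations only occur when the initial
parameters put the profile in a degenerate region (no barrier found). The
parameters so obtained carry a sampling uncertainty of order 1–2 kcal/mol
between independent calibrations at the default desk-scale sampling; the
*profile* recomputed from the calibration data meets the targets to the
stated tolerance by construction, which is precisely what an EVB
calibration asserts.

The reaction free-energy target has no published value for this reference;
the package default of +5 kcal/mol encodes a mildly endothermic proton
transfer, consistent with a late, intermediate-like transition state for a
reaction whose barrier (21.2 kcal/mol) is rate-limited by C–H cleavage. It
is an explicit, documented input: users calibrating against their own
reference should set it.

Desk-scale problem sizes were chosen once as the package's defaults: 51
mapping frames of 4000 × 1 fs steps (samples every 5 steps, first 20%
discarded), three pooled trajectories, ~120 atoms. These are scaled-down
analogs of production EVB protocols (which use 100 ps frames on
protein-sized droplets) sized so that a full calibration completes in
minutes while the statistical checks in the test suite still pass.

## Conformational substates

Dihedrals use the right-handed IUPAC sign convention in (−180°, 180°]
(note that some structural packages report the opposite sign — the tests
pin the convention against an independent geometric construction).
Substate classification assigns each frame to the library state nearest by
the *maximum* circular distance over the library's dihedrals, within a
per-state tolerance; everything else falls into the unassigned/disordered
state D. The shipped library encodes editable estimates of the three
active-site tryptophan rotamer configurations (A: designed rotamer; B: χ₂
rotated by roughly 100°; C: indole flipped so its NH can hydrogen-bond the
catalytic glutamate); the published distributions are graphical, so these
centers are documented estimates, every assignment records the library
used, and population claims should cite it. Exact distance ties break to
the lexicographically smaller label; under the library validity rule
(centers separated by more than the summed tolerances on at least one
dihedral) a tie can only be label-determining when the tied states have
unequal tolerances. Populations carry Goodman simultaneous 95% multinomial
intervals.

The replica-exchange ladder is geometric, `λᵢ = λ_min^{i/(n−1)}`, so its
logarithms are equally spaced; with six replicas and λ_min = 0.667 it
reproduces the published factors 1.000, 0.922, 0.850, 0.784, 0.723, 0.667
at three-decimal display. Exchange bookkeeping is implemented as analysis
of attempt logs — running replica-exchange MD itself is the job of an
external engine and out of scope. Daura clustering computes all pairwise
Kabsch-superposed RMSDs and greedily extracts the frame with the most
neighbors within the cutoff (0.5 Å in the published protocol), ties going
to the lowest frame index; the suite checks it against an independent
brute-force implementation.

## Tunneling

The published tunneling analysis uses variational transition-state theory
with multidimensional tunneling on a quantum-chemical surface; that is out
of scope here, and this module is documented as a one-dimensional stand-in
that never claims to reproduce those coefficients or the corrected KIE
reported from them. It provides the Wigner leading-order correction
`κ = 1 + u²/24`, `u = hcν̃/k_BT = 1.43877·ν̃/T`, and the thermally averaged
transmission through an asymmetric Eckart barrier,
`κ(T) = e^{V₁/k_BT}∫P(E)e^{−E/k_BT}dE/k_BT`, with the closed-form `P(E)`
evaluated in log-space to avoid overflow, energy zero at the reactant
asymptote, an integration ceiling of `V₁ + 40k_BT`, and adaptive quadrature
to a relative tolerance of 10⁻⁶ (checked against dense trapezoid
integration). Deuterium parameters derive from hydrogen's by
`ν̃_D = ν̃_H/√(m_D/m_H)`, the pure H-transfer-mode limit, so κ_H ≥ κ_D and
tunneling always inflates the KIE: `KIE_corr = (κ_H/κ_D)·KIE_classical`.

## Synthetic data: what it does and does not emulate

Generators are pure functions of seed + configuration. Noise models are
stated rather than fitted: multiplicative lognormal on rates (the standard
assay-error model), von Mises on angles, isotropic Gaussian on coordinates.
Rate tables default to eight temperatures spanning 283–323 K, ten substrate
concentrations in 0.01–1.1 mM, three replicates, and planted Arrhenius
parameters of the same magnitude as the earliest published variant — i.e.
the assay design of a real temperature-series kinetics experiment. What the
generators do *not* emulate: correlated instrument drift, substrate
depletion within a trace, conformational kinetics beyond a first-order
Markov chain between rotamer states, and real force-field energetics.
Passing tests therefore demonstrate correctness of the estimators and
algorithms under their stated assumptions, not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

* Gas constant / Boltzmann constant 1.9872×10⁻³ kcal mol⁻¹ K⁻¹ everywhere;
  Coulomb constant 332.06 kcal Å mol⁻¹ e⁻²; `hc/k_B` = 1.43877 cm K.
* Atom pairs closer than 0.1 Å are refused as overlapping; mapping
  energies beyond 10⁶ kcal/mol abort with diagnostics.
* Energy conservation holds to ~10⁻³ kcal/mol/ps at 0.5 fs steps only when
  the nonbonded cutoff exceeds the droplet diameter (a truncated cutoff is
  non-conservative by construction); the default 10 Å cutoff with the
  reacting atoms exempted mirrors the production protocol instead.
* Michaelis–Menten fits refuse < 5 distinct concentrations; Arrhenius fits
  refuse < 3 temperatures or any non-positive rate.
* The altloc policy for PDB input is highest occupancy, ties to 'A';
  residue numbering is preserved as deposited.
* Profiles are referenced to the reactant-side minimum; reactant and
  product are identified by the sign of the gap coordinate.

## Known limitations

The EVB droplet is a toy: no protein, simplified charges, plain-cutoff
electrostatics. Calibrated `(H₁₂, α)` values are therefore meaningful only
within this model, and their run-to-run spread (1–2 kcal/mol at default
sampling) should be treated as the parameter uncertainty. The tunneling
module is one-dimensional. The substate library centers are estimates to
be refined against the user's own simulations. None of the enzyme-variant
observables (catalytic barriers of the evolved variants, active-site
geometry averages, pKa shifts) are desk-reproducible with this package
alone, and the package deliberately makes no numeric claims about them.
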