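# kemptools

Analysis toolkit for laboratory-evolved Kemp eliminases — enzymes designed to
catalyze the base-mediated ring opening of 5-nitrobenzisoxazole via
rate-limiting C–H proton abstraction. The package is aimed at enzymologists
and simulators who want to reproduce, on their own data or on synthetic data
with known ground truth, the quantitative analyses that underpin studies of
how directed evolution reshapes a designed active site:

* **Kinetics** — Michaelis–Menten fits with background subtraction, Arrhenius
  fits of `ln k` vs `1/T` (`ln k = ln A − Ea/RT`, `R = 1.9872×10⁻³`
  kcal mol⁻¹ K⁻¹), and decomposition of H/D kinetic isotope effects into an
  activation-energy difference and a pre-exponential ratio,
  `KIE(T) = (A_H/A_D)·exp[(Ea(D)−Ea(H))/RT]`, with delta-method error
  propagation from the full fit covariances.
* **EVB engine** — a two-state empirical valence bond model for a toy
  donor–H–acceptor triad in a water droplet: diabatic energies
  `ε₁, ε₂′ = ε₂ + α` with analytic forces, ground state
  `Eg = ½(ε₁+ε₂′) − ½√((ε₁−ε₂′)² + 4H₁₂²)`, leapfrog dynamics with a
  Berendsen thermostat and SHAKE-constrained waters, mapping-potential
  free-energy perturbation over `Em = (1−λ)ε₁ + λε₂′` (51 frames by
  default), umbrella-sampling assembly of the free energy along the energy
  gap `X = ε₁ − ε₂′`, and calibration of `(H₁₂, α)` against a reference
  activation free energy (21.2 kcal/mol for the aqueous Kemp elimination).
* **Substates** — χ-dihedral computation, classification of active-site
  rotamer substates (configurations A/B/C with an unassigned state D),
  geometric Hamiltonian-replica-exchange scaling ladders
  (`λᵢ = λ_min^{i/(n−1)}`), hot-region selection, Daura RMSD clustering, and
  active-site geometry metrics.
* **Tunneling** — 1D Eckart and Wigner transmission coefficients κ(T) for H
  and D and tunneling-corrected KIEs.
* **Synthetic data** — seeded generators for every input (rate tables, toy
  EVB droplets, analytic Marcus surrogates, rotamer trajectories, cluster
  fixtures) with the planted truth attached.

## Worked example

Decompose the KIE of an Arrhenius data set with planted parameters:

```r
library(kemptools)
tab <- gen_rate_data(seed = 1, noise_sdlog = 0)     # planted Ea/lnA per isotope
temps <- unique(tab$temp_K)
kcat <- function(iso) vapply(temps, function(T) {
  d <- subset(tab, variant == "R1" & isotope == iso &
                   temp_K == T & replicate == 1)
  fit_michaelis_menten(data.frame(conc_mM = d$conc_mM,
                                  rate = d$rate_per_s))$kcat
}, 0)
fH <- fit_arrhenius(temps, kcat("H"))
fD <- fit_arrhenius(temps, kcat("D"))
kie_decomposition(fH, fD, temp_K = 303)
#> KIE at 303 K: 4.67 (7.3e-15)
#>   Ea(D)-Ea(H) = 4.3 (2.3e-14) kcal/mol
#>   A_H/A_D     = 0.0037 (1.4e-16)
```

The KIE of 4.67 is exactly `exp(14.0 − 19.6)·exp(4.3/(R·303))`, the closed
form of the planted parameters; with noiseless input the propagated standard
errors collapse to numerical noise.

Calibrate the EVB coupling on the packaged toy solution reference and read
off the activation free energy:

```r
set.seed(2024)
sys <- gen_toy_evb_system(seed = 1)          # triad + ~40 waters, 8 A droplet
sys <- minimize_system(sys, 0, 400)
eqp <- equilibration_protocol(sys)           # staged heating to 300 K
cal <- calibrate_reference(eqp$system, target_dG_barrier = 21.2,
                           target_dG_reaction = 5)
cal$profile
#> EVB free-energy profile (137 bins of 2 kcal/mol)
#>   dG_barrier  = 21.20 kcal/mol
#>   dG_reaction = 5.00 kcal/mol
```

The six-replica scaling ladder used for replica-exchange sampling:

```r
hrex_ladder(6, 0.667)
#> HREX scaling ladder: 1.000, 0.922, 0.850, 0.784, 0.723, 0.667
```

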