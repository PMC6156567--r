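#' Synthetic Michaelis-Menten / Arrhenius rate tables
#'
#' Generates replicate rate measurements for H and D substrate isotopologues
#' over a temperature series, from planted Arrhenius parameters (kcat per
#' temperature) and Michaelis constants, with multiplicative lognormal noise
#' (the standard model for kinetic assay error). A first-order background
#' (buffer) series is included. The planted truth is attached as an
#' attribute so downstream fits can be scored.
#'
#' Defaults emulate a typical assay design for this system: eight
#' temperatures spanning 283-323 K, ten substrate concentrations between
#' 0.01 and 1.1 mM, three replicates, and Arrhenius parameters of the same
#' magnitude as the R1 variant (Ea_H = 10.8, lnA_H = 14.0, Ea_D = 15.1,
#' lnA_D = 19.6).
#'
#' @param seed integer RNG seed; recorded in the output
#' @param temps_K assay temperatures (K)
#' @param concs_mM substrate concentrations (mM)
#' @param n_rep replicates per condition
#' @param noise_sdlog lognormal noise sdlog (0 = noiseless)
#' @param params list of planted parameters: per-isotope `Ea`, `lnA`
#'   (kcat Arrhenius), `KM_mM`; `bg` with `Ea`, `lnA` for the background
#' @param variant variant label written into the table
#' @return data.frame with columns `variant`, `isotope`, `conc_mM`,
#'   `temp_K`, `rate_per_s`, `replicate` plus background rows
#'   (`variant = "B"`); attributes `truth` and `seed`
#' @export
gen_rate_data <- function(seed = 1,
                          temps_K = c(283, 293, 298, 303, 308, 313, 318, 323),
                          concs_mM = seq(0.01, 1.1, length.out = 10),
                          n_rep = 3, noise_sdlog = 0.02,
                          params = list(
                            H = list(Ea = 10.8, lnA = 14.0, KM_mM = 0.96),
                            D = list(Ea = 15.1, lnA = 19.6, KM_mM = 0.96),
                            bg = list(Ea = 14.5, lnA = 13.7)),
                          variant = "R1") {
  if (any(temps_K <= 0)) stop("temperatures must be positive (Kelvin)")
  set.seed(seed)
  rows <- list()
  for (iso in c("H", "D")) {
    p <- params[[iso]]
    for (T in temps_K) {
      kcat <- exp(p$lnA - p$Ea / (.R_GAS * T))
      for (s in concs_mM) {
        v <- kcat * s / (p$KM_mM + s)
        noise <- if (noise_sdlog > 0)
          exp(rnorm(n_rep, -noise_sdlog^2 / 2, noise_sdlog)) else rep(1, n_rep)
        rows[[length(rows) + 1]] <- data.frame(
          variant = variant, isotope = iso, conc_mM = s, temp_K = T,
          rate_per_s = v * noise, replicate = seq_len(n_rep))
      }
    }
  }
  ## first-order background: rate per substrate concentration, H only noise-free
  bg <- params$bg
  for (T in temps_K) {
    kbg <- exp(bg$lnA - bg$Ea / (.R_GAS * T))
    rows[[length(rows) + 1]] <- data.frame(
      variant = "B", isotope = "H", conc_mM = concs_mM, temp_K = T,
      rate_per_s = kbg, replicate = 1L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- params
  attr(out, "seed") <- seed
  out
}

#' Toy donor-H-acceptor EVB droplet system
#'
#' Builds the minimal two-state proton-transfer system used throughout the
#' EVB engine: a united-atom C-H donor (carbanion precursor), a
#' carboxylate-like acceptor (C2 with two oxygens, modeling a propionate
#' base), and flexible 3-site waters packed on a jittered grid inside a
#' droplet with a harmonic radial wall. State 1 has the hydrogen
#' Morse-bonded to the donor carbon and carboxylate charges on the base;
#' state 2 has the hydrogen Morse-bonded to the acceptor oxygen with a
#' carbanion charge pattern. Water O-H and H-H distances are SHAKE
#' constraints; the transferring hydrogen is never constrained. A weak
#' harmonic restraint holds the donor-acceptor distance near reacting
#' range, playing the role of the reacting-atom restraint of a solution
#' reference simulation.
#'
#' @param seed RNG seed for water placement
#' @param droplet_radius droplet radius (Angstrom), >= 6
#' @param n_waters water count; `NULL` packs the droplet at roughly
#'   0.0334/3 molecules per cubic Angstrom capped at 40
#' @param h12,alpha initial coupling (calibration adjusts these)
#' @param wall_k radial wall force constant (kcal/mol/A^2)
#' @param restraint_k force constant (kcal/mol/A^2) of the reacting-atom
#'   restraints: a donor-acceptor distance restraint plus weak position
#'   restraints on the solute heavy atoms, which keep the triad from
#'   drifting and reorienting in the droplet (the role the reacting-atom
#'   restraint plays in a solution reference simulation)
#' @return an [evb_system()]; attribute `seed` records the seed
#' @export
gen_toy_evb_system <- function(seed = 1, droplet_radius = 8, n_waters = NULL,
                               h12 = 2, alpha = 0, wall_k = 10,
                               restraint_k = 1) {
  if (droplet_radius < 6) stop("droplet radius must be >= 6 A")
  set.seed(seed)

  ## solute: C (donor), H (transferring), C2, O1 (acceptor), O2
  solute_xyz <- rbind(
    C  = c(-1.45, 0.00, 0.00),
    H  = c(-0.36, 0.00, 0.00),
    C2 = c( 2.55, 0.00, 0.00),
    O1 = c( 1.45, 0.55, 0.00),
    O2 = c( 3.05, -0.90, 0.60))
  atom <- c("C", "H", "C2", "O1", "O2")
  mass <- c(12.011, 1.008, 12.011, 15.999, 15.999)
  lj_sigma <- c(3.40, 0.40, 3.40, 2.96, 2.96)
  lj_eps <- c(0.10, 0.02, 0.10, 0.21, 0.21)
  q1 <- c(-0.25, 0.25, 0.44, -0.72, -0.72)   # reactant: C-H + carboxylate
  q2 <- c(-0.90, 0.37, 0.55, -0.51, -0.51)   # product: carbanion + O1-H acid

  morse1 <- cbind(1, 2, 98, 1.8, 1.09)       # C-H
  morse2 <- cbind(4, 2, 102, 2.2, 0.96)      # O1-H
  bonds <- rbind(c(3, 4, 320, 1.25),         # C2-O1
                 c(3, 5, 320, 1.25))         # C2-O2
  angles <- rbind(c(4, 3, 5, 80, 126))       # O1-C2-O2
  ## reacting triad excluded from nonbonded in both states (bonded terms
  ## and the distance restraint describe their interaction)
  triad_excl <- rbind(c(1, 2), c(2, 4), c(1, 4), c(2, 3), c(2, 5))
  excl_bonded <- rbind(c(3, 4), c(3, 5), c(4, 5))

  ## waters on a jittered grid inside the droplet, clear of the solute
  xyz <- solute_xyz
  wat_types <- character(0)
  spacing <- 3.1
  g <- seq(-droplet_radius, droplet_radius, by = spacing)
  sites <- as.matrix(expand.grid(x = g, y = g, z = g))
  ok <- sqrt(rowSums(sites^2)) < droplet_radius - 1.2
  sites <- sites[ok, , drop = FALSE]
  mind <- apply(sites, 1, function(p)
    sqrt(min(rowSums((solute_xyz - matrix(p, nrow(solute_xyz), 3,
                                          byrow = TRUE))^2))))
  sites <- sites[mind > 2.6, , drop = FALSE]
  cap <- if (is.null(n_waters)) min(nrow(sites), 40L) else n_waters
  if (cap > nrow(sites))
    stop("cannot place ", cap, " waters in a ", droplet_radius, " A droplet")
  pick <- sites[sample(nrow(sites), cap), , drop = FALSE] +
    matrix(rnorm(3 * cap, 0, 0.15), cap, 3)

  rOH <- 0.9572; aHOH <- 104.52 * pi / 180
  constraints <- NULL
  wat_bonds <- NULL; wat_angles <- NULL; wat_excl <- NULL
  for (w in seq_len(cap)) {
    o <- nrow(xyz) + 1
    ## random orientation
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    h1 <- pick[w, ] + rOH * u
    h2 <- pick[w, ] + rOH * (cos(aHOH) * u + sin(aHOH) * v)
    xyz <- rbind(xyz, OW = pick[w, ], HW1 = h1, HW2 = h2)
    atom <- c(atom, "OW", "HW1", "HW2")
    mass <- c(mass, 15.999, 1.008, 1.008)
    lj_sigma <- c(lj_sigma, 3.1506, 0.4, 0.4)
    lj_eps <- c(lj_eps, 0.1521, 0, 0)
    q1 <- c(q1, -0.834, 0.417, 0.417)
    q2 <- c(q2, -0.834, 0.417, 0.417)
    wat_bonds <- rbind(wat_bonds, c(o, o + 1, 450, rOH), c(o, o + 2, 450, rOH))
    wat_angles <- rbind(wat_angles, c(o + 1, o, o + 2, 55, 104.52))
    wat_excl <- rbind(wat_excl, c(o, o + 1), c(o, o + 2), c(o + 1, o + 2))
    dHH <- 2 * rOH * sin(aHOH / 2)
    constraints <- rbind(constraints, c(o, o + 1, rOH), c(o, o + 2, rOH),
                         c(o + 1, o + 2, dHH))
  }

  excl <- rbind(triad_excl, excl_bonded, wat_excl)
  st1 <- list(charges = q1, morse = morse1,
              bonds = rbind(bonds, wat_bonds),
              angles = rbind(angles, wat_angles), exclusions = excl)
  st2 <- list(charges = q2, morse = morse2,
              bonds = rbind(bonds, wat_bonds),
              angles = rbind(angles, wat_angles), exclusions = excl)

  sys <- evb_system(
    xyz = xyz, mass = mass, atom = atom,
    lj_sigma = lj_sigma, lj_eps = lj_eps,
    state1 = st1, state2 = st2,
    coupling = list(h12 = h12, alpha = alpha),
    droplet_radius = droplet_radius, wall_k = wall_k,
    cutoff = 10, reacting = c(1L, 2L, 4L),
    posres = cbind(c(1, 3, 4, 5), restraint_k,
                   solute_xyz[c(1, 3, 4, 5), , drop = FALSE]),
    distres = rbind(c(1, 4, restraint_k, 2.6)),
    constraints = constraints,
    solute = 1:5)
  ## make sure the starting configuration is finite
  e <- diabatic_energies(sys)
  stopifnot(is.finite(e$e1), is.finite(e$e2p))
  attr(sys, "seed") <- seed
  sys
}

#' Exhaustively sampled two-parabola (Marcus) mapping frames
#'
#' Analytic surrogate for the EVB engine: shifted harmonic diabats
#' `e1 = k x^2 / 2`, `e2 = k (x - d)^2 / 2 + dG0` on a dense grid, with each
#' mapping frame carrying Boltzmann weights under its mapping potential
#' instead of MD samples. The reorganization energy is `lambda_r = k d^2 / 2`
#' and the Marcus barrier `(lambda_r + dG0)^2 / (4 lambda_r)`, which
#' [umbrella_profile()] must reproduce.
#'
#' @param lambda_r reorganization energy (kcal/mol)
#' @param dG0 reaction free energy (kcal/mol)
#' @param h12 constant coupling applied to the ground state
#' @param temp_K temperature (K)
#' @param n_lambda number of mapping frames
#' @param n_grid grid points along the 1D coordinate
#' @return list of [mapping_frame()] objects; attribute `truth` holds the
#'   analytic barrier and reaction free energies
#' @export
gen_marcus_frames <- function(lambda_r = 40, dG0 = 0, h12 = 0, temp_K = 300,
                              n_lambda = 51, n_grid = 4001) {
  stopifnot(lambda_r > 0)
  k <- 2; d <- sqrt(2 * lambda_r / k)
  beta <- 1 / (.R_GAS * temp_K)
  span <- 3 / sqrt(beta * k / 2)      # a few thermal widths past both minima
  x <- seq(-span, d + span, length.out = n_grid)
  e1 <- 0.5 * k * x^2
  e2 <- 0.5 * k * (x - d)^2 + dG0
  frames <- lapply(lambda_schedule(n_lambda), function(lam) {
    em <- (1 - lam) * e1 + lam * e2
    w <- exp(-beta * (em - min(em)))
    mapping_frame(lam, e1, e2, h12, weight = w)
  })
  attr(frames, "truth") <- list(
    dG_barrier = (lambda_r + dG0)^2 / (4 * lambda_r) -
      if (h12 > 0) h12 else 0,   # leading-order coupling correction
    dG_reaction = dG0, lambda_r = lambda_r)
  frames
}

#' Harmonic-toggle mapping frames with a known free energy
#'
#' Samples a 1D harmonic oscillator whose force constant is interpolated
#' between `k1` and `k2` across the mapping schedule; the exact free-energy
#' difference is `kB T ln(k2 / k1) / 2`, the closed-form Gaussian result
#' used to validate [fep_free_energy()].
#'
#' @param k1,k2 endpoint force constants (kcal/mol/A^2)
#' @param temp_K temperature (K)
#' @param n_lambda mapping frames
#' @param n_samp samples per frame
#' @param seed RNG seed
#' @return list of [mapping_frame()] objects; attribute `truth` holds the
#'   analytic `dG`
#' @export
gen_harmonic_toggle_frames <- function(k1 = 1, k2 = 4, temp_K = 300,
                                       n_lambda = 21, n_samp = 4000,
                                       seed = 1) {
  set.seed(seed)
  beta <- 1 / (.R_GAS * temp_K)
  frames <- lapply(lambda_schedule(n_lambda), function(lam) {
    keff <- (1 - lam) * k1 + lam * k2
    x <- rnorm(n_samp, 0, sqrt(1 / (beta * keff)))
    mapping_frame(lam, 0.5 * k1 * x^2, 0.5 * k2 * x^2, 0)
  })
  attr(frames, "truth") <- list(dG = 0.5 * .R_GAS * temp_K * log(k2 / k1))
  frames
}

#' Synthetic rotamer dihedral trajectories with planted substates
#'
#' Per-frame states follow a Markov chain with stationary distribution
#' `fractions` and configurable persistence; dihedrals are drawn von Mises
#' around the library's state centers. Ground-truth labels are returned for
#' scoring classification.
#'
#' @param seed RNG seed
#' @param n_frames trajectory length
#' @param fractions named stationary state fractions (must sum to 1; names
#'   must be states of `library`)
#' @param kappa von Mises concentration
#' @param persistence probability of staying in the current state per step
#' @param library a [substate_library()]
#' @return list: `series` (data.frame of dihedral angles), `labels` (true
#'   states), `seed`
#' @export
gen_rotamer_traj <- function(seed = 1, n_frames = 5000,
                             fractions = c(A = 0.7, B = 0.2, C = 0.1),
                             kappa = 20, persistence = 0,
                             library = substate_library()) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  unknown <- setdiff(names(fractions), names(library$states))
  if (length(unknown)) stop("unknown state label(s): ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  snames <- names(fractions)
  k <- length(snames)
  ## Markov chain: P = p I + (1-p) 1 pi^T keeps pi stationary
  labels <- character(n_frames)
  labels[1] <- sample(snames, 1, prob = fractions)
  for (i in seq_len(n_frames - 1)) {
    labels[i + 1] <- if (runif(1) < persistence) labels[i] else
      sample(snames, 1, prob = fractions)
  }
  series <- sapply(library$dihedrals, function(dn) {
    centers <- vapply(labels, function(l) library$states[[l]]$centers[[dn]], 0)
    (centers + rvonmises_deg(n_frames, kappa)) %% 360
  })
  series <- as.data.frame(series)
  ## map back to (-180, 180]
  series[] <- lapply(series, function(a) ifelse(a > 180, a - 360, a))
  list(series = series, labels = labels, seed = seed)
}

#' von Mises deviates (degrees, zero mean)
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` gives uniform angles.
#' Used by the rotamer-trajectory generator.
#'
#' @param n number of deviates
#' @param kappa concentration parameter (>= 0)
#' @return angles in degrees in (-180, 180]
#' @export
rvonmises_deg <- function(n, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, -180, 180))
  if (kappa > 1e6) return(rep(0, n))   # effectively a point mass
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        out[i] <- sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  out * 180 / pi
}

#' Synthetic coordinate frames with planted cluster structure
#'
#' Builds `n_blobs` deformed copies of a rigid template (per-blob internal
#' deformation of RMS magnitude `separation`, so inter-blob RMSD survives
#' superposition) and jitters members isotropically within each blob.
#'
#' @param seed RNG seed
#' @param n_blobs number of clusters (>= 1)
#' @param frames_per_blob members per cluster
#' @param n_atoms atoms per frame
#' @param separation RMS internal deformation between blob templates
#'   (Angstrom)
#' @param spread intra-blob Gaussian jitter sd (Angstrom)
#' @return list: `frames` (list of coordinate matrices), `labels` (true
#'   blob index per frame), `seed`
#' @export
gen_cluster_fixture <- function(seed = 1, n_blobs = 2, frames_per_blob = 10,
                                n_atoms = 12, separation = 5, spread = 0.1) {
  stopifnot(n_blobs >= 1)
  set.seed(seed)
  template <- matrix(rnorm(n_atoms * 3, 0, 3), n_atoms, 3)
  blobs <- lapply(seq_len(n_blobs), function(b) {
    if (b == 1) template else
      template + matrix(rnorm(n_atoms * 3, 0, separation / sqrt(3)),
                        n_atoms, 3)
  })
  frames <- list(); labels <- integer(0)
  for (b in seq_len(n_blobs)) for (f in seq_len(frames_per_blob)) {
    frames[[length(frames) + 1]] <-
      blobs[[b]] + matrix(rnorm(n_atoms * 3, 0, spread / sqrt(3)), n_atoms, 3)
    labels <- c(labels, b)
  }
  list(frames = frames, labels = labels, seed = seed)
}
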