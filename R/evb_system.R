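#' Construct a two-state EVB system
#'
#' Bundles coordinates, masses, per-state force-field terms, the off-diagonal
#' coupling, droplet boundary and restraints into an `evb_system`. Energies
#' are kcal/mol, distances Angstrom, masses amu, charges elementary.
#'
#' Each state is a list with `charges` (length-n vector, must sum to an
#' integer), `morse` (matrix with columns i, j, D, beta, r0 for the
#' forming/breaking bond), `bonds` (i, j, k, r0; `E = k (r - r0)^2`),
#' `angles` (i, j, k, ktheta, theta0_deg; j is the vertex) and `exclusions`
#' (pairs excluded from nonbonded interactions in that state).
#'
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param mass atomic masses (amu)
#' @param atom atom name labels
#' @param lj_sigma,lj_eps per-atom Lennard-Jones parameters (Angstrom,
#'   kcal/mol); Lorentz-Berthelot combining
#' @param state1,state2 per-state term lists, see Details
#' @param coupling list: `h12` (constant coupling, kcal/mol) or `A`, `mu`
#'   with `pair = c(i, j)` for the exponential form `A exp(-mu r_ij)`;
#'   `alpha` is the gas-phase shift added to state 2
#' @param droplet_radius radius (Angstrom) of the harmonic radial wall
#' @param wall_k wall force constant (kcal/mol/A^2)
#' @param cutoff nonbonded cutoff (Angstrom); pairs involving `reacting`
#'   atoms are never cut off
#' @param reacting indices of the reacting atoms
#' @param posres position restraints (matrix: atom, k, x, y, z) or NULL
#' @param distres distance restraints (matrix: i, j, k, r0) or NULL
#' @param constraints SHAKE constraints (matrix: i, j, distance); must never
#'   include the transferring hydrogen
#' @param solute indices of solute atoms (used for RMSD traces and
#'   equilibration restraints); default = all non-water atoms
#' @return object of class `evb_system`
#' @export
evb_system <- function(xyz, mass, atom = NULL, lj_sigma, lj_eps,
                       state1, state2, coupling,
                       droplet_radius = Inf, wall_k = 0,
                       cutoff = 10, reacting = integer(),
                       posres = NULL, distres = NULL, constraints = NULL,
                       solute = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(mass) == n,
            length(lj_sigma) == n, length(lj_eps) == n)
  if (is.finite(droplet_radius) && cutoff > 2 * droplet_radius)
    stop("nonbonded cutoff exceeds droplet diameter")
  for (st in list(state1, state2)) {
    stopifnot(length(st$charges) == n)
    tot <- sum(st$charges)
    if (abs(tot - round(tot)) > 1e-9)
      stop("state charges must sum to an integer (got ", tot, ")")
    m <- st$morse
    if (!is.null(m) && nrow(m) > 0 &&
        (any(m[, 3] <= 0) || any(m[, 4] <= 0) || any(m[, 5] <= 0)))
      stop("Morse parameters D, beta, r0 must all be positive")
  }
  if (!is.null(coupling$h12) && coupling$h12 < 0)
    stop("H12 must be >= 0")
  tH <- which(mass < 2.5)  # hydrogens
  if (!is.null(constraints) && nrow(constraints) > 0 && length(reacting)) {
    rH <- intersect(reacting, tH)
    if (length(rH) && any(constraints[, 1] %in% rH | constraints[, 2] %in% rH))
      stop("the transferring hydrogen must not be SHAKE-constrained")
  }
  norm_state <- function(st) {
    st$morse <- .as_mat(st$morse, 5)
    st$bonds <- .as_mat(st$bonds, 4)
    st$angles <- .as_mat(st$angles, 5)
    st$exclusions <- .as_mat(st$exclusions, 2)
    st
  }
  structure(list(
    xyz = xyz, mass = as.numeric(mass),
    atom = if (is.null(atom)) rep("X", n) else atom,
    lj_sigma = as.numeric(lj_sigma), lj_eps = as.numeric(lj_eps),
    states = list(norm_state(state1), norm_state(state2)),
    coupling = coupling,
    droplet_radius = droplet_radius, wall_k = wall_k,
    cutoff = cutoff, reacting = as.integer(reacting),
    posres = .as_mat(posres, 5), distres = .as_mat(distres, 4),
    constraints = .as_mat(constraints, 3),
    solute = if (is.null(solute)) which(!grepl("^[OH]W", if (is.null(atom)) rep("X", n) else atom)) else solute
  ), class = "evb_system")
}

.as_mat <- function(m, ncols) {
  if (is.null(m) || length(m) == 0) return(matrix(numeric(), 0, ncols))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == ncols)
  unname(m)
}

#' @export
print.evb_system <- function(x, ...) {
  cat(sprintf("EVB system: %d atoms (%d solute, %d reacting), droplet %.1f A\n",
              nrow(x$xyz), length(x$solute), length(x$reacting),
              x$droplet_radius))
  cpl <- x$coupling
  if (!is.null(cpl$h12))
    cat(sprintf("  coupling: H12 = %.3f kcal/mol (constant), alpha = %.3f\n",
                cpl$h12, cpl$alpha))
  else
    cat(sprintf("  coupling: A = %.3f, mu = %.3f (exponential), alpha = %.3f\n",
                cpl$A, cpl$mu, cpl$alpha))
  invisible(x)
}

## flatten for the C++ kernel
.pack_system <- function(sys, coupling = sys$coupling) {
  list(mass = sys$mass, lj_sigma = sys$lj_sigma, lj_eps = sys$lj_eps,
       states = lapply(sys$states, function(st)
         list(charges = as.numeric(st$charges), morse = st$morse,
              bonds = st$bonds, angles = st$angles,
              exclusions = st$exclusions)),
       alpha = as.numeric(coupling$alpha %||% 0),
       cutoff = as.numeric(sys$cutoff),
       reacting = as.integer(sys$reacting),
       wall_radius = as.numeric(if (is.finite(sys$droplet_radius)) sys$droplet_radius else 1e9),
       wall_k = as.numeric(sys$wall_k),
       posres = sys$posres, distres = sys$distres,
       constraints = sys$constraints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the off-diagonal EVB coupling
#'
#' Constant couplings return `h12` unchanged; the exponential form returns
#' `A * exp(-mu * r)` at the current distance between the coupling pair.
#'
#' @param coupling coupling list from an [evb_system()]
#' @param xyz coordinates (needed for the exponential form)
#' @return H12 in kcal/mol
#' @export
coupling_h12 <- function(coupling, xyz = NULL) {
  if (!is.null(coupling$h12)) return(coupling$h12)
  stopifnot(!is.null(xyz), !is.null(coupling$pair))
  r <- sqrt(sum((xyz[coupling$pair[1], ] - xyz[coupling$pair[2], ])^2))
  coupling$A * exp(-coupling$mu * r)
}

#' Diabatic energies and analytic forces of an EVB system
#'
#' Evaluates both valence-bond states at the given coordinates:
#' `e1` and `e2p = e2 + alpha` include Morse, harmonic bond/angle,
#' Lennard-Jones and Coulomb terms (state-specific charges and exclusions)
#' plus the state-independent droplet wall and restraints.
#'
#' @param system an [evb_system()]
#' @param xyz coordinates; defaults to the system's own
#' @return list with `e1`, `e2p` (kcal/mol), forces `f1`, `f2`
#'   (kcal/mol/A, n x 3) and the evaluated `h12`
#' @export
diabatic_energies <- function(system, xyz = system$xyz) {
  out <- .evb_eval_cpp(.pack_system(system), as.matrix(xyz))
  out$h12 <- coupling_h12(system$coupling, xyz)
  out
}

#' EVB ground-state energy from diabatic energies
#'
#' Lowest eigenvalue of the 2x2 valence-bond Hamiltonian:
#' `Eg = (e1 + e2p)/2 - sqrt((e1 - e2p)^2 + 4 h12^2)/2`, with normalized
#' ground-state mixing coefficients. Vectorized over samples.
#'
#' @param e1,e2p diabatic energies (kcal/mol); `e2p` includes the gas shift
#' @param h12 off-diagonal coupling (kcal/mol), `>= 0`
#' @return list with `eg` and mixing coefficients `c1`, `c2`
#'   (`c1^2 + c2^2 = 1`)
#' @export
ground_state <- function(e1, e2p, h12) {
  if (any(h12 < 0)) stop("H12 must be >= 0")
  d <- e1 - e2p
  disc <- sqrt(d^2 + 4 * h12^2)
  eg <- 0.5 * (e1 + e2p) - 0.5 * disc
  ## eigenvector for the lower root: (H11 - Eg) c1 + H12 c2 = 0
  c1 <- ifelse(h12 == 0, as.numeric(e1 <= e2p),
               h12 / sqrt(h12^2 + (e1 - eg)^2))
  c2 <- ifelse(h12 == 0, as.numeric(e1 > e2p),
               -(e1 - eg) / sqrt(h12^2 + (e1 - eg)^2))
  nrm <- sqrt(c1^2 + c2^2)
  list(eg = eg, c1 = c1 / nrm, c2 = c2 / nrm)
}
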