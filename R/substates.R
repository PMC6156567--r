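#' Signed dihedral angle from four atom positions
#'
#' Right-handed IUPAC convention, degrees in (-180, 180]. Vectorized over
#' frames: inputs may be single positions (length 3) or n x 3 matrices.
#'
#' @param p1,p2,p3,p4 positions of the four consecutive atoms
#' @return dihedral angle(s) in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as3 <- function(p) if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
  p1 <- as3(p1); p2 <- as3(p2); p3 <- as3(p3); p4 <- as3(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ## fold -180 to +180 so the range is (-180, 180]
  ifelse(ang <= -180, ang + 360, ang)
}

#' Dihedral time series from a coordinate trajectory
#'
#' @param traj list of n x 3 coordinate matrices (frames)
#' @param spec list with `name` and `atoms` (four atom indices into the
#'   frame's rows); a data.frame row with columns `a1..a4` also works
#' @return numeric vector of dihedrals (degrees), one per frame
#' @export
compute_dihedral <- function(traj, spec) {
  idx <- if (!is.null(spec$atoms)) spec$atoms else
    c(spec$a1, spec$a2, spec$a3, spec$a4)
  stopifnot(length(idx) == 4, length(unique(idx)) == 4)
  vapply(traj, function(fr) {
    fr <- as.matrix(fr)
    if (any(idx > nrow(fr)))
      stop("atom index ", max(idx), " missing from frame (",
           nrow(fr), " atoms)")
    dihedral_angle(fr[idx[1], ], fr[idx[2], ], fr[idx[3], ], fr[idx[4], ])
  }, 0)
}

#' Circular distance between angles
#'
#' Shortest arc in degrees, in `[0, 180]`; invariant to adding multiples
#' of 360 to either argument.
#'
#' @param a,b angles in degrees
#' @return circular distances
#' @export
circular_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Define a library of conformational substates
#'
#' Each state is a set of dihedral centers (degrees) with a circular
#' tolerance; frames outside every state's tolerance get the `unassigned`
#' label (the "intermediate/disordered" state). The default library encodes
#' editable estimates of the Trp50 rotamer substates of the KE07 active
#' site: A the designed rotamer, B the indole rotated by roughly 100
#' degrees about chi2, C the flipped indole that hydrogen bonds the
#' catalytic glutamate; D collects intermediate frames.
#'
#' @param states named list; each element a list with `centers` (named
#'   numeric vector, one entry per dihedral) and `tolerance` (degrees)
#' @param unassigned label for frames outside all states
#' @return object of class `substate_library`
#' @export
substate_library <- function(states = NULL, unassigned = "D") {
  if (is.null(states)) {
    states <- list(
      A = list(centers = c(chi1 = -65, chi2 = -90), tolerance = 45),
      B = list(centers = c(chi1 = -65, chi2 = 15), tolerance = 45),
      C = list(centers = c(chi1 = 175, chi2 = 80), tolerance = 45))
  }
  stopifnot(length(states) >= 1, !is.null(names(states)))
  dihnames <- names(states[[1]]$centers)
  for (st in states) stopifnot(identical(names(st$centers), dihnames))
  ## centers must be separated beyond summed tolerances on >= 1 dihedral
  nm <- names(states)
  for (i in seq_along(states)) for (j in seq_len(i - 1)) {
    sep <- circular_distance(states[[i]]$centers, states[[j]]$centers)
    if (!any(sep > states[[i]]$tolerance + states[[j]]$tolerance))
      stop("states ", nm[i], " and ", nm[j],
           " are not separated beyond their tolerances on any dihedral")
  }
  structure(list(states = states, dihedrals = dihnames,
                 unassigned = unassigned),
            class = "substate_library")
}

#' Classify frames into conformational substates
#'
#' Assigns every frame to the state whose centers are nearest by the maximum
#' circular distance across the library's dihedrals, provided that distance
#' is within the state's tolerance; otherwise the frame gets the library's
#' unassigned label. Exact ties break to the lexicographically smaller state
#' label. Populations carry simultaneous 95% multinomial confidence
#' intervals (Goodman).
#'
#' @param series named list (or data.frame) of dihedral time series in
#'   degrees; names must cover the library's dihedrals
#' @param library a [substate_library()]
#' @return object of class `substate_assignment`: `labels` (per frame),
#'   `populations` (data.frame: state, count, fraction, ci_lo, ci_hi),
#'   `transitions` (count matrix), `library`
#' @export
classify_substates <- function(series, library = substate_library()) {
  series <- as.data.frame(series)
  if (nrow(series) == 0) stop("empty dihedral series")
  miss <- setdiff(library$dihedrals, names(series))
  if (length(miss)) stop("missing dihedral series: ", paste(miss, collapse = ", "))
  nf <- nrow(series)
  snames <- sort(names(library$states))
  ## max circular distance to each state's centers
  dmat <- sapply(snames, function(s) {
    st <- library$states[[s]]
    d <- sapply(library$dihedrals, function(dn)
      circular_distance(series[[dn]], st$centers[[dn]]))
    if (nf == 1) max(d) else apply(as.matrix(d), 1, max)
  })
  dmat <- matrix(dmat, nrow = nf, dimnames = list(NULL, snames))
  tols <- vapply(snames, function(s) library$states[[s]]$tolerance, 0)
  best <- apply(dmat, 1, which.min)   # ties -> first = lexicographically smaller
  labels <- snames[best]
  within <- dmat[cbind(seq_len(nf), best)] <= tols[best]
  labels[!within] <- library$unassigned

  all_states <- c(snames, library$unassigned)
  counts <- table(factor(labels, levels = all_states))
  frac <- as.numeric(counts) / nf
  ## Goodman (1965) simultaneous multinomial CIs
  k <- length(all_states)
  chi <- stats::qchisq(1 - 0.05 / k, df = 1)
  ci_lo <- (chi + 2 * counts - sqrt(chi * (chi + 4 * counts * (nf - counts) / nf))) /
    (2 * (nf + chi))
  ci_hi <- (chi + 2 * counts + sqrt(chi * (chi + 4 * counts * (nf - counts) / nf))) /
    (2 * (nf + chi))
  pops <- data.frame(state = all_states, count = as.integer(counts),
                     fraction = frac, ci_lo = as.numeric(ci_lo),
                     ci_hi = as.numeric(ci_hi))
  trans <- table(factor(labels[-nf], levels = all_states),
                 factor(labels[-1], levels = all_states))
  structure(list(labels = labels, populations = pops,
                 transitions = unclass(trans), library = library),
            class = "substate_assignment")
}

#' @export
print.substate_assignment <- function(x, ...) {
  cat(sprintf("Substate assignment over %d frames\n", length(x$labels)))
  print(x$populations, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Geometric Hamiltonian-scaling ladder for replica exchange
#'
#' `factor[i] = lambda_min^(i/(n-1))`, a geometric sequence from 1 to
#' `lambda_min` whose logarithms are equally spaced; with six replicas and
#' `lambda_min = 0.667` this reproduces the ladder
#' 1.000, 0.922, 0.850, 0.784, 0.723, 0.667 at 3-decimal display.
#'
#' @param n number of replicas (>= 2)
#' @param lambda_min smallest scaling factor, in (0, 1)
#' @return object of class `hrex_ladder`: `factors` (exact values),
#'   `display` (rounded to 3 decimals), `n`, `lambda_min`
#' @export
hrex_ladder <- function(n, lambda_min) {
  stopifnot(n >= 2)
  if (lambda_min >= 1 || lambda_min <= 0)
    stop("lambda_min must lie in (0, 1)")
  f <- lambda_min^((seq_len(n) - 1) / (n - 1))
  structure(list(factors = f, display = round(f, 3), n = n,
                 lambda_min = lambda_min),
            class = "hrex_ladder")
}

#' @export
print.hrex_ladder <- function(x, ...) {
  cat("HREX scaling ladder:", paste(sprintf("%.3f", x$display), collapse = ", "), "\n")
  invisible(x)
}

#' Residues within a radius of a center residue
#'
#' The "hot region" of a replica-exchange setup: every residue having any
#' atom within `radius` of any atom of the center residue, plus the center
#' residue itself. `radius = 0` returns the center alone.
#'
#' @param structure data.frame with columns `resno`, `x`, `y`, `z`
#'   (e.g. from [read_pdb()])
#' @param center_resno residue number of the center residue
#' @param radius Angstrom
#' @return sorted integer vector of residue numbers
#' @export
select_hot_region <- function(structure, center_resno, radius) {
  stopifnot(all(c("resno", "x", "y", "z") %in% names(structure)), radius >= 0)
  ctr <- structure[structure$resno == center_resno, c("x", "y", "z")]
  if (nrow(ctr) == 0) stop("center residue ", center_resno, " absent from structure")
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  cm <- as.matrix(ctr)
  ## min distance of each atom to any center atom
  mind <- apply(xyz, 1, function(p) sqrt(min(colSums((t(cm) - p)^2))))
  sort(unique(c(center_resno, structure$resno[mind <= radius])))
}

#' Optimal-superposition RMSD between two coordinate sets (Kabsch)
#'
#' @param a,b n x 3 matrices with matched atoms
#' @return RMSD in the units of the input after optimal rigid-body
#'   superposition of `a` onto `b`
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("atom-count mismatch: ",
                                   nrow(a), " vs ", nrow(b))
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u) * det(s$v))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- ac %*% t(R) - bc
  sqrt(mean(rowSums(diff^2)))
}

#' Backbone RMSD trace along a trajectory
#'
#' Kabsch-superposed RMSD of each frame against a reference, over an atom
#' selection. `superpose = FALSE` skips the rigid-body fit and returns the
#' plain coordinate RMSD (useful when frames share a fixed frame of
#' reference, e.g. a restrained droplet).
#'
#' @param traj list of n x 3 coordinate matrices
#' @param reference n x 3 reference coordinates
#' @param selection atom indices (default all)
#' @param superpose optimally superpose each frame first (default TRUE)
#' @return numeric vector, one RMSD (Angstrom) per frame
#' @export
backbone_rmsd <- function(traj, reference, selection = NULL, superpose = TRUE) {
  reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  ref <- reference[selection, , drop = FALSE]
  vapply(traj, function(fr) {
    fr <- as.matrix(fr)
    if (nrow(fr) != nrow(reference))
      stop("atom-count mismatch: ", nrow(fr), " vs ", nrow(reference))
    a <- fr[selection, , drop = FALSE]
    if (superpose) kabsch_rmsd(a, ref)
    else sqrt(mean(rowSums((a - ref)^2)))
  }, 0)
}

#' Greedy RMSD clustering (Daura algorithm)
#'
#' Computes all pairwise superposed RMSDs over the atom selection, then
#' repeatedly takes the frame with the most neighbors within `cutoff` as a
#' cluster centroid, removes the cluster, and recounts. Ties break to the
#' lowest frame index. Cluster sizes are non-increasing in output order;
#' every frame belongs to exactly one cluster.
#'
#' @param frames list of n x 3 coordinate matrices
#' @param cutoff RMSD cutoff (Angstrom), > 0
#' @param selection atom indices used for superposition/RMSD (default all)
#' @return list of clusters, each a list with `centroid` (frame index) and
#'   `members` (frame indices, centroid included)
#' @export
daura_cluster <- function(frames, cutoff = 0.5, selection = NULL) {
  stopifnot(length(frames) >= 1, cutoff > 0)
  if (is.null(selection)) selection <- seq_len(nrow(as.matrix(frames[[1]])))
  if (length(selection) == 0) stop("empty atom selection")
  nf <- length(frames)
  sel <- lapply(frames, function(fr) as.matrix(fr)[selection, , drop = FALSE])
  adj <- matrix(FALSE, nf, nf)
  diag(adj) <- TRUE
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      adj[i, j] <- adj[j, i] <- kabsch_rmsd(sel[[i]], sel[[j]]) <= cutoff
    }
  }
  remaining <- rep(TRUE, nf)
  clusters <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    nn <- rowSums(adj[idx, idx, drop = FALSE])
    ctr <- idx[which.max(nn)]            # ties -> lowest frame index
    members <- idx[adj[ctr, idx]]
    clusters[[length(clusters) + 1]] <- list(centroid = ctr, members = members)
    remaining[members] <- FALSE
  }
  clusters
}

#' Active-site geometry metrics
#'
#' Computes the ring-plane alignment angle (angle between the best-fit plane
#' normals of two ring atom sets, via SVD, folded to `[0, 90]` degrees), the
#' donor-H-acceptor angle (angle at the hydrogen) and any requested
#' interatomic distances.
#'
#' @param frame n x 3 coordinate matrix
#' @param ring1,ring2 atom indices of the two rings (>= 3 atoms each), or
#'   NULL to skip
#' @param dha length-3 atom indices (donor, H, acceptor), or NULL to skip
#' @param distances optional 2-column matrix of atom index pairs
#' @return list with `ring_plane_angle`, `donor_H_acceptor_angle` (degrees)
#'   and `distances` (Angstrom)
#' @export
geometry_metrics <- function(frame, ring1 = NULL, ring2 = NULL, dha = NULL,
                             distances = NULL) {
  frame <- as.matrix(frame)
  out <- list(ring_plane_angle = NA_real_, donor_H_acceptor_angle = NA_real_,
              distances = numeric(0))
  plane_normal <- function(idx) {
    if (length(idx) < 3) stop("need >= 3 atoms to fit a plane")
    p <- frame[idx, , drop = FALSE]
    svd(scale(p, scale = FALSE))$v[, 3]
  }
  if (!is.null(ring1) && !is.null(ring2)) {
    n1 <- plane_normal(ring1); n2 <- plane_normal(ring2)
    cosang <- abs(sum(n1 * n2))    # fold to [0, 90]
    out$ring_plane_angle <- acos(pmin(1, cosang)) * 180 / pi
  }
  if (!is.null(dha)) {
    stopifnot(length(dha) == 3)
    v1 <- frame[dha[1], ] - frame[dha[2], ]
    v2 <- frame[dha[3], ] - frame[dha[2], ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    out$donor_H_acceptor_angle <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  }
  if (!is.null(distances)) {
    distances <- matrix(distances, ncol = 2)
    out$distances <- apply(distances, 1, function(p)
      sqrt(sum((frame[p[1], ] - frame[p[2], ])^2)))
  }
  out
}

#' Replica-exchange bookkeeping from replica logs
#'
#' Summarizes exchange attempts between neighboring rungs of a scaling
#' ladder: per-pair attempt and acceptance counts and the overall acceptance
#' ratio. Implemented as analysis of recorded attempts, not as a parallel
#' MD driver.
#'
#' @param attempts data.frame with columns `pair` (lower rung index) and
#'   `accepted` (logical)
#' @param n_replicas number of replicas in the ladder
#' @return data.frame per neighbor pair plus an `overall` attribute
#' @export
hrex_exchange_summary <- function(attempts, n_replicas) {
  stopifnot(all(c("pair", "accepted") %in% names(attempts)),
            all(attempts$pair >= 1), all(attempts$pair < n_replicas))
  pairs <- seq_len(n_replicas - 1)
  out <- data.frame(
    pair = pairs,
    attempts = vapply(pairs, function(p) sum(attempts$pair == p), 0L),
    accepted = vapply(pairs, function(p)
      sum(attempts$accepted[attempts$pair == p]), 0L))
  out$ratio <- ifelse(out$attempts > 0, out$accepted / out$attempts, NA)
  attr(out, "overall") <- sum(out$accepted) / max(sum(out$attempts), 1)
  out
}
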