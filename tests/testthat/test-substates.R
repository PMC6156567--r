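test_that("dihedral angle matches planar limits and the vector-algebra oracle", {
  ## planar cis -> 0, planar trans -> 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                  c(1, 0, 0))), 180)
  ## staggered ethane-like geometry: +/- 60 degrees
  ct <- -1 / 3; st <- sqrt(1 - ct^2)       # tetrahedral angle
  p1 <- c(st, 0, ct)
  p2 <- c(0, 0, 0)
  p3 <- c(0, 0, -1)
  for (phi_deg in c(60, -60, 175)) {
    phi <- phi_deg * pi / 180
    p4 <- c(st * cos(phi), st * sin(phi), -1 - ct)
    expect_equal(dihedral_angle(p1, p2, p3, p4), phi_deg, tolerance = 1e-9)
  }
  ## chirality: mirrored coordinates negate the angle
  mirror <- function(p) c(-p[1], p[2], p[3])
  phi <- 60 * pi / 180
  p4 <- c(st * cos(phi), st * sin(phi), -1 - ct)
  expect_equal(dihedral_angle(mirror(p1), mirror(p2), mirror(p3), mirror(p4)),
               -60, tolerance = 1e-9)
})

test_that("dihedral time series agrees with the bio3d torsion oracle", {
  set.seed(12)
  traj <- lapply(1:25, function(i) matrix(rnorm(12), 4, 3))
  mine <- compute_dihedral(traj, list(atoms = 1:4))
  ## bio3d measures the same torsion with the opposite sign convention
  oracle <- -vapply(traj, function(fr)
    bio3d::torsion.xyz(as.numeric(t(fr)), atm.inc = 4), 0)
  d <- abs(mine - oracle)
  expect_lt(max(pmin(d, 360 - d)), 1e-6)
})

test_that("missing atoms in a frame are refused with the atom identifier", {
  traj <- list(matrix(rnorm(9), 3, 3))
  expect_error(compute_dihedral(traj, list(atoms = c(1, 2, 3, 4))), "4")
})

test_that("classification is exact at state centers and breaks ties lexicographically", {
  lib <- substate_library()
  centers <- t(vapply(lib$states, function(s) s$centers, c(chi1 = 0, chi2 = 0)))
  series <- as.data.frame(centers)
  out <- classify_substates(series, lib)
  expect_equal(out$labels, names(lib$states))
  ## a frame far from every state gets the unassigned label
  out2 <- classify_substates(data.frame(chi1 = 60, chi2 = -170), lib)
  expect_equal(out2$labels, "D")
  ## equidistant tie breaks to the lexicographically smaller label
  lib2 <- substate_library(list(
    A = list(centers = c(chi1 = -20.5), tolerance = 30),
    B = list(centers = c(chi1 = 20.5), tolerance = 10)))
  tie <- classify_substates(data.frame(chi1 = 0), lib2)
  expect_equal(tie$labels, "A")
  expect_error(classify_substates(data.frame(chi1 = numeric(0)), lib2),
               "empty")
})

test_that("classification is invariant to 360-degree wraps", {
  tr <- gen_rotamer_traj(seed = 4, n_frames = 400, kappa = 20)
  base <- classify_substates(tr$series)
  wrapped <- tr$series + 360
  expect_equal(classify_substates(wrapped)$labels, base$labels)
})

test_that("planted von Mises mixtures are recovered within the multinomial CI", {
  tr <- gen_rotamer_traj(seed = 7, n_frames = 5000,
                         fractions = c(A = 0.7, B = 0.2, C = 0.1), kappa = 20)
  out <- classify_substates(tr$series)
  pops <- out$populations
  for (st in c("A", "B", "C")) {
    truth <- c(A = 0.7, B = 0.2, C = 0.1)[[st]]
    row <- pops[pops$state == st, ]
    expect_gte(truth, row$ci_lo)
    expect_lte(truth, row$ci_hi)
  }
  expect_equal(sum(pops$fraction), 1, tolerance = 1e-12)
  ## transition-count bookkeeping: row sums equal label counts minus the
  ## final frame's state
  n <- table(factor(out$labels, levels = pops$state))
  last <- out$labels[length(out$labels)]
  expected <- as.integer(n) - as.integer(pops$state == last)
  expect_equal(unname(rowSums(out$transitions)), expected)
})

test_that("population estimates converge to the planted fractions", {
  tr <- gen_rotamer_traj(seed = 8, n_frames = 50000,
                         fractions = c(A = 0.5, B = 0.3, C = 0.2), kappa = 50)
  pops <- classify_substates(tr$series)$populations
  for (st in c("A", "B", "C")) {
    truth <- c(A = 0.5, B = 0.3, C = 0.2)[[st]]
    expect_lt(abs(pops$fraction[pops$state == st] - truth), 0.01)
  }
})

test_that("HREX ladder reproduces the published six-replica factors", {
  lad <- hrex_ladder(6, 0.667)
  expect_identical(lad$display,
                   c(1.000, 0.922, 0.850, 0.784, 0.723, 0.667))
  expect_equal(hrex_ladder(2, 0.5)$factors, c(1, 0.5))
  expect_equal(hrex_ladder(3, 0.25)$factors, c(1, 0.5, 0.25))
  ## log spacing is uniform
  lf <- diff(log(lad$factors))
  expect_lt(max(abs(lf - lf[1])), 1e-9)
  expect_error(hrex_ladder(6, 1.2), "lambda_min")
  expect_error(hrex_ladder(1, 0.5), "n >= 2")
})

test_that("hot-region selection matches brute-force distances", {
  ## two-residue toy with known atom spacing
  st <- data.frame(resno = c(1, 1, 2, 2, 3),
                   x = c(0, 1, 4, 5, 20), y = 0, z = 0)
  expect_equal(select_hot_region(st, 1, 0), 1)
  expect_equal(select_hot_region(st, 1, 3), c(1, 2))
  expect_equal(select_hot_region(st, 1, 4.5), c(1, 2))
  expect_equal(select_hot_region(st, 1, 19.5), c(1, 2, 3))
  expect_error(select_hot_region(st, 9, 4), "absent")
})

test_that("Daura clustering handles degenerate and planted cases", {
  fr <- gen_cluster_fixture(seed = 2, n_blobs = 1, frames_per_blob = 6,
                            spread = 0)
  cl <- daura_cluster(fr$frames, 0.5)
  expect_length(cl, 1)
  expect_equal(sort(cl[[1]]$members), 1:6)
  ## two well-separated blobs -> exactly 2 clusters with correct membership
  fx <- gen_cluster_fixture(seed = 3, n_blobs = 2, frames_per_blob = 8,
                            separation = 5, spread = 0.1)
  cl2 <- daura_cluster(fx$frames, 0.5)
  expect_length(cl2, 2)
  got <- integer(length(fx$labels))
  for (i in seq_along(cl2)) got[cl2[[i]]$members] <- i
  expect_equal(length(unique(paste(got, fx$labels))), 2)
  expect_error(daura_cluster(fx$frames, 0.5, selection = integer(0)), "empty")
})

test_that("Daura clustering equals the brute-force oracle on random frames", {
  set.seed(31)
  for (rep in 1:3) {
    fx <- gen_cluster_fixture(seed = 40 + rep, n_blobs = 3,
                              frames_per_blob = 6, separation = 1.2,
                              spread = 0.45)
    mine <- daura_cluster(fx$frames, 0.8)
    oracle <- brute_daura(fx$frames, 0.8)
    expect_equal(lapply(mine, function(c) sort(c$members)),
                 lapply(oracle, function(c) sort(c$members)))
  }
})

test_that("Daura output is a partition with non-increasing cluster sizes", {
  fx <- gen_cluster_fixture(seed = 9, n_blobs = 3, frames_per_blob = 5,
                            separation = 2, spread = 0.4)
  cl <- daura_cluster(fx$frames, 0.7)
  sizes <- vapply(cl, function(c) length(c$members), 0L)
  expect_true(all(diff(sizes) <= 0))
  all_members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_equal(all_members, seq_along(fx$frames))
})

test_that("geometry metrics match constructed fixtures", {
  ## two coplanar rings -> 0 degrees
  hexagon <- function(z, rot = 0) t(vapply(0:5, function(i)
    c(cos(i * pi / 3 + rot), sin(i * pi / 3 + rot), z), numeric(3)))
  fr <- rbind(hexagon(0), hexagon(2, 0.3))
  g <- geometry_metrics(fr, ring1 = 1:6, ring2 = 7:12)
  expect_equal(g$ring_plane_angle, 0, tolerance = 1e-8)
  ## perpendicular rings -> 90 degrees
  ringYZ <- t(vapply(0:5, function(i)
    c(0, cos(i * pi / 3), sin(i * pi / 3) + 5), numeric(3)))
  g2 <- geometry_metrics(rbind(hexagon(0), ringYZ), ring1 = 1:6, ring2 = 7:12)
  expect_equal(g2$ring_plane_angle, 90, tolerance = 1e-8)
  ## collinear donor-H-acceptor -> 180; right angle -> 90
  fr3 <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1.8, 0, 0), c(0, 2, 0))
  g3 <- geometry_metrics(fr3, dha = c(1, 2, 3),
                         distances = rbind(c(1, 3), c(2, 4)))
  expect_equal(g3$donor_H_acceptor_angle, 180)
  expect_equal(g3$distances, c(2.8, 2))
  g4 <- geometry_metrics(fr3, dha = c(1, 2, 4))
  expect_equal(g4$donor_H_acceptor_angle, 90)
  expect_error(geometry_metrics(fr3, ring1 = 1:2, ring2 = 3:4), ">= 3")
})

test_that("backbone RMSD is zero under rigid motion and exact for known shifts", {
  set.seed(14)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(backbone_rmsd(list(ref), ref), 0, tolerance = 1e-10)
  ## rigid rotation + translation -> 0 after superposition
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ref %*% Rz + matrix(rep(c(3, -2, 5), each = 10), 10, 3)
  expect_equal(backbone_rmsd(list(moved), ref), 0, tolerance = 1e-8)
  ## superposition-free mode: a uniform 1 A displacement gives exactly 1
  shift <- ref; shift[, 1] <- shift[, 1] + 1
  expect_equal(backbone_rmsd(list(shift), ref, superpose = FALSE), 1,
               tolerance = 1e-12)
  expect_error(backbone_rmsd(list(ref[1:5, ]), ref), "mismatch")
})

test_that("replica-exchange bookkeeping summarizes attempt logs", {
  logs <- data.frame(pair = c(1, 1, 2, 2, 2, 5),
                     accepted = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  out <- hrex_exchange_summary(logs, 6)
  expect_equal(out$attempts, c(2L, 3L, 0L, 0L, 1L))
  expect_equal(out$ratio[1:2], c(0.5, 2 / 3))
  expect_equal(attr(out, "overall"), 4 / 6)
})
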