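test_that("noiseless rate tables are recovered exactly by the downstream fits", {
  tab <- gen_rate_data(seed = 1, noise_sdlog = 0)
  truth <- attr(tab, "truth")
  ## Michaelis-Menten at one temperature
  d <- tab[tab$variant == "R1" & tab$isotope == "H" & tab$temp_K == 303 &
             tab$replicate == 1, ]
  fit <- fit_michaelis_menten(d[, c("conc_mM", "rate_per_s")] |>
                                setNames(c("conc_mM", "rate")))
  kcat_true <- exp(truth$H$lnA - truth$H$Ea / (R_GAS * 303))
  expect_equal(fit$kcat, kcat_true, tolerance = 1e-6)
  expect_equal(fit$KM, truth$H$KM_mM, tolerance = 1e-6)
  ## Arrhenius over kcat(T) per isotope
  for (iso in c("H", "D")) {
    kc <- vapply(unique(tab$temp_K), function(T) {
      di <- tab[tab$variant == "R1" & tab$isotope == iso & tab$temp_K == T &
                  tab$replicate == 1, ]
      fit_michaelis_menten(setNames(di[, c("conc_mM", "rate_per_s")],
                                    c("conc_mM", "rate")))$kcat
    }, 0)
    fa <- fit_arrhenius(unique(tab$temp_K), kc)
    expect_equal(fa$Ea, truth[[iso]]$Ea, tolerance = 1e-5)
    expect_equal(fa$lnA, truth[[iso]]$lnA, tolerance = 1e-5)
  }
})

test_that("the full pipeline KIE matches the analytic value of the planted parameters", {
  tab <- gen_rate_data(seed = 2, noise_sdlog = 0)
  truth <- attr(tab, "truth")
  kie_true <- exp((truth$H$lnA - truth$D$lnA) +
                    (truth$D$Ea - truth$H$Ea) / (R_GAS * 303))
  temps <- unique(tab$temp_K)
  rates <- do.call(rbind, lapply(c("H", "D"), function(iso)
    data.frame(variant = "R1", isotope = iso, temp_K = temps,
               rate_per_s = vapply(temps, function(T) {
                 d <- tab[tab$variant == "R1" & tab$isotope == iso &
                            tab$temp_K == T & tab$replicate == 1, ]
                 fit_michaelis_menten(setNames(d[, c("conc_mM", "rate_per_s")],
                                               c("conc_mM", "rate")))$kcat
               }, 0))))
  out <- kie_table(rates, 303)
  expect_equal(out$kie, kie_true, tolerance = 1e-5)
})

test_that("rate generation is a pure function of its seed", {
  a <- gen_rate_data(seed = 42)
  b <- gen_rate_data(seed = 42)
  expect_identical(a, b)
  expect_false(identical(gen_rate_data(seed = 43)$rate_per_s, a$rate_per_s))
  expect_error(gen_rate_data(temps_K = c(-1, 300)), "positive")
})

test_that("gas-phase triad has finite, force-consistent energies", {
  s <- gen_toy_evb_system(seed = 5, n_waters = 0)
  e <- diabatic_energies(s)
  expect_true(is.finite(e$e1) && is.finite(e$e2p))
  h <- 1e-5; x <- s$xyz
  for (i in 1:2) for (d in 1:2) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num <- -(diabatic_energies(s, xp)$e1 - diabatic_energies(s, xm)$e1) / (2 * h)
    expect_lt(abs(num - e$f1[i, d]), 1e-4)
  }
  expect_error(gen_toy_evb_system(droplet_radius = 4), ">= 6")
  ## determinism
  expect_identical(gen_toy_evb_system(seed = 5)$xyz,
                   gen_toy_evb_system(seed = 5)$xyz)
})

test_that("rotamer trajectories honor their planted state structure", {
  ## near-infinite concentration -> perfect classification
  tr <- gen_rotamer_traj(seed = 3, n_frames = 500, kappa = 2e6)
  out <- classify_substates(tr$series)
  expect_equal(out$labels, tr$labels)
  ## full persistence -> a single state throughout
  tr2 <- gen_rotamer_traj(seed = 4, n_frames = 300, persistence = 1)
  expect_length(unique(tr2$labels), 1)
  expect_error(gen_rotamer_traj(fractions = c(A = 0.5, Z = 0.5)), "unknown")
  expect_error(gen_rotamer_traj(fractions = c(A = 0.5, B = 0.1)), "sum to 1")
  ## determinism
  expect_identical(gen_rotamer_traj(seed = 11)$series,
                   gen_rotamer_traj(seed = 11)$series)
})

test_that("cluster fixtures have the promised geometry", {
  ## zero jitter: all frames within a blob are identical
  fx <- gen_cluster_fixture(seed = 6, n_blobs = 1, frames_per_blob = 4,
                            spread = 0)
  for (i in 2:4)
    expect_lt(kabsch_rmsd(fx$frames[[1]], fx$frames[[i]]), 1e-10)
  ## blobs separated well beyond the intra-blob spread
  fx2 <- gen_cluster_fixture(seed = 7, n_blobs = 2, frames_per_blob = 5,
                             separation = 5, spread = 0.1)
  intra <- kabsch_rmsd(fx2$frames[[1]], fx2$frames[[2]])
  inter <- kabsch_rmsd(fx2$frames[[1]], fx2$frames[[6]])
  expect_lt(intra, 0.3)
  expect_gt(inter, 2)
})

test_that("von Mises sampler produces the right concentration behavior", {
  set.seed(5)
  tight <- rvonmises_deg(2000, 200)
  loose <- rvonmises_deg(2000, 1)
  expect_lt(sd(tight), sd(loose))
  ## circular mean at the center
  expect_lt(abs(atan2(mean(sin(tight * pi / 180)),
                      mean(cos(tight * pi / 180)))), 0.05)
  unif <- rvonmises_deg(2000, 0)
  expect_true(all(unif > -180 & unif <= 180))
})
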