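test_that("a constant perturbation gives dG equal to the offset, exactly", {
  set.seed(2)
  cst <- 7.3
  frames <- lapply(lambda_schedule(11), function(lam) {
    e1 <- rnorm(500, -20, 5)
    mapping_frame(lam, e1, e1 + cst, 0)
  })
  fep <- fep_free_energy(frames, 300)
  expect_equal(tail(fep$dG, 1), cst, tolerance = 1e-10)
  ## bidirectional averaging agrees
  fep2 <- fep_free_energy(frames, 300, bidirectional = TRUE)
  expect_equal(tail(fep2$dG, 1), cst, tolerance = 1e-10)
})

test_that("harmonic force-constant toggle reproduces the Gaussian closed form", {
  fr <- gen_harmonic_toggle_frames(k1 = 1, k2 = 4, temp_K = 300,
                                   n_lambda = 31, n_samp = 8000, seed = 5)
  exact <- attr(fr, "truth")$dG
  expect_equal(exact, 0.5 * R_GAS * 300 * log(4), tolerance = 1e-12)
  got <- tail(fep_free_energy(fr, 300)$dG, 1)
  expect_lt(abs(got / exact - 1), 0.01)
})

test_that("reversing the mapping direction negates the free energy", {
  fr <- gen_harmonic_toggle_frames(k1 = 1, k2 = 4, temp_K = 300, seed = 6)
  fwd <- tail(fep_free_energy(fr, 300)$dG, 1)
  rev_frames <- lapply(rev(seq_along(fr)), function(m) {
    s <- fr[[m]]$samples
    mapping_frame(1 - fr[[m]]$lambda, s$e2p, s$e1, 0)
  })
  bwd <- tail(fep_free_energy(rev_frames, 300)$dG, 1)
  expect_lt(abs(bwd + fwd), 0.01)
})

test_that("free energy is additive over frame subdivisions", {
  fr <- gen_harmonic_toggle_frames(k1 = 1, k2 = 4, temp_K = 300,
                                   n_lambda = 41, seed = 7)
  full <- tail(fep_free_energy(fr, 300)$dG, 1)
  merged <- tail(fep_free_energy(fr[seq(1, 41, 2)], 300)$dG, 1)
  expect_lt(abs(full - merged), 0.02)
})

test_that("poor-overlap windows are reported", {
  set.seed(3)
  frames <- lapply(c(0, 1), function(lam) {
    e1 <- rnorm(40, 0, 1)
    mapping_frame(lam, e1, e1 * 60, 0)   # wildly different endpoint
  })
  expect_warning(fep_free_energy(frames, 300), "ESS")
})

test_that("mapping frames verify the mixing identity", {
  e1 <- c(1, 2); e2 <- c(3, 4)
  expect_error(mapping_frame(0.5, e1, e2, 0, em = c(2, 3) + 0.001),
               "inconsistent")
  fr <- mapping_frame(0.5, e1, e2, 0)
  expect_equal(fr$samples$em, c(2, 3))
  expect_equal(fr$samples$gap, c(-2, -2))
})

test_that("umbrella profile reproduces Marcus closed forms", {
  ## symmetric: barrier = lambda_r / 4
  fr <- gen_marcus_frames(lambda_r = 40, dG0 = 0, h12 = 0, n_grid = 12001)
  p <- umbrella_profile(fr, 300, bin_width = 0.25, min_count = 1)
  expect_lt(abs(p$dG_barrier - 10), 0.1)
  expect_lt(abs(p$dG_reaction - 0), 0.05)
  ## asymmetric: barrier = (lambda_r + dG0)^2 / (4 lambda_r)
  fr2 <- gen_marcus_frames(lambda_r = 40, dG0 = -8, h12 = 0, n_grid = 12001)
  p2 <- umbrella_profile(fr2, 300, bin_width = 0.25, min_count = 1)
  expect_lt(abs(p2$dG_barrier - (40 - 8)^2 / 160), 0.1)
  expect_lt(abs(p2$dG_reaction - (-8)), 0.05)
})

test_that("coupling at a symmetric crossing lowers the barrier by about H12", {
  p0 <- umbrella_profile(gen_marcus_frames(40, 0, 0, n_grid = 12001),
                         300, 0.25, 1)
  p2 <- umbrella_profile(gen_marcus_frames(40, 0, 2, n_grid = 12001),
                         300, 0.25, 1)
  expect_lt(abs((p0$dG_barrier - p2$dG_barrier) - 2), 0.3)
})

test_that("umbrella profile matches a direct Boltzmann-integral oracle", {
  ## independent oracle: exact binned free energy from the grid density
  lambda_r <- 40; k <- 2; d <- sqrt(2 * lambda_r / k)
  beta <- 1 / (R_GAS * 300)
  x <- seq(-3, d + 3, length.out = 20001)
  e1 <- 0.5 * k * x^2; e2 <- 0.5 * k * (x - d)^2
  eg <- pmin(e1, e2)
  gap <- e1 - e2
  bw <- 0.25
  edges <- seq(floor(min(gap) / bw) * bw, ceiling(max(gap) / bw) * bw, bw)
  b <- findInterval(gap, edges, rightmost.closed = TRUE)
  w <- exp(-beta * eg)
  dg_oracle <- -log(vapply(seq_len(length(edges) - 1),
                           function(i) sum(w[b == i]), 0)) / beta
  centers <- edges[-1] - bw / 2
  ok <- is.finite(dg_oracle)
  dg_oracle <- dg_oracle[ok] - min(dg_oracle[ok])

  fr <- gen_marcus_frames(lambda_r = 40, dG0 = 0, h12 = 0, n_grid = 20001)
  p <- umbrella_profile(fr, 300, bin_width = bw, min_count = 1)
  m <- match(round(p$profile$X, 6), round(centers[ok], 6))
  cmp <- !is.na(m) & dg_oracle[m] < 25   # compare well-sampled region
  expect_gt(sum(cmp), 50)
  expect_lt(max(abs(p$profile$dg[cmp] - dg_oracle[m][cmp])), 0.1)
})

test_that("profiles without both basins or without a barrier are flagged", {
  ## gap never changes sign -> refuse
  frames <- lapply(c(0.2, 0.4), function(lam) {
    e1 <- rnorm(100, 0, 1)
    mapping_frame(lam, e1, e1 + 50, 0)
  })
  expect_error(umbrella_profile(frames, 300), "sign")
  ## strong coupling over a tiny Marcus barrier washes the barrier out
  fr <- gen_marcus_frames(lambda_r = 10, dG0 = -9, h12 = 4)
  p <- suppressWarnings(umbrella_profile(fr, 300, bin_width = 1, min_count = 1))
  expect_true(any(grepl("no barrier", p$flags)))
})
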