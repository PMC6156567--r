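test_that("noiseless Arrhenius data is reproduced to high precision", {
  T <- seq(283, 323, 5)
  k <- exp(15.0 - 10.0 / (R_GAS * T))
  fit <- fit_arrhenius(T, k)
  expect_equal(fit$Ea, 10.0, tolerance = 1e-10)
  expect_equal(fit$lnA, 15.0, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  ## round trip: every input point reproduced to >= 10 significant digits
  expect_equal(evaluate_rate(fit, T), k, tolerance = 1e-10)
})

test_that("two-point fit equals the analytic line through two points", {
  T <- c(288, 318); k <- c(0.013, 0.21)
  ## closed-form slope/intercept in (1/T, ln k)
  slope <- (log(k[2]) - log(k[1])) / (1 / T[2] - 1 / T[1])
  intercept <- log(k[1]) - slope / T[1]
  fit <- fit_arrhenius(c(T, 303), c(k, exp(intercept + slope / 303)))
  expect_equal(fit$Ea, -slope * R_GAS, tolerance = 1e-9)
  expect_equal(fit$lnA, intercept, tolerance = 1e-9)
})

test_that("invalid rate inputs are refused", {
  expect_error(fit_arrhenius(c(283, 293, 303), c(1, -2, 3)), "> 0")
  expect_error(fit_arrhenius(c(303, 303, 303), c(1, 1.1, 0.9)), "distinct")
  expect_error(evaluate_rate(list(Ea = 10, lnA = 15), -5), "> 0")
})

test_that("evaluate_rate matches direct substitution and the printed R1 rate", {
  ## published R1 Arrhenius components evaluated at the assay temperature
  k <- evaluate_rate(list(Ea = 10.8, lnA = 14.0), 303)
  expect_equal(k, exp(14.0 - 10.8 / (R_GAS * 303)), tolerance = 1e-12)
  expect_equal(round(k, 2), 0.02)       # printed kH at the table's rounding
  ## flat Arrhenius: Ea = 0 gives exp(lnA) at every temperature
  expect_equal(evaluate_rate(list(Ea = 0, lnA = 2.5), c(200, 300, 400)),
               rep(exp(2.5), 3))
  ## independent high-precision evaluation
  expect_equal(evaluate_rate(list(Ea = 5.6, lnA = 9.1), 303),
               exp(9.1) * exp(-5.6 / (1.9872e-3 * 303)), tolerance = 1e-10)
})

test_that("KIE decomposition obeys its construction identity and matches printed rows", {
  T303 <- 303
  fit_from <- function(Ea, lnA) {
    Ts <- seq(283, 323, 10)
    fit_arrhenius(Ts, exp(lnA - Ea / (R_GAS * Ts)))
  }
  fH <- fit_from(10.8, 14.0); fD <- fit_from(15.1, 19.6)
  kd <- kie_decomposition(fH, fD, T303)
  expect_equal(kd$delta_Ea, 4.3, tolerance = 1e-8)
  expect_equal(kd$A_ratio, exp(14.0 - 19.6), tolerance = 1e-8)
  ## identity: kie = A_ratio * exp(delta_Ea / RT) exactly, by construction
  expect_identical(kd$kie_at_T, kd$A_ratio * exp(kd$delta_Ea / (R_GAS * T303)))
  ## printed row: 4.3, 0.004, 4.9(0.2); reconstructed values agree within
  ## input-rounding tolerance
  expect_equal(kd$A_ratio, 0.004, tolerance = 0.1)
  expect_equal(kd$kie_at_T, 4.9, tolerance = 0.07)
  ## identical fits give the identity decomposition
  kd0 <- kie_decomposition(fH, fH, T303)
  expect_equal(kd0$delta_Ea, 0)
  expect_equal(kd0$A_ratio, 1)
  expect_equal(kd0$kie_at_T, 1)
})

test_that("KIE from printed components matches brute-force arithmetic", {
  expect_equal(kie_from_components(4.4, 0.005, 303),
               0.005 * exp(4.4 / 0.6021216), tolerance = 1e-10)
})

test_that("kie_at_T is invariant to a common shift of both lnA values", {
  Ts <- seq(283, 323, 10)
  fH <- fit_arrhenius(Ts, exp(14.0 - 10.8 / (R_GAS * Ts)))
  fD <- fit_arrhenius(Ts, exp(19.6 - 15.1 / (R_GAS * Ts)))
  base <- kie_decomposition(fH, fD, 303)$kie_at_T
  for (c0 in c(-3, 1.7)) {
    fHs <- fH; fDs <- fD
    fHs$lnA <- fH$lnA + c0; fDs$lnA <- fD$lnA + c0
    expect_equal(kie_decomposition(fHs, fDs, 303)$kie_at_T, base,
                 tolerance = 1e-12)
  }
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  set.seed(21)
  Ts <- seq(283, 323, 5)
  gen <- function(Ea, lnA) exp(lnA - Ea / (R_GAS * Ts) + rnorm(length(Ts), 0, 0.02))
  fH <- fit_arrhenius(Ts, gen(10.8, 14.0))
  fD <- fit_arrhenius(Ts, gen(15.1, 19.6))
  kd <- kie_decomposition(fH, fD, 303)
  boot <- replicate(1000, {
    bH <- fit_arrhenius(Ts, exp(fH$lnA - fH$Ea / (R_GAS * Ts) +
                                  rnorm(length(Ts), 0, 0.02)))
    bD <- fit_arrhenius(Ts, exp(fD$lnA - fD$Ea / (R_GAS * Ts) +
                                  rnorm(length(Ts), 0, 0.02)))
    b <- kie_decomposition(bH, bD, 303)
    c(b$delta_Ea, b$kie_at_T)
  })
  expect_lt(abs(sd(boot[1, ]) / kd$se_delta_Ea - 1), 0.15)
  expect_lt(abs(sd(boot[2, ]) / kd$se_kie - 1), 0.15)
})

test_that("kie_table recovers planted values, is order-invariant, and skips incomplete variants", {
  Ts <- seq(283, 323, 10)
  mk <- function(variant, Ea, lnA, iso)
    data.frame(variant = variant, isotope = iso, temp_K = Ts,
               rate_per_s = exp(lnA - Ea / (R_GAS * Ts)))
  tab <- rbind(mk("v1", 10, 14, "H"), mk("v1", 14, 19, "D"),
               mk("v2", 7, 12, "H"), mk("v2", 11, 17, "D"))
  out <- kie_table(tab, 303)
  expect_equal(out$variant, c("v1", "v2"))
  expect_equal(out$delta_Ea, c(4, 4), tolerance = 1e-8)
  expect_equal(out$A_ratio, exp(c(-5, -5)), tolerance = 1e-8)
  ## shuffled rows give identical output
  set.seed(3)
  out2 <- kie_table(tab[sample(nrow(tab)), ], 303)
  expect_equal(out2, out, ignore_attr = TRUE)
  ## missing D series -> variant skipped with a warning
  expect_warning(out3 <- kie_table(rbind(tab, mk("v3", 9, 13, "H")), 303),
                 "v3")
  expect_equal(out3$variant, c("v1", "v2"))
})

test_that("published-table Arrhenius columns reproduce the printed isotope differences", {
  tab <- ke07_table()
  expect_equal(nrow(tab), 7)
  ## delta_Ea column equals Ea(D) - Ea(H) within printing precision
  expect_true(all(abs((tab$Ea_D - tab$Ea_H) - tab$delta_Ea) <= 0.1 + 1e-9))
  ## the KIE identity applied to printed (rounded) components stays near the
  ## printed KIE; the loosest row reconstructs to ~7.5%
  kie <- kie_from_components(tab$delta_Ea, tab$A_ratio, 303)
  expect_true(all(abs(kie / tab$kie - 1) < 0.08))
})
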