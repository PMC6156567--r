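#' Fit the linear Arrhenius model to rate constants
#'
#' Regresses `ln(k)` on `1/T`: the slope is `-Ea/R` and the intercept `ln(A)`,
#' with `R = 1.9872e-3` kcal mol^-1 K^-1 so activation energies come out in
#' kcal/mol. The default is ordinary least squares on `ln k` (the conventional
#' Arrhenius plot); optional per-point weights are passed straight to the
#' regression.
#'
#' @param temp_K temperatures in Kelvin (>= 3 distinct values)
#' @param rate rate constants in s^-1, all > 0
#' @param weights optional regression weights (same length as `rate`)
#' @return Object of class `arrhenius_fit`: `Ea` (kcal/mol), `lnA`, `se_Ea`,
#'   `se_lnA`, `cov_Ea_lnA`, the 2x2 covariance `vcov` on (lnA, Ea),
#'   `temperature_range`, `n_points`, `residuals`.
#' @examples
#' T <- seq(283, 323, 10)
#' k <- exp(15 - 10 / (1.9872e-3 * T))
#' fit_arrhenius(T, k)
#' @export
fit_arrhenius <- function(temp_K, rate, weights = NULL) {
  stopifnot(length(temp_K) == length(rate))
  if (any(temp_K <= 0)) stop("temperatures must be positive (Kelvin)")
  if (any(rate <= 0)) stop("all rates must be > 0 for the log-linear fit")
  if (length(unique(temp_K)) < 3)
    stop("need rates at >= 3 distinct temperatures (got ",
         length(unique(temp_K)), ")")

  x <- 1 / temp_K
  y <- log(rate)
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  cf <- coef(fit)
  ## noiseless series are legitimate input; vcov warns on zero residuals
  V <- suppressWarnings(vcov(fit))

  Ea <- -cf[[2]] * .R_GAS
  lnA <- cf[[1]]
  ## (lnA, Ea) covariance from (intercept, slope) covariance
  se_lnA <- sqrt(V[1, 1])
  se_Ea <- .R_GAS * sqrt(V[2, 2])
  cov_Ea_lnA <- -.R_GAS * V[1, 2]
  vc <- matrix(c(V[1, 1], cov_Ea_lnA, cov_Ea_lnA, se_Ea^2), 2, 2,
               dimnames = list(c("lnA", "Ea"), c("lnA", "Ea")))

  structure(list(Ea = Ea, lnA = lnA, se_Ea = se_Ea, se_lnA = se_lnA,
                 cov_Ea_lnA = cov_Ea_lnA, vcov = vc,
                 temperature_range = range(temp_K),
                 n_points = length(rate),
                 residuals = unname(stats::residuals(fit))),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.3g (%.2g) kcal/mol, lnA = %.3g (%.2g)  [n = %d, %g-%g K]\n",
              x$Ea, x$se_Ea, x$lnA, x$se_lnA, x$n_points,
              x$temperature_range[1], x$temperature_range[2]))
  invisible(x)
}

#' Evaluate an Arrhenius model at a temperature
#'
#' `k = exp(lnA - Ea / (R T))`.
#'
#' @param fit an `arrhenius_fit`, or a list with elements `Ea` and `lnA`
#' @param temp_K temperature(s) in Kelvin, > 0
#' @return rate constant(s) in s^-1
#' @export
evaluate_rate <- function(fit, temp_K) {
  if (any(temp_K <= 0)) stop("temperature must be > 0")
  exp(fit$lnA - fit$Ea / (.R_GAS * temp_K))
}

#' Decompose an H/D kinetic isotope effect from Arrhenius fits
#'
#' Splits a primary KIE into its activation-energy and pre-exponential
#' components: `delta_Ea = Ea(D) - Ea(H)`, `A_ratio = A_H/A_D =
#' exp(lnA_H - lnA_D)` and `KIE(T) = A_ratio * exp(delta_Ea / (R T))`, which
#' equals `k_H(T)/k_D(T)` by construction. Standard errors are propagated to
#' first order (delta method) from the full per-isotope fit covariances.
#'
#' @param fit_H,fit_D `arrhenius_fit` objects for the protiated and
#'   deuterated substrate
#' @param temp_K temperature at which to report the KIE (default 303 K, the
#'   temperature of the kinetic-constant determinations)
#' @return Object of class `kie_decomposition`: `delta_Ea`, `A_ratio`,
#'   `kie_at_T`, `temp_K`, and standard errors `se_delta_Ea`, `se_A_ratio`,
#'   `se_kie`.
#' @export
kie_decomposition <- function(fit_H, fit_D, temp_K = 303) {
  stopifnot(temp_K > 0)
  RT <- .R_GAS * temp_K
  delta_Ea <- fit_D$Ea - fit_H$Ea
  A_ratio <- exp(fit_H$lnA - fit_D$lnA)
  kie <- A_ratio * exp(delta_Ea / RT)

  se_delta_Ea <- sqrt(fit_H$se_Ea^2 + fit_D$se_Ea^2)
  se_lnAr <- sqrt(fit_H$se_lnA^2 + fit_D$se_lnA^2)
  se_A_ratio <- A_ratio * se_lnAr
  ## ln KIE = (lnA_H - Ea_H/RT) - (lnA_D - Ea_D/RT); per-isotope covariance
  ## between lnA and Ea enters with a cross term.
  vH <- fit_H$se_lnA^2 + (fit_H$se_Ea / RT)^2 - 2 * fit_H$cov_Ea_lnA / RT
  vD <- fit_D$se_lnA^2 + (fit_D$se_Ea / RT)^2 - 2 * fit_D$cov_Ea_lnA / RT
  se_kie <- kie * sqrt(pmax(vH, 0) + pmax(vD, 0))

  structure(list(delta_Ea = delta_Ea, A_ratio = A_ratio, kie_at_T = kie,
                 temp_K = temp_K, se_delta_Ea = se_delta_Ea,
                 se_A_ratio = se_A_ratio, se_kie = se_kie),
            class = "kie_decomposition")
}

#' @export
print.kie_decomposition <- function(x, ...) {
  cat(sprintf("KIE at %g K: %.3g (%.2g)\n", x$temp_K, x$kie_at_T, x$se_kie))
  cat(sprintf("  Ea(D)-Ea(H) = %.3g (%.2g) kcal/mol\n", x$delta_Ea, x$se_delta_Ea))
  cat(sprintf("  A_H/A_D     = %.3g (%.2g)\n", x$A_ratio, x$se_A_ratio))
  invisible(x)
}

#' KIE directly from printed Arrhenius components
#'
#' Convenience for consistency checks against tabulated values:
#' `KIE = A_ratio * exp(delta_Ea / (R T))`.
#'
#' @param delta_Ea `Ea(D) - Ea(H)` in kcal/mol
#' @param A_ratio `A_H / A_D`
#' @param temp_K temperature in Kelvin
#' @return the KIE `k_H/k_D` at `temp_K`
#' @export
kie_from_components <- function(delta_Ea, A_ratio, temp_K = 303) {
  stopifnot(temp_K > 0, A_ratio > 0)
  A_ratio * exp(delta_Ea / (.R_GAS * temp_K))
}

#' Per-variant KIE decomposition table
#'
#' Fits Arrhenius models for both isotopes of every variant present in a rate
#' table and decomposes the KIE of each. Variants missing one isotope series
#' are skipped with a warning. Output row order follows `variant_order` where
#' given (e.g. the evolutionary trajectory B, R1, R4...R7-2), otherwise the
#' sorted variant names, so shuffled input rows give identical output.
#'
#' @param rate_table data.frame with columns `variant`, `isotope` ("H"/"D"),
#'   `temp_K`, `rate_per_s` (already per-temperature rate constants, e.g. kcat)
#' @param temp_K temperature for the reported KIE column
#' @param variant_order optional character vector fixing row order
#' @return data.frame with one row per variant: Ea/lnA per isotope, delta_Ea,
#'   A_ratio, kie and standard errors; attribute `"fits"` holds the per-variant
#'   `arrhenius_fit` pairs.
#' @export
kie_table <- function(rate_table, temp_K = 303, variant_order = NULL) {
  stopifnot(all(c("variant", "isotope", "temp_K", "rate_per_s") %in% names(rate_table)))
  vars <- unique(as.character(rate_table$variant))
  vars <- if (is.null(variant_order)) sort(vars) else
    intersect(variant_order, vars)

  rows <- list(); fits <- list()
  for (v in vars) {
    d <- rate_table[rate_table$variant == v, ]
    if (!all(c("H", "D") %in% d$isotope)) {
      warning("variant ", v, " lacks an isotope series; skipped")
      next
    }
    dH <- d[d$isotope == "H", ]; dD <- d[d$isotope == "D", ]
    fH <- fit_arrhenius(dH$temp_K, dH$rate_per_s)
    fD <- fit_arrhenius(dD$temp_K, dD$rate_per_s)
    kd <- kie_decomposition(fH, fD, temp_K)
    fits[[v]] <- list(H = fH, D = fD, kie = kd)
    rows[[v]] <- data.frame(
      variant = v,
      Ea_H = fH$Ea, se_Ea_H = fH$se_Ea, Ea_D = fD$Ea, se_Ea_D = fD$se_Ea,
      lnA_H = fH$lnA, se_lnA_H = fH$se_lnA, lnA_D = fD$lnA, se_lnA_D = fD$se_lnA,
      delta_Ea = kd$delta_Ea, se_delta_Ea = kd$se_delta_Ea,
      A_ratio = kd$A_ratio, se_A_ratio = kd$se_A_ratio,
      kie = kd$kie_at_T, se_kie = kd$se_kie,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "temp_K") <- temp_K
  out
}

#' Published Arrhenius/KIE table for the KE07 trajectory
#'
#' The tabulated kinetic and Arrhenius parameters for the KE07 evolutionary
#' trajectory (buffer reaction B and variants R1-R7-2): kcat and KM for the
#' protiated substrate at 303 K, catalytic efficiency, activation energies and
#' pre-exponential factors for both isotopes, their isotope differences/ratios
#' and the observed KIE, each with its standard error. Used as an input for
#' internal-consistency checks of the decomposition identities.
#'
#' @return data.frame, one row per variant; `NA` where no value was reported.
#' @export
ke07_table <- function() {
  path <- system.file("extdata", "ke07_arrhenius_table1.tsv",
                      package = "kemptools", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
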