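#' Wigner tunneling correction
#'
#' Leading-order quantum correction for passage over a parabolic barrier:
#' `kappa = 1 + u^2 / 24` with `u = h c nu / (kB T) = 1.43877 nu / T` for a
#' wavenumber `nu` in cm^-1.
#'
#' @param freq_cm imaginary-frequency magnitude (cm^-1), > 0
#' @param temp_K temperature (K), > 0
#' @return transmission coefficient kappa (>= 1); vectorized over both inputs
#' @export
wigner_kappa <- function(freq_cm, temp_K) {
  if (any(freq_cm < 0) || any(temp_K <= 0))
    stop("frequency must be >= 0 and temperature > 0")
  u <- .HC_OVER_KB * freq_cm / temp_K
  1 + u^2 / 24
}

#' Specify a 1D Eckart barrier
#'
#' An asymmetric Eckart barrier characterized by its forward and reverse
#' barrier heights and the magnitude of the imaginary frequency at the top.
#' When `mass_amu` differs from the reference mass (e.g. deuterium), the
#' frequency is rescaled by `1/sqrt(mass ratio)` as for a pure
#' hydrogen-transfer mode.
#'
#' @param V1 forward barrier (kcal/mol), > 0
#' @param V2 reverse barrier (kcal/mol), > 0
#' @param freq_cm imaginary-frequency magnitude (cm^-1) for the reference
#'   particle, > 0
#' @param mass_amu transferring-particle mass (amu); default 1.008 (H)
#' @param ref_mass_amu mass to which `freq_cm` refers
#' @return object of class `barrier_spec` with the mass-scaled frequency
#' @export
barrier_spec <- function(V1, V2, freq_cm, mass_amu = 1.008,
                         ref_mass_amu = 1.008) {
  stopifnot(V1 > 0, V2 > 0, freq_cm > 0, mass_amu > 0)
  structure(list(V1 = V1, V2 = V2,
                 freq_cm = freq_cm / sqrt(mass_amu / ref_mass_amu),
                 mass_amu = mass_amu),
            class = "barrier_spec")
}

## Closed-form transmission probability for the asymmetric Eckart barrier,
## in the reduced parametrization a1 = 2 pi V1 / (h nu), a2 = 2 pi V2 / (h nu).
## E is measured from the reactant asymptote. Evaluated in log space to
## avoid cosh overflow.
.eckart_p <- function(E, V1, V2, hnu) {
  a1 <- 2 * pi * V1 / hnu
  a2 <- 2 * pi * V2 / hnu
  inv <- 1 / sqrt(a1) + 1 / sqrt(a2)
  d2 <- a1 * a2 - pi^2 / 4
  lcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)
  p <- numeric(length(E))
  xi <- E / V1
  ## transmission requires the product channel open: (xi-1) a1 + a2 > 0
  open <- E > 0 & (xi - 1) * a1 + a2 > 0
  if (!any(open)) return(p)
  a <- 2 * sqrt(a1 * xi[open]) / inv
  b <- 2 * sqrt((xi[open] - 1) * a1 + a2) / inv
  Lab <- lcosh(a + b)
  ## P = (cosh(a+b) - cosh(a-b)) / (cosh(a+b) + cosh(c)), c = 2 sqrt(d2);
  ## cosh(c) -> cos(2 sqrt(-d2)) for thin barriers (d2 < 0)
  num <- 1 - exp(lcosh(a - b) - Lab)
  den <- if (d2 >= 0) 1 + exp(lcosh(2 * sqrt(d2)) - Lab)
         else 1 + cos(2 * sqrt(-d2)) * exp(-Lab)
  p[open] <- num / den
  pmax(pmin(p, 1), 0)
}

#' Eckart tunneling coefficient
#'
#' Thermally averaged transmission through a 1D asymmetric Eckart barrier:
#' `kappa(T) = exp(V1 / kB T) * integral P(E) exp(-E / kB T) dE / kB T`
#' over `E >= 0` (energy zero at the reactant asymptote), with the
#' closed-form Eckart transmission probability `P(E)` and adaptive
#' quadrature to a relative tolerance of 1e-6. The integration upper limit
#' is `V1 + 40 kB T`.
#'
#' @param barrier a [barrier_spec()]
#' @param temp_K temperature (K)
#' @return list (class `tunneling_result`): `kappa`, `temp_K`, `method`,
#'   `flag` (non-NULL if the quadrature failed to converge)
#' @export
eckart_kappa <- function(barrier, temp_K) {
  stopifnot(inherits(barrier, "barrier_spec"), temp_K > 0)
  kT <- .R_GAS * temp_K
  hnu <- barrier$freq_cm * .HC_OVER_KB * .R_GAS  # h nu in kcal/mol
  upper <- barrier$V1 + 40 * kT
  integrand <- function(E)
    .eckart_p(E, barrier$V1, barrier$V2, hnu) * exp(-(E - barrier$V1) / kT)
  flag <- NULL
  val <- tryCatch(
    stats::integrate(integrand, 0, upper, rel.tol = 1e-6,
                     subdivisions = 500L)$value,
    error = function(e) {
      flag <<- paste("quadrature failed:", conditionMessage(e))
      NA_real_
    })
  structure(list(kappa = val / kT, temp_K = temp_K, method = "eckart",
                 barrier = barrier, flag = flag),
            class = "tunneling_result")
}

#' Tunneling coefficients over a temperature range
#'
#' @param barrier a [barrier_spec()] (ignored for `method = "wigner"` except
#'   for its frequency)
#' @param temps_K temperatures (K)
#' @param method `"eckart"` or `"wigner"`
#' @return data.frame with `temp_K` and `kappa`
#' @export
kappa_curve <- function(barrier, temps_K, method = c("eckart", "wigner")) {
  method <- match.arg(method)
  kap <- vapply(temps_K, function(T)
    if (method == "eckart") eckart_kappa(barrier, T)$kappa
    else wigner_kappa(barrier$freq_cm, T), 0)
  data.frame(temp_K = temps_K, kappa = kap)
}

#' Tunneling-corrected kinetic isotope effect
#'
#' `KIE_corr = (kappa_H / kappa_D) * KIE_classical`. A `kappa_H < kappa_D`
#' input violates the mass-scaling expectation for a hydrogen-transfer mode
#' and is flagged.
#'
#' @param classical_kie semiclassical KIE, > 0
#' @param kappa_H,kappa_D transmission coefficients, > 0
#' @return list: `kie` and `flag` (NULL, or a note when `kappa_H < kappa_D`)
#' @export
corrected_kie <- function(classical_kie, kappa_H, kappa_D) {
  stopifnot(classical_kie > 0, kappa_H > 0, kappa_D > 0)
  flag <- if (kappa_H < kappa_D)
    "kappa_H < kappa_D: inconsistent with mass-scaled frequencies" else NULL
  list(kie = (kappa_H / kappa_D) * classical_kie, flag = flag)
}
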