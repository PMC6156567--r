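#' Fit a Michaelis-Menten saturation curve
#'
#' Fits `v = kcat * S / (KM + S)` to background-subtracted turnover rates at a
#' single temperature, by nonlinear least squares on log-parameterized
#' `(kcat, KM)` so positivity is enforced by construction. Initial guesses come
#' from a double-reciprocal (Lineweaver-Burk) linearization.
#'
#' Rates are turnover numbers in s^-1 (observed velocity divided by enzyme
#' concentration). The uncatalyzed background is subtracted from every rate
#' before fitting, mirroring standard practice for slow spontaneous reactions.
#'
#' @param rates data.frame with columns `conc_mM` (substrate concentration, mM)
#'   and `rate` (s^-1). Replicates are simply additional rows.
#' @param background background reaction rate. Either a single rate (s^-1)
#'   subtracted from all points, a vector matching `nrow(rates)`, or a
#'   data.frame with columns `conc_mM`, `rate` that is linearly interpolated
#'   at the assay concentrations.
#' @return Object of class `mm_fit`: list with `kcat`, `KM` (mM), `se_kcat`,
#'   `se_KM`, `efficiency` (s^-1 M^-1, computed from the fitted, not rounded,
#'   values), `background_rate`, `converged`, `n`, and the fit `vcov` on the
#'   log scale.
#' @examples
#' s <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8, 1.1)
#' v <- 1.43 * s / (0.53 + s)
#' fit <- fit_michaelis_menten(data.frame(conc_mM = s, rate = v))
#' c(fit$kcat, fit$KM)
#' @export
fit_michaelis_menten <- function(rates, background = 0) {
  stopifnot(is.data.frame(rates), all(c("conc_mM", "rate") %in% names(rates)))
  s <- rates$conc_mM
  if (any(s < 0)) stop("substrate concentrations must be >= 0")
  if (length(unique(s)) < 5)
    stop("need at least 5 distinct substrate concentrations (got ",
         length(unique(s)), ")")

  bg <- .background_at(background, s)
  v <- rates$rate - bg
  if (all(v <= 0) || max(v) < 1e-12 * max(abs(rates$rate), 1e-300))
    stop("no signal above background: all background-subtracted rates <= 0")

  keep <- v > 0 & s > 0
  if (sum(keep) < 5) stop("fewer than 5 usable points after background subtraction")
  sv <- s[keep]; vv <- v[keep]

  ## Lineweaver-Burk start values: 1/v = (KM/kcat)(1/S) + 1/kcat
  lb <- stats::lm(I(1 / vv) ~ I(1 / sv))
  kcat0 <- 1 / coef(lb)[[1]]
  KM0 <- coef(lb)[[2]] * kcat0
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(vv)
  if (!is.finite(KM0) || KM0 <= 0) KM0 <- stats::median(sv)

  fit <- try(minpack.lm::nlsLM(
    vv ~ exp(lk) * sv / (exp(lK) + sv),
    start = list(lk = log(kcat0), lK = log(KM0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  if (inherits(fit, "try-error")) {
    return(structure(list(kcat = NA_real_, KM = NA_real_, se_kcat = NA_real_,
                          se_KM = NA_real_, efficiency = NA_real_,
                          background_rate = bg, converged = FALSE,
                          diagnostics = attr(fit, "condition")$message,
                          n = length(vv)),
                     class = "mm_fit"))
  }

  cf <- coef(fit)
  kcat <- exp(cf[["lk"]]); KM <- exp(cf[["lK"]])
  V <- suppressWarnings(vcov(fit))
  ## delta method back from log scale
  se_kcat <- kcat * sqrt(V["lk", "lk"])
  se_KM <- KM * sqrt(V["lK", "lK"])
  structure(list(kcat = kcat, KM = KM, se_kcat = se_kcat, se_KM = se_KM,
                 efficiency = kcat / (KM * 1e-3),
                 background_rate = bg, converged = TRUE,
                 vcov_log = V, n = length(vv)),
            class = "mm_fit")
}

.background_at <- function(background, s) {
  if (is.data.frame(background)) {
    stopifnot(all(c("conc_mM", "rate") %in% names(background)))
    stats::approx(background$conc_mM, background$rate, xout = s, rule = 2)$y
  } else if (length(background) == 1L) {
    if (background < 0) stop("background rate must be >= 0")
    rep(background, length(s))
  } else if (length(background) == length(s)) {
    background
  } else {
    stop("background must be scalar, per-row vector, or data.frame(conc_mM, rate)")
  }
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit: NOT CONVERGED (", x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Michaelis-Menten fit (n = %d)\n", x$n))
  cat(sprintf("  kcat    = %.4g (%.2g) s^-1\n", x$kcat, x$se_kcat))
  cat(sprintf("  KM      = %.4g (%.2g) mM\n", x$KM, x$se_KM))
  cat(sprintf("  kcat/KM = %.4g s^-1 M^-1\n", x$efficiency))
  invisible(x)
}

#' Catalytic efficiency from a turnover number and a Michaelis constant
#'
#' `kcat / KM` with `KM` converted from mM to M, so the result is in
#' s^-1 M^-1 as conventionally tabulated.
#'
#' @param kcat turnover number, s^-1
#' @param KM_mM Michaelis constant, mM
#' @return efficiency in s^-1 M^-1
#' @export
catalytic_efficiency <- function(kcat, KM_mM) {
  stopifnot(kcat > 0, KM_mM > 0)
  kcat / (KM_mM * 1e-3)
}
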