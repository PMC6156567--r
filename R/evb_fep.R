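#' Free energy along the mapping schedule (FEP)
#'
#' Zwanzig exponential averaging between adjacent mapping frames:
#' `dG(m -> m+1) = -kT ln < exp(-beta (E_{m+1} - E_m)) >_m`, with
#' `E_{m+1} - E_m = -(lambda_{m+1} - lambda_m) * X` computed from the stored
#' gap samples, accumulated and referenced to `lambda = 0`. The default is
#' forward-only averaging; `bidirectional = TRUE` averages the forward
#' estimate with the reverse estimate from the target frame's samples.
#'
#' @param frames list of [mapping_frame()] objects with increasing lambda
#' @param temp_K temperature (K)
#' @param bidirectional average forward and reverse window estimates
#' @param min_ess effective-sample-size fraction below which a window
#'   warning is recorded
#' @return data.frame (class `fep_result`) with `lambda`, `dG` (cumulative,
#'   kcal/mol), per-window `dG_window` and `ess_frac`; attribute `"warnings"`
#'   lists low-overlap windows
#' @export
fep_free_energy <- function(frames, temp_K = 300, bidirectional = FALSE,
                            min_ess = 0.1) {
  stopifnot(length(frames) >= 2)
  lams <- vapply(frames, function(f) f$lambda, 0)
  stopifnot(all(diff(lams) > 0))
  beta <- 1 / (.R_GAS * temp_K)
  nw <- length(frames) - 1
  dGw <- ess <- numeric(nw)
  warn <- character(0)
  for (m in seq_len(nw)) {
    dlam <- lams[m + 1] - lams[m]
    sm <- frames[[m]]$samples
    du_f <- -dlam * sm$gap          # E_{m+1} - E_m on frame-m samples
    wf <- sm$weight
    lw <- -beta * du_f + log(wf)
    M <- max(lw)
    dG_f <- -(M + log(sum(exp(lw - M))) - log(sum(wf))) / beta
    ## ESS fraction of the exponential weights
    w <- exp(lw - M)
    ess[m] <- (sum(w)^2 / sum(w^2)) / length(w)
    if (bidirectional) {
      sp <- frames[[m + 1]]$samples
      du_r <- dlam * sp$gap         # E_m - E_{m+1} on frame-(m+1) samples
      lwr <- -beta * du_r + log(sp$weight)
      Mr <- max(lwr)
      dG_r <- (Mr + log(sum(exp(lwr - Mr))) - log(sum(sp$weight))) / beta
      dGw[m] <- 0.5 * (dG_f + dG_r)
    } else {
      dGw[m] <- dG_f
    }
    if (ess[m] < min_ess)
      warn <- c(warn, sprintf("window %d (lambda %.3f -> %.3f): ESS fraction %.3f",
                              m, lams[m], lams[m + 1], ess[m]))
  }
  out <- data.frame(lambda = lams, dG = c(0, cumsum(dGw)),
                    dG_window = c(NA, dGw), ess_frac = c(NA, ess))
  class(out) <- c("fep_result", "data.frame")
  attr(out, "warnings") <- warn
  for (w in warn) warning(w, call. = FALSE)
  out
}

#' Free-energy profile along the energy-gap coordinate (FEP/US)
#'
#' Assembles the EVB ground-state free energy `dg(X)` on the gap coordinate
#' `X = e1 - e2p` by the umbrella-sampling correction: within each mapping
#' frame the bin estimate is
#' `dg_mb = dG(lambda_m) - kT ln( <delta_b exp(-beta (Eg - Em))>_m )`,
#' and bins are combined across frames weighted by their sample counts.
#' The profile is referenced to the reactant minimum; the transition-state
#' bin is the maximum of `dg` between the reactant and product minima.
#'
#' @param frames list of [mapping_frame()] objects spanning both basins
#' @param temp_K temperature (K)
#' @param bin_width gap-bin width (kcal/mol)
#' @param min_count minimum (weighted) samples for a reported bin
#' @param fep optional precomputed [fep_free_energy()] result
#' @param bidirectional passed to [fep_free_energy()]
#' @return object of class `free_energy_profile`: data.frame `profile`
#'   (`X`, `dg`, `count`), `dG_barrier`, `dG_reaction`, indices of the
#'   reactant/TS/product bins, and `flags`
#' @export
umbrella_profile <- function(frames, temp_K = 300, bin_width = 2,
                             min_count = 10, fep = NULL,
                             bidirectional = FALSE) {
  stopifnot(length(frames) >= 2, bin_width > 0)
  gaps <- unlist(lapply(frames, function(f) f$samples$gap))
  if (min(gaps) >= 0 || max(gaps) <= 0)
    stop("mapping frames do not span both basins: gap never changes sign")
  if (is.null(fep))
    fep <- suppressWarnings(fep_free_energy(frames, temp_K, bidirectional))
  beta <- 1 / (.R_GAS * temp_K)

  edges <- seq(floor(min(gaps) / bin_width) * bin_width,
               ceiling(max(gaps) / bin_width) * bin_width, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  nb <- length(centers)
  num <- den <- tot <- numeric(nb)   # accumulators per bin

  for (m in seq_along(frames)) {
    sm <- frames[[m]]$samples
    b <- findInterval(sm$gap, edges, rightmost.closed = TRUE)
    b[b < 1] <- 1; b[b > nb] <- nb
    w <- sm$weight
    ## scale weights so each frame contributes its nominal sample count
    w <- w / sum(w) * length(w)
    lfac <- -beta * (sm$eg - sm$em)
    M <- max(lfac)
    contrib <- w * exp(lfac - M)
    S_mb <- vapply(seq_len(nb), function(k) sum(contrib[b == k]), 0)
    n_mb <- vapply(seq_len(nb), function(k) sum(w[b == k]), 0)
    N_m <- sum(w)
    nz <- S_mb > 0
    dg_mb <- rep(NA_real_, nb)
    dg_mb[nz] <- fep$dG[m] - (log(S_mb[nz] / N_m) + M) / beta
    num[nz] <- num[nz] + n_mb[nz] * dg_mb[nz]
    den[nz] <- den[nz] + n_mb[nz]
    tot <- tot + n_mb
  }

  keep <- den > 0 & tot >= min_count
  prof <- data.frame(X = centers[keep], dg = num[keep] / den[keep],
                     count = tot[keep])
  if (nrow(prof) < 3) stop("too few populated gap bins for a profile")

  flags <- character(0)
  ir_side <- which(prof$X < 0)
  ip_side <- which(prof$X > 0)
  if (!length(ir_side) || !length(ip_side))
    stop("empty reactant or product region on the gap coordinate")
  ir <- ir_side[which.min(prof$dg[ir_side])]
  ip <- ip_side[which.min(prof$dg[ip_side])]
  between <- seq(min(ir, ip), max(ir, ip))
  its <- between[which.max(prof$dg[between])]
  if (its == ir || its == ip) {
    flags <- c(flags, "no barrier: profile monotone between basin minima")
    dgb <- NA_real_
  } else {
    dgb <- prof$dg[its] - prof$dg[ir]
  }
  prof$dg <- prof$dg - prof$dg[ir]
  dg0 <- prof$dg[ip]

  structure(list(profile = prof, dG_barrier = dgb, dG_reaction = dg0,
                 reactant_bin = ir, ts_bin = its, product_bin = ip,
                 temp_K = temp_K, bin_width = bin_width,
                 fep = fep, flags = flags),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("EVB free-energy profile (%d bins of %.2g kcal/mol)\n",
              nrow(x$profile), x$bin_width))
  cat(sprintf("  dG_barrier  = %.2f kcal/mol\n", x$dG_barrier))
  cat(sprintf("  dG_reaction = %.2f kcal/mol\n", x$dG_reaction))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Re-evaluate mapping frames under a new coupling
#'
#' Because the mapping potential depends on the gas-phase shift only through
#' a per-frame constant (which does not alter forces) and not on `H12` at
#' all, stored samples can be re-evaluated exactly under any candidate
#' `(H12, alpha)` without re-simulation. This is the screening step of the
#' calibration loop.
#'
#' @param frames list of [mapping_frame()] objects
#' @param h12 new constant coupling (kcal/mol)
#' @param alpha new gas-phase shift (kcal/mol)
#' @param alpha_old the shift in effect when the frames were generated
#' @return new list of frames with energies under `(h12, alpha)`
#' @export
reweight_frames <- function(frames, h12, alpha, alpha_old) {
  lapply(frames, function(f) {
    s <- f$samples
    e2p_new <- s$e2p - alpha_old + alpha
    mapping_frame(f$lambda, s$e1, e2p_new, h12,
                  ke = s$ke, weight = s$weight)
  })
}

#' Pool mapping frames from replicate trajectories
#'
#' Concatenates, per mapping frame, the samples of several independent
#' FEP runs over the same lambda schedule. Because the mapping forces do
#' not depend on the coupling (`H12` never enters the mapping potential and
#' the gas shift only adds a per-frame constant), runs generated under
#' different couplings sample the same ensembles and pool exactly. Samples
#' are stored with the gas shift removed (`alpha = 0` convention) so the
#' pooled frames can be re-evaluated under any candidate coupling.
#'
#' @param runs list of frame lists (each as returned by [run_evb_fep()])
#' @param alphas gas shift in effect when each run was generated
#' @return single list of [mapping_frame()] objects with `h12 = 0`,
#'   `alpha = 0` energies
#' @export
merge_mapping_frames <- function(runs, alphas = vapply(runs, function(r)
  attr(r, "alpha") %||% 0, 0)) {
  stopifnot(length(runs) >= 1, length(alphas) == length(runs))
  nl <- length(runs[[1]])
  lapply(seq_len(nl), function(m) {
    lam <- runs[[1]][[m]]$lambda
    e1 <- unlist(lapply(runs, function(r) r[[m]]$samples$e1))
    e2r <- unlist(lapply(seq_along(runs), function(k)
      runs[[k]][[m]]$samples$e2p - alphas[k]))
    w <- unlist(lapply(runs, function(r) r[[m]]$samples$weight))
    mapping_frame(lam, e1, e2r, 0, weight = w)
  })
}

#' Calibrate the EVB coupling against a reference reaction
#'
#' Adjusts the constant off-diagonal coupling `H12` and the gas-phase shift
#' `alpha` of a two-state system until the FEP/US profile recomputed from
#' the simulation data reproduces target activation and reaction free
#' energies (for Kemp elimination, the aqueous-solution reference barrier
#' of 21.2 kcal/mol).
#'
#' Each outer iteration runs `n_traj` independent mapping series (fresh
#' velocities each), pools them with all frames accumulated so far, and
#' solves for `(H12, alpha)` on the pooled samples by exact re-evaluation
#' ([reweight_frames()]) with a Nelder-Mead search; because neither
#' parameter alters the sampled trajectories, this screening step is exact
#' rather than an importance-sampling approximation, and the profile
#' recomputed at the solved parameters meets the targets whenever the
#' response surface can reach them. A further outer iteration (adding
#' simulation data) is only taken if the solve fails, so a calibration
#' started from converged parameters terminates after one outer iteration.
#'
#' @param system toy solution-reference [evb_system()]
#' @param target_dG_barrier target activation free energy (kcal/mol)
#' @param target_dG_reaction target reaction free energy (kcal/mol);
#'   not experimentally pinned for this reference, so it is an explicit
#'   config input
#' @param tol acceptable absolute deviation on both targets (kcal/mol)
#' @param n_traj replicate trajectories pooled per outer iteration
#' @param max_outer maximum outer (re-simulation) iterations
#' @param lambdas,n_steps,dt,temp_K,stride,equil_steps simulation settings
#'   passed to [run_evb_fep()]
#' @param bin_width,min_count profile settings passed to [umbrella_profile()]
#' @param verbose print the convergence trace
#' @return list: `coupling` (converged `h12`, `alpha`), `profile`
#'   (recomputed from the pooled frames under the converged coupling),
#'   `converged`, `trace` (data.frame of evaluations), `frames` (pooled,
#'   alpha = 0 convention), `system` (with the converged coupling)
#' @export
calibrate_reference <- function(system, target_dG_barrier = 21.2,
                                target_dG_reaction = 5,
                                tol = 0.3, n_traj = 3, max_outer = 3,
                                lambdas = lambda_schedule(51),
                                n_steps = 4000, dt = 1, temp_K = 300,
                                stride = 5, equil_steps = 500,
                                bin_width = 2, min_count = 10,
                                verbose = FALSE) {
  stopifnot(is.finite(target_dG_barrier), is.finite(target_dG_reaction))
  h12 <- system$coupling$h12 %||% 0
  alpha <- system$coupling$alpha %||% 0
  trace <- data.frame()
  pooled <- NULL

  measure <- function(frames, h12c, alphac) {
    fr <- reweight_frames(frames, h12c, alphac, 0)
    p <- suppressWarnings(umbrella_profile(fr, temp_K, bin_width, min_count))
    if (length(p$flags)) c(barrier = NA_real_, reaction = NA_real_)
    else c(barrier = p$dG_barrier, reaction = p$dG_reaction)
  }
  note <- function(outer, stage, h, a, got) {
    trace <<- rbind(trace, data.frame(
      outer = outer, stage = stage, h12 = h, alpha = a,
      dG_barrier = unname(got["barrier"]), dG_reaction = unname(got["reaction"])))
    if (verbose)
      message(sprintf("outer %d [%s]: H12 = %.3f, alpha = %.3f -> barrier %.2f, dG0 %.2f",
                      outer, stage, h, a, got["barrier"], got["reaction"]))
  }
  finish <- function(converged) {
    system$coupling$h12 <- h12
    system$coupling$alpha <- alpha
    prof <- tryCatch(suppressWarnings(umbrella_profile(
      reweight_frames(pooled, h12, alpha, 0), temp_K, bin_width, min_count)),
      error = function(e) NULL)
    list(coupling = list(h12 = h12, alpha = alpha), profile = prof,
         converged = converged, trace = trace, frames = pooled,
         system = system)
  }

  for (outer in seq_len(max_outer)) {
    system$coupling$h12 <- h12
    system$coupling$alpha <- alpha
    runs <- lapply(seq_len(n_traj), function(i)
      run_evb_fep(system, lambdas, n_steps, dt, temp_K,
                  stride = stride, equil_steps = equil_steps))
    new_frames <- merge_mapping_frames(runs, rep(alpha, n_traj))
    pooled <- if (is.null(pooled)) new_frames else
      merge_mapping_frames(list(pooled, new_frames), c(0, 0))

    got <- tryCatch(measure(pooled, h12, alpha),
                    error = function(e) c(barrier = NA_real_, reaction = NA_real_))
    note(outer, "measure", h12, alpha, got)
    if (all(is.finite(got)) &&
        abs(got["barrier"] - target_dG_barrier) <= tol &&
        abs(got["reaction"] - target_dG_reaction) <= tol)
      return(finish(TRUE))

    obj <- function(par) {
      g <- tryCatch(measure(pooled, abs(par[1]), par[2]),
                    error = function(e) c(barrier = NA_real_, reaction = NA_real_))
      if (!all(is.finite(g))) return(1e6)
      (g["barrier"] - target_dG_barrier)^2 +
        (g["reaction"] - target_dG_reaction)^2
    }
    start <- c(max(h12, 1), alpha + target_dG_reaction -
                 (if (is.finite(got["reaction"])) got["reaction"] else 0))
    if (obj(start) >= 1e6) {
      ## coarse feasibility scan for a usable starting point
      grid <- expand.grid(h = c(0, 2, 5, 10), a = seq(alpha - 40, alpha + 40, 10))
      vals <- apply(grid, 1, function(g) obj(c(g[1], g[2])))
      if (min(vals) < 1e6) start <- as.numeric(grid[which.min(vals), ])
    }
    opt <- stats::optim(unname(start), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    h12 <- unname(abs(opt$par[1])); alpha <- unname(opt$par[2])
    got <- tryCatch(measure(pooled, h12, alpha),
                    error = function(e) c(barrier = NA_real_, reaction = NA_real_))
    note(outer, "solve", h12, alpha, got)
    if (all(is.finite(got)) &&
        abs(got["barrier"] - target_dG_barrier) <= tol &&
        abs(got["reaction"] - target_dG_reaction) <= tol)
      return(finish(TRUE))
  }
  warning("calibration did not converge within ", max_outer, " outer iterations")
  finish(FALSE)
}
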