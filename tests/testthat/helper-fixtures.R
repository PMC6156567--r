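## Shared, lazily built fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

## A small equilibrated water droplet with the donor-H-acceptor triad.
eq_droplet <- function() {
  if (is.null(.fixtures$droplet)) {
    set.seed(99)
    s <- gen_toy_evb_system(seed = 2, droplet_radius = 6.5)
    s <- minimize_system(s, 0, 300)
    .fixtures$droplet <- equilibration_protocol(s)
  }
  .fixtures$droplet
}

## Gas-phase triad (no waters): cheap system for force/energy checks.
gas_triad <- function() {
  if (is.null(.fixtures$triad)) {
    s <- gen_toy_evb_system(seed = 1, n_waters = 0)
    .fixtures$triad <- minimize_system(s, 0, 100)
  }
  .fixtures$triad
}

## Independent brute-force Daura clustering used as an oracle.
brute_daura <- function(frames, cutoff, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(frames[[1]]))
  nf <- length(frames)
  rms <- outer(seq_len(nf), seq_len(nf), Vectorize(function(i, j)
    kabsch_rmsd(frames[[i]][selection, , drop = FALSE],
                frames[[j]][selection, , drop = FALSE])))
  left <- seq_len(nf)
  out <- list()
  while (length(left)) {
    counts <- vapply(left, function(i) sum(rms[i, left] <= cutoff), 0L)
    ctr <- left[which.max(counts)]
    mem <- left[rms[ctr, left] <= cutoff]
    out[[length(out) + 1]] <- list(centroid = ctr, members = mem)
    left <- setdiff(left, mem)
  }
  out
}

R_GAS <- 1.9872e-3
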