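# Metropolis Monte Carlo sampling of near-native dynamics.

#' Simulation parameters
#'
#' Defaults: 2000 recorded snapshots, one Monte Carlo sweep (n_residues
#' attempted moves) between snapshots, 100 discarded equilibration sweeps,
#' temperature 1.0 in reduced units. Move amplitudes are the half-widths of
#' the uniform displacement cube in Angstrom.
#'
#' @param temperature Reduced temperature (> 0).
#' @param n_snapshots Number of recorded trajectory frames.
#' @param cycles_between_snapshots Sweeps between consecutive snapshots.
#' @param equilibration_cycles Discarded initial sweeps.
#' @param amp_single Amplitude of single/two-residue moves, Angstrom.
#' @param amp_terminal Amplitude of terminal-residue moves, Angstrom.
#' @param seed Integer RNG seed recorded in trajectory provenance.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(temperature = 1.0, n_snapshots = 2000,
                       cycles_between_snapshots = 1,
                       equilibration_cycles = 100,
                       amp_single = 0.5, amp_terminal = 1.0, seed = 1) {
  stopifnot(temperature > 0, n_snapshots >= 1, cycles_between_snapshots >= 1,
            equilibration_cycles >= 0, amp_single >= 0, amp_terminal >= 0)
  structure(list(temperature = temperature, n_snapshots = n_snapshots,
                 cycles_between_snapshots = cycles_between_snapshots,
                 equilibration_cycles = equilibration_cycles,
                 amp_single = amp_single, amp_terminal = amp_terminal,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Propose one small local move
#'
#' Draws a move from the mixture 80% single-residue displacement, 15%
#' two-residue segment displacement, 5% terminal-residue displacement; the
#' displacement vector is uniform in a cube of the given amplitude, so the
#' proposal is symmetric and preserves detailed balance. Uses (and advances)
#' R's global RNG stream.
#'
#' @param ca Calpha coordinate matrix (n x 3).
#' @param amp_single,amp_terminal Move amplitudes, Angstrom.
#' @return List with `ca` (new coordinates) and `move` (descriptor: type,
#'   residues, delta).
#' @export
propose_move <- function(ca, amp_single = 0.5, amp_terminal = 1.0) {
  n <- nrow(ca)
  u <- runif(1)
  if (u < 0.8 || n < 2) {
    type <- "single"
    k <- sample.int(n, 1)
    residues <- k
    amp <- amp_single
  } else if (u < 0.95) {
    type <- "pair"
    k <- sample.int(n - 1, 1)
    residues <- c(k, k + 1)
    amp <- amp_single
  } else {
    type <- "terminal"
    residues <- if (runif(1) < 0.5) 1L else n
    amp <- amp_terminal
  }
  delta <- runif(3, -amp, amp)
  new_ca <- ca
  new_ca[residues, ] <- new_ca[residues, , drop = FALSE] +
    rep(delta, each = length(residues))
  list(ca = new_ca,
       move = list(type = type, residues = residues, delta = delta))
}

#' Metropolis acceptance rule
#'
#' Accepts downhill moves always and uphill moves with probability
#' exp(-(e_new - e_old) / temperature). Uses R's global RNG stream.
#'
#' @param e_old,e_new Total energies of the current and proposed states.
#' @param temperature Reduced temperature (> 0).
#' @return Logical.
#' @export
metropolis_accept <- function(e_old, e_new, temperature) {
  if (!is.finite(e_old) || !is.finite(e_new))
    stop("energies must be finite", call. = FALSE)
  if (temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  if (e_new <= e_old) return(TRUE)
  runif(1) < exp(-(e_new - e_old) / temperature)
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Samples near-native dynamics of the coarse-grained chain: after the
#' equilibration sweeps (discarded), one Calpha frame is recorded every
#' `cycles_between_snapshots` sweeps until `n_snapshots` frames are collected.
#' Proposals that would push a Calpha pseudo-bond outside [3.2, 4.2] Angstrom
#' are pre-filtered and counted as rejected. The same seed reproduces the
#' trajectory bit-for-bit.
#'
#' @param cg A `cg_chain` from [build_cg()].
#' @param restraints A `restraint_set` from [derive_restraints()].
#' @param eparams An `energy_params` object.
#' @param sparams A `sim_params` object.
#' @return An object of class `cabs_trajectory`: `frames` (list of n x 3
#'   Calpha matrices), `energies` (data frame of per-frame weighted
#'   components), `acceptance_rate`, `params`, `sequence`, `ss`,
#'   `provenance`.
#' @export
run_simulation <- function(cg, restraints, eparams = default_energy_params(),
                           sparams = sim_params()) {
  stopifnot(inherits(cg, "cg_chain"), inherits(sparams, "sim_params"))
  eparams <- validate_energy_params(eparams)
  n <- cg$n_residues
  ssc <- ss_codes(cg$ss)
  aa <- aa_index(cg$sequence)
  scd <- sc_pseudo_distance(cg$sequence)
  rmat <- restraint_matrix(restraints)
  plist <- unclass(eparams)

  set.seed(sparams$seed)
  ca <- cg$ca
  e_raw <- cpp_energy_ca(ca, scd, ssc, aa, eparams$pair_eps, rmat, plist)
  e_cur <- sum(eparams$weights * e_raw)

  frames <- vector("list", sparams$n_snapshots)
  energies <- matrix(NA_real_, sparams$n_snapshots, 6)
  attempted <- 0L
  accepted <- 0L

  sweep <- function() {
    for (m in seq_len(n)) {
      attempted <<- attempted + 1L
      prop <- propose_move(ca, sparams$amp_single, sparams$amp_terminal)
      if (!bonds_ok(prop$ca, prop$move$residues)) next
      e_new_raw <- cpp_energy_ca(prop$ca, scd, ssc, aa, eparams$pair_eps,
                                 rmat, plist)
      e_new <- sum(eparams$weights * e_new_raw)
      if (metropolis_accept(e_cur, e_new, sparams$temperature)) {
        ca <<- prop$ca
        e_cur <<- e_new
        e_raw <<- e_new_raw
        accepted <<- accepted + 1L
      }
    }
  }
  bonds_ok <- function(m, residues) {
    for (r in residues) {
      for (b in c(r - 1L, r)) {
        if (b < 1L || b >= n) next
        d2 <- sum((m[b + 1L, ] - m[b, ])^2)
        if (d2 < 3.2^2 || d2 > 4.2^2) return(FALSE)
      }
    }
    TRUE
  }

  for (s in seq_len(sparams$equilibration_cycles)) sweep()
  for (f in seq_len(sparams$n_snapshots)) {
    for (s in seq_len(sparams$cycles_between_snapshots)) sweep()
    check_bond_invariant(ca)
    frames[[f]] <- ca
    wcomp <- eparams$weights * e_raw
    energies[f, ] <- c(wcomp, sum(wcomp))
  }

  energies <- as.data.frame(energies)
  names(energies) <- c("e_short", "e_pair", "e_hbond", "e_restraint",
                       "e_excluded", "e_total")
  structure(list(frames = frames, energies = energies,
                 acceptance_rate = accepted / attempted,
                 params = sparams, sequence = cg$sequence, ss = cg$ss,
                 provenance = list(seed = sparams$seed, n_residues = n,
                                   input_checksum = sprintf("%.6f", sum(cg$ca)))),
            class = "cabs_trajectory")
}

check_bond_invariant <- function(ca) {
  n <- nrow(ca)
  if (n < 2) return(invisible(TRUE))
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(d < 3.2 | d > 4.2))
    stop("internal consistency error: recorded frame violates the pseudo-bond window",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cabs_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d residues, acceptance %.2f, T = %.2f, seed %d\n",
              length(x$frames), x$provenance$n_residues, x$acceptance_rate,
              x$params$temperature, x$provenance$seed))
  invisible(x)
}

# frames as an M x (3n) matrix (rows are flattened frames, xyz fastest)
frames_matrix <- function(frames) {
  do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
}

matrix_to_frames <- function(m) {
  lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], ncol = 3, byrow = TRUE))
}

#' Write a trajectory as a multi-model Calpha PDB file
#'
#' @param traj A `cabs_trajectory`.
#' @param path Output path.
#' @param bfactors Optional per-residue values for the temperature-factor
#'   column.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path, bfactors = NULL) {
  write_models(traj$frames, ca_atom_spec(traj$sequence), path,
               bfactors = bfactors)
}
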