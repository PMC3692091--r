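# End-to-end pipeline: read -> validate -> secondary structure -> CG model ->
# restraints -> Monte Carlo -> fluctuation profile -> clustering -> ranked
# medoids -> backbone reconstruction -> superpositions -> writers.

#' Pipeline configuration
#'
#' @param input Path to the input PDB file (or PDB text).
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; the simulation uses it directly and the
#'   clustering derives its own stream from it.
#' @param n_snapshots Trajectory length (default 2000).
#' @param k_clusters Number of output models (default 10).
#' @param temperature Reduced simulation temperature.
#' @param cycles_between_snapshots,equilibration_cycles See [sim_params()].
#' @param restraint_args Named list of overrides for [derive_restraints()].
#' @param energy_args Named list of overrides for [default_energy_params()].
#' @param verbose Print stage banners to the console as well as the log.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, outdir, seed = 1, n_snapshots = 2000,
                            k_clusters = 10, temperature = 1.0,
                            cycles_between_snapshots = 1,
                            equilibration_cycles = 100,
                            restraint_args = list(), energy_args = list(),
                            verbose = FALSE) {
  structure(list(input = input, outdir = outdir, seed = as.integer(seed),
                 n_snapshots = n_snapshots, k_clusters = k_clusters,
                 temperature = temperature,
                 cycles_between_snapshots = cycles_between_snapshots,
                 equilibration_cycles = equilibration_cycles,
                 restraint_args = restraint_args, energy_args = energy_args,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full flexibility pipeline
#'
#' Executes every stage on the input structure and writes the output layout
#' into `outdir`: `trajectory.pdb` (Calpha trace, one MODEL per snapshot),
#' `model_1.pdb` .. `model_k.pdb` (backbone + Cbeta representatives, ranked
#' by cluster density, with the fluctuation profile in the temperature-factor
#' column), `fluctuations.txt`, `clusters.txt`, `restraints.txt`,
#' `ensemble_superposed.pdb` (maximum-likelihood superposition of all
#' models), `ensemble_with_input.pdb` (models plus the input structure),
#' `rmsd_to_input.txt` (pairwise least-squares RMSD of each model to the
#' input), `config.txt` and `run.log`. With the same configuration and seed
#' the text outputs (log excepted, which carries timestamps) are
#' byte-identical across runs.
#'
#' @param config A `pipeline_config`.
#' @return An object of class `flexens_result` collecting the validated
#'   chain, secondary structure, restraints, trajectory, fluctuation
#'   profile, cluster result, ranked ensemble with rebuilt backbones, and
#'   superposition results. A validation failure signals a condition of
#'   class `flexens_validation_error`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  cat("", file = logfile)
  log_msg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    if (config$verbose) message(line)
  }

  log_msg("stage: read + validate (%s)", config$input)
  raw <- read_structure(config$input)
  vc <- validate_chain(raw)
  if (!vc$report$accepted) {
    msgs <- paste(sprintf("[%s] %s", vc$report$violations$rule,
                          vc$report$violations$message), collapse = "; ")
    log_msg("validation failed: %s", msgs)
    stop(structure(class = c("flexens_validation_error", "error", "condition"),
                   list(message = paste("input rejected:", msgs),
                        call = sys.call(-1), report = vc$report)))
  }
  chain <- vc$chain
  log_msg("chain %s: %d residues", chain$chain_id, chain$n_residues)

  log_msg("stage: secondary structure")
  ss <- assign_ss(chain)
  log_msg("ss: %s", ss)

  log_msg("stage: coarse-grained model + restraints")
  cg <- build_cg(chain, ss)
  restraints <- do.call(derive_restraints, c(list(cg), config$restraint_args))
  write_restraints(restraints, file.path(config$outdir, "restraints.txt"))
  log_msg("%d near-native restraints", nrow(restraints))

  eparams <- do.call(default_energy_params, config$energy_args)
  sparams <- sim_params(temperature = config$temperature,
                        n_snapshots = config$n_snapshots,
                        cycles_between_snapshots = config$cycles_between_snapshots,
                        equilibration_cycles = config$equilibration_cycles,
                        seed = config$seed)
  log_msg("stage: Monte Carlo simulation (%d snapshots, T = %.2f, seed %d)",
          sparams$n_snapshots, sparams$temperature, sparams$seed)
  traj <- run_simulation(cg, restraints, eparams, sparams)
  log_msg("acceptance rate %.3f, final E %.3f", traj$acceptance_rate,
          traj$energies$e_total[nrow(traj$energies)])
  write_trajectory(traj, file.path(config$outdir, "trajectory.pdb"))

  log_msg("stage: fluctuation profile")
  profile <- compute_msf(traj)
  write_fluctuations(profile, file.path(config$outdir, "fluctuations.txt"))

  k <- min(config$k_clusters, length(traj$frames))
  log_msg("stage: clustering (k = %d)", k)
  cr <- cluster_frames(traj, k = k, seed = config$seed)
  write_cluster_report(cr, file.path(config$outdir, "clusters.txt"))
  ensemble <- rank_and_extract(cr, traj)

  log_msg("stage: backbone reconstruction of %d representatives", k)
  spec <- backbone_atom_spec(chain$sequence)
  backbones <- lapply(ensemble$models, function(m) rebuild_backbone(m$ca))
  for (r in seq_len(k)) {
    write_models(backbone_frame(backbones[[r]], chain$sequence), spec,
                 file.path(config$outdir, sprintf("model_%d.pdb", r)),
                 bfactors = profile$msf, chain_id = chain$chain_id)
  }

  log_msg("stage: superpositions")
  model_ca <- lapply(ensemble$models, `[[`, "ca")
  input_ca <- chain_coords(chain, "CA")
  sup_models <- if (k >= 2) ml_superpose(model_ca) else NULL
  sup_with_input <- ml_superpose(c(list(input_ca), model_ca))
  ca_spec <- ca_atom_spec(chain$sequence)
  if (!is.null(sup_models))
    write_models(sup_models$aligned, ca_spec,
                 file.path(config$outdir, "ensemble_superposed.pdb"),
                 bfactors = profile$msf, chain_id = chain$chain_id)
  write_models(sup_with_input$aligned, ca_spec,
               file.path(config$outdir, "ensemble_with_input.pdb"),
               bfactors = profile$msf, chain_id = chain$chain_id)
  rmsd_in <- vapply(model_ca, function(m)
    kabsch_superpose(m, input_ca)$rmsd, numeric(1))
  writeLines(c("model rmsd_to_input",
               sprintf("%d %.4f", seq_len(k), rmsd_in)),
             file.path(config$outdir, "rmsd_to_input.txt"))

  writeLines(config_echo(config), file.path(config$outdir, "config.txt"))
  log_msg("done")

  structure(list(chain = chain, ss = ss, restraints = restraints,
                 trajectory = traj, profile = profile, clusters = cr,
                 ensemble = ensemble, backbones = backbones,
                 superposition = sup_models,
                 superposition_with_input = sup_with_input,
                 rmsd_to_input = rmsd_in, config = config),
            class = "flexens_result")
}

config_echo <- function(config) {
  fields <- c("input", "outdir", "seed", "n_snapshots", "k_clusters",
              "temperature", "cycles_between_snapshots",
              "equilibration_cycles")
  c(sprintf("%s=%s", fields, vapply(config[fields], format, character(1))),
    if (length(config$restraint_args))
      sprintf("restraint.%s=%s", names(config$restraint_args),
              vapply(config$restraint_args, format, character(1))),
    if (length(config$energy_args))
      sprintf("energy.%s=%s", names(config$energy_args),
              vapply(config$energy_args, format, character(1))))
}

#' @export
print.flexens_result <- function(x, ...) {
  cat(sprintf("flexibility pipeline result: %d residues, %d frames, %d models\n",
              x$chain$n_residues, length(x$trajectory$frames),
              length(x$ensemble$models)))
  cat(sprintf("  mean MSF %.3f A^2 (max %.3f at residue %d)\n",
              mean(x$profile$msf), max(x$profile$msf),
              which.max(x$profile$msf)))
  cat(sprintf("  acceptance rate %.3f; rmsd to input %.3f - %.3f A\n",
              x$trajectory$acceptance_rate, min(x$rmsd_to_input),
              max(x$rmsd_to_input)))
  invisible(x)
}
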