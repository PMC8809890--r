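# shared fixtures: tiny configurations and lazily cached desk ensembles

desk_cfg <- function(seed = 1, mutant = "", rounds = NULL, md = NULL) {
  fo_sim_config(rounds = rounds, md_steps_per_round = md,
                profile = "desk", seed = seed, mutant = mutant)
}

# short run used by unit tests (fast, still shows transport)
tiny_traj <- function(seed = 1, mutant = "", rounds = 200) {
  run_trajectory(desk_cfg(seed, mutant, rounds = rounds, md = 1e4))
}

# desk ensembles shared between the trajectory-observable tests and the
# acceptance suite; built once per test run on first use
.ens_cache <- new.env(parent = emptyenv())

desk_ensemble <- function(mutant = "", seeds = 1:10) {
  key <- paste0("m", mutant, "_", paste(range(seeds), collapse = "-"))
  if (is.null(.ens_cache[[key]])) {
    model <- fo_model(mutant)
    .ens_cache[[key]] <- structure(lapply(seeds, function(s) {
      run_trajectory(desk_cfg(s, mutant), model = model)
    }), class = "fo_ensemble")
  }
  .ens_cache[[key]]
}

ensemble_velocities <- function(ens) {
  vapply(ens, function(tr) rotational_velocity(tr)$velocity, numeric(1))
}

# mean stage-3 (uptake) duration of one subunit per trajectory, in frames
subunit_stage3 <- function(tr, subunit) {
  d <- stage_durations(tr)
  mean(d$uptake[d$subunit == subunit])
}

stage3_overlap <- function(tr, pair) {
  d <- stage_durations(tr)
  duration_overlap(stage_intervals(d, pair[1]), stage_intervals(d, pair[2]))
}
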