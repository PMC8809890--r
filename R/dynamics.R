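#' Simulation configuration
#'
#' The production profile runs 6000 rounds of one Monte Carlo sweep followed
#' by 1e5 Langevin steps (6e8 MD steps, 60,000 saved frames).  The `"desk"`
#' profile keeps the same round structure at 1000 rounds x 1e4 steps with
#' the time step rescaled so that a wild-type run still completes several
#' net turns; it is the profile used throughout the tests.
#'
#' @param rounds Number of MC/MD rounds.
#' @param md_steps_per_round Langevin steps per round.
#' @param frames_per_round Frames saved per round (must divide
#'   `md_steps_per_round`).
#' @param dt Reduced time per MD step.
#' @param D_rot Rotational diffusion coefficient (rad^2 per unit time).
#' @param seed Integer seed.
#' @param mutant Mutation pattern string.
#' @param profile `"paper"` or `"desk"`; presets overridden by explicit
#'   arguments.
#' @return List of class `fo_sim_config`.
#' @examples
#' fo_sim_config(profile = "desk", seed = 1)
#' @export
fo_sim_config <- function(rounds = NULL, md_steps_per_round = NULL,
                          frames_per_round = 10L, dt = NULL,
                          D_rot = 1.4e-8, seed = 1L, mutant = "",
                          profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   paper = list(rounds = 6000L, md = 1e5, dt = 1),
                   desk = list(rounds = 1000L, md = 1e4, dt = 100))
  rounds <- as.integer(if (is.null(rounds)) preset$rounds else rounds)
  md_steps_per_round <- as.integer(
    if (is.null(md_steps_per_round)) preset$md else md_steps_per_round)
  if (is.null(dt)) dt <- preset$dt
  frames_per_round <- as.integer(frames_per_round)
  if (rounds < 1L || md_steps_per_round < 1L)
    stop("rounds and md_steps_per_round must be positive")
  if (md_steps_per_round %% frames_per_round != 0L)
    stop("frames_per_round must divide md_steps_per_round")
  if (!is.finite(D_rot) || D_rot <= 0)
    stop("schema error: D_rot must be positive")
  if (dt <= 0) stop("schema error: dt must be positive")
  structure(list(rounds = rounds, md_steps_per_round = md_steps_per_round,
                 frames_per_round = frames_per_round, dt = dt,
                 D_rot = D_rot, seed = as.integer(seed), mutant = mutant,
                 profile = profile),
            class = "fo_sim_config")
}

#' Overdamped Langevin steps of the ring angle
#'
#' Euler-Maruyama integration of
#' `phi' = phi + (D/kT) tau(phi) dt + sqrt(2 D dt) zeta` at fixed
#' protonation state.
#'
#' @param model An [fo_model()].
#' @param state An [fo_state()] held fixed during integration.
#' @param phi Starting angle (degrees).
#' @param n_steps Number of steps.
#' @param dt,D_rot Time step and diffusion coefficient.
#' @param seed Optional seed.
#' @param record_every Keep every k-th angle.
#' @return Numeric vector of angles (degrees, cumulative).
#' @export
langevin_steps <- function(model, state, phi, n_steps, dt = 1,
                           D_rot = 1.4e-8, seed = NULL, record_every = 1L) {
  if (D_rot <= 0) stop("D_rot must be positive")
  if (!is.null(seed)) set.seed(seed)
  .rad2deg(fo_langevin_cpp(.model_to_cpp(model), as.integer(state),
                           .deg2rad(phi), as.integer(n_steps), dt, D_rot,
                           as.integer(record_every)))
}

#' One MC/MD round
#'
#' A single proton-transfer sweep followed by `md_steps_per_round` Langevin
#' steps, sampling frames on the way.
#'
#' @inheritParams langevin_steps
#' @param config An [fo_sim_config()].
#' @return List with `phi` (final angle, degrees), `state`, `frames`
#'   (data frame), `events` (data frame).
#' @export
run_round <- function(model, state, phi, config = fo_sim_config(),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- fo_run_cpp(.model_to_cpp(model), as.integer(state), .deg2rad(phi),
                    1L, config$md_steps_per_round, config$frames_per_round,
                    config$dt, config$D_rot)
  list(phi = .rad2deg(res$phi_final), state = fo_state(res$occ_final),
       frames = .frames_df(res, model), events = .decorate_events(res$events))
}

.frames_df <- function(res, model) {
  occ <- res$occ
  data.frame(
    frame = seq_along(res$md_step),
    md_step = res$md_step,
    phi_deg_cum = .rad2deg(res$phi),
    occupancy = apply(occ, 1, paste, collapse = ""),
    n_ims_in = res$n_ims_in,
    n_matrix_out = res$n_matrix_out,
    stringsAsFactors = FALSE
  )
}

#' Run one hybrid MC/MD trajectory
#'
#' Rounds of one Monte Carlo proton sweep followed by a block of Langevin
#' steps, starting from [initial_state()] at `phi = 0`.  With the default
#' synthesis-mode driving (pH 7.0 IMS / 8.0 matrix, 150 mV) the wild-type
#' ring rotates counterclockwise (positive), delivering ten protons from the
#' IMS to the matrix per net turn.
#'
#' @param config An [fo_sim_config()]; its `mutant` and `seed` fields are
#'   used unless overridden.
#' @param model Optional prebuilt [fo_model()]; by default built from
#'   `config$mutant`.
#' @param seed Optional seed override.
#' @param state,phi Optional initial protonation state and angle (degrees).
#' @return Object of class `fo_trajectory`: list with `frames`, `events`,
#'   `config`, `model`, `seed`.
#' @examples
#' \donttest{
#' traj <- run_trajectory(fo_sim_config(profile = "desk", seed = 1))
#' summary(traj)
#' }
#' @export
run_trajectory <- function(config = fo_sim_config(), model = NULL,
                           seed = NULL, state = NULL, phi = 0) {
  if (is.null(model)) model <- fo_model(config$mutant)
  if (is.null(seed)) seed <- config$seed
  if (is.null(state)) state <- initial_state(model, phi)
  set.seed(seed)
  res <- fo_run_cpp(.model_to_cpp(model), as.integer(state), .deg2rad(phi),
                    config$rounds, config$md_steps_per_round,
                    config$frames_per_round, config$dt, config$D_rot)
  structure(list(frames = .frames_df(res, model),
                 events = .decorate_events(res$events),
                 config = config, model = model, seed = seed),
            class = "fo_trajectory")
}

#' Run an ensemble of independent trajectories
#'
#' @inheritParams run_trajectory
#' @param n_replicates Number of independent runs.
#' @param base_seed Replicate seeds are `base_seed + 0:(n-1)`.
#' @return Object of class `fo_ensemble` (list of `fo_trajectory`).
#' @export
run_ensemble <- function(config = fo_sim_config(), n_replicates = 10L,
                         base_seed = NULL, model = NULL) {
  if (is.null(base_seed)) base_seed <- config$seed
  runs <- lapply(seq_len(n_replicates) - 1L, function(k) {
    run_trajectory(config, model = model, seed = base_seed + k)
  })
  structure(runs, class = "fo_ensemble")
}

#' @export
print.fo_trajectory <- function(x, ...) {
  nm <- if (nzchar(x$config$mutant)) x$config$mutant else "WT"
  nf <- nrow(x$frames)
  cat(sprintf(
    "Fo trajectory (%s, seed %d): %d frames, %.0f MD steps\n", nm, x$seed,
    nf, x$frames$md_step[nf]))
  cat(sprintf("  final angle %.1f deg (%.2f turns); protons: %d IMS in, %d matrix out (gross)\n",
              x$frames$phi_deg_cum[nf], x$frames$phi_deg_cum[nf] / 360,
              x$frames$n_ims_in[nf], x$frames$n_matrix_out[nf]))
  invisible(x)
}

#' @export
summary.fo_trajectory <- function(object, ...) {
  v <- rotational_velocity(object)
  pc <- net_proton_count(object)
  out <- list(mutant = object$config$mutant, seed = object$seed,
              frames = nrow(object$frames),
              final_angle_deg = tail(object$frames$phi_deg_cum, 1),
              velocity = v, protons = pc)
  class(out) <- "summary.fo_trajectory"
  out
}

#' @export
print.summary.fo_trajectory <- function(x, ...) {
  nm <- if (nzchar(x$mutant)) x$mutant else "WT"
  cat(sprintf("Fo trajectory summary (%s, seed %d)\n", nm, x$seed))
  cat(sprintf("  final angle: %.1f deg over %d frames\n", x$final_angle_deg,
              x$frames))
  if (is.na(x$velocity$velocity)) {
    cat("  last-return velocity: undefined (no full-turn return)\n")
  } else {
    cat(sprintf("  last-return velocity: %.1f deg / 1e6 MD steps (%.2f turns at last return)\n",
                x$velocity$velocity, x$velocity$cumulative_angle / 360))
  }
  cat(sprintf("  net protons: %d IMS->aE223, %d aE162->matrix\n",
              x$protons[["ims_in"]], x$protons[["matrix_out"]]))
  invisible(x)
}

#' @export
plot.fo_trajectory <- function(x, ...) {
  fr <- x$frames
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(fr$md_step, fr$phi_deg_cum, type = "l", xlab = "MD step",
       ylab = "cumulative angle (deg)", ...)
  abline(h = seq(0, max(fr$phi_deg_cum), by = 360), col = "grey80")
  plot(fr$md_step, fr$n_matrix_out, type = "s", xlab = "MD step",
       ylab = "protons to matrix (gross)", ...)
  invisible(x)
}

#' @export
print.fo_ensemble <- function(x, ...) {
  cat("Fo ensemble of", length(x), "trajectories\n")
  invisible(x)
}
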