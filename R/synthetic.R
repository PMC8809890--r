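#' Reference activity summaries of the hetero-mutant set
#'
#' Mean, standard deviation and replicate count of the ATP-synthesis
#' activity (percent of the fusion-control construct) for the single mutant
#' "e" and the five double mutants, as used throughout the summary-statistic
#' pipeline and as the default ground truth of the replicate generator.
#'
#' @return Data frame with columns `label`, `mean`, `sd`, `n`, `distance`
#'   (separation of the two mutations; `NA` for the single mutant).
#' @export
activity_summaries <- function() {
  data.frame(
    label = c("e", "ef", "eg", "eh", "ei", "ej"),
    mean = c(35.6, 22.3, 18.8, 13.0, 14.4, 12.0),
    sd = c(8.8, 9.3, 8.8, 8.9, 6.7, 4.7),
    n = c(9L, 10L, 9L, 10L, 10L, 8L),
    distance = c(NA, 1L, 2L, 3L, 4L, 5L),
    stringsAsFactors = FALSE
  )
}

#' Reference membrane ATPase activities with and without DCCD
#'
#' Activities (micromol/min/mg) of membranes expressing the mutated
#' constructs, measured after pre-incubation with or without the c-ring
#' inhibitor DCCD; input of [dccd_sensitivity()].
#'
#' @return Data frame `label`, `minus_dccd`, `plus_dccd`.
#' @export
atpase_dccd_table <- function() {
  data.frame(
    label = c("WT", "c10", "e", "ef", "eg", "eh", "ei", "ej"),
    minus_dccd = c(0.23, 0.15, 0.087, 0.090, 0.078, 0.086, 0.088, 0.083),
    plus_dccd = c(0.076, 0.067, 0.076, 0.065, 0.070, 0.073, 0.080, 0.068),
    stringsAsFactors = FALSE
  )
}

#' Structure-based pKa reference table
#'
#' Static table of per-chain pKa estimates (PROPKA, computed on the
#' ring-stator complex) for the proton-carrying carboxylate of each c-chain
#' `a`..`j`, for the wild-type glutamate and for the aspartate mutant.
#' These estimates motivate the default site pKa values (8.0 for Glu, 7.0
#' for Asp; the largest Glu value, 8.03 on chain i, anchors the wild-type
#' choice).
#'
#' @return 2 x 10 numeric matrix with rows `cE59`, `cE59D` and columns
#'   `a`..`j`.
#' @examples
#' max(table3_fixture()["cE59", ])  # 8.03
#' @export
table3_fixture <- function() {
  m <- rbind(
    cE59 = c(7.40, 6.10, 5.89, 5.89, 5.89, 5.89, 5.89, 6.73, 8.03, 7.34),
    cE59D = c(6.49, 5.37, 5.16, 5.16, 5.16, 5.16, 5.16, 5.85, 7.08, 6.54)
  )
  colnames(m) <- letters[1:10]
  m
}

#' Generate replicate-level activity measurements
#'
#' Gaussian (optionally lognormal) replicates per mutant with configured
#' true mean, SD and replicate count; a seeded stand-in for replicate-level
#' activity data underlying printed summaries.
#'
#' @param spec Data frame with columns `label`, `mean`, `sd`, `n` (default
#'   [activity_summaries()]).
#' @param seed Integer seed.
#' @param family `"gaussian"` or `"lognormal"`.
#' @return Data frame with columns `label`, `replicate`, `activity`.
#' @export
gen_activity_replicates <- function(spec = activity_summaries(), seed = 1,
                                    family = c("gaussian", "lognormal")) {
  family <- match.arg(family)
  stopifnot(all(spec$sd >= 0), all(spec$n >= 2))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    x <- if (family == "gaussian") {
      rnorm(n, spec$mean[i], spec$sd[i])
    } else {
      s2 <- log(1 + (spec$sd[i] / spec$mean[i])^2)
      exp(rnorm(n, log(spec$mean[i]) - s2 / 2, sqrt(s2)))
    }
    data.frame(label = spec$label[i], replicate = seq_len(n), activity = x,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a luciferase luminescence trace
#'
#' Piecewise-linear synthetic instrument record: a baseline slope, a
#' post-NADH synthesis slope that plateaus once the reaction has run its
#' course, and four stepwise end-of-run ATP-calibration additions at 20-s
#' intervals, plus Gaussian noise.  Annotations mark the NADH and ATP
#' additions.
#'
#' @param baseline_slope,post_slope Total signal slope (units per second)
#'   before and after the NADH addition.
#' @param step_height Luminescence increase per ATP addition.
#' @param atp_amount ATP amount per addition.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param t_nadh Time of the NADH addition (s); the trace starts at 0.
#' @param t_plateau Time at which synthesis plateaus (signal flat after).
#' @param t_calib Time of the first calibration addition (s).
#' @param dt Sampling interval (s).
#' @param seed Integer seed.
#' @return List of class `fo_trace`: `time`, `signal`, `annotations`, and
#'   the ground-truth `spec`.
#' @export
gen_luminescence_trace <- function(baseline_slope = 1, post_slope = 5,
                                   step_height = 50, atp_amount = 1,
                                   noise_sd = 0, t_nadh = 100,
                                   t_plateau = t_nadh + 60,
                                   t_calib = 200, dt = 0.5, seed = 1) {
  stopifnot(noise_sd >= 0, t_nadh >= 90, t_plateau >= t_nadh + 50,
            t_calib >= t_plateau)
  set.seed(seed)
  t_steps <- t_calib + 20 * (0:3)
  t_end <- max(t_steps) + 10
  time <- seq(0, t_end, by = dt)
  base <- baseline_slope * pmin(time, t_plateau)
  post <- (post_slope - baseline_slope) *
    pmin(pmax(time - t_nadh, 0), t_plateau - t_nadh)
  steps <- rowSums(outer(time, t_steps, function(tt, ts) (tt > ts) *
                           step_height))
  signal <- base + post + steps + rnorm(length(time), 0, noise_sd)
  structure(list(
    time = time, signal = signal,
    annotations = data.frame(time = c(t_nadh, t_steps),
                             label = c("NADH", rep("ATP", 4)),
                             stringsAsFactors = FALSE),
    spec = list(baseline_slope = baseline_slope, post_slope = post_slope,
                step_height = step_height, atp_amount = atp_amount,
                noise_sd = noise_sd, seed = seed)
  ), class = "fo_trace")
}

#' Generate an ACMA fluorescence quench trace
#'
#' ATP addition triggers an exponential quench to the configured depth;
#' FCCP addition five minutes later collapses the pH gradient and the
#' fluorescence recovers exponentially to the plateau.
#'
#' @param depth Quench depth as a fraction of the plateau (0..1).
#' @param plateau Fluorescence level recovered after FCCP (and initial
#'   baseline).
#' @param tau_quench,tau_recover Exponential time constants (s).
#' @param t_atp,t_fccp Addition times (s); default FCCP 5 min after ATP.
#' @param t_end End of the record (s).
#' @param noise_sd Gaussian noise SD.
#' @param dt Sampling interval (s).
#' @param seed Integer seed.
#' @return List of class `fo_trace` as in [gen_luminescence_trace()].
#' @export
gen_acma_trace <- function(depth = 0.4, plateau = 100, tau_quench = 20,
                           tau_recover = 15, t_atp = 60, t_fccp = t_atp + 300,
                           t_end = t_fccp + 240, noise_sd = 0, dt = 0.5,
                           seed = 1) {
  stopifnot(depth >= 0, depth <= 1, noise_sd >= 0, t_fccp > t_atp,
            t_end > t_fccp)
  set.seed(seed)
  time <- seq(0, t_end, by = dt)
  f <- rep(plateau, length(time))
  q <- time > t_atp & time <= t_fccp
  f[q] <- plateau * (1 - depth * (1 - exp(-(time[q] - t_atp) / tau_quench)))
  f_at_fccp <- plateau * (1 - depth * (1 - exp(-(t_fccp - t_atp) /
                                                 tau_quench)))
  r <- time > t_fccp
  f[r] <- plateau + (f_at_fccp - plateau) * exp(-(time[r] - t_fccp) /
                                                  tau_recover)
  signal <- f + rnorm(length(time), 0, noise_sd)
  structure(list(
    time = time, signal = signal,
    annotations = data.frame(time = c(t_atp, t_fccp),
                             label = c("ATP", "FCCP"),
                             stringsAsFactors = FALSE),
    spec = list(depth = depth, plateau = plateau, seed = seed)
  ), class = "fo_trace")
}

#' Build a scripted event log and minimal trajectory
#'
#' Turns a hand-written script of proton-transfer events and angle waypoints
#' into well-formed event/trajectory structures for exercising the
#' trajectory analyses without running the simulator.
#'
#' @param events Data frame with columns `md_step`, `channel_kind`,
#'   `subunit`, `direction`, `outcome` and optionally `delta_energy`.
#' @param waypoints Optional data frame with columns `md_step`, `phi_deg`;
#'   frames are linearly interpolated on the frame grid.
#' @param steps_per_frame MD steps per frame (default 10).
#' @param total_steps Total span (default: last scripted time).
#' @return List of class `fo_script_log` with `events`, `frames`,
#'   `steps_per_frame`, `total_steps`.
#' @export
gen_event_log <- function(events, waypoints = NULL, steps_per_frame = 10,
                          total_steps = NULL) {
  stopifnot(is.data.frame(events))
  if (is.null(events$delta_energy))
    events$delta_energy <- rep(0, nrow(events))
  if (nrow(events) && is.unsorted(events$md_step))
    stop("unordered script: md_step must be non-decreasing")
  bad <- setdiff(events$channel_kind, .kind_names)
  if (length(bad)) stop("unknown channel kind(s): ", paste(bad, collapse = ", "))
  if (is.null(total_steps))
    total_steps <- if (nrow(events)) max(events$md_step) else 0
  if (!is.null(waypoints)) total_steps <- max(total_steps, waypoints$md_step)
  frames <- if (total_steps >= steps_per_frame) {
    grid <- seq(steps_per_frame, total_steps, by = steps_per_frame)
    phi <- if (!is.null(waypoints) && nrow(waypoints) >= 2) {
      approx(waypoints$md_step, waypoints$phi_deg, xout = grid,
             rule = 2)$y
    } else rep(0, length(grid))
    data.frame(frame = seq_along(grid), md_step = grid, phi_deg_cum = phi,
               occupancy = strrep("1", 12), n_ims_in = 0L,
               n_matrix_out = 0L, stringsAsFactors = FALSE)
  } else {
    data.frame(frame = integer(0), md_step = numeric(0),
               phi_deg_cum = numeric(0), occupancy = character(0),
               n_ims_in = integer(0), n_matrix_out = integer(0))
  }
  structure(list(events = events, frames = frames,
                 steps_per_frame = steps_per_frame,
                 total_steps = total_steps),
            class = "fo_script_log")
}
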