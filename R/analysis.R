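#' Unwrap a possibly wrapped angle series
#'
#' Restores a continuous cumulative angle from a series that may have been
#' wrapped into `[0, 360)` or `(-180, 180]`.  Frame-to-frame increments are
#' re-wrapped into `(-180, 180]` and accumulated; a series that is already
#' cumulative (small increments) is returned unchanged.
#'
#' @param angle Numeric vector of angles (degrees), time ordered.
#' @return Continuous cumulative angle series (degrees).
#' @export
unwrap_cumulative_angle <- function(angle) {
  if (length(angle) < 2L) return(angle)
  d <- diff(angle)
  dw <- .wrap_deg(d)
  if (any(abs(dw) > 120))
    warning("angle gaps exceed 120 degrees between frames; ",
            "series may be undersampled")
  angle[1] + cumsum(c(0, dw))
}

#' Last-return rotational velocity
#'
#' Because an asymmetric (mutant) ring only samples its stages uniformly
#' over whole turns, the velocity is estimated from the last time the
#' cumulative angle equals a multiple of 360 degrees (the ring back in its
#' initial orientation), with the crossing linearly interpolated between
#' frames: `velocity = angle_at_last_return / t_last_return`.
#'
#' @param trajectory An `fo_trajectory`, or a data frame with columns
#'   `md_step` and `phi_deg_cum`.
#' @return List of class `fo_velocity`: `cumulative_angle` (deg),
#'   `t_last_return` (MD steps), `velocity_per_step` (deg/step), `velocity`
#'   (deg per 1e6 MD steps), `n_turns`, `defined`.  When the angle never
#'   returns to a full-turn multiple the velocity is `NA` and `defined` is
#'   `FALSE` (not an error).
#' @export
rotational_velocity <- function(trajectory) {
  fr <- if (inherits(trajectory, "fo_trajectory")) trajectory$frames
        else trajectory
  t <- c(0, fr$md_step)
  x <- c(0, fr$phi_deg_cum)
  last_t <- NA_real_; last_lvl <- NA_real_
  for (i in seq_len(length(t) - 1L)) {
    x1 <- x[i]; x2 <- x[i + 1L]
    lo <- ceiling(min(x1, x2) / 360); hi <- floor(max(x1, x2) / 360)
    if (lo > hi) next
    lvls <- (lo:hi) * 360
    for (L in lvls) {
      tc <- if (x2 == x1) t[i + 1L] else
        t[i] + (L - x1) / (x2 - x1) * (t[i + 1L] - t[i])
      if (tc > 0 && (is.na(last_t) || tc >= last_t)) {
        last_t <- tc; last_lvl <- L
      }
    }
  }
  out <- if (is.na(last_t)) {
    list(cumulative_angle = NA_real_, t_last_return = NA_real_,
         velocity_per_step = NA_real_, velocity = NA_real_,
         n_turns = NA_real_, defined = FALSE)
  } else {
    vps <- last_lvl / last_t
    list(cumulative_angle = last_lvl, t_last_return = last_t,
         velocity_per_step = vps, velocity = vps * 1e6,
         n_turns = last_lvl / 360, defined = TRUE)
  }
  class(out) <- "fo_velocity"
  out
}

#' @export
print.fo_velocity <- function(x, ...) {
  if (!x$defined) cat("rotational velocity: undefined (no full-turn return)\n")
  else cat(sprintf(
    "rotational velocity: %.2f deg/1e6 MD steps (%.1f turns, last return at step %.0f)\n",
    x$velocity, x$n_turns, x$t_last_return))
  invisible(x)
}

#' Net proton transport counts
#'
#' Net number of protons taken up from the IMS by the relay aE223 and net
#' number delivered by aE162 to the matrix (successful forward reservoir
#' events minus reverse ones, so that equilibrium back-exchange cancels).
#' `net` is the matrix-delivered count; `ims_in` is reported alongside for
#' leak detection.
#'
#' @param trajectory An `fo_trajectory` or an events data frame.
#' @param t_max Optional cutoff (MD steps): only events at or before it.
#' @return Named numeric vector `c(ims_in, matrix_out, net)`.
#' @export
net_proton_count <- function(trajectory, t_max = Inf) {
  ev <- if (inherits(trajectory, "fo_trajectory")) trajectory$events
        else trajectory
  ev <- ev[ev$outcome == "success" & ev$md_step <= t_max, , drop = FALSE]
  cnt <- function(kind) {
    f <- sum(ev$channel_kind == kind & ev$direction == "forward")
    r <- sum(ev$channel_kind == kind & ev$direction == "reverse")
    f - r
  }
  ims <- cnt("relay_ims"); mat <- cnt("relay_matrix")
  c(ims_in = ims, matrix_out = mat, net = mat)
}

#' Per-subunit stage-duration decomposition
#'
#' Partitions each subunit's transport cycle into: stage 1, proton release
#' (first trial of the c-site-to-aE162 transfer up to its success); stage 2,
#' deprotonated rotation (release success up to arrival at the uptake angle,
#' operationalized as the first aE223-to-c uptake trial); stage 3, proton
#' uptake (first uptake trial up to uptake success); and the resting time in
#' between cycles.  Transient re-protonation from aE162 before any uptake
#' trial restarts the release stage clock at the release that finally
#' sticks.  Truncated cycles at the end of the trajectory are dropped and
#' counted.
#'
#' @param trajectory An `fo_trajectory`, or an events data frame (then give
#'   `steps_per_frame` and `total_steps`).
#' @param steps_per_frame MD steps per saved frame (for frame units).
#' @param total_steps Total MD steps of the analyzed span.
#' @return Data frame with one row per completed cycle: `subunit`, `cycle`,
#'   absolute event times (`t_release_trial`, `t_release_success`,
#'   `t_uptake_trial`, `t_uptake_success`, MD steps) and durations
#'   `release`, `deprot_rotation`, `uptake`, `resting` in frames.  The
#'   number of truncated cycles is attached as attribute `truncated`.
#' @export
stage_durations <- function(trajectory, steps_per_frame = NULL,
                            total_steps = NULL) {
  if (inherits(trajectory, "fo_trajectory")) {
    ev <- trajectory$events
    cfg <- trajectory$config
    if (is.null(steps_per_frame))
      steps_per_frame <- cfg$md_steps_per_round / cfg$frames_per_round
    if (is.null(total_steps))
      total_steps <- as.numeric(cfg$rounds) * cfg$md_steps_per_round
  } else {
    ev <- trajectory
    if (is.null(steps_per_frame)) steps_per_frame <- 1
    if (is.null(total_steps)) total_steps <- max(ev$md_step, 0)
  }
  rows <- list(); truncated <- 0L
  for (su in .site_labels) {
    e <- ev[!is.na(ev$subunit) & ev$subunit == su, , drop = FALSE]
    e <- e[order(e$md_step), , drop = FALSE]
    f_trial <- NA_real_; r_succ <- NA_real_; u_trial <- NA_real_
    cyc_end <- 0; cycle <- 0L
    pending <- FALSE
    for (k in seq_len(nrow(e))) {
      kind <- e$channel_kind[k]; dir <- e$direction[k]
      out <- e$outcome[k]; tt <- e$md_step[k]
      if (kind == "release" && dir == "forward") {
        if (out == "trial" && is.na(f_trial)) { f_trial <- tt; pending <- TRUE }
        if (out == "success") {
          if (!is.na(u_trial)) u_trial <- NA_real_  # new deprotonation period
          r_succ <- tt
        }
      } else if (kind == "release" && dir == "reverse" && out == "success") {
        # re-protonated from aE162: the release did not stick
        r_succ <- NA_real_; u_trial <- NA_real_
      } else if (kind == "uptake" && dir == "forward") {
        if (out == "trial" && !is.na(r_succ) && is.na(u_trial)) u_trial <- tt
        if (out == "success" && !is.na(r_succ)) {
          cycle <- cycle + 1L
          ut <- if (is.na(u_trial)) tt else u_trial
          rows[[length(rows) + 1L]] <- data.frame(
            subunit = su, cycle = cycle,
            t_release_trial = f_trial, t_release_success = r_succ,
            t_uptake_trial = ut, t_uptake_success = tt,
            release = (r_succ - f_trial) / steps_per_frame,
            deprot_rotation = (ut - r_succ) / steps_per_frame,
            uptake = (tt - ut) / steps_per_frame,
            resting = (f_trial - cyc_end) / steps_per_frame,
            stringsAsFactors = FALSE)
          cyc_end <- tt
          f_trial <- NA_real_; r_succ <- NA_real_; u_trial <- NA_real_
          pending <- FALSE
        }
      } else if (kind == "uptake" && dir == "reverse" && out == "success") {
        # proton handed back to aE223 without a matrix-side release
        if (is.na(r_succ)) { u_trial <- NA_real_ }
      }
    }
    if (pending) truncated <- truncated + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subunit = character(0), cycle = integer(0),
               t_release_trial = numeric(0), t_release_success = numeric(0),
               t_uptake_trial = numeric(0), t_uptake_success = numeric(0),
               release = numeric(0), deprot_rotation = numeric(0),
               uptake = numeric(0), resting = numeric(0))
  attr(out, "truncated") <- truncated
  attr(out, "total_frames") <- total_steps / steps_per_frame
  out
}

#' Uptake-stage intervals of one subunit
#'
#' @param durations Output of [stage_durations()].
#' @param subunit Subunit label.
#' @param stage `"uptake"` (stage 3), `"release"` or `"deprot_rotation"`.
#' @return Data frame with columns `start`, `end` (MD steps).
#' @export
stage_intervals <- function(durations, subunit,
                            stage = c("uptake", "release",
                                      "deprot_rotation")) {
  stage <- match.arg(stage)
  d <- durations[durations$subunit == subunit, , drop = FALSE]
  switch(stage,
         uptake = data.frame(start = d$t_uptake_trial,
                             end = d$t_uptake_success),
         release = data.frame(start = d$t_release_trial,
                              end = d$t_release_success),
         deprot_rotation = data.frame(start = d$t_release_success,
                                      end = d$t_uptake_trial))
}

#' Shared fraction of two interval sets
#'
#' Fraction of time two subunits' stage intervals overlap, normalized by the
#' smaller of the two total durations (symmetric and scale free):
#' `|A intersect B| / min(|A|, |B|)`; 0 if either total is zero.
#'
#' @param durA,durB Data frames with columns `start`, `end`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' duration_overlap(data.frame(start = 0, end = 100),
#'                  data.frame(start = 50, end = 150))  # 0.5
#' @export
duration_overlap <- function(durA, durB) {
  lenA <- sum(pmax(durA$end - durA$start, 0))
  lenB <- sum(pmax(durB$end - durB$start, 0))
  if (lenA == 0 || lenB == 0) return(0)
  inter <- 0
  for (i in seq_len(nrow(durA))) {
    lo <- pmax(durA$start[i], durB$start)
    hi <- pmin(durA$end[i], durB$end)
    inter <- inter + sum(pmax(hi - lo, 0))
  }
  inter / min(lenA, lenB)
}

#' Ensemble summary of velocities, durations and sharing
#'
#' Mean and standard error across replicate trajectories of the last-return
#' velocity, the per-stage durations, and (optionally) the stage-3 overlap
#' of a pair of subunits.  Undefined velocities are excluded and counted.
#'
#' @param trajectories An `fo_ensemble` or list of `fo_trajectory`.
#' @param overlap_pair Optional character vector of two subunit labels.
#' @return List of class `fo_ensemble_summary` with a per-replicate data
#'   frame and mean/SE rows.
#' @export
ensemble_summary <- function(trajectories, overlap_pair = NULL) {
  stopifnot(length(trajectories) >= 2L)
  per <- lapply(trajectories, function(tr) {
    v <- rotational_velocity(tr)
    sd3 <- stage_durations(tr)
    np <- net_proton_count(tr)
    ov <- if (!is.null(overlap_pair)) {
      duration_overlap(stage_intervals(sd3, overlap_pair[1]),
                       stage_intervals(sd3, overlap_pair[2]))
    } else NA_real_
    data.frame(seed = if (inherits(tr, "fo_trajectory")) tr$seed else NA,
               velocity = v$velocity, n_turns = v$n_turns,
               net_protons = np[["net"]],
               release = mean(sd3$release),
               deprot_rotation = mean(sd3$deprot_rotation),
               uptake = mean(sd3$uptake),
               overlap = ov)
  })
  per <- do.call(rbind, per)
  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  mn <- function(x) mean(x[is.finite(x)])
  cols <- c("velocity", "n_turns", "net_protons", "release",
            "deprot_rotation", "uptake", "overlap")
  out <- list(replicates = per,
              mean = vapply(per[cols], mn, numeric(1)),
              se = vapply(per[cols], se, numeric(1)),
              n_undefined = sum(!is.finite(per$velocity)))
  class(out) <- "fo_ensemble_summary"
  out
}

#' @export
print.fo_ensemble_summary <- function(x, ...) {
  cat("Ensemble of", nrow(x$replicates), "replicates",
      if (x$n_undefined) sprintf("(%d undefined velocities excluded)",
                                 x$n_undefined) else "", "\n")
  cat(sprintf("  velocity: %.1f +/- %.1f deg/1e6 MD steps (mean +/- SE)\n",
              x$mean[["velocity"]], x$se[["velocity"]]))
  cat(sprintf("  stage durations (frames): release %.1f, rotation %.1f, uptake %.1f\n",
              x$mean[["release"]], x$mean[["deprot_rotation"]],
              x$mean[["uptake"]]))
  invisible(x)
}
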