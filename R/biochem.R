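#' First-order error propagation for a ratio
#'
#' Standard deviation of `a/b` for independent errors:
#' `s = |a/b| sqrt((sa/a)^2 + (sb/b)^2)`, with the `a = 0` case handled by
#' the direct form `s = sqrt((sa/b)^2 + (a sb / b^2)^2)`.
#'
#' @param a,sa Numerator and its standard deviation.
#' @param b,sb Denominator and its standard deviation.
#' @return Named vector `c(value, sd)`.
#' @examples
#' propagate_ratio_error(10, 1, 2, 0.2)
#' @export
propagate_ratio_error <- function(a, sa, b, sb) {
  if (any(b == 0)) stop("division by zero: b must be nonzero")
  s <- sqrt((sa / b)^2 + (a * sb / b^2)^2)
  c(value = a / b, sd = s)
}

.window_slope <- function(time, signal, t0, t1) {
  sel <- time >= t0 & time <= t1
  if (sum(sel) < 3L) stop("insufficient points in window [", t0, ", ", t1, "]")
  fit <- lm(signal[sel] ~ time[sel])
  c(slope = unname(coef(fit)[2]),
    se = suppressWarnings(summary(fit))$coefficients[2, 2])
}

.annotation_time <- function(trace, label) {
  an <- trace$annotations
  tt <- an$time[an$label == label]
  if (!length(tt)) stop("missing annotation: ", label)
  tt
}

#' ATP-synthesis slope from a luciferase luminescence trace
#'
#' Least-squares slope over the 50 s after the NADH addition minus the
#' baseline slope over the 90 s before it, with standard errors combined in
#' quadrature.
#'
#' @param trace List with `time` (s), `signal`, and `annotations`
#'   (data frame with `time`, `label`; must contain one `"NADH"` mark).
#' @param pre_window,post_window Window lengths in seconds (defaults 90/50).
#' @return Named vector `c(slope, sd)` in signal units per second.
#' @export
synthesis_slope <- function(trace, pre_window = 90, post_window = 50) {
  tn <- .annotation_time(trace, "NADH")[1]
  if (tn - min(trace$time) < pre_window ||
      max(trace$time) - tn < post_window)
    stop("insufficient span around the NADH addition")
  pre <- .window_slope(trace$time, trace$signal, tn - pre_window, tn)
  post <- .window_slope(trace$time, trace$signal, tn, tn + post_window)
  c(slope = unname(post["slope"] - pre["slope"]),
    sd = unname(sqrt(post["se"]^2 + pre["se"]^2)))
}

#' Luminescence-per-ATP calibration
#'
#' A defined amount of ATP is added four times at 20-s intervals; each step
#' height is the mean luminescence over the 5 s immediately after the
#' addition minus the mean over the 5 s immediately before it.  The
#' calibration factor is the average step height per ATP amount, with the
#' standard deviation over the four steps.
#'
#' @param trace As in [synthesis_slope()]; annotations must contain the ATP
#'   addition marks.
#' @param atp_amount Amount of ATP per addition (mol).
#' @param n_additions Number of additions (default 4).
#' @param window Averaging window (s, default 5).
#' @param label Annotation label of the additions (default `"ATP"`).
#' @return Named vector `c(value, sd)`: luminescence units per ATP amount.
#' @export
atp_calibration <- function(trace, atp_amount = 1, n_additions = 4,
                            window = 5, label = "ATP") {
  tt <- .annotation_time(trace, label)
  if (length(tt) != n_additions)
    stop("expected ", n_additions, " ATP additions, found ", length(tt))
  heights <- vapply(tt, function(t0) {
    pre <- trace$time >= t0 - window & trace$time < t0
    post <- trace$time > t0 & trace$time <= t0 + window
    if (sum(pre) < 2L || sum(post) < 2L)
      stop("missing clean 5-s windows around the ATP addition at t = ", t0)
    mean(trace$signal[post]) - mean(trace$signal[pre])
  }, numeric(1))
  c(value = mean(heights) / atp_amount, sd = sd(heights) / atp_amount)
}

#' Specific ATP-synthesis activity
#'
#' The baseline-deducted synthesis slope divided by the luminescence
#' calibration per ATP amount and by the membrane protein added, with
#' first-order error propagation.
#'
#' @param slope Named vector `c(slope, sd)` from [synthesis_slope()].
#' @param calibration Named vector `c(value, sd)` from [atp_calibration()].
#' @param protein_mg Membrane protein added (mg).
#' @return Named vector `c(value, sd)` (mol ATP per second per mg, in the
#'   units of the calibration amount).
#' @export
specific_activity <- function(slope, calibration, protein_mg = 1) {
  if (calibration[["value"]] <= 0) stop("calibration must be positive")
  if (protein_mg <= 0) stop("protein_mg must be positive")
  r <- propagate_ratio_error(slope[[1]], slope[["sd"]],
                             calibration[["value"]], calibration[["sd"]])
  c(value = r[["value"]] / protein_mg, sd = r[["sd"]] / protein_mg)
}

#' Expression-level normalization of synthesis activities
#'
#' Divides each mutant's ATP-synthesis activity by its ATP-hydrolysis
#' activity in the presence of LDAO (a proxy for the amount of enzyme
#' expressed) and multiplies by the mean LDAO activity of the reference
#' mutants, with error propagation at each step.
#'
#' @param activities Data frame with columns `label`, `mean`, `sd`.
#' @param ldao_activities Data frame with columns `label`, `mean`, `sd`.
#' @param reference Labels averaged into the reference LDAO level
#'   (default `c("e", "ef", "eg", "eh")`).
#' @return Data frame `label`, `mean`, `sd` of normalized activities.
#' @export
expression_normalize <- function(activities, ldao_activities,
                                 reference = c("e", "ef", "eg", "eh")) {
  miss <- setdiff(reference, ldao_activities$label)
  if (length(miss))
    stop("missing LDAO values for reference mutants: ",
         paste(miss, collapse = ", "))
  ref <- ldao_activities[match(reference, ldao_activities$label), ]
  ref_mean <- mean(ref$mean)
  ref_sd <- sqrt(sum(ref$sd^2)) / length(reference)
  out <- activities
  for (i in seq_len(nrow(activities))) {
    lab <- activities$label[i]
    j <- match(lab, ldao_activities$label)
    if (is.na(j)) stop("missing LDAO value for mutant: ", lab)
    if (ldao_activities$mean[j] == 0)
      stop("zero LDAO activity for mutant: ", lab)
    r <- propagate_ratio_error(activities$mean[i], activities$sd[i],
                               ldao_activities$mean[j],
                               ldao_activities$sd[j])
    v <- r[["value"]] * ref_mean
    s <- abs(v) * sqrt((r[["sd"]] / r[["value"]])^2 +
                         (ref_sd / ref_mean)^2)
    if (r[["value"]] == 0) s <- ref_mean * r[["sd"]]
    out$mean[i] <- v; out$sd[i] <- s
  }
  out
}

#' ACMA fluorescence quench (proton-pump activity)
#'
#' Magnitude of the fluorescence quench 3 minutes after the ATP addition
#' relative to the recovered level after FCCP addition:
#' `100 (F_postFCCP - F_3min) / F_postFCCP`.
#'
#' @param trace As in [synthesis_slope()]; annotations must contain `"ATP"`
#'   and `"FCCP"` marks.
#' @param at Quench readout time after ATP (s, default 180).
#' @param plateau_window Length of the final window averaged for the
#'   post-FCCP plateau (s, default 30).
#' @return Percent quench.
#' @export
acma_quench <- function(trace, at = 180, plateau_window = 30) {
  t_atp <- .annotation_time(trace, "ATP")[1]
  t_fccp <- .annotation_time(trace, "FCCP")[1]
  t_read <- t_atp + at
  if (t_read > max(trace$time) || t_read > t_fccp)
    stop("trace does not cover the quench readout time")
  f3 <- approx(trace$time, trace$signal, xout = t_read)$y
  sel <- trace$time >= max(trace$time) - plateau_window &
    trace$time > t_fccp
  if (sum(sel) < 2L) stop("no post-FCCP plateau available")
  plateau <- mean(trace$signal[sel])
  100 * (plateau - f3) / plateau
}

#' DCCD-sensitive fraction of ATPase activity
#'
#' `1 - activity(+DCCD) / activity(-DCCD)`: the fraction of membrane ATPase
#' activity abolished by the covalent c-ring inhibitor DCCD, reporting the
#' coupled Fo-F1 fraction.  Note that applying this plain ratio to the
#' reference activity table ([atpase_dccd_table()]) gives roughly 9-28%
#' across the mutant constructs, a wider spread than the 10-15% usually
#' quoted for them; the ratio itself is the implemented definition.
#'
#' @param activity_minus Activity without DCCD (must be positive).
#' @param activity_plus Activity after DCCD pre-incubation.
#' @return Sensitive fraction.
#' @examples
#' dccd_sensitivity(0.087, 0.076)  # mutant "e"
#' @export
dccd_sensitivity <- function(activity_minus, activity_plus) {
  if (any(activity_minus <= 0)) stop("activity without DCCD must be positive")
  1 - activity_plus / activity_minus
}

#' Pooled two-sample Student's t-test from summary statistics
#'
#' The unbiased variance estimate is recovered from each group's standard
#' deviation and the two groups are compared with the pooled-variance
#' Student's t statistic, `df = n1 + n2 - 2`, two-sided p-value.
#'
#' @param summary1,summary2 Lists or rows with fields `mean`, `sd`, `n`
#'   (n >= 2).
#' @param dispersion How to read the `sd` fields: `"sd"` (default) treats
#'   them as standard deviations, `"se"` as standard errors of the mean
#'   (converted via `sd = se * sqrt(n)`).  Reported "+/-" spreads are
#'   sometimes one or the other; the default is the interpretation
#'   consistent with the reference p-values given the replicate counts.
#' @return List `t`, `df`, `p`, and `degenerate` (`TRUE` when the pooled
#'   variance is zero with unequal means, in which case `p = 0`).
#' @examples
#' pooled_t_test(list(mean = 22.3, sd = 9.3, n = 10),
#'               list(mean = 12.0, sd = 4.7, n = 8))
#' @export
pooled_t_test <- function(summary1, summary2, dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  n1 <- summary1$n; n2 <- summary2$n
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  s1 <- summary1$sd; s2 <- summary2$sd
  if (dispersion == "se") { s1 <- s1 * sqrt(n1); s2 <- s2 * sqrt(n2) }
  summary1 <- list(mean = summary1$mean, sd = s1, n = n1)
  summary2 <- list(mean = summary2$mean, sd = s2, n = n2)
  sp2 <- ((n1 - 1) * summary1$sd^2 + (n2 - 1) * summary2$sd^2) /
    (n1 + n2 - 2)
  df <- n1 + n2 - 2
  dm <- summary1$mean - summary2$mean
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(dm) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tstat <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), degenerate = FALSE)
}

#' Distance-activity regression across double mutants
#'
#' Ordinary least-squares regression of ATP-synthesis activity on the
#' separation between the two mutated c-subunits (ef = 1 ... ej = 5), with
#' the two-sided p-value for a nonzero slope.  Replicate-level rows are used
#' when provided; otherwise one row per mutant mean.
#'
#' @param data Data frame with columns `distance` and `activity`.
#' @return List `slope`, `intercept`, `p`, `degenerate` (`TRUE` when the
#'   fit has zero residual variance).
#' @export
distance_regression <- function(data) {
  if (length(unique(data$distance)) < 3L)
    stop("need at least 3 distinct distances")
  fit <- lm(activity ~ distance, data = data)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  if (sm$sigma <= 1e-10 * max(abs(data$activity), 1)) {
    flat <- abs(slope) <= 1e-10 * max(abs(data$activity), 1)
    if (flat) slope <- 0
    return(list(slope = slope, intercept = unname(coef(fit)[1]),
                p = if (flat) 1 else 0, degenerate = !flat))
  }
  list(slope = slope, intercept = unname(coef(fit)[1]),
       p = sm$coefficients[2, 4], degenerate = FALSE)
}
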