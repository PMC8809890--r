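test_that("angle unwrapping restores continuity", {
  mono <- c(0, 30, 100, 190, 280)
  expect_equal(unwrap_cumulative_angle(mono), mono)
  saw <- c(0, 120, 240, 359, 0, 120) # wrapped sawtooth keeps climbing
  expect_equal(unwrap_cumulative_angle(saw), c(0, 120, 240, 359, 360, 480))
  expect_equal(unwrap_cumulative_angle(rep(42, 5)), rep(42, 5))
  expect_warning(unwrap_cumulative_angle(c(0, 150, 0)), "undersampled")
})

test_that("last-return velocity applies the full-turn convention", {
  # constant rate 0.036 deg/step ending exactly at 360
  fr <- data.frame(md_step = 1:10000, phi_deg_cum = 0.036 * (1:10000))
  v <- rotational_velocity(fr)
  expect_true(v$defined)
  expect_equal(v$cumulative_angle, 360)
  expect_equal(v$velocity_per_step, 0.036, tolerance = 1e-12)
  # reaches 719 deg; last 360-multiple at step 5000; final 359 deg excluded
  t <- 1:10000
  phi <- ifelse(t <= 5000, 0.072 * t, 360 + (t - 5000) * (719 - 360) / 5000)
  v2 <- rotational_velocity(data.frame(md_step = t, phi_deg_cum = phi))
  expect_equal(v2$t_last_return, 5000)
  expect_equal(v2$velocity_per_step, 360 / 5000, tolerance = 1e-12)
  # never completes a turn: undefined, not an error
  v3 <- rotational_velocity(data.frame(md_step = 1:100,
                                       phi_deg_cum = seq(1, 300, length = 100)))
  expect_false(v3$defined)
  expect_true(is.na(v3$velocity))
  # a backward crossing later in the run supersedes earlier returns
  phi4 <- c(100, 380, 420, 350, 380)
  v4 <- rotational_velocity(data.frame(md_step = 1:5 * 10, phi_deg_cum = phi4))
  expect_equal(v4$cumulative_angle, 360)
  expect_gt(v4$t_last_return, 40)
})

test_that("net proton counts cancel reservoir back-exchange", {
  empty <- data.frame(md_step = numeric(0), channel_kind = character(0),
                      subunit = character(0), direction = character(0),
                      outcome = character(0), delta_energy = numeric(0))
  expect_equal(net_proton_count(empty), c(ims_in = 0, matrix_out = 0, net = 0))
  ev <- data.frame(
    md_step = 1:23,
    channel_kind = c(rep("relay_ims", 12), rep("relay_matrix", 11)),
    subunit = NA,
    direction = c(rep("forward", 10), "reverse", "reverse",
                  rep("forward", 10), "reverse"),
    outcome = "success", delta_energy = 0)
  expect_equal(net_proton_count(ev),
               c(ims_in = 8, matrix_out = 9, net = 9))
  expect_equal(net_proton_count(ev, t_max = 10)[["ims_in"]], 10)
})

test_that("stage durations follow the event-defined boundaries", {
  script <- data.frame(
    md_step = c(100, 600, 600, 1700, 1900, 1900),
    channel_kind = c("release", "release", "release", "uptake", "uptake",
                     "uptake"),
    subunit = "e",
    direction = "forward",
    outcome = c("trial", "trial", "success", "trial", "trial", "success"))
  log <- gen_event_log(script, steps_per_frame = 10)
  d <- stage_durations(log$events, steps_per_frame = 10)
  expect_equal(nrow(d), 1L)
  expect_equal(d$release, 50)
  expect_equal(d$deprot_rotation, 110)
  expect_equal(d$uptake, 20)
  # immediately successful release: stage 1 lasts zero frames
  quick <- data.frame(
    md_step = c(50, 50, 80, 90),
    channel_kind = c("release", "release", "uptake", "uptake"),
    subunit = "a", direction = "forward",
    outcome = c("trial", "success", "trial", "success"))
  dq <- stage_durations(quick, steps_per_frame = 10)
  expect_equal(dq$release, 0)
  expect_equal(dq$uptake, 1)
  # a subunit without events contributes no cycles
  expect_equal(nrow(stage_durations(quick)[
    stage_durations(quick)$subunit == "b", ]), 0L)
})

test_that("re-protonation from the matrix relay restarts the release clock", {
  script <- data.frame(
    md_step = c(100, 200, 300, 400, 500, 600, 700),
    channel_kind = c("release", "release", "release", "release", "release",
                     "uptake", "uptake"),
    subunit = "a",
    direction = c("forward", "forward", "reverse", "forward", "forward",
                  "forward", "forward"),
    outcome = c("trial", "success", "success", "trial", "success", "trial",
                "success"))
  d <- stage_durations(script, steps_per_frame = 10)
  expect_equal(nrow(d), 1L)
  # release that sticks is the one at t = 500; first trial at t = 100
  expect_equal(d$release, 40)
  expect_equal(d$deprot_rotation, 10)
  expect_equal(d$uptake, 10)
})

test_that("stage intervals tile the cycle without overlap", {
  tr <- tiny_traj(seed = 2, rounds = 400)
  d <- stage_durations(tr)
  expect_gt(nrow(d), 0)
  expect_true(all(d$release >= 0))
  expect_true(all(d$deprot_rotation >= 0))
  expect_true(all(d$uptake >= 0))
  expect_true(all(d$t_release_trial <= d$t_release_success))
  expect_true(all(d$t_release_success <= d$t_uptake_trial))
  expect_true(all(d$t_uptake_trial <= d$t_uptake_success))
  # within a subunit, consecutive cycles do not overlap
  for (su in unique(d$subunit)) {
    ds <- d[d$subunit == su, ]
    if (nrow(ds) > 1)
      expect_true(all(diff(ds$t_release_trial) > 0) &&
                    all(ds$t_release_trial[-1] >=
                          ds$t_uptake_success[-nrow(ds)]))
  }
})

test_that("duration overlap is the shared fraction of the smaller set", {
  a <- data.frame(start = c(0, 200), end = c(100, 260))
  expect_equal(duration_overlap(a, a), 1)
  b <- data.frame(start = 300, end = 400)
  expect_equal(duration_overlap(a, b), 0)
  expect_equal(duration_overlap(data.frame(start = 0, end = 100),
                                data.frame(start = 50, end = 150)), 0.5)
  expect_equal(duration_overlap(a, data.frame(start = numeric(0),
                                              end = numeric(0))), 0)
})

test_that("wild-type stage durations are uniform across the ten subunits", {
  d <- do.call(rbind, lapply(desk_ensemble(""), stage_durations))
  expect_gt(nrow(d), 100)
  for (col in c("release", "deprot_rotation", "uptake")) {
    kw <- stats::kruskal.test(d[[col]] ~ factor(d$subunit))
    expect_gt(kw$p.value, 0.01)
  }
})

test_that("ensemble summaries match brute-force recomputation", {
  cfg <- desk_cfg(seed = 3, rounds = 250, md = 1e4)
  ens <- run_ensemble(cfg, n_replicates = 3)
  s <- ensemble_summary(ens)
  vels <- vapply(ens, function(tr) rotational_velocity(tr)$velocity,
                 numeric(1))
  ok <- is.finite(vels)
  expect_equal(s$mean[["velocity"]], mean(vels[ok]))
  if (sum(ok) > 1)
    expect_equal(s$se[["velocity"]], sd(vels[ok]) / sqrt(sum(ok)))
  # identical replicates give zero spread
  twin <- structure(list(ens[[1]], ens[[1]]), class = "fo_ensemble")
  st <- ensemble_summary(twin)
  expect_equal(unname(st$se[["velocity"]]), 0)
})
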