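test_that("transfer weight factors evaluate to their closed forms", {
  glu <- fo_site_params("GLU")
  asp <- fo_site_params("ASP")
  expect_equal(distance_factor(glu$r0, glu), 1)
  expect_equal(distance_factor(1.2, glu), exp(-1))
  expect_equal(distance_factor(0.8, asp), exp(-1.8))
  # capped at 1 below r0
  expect_equal(distance_factor(0.1, glu), 1)

  expect_equal(orientation_factor(0), 1)
  expect_equal(orientation_factor(30, 0, 30), exp(-0.5))
  # even function around the centre
  th <- seq(5, 90, by = 17)
  expect_equal(orientation_factor(th, 0, 30), orientation_factor(-th, 0, 30))
  expect_error(orientation_factor(0, 0, sigma = -1), "sigma")
})

test_that("the arginine gate separates the two half-channels", {
  g <- fo_geometry()
  expect_equal(arg_gate(-10, "release", g), 1)   # matrix side
  expect_equal(arg_gate(-10, "uptake", g), 0)    # would leak past aR176
  expect_equal(arg_gate(10, "uptake", g), 1)
  expect_equal(arg_gate(10, "release", g), 0)
  expect_equal(arg_gate(123, "relay_ims", g), 1) # reservoirs ungated
  expect_equal(arg_gate(-77, "relay_matrix", g), 1)
})

test_that("channel weights are products of factors and direction-symmetric", {
  m <- fo_model()
  # gated-off channel has zero weight
  expect_equal(transfer_weight(m, "a", "uptake", phi = -10), 0)
  # aligned release channel: f = g = h = 1
  expect_equal(transfer_weight(m, "a", "release", phi = -36), 1,
               tolerance = 1e-12)
  # hand-computed product at 10 degrees past the matrix relay
  g <- m$geometry
  r <- protonmotor:::.site_relay_distance(g, -46, -36)
  th <- protonmotor:::.site_relay_theta(g, -46, -36)
  w <- distance_factor(r, fo_site_params("GLU")) *
    orientation_factor(th, 0, 30)
  expect_equal(transfer_weight(m, "a", "release", phi = -46), w)
  # C++ kernel agrees with the R evaluation
  expect_equal(protonmotor:::fo_weight_cpp(protonmotor:::.model_to_cpp(m),
                                           0L, 0L, -46 * pi / 180),
               w, tolerance = 1e-12)
  expect_equal(transfer_weight(m, "a", "relay_ims"), 1)
})

test_that("Metropolis acceptance follows min(1, exp(-dV))", {
  expect_equal(metropolis_acceptance(-3), 1)
  expect_equal(metropolis_acceptance(0), 1)
  expect_equal(metropolis_acceptance(1), exp(-1))
  expect_equal(metropolis_acceptance(2.3026), 0.1, tolerance = 1e-4)
})

test_that("a sweep conserves protons except at reservoirs and respects occupancy", {
  m <- fo_model("ef")
  set.seed(21)
  st <- initial_state(m)
  phi <- 0
  for (k in 1:300) {
    res <- mc_sweep(m, st, phi)
    s2 <- res$state
    ev <- res$events
    succ <- ev[ev$outcome == "success", , drop = FALSE]
    res_in <- sum(succ$channel_kind == "relay_ims" &
                    succ$direction == "forward") +
      sum(succ$channel_kind == "relay_matrix" & succ$direction == "reverse")
    res_out <- sum(succ$channel_kind == "relay_ims" &
                     succ$direction == "reverse") +
      sum(succ$channel_kind == "relay_matrix" & succ$direction == "forward")
    expect_equal(sum(s2) - sum(st), res_in - res_out)
    expect_true(all(as.integer(s2) %in% 0:1))
    st <- s2
    phi <- phi + runif(1, -20, 20)
  }
})

test_that("weights of zero freeze the state and log nothing", {
  en <- fo_energetics(reservoir_weight = 0, g_sigma = 1e-9)
  # a tiny sigma kills every site-relay weight away from exact alignment
  m <- fo_model(energetics = en)
  st <- fo_state(deprotonated = "a")
  res <- mc_sweep(m, st, phi = 17, seed = 4)
  expect_equal(as.integer(res$state), as.integer(st))
  expect_equal(nrow(res$events), 0L)
})

test_that("no successful site-relay transfer ever occurs against the gate", {
  tr <- tiny_traj(seed = 3, mutant = "e")
  ev <- tr$events
  sr <- ev[ev$channel_kind %in% c("release", "uptake") &
             ev$outcome == "success", , drop = FALSE]
  expect_gt(nrow(sr), 0)
  g <- fo_model("e")$geometry
  # reconstruct the site angle at each event from the nearest frame angle
  phi_at <- approx(c(0, tr$frames$md_step), c(0, tr$frames$phi_deg_cum),
                   xout = sr$md_step, rule = 2)$y
  off <- g$site_offsets[match(sr$subunit, letters[1:10])]
  gate <- vapply(seq_len(nrow(sr)), function(i) {
    arg_gate(phi_at[i] + off[i], sr$channel_kind[i], g)
  }, numeric(1))
  expect_true(all(gate == 1))
})

test_that("empirical acceptance frequency matches w * min(1, exp(-dV))", {
  # binomial oracle: repeat single sweeps from a frozen configuration and
  # compare the success frequency of one channel with its predicted rate
  en <- fo_energetics(reservoir_weight = 0)
  m <- fo_model(energetics = en)
  for (phi in c(-36, -46)) {
    st <- fo_state(deprotonated = "aE162")   # site a protonated, aE162 empty
    w <- transfer_weight(m, "a", "release", phi = phi)
    st_after <- fo_state(deprotonated = "a")
    dv <- total_energy(st_after, phi, m)$total -
      total_energy(st, phi, m)$total
    p_expect <- w * metropolis_acceptance(dv)
    n <- 4000
    set.seed(97 + phi)
    hits <- 0
    for (k in seq_len(n)) {
      res <- protonmotor:::fo_sweep_cpp(protonmotor:::.model_to_cpp(m),
                                        as.integer(st), phi * pi / 180, 0)
      ev <- protonmotor:::.decorate_events(res$events)
      hits <- hits + any(ev$outcome == "success" &
                           ev$channel_kind == "release" &
                           !is.na(ev$subunit) & ev$subunit == "a")
    }
    se <- sqrt(p_expect * (1 - p_expect) / n)
    expect_lt(abs(hits / n - p_expect), 3 * se + 1e-3)
  }
})

test_that("equal reservoirs and zero potential give no net proton flux", {
  m <- fo_model(env = fo_env(pH_IMS = 7, pH_matrix = 7, delta_psi = 0))
  tr <- run_trajectory(desk_cfg(seed = 8, rounds = 400, md = 1e4),
                       model = m)
  np <- net_proton_count(tr)
  gross <- sum(tr$events$outcome == "success" &
                 tr$events$channel_kind %in% c("relay_ims", "relay_matrix"))
  expect_lt(abs(np[["net"]]), 3 * sqrt(gross) + 1)
  expect_lt(abs(np[["ims_in"]]), 3 * sqrt(gross) + 1)
})
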