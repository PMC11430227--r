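mk_state <- function(distal = c(hr = 0, efe = 90, fps = 0, wru = 0, wfe = 0),
                     hand = c(0, -0.3, 0.34), time = 0, id = "t1") {
  controller_state(distal, hand, time, id)
}

test_that("the angular gap is the plain difference to the goal", {
  st <- mk_state()
  goal <- c(hr = 0, efe = 100, fps = 0, wru = 0, wfe = 0)
  gap <- compute_gap(goal, st)
  expect_equal(unname(gap["efe"]), 10)
  expect_equal(unname(gap["hr"]), 0)
  expect_equal(compute_gap(st$distal_prev, st),
               stats::setNames(rep(0, 5), DISTAL_NAMES))
  # previous above goal gives a negative gap
  st2 <- mk_state(distal = c(hr = 0, efe = 120, fps = 0, wru = 0, wfe = 0))
  expect_lt(compute_gap(goal, st2)[["efe"]], 0)
})

test_that("locked-hand speed ignores distal motion and measures proximal", {
  geom <- fx_geometry()
  ang <- as_joint_angles(c(sfe = 20, saa = 10, hr = 0, efe = 90, fps = 0,
                           wru = 0, wfe = 0))
  hand0 <- forward_kinematics(geom, ang)$position
  st <- controller_state(distal_of(ang), hand0, time = 0, target_id = "a")
  # stationary proximal: zero speed
  expect_equal(locked_hand_speed(geom, proximal_of(ang), st, 1 / 90), 0)
  # distal-only change between ticks contributes nothing
  st_moved <- st
  st_moved$distal_prev <- distal_of(ang) + c(5, -5, 5, 2, -2)
  st_moved$hand_prev <- forward_kinematics(
    geom, c(proximal_of(ang), st_moved$distal_prev))$position
  expect_equal(locked_hand_speed(geom, proximal_of(ang), st_moved, 1 / 90), 0)
  # a proximal step moving the locked hand 1 cm in 1/90 s gives 0.9 m/s
  st2 <- controller_state(distal_of(ang), hand0, time = 0, target_id = "a")
  prox2 <- proximal_of(ang) + c(sfe = 2, saa = 0)
  ph2 <- locked_hand_position(geom, prox2, distal_of(ang))
  d <- sqrt(sum((ph2 - hand0)^2))
  expect_equal(locked_hand_speed(geom, prox2, st2, 1 / 90), d * 90)
  expect_error(locked_hand_speed(geom, prox2, st2, 0), "increase")
})

test_that("estimated movement time is distance over speed", {
  tg <- target_spec(c(0.1, 0, 0), 0, 0)
  expect_equal(estimate_movement_time(tg, c(0, 0, 0), 0.5), 0.2)
  expect_equal(estimate_movement_time(tg, tg$position, 0.5), 0)
  expect_equal(estimate_movement_time(tg, c(0, 0, 0), 1.0), 0.1)
  expect_error(estimate_movement_time(tg, c(0, 0, 0), 0), "> 0")
})

test_that("the two update formulations agree when rates coincide", {
  set.seed(31)
  freq <- 90
  for (i in 1:500) {
    prev <- stats::setNames(stats::runif(5, -90, 90), DISTAL_NAMES)
    goal <- prev + stats::setNames(stats::runif(5, -40, 40), DISTAL_NAMES)
    disp <- stats::runif(1, 0, 0.02)
    rem <- stats::runif(1, 0.05, 0.6)
    latched <- stats::setNames(stats::runif(5) < 0.2, DISTAL_NAMES)
    a <- angular_update(prev, goal, disp, rem, latched,
                        form = "distance_ratio")
    b <- angular_update(prev, goal, disp, rem, latched,
                        form = "time_estimate", dt = 1 / freq, freq = freq)
    expect_equal(a$angles, b$angles, tolerance = 1e-9)
    expect_identical(a$latched, b$latched)
  }
})

test_that("per-tick displacement follows the distance-ratio law", {
  prev <- c(hr = 0, efe = 90, fps = 0, wru = 0, wfe = 0)
  goal <- c(hr = 0, efe = 100, fps = 0, wru = 0, wfe = 0)
  latched <- stats::setNames(rep(FALSE, 5), DISTAL_NAMES)
  # gap 10 deg, displacement 0.01 m, remaining 0.10 m -> +1 deg
  upd <- angular_update(prev, goal, 0.01, 0.10, latched)
  expect_equal(unname(upd$angles["efe"]), 91)
  expect_false(upd$latched[["efe"]])
  # zero displacement holds the previous value
  upd0 <- angular_update(prev, goal, 0, 0.10, latched)
  expect_equal(upd0$angles, prev)
  # fraction clipped at 1: never overshoots the goal
  updc <- angular_update(prev, goal, 0.5, 0.01, latched)
  expect_equal(unname(updc$angles["efe"]), 100)
})

test_that("joints latch within the threshold and track the goal", {
  prev <- c(hr = 0, efe = 99.5, fps = 0, wru = 0, wfe = 0)
  goal <- c(hr = 20, efe = 100, fps = 0, wru = 0, wfe = 0)
  latched <- stats::setNames(rep(FALSE, 5), DISTAL_NAMES)
  upd <- angular_update(prev, goal, 0.001, 0.3, latched)
  # |gap| = 0.5 < 1: snaps to the prediction and latches
  expect_equal(unname(upd$angles["efe"]), 100)
  expect_true(upd$latched[["efe"]])
  # hr far from goal: interpolates, not latched
  expect_false(upd$latched[["hr"]])
  expect_lt(upd$angles[["hr"]], 1)
  # once latched, follows a moved goal directly even with zero displacement
  goal2 <- goal
  goal2["efe"] <- 97
  upd2 <- angular_update(upd$angles, goal2, 0, 0.3, upd$latched)
  expect_equal(unname(upd2$angles["efe"]), 97)
})

test_that("linear gap decay matches the telescoped closed form", {
  # constant goal, straight-line constant-speed locked approach
  prev <- c(hr = -30, efe = 60, fps = 20, wru = -10, wfe = 40)
  goal <- c(hr = 10, efe = 110, fps = -25, wru = 12, wfe = -15)
  gap0 <- goal - prev
  R0 <- 0.5
  step <- 0.002
  latched <- stats::setNames(rep(FALSE, 5), DISTAL_NAMES)
  R <- R0
  cur <- prev
  while (R - step > 1e-6) {
    upd <- angular_update(cur, goal, step, R, latched)
    if (any(upd$latched)) break
    cur <- upd$angles
    R <- R - step
    expect_equal((goal - cur) / gap0,
                 stats::setNames(rep(R / R0, 5), DISTAL_NAMES),
                 tolerance = 1e-6)
  }
  expect_lt(R, 0.1 * R0) # the loop really ran deep into the approach
})

test_that("interpolation steps keep outputs within the ROM", {
  geom <- fx_geometry()
  rom <- fx_rom()
  pred <- fx_pc_plus()
  tg <- target_from_set(sample_plausible_targets(geom, rom, 1, seed = 77), 1)
  start <- as_joint_angles(stats::setNames(
    (rom$min_deg + rom$max_deg) / 2, JOINT_NAMES))
  st <- controller_state(distal_of(start),
                         forward_kinematics(geom, start)$position,
                         0, target_identifier(tg))
  prox <- proximal_of(start)
  for (k in 1:30) {
    prox <- prox + c(sfe = 0.5, saa = -0.3)
    out <- interpolation_step(geom, pred, rom, tg, prox, st, k / 90)
    st <- out$state
    expect_true(all(out$distal >= rom[DISTAL_NAMES, "min_deg"] &
                      out$distal <= rom[DISTAL_NAMES, "max_deg"]))
  }
  # changing targets without reset errors; after reset it continues smoothly
  tg2 <- target_from_set(sample_plausible_targets(geom, rom, 2, seed = 78), 2)
  expect_error(interpolation_step(geom, pred, rom, tg2, prox, st, 31 / 90),
               "reset_on_target_change")
  st2 <- reset_on_target_change(st, tg2)
  expect_false(any(st2$latched))
  expect_identical(st2$distal_prev, st$distal_prev)
  out2 <- interpolation_step(geom, pred, rom, tg2, prox, st2, 31 / 90)
  expect_lt(max(abs(out2$distal - st$distal_prev)), 5)
  # reset with the same target id is a no-op on the latches
  st$latched["efe"] <- TRUE
  expect_identical(reset_on_target_change(st, tg)$latched, st$latched)
})

test_that("direct control equals the saturated prediction, stateless", {
  geom <- fx_geometry()
  rom <- fx_rom()
  pred <- fx_pc_minus_small()
  tg <- target_from_set(sample_plausible_targets(geom, rom, 1, seed = 9), 1)
  prox <- c(sfe = 30, saa = 10)
  d1 <- direct_step(pred, rom, tg, prox)
  d2 <- direct_step(pred, rom, tg, prox)
  expect_identical(d1, d2)
  expect_equal(d1, saturate(predict_goal(pred, tg, prox), rom))
  # equals the interpolation goal once every joint has latched
  st <- controller_state(d1, forward_kinematics(
    geom, c(prox, d1))$position, 0, target_identifier(tg))
  out <- interpolation_step(geom, pred, rom, tg, prox + c(0.2, 0.1), st,
                            1 / 90)
  expect_equal(out$distal, direct_step(pred, rom, tg, prox + c(0.2, 0.1)),
               tolerance = 1e-9)
})
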