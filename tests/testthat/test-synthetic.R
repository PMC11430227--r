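test_that("minimum-jerk movements have exact endpoints and rest boundary", {
  start <- joint_angles(sfe = 10, efe = 30)
  end <- joint_angles(sfe = 60, saa = 20, efe = 120, wfe = -30)
  tr <- generate_natural_movement(start, end, duration = 1.5, freq = 90)
  expect_equal(unlist(tr[1, JOINT_NAMES]), start,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unlist(tr[nrow(tr), JOINT_NAMES]), end,
               ignore_attr = TRUE, tolerance = 1e-12)
  # endpoint joint velocities vanish (numeric differentiation)
  v <- diff(tr$efe) / diff(tr$t)
  expect_lt(abs(v[1]), 0.5)
  expect_lt(abs(v[length(v)]), 0.5)
  # start = end gives a constant trajectory
  tr0 <- generate_natural_movement(start, start, duration = 1, freq = 90)
  expect_true(all(vapply(JOINT_NAMES, function(j)
    all(tr0[[j]] == start[[j]]), logical(1))))
})

test_that("single-joint movement yields a bell-shaped single-peak speed", {
  geom <- fx_geometry()
  tr <- generate_natural_movement(joint_angles(efe = 20),
                                  joint_angles(efe = 120), 1.2, 90)
  p <- t(vapply(seq_len(nrow(tr)), function(i)
    forward_kinematics(geom, stats::setNames(as.numeric(tr[i, JOINT_NAMES]),
                                             JOINT_NAMES))$position,
    numeric(3)))
  v <- sqrt(rowSums(diff(p)^2)) / diff(tr$t)
  pk <- which.max(v)
  expect_gt(pk, length(v) * 0.3)
  expect_lt(pk, length(v) * 0.7)
  # single-peaked: non-decreasing to the peak, non-increasing after
  expect_true(all(diff(v[1:pk]) > -1e-9))
  expect_true(all(diff(v[pk:length(v)]) < 1e-9))
})

test_that("plausible targets are reachable, elbow-restricted, reproducible", {
  geom <- fx_geometry()
  rom <- fx_rom()
  tg <- sample_plausible_targets(geom, rom, n = 300, seed = 123)
  expect_equal(nrow(tg), 300)
  # elbow 85% rule: generating postures avoid the outer 7.5% on each side
  span <- rom["efe", "max_deg"] - rom["efe", "min_deg"]
  expect_true(all(tg$gen_efe >= rom["efe", "min_deg"] + 0.075 * span))
  expect_true(all(tg$gen_efe <= rom["efe", "max_deg"] - 0.075 * span))
  # other joints within full ROM
  for (j in setdiff(JOINT_NAMES, "efe")) {
    expect_true(all(tg[[paste0("gen_", j)]] >= rom[j, "min_deg"]))
    expect_true(all(tg[[paste0("gen_", j)]] <= rom[j, "max_deg"]))
  }
  # reachable with zero error by the generating posture
  for (i in c(1, 57, 300)) {
    pose <- forward_kinematics(geom, target_from_set(tg, i)$posture)
    expect_equal(pose$position, c(tg$x[i], tg$y[i], tg$z[i]))
    expect_equal(c(pose$alpha, pose$beta), c(tg$alpha[i], tg$beta[i]))
  }
  # bit-reproducible under the seed
  expect_identical(tg, sample_plausible_targets(geom, rom, 300, seed = 123))
  expect_error(sample_plausible_targets(geom, rom, 0, seed = 1))
})

test_that("possible targets come from performed configurations", {
  geom <- fx_geometry()
  tr <- generate_natural_movement(joint_angles(efe = 40),
                                  joint_angles(sfe = 50, efe = 100), 1, 90)
  tg <- sample_possible_targets(list(tr), geom, n = 200, seed = 5)
  expect_equal(nrow(tg), 200)
  # replay: each target reachable with zero error by its source posture
  for (i in c(1, 100, 200)) {
    pose <- forward_kinematics(geom, target_from_set(tg, i)$posture)
    expect_equal(pose$position, c(tg$x[i], tg$y[i], tg$z[i]))
  }
  # single-posture pool: all targets identical
  one <- tr[1, ]
  tg1 <- sample_possible_targets(list(one), geom, n = 10, seed = 1)
  expect_true(all(vapply(c("x", "y", "z", "alpha", "beta"), function(cl)
    length(unique(tg1[[cl]])) == 1, logical(1))))
  expect_error(sample_possible_targets(list(), geom, 10), "empty")
})

test_that("movement database respects participant ROMs and chains postures", {
  geom <- fx_geometry()
  rom <- fx_rom()
  db <- synthesize_movement_database(geom, rom, n_movements = 24,
                                     n_participants = 4, rom_jitter = 5,
                                     seed = 2)
  expect_length(db, 24)
  for (tr in db) {
    expect_gte(nrow(tr), 2)
    # within jittered ROM: at most rom_jitter beyond the base limits
    for (j in JOINT_NAMES) {
      expect_true(all(tr[[j]] >= rom[j, "min_deg"] - 5 - 1e-9))
      expect_true(all(tr[[j]] <= rom[j, "max_deg"] + 5 + 1e-9))
    }
  }
  # pick-and-place chaining: consecutive movements share a posture
  expect_equal(unlist(db[[1]][nrow(db[[1]]), JOINT_NAMES]),
               unlist(db[[2]][1, JOINT_NAMES]), tolerance = 1e-12)
  expect_identical(db, synthesize_movement_database(
    geom, rom, n_movements = 24, n_participants = 4, rom_jitter = 5,
    seed = 2))
})

test_that("training samples are self-consistent with forward kinematics", {
  geom <- fx_geometry()
  tr <- generate_natural_movement(joint_angles(efe = 40, sfe = 20),
                                  joint_angles(sfe = 70, efe = 110, fps = 30),
                                  1, 90)
  ts <- build_training_set(list(tr), geom)
  expect_equal(nrow(ts), nrow(tr))
  for (i in c(1, 25, nrow(ts))) {
    pose <- forward_kinematics(geom, stats::setNames(
      as.numeric(ts[i, JOINT_NAMES]), JOINT_NAMES))
    expect_equal(as.numeric(ts[i, c("x", "y", "z")]), pose$position)
    expect_equal(as.numeric(ts[i, c("alpha", "beta")]),
                 c(pose$alpha, pose$beta))
  }
  # retargeting: another geometry keeps angles, changes contexts
  geom2 <- arm_geometry(0.35, 0.30, 0.10)
  ts2 <- build_training_set(list(tr), geom2)
  expect_equal(ts2[JOINT_NAMES], ts[JOINT_NAMES])
  expect_false(isTRUE(all.equal(ts2$y, ts$y)))
})

test_that("simulated shoulder profiles behave as specified", {
  start <- c(sfe = 0, saa = 0)
  goal <- c(sfe = 60, saa = 30)
  # sigma = 0 noisy reduces to minimum jerk
  mj <- simulate_user_shoulder(start, goal, 1, profile = "minimum_jerk")
  ns0 <- simulate_user_shoulder(start, goal, 1, profile = "noisy",
                                noise_sd = 0)
  expect_equal(ns0, mj)
  # constant-speed: near-constant per-tick proximal displacement mid-move
  cs <- simulate_user_shoulder(start, goal, 1, profile = "constant_speed")
  d <- sqrt(diff(cs$sfe)^2 + diff(cs$saa)^2)
  expect_lt(max(d) - min(d), 1e-9)
  # seeded noise reproducible
  n1 <- simulate_user_shoulder(start, goal, 1, profile = "noisy",
                               noise_sd = 1, seed = 3)
  n2 <- simulate_user_shoulder(start, goal, 1, profile = "noisy",
                               noise_sd = 1, seed = 3)
  expect_identical(n1, n2)
})

test_that("ROM from a database combines shoulder limits with distal quantiles", {
  db <- fx_database()[1:40]
  rom <- fx_rom()
  dr <- rom_from_database(db, rom, probs = c(0.05, 0.95))
  expect_equal(dr["sfe", "min_deg"], rom["sfe", "min_deg"])
  expect_equal(dr["saa", "max_deg"], rom["saa", "max_deg"])
  frames <- do.call(rbind, lapply(db, function(tr) tr[JOINT_NAMES]))
  expect_equal(dr["wfe", "min_deg"],
               unname(stats::quantile(frames$wfe, 0.05)))
  expect_equal(dr["efe", "max_deg"],
               unname(stats::quantile(frames$efe, 0.95)))
})

test_that("trajectories and target sets round-trip through CSV", {
  tr <- generate_natural_movement(joint_angles(), joint_angles(efe = 90),
                                  0.5, 90)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  tg <- sample_plausible_targets(fx_geometry(), fx_rom(), 10, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_targets(tg, f2)
  tg2 <- read_targets(f2)
  expect_equal(tg2$x, tg$x)
  expect_equal(tg2$gen_wfe, tg$gen_wfe)
})
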