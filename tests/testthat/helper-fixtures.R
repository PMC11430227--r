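# Shared fixtures, built lazily and memoised for the session: the reference
# synthetic database (the study-scale conditions), its training set, and
# the standard PC+ predictor trained on it.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fx_geometry <- function() fixture("geometry", function() arm_geometry())
fx_rom <- function() fixture("rom", function() default_rom())

# study-scale database: 400 movements x 90 Hz x 1-2 s ~ 5e4 frames
fx_database <- function() fixture("database", function()
  synthesize_movement_database(fx_geometry(), fx_rom(), n_movements = 400,
                               seed = 11))

fx_training_set <- function() fixture("training_set", function()
  build_training_set(fx_database(), fx_geometry()))

fx_pc_plus <- function() fixture("pc_plus", function()
  train_predictor(network_spec("PC+"), fx_training_set(), seed = 42))

# a small, quickly trained PC- for direct-control scenarios
fx_pc_minus_small <- function() fixture("pc_minus_small", function() {
  ts <- fx_training_set()
  train_predictor(network_spec("PC-", lr = 5e-6),
                  ts[seq_len(5000), ], seed = 42)
})

# goal-pose errors of saturated predictions at the generating proximal
heldout_pose_errors <- function(predictor, targets, geometry, rom) {
  prox <- data.frame(sfe = targets$gen_sfe, saa = targets$gen_saa)
  P <- predict_goal(predictor, targets, proximal = prox)
  n <- nrow(targets)
  pos <- ax <- numeric(n)
  for (i in seq_len(n)) {
    d <- saturate(P[i, ], rom)
    pose <- forward_kinematics(geometry, c(sfe = targets$gen_sfe[i],
                                           saa = targets$gen_saa[i], d))
    pos[i] <- sqrt(sum((pose$position -
                          c(targets$x[i], targets$y[i], targets$z[i]))^2))
    ta <- axis_from_alpha_beta(targets$alpha[i], targets$beta[i])
    ax[i] <- axis_angle_deg(pose$axis, ta)
  }
  list(position = pos, axis = ax)
}
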