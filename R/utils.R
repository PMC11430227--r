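# internal helpers

# Evaluate expr under a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

vnorm <- function(x) sqrt(sum(x * x))

deg_angle_between <- function(u, v) {
  d <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, d))) * 180 / pi
}

# minimum-jerk position profile on tau in [0, 1]
min_jerk_profile <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
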