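# Heavy shared fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# default four-module stack, settled and gain-calibrated
acc_stack <- function() {
  memo("stack", {
    s <- grid_stack(seed = 1)
    calibrate_stack(s, target_gain = 150, probe_speed = 0.25)
  })
}

# place module trained on 60 s of foraging in a 4 m arena
acc_trained <- function() {
  memo("trained", {
    traj <- gen_foraging_trajectory(arena = 4, duration = 60, speed = 0.25,
                                    seed = 7)
    train_weights(acc_stack(), traj$odometry)
  })
}

# small settled module for fast unit tests (N = 24 forms a coarse pattern)
small_module <- function() {
  memo("small_module", {
    suppressWarnings(grid_module(grid_module_spec(N = 24, n_m = 2, seed = 1),
                                 settle_steps = 800))
  })
}

# tiny two-module stack for fast integration tests (patterns not required)
tiny_stack <- function() {
  memo("tiny_stack", {
    suppressWarnings(grid_stack(n = c(2L, 3L), N = 16, settle_steps = 100,
                                seed = 1))
  })
}

# analytic hexagonal field sampled on a grid
hex_field <- function(x, y, a = 0.3) {
  k <- 4 * pi / (sqrt(3) * a)
  ang <- c(0, pi / 3, 2 * pi / 3)
  f <- 0
  for (t in ang) f <- f + cos(k * (cos(t) * x + sin(t) * y))
  (f + 1.5) / 4.5
}

hex_matrix <- function(B = 50, a = 0.3) {
  xs <- (seq_len(B) - 0.5) / B
  outer(xs, xs, function(yy, xx) hex_field(xx, yy, a))
}
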