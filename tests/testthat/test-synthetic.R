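test_that("foraging trajectories are reproducible, bounded, and self-consistent", {
  t1 <- gen_foraging_trajectory(arena = 1, duration = 20, seed = 3)
  t2 <- gen_foraging_trajectory(arena = 1, duration = 20, seed = 3)
  expect_identical(t1$poses, t2$poses)
  expect_true(all(t1$poses$x >= 0 & t1$poses$x <= 1))
  expect_true(all(t1$poses$y >= 0 & t1$poses$y <= 1))
  # integrating the odometry reproduces the poses exactly
  xi <- t1$poses$x[1] + cumsum(t1$odometry$vx * 0.001)
  yi <- t1$poses$y[1] + cumsum(t1$odometry$vy * 0.001)
  expect_equal(xi, t1$poses$x[-1], tolerance = 1e-12)
  expect_equal(yi, t1$poses$y[-1], tolerance = 1e-12)
  t0 <- gen_foraging_trajectory(duration = 0, seed = 1)
  expect_equal(nrow(t0$poses), 1L)
})

test_that("200 s of foraging covers most of the arena", {
  tr <- gen_foraging_trajectory(arena = 1, duration = 200, dt = 0.01,
                                seed = 5)
  bx <- pmin(floor(tr$poses$x * 10) + 1, 10)
  by <- pmin(floor(tr$poses$y * 10) + 1, 10)
  visited <- length(unique(paste(bx, by)))
  expect_gte(visited, 80)
})

test_that("loop odometry closes without bias and opens proportionally with it", {
  clean <- gen_loop_odometry(side = 10, laps = 2, speed = 1, dt = 0.005,
                             bias = 0, noise_sd = 0, seed = 1)
  expect_lt(clean$endpoint_gap, 1e-9)
  expect_equal(clean$lap_boundaries, 8001L)
  # true poses close every lap
  n <- clean$per_lap
  expect_equal(clean$poses$x[n + 1], 0, tolerance = 1e-9)
  expect_equal(clean$poses$y[n + 1], 0, tolerance = 1e-9)
  gaps <- vapply(1:4, function(s)
    gen_loop_odometry(side = 10, laps = 2, speed = 1, dt = 0.005,
                      bias = 0.05, noise_sd = 0.01, seed = s)$endpoint_gap,
    0)
  expect_true(all(abs(gaps - 2) < 0.5))  # about bias x lap length
  sweep <- vapply(c(0.01, 0.03, 0.05, 0.08), function(b)
    gen_loop_odometry(side = 10, laps = 2, speed = 1, dt = 0.005,
                      bias = b, noise_sd = 0, seed = 1)$endpoint_gap, 0)
  expect_true(all(diff(sweep) > 0))
  expect_error(gen_loop_odometry(bias = 0.2), "bias")
})

test_that("the scene renderer is pose-deterministic with a local pose-difference link", {
  po <- data.frame(x = c(3, 3, 6), y = c(4, 4, 7), heading = c(1, 1, 2))
  fr <- gen_scene_stream(po, arena = 10, seed = 11)
  expect_identical(fr[[1]], fr[[2]])
  expect_false(identical(fr[[1]], fr[[3]]))
  # revisited pose on lap 2 reproduces the loop-closure signal
  cfg <- vtt_config()
  loop <- gen_loop_odometry(side = 4, laps = 2, speed = 1, dt = 0.01,
                            bias = 0, seed = 3)
  keep <- seq(1, nrow(loop$poses), by = 25)
  fr2 <- gen_scene_stream(loop$poses[keep, ], arena = 10, seed = 11)
  half <- length(keep) %/% 2
  s <- function(k) scene_features(fr2[[k]]$rgb, fr2[[k]]$depth,
                                  depth_max = 15)
  expect_lt(scene_difference(s(6), s(6 + half), cfg), cfg$mt0)
  # antipodal poses exceed the top-layer threshold
  anti <- gen_scene_stream(data.frame(x = c(2, 8), y = c(2, 8),
                                      heading = c(0.5, 0.5 + pi)),
                           arena = 10, seed = 11)
  sa <- lapply(anti, function(f) scene_features(f$rgb, f$depth,
                                                depth_max = 15))
  expect_gt(scene_difference(sa[[1]], sa[[2]], cfg),
            cfg$mt0 + (cfg$L - 1) * cfg$delta_d)
})

test_that("scene differences grow with pose distance for nearby same-heading poses", {
  set.seed(2)
  base <- data.frame(x = runif(40, 2, 8), y = runif(40, 2, 8),
                     heading = runif(40, 0, 2 * pi))
  offs <- runif(40, 0.05, 1)
  ang <- runif(40, 0, 2 * pi)
  probe <- data.frame(x = base$x + offs * cos(ang),
                      y = base$y + offs * sin(ang), heading = base$heading)
  f1 <- gen_scene_stream(base, arena = 10, seed = 11)
  f2 <- gen_scene_stream(probe, arena = 10, seed = 11)
  dd <- vapply(1:40, function(k) scene_difference(
    scene_features(f1[[k]]$rgb, f1[[k]]$depth, depth_max = 15),
    scene_features(f2[[k]]$rgb, f2[[k]]$depth, depth_max = 15)), 0)
  expect_gt(cor(offs, dd, method = "spearman"), 0.7)
})

test_that("the scene bank keeps its separation guarantees", {
  cfg <- vtt_config()
  bank <- gen_scene_bank(branching = c(4L, 3L, 2L, 2L), cfg = cfg, seed = 6)
  set.seed(1)
  ii <- sample(length(bank$scenes), 12)
  for (a in 1:11) for (b in (a + 1):12) {
    d <- scene_difference(bank$scenes[[ii[a]]], bank$scenes[[ii[b]]], cfg)
    expect_gt(d, cfg$mt0)
  }
  # different top groups exceed the top-layer threshold
  top_thr <- cfg$mt0 + (cfg$L - 1) * cfg$delta_d
  i1 <- which(bank$labels[, 1] == 1)[1]
  i2 <- which(bank$labels[, 1] == 2)[1]
  expect_gt(scene_difference(bank$scenes[[i1]], bank$scenes[[i2]], cfg),
            top_thr)
})

test_that("workspace generation is seeded and feasible", {
  w1 <- gen_workspace("cluttered", seed = 3)
  w2 <- gen_workspace("cluttered", seed = 3)
  expect_identical(w1, w2)
  expect_true(length(w1$obstacles) >= 3 && length(w1$obstacles) <= 6)
  expect_true(workspace_feasible(w1, c(2, 2), c(18, 18)))
  open <- gen_workspace("open", seed = 1)
  expect_equal(length(open$obstacles), 0L)
})
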