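test_that("recall metrics reproduce the printed two-lap arithmetic", {
  m1 <- recall_metrics(M_1 = 172, M_2 = 69, M_p = 116)
  expect_equal(m1$M_r, 67.44)
  expect_equal(m1$M_t, 241)
  m2 <- recall_metrics(M_1 = 159, M_2 = 73, M_p = 113)
  expect_equal(m2$M_r, 71.06)
  expect_equal(m2$M_t, 232)
})

test_that("activity reset restores snapshots and is idempotent", {
  stack <- tiny_stack()
  snap <- list(g = lapply(stack$modules, function(m) m$g), p = NULL)
  exp_node <- list(id = 1L, pose = c(0, 0), place_id = 1L, template_id = 1L,
                   snapshots = snap, created_step = 1L)
  odo <- data.frame(t = (1:100) * 0.001, vx = 0.3, vy = 0)
  moved <- integrate_path(stack, odo, record_every = 0L)$stack
  expect_false(identical(moved$modules[[1]]$g, stack$modules[[1]]$g))
  back <- reset_activities(moved, exp_node)
  expect_identical(back$modules[[1]]$g, stack$modules[[1]]$g)
  again <- reset_activities(back, exp_node)
  expect_identical(again$modules[[1]]$g, back$modules[[1]]$g)
  bad <- exp_node
  bad$snapshots$g <- bad$snapshots$g[1]
  expect_error(reset_activities(moved, bad), "mismatch")
})

# hand-built square loop with drift delta at the closing link
drifted_square_map <- function(delta) {
  side <- 2
  poses <- list(c(0, 0), c(side, 0), c(side, side), c(0, side))
  # odometry drifts: each measured leg is slightly long in x
  nodes <- lapply(1:4, function(i)
    list(id = i, pose = c(poses[[i]][1] + (i - 1) * delta / 3, poses[[i]][2]),
         place_id = i, template_id = i, snapshots = NULL, created_step = i))
  links <- data.frame(
    from = 1:4, to = c(2, 3, 4, 1),
    dx = c(side, 0, -side, 0), dy = c(0, side, 0, -side))
  list(nodes = nodes, links = links,
       loop_events = list(list(step = 5, experience = 1, link = 4L)),
       n_steps = 5L)
}

test_that("relaxation closes a drifted square loop and is monotone", {
  delta <- 0.6
  map <- drifted_square_map(delta)
  gap0 <- endpoint_gap(map)
  expect_gt(gap0, 0.5 * delta)
  inc <- map_inconsistency(map)
  relaxed <- relax_map(map, iterations = 100, rate = 0.5)
  expect_lt(map_inconsistency(relaxed), inc)
  expect_lt(endpoint_gap(relaxed), 0.1 * delta)
  # intermediate sweeps never increase the inconsistency
  m <- map
  prev <- inc
  for (i in 1:10) {
    m <- relax_map(m, iterations = 5, rate = 0.5)
    cur <- map_inconsistency(m)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("maps without loop events or with consistent links stay unchanged", {
  map <- drifted_square_map(0.4)
  map$loop_events <- list()
  out <- relax_map(map)
  expect_identical(out$nodes, map$nodes)
  two <- list(nodes = list(list(id = 1, pose = c(0, 0)),
                           list(id = 2, pose = c(1, 0))),
              links = data.frame(from = 1, to = 2, dx = 1, dy = 0),
              loop_events = list(list(step = 2, experience = 1, link = 1L)))
  out2 <- relax_map(two, iterations = 50, rate = 0.5)
  expect_equal(out2$nodes[[1]]$pose, c(0, 0), tolerance = 1e-12)
  expect_equal(out2$nodes[[2]]$pose, c(1, 0), tolerance = 1e-12)
})

test_that("the mapping loop creates experiences and matches Algorithm-1 branching", {
  res <- acc_trained()
  loop <- gen_loop_odometry(side = 1.25, laps = 1, speed = 0.25, dt = 0.001,
                            bias = 0, noise_sd = 0, seed = 5)
  # stop short of the lap end so the return to the start (a genuine loop
  # closure) is not part of this pre-closure check
  fidx <- seq(625, nrow(loop$poses) - 700, by = 625)
  frames <- gen_scene_stream(loop$poses[fidx, ], arena = 2, seed = 11)
  map <- build_map(res$stack, res$place, loop$odometry, frames, gain = 150,
                   cfg = list(d_exp = 0.1, min_age = 5L))
  # first frame creates exactly one experience with no links
  expect_equal(map$nodes[[1]]$created_step, 1L)
  expect_gt(length(map$nodes), 5)
  expect_equal(nrow(map$links), length(map$nodes) - 1)  # single chain
  # before any loop closure the map trajectory follows raw odometry
  expect_equal(length(map$loop_events), 0L)
  raw_x <- cumsum(loop$odometry$vx * 0.001)[fidx - 1]
  raw_y <- cumsum(loop$odometry$vy * 0.001)[fidx - 1]
  # the neural dead reckoning tracks raw odometry to a few percent of the
  # 4+ m path
  expect_lt(max(abs(map$trajectory$x - raw_x)), 0.5)
  expect_lt(max(abs(map$trajectory$y - raw_y)), 0.5)
  expect_gt(cor(map$trajectory$x, raw_x), 0.95)
  expect_gt(cor(map$trajectory$y, raw_y), 0.95)
})

test_that("lap boundaries outside the run are rejected", {
  map <- list(nodes = list(list(created_step = 1L)), loop_events = list(),
              n_steps = 10L)
  class(map) <- "experience_map"
  expect_error(dead_reckoning_metrics(map, 20L), "boundary")
})
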