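test_that("place activation pins the winner at 0.5 and breaks ties row-major", {
  set.seed(1)
  acts <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  pm <- place_module(3)
  pa <- place_activation(acts, pm)
  expect_equal(max(pa$p), 0.5)
  expect_true(all(pa$p > 0 & pa$p < 1))
  u <- pm$w[1] * acts[, , 1] + pm$w[2] * acts[, , 2] + pm$w[3] * acts[, , 3]
  expect_equal(pa$p[which.max(u)], 0.5)
  # uniform activities: every cell ties at 0.5, winner is index 1
  pa0 <- place_activation(array(0.3, dim = c(8, 8, 3)), pm)
  expect_true(all(pa0$p == 0.5))
  expect_equal(pa0$winner, 1L)
  expect_equal(unname(pa0$winner_rc), c(1L, 1L))
  expect_error(place_activation(array(0.3, dim = c(8, 6, 3)), pm))
})

test_that("sharper place activation concentrates the population", {
  set.seed(2)
  acts <- array(runif(16 * 16 * 2), dim = c(16, 16, 2))
  counts <- vapply(c(5, 20, 50, 200), function(kp) {
    pa <- place_activation(acts, place_module(2, k_p = kp))
    sum(pa$p > 0.25)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("Hebbian updates keep weights non-negative with unit square norm", {
  set.seed(3)
  acts <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  pm <- place_module(4, lr = 1e-3)
  for (i in 1:50) {
    pa <- place_activation(acts, pm)
    pm <- hebbian_update(pm, pa, acts)
    expect_lt(abs(sum(pm$w^2) - 1), 1e-9)
    expect_gte(min(pm$w), 0)
  }
  # zero place activity leaves weights unchanged before renormalization
  pm2 <- place_module(4)
  pm3 <- hebbian_update(pm2, matrix(0, 8, 8), acts)
  expect_equal(pm3$w, pm2$w)
})

test_that("repeated updates on a fixed snapshot reach a fixed point", {
  set.seed(5)
  acts <- array(runif(8 * 8 * 2), dim = c(8, 8, 2))
  pm <- place_module(2, k_p = 5)
  deltas <- numeric(10000)
  for (it in seq_len(10000)) {
    pm <- hebbian_update(pm, place_activation(acts, pm), acts)
    deltas[it] <- attr(pm, "delta")
    if (deltas[it] < 1e-6 && it > 10) break
  }
  expect_lt(deltas[it], 1e-6)
})

test_that("training is deterministic and inert at zero learning rate", {
  stack <- tiny_stack()
  odo <- data.frame(t = (1:300) * 0.001, vx = 0.15, vy = 0.05)
  tr1 <- train_weights(stack, odo, place_module(2), consolidate = FALSE)
  tr2 <- train_weights(stack, odo, place_module(2), consolidate = FALSE)
  expect_identical(tr1$place$w, tr2$place$w)
  tr0 <- train_weights(stack, odo, place_module(2, lr = 0),
                       consolidate = FALSE)
  expect_equal(tr0$place$w, place_module(2)$w)
  expect_true(all(tr0$trace == 0))
})

test_that("decoding recovers a stationary and a linear path", {
  res <- acc_trained()
  # stationary: constant decoded position
  odo0 <- data.frame(t = (1:400) * 0.001, vx = 0, vy = 0)
  h0 <- integrate_path(res$stack, odo0, record_every = 10L,
                       place = res$place)
  truth0 <- data.frame(t = odo0$t, x = 1, y = 1)
  dec0 <- decode_trajectory(h0, truth0)
  expect_lt(diff(range(dec0$x)), 0.02)
  expect_lt(diff(range(dec0$y)), 0.02)
  # ground-truth linear path: decoded path collinear with truth
  n <- 1500
  odo1 <- data.frame(t = (1:n) * 0.001, vx = 0.25 * cos(0.4),
                     vy = 0.25 * sin(0.4))
  h1 <- integrate_path(h0$stack, odo1, record_every = 10L,
                       place = res$place)
  truth1 <- data.frame(t = odo1$t, x = odo1$t * odo1$vx[1],
                       y = odo1$t * odo1$vy[1])
  for (meth in c("displacement", "winner")) {
    dec1 <- suppressWarnings(decode_trajectory(h1, truth1, method = meth))
    fit <- suppressWarnings(summary(lm(dec1$y ~ dec1$x)))
    expect_gt(fit$r.squared, 0.95)
  }
})

test_that("revisiting a position under drift-free odometry reactivates the same place code", {
  res <- acc_trained()
  N <- 40L
  # short out-and-back: return exactly to the start; the attractor ripple
  # bounds how precisely the state returns, and an activity reset restores
  # the winner exactly
  n <- 400
  out <- data.frame(t = (1:n) * 0.001, vx = 0.25, vy = 0)
  back <- data.frame(t = (n + 1:n) * 0.001, vx = -0.25, vy = 0)
  w_start <- place_activation(res$stack, res$place)
  h_out <- integrate_path(res$stack, out, record_every = 10L,
                          place = res$place)
  h_back <- integrate_path(h_out$stack, back, record_every = 10L,
                           place = res$place)
  # every module's pattern returns to its start within the attractor's
  # ripple scale (a few neurons, ~2-3 cm at the default gain)
  round_trip <- h_out$disp[nrow(h_out$disp), ] +
    h_back$disp[nrow(h_back$disp), ]
  expect_lt(max(abs(round_trip)), 5)
  # resetting to the stored snapshots makes the recall exact
  snap <- list(g = lapply(res$stack$modules, function(m) m$g), p = NULL)
  exp_node <- list(id = 1L, snapshots = snap)
  restored <- reset_activities(h_back$stack, exp_node)
  expect_identical(place_activation(restored, res$place)$winner,
                   w_start$winner)
})
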