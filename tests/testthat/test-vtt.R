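# features with every pixel equal, so the shift search leaves the mean
# absolute difference untouched and modality differences are exact
flat_scene <- function(rgb_val, depth_val) {
  structure(list(rgb_feat = matrix(rgb_val, 24, 32),
                 depth_feat = matrix(depth_val, 24, 32),
                 frame_id = NA_integer_), class = "scene")
}

test_that("scene features are deterministic and tolerate brightness shifts", {
  traj <- data.frame(x = 5, y = 5, heading = 1)
  fr <- gen_scene_stream(traj, arena = 10, seed = 4)[[1]]
  s1 <- scene_features(fr$rgb, fr$depth, depth_max = 15)
  s2 <- scene_features(fr$rgb, fr$depth, depth_max = 15)
  expect_identical(s1, s2)
  # global brightness shift is removed by contrast normalization
  s3 <- scene_features(pmin(fr$rgb + 0.2, 1.2), fr$depth, depth_max = 15)
  expect_lt(mean(abs(s3$rgb_feat - s1$rgb_feat)), 0.05)
  expect_error(scene_features(fr$rgb, fr$depth[1:10, ]), "same size")
  # zero-variance frame stays defined
  s4 <- scene_features(matrix(0.5, 24, 32), matrix(1, 24, 32), depth_max = 2)
  expect_true(all(is.finite(s4$rgb_feat)))
})

test_that("scene difference implements the weighted two-modality metric", {
  cfg <- vtt_config(Wr = 0.6, Wd = 0.4)
  a <- flat_scene(0, 0)
  b <- flat_scene(0.5, 0.25)
  expect_equal(scene_difference(a, b, cfg), 0.6 * 0.5 + 0.4 * 0.25)
  expect_equal(scene_difference(a, a, cfg), 0)
  # symmetry on random feature pairs
  set.seed(6)
  for (i in 1:5) {
    s1 <- structure(list(rgb_feat = matrix(runif(768), 24, 32),
                         depth_feat = matrix(runif(768), 24, 32),
                         frame_id = NA), class = "scene")
    s2 <- structure(list(rgb_feat = matrix(runif(768), 24, 32),
                         depth_feat = matrix(runif(768), 24, 32),
                         frame_id = NA), class = "scene")
    expect_equal(scene_difference(s1, s2, cfg),
                 scene_difference(s2, s1, cfg))
  }
  bad <- structure(list(rgb_feat = matrix(0, 12, 32),
                        depth_feat = matrix(0, 12, 32), frame_id = NA),
                   class = "scene")
  expect_error(scene_difference(a, bad), "lengths differ")
})

test_that("tree insert/query handles the empty tree and exact re-queries", {
  cfg <- vtt_config()
  tree <- vtt_new(cfg)
  bank <- gen_scene_bank(branching = c(3L, 2L, 2L, 2L), cfg = cfg, seed = 9)
  r1 <- vtt_query_insert(tree, bank$scenes[[1]])
  expect_false(r1$matched)
  expect_equal(r1$template_id, 1L)
  expect_equal(r1$comparisons, 0L)
  expect_equal(length(tree$nodes), cfg$L)  # one full branch to a leaf
  r2 <- vtt_query_insert(tree, bank$scenes[[1]])
  expect_true(r2$matched)
  expect_equal(r2$template_id, 1L)
  expect_equal(r2$difference, 0)
})

test_that("a repeated stream of separated scenes creates no second-pass templates", {
  cfg <- vtt_config()
  bank <- gen_scene_bank(branching = c(4L, 2L, 2L, 2L), cfg = cfg, seed = 2)
  tree <- vtt_new(cfg)
  for (s in bank$scenes) vtt_query_insert(tree, s)
  n1 <- tree$n_templates
  for (s in bank$scenes) {
    r <- vtt_query_insert(tree, s)
    expect_true(r$matched)
  }
  expect_equal(tree$n_templates, n1)
  expect_equal(n1, length(bank$scenes))
})

test_that("linear library implements the exhaustive matching contract", {
  cfg <- vtt_config()
  lib <- linear_library_new(cfg)
  bank <- gen_scene_bank(branching = c(3L, 2L, 2L, 2L), cfg = cfg, seed = 3)
  r1 <- linear_query_insert(lib, bank$scenes[[1]])
  expect_false(r1$matched)
  expect_equal(r1$template_id, 1L)
  expect_equal(r1$comparisons, 0L)
  for (s in bank$scenes[-1]) linear_query_insert(lib, s)
  n <- length(lib$templates)
  r <- linear_query_insert(lib, bank$scenes[[5]])
  expect_true(r$matched)
  expect_equal(r$template_id, 5L)
  expect_equal(r$comparisons, n)
})

test_that("tree and linear matching agree on well-separated streams", {
  cfg <- vtt_config()
  bank <- gen_scene_bank(branching = c(4L, 3L, 3L), cfg = vtt_config(L = 4),
                         seed = 5)
  set.seed(8)
  stream <- c(sample(length(bank$scenes)), sample(length(bank$scenes), 30))
  tree <- vtt_new(cfg)
  lib <- linear_library_new(cfg)
  tid_t <- tid_l <- integer(0)
  for (k in stream) {
    tid_t <- c(tid_t, vtt_query_insert(tree, bank$scenes[[k]])$template_id)
    tid_l <- c(tid_l, linear_query_insert(lib, bank$scenes[[k]])$template_id)
  }
  expect_identical(tid_t, tid_l)
})

test_that("template ids replay deterministically and mt0 is monotone", {
  cfg <- vtt_config()
  bank <- gen_scene_bank(branching = c(3L, 2L, 2L, 2L), cfg = cfg, seed = 4)
  set.seed(2)
  stream <- sample(length(bank$scenes), 40, replace = TRUE)
  run <- function(cfg) {
    tree <- vtt_new(cfg)
    ids <- vapply(stream, function(k)
      vtt_query_insert(tree, bank$scenes[[k]])$template_id, 1L)
    list(ids = ids, n = tree$n_templates)
  }
  a <- run(cfg)
  b <- run(cfg)
  expect_identical(a$ids, b$ids)
  # lowering mt0 never decreases the number of templates created
  n_by_mt0 <- vapply(c(0.3, 0.1, 0.02, 0.005), function(m)
    run(vtt_config(mt0 = m, delta_d = cfg$delta_d))$n, 1L)
  expect_true(all(diff(n_by_mt0) >= 0))
})
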