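#' Planning workspace
#'
#' Rectangular workspace with axis-aligned rectangular obstacles and a fixed
#' collision-check resolution.
#'
#' @param bounds \code{c(xmin, xmax, ymin, ymax)} in meters.
#' @param obstacles List of rectangles \code{c(xmin, xmax, ymin, ymax)}.
#' @param resolution Collision-check step in meters.
#' @return An object of class \code{"workspace"}.
#' @export
workspace <- function(bounds = c(0, 20, 0, 20), obstacles = list(),
                      resolution = 0.1) {
  stopifnot(length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3],
            resolution > 0)
  for (ob in obstacles) {
    stopifnot(length(ob) == 4)
    if (ob[1] < bounds[1] - 1e-9 || ob[2] > bounds[2] + 1e-9 ||
        ob[3] < bounds[3] - 1e-9 || ob[4] > bounds[4] + 1e-9)
      stop("obstacle outside bounds", call. = FALSE)
  }
  structure(list(bounds = bounds, obstacles = obstacles,
                 resolution = resolution), class = "workspace")
}

#' Point collision test
#' @param ws A [workspace()].
#' @param q Point \code{c(x, y)}.
#' @return \code{TRUE} if \code{q} lies inside an obstacle or outside bounds.
#' @export
point_in_collision <- function(ws, q) {
  b <- ws$bounds
  if (q[1] < b[1] || q[1] > b[2] || q[2] < b[3] || q[2] > b[4]) return(TRUE)
  for (ob in ws$obstacles)
    if (q[1] >= ob[1] && q[1] <= ob[2] && q[2] >= ob[3] && q[2] <= ob[4])
      return(TRUE)
  FALSE
}

# vectorized point-set collision test
.points_in_collision <- function(ws, x, y) {
  b <- ws$bounds
  hit <- x < b[1] | x > b[2] | y < b[3] | y > b[4]
  for (ob in ws$obstacles)
    hit <- hit | (x >= ob[1] & x <= ob[2] & y >= ob[3] & y <= ob[4])
  hit
}

#' Segment collision test
#'
#' Densifies the segment at the workspace resolution and tests every sample.
#'
#' @param ws A [workspace()].
#' @param a,b Segment endpoints.
#' @param step Sampling step (defaults to the workspace resolution).
#' @return \code{TRUE} if every sample is collision-free.
#' @export
segment_free <- function(ws, a, b, step = ws$resolution) {
  len <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(len / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  !any(.points_in_collision(ws, a[1] + tt * (b[1] - a[1]),
                            a[2] + tt * (b[2] - a[2])))
}

#' Coarse-grid feasibility check
#'
#' Breadth-first search on a coarse occupancy grid; used to verify that a
#' generated workspace leaves a corridor between two query points.
#'
#' @param ws A [workspace()].
#' @param a,b Query points.
#' @param cell Coarse cell size in meters.
#' @return \code{TRUE} if a free-cell path connects the two points.
#' @export
workspace_feasible <- function(ws, a, b, cell = 0.5) {
  bnd <- ws$bounds
  nx <- ceiling((bnd[2] - bnd[1]) / cell)
  ny <- ceiling((bnd[4] - bnd[3]) / cell)
  cx <- bnd[1] + (seq_len(nx) - 0.5) * cell
  cy <- bnd[3] + (seq_len(ny) - 0.5) * cell
  free <- !outer(cy, cx, function(yy, xx) .points_in_collision(ws, xx, yy))
  idx <- function(q) c(pmin(pmax(ceiling((q[2] - bnd[3]) / cell), 1), ny),
                       pmin(pmax(ceiling((q[1] - bnd[1]) / cell), 1), nx))
  ia <- idx(a); ib <- idx(b)
  if (!free[ia[1], ia[2]] || !free[ib[1], ib[2]]) return(FALSE)
  seen <- matrix(FALSE, ny, nx)
  queue <- matrix(ia, 1, 2)
  seen[ia[1], ia[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    if (cur[1] == ib[1] && cur[2] == ib[2]) return(TRUE)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r >= 1 && r <= ny && c >= 1 && c <= nx &&
          free[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  FALSE
}

#' Analytic hexagonal grid-cell firing field
#'
#' Three-cosine hexagonal interference pattern over the workspace bins:
#' \code{f(x) = sum_i cos(k_i . (x - phase))} with 60-degree-spaced wave
#' vectors of magnitude \code{4 * pi / (sqrt(3) * g_scale)}, rescaled to
#' \[0, 1\]. Used as the planner-side stand-in for a simulated rate map;
#' any matrix of non-negative rates can be supplied instead.
#'
#' @param ws A [workspace()].
#' @param g_scale Grid period (nearest-field distance) in meters.
#' @param phase Spatial phase offset \code{c(x, y)} in meters.
#' @param orientation Grid orientation in radians.
#' @param bin Field sampling step in meters.
#' @return An object of class \code{"grid_pattern"}: \code{field} matrix
#'   (rows = y), bin centers \code{xs}, \code{ys}, and \code{g_scale}.
#' @export
hex_grid_pattern <- function(ws, g_scale, phase = c(0, 0), orientation = 0,
                             bin = 0.2) {
  b <- ws$bounds
  xs <- seq(b[1] + bin / 2, b[2] - bin / 2, by = bin)
  ys <- seq(b[3] + bin / 2, b[4] - bin / 2, by = bin)
  kmag <- 4 * pi / (sqrt(3) * g_scale)
  ang <- orientation + c(0, pi / 3, 2 * pi / 3)
  X <- outer(rep(1, length(ys)), xs) - phase[1]
  Y <- outer(ys, rep(1, length(xs))) - phase[2]
  f <- matrix(0, length(ys), length(xs))
  for (a in ang) f <- f + cos(kmag * (cos(a) * X + sin(a) * Y))
  f <- (f - min(f)) / (max(f) - min(f))
  structure(list(field = f, xs = xs, ys = ys, g_scale = g_scale, bin = bin),
            class = "grid_pattern")
}

#' Multi-scale grid patterns for planning
#'
#' A bank of analytic hexagonal fields: \code{n_scales} spatial scales with
#' successive ratio \code{ratio} (within the biological 1.4-1.7 module
#' ratio range), each at a small grid of phase offsets so that some cell of
#' every scale is active near any query point.
#'
#' @param ws A [workspace()].
#' @param base_scale Smallest grid period in meters.
#' @param ratio Scale ratio between successive modules.
#' @param n_scales Number of scales.
#' @param phases_per_scale Side of the phase-offset grid per scale.
#' @return List of [hex_grid_pattern()] objects with \code{$id} and
#'   \code{$scale_index} attached.
#' @export
planning_patterns <- function(ws, base_scale = 2, ratio = 1.5, n_scales = 3,
                              phases_per_scale = 3) {
  out <- list()
  id <- 0L
  for (s in seq_len(n_scales)) {
    g_scale <- base_scale * ratio^(s - 1)
    offs <- (seq_len(phases_per_scale) - 1) / phases_per_scale * g_scale
    for (ox in offs) for (oy in offs) {
      id <- id + 1L
      pat <- hex_grid_pattern(ws, g_scale, phase = c(ox, oy))
      pat$id <- id
      pat$scale_index <- s
      out[[id]] <- pat
    }
  }
  out
}

# field value at a point (nearest bin)
.pattern_value <- function(pattern, q) {
  ix <- which.min(abs(pattern$xs - q[1]))
  iy <- which.min(abs(pattern$ys - q[2]))
  pattern$field[iy, ix]
}

#' Select grid cells whose firing fields cover start and goal
#'
#' From a pattern bank, keeps per scale the cell with the strongest joint
#' activation \code{min(field(q_init), field(q_goal))}, excluding cells
#' whose field is (near) zero at either endpoint.
#'
#' @param patterns List from [planning_patterns()] (or compatible).
#' @param q_init,q_goal Query points.
#' @param floor_value Minimum field value at both endpoints.
#' @return Sub-list of selected patterns (possibly empty).
#' @export
select_active_cells <- function(patterns, q_init, q_goal,
                                floor_value = 0.05) {
  scales <- vapply(patterns, function(p)
    if (is.null(p$scale_index)) 1L else p$scale_index, 1L)
  sel <- list()
  for (s in unique(scales)) {
    cand <- patterns[scales == s]
    score <- vapply(cand, function(p)
      min(.pattern_value(p, q_init), .pattern_value(p, q_goal)), 0)
    k <- which.max(score)
    if (score[k] >= floor_value) sel[[length(sel) + 1L]] <- cand[[k]]
  }
  sel
}

#' Active positions of a firing field
#'
#' The sampling support: bin centers where the field reaches the given
#' activation quantile.
#'
#' @param pattern A [hex_grid_pattern()].
#' @param threshold Activation quantile in \[0, 1).
#' @return Matrix of \code{(x, y)} support bin centers.
#' @export
active_positions <- function(pattern, threshold = 0.8) {
  cut <- stats::quantile(pattern$field, threshold)
  hit <- which(pattern$field >= cut, arr.ind = TRUE)
  if (nrow(hit) == 0L) stop("empty sampling support", call. = FALSE)
  cbind(x = pattern$xs[hit[, 2]], y = pattern$ys[hit[, 1]])
}

# core RRT* loop; sample_fun() returns one q_rand
.rrt_star_core <- function(ws, q_init, q_goal, iters, sample_fun, steer_step,
                           near_radius, goal_radius, goal_bias) {
  V <- matrix(0, iters + 1L, 2)
  V[1, ] <- q_init
  parent <- integer(iters + 1L)
  parent[1] <- 0L
  cost <- numeric(iters + 1L)
  n <- 1L
  for (it in seq_len(iters)) {
    q_rand <- if (runif(1) < goal_bias) q_goal else sample_fun()
    d2 <- (V[1:n, 1] - q_rand[1])^2 + (V[1:n, 2] - q_rand[2])^2
    i_near <- which.min(d2)
    q_nearest <- V[i_near, ]
    dd <- sqrt(d2[i_near])
    q_new <- if (dd <= steer_step) q_rand else
      q_nearest + steer_step * (q_rand - q_nearest) / dd
    if (!segment_free(ws, q_nearest, q_new)) next
    nd <- sqrt((V[1:n, 1] - q_new[1])^2 + (V[1:n, 2] - q_new[2])^2)
    near_set <- which(nd <= near_radius)
    # choose parent
    i_min <- i_near
    c_min <- cost[i_near] + sqrt(sum((q_new - q_nearest)^2))
    for (i in near_set) {
      ci <- cost[i] + nd[i]
      if (ci < c_min && segment_free(ws, V[i, ], q_new)) {
        i_min <- i
        c_min <- ci
      }
    }
    n <- n + 1L
    V[n, ] <- q_new
    parent[n] <- i_min
    cost[n] <- c_min
    # rewire neighbors through q_new, propagating cost to descendants
    for (i in near_set) {
      ci <- cost[n] + nd[i]
      if (ci < cost[i] && segment_free(ws, q_new, V[i, ])) {
        delta <- cost[i] - ci
        parent[i] <- n
        # propagate the improvement through the subtree rooted at i
        aff <- i
        frontier <- i
        while (length(frontier) > 0) {
          kids <- which(parent[1:n] %in% frontier)
          kids <- setdiff(kids, aff)
          if (length(kids) == 0) break
          aff <- c(aff, kids)
          frontier <- kids
        }
        cost[aff] <- cost[aff] - delta
      }
    }
  }
  list(V = V[1:n, , drop = FALSE], parent = parent[1:n], cost = cost[1:n],
       n = n)
}

# best goal-reaching path of a tree, or NULL
.tree_best_path <- function(tree, q_goal, goal_radius) {
  gd <- sqrt((tree$V[, 1] - q_goal[1])^2 + (tree$V[, 2] - q_goal[2])^2)
  in_goal <- which(gd <= goal_radius)
  if (length(in_goal) == 0L) return(NULL)
  best <- in_goal[which.min(tree$cost[in_goal])]
  path <- best
  while (tree$parent[path[1]] != 0L) path <- c(tree$parent[path[1]], path)
  list(waypoints = tree$V[path, , drop = FALSE], cost = tree$cost[best])
}

# greedy shortcut of a waypoint path against the workspace
.shortcut_path <- function(ws, waypoints) {
  n <- nrow(waypoints)
  keep <- 1L
  i <- 1L
  while (i < n) {
    j <- n
    while (j > i + 1L && !segment_free(ws, waypoints[i, ], waypoints[j, ]))
      j <- j - 1L
    keep <- c(keep, j)
    i <- j
  }
  wp <- waypoints[keep, , drop = FALSE]
  list(waypoints = wp,
       cost = sum(sqrt(rowSums((wp[-1, , drop = FALSE] -
                                  wp[-nrow(wp), , drop = FALSE])^2))))
}

#' Plain RRT* planner (baseline)
#'
#' Uniform free-space sampling, fixed near radius, standard choose-parent
#' and rewire steps with cost propagation.
#'
#' @param ws A [workspace()].
#' @param q_init,q_goal Start point and goal point.
#' @param iters Iteration budget.
#' @param seed RNG seed.
#' @param steer_step Steering step in meters.
#' @param near_radius Fixed rewiring radius in meters.
#' @param goal_radius Goal region radius in meters.
#' @param goal_bias Probability of sampling the goal.
#' @return An object of class \code{"plan_result"}: \code{success},
#'   \code{path} (waypoint matrix or \code{NULL}), \code{cost}, and the
#'   \code{trees} used.
#' @export
rrt_star_baseline <- function(ws, q_init, q_goal, iters = 1000L, seed = 1L,
                              steer_step = 1, near_radius = 2,
                              goal_radius = 0.5, goal_bias = 0.05) {
  if (point_in_collision(ws, q_init) || point_in_collision(ws, q_goal))
    stop("start or goal in collision", call. = FALSE)
  set.seed(seed)
  b <- ws$bounds
  sample_fun <- function() {
    repeat {
      q <- c(runif(1, b[1], b[2]), runif(1, b[3], b[4]))
      if (!point_in_collision(ws, q)) return(q)
    }
  }
  tree <- .rrt_star_core(ws, q_init, q_goal, iters, sample_fun, steer_step,
                         near_radius, goal_radius, goal_bias)
  best <- .tree_best_path(tree, q_goal, goal_radius)
  structure(list(success = !is.null(best),
                 path = if (is.null(best)) NULL else best$waypoints,
                 cost = if (is.null(best)) NA_real_ else best$cost,
                 trees = list(tree)), class = "plan_result")
}

#' Grid-cell-guided multi-scale RRT*
#'
#' For each selected grid cell (one per scale whose firing field is active
#' at both endpoints) an RRT* tree is grown with samples drawn from that
#' cell's active firing positions, steering step \code{g_scale / 2} and
#' rewiring radius \code{gamma * g_scale}. The per-scale candidate paths are
#' then cross-rewired (greedy shortcutting against the workspace) and the
#' cheapest collision-free path is returned. With no covering cell at any
#' scale the planner falls back to the uniform baseline with a warning.
#'
#' @inheritParams rrt_star_baseline
#' @param patterns Pattern bank from [planning_patterns()] (or simulated
#'   rate maps wrapped as \code{"grid_pattern"} objects).
#' @param gamma Rewiring-radius multiple of the grid scale.
#' @param support_threshold Activation quantile defining the sampling
#'   support.
#' @return A \code{"plan_result"} with per-cell trees and candidate paths.
#' @export
gc_rrt_star <- function(ws, patterns, q_init, q_goal, iters = 1000L,
                        seed = 1L, gamma = 3, goal_radius = 0.5,
                        goal_bias = 0.05, support_threshold = 0.8) {
  if (point_in_collision(ws, q_init) || point_in_collision(ws, q_goal))
    stop("start or goal in collision", call. = FALSE)
  cells <- select_active_cells(patterns, q_init, q_goal)
  if (length(cells) == 0L) {
    warning("no grid cell covers both endpoints; falling back to plain RRT*")
    return(rrt_star_baseline(ws, q_init, q_goal, iters = iters, seed = seed,
                             goal_radius = goal_radius,
                             goal_bias = goal_bias))
  }
  trees <- list()
  cands <- list()
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    set.seed(seed + k - 1L)
    sup <- active_positions(cell, support_threshold)
    jit <- cell$bin / 2
    sample_fun <- function() {
      repeat {
        i <- sample.int(nrow(sup), 1L)
        q <- sup[i, ] + runif(2, -jit, jit)
        if (!point_in_collision(ws, q)) return(q)
      }
    }
    tree <- .rrt_star_core(ws, q_init, q_goal, iters, sample_fun,
                           steer_step = cell$g_scale / 2,
                           near_radius = gamma * cell$g_scale,
                           goal_radius = goal_radius, goal_bias = goal_bias)
    trees[[k]] <- tree
    best <- .tree_best_path(tree, q_goal, goal_radius)
    if (!is.null(best)) cands[[length(cands) + 1L]] <- best
  }
  if (length(cands) == 0L)
    return(structure(list(success = FALSE, path = NULL, cost = NA_real_,
                          trees = trees), class = "plan_result"))
  # cross-tree rewiring: shortcut each candidate against the workspace and
  # keep the cheapest
  cands <- lapply(cands, function(p) .shortcut_path(ws, p$waypoints))
  costs <- vapply(cands, function(p) p$cost, 0)
  best <- cands[[which.min(costs)]]
  structure(list(success = TRUE, path = best$waypoints, cost = best$cost,
                 trees = trees), class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  if (x$success)
    cat(sprintf("plan_result: success, cost = %.2f m, %d waypoints\n",
                x$cost, nrow(x$path)))
  else cat("plan_result: failure (no tree reached the goal region)\n")
  invisible(x)
}
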