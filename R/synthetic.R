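#' Generate a smooth foraging trajectory
#'
#' Random exploratory path in a square arena: constant speed, heading
#' diffusing as a random walk (Ornstein-Uhlenbeck-style smooth turning),
#' reflective walls (heading mirrors at a wall, keeping speed statistics
#' stationary). Velocities are exact pose differences, so integrating the
#' returned odometry reproduces the poses to machine precision.
#'
#' @param arena Square side length in meters.
#' @param duration Duration in seconds.
#' @param dt Time step in seconds (match the consumer's integration step).
#' @param speed Constant running speed in m/s.
#' @param turn_sd Heading diffusion scale in rad per sqrt(s).
#' @param seed RNG seed.
#' @return List with \code{poses} (data frame \code{t, x, y, heading}) and
#'   \code{odometry} (data frame \code{t, vx, vy}; row k moves pose k to
#'   pose k+1).
#' @export
gen_foraging_trajectory <- function(arena = 1, duration = 200, dt = 0.001,
                                    speed = 0.25, turn_sd = 1.2, seed = 1L) {
  set.seed(seed)
  steps <- round(duration / dt)
  x <- numeric(steps + 1)
  y <- numeric(steps + 1)
  th <- numeric(steps + 1)
  x[1] <- arena / 2
  y[1] <- arena / 2
  th[1] <- runif(1, 0, 2 * pi)
  if (steps > 0) {
    dth <- rnorm(steps, 0, turn_sd * sqrt(dt))
    for (k in seq_len(steps)) {
      th[k + 1] <- th[k] + dth[k]
      nx <- x[k] + speed * cos(th[k + 1]) * dt
      ny <- y[k] + speed * sin(th[k + 1]) * dt
      # reflective boundary: mirror position and heading at the wall
      if (nx < 0 || nx > arena) {
        th[k + 1] <- pi - th[k + 1]
        nx <- pmin(pmax(2 * (nx > arena) * arena - nx + 2 * (nx < 0) * 0,
                        0), arena)
        nx <- if (nx < 0) -nx else if (nx > arena) 2 * arena - nx else nx
      }
      if (ny < 0 || ny > arena) {
        th[k + 1] <- -th[k + 1]
        ny <- if (ny < 0) -ny else if (ny > arena) 2 * arena - ny else ny
      }
      x[k + 1] <- nx
      y[k + 1] <- ny
    }
  }
  t_pose <- (0:steps) * dt
  poses <- data.frame(t = t_pose, x = x, y = y, heading = th %% (2 * pi))
  odometry <- data.frame(t = t_pose[-1],
                         vx = diff(x) / dt, vy = diff(y) / dt)
  list(poses = poses, odometry = odometry)
}

#' Generate closed-loop odometry with encoder drift
#'
#' Builds a closed square path traversed \code{laps} times and corrupts the
#' body-frame odometry increments with a multiplicative encoder scale bias
#' plus additive speed noise. The bias scales both the translational and the
#' rotational increments, as a uniform wheel-encoder scale error does; a
#' bias applied to planar velocity components alone is a linear map and
#' cannot open a closed loop, so it would produce no endpoint gap.
#'
#' @param side Square side length in meters (lap length is \code{4 * side}).
#' @param laps Number of laps (>= 2 for dead-reckoning analyses).
#' @param speed Speed along the path in m/s.
#' @param dt Time step in seconds.
#' @param bias Multiplicative encoder bias in \[0, 0.1\].
#' @param noise_sd Additive speed noise (m/s).
#' @param seed RNG seed.
#' @return List with \code{poses} (true \code{t, x, y, heading}),
#'   \code{odometry} (corrupted \code{t, vx, vy}), \code{lap_boundaries}
#'   (odometry row index where each new lap starts), and
#'   \code{endpoint_gap} (distance between the corrupted integration's
#'   endpoint and start, for a single lap's worth of rows per lap).
#' @export
gen_loop_odometry <- function(side = 10, laps = 2L, speed = 1, dt = 0.001,
                              bias = 0.05, noise_sd = 0, seed = 1L) {
  if (bias < 0 || bias > 0.1)
    stop("bias must lie in [0, 0.1]", call. = FALSE)
  if (laps < 1L) stop("laps must be >= 1", call. = FALSE)
  set.seed(seed)
  per_side <- round(side / (speed * dt))
  per_lap <- 4L * per_side
  steps <- per_lap * laps
  # true headings: four axis-aligned legs per lap, counterclockwise
  leg_dirs <- c(0, pi / 2, pi, 3 * pi / 2)
  th_true <- rep(rep(leg_dirs, each = per_side), laps)
  ds_true <- rep(speed * dt, steps)
  dth_true <- c(0, diff(th_true))
  dth_true <- (dth_true + pi) %% (2 * pi) - pi  # minimal turn increments
  # true poses
  x_true <- cumsum(c(0, ds_true * cos(th_true)))
  y_true <- cumsum(c(0, ds_true * sin(th_true)))
  t_pose <- (0:steps) * dt
  poses <- data.frame(t = t_pose, x = x_true, y = y_true,
                      heading = c(th_true[1], th_true))
  # corrupted body-frame increments
  ds_odo <- ds_true * (1 + bias) + rnorm(steps, 0, noise_sd) * dt
  dth_odo <- dth_true * (1 + bias)
  th_odo <- th_true[1] + cumsum(dth_odo)
  vx <- ds_odo * cos(th_odo) / dt
  vy <- ds_odo * sin(th_odo) / dt
  odometry <- data.frame(t = t_pose[-1], vx = vx, vy = vy)
  xi <- cumsum(vx * dt)
  yi <- cumsum(vy * dt)
  gap <- sqrt(xi[per_lap]^2 + yi[per_lap]^2)
  list(poses = poses, odometry = odometry,
       lap_boundaries = if (laps > 1L)
         seq(per_lap + 1L, steps, by = per_lap) else integer(0),
       per_lap = per_lap, endpoint_gap = gap)
}

# perimeter texture of the procedural arena: smooth positive function of
# the perimeter coordinate, drawn once from the world seed
.wall_texture <- function(seed, n_harmonics = 24L) {
  set.seed(seed)
  freq <- sample(1:40, n_harmonics, replace = TRUE)
  amp <- runif(n_harmonics, 0.3, 1) / sqrt(seq_len(n_harmonics))
  phase <- runif(n_harmonics, 0, 2 * pi)
  function(s01) {
    v <- rep(0, length(s01))
    for (k in seq_len(n_harmonics))
      v <- v + amp[k] * sin(2 * pi * freq[k] * s01 + phase[k])
    (v - min(v)) / max(max(v) - min(v), 1e-12) * 0.8 + 0.1
  }
}

# cast one set of rays from (x, y) at absolute angles into the square
# [0, A]^2; returns hit distance and perimeter coordinate in [0, 1)
.cast_rays <- function(x, y, angles, A) {
  dx <- cos(angles)
  dy <- sin(angles)
  tbest <- rep(Inf, length(angles))
  sper <- rep(0, length(angles))
  # walls: x = 0, x = A, y = 0, y = A
  cand <- list(
    list(t = (0 - x) / dx, coord = function(t) y + t * dy, wall = 1L),
    list(t = (A - x) / dx, coord = function(t) y + t * dy, wall = 2L),
    list(t = (0 - y) / dy, coord = function(t) x + t * dx, wall = 3L),
    list(t = (A - y) / dy, coord = function(t) x + t * dx, wall = 4L))
  for (w in cand) {
    tt <- w$t
    cc <- w$coord(tt)
    ok <- is.finite(tt) & tt > 1e-9 & cc >= -1e-9 & cc <= A + 1e-9 &
      tt < tbest
    if (any(ok)) {
      tbest[ok] <- tt[ok]
      # perimeter parameterization, counterclockwise from (0,0):
      # y=0 wall [0,A), x=A wall [A,2A), y=A wall [2A,3A), x=0 wall [3A,4A)
      p <- switch(w$wall,
                  `1` = 4 * A - cc[ok],
                  `2` = A + cc[ok],
                  `3` = cc[ok],
                  `4` = 3 * A - cc[ok])
      sper[ok] <- (p %% (4 * A)) / (4 * A)
    }
  }
  list(dist = tbest, s = sper)
}

#' Render a pose-indexed RGB-D scene stream
#'
#' Procedural textured-arena renderer: for each pose a pinhole panorama of
#' the arena walls is ray-cast, with a seed-hashed smooth wall texture for
#' the intensity channel and the ray hit distance for the depth channel.
#' Frames are a pure function of (pose, seed): nearby poses yield similar
#' frames, and revisiting a pose reproduces its frame exactly.
#'
#' @param poses Data frame with \code{x}, \code{y}, \code{heading}.
#' @param arena Square arena side in meters.
#' @param seed Visual world seed (selects the wall texture).
#' @param width,height Frame size in pixels.
#' @param fov Horizontal field of view in radians.
#' @param depth_max Depth saturation in meters.
#' @return List of frames, each \code{list(rgb, depth)} with \code{rgb} in
#'   \[0, 1\] and \code{depth} in meters, both \code{height x width}.
#' @export
gen_scene_stream <- function(poses, arena = 10, seed = 1L, width = 32L,
                             height = 24L, fov = pi / 2,
                             depth_max = 1.5 * arena) {
  tex <- .wall_texture(seed)
  tex_floor <- .wall_texture(seed + 7919L)
  tex_ceil <- .wall_texture(seed + 104729L)
  tex_height <- .wall_texture(seed + 15485863L)
  rel <- seq(-fov / 2, fov / 2, length.out = width)
  rowc <- (seq_len(height) - (height + 1) / 2)  # signed row offset
  lapply(seq_len(nrow(poses)), function(k) {
    hit <- .cast_rays(poses$x[k], poses$y[k], poses$heading[k] + rel, arena)
    wallcol <- tex(hit$s)
    floorcol <- 0.15 + 0.5 * tex_floor(hit$s)
    ceilcol <- 0.45 + 0.5 * tex_ceil(hit$s)
    d <- pmin(hit$dist, depth_max)
    # projected wall half-height in rows: closer walls fill more rows;
    # the wall height itself varies along the perimeter so the depth
    # image is textured too
    half <- (height / 2) * (0.3 * arena) * (0.5 + 1.0 * tex_height(hit$s)) /
      pmax(d, 0.05 * arena)
    rgb <- matrix(0, height, width)
    depth <- matrix(0, height, width)
    for (cc in seq_len(width)) {
      onwall <- abs(rowc) <= half[cc]
      shade <- 1 - 0.5 * d[cc] / depth_max
      rgb[, cc] <- ifelse(onwall, wallcol[cc] * shade,
                          ifelse(rowc > 0, floorcol[cc], ceilcol[cc]))
      depth[, cc] <- ifelse(onwall, d[cc], depth_max)
    }
    list(rgb = rgb, depth = depth)
  })
}

#' Generate a hierarchically structured bank of well-separated scenes
#'
#' Builds synthetic scene features whose pairwise differences follow a
#' known hierarchy: scenes share coarse structure within top-level groups
#' and differ by controlled amounts at each refinement level, placed inside
#' the matching-threshold bands of a [vtt_config()]. Each hierarchy level
#' writes a random bit pattern on its own disjoint pixel block, so level
#' contributions to the mean absolute difference add linearly. Any two
#' distinct scenes differ by more than \code{cfg$mt0} and scenes from
#' different top groups by more than the top-layer threshold, so template
#' assignment is unambiguous for an exact matcher.
#'
#' @param branching Integer vector, groups per hierarchy level (its length
#'   should be \code{cfg$L - 1}; the product is the number of scenes).
#' @param cfg The [vtt_config()] whose threshold ladder the level
#'   amplitudes are calibrated against.
#' @param seed RNG seed.
#' @param height,width Feature size in pixels.
#' @return List with \code{scenes} (list of \code{"scene"} objects) and
#'   \code{labels} (matrix of group indices per level).
#' @export
gen_scene_bank <- function(branching = c(6L, 4L, 4L, 3L),
                           cfg = vtt_config(), seed = 1L,
                           height = 24L, width = 32L) {
  set.seed(seed)
  n_lvl <- length(branching)
  stopifnot(n_lvl >= 2)
  n <- prod(branching)
  npx <- height * width
  # disjoint pixel blocks per level; deeper levels get more pixels so the
  # tightest threshold band has the least sampling noise
  frac <- c(rep(0.6 / n_lvl, n_lvl - 1), 0.4)
  sizes <- floor(npx * frac)
  starts <- cumsum(c(1, utils::head(sizes, -1)))
  # target mean-absolute differences: scenes first differing at level l
  # must land in the layer-l threshold band (see vtt_query_insert):
  #   D_l in (mt0 + (L-l)*delta_d - delta_d, mt0 + (L-l)*delta_d]
  # choose the band centers D_l = mt0 + (L - l - 0.5)*delta_d for l >= 2
  # and D_1 comfortably above the top threshold.
  D <- cfg$mt0 + (cfg$L - seq_len(n_lvl) - 0.5) * cfg$delta_d
  D[1] <- cfg$mt0 + (cfg$L + 1.5) * cfg$delta_d
  c_lvl <- D - c(D[-1], 0)  # per-level contribution (disjoint blocks add)
  amp <- 2 * c_lvl * npx / sizes  # random bits differ on half the pixels
  labels <- as.matrix(do.call(expand.grid, lapply(branching, seq_len)))
  labels <- labels[, rev(seq_len(n_lvl)), drop = FALSE]  # level1 slowest
  colnames(labels) <- paste0("level", seq_len(n_lvl))
  pat_cache <- new.env(parent = emptyenv())
  lvl_pat <- function(lvl, grp) {
    key <- paste(lvl, paste(grp, collapse = "."), sep = ":")
    if (is.null(pat_cache[[key]]))
      pat_cache[[key]] <- amp[lvl] * stats::rbinom(sizes[lvl], 1L, 0.5)
    pat_cache[[key]]
  }
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    v <- numeric(npx)
    for (lvl in seq_len(n_lvl)) {
      idx <- starts[lvl]:(starts[lvl] + sizes[lvl] - 1L)
      v[idx] <- lvl_pat(lvl, labels[i, seq_len(lvl)])
    }
    m <- matrix(pmin(v, 1), height, width)
    scenes[[i]] <- structure(list(rgb_feat = m, depth_feat = m,
                                  frame_id = i), class = "scene")
  }
  list(scenes = scenes, labels = labels)
}

#' Generate a planning workspace
#'
#' Square planning arenas with axis-aligned rectangular obstacles at a
#' fixed collision-check resolution. Shipped templates: \code{"open"} (no
#' obstacles) and \code{"cluttered"} (3-6 random rectangles leaving a
#' feasible corridor between the default start and goal, verified by a
#' coarse-grid breadth-first search; infeasible draws are regenerated from
#' the next sub-seed).
#'
#' @param template \code{"open"} or \code{"cluttered"}.
#' @param seed RNG seed.
#' @param size Side length in meters.
#' @param resolution Collision-check step in meters.
#' @return A [workspace()] object.
#' @export
gen_workspace <- function(template = c("cluttered", "open"), seed = 1L,
                          size = 20, resolution = 0.1) {
  template <- match.arg(template)
  if (template == "open")
    return(workspace(bounds = c(0, size, 0, size), obstacles = list(),
                     resolution = resolution))
  q_init <- c(0.1 * size, 0.1 * size)
  q_goal <- c(0.9 * size, 0.9 * size)
  for (sub in 0:50) {
    set.seed(seed + sub)
    n_obs <- sample(3:6, 1)
    obstacles <- lapply(seq_len(n_obs), function(i) {
      w <- runif(1, 0.1, 0.3) * size
      h <- runif(1, 0.1, 0.3) * size
      x0 <- runif(1, 0.05 * size, 0.95 * size - w)
      y0 <- runif(1, 0.05 * size, 0.95 * size - h)
      c(x0, x0 + w, y0, y0 + h)
    })
    ws <- workspace(bounds = c(0, size, 0, size), obstacles = obstacles,
                    resolution = resolution)
    if (!point_in_collision(ws, q_init) && !point_in_collision(ws, q_goal) &&
        workspace_feasible(ws, q_init, q_goal))
      return(ws)
  }
  stop("could not generate a feasible workspace", call. = FALSE)
}
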