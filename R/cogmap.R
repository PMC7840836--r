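#' Dead-reckoning recall metrics
#'
#' Worked-example arithmetic on the lap counters of a two-lap run:
#' \code{M_t = M_1 + M_2} and \code{M_r = 100 * M_p / M_1} (percent,
#' truncated at two decimals). \code{M_1} and \code{M_2} count experiences
#' created on the first and second lap; \code{M_p} counts second-lap steps
#' that localized to history experiences (localization events, so it may
#' exceed \code{M_1}).
#'
#' @param M_1,M_2 Experiences created during lap one / lap two.
#' @param M_p Second-lap localization events.
#' @return An object of class \code{"recall_metrics"} with fields
#'   \code{M_t, M_1, M_2, M_p, M_r}.
#' @export
recall_metrics <- function(M_1, M_2, M_p) {
  # percentages are truncated (not rounded) at the second decimal
  structure(list(M_t = M_1 + M_2, M_1 = M_1, M_2 = M_2, M_p = M_p,
                 M_r = trunc(1e4 * M_p / M_1) / 1e2),
            class = "recall_metrics")
}

#' @export
print.recall_metrics <- function(x, ...) {
  cat(sprintf("recall_metrics: M_t=%d (M_1=%d, M_2=%d), M_p=%d, M_r=%.2f%%\n",
              x$M_t, x$M_1, x$M_2, x$M_p, x$M_r))
  invisible(x)
}

#' Compute recall metrics from a built experience map
#'
#' @param map An [build_map()] result.
#' @param boundary_step Frame index where the second lap starts.
#' @return A [recall_metrics()] object.
#' @export
dead_reckoning_metrics <- function(map, boundary_step) {
  steps <- vapply(map$nodes, function(e) e$created_step, 1L)
  if (boundary_step < 1L || boundary_step > map$n_steps)
    stop("lap boundary outside the run", call. = FALSE)
  M_1 <- sum(steps < boundary_step)
  M_2 <- sum(steps >= boundary_step)
  M_p <- sum(vapply(map$loop_events, function(e)
    e$step >= boundary_step, TRUE))
  recall_metrics(M_1, M_2, M_p)
}

# experience node constructor
.experience <- function(id, pose, place_id, template_id, snapshots, step) {
  list(id = id, pose = pose, place_id = place_id,
       template_id = template_id, snapshots = snapshots,
       created_step = step)
}

#' Restore grid and place activities from an experience
#'
#' Sets every grid module's sheet and the decoder's unwrap state to the
#' snapshots stored when the experience was created, so subsequent
#' decoding returns the experience's place cell. Idempotent.
#'
#' @param stack A [grid_stack()].
#' @param experience An experience node of an [build_map()] map.
#' @return The stack with restored activities.
#' @export
reset_activities <- function(stack, experience) {
  snaps <- experience$snapshots
  if (length(snaps$g) != length(stack$modules))
    stop("snapshot/stack shape mismatch", call. = FALSE)
  for (m in seq_along(stack$modules)) {
    if (!all(dim(snaps$g[[m]]) == dim(stack$modules[[m]]$g)))
      stop("snapshot/stack shape mismatch", call. = FALSE)
    stack$modules[[m]]$g <- snaps$g[[m]]
  }
  stack
}

#' Build a cognitive experience map from odometry and scenes
#'
#' The mapping loop: per camera frame, advance the grid-cell stack over the
#' odometry slice, read the place-cell winner, decode the position by
#' continuity, and query the visual template tree. A frame whose scene
#' matches a stored template AND whose decoded position lies within
#' \code{r_exp} of that template's experience declares a loop closure: grid
#' and place activities are reset to the stored snapshots, the decoded
#' position is re-anchored to the matched experience, the current view is
#' merged into it (pose averaging, keeping the older id), and the map is
#' relaxed. Otherwise a new experience is created once the decoded position
#' has moved at least \code{d_exp} from the last node.
#'
#' @param stack A settled, gain-calibrated [grid_stack()] (see
#'   [calibrate_stack()]).
#' @param place A trained [place_module()].
#' @param odometry Odometry data frame \code{t, vx, vy} at the integration
#'   step.
#' @param frames List of RGB-D frames, one every \code{frame_every}
#'   integration steps.
#' @param gain Signed path-integration gain (sheet neurons per meter), as
#'   measured by [calibrate_gain()]; used to convert winner motion to
#'   meters.
#' @param start_pose Arena coordinates of the first frame.
#' @param cfg List of mapping parameters: \code{r_exp} (loop-closure
#'   gating radius, m), \code{d_exp} (experience spacing, m),
#'   \code{min_age} (frames an experience must age before it can close a
#'   loop), \code{vtt_cfg} (a [vtt_config()]), \code{relax_iters},
#'   \code{relax_rate}.
#' @param matcher \code{"linear"} (default) uses the exact exhaustive
#'   template library; \code{"vtt"} uses the hierarchical template tree,
#'   whose depth-bounded greedy descent is faster but can duplicate
#'   templates on streams of smoothly varying (aliased) scenes.
#' @param depth_max Depth normalization for [scene_features()].
#' @return An object of class \code{"experience_map"}: \code{nodes},
#'   \code{links} (rows \code{from, to, dx, dy}), \code{loop_events},
#'   \code{trajectory} (decoded pose per frame), \code{n_steps} (frames
#'   processed), plus the final \code{stack}, \code{place}, \code{vtt}.
#' @export
build_map <- function(stack, place, odometry, frames, gain,
                      start_pose = c(0, 0), cfg = list(),
                      matcher = c("linear", "vtt"), depth_max = NULL) {
  matcher <- match.arg(matcher)
  defaults <- list(r_exp = 1.0, d_exp = 0.25, min_age = 10L,
                   vtt_cfg = vtt_config(), relax_iters = 100L,
                   relax_rate = 0.5)
  cfg <- utils::modifyList(defaults, cfg)
  n_frames <- length(frames)
  steps <- nrow(odometry)
  frame_every <- steps %/% n_frames
  if (frame_every < 1L)
    stop("sync error: more frames than odometry steps", call. = FALSE)
  if (is.null(depth_max))
    depth_max <- max(vapply(frames, function(f) max(f$depth), 0))
  tree <- if (matcher == "vtt") vtt_new(cfg$vtt_cfg)
          else linear_library_new(cfg$vtt_cfg)
  N <- stack$N

  nodes <- list()
  links <- data.frame(from = integer(0), to = integer(0),
                      dx = numeric(0), dy = numeric(0))
  loop_events <- list()
  trajectory <- data.frame(t = numeric(n_frames), x = numeric(n_frames),
                           y = numeric(n_frames))
  M <- length(stack$modules)
  pose <- start_pose      # decoded pose of the current frame
  last_node <- 0L
  last_node_pose <- NULL

  for (k in seq_len(n_frames)) {
    lo <- (k - 1L) * frame_every + 1L
    hi <- k * frame_every
    # record densely within the chunk so the displacement tracker's
    # search window is never outrun
    h <- integrate_path(stack, odometry[lo:hi, , drop = FALSE],
                        record_every = min(frame_every, 10L), place = place)
    stack <- h$stack
    place <- h$place
    # neural dead reckoning: mean pattern displacement over the chunk
    nr <- nrow(h$disp)
    step_m <- c(mean(h$disp[nr, 2 * seq_len(M) - 1]),
                mean(h$disp[nr, 2 * seq_len(M)])) / gain
    pose <- pose + step_m

    sc <- scene_features(frames[[k]]$rgb, frames[[k]]$depth,
                         depth_max = depth_max, frame_id = k)
    vr <- if (matcher == "vtt") vtt_query_insert(tree, sc)
          else linear_query_insert(tree, sc)

    closed <- FALSE
    if (vr$matched) {
      # spatial gate: the matched template's experience must be nearby and
      # old enough that matching it means revisiting, not just lingering
      cand <- Filter(function(e) e$template_id == vr$template_id &&
                       k - e$created_step >= cfg$min_age, nodes)
      if (length(cand) > 0L) {
        dists <- vapply(cand, function(e)
          sqrt(sum((e$pose - pose)^2)), 0)
        j <- which.min(dists)
        if (dists[j] <= cfg$r_exp) {
          exp_hit <- cand[[j]]
          stack <- reset_activities(stack, exp_hit)
          # the loop-closing link stores the odometric (pre-reset) step, so
          # the accumulated drift enters the graph as inconsistency for the
          # relaxation to distribute
          if (last_node != 0L && last_node != exp_hit$id) {
            links <- rbind(links, data.frame(
              from = last_node, to = exp_hit$id,
              dx = pose[1] - last_node_pose[1],
              dy = pose[2] - last_node_pose[2]))
          }
          # merge: keep the older experience, average poses; decoding
          # re-anchors at the merged experience
          merged_pose <- (exp_hit$pose + pose) / 2
          nodes[[exp_hit$id]]$pose <- merged_pose
          pose <- merged_pose
          loop_events[[length(loop_events) + 1L]] <-
            list(step = k, experience = exp_hit$id,
                 link = if (last_node != 0L && last_node != exp_hit$id)
                   nrow(links) else NA_integer_)
          last_node <- exp_hit$id
          last_node_pose <- nodes[[exp_hit$id]]$pose
          closed <- TRUE
          # correct the map toward the recalled experiences
          relaxed <- relax_map(
            list(nodes = nodes, links = links, loop_events = loop_events),
            iterations = cfg$relax_iters, rate = cfg$relax_rate)
          nodes <- relaxed$nodes
        }
      }
    }

    if (!closed) {
      far_enough <- last_node == 0L ||
        sqrt(sum((pose - last_node_pose)^2)) >= cfg$d_exp
      if (far_enough) {
        id <- length(nodes) + 1L
        snaps <- list(g = lapply(stack$modules, function(m) m$g),
                      p = h$p)
        nodes[[id]] <- .experience(id, pose, h$winners[length(h$winners)],
                                   vr$template_id, snaps, k)
        if (last_node != 0L)
          links <- rbind(links, data.frame(
            from = last_node, to = id,
            dx = pose[1] - last_node_pose[1],
            dy = pose[2] - last_node_pose[2]))
        last_node <- id
        last_node_pose <- pose
      }
    }
    trajectory$t[k] <- odometry$t[hi]
    trajectory$x[k] <- pose[1]
    trajectory$y[k] <- pose[2]
  }

  structure(list(nodes = nodes, links = links, loop_events = loop_events,
                 trajectory = trajectory, n_steps = n_frames,
                 stack = stack, place = place, vtt = tree),
            class = "experience_map")
}

#' @export
print.experience_map <- function(x, ...) {
  cat(sprintf(
    "experience_map: %d experiences, %d links, %d loop events over %d frames\n",
    length(x$nodes), nrow(x$links), length(x$loop_events), x$n_steps))
  invisible(x)
}

#' Residual endpoint gap across the first loop closure
#'
#' The pose mismatch across the link created at the first loop-closure
#' event (the ring-closing constraint): before relaxation it carries the
#' accumulated odometric drift, afterwards the drift has been distributed
#' around the loop and the residual should be a small fraction of it.
#'
#' @param map An \code{"experience_map"} with at least one loop event.
#' @return Euclidean residual in meters (\code{NA} if no closure link).
#' @export
endpoint_gap <- function(map) {
  ev <- Filter(function(e) !is.na(e$link), map$loop_events)
  if (length(ev) == 0L) return(NA_real_)
  r <- ev[[1]]$link
  pf <- map$nodes[[map$links$from[r]]]$pose
  pt <- map$nodes[[map$links$to[r]]]$pose
  sqrt(sum((pt - pf - c(map$links$dx[r], map$links$dy[r]))^2))
}

#' Total link inconsistency of an experience map
#'
#' Sum of squared mismatches between each link's stored odometric
#' transform and the current node poses.
#'
#' @param map An \code{"experience_map"} (or a list with \code{nodes} and
#'   \code{links}).
#' @return Scalar inconsistency (m^2).
#' @export
map_inconsistency <- function(map) {
  if (nrow(map$links) == 0L) return(0)
  s <- 0
  for (r in seq_len(nrow(map$links))) {
    pf <- map$nodes[[map$links$from[r]]]$pose
    pt <- map$nodes[[map$links$to[r]]]$pose
    s <- s + sum((pt - pf - c(map$links$dx[r], map$links$dy[r]))^2)
  }
  s
}

#' Relax an experience map after loop closure
#'
#' Iterative pose relaxation: each node moves by \code{rate} times the mean
#' inconsistency between its pose and the poses implied by its incident
#' links' stored transforms. With \code{rate <= 1} the total inconsistency
#' is non-increasing; maps without loop events are returned unchanged.
#'
#' @param map An \code{"experience_map"} (or compatible list).
#' @param iterations Relaxation sweeps.
#' @param rate Fraction of the mean correction applied per sweep.
#' @return The map with updated node poses.
#' @export
relax_map <- function(map, iterations = 100L, rate = 0.5) {
  if (length(map$loop_events) == 0L || nrow(map$links) == 0L) return(map)
  n <- length(map$nodes)
  px <- vapply(map$nodes, function(e) e$pose[1], 0)
  py <- vapply(map$nodes, function(e) e$pose[2], 0)
  fr <- map$links$from
  to <- map$links$to
  dx <- map$links$dx
  dy <- map$links$dy
  for (it in seq_len(iterations)) {
    cx <- numeric(n)
    cy <- numeric(n)
    cnt <- numeric(n)
    # each link pulls its endpoints toward consistency, split evenly
    ex <- px[to] - px[fr] - dx
    ey <- py[to] - py[fr] - dy
    for (r in seq_along(fr)) {
      cx[to[r]] <- cx[to[r]] - ex[r] / 2
      cy[to[r]] <- cy[to[r]] - ey[r] / 2
      cx[fr[r]] <- cx[fr[r]] + ex[r] / 2
      cy[fr[r]] <- cy[fr[r]] + ey[r] / 2
      cnt[to[r]] <- cnt[to[r]] + 1
      cnt[fr[r]] <- cnt[fr[r]] + 1
    }
    upd <- cnt > 0
    px[upd] <- px[upd] + rate * cx[upd] / cnt[upd]
    py[upd] <- py[upd] + rate * cy[upd] / cnt[upd]
  }
  for (i in seq_len(n)) map$nodes[[i]]$pose <- c(px[i], py[i])
  map
}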