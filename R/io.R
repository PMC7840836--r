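#' Read / write odometry CSV
#'
#' Columns \code{t, vx, vy} (seconds, m/s), header required.
#'
#' @param path File path.
#' @return [read_odometry()]: a validated odometry data frame.
#' @export
read_odometry <- function(path) {
  as_odometry(utils::read.csv(path))
}

#' @rdname read_odometry
#' @param odometry Odometry data frame.
#' @export
write_odometry <- function(odometry, path) {
  utils::write.csv(as_odometry(odometry)[c("t", "vx", "vy")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write an activity snapshot as CSV and/or PNG heat map
#'
#' @param g Activity matrix.
#' @param csv,png Output paths (either may be \code{NULL}).
#' @export
write_snapshot <- function(g, csv = NULL, png = NULL) {
  if (!is.null(csv))
    utils::write.table(g, csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(png)) {
    v <- (g - min(g)) / max(max(g) - min(g), 1e-12)
    png::writePNG(v[nrow(v):1, , drop = FALSE], png)
  }
  invisible(NULL)
}

#' Read an activity snapshot CSV
#' @param csv Path written by [write_snapshot()].
#' @return Activity matrix.
#' @export
read_snapshot <- function(csv) {
  as.matrix(utils::read.csv(csv, header = FALSE))
}

#' Write / read an RGB-D frame pair as PNG files
#'
#' Frames follow the \code{frame_\%06d_rgb.png} / \code{frame_\%06d_depth.png}
#' convention; depth is stored at 16-bit precision (scaled by
#' \code{depth_max}, split over the first two 8-bit PNG channels).
#'
#' @param frames List of \code{list(rgb, depth)} frames.
#' @param dir Output directory (created if missing).
#' @param depth_max Depth scale for the 16-bit encoding, in meters.
#' @return Invisibly, the directory.
#' @export
write_frames <- function(frames, dir, depth_max = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(depth_max))
    depth_max <- max(vapply(frames, function(f) max(f$depth), 0))
  for (k in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[k]]$rgb, 0), 1),
                  file.path(dir, sprintf("frame_%06d_rgb.png", k)))
    # 16-bit depth split over two 8-bit channels (high byte, low byte)
    q <- round(pmin(pmax(frames[[k]]$depth / depth_max, 0), 1) * 65535)
    hi <- q %/% 256
    lo <- q %% 256
    d2 <- array(0, dim = c(nrow(q), ncol(q), 3))
    d2[, , 1] <- hi / 255
    d2[, , 2] <- lo / 255
    png::writePNG(d2, file.path(dir, sprintf("frame_%06d_depth.png", k)))
  }
  writeLines(as.character(depth_max), file.path(dir, "depth_max.txt"))
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  depth_max <- as.numeric(readLines(file.path(dir, "depth_max.txt")))
  rgbs <- sort(list.files(dir, pattern = "_rgb\\.png$", full.names = TRUE))
  lapply(rgbs, function(f) {
    d2 <- png::readPNG(sub("_rgb\\.png$", "_depth.png", f))
    q <- round(d2[, , 1] * 255) * 256 + round(d2[, , 2] * 255)
    list(rgb = png::readPNG(f), depth = q / 65535 * depth_max)
  })
}

#' Write / read a model configuration YAML
#'
#' Mirrors the [grid_module_spec()] field names plus the stack's period
#' counts.
#'
#' @param config Named list (e.g. \code{list(N = 40, n = c(2, 3, 4, 5),
#'   tau = 0.005, ...)}).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Build a grid stack from a configuration list
#'
#' @param config List with \code{n} (period counts) and any
#'   [grid_module_spec()] fields, e.g. from [read_config()].
#' @param settle_steps Settling iterations.
#' @return A [grid_stack()].
#' @export
stack_from_config <- function(config, settle_steps = 1500L) {
  args <- config
  args$n <- NULL
  args$settle_steps <- settle_steps
  do.call(grid_stack, c(list(n = config$n %||% c(2L, 3L, 4L, 5L)), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an experience map as JSON
#'
#' @param map An \code{"experience_map"}.
#' @param path Output path.
#' @export
write_map_json <- function(map, path) {
  out <- list(
    nodes = lapply(map$nodes, function(e)
      list(id = e$id, x = e$pose[1], y = e$pose[2],
           place_id = e$place_id, template_id = e$template_id,
           created_step = e$created_step)),
    links = map$links,
    loop_events = lapply(map$loop_events, function(e)
      list(step = e$step, experience = e$experience)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an experience map as GraphML
#'
#' @param map An \code{"experience_map"}.
#' @param path Output path.
#' @export
write_map_graphml <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="x" for="node" attr.name="x" attr.type="double"/>',
    '<key id="y" for="node" attr.name="y" attr.type="double"/>',
    '<graph id="experience_map" edgedefault="directed">'), con)
  for (e in map$nodes)
    writeLines(sprintf(
      '<node id="n%d"><data key="x">%g</data><data key="y">%g</data></node>',
      e$id, e$pose[1], e$pose[2]), con)
  if (nrow(map$links) > 0)
    for (r in seq_len(nrow(map$links)))
      writeLines(sprintf('<edge source="n%d" target="n%d"/>',
                         map$links$from[r], map$links$to[r]), con)
  writeLines(c("</graph>", "</graphml>"), con)
  invisible(path)
}

#' Dump a visual template tree as JSON
#'
#' @param tree A [vtt_new()] tree.
#' @param path Output path.
#' @export
write_vtt_json <- function(tree, path) {
  out <- list(
    config = unclass(tree$cfg),
    n_templates = tree$n_templates,
    nodes = lapply(tree$nodes, function(n)
      list(id = n$id, layer = n$layer, parent = n$parent,
           children = n$children, template_id = n$template_id,
           frame_id = n$scene$frame_id)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write learned place weights / a convergence trace / a decoded trajectory
#'
#' Small CSV exports used by the offline training workflow.
#'
#' @param pm A trained [place_module()].
#' @param path Output path.
#' @export
write_place_weights <- function(pm, path) {
  utils::write.csv(data.frame(module = seq_along(pm$w), weight = pm$w),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_place_weights
#' @param trace Per-step weight change norms.
#' @export
write_convergence_trace <- function(trace, path) {
  utils::write.csv(data.frame(step = seq_along(trace), delta_norm = trace),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_place_weights
#' @param decoded A [decode_trajectory()] result.
#' @export
write_decoded_trajectory <- function(decoded, path) {
  utils::write.csv(as.data.frame(decoded)[c("t", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write a planning workspace YAML
#'
#' @param ws A [workspace()].
#' @param path File path.
#' @export
write_workspace <- function(ws, path) {
  yaml::write_yaml(list(bounds = ws$bounds,
                        obstacles = lapply(ws$obstacles, as.numeric),
                        resolution = ws$resolution), path)
  invisible(path)
}

#' @rdname write_workspace
#' @export
read_workspace <- function(path) {
  y <- yaml::read_yaml(path)
  workspace(bounds = as.numeric(y$bounds),
            obstacles = lapply(y$obstacles, as.numeric),
            resolution = y$resolution)
}

#' Write plan waypoints as CSV
#'
#' @param plan A \code{"plan_result"}.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(plan$success)
  utils::write.csv(data.frame(x = plan$path[, 1], y = plan$path[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}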