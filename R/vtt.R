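#' Visual-template matching configuration
#'
#' Thresholds and modality weights for scene matching. The leaf (optimal)
#' matching threshold is \code{mt0}; tree layer \code{k} of \code{L}
#' matches with the relaxed threshold \code{mt0 + (L - k) * delta_d}, so
#' criteria tighten from coarse at the top to \code{mt0} at the leaves.
#'
#' @param L Number of non-root layers (leaves live at layer \code{L}).
#' @param mt0 Leaf matching threshold, in scene-difference units.
#' @param delta_d Per-layer threshold increment (> 0).
#' @param Wr,Wd Weights of the intensity and depth differences
#'   (\code{Wr + Wd = 1}).
#' @return An object of class \code{"vtt_config"}.
#' @export
vtt_config <- function(L = 5L, mt0 = 0.02, delta_d = 0.015, Wr = 0.5,
                       Wd = 0.5) {
  stopifnot(L >= 2, delta_d > 0, Wr >= 0, Wd >= 0)
  if (abs(Wr + Wd - 1) > 1e-9)
    stop("modality weights must satisfy Wr + Wd = 1", call. = FALSE)
  structure(list(L = as.integer(L), mt0 = mt0, delta_d = delta_d,
                 Wr = Wr, Wd = Wd), class = "vtt_config")
}

#' Extract matching features from an RGB-D frame
#'
#' Downsamples the intensity image to a fixed resolution, contrast
#' normalizes it (zero mean, unit variance, then rescaled into \[0, 1\];
#' guarded for zero-variance frames), and normalizes depth by its
#' saturation range. Deterministic: identical frames give identical
#' features.
#'
#' @param rgb Intensity matrix in \[0, 1\] (rows x cols).
#' @param depth Depth matrix in meters, same size as \code{rgb}.
#' @param width,height Feature resolution (defaults keep the renderer's
#'   native 32 x 24).
#' @param depth_max Depth normalization constant in meters.
#' @param frame_id Optional source frame index.
#' @return An object of class \code{"scene"} with matrices
#'   \code{rgb_feat}, \code{depth_feat} in \[0, 1\].
#' @export
scene_features <- function(rgb, depth, width = 32L, height = 24L,
                           depth_max = max(depth), frame_id = NA_integer_) {
  if (!all(dim(rgb) == dim(depth)))
    stop("rgb and depth must have the same size", call. = FALSE)
  down <- function(m) {
    ri <- round(seq(1, nrow(m), length.out = height))
    ci <- round(seq(1, ncol(m), length.out = width))
    m[ri, ci]
  }
  norm01 <- function(m) {
    s <- stats::sd(m)
    if (s < 1e-12) return(matrix(0.5, nrow(m), ncol(m)))
    z <- (m - mean(m)) / s
    (z - min(z)) / (max(z) - min(z))
  }
  structure(list(rgb_feat = norm01(down(rgb)),
                 depth_feat = pmin(pmax(down(depth) / depth_max, 0), 1),
                 frame_id = frame_id),
            class = "scene")
}

# mean absolute difference minimized over a small horizontal shift window
.shift_mad <- function(A, B, window = 4L) {
  W <- ncol(A)
  best <- Inf
  for (s in -window:window) {
    ca <- max(1, 1 + s):min(W, W + s)
    cb <- ca - s
    d <- mean(abs(A[, ca, drop = FALSE] - B[, cb, drop = FALSE]))
    if (d < best) best <- d
  }
  best
}

#' Difference between two visual scenes
#'
#' \code{d = Wr * d_r + Wd * d_d}, where each modality difference is the
#' mean absolute feature difference minimized over a +/- 4 column shift
#' window (a cheap tolerance to small heading changes). Symmetric and zero
#' iff the features coincide (up to the shift search).
#'
#' @param a,b [scene_features()] objects.
#' @param cfg A [vtt_config()] (for the modality weights).
#' @param shift_window Horizontal shift tolerance in feature columns.
#' @return Scalar difference in \[0, 1\].
#' @export
scene_difference <- function(a, b, cfg = vtt_config(), shift_window = 4L) {
  if (!all(dim(a$rgb_feat) == dim(b$rgb_feat)) ||
      !all(dim(a$depth_feat) == dim(b$depth_feat)))
    stop("feature lengths differ", call. = FALSE)
  d_r <- .shift_mad(a$rgb_feat, b$rgb_feat, shift_window)
  d_d <- .shift_mad(a$depth_feat, b$depth_feat, shift_window)
  cfg$Wr * d_r + cfg$Wd * d_d
}

#' Create an empty visual template tree
#'
#' Mutable tree (an environment): non-leaf nodes carry the scene that
#' founded their branch as representative; leaves are the stored visual
#' templates with dense ids starting at 1.
#'
#' @param cfg A [vtt_config()].
#' @return An object of class \code{"vtt"}.
#' @export
vtt_new <- function(cfg = vtt_config()) {
  tr <- new.env(parent = emptyenv())
  tr$cfg <- cfg
  tr$nodes <- list()       # each: list(id, layer, parent, children, scene,
                           #            template_id)
  tr$root_children <- integer(0)
  tr$n_templates <- 0L
  class(tr) <- "vtt"
  tr
}

#' @export
print.vtt <- function(x, ...) {
  cat(sprintf("vtt: %d layers, %d templates, %d nodes\n",
              x$cfg$L, x$n_templates, length(x$nodes)))
  invisible(x)
}

# append a chain of nodes carrying `scene` from layer `from` under `parent`
.vtt_grow_branch <- function(tree, scene, from, parent) {
  for (layer in from:tree$cfg$L) {
    id <- length(tree$nodes) + 1L
    tid <- NA_integer_
    if (layer == tree$cfg$L) {
      tree$n_templates <- tree$n_templates + 1L
      tid <- tree$n_templates
    }
    tree$nodes[[id]] <- list(id = id, layer = layer, parent = parent,
                             children = integer(0), scene = scene,
                             template_id = tid)
    if (parent == 0L) tree$root_children <- c(tree$root_children, id)
    else tree$nodes[[parent]]$children <-
        c(tree$nodes[[parent]]$children, id)
    parent <- id
  }
  tree$n_templates
}

#' Query the template tree and insert on miss
#'
#' Descends from the top layer with progressively tighter thresholds
#' (\code{mt0 + (L - k) * delta_d} at layer \code{k}): at each layer the
#' scene is compared with the current node set's representatives and
#' follows the minimum-difference child (earliest-created on ties). When
#' the minimum difference exceeds the layer threshold, a fresh branch is
#' grown from that point down to a new leaf template; reaching a leaf
#' within \code{mt0} is a match. Every [scene_difference()] evaluation is
#' counted.
#'
#' @param tree A [vtt_new()] tree (modified in place).
#' @param scene A [scene_features()] object.
#' @return List with \code{matched} (logical), \code{template_id},
#'   \code{difference} (to the matched leaf, \code{NA} for new templates),
#'   and \code{comparisons}.
#' @export
vtt_query_insert <- function(tree, scene) {
  cfg <- tree$cfg
  comparisons <- 0L
  parent <- 0L
  cand <- tree$root_children
  for (layer in seq_len(cfg$L)) {
    thr <- cfg$mt0 + (cfg$L - layer) * cfg$delta_d
    if (length(cand) == 0L) {
      tid <- .vtt_grow_branch(tree, scene, layer, parent)
      return(list(matched = FALSE, template_id = tid, difference = NA_real_,
                  comparisons = comparisons))
    }
    diffs <- vapply(cand, function(id)
      scene_difference(scene, tree$nodes[[id]]$scene, cfg), 0)
    comparisons <- comparisons + length(diffs)
    k <- which.min(diffs)  # earliest-created wins ties
    if (diffs[k] > thr) {
      tid <- .vtt_grow_branch(tree, scene, layer, parent)
      return(list(matched = FALSE, template_id = tid, difference = NA_real_,
                  comparisons = comparisons))
    }
    best <- cand[k]
    if (tree$nodes[[best]]$layer == cfg$L)
      return(list(matched = TRUE,
                  template_id = tree$nodes[[best]]$template_id,
                  difference = diffs[k], comparisons = comparisons))
    parent <- best
    cand <- tree$nodes[[best]]$children
  }
  stop("internal error: descent fell through the leaf layer")
}

#' Create an empty linear template library (baseline)
#'
#' @param cfg A [vtt_config()].
#' @return An object of class \code{"linear_library"}.
#' @export
linear_library_new <- function(cfg = vtt_config()) {
  lib <- new.env(parent = emptyenv())
  lib$cfg <- cfg
  lib$templates <- list()
  class(lib) <- "linear_library"
  lib
}

#' Query the linear library and insert on miss (baseline)
#'
#' Compares the scene against every stored template; the minimum
#' difference decides: a match iff it is at most \code{mt0}, otherwise the
#' scene is appended as a new template. Comparisons equal the library
#' size.
#'
#' @param lib A [linear_library_new()] library (modified in place).
#' @param scene A [scene_features()] object.
#' @return Same contract as [vtt_query_insert()].
#' @export
linear_query_insert <- function(lib, scene) {
  cfg <- lib$cfg
  n <- length(lib$templates)
  if (n > 0L) {
    diffs <- vapply(lib$templates, function(s)
      scene_difference(scene, s, cfg), 0)
    k <- which.min(diffs)
    if (diffs[k] <= cfg$mt0)
      return(list(matched = TRUE, template_id = k, difference = diffs[k],
                  comparisons = n))
  }
  lib$templates[[n + 1L]] <- scene
  list(matched = FALSE, template_id = n + 1L, difference = NA_real_,
       comparisons = n)
}

#' Run a whole frame stream through a matcher
#'
#' Convenience driver used by the mapping pipeline and the benchmarks:
#' extracts features and queries/inserts frame by frame.
#'
#' @param frames List of \code{list(rgb, depth)} frames (e.g. from
#'   [gen_scene_stream()]).
#' @param matcher A \code{"vtt"} or \code{"linear_library"}.
#' @param depth_max Depth normalization passed to [scene_features()].
#' @return Data frame \code{frame_id, template_id, matched, difference,
#'   comparisons}.
#' @export
match_stream <- function(frames, matcher, depth_max = NULL) {
  if (is.null(depth_max))
    depth_max <- max(vapply(frames, function(f) max(f$depth), 0))
  rows <- lapply(seq_along(frames), function(k) {
    sc <- scene_features(frames[[k]]$rgb, frames[[k]]$depth,
                         depth_max = depth_max, frame_id = k)
    r <- if (inherits(matcher, "vtt")) vtt_query_insert(matcher, sc)
         else linear_query_insert(matcher, sc)
    data.frame(frame_id = k, template_id = r$template_id,
               matched = r$matched,
               difference = ifelse(is.na(r$difference), NA_real_,
                                   r$difference),
               comparisons = r$comparisons)
  })
  do.call(rbind, rows)
}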