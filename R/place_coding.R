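#' Place-cell module
#'
#' A place-cell sheet the size of the grid sheets, driven by the weighted
#' sum of the grid modules' activities. All grid cells of one module share
#' a single scalar weight to the place sheet, so only \code{M} weights are
#' learned. Weights are kept non-negative with unit square norm
#' (competitive normalization).
#'
#' @param M Number of grid modules feeding the place sheet.
#' @param k_p Activation steepness: larger values sharpen the place
#'   population toward a single active cell.
#' @param lr Hebbian learning rate per integration step.
#' @return An object of class \code{"place_module"} with uniform initial
#'   weights \code{1/sqrt(M)}.
#' @export
place_module <- function(M, k_p = 50, lr = 1e-4) {
  stopifnot(M >= 1, k_p > 0, lr >= 0)
  structure(list(w = rep(1 / sqrt(M), M), k_p = k_p, lr = lr, M = M),
            class = "place_module")
}

#' @export
print.place_module <- function(x, ...) {
  cat(sprintf("place_module: M = %d, k_p = %g, lr = %g\n  w = (%s)\n",
              x$M, x$k_p, x$lr, paste(sprintf("%.4f", x$w), collapse = ", ")))
  invisible(x)
}

# stack activities as an N x N x M array
.stack_acts <- function(stack) {
  N <- stack$N
  M <- length(stack$modules)
  g <- array(0, dim = c(N, N, M))
  for (m in seq_len(M)) g[, , m] <- stack$modules[[m]]$g
  g
}

#' Place-cell activation
#'
#' \code{u = sum_j w_j g_j} elementwise over the aligned grid sheets, then
#' \code{p = 1 / (1 + exp(k_p (max(u) - u)))}: the cell(s) achieving the
#' momentary population maximum sit at exactly 0.5 and all others are
#' suppressed exponentially in their shortfall, which selects a single
#' activated place cell. The winner is the row-major argmax with ties
#' broken toward the lowest row-major index.
#'
#' @param acts An \code{N x N x M} activity array (or a [grid_stack()]).
#' @param pm A [place_module()].
#' @return An object of class \code{"place_activity"}: \code{p} (the
#'   \code{N x N} sheet), \code{winner} (1-based row-major index), and
#'   \code{winner_rc} (row, col).
#' @export
place_activation <- function(acts, pm) {
  if (inherits(acts, "grid_stack")) acts <- .stack_acts(acts)
  stopifnot(inherits(pm, "place_module"), dim(acts)[3] == pm$M,
            dim(acts)[1] == dim(acts)[2])
  N <- dim(acts)[1]
  u <- matrix(0, N, N)
  for (m in seq_len(pm$M)) u <- u + pm$w[m] * acts[, , m]
  p <- 1 / (1 + exp(pm$k_p * (max(u) - u)))
  # row-major argmax with strict improvement: lowest row-major index wins
  pt <- t(p)  # row-major scan = column-major scan of the transpose
  k0 <- which.max(pt) - 1L
  row <- k0 %/% N + 1L
  col <- k0 %% N + 1L
  structure(list(p = p, winner = as.integer(k0 + 1L),
                 winner_rc = c(row = row, col = col)),
            class = "place_activity")
}

#' Competitive Hebbian update of the grid-to-place weights
#'
#' Applies \code{dw_j = lr * sum_i p_i (g_{j,i} - p_i w_j)} per module,
#' then clamps weights at zero and renormalizes to unit square norm. A
#' weight vector that collapses to all zeros after clamping is
#' reinitialized to uniform with a warning.
#'
#' @param pm A [place_module()].
#' @param p A [place_activation()] result (or a plain activity matrix).
#' @param acts The \code{N x N x M} grid activities that produced \code{p}.
#' @return The updated \code{"place_module"}, with the applied weight
#'   change norm in \code{attr(, "delta")}.
#' @export
hebbian_update <- function(pm, p, acts) {
  if (inherits(acts, "grid_stack")) acts <- .stack_acts(acts)
  if (inherits(p, "place_activity")) p <- p$p
  w_old <- pm$w
  w <- pm$w
  for (m in seq_len(pm$M))
    w[m] <- w[m] + pm$lr * sum(p * (acts[, , m] - p * w[m]))
  w <- pmax(w, 0)
  nw <- sqrt(sum(w^2))
  if (nw <= 0) {
    warning("place weights collapsed to zero; reinitialized to uniform")
    w <- rep(1 / sqrt(pm$M), pm$M)
  } else {
    w <- w / nw
  }
  pm$w <- w
  attr(pm, "delta") <- sqrt(sum((w - w_old)^2))
  pm
}

#' Train grid-to-place weights along a trajectory
#'
#' Offline pre-training: runs [integrate_path()] with per-step Hebbian
#' updates over the exploration odometry, then (by default) consolidates
#' the weights by iterating the same update rule on the final activity
#' snapshot until the fixed point is reached. During motion the per-step
#' weight change fluctuates at the scale of \code{lr}; the consolidation
#' phase is where the change norm genuinely vanishes. Convergence is
#' declared when the change norm stays below \code{tol} for \code{hold}
#' consecutive steps anywhere in the combined trace.
#'
#' @param stack A settled [grid_stack()].
#' @param odometry Odometry data frame (\code{t, vx, vy}).
#' @param pm A [place_module()] (defaults to a fresh one for the stack).
#' @param tol Convergence tolerance on the per-step weight change norm.
#' @param hold Consecutive sub-tolerance steps required.
#' @param consolidate Run the fixed-snapshot consolidation phase.
#' @param max_consolidate Iteration cap for the consolidation phase.
#' @return List with the trained \code{place} module, the updated
#'   \code{stack}, \code{trace} (per-step weight change norms; online
#'   phase then consolidation), \code{converged}, and \code{converged_at}
#'   (first step satisfying the criterion, \code{NA} if never).
#' @export
train_weights <- function(stack, odometry, pm = NULL, tol = 1e-7,
                          hold = 100L, consolidate = TRUE,
                          max_consolidate = 500000L) {
  if (is.null(pm)) pm <- place_module(length(stack$modules))
  h <- integrate_path(stack, odometry, record_every = 0L, place = pm,
                      learn = TRUE)
  trace <- h$dwtrace
  pm <- h$place
  if (consolidate) {
    acts <- .stack_acts(h$stack)
    extra <- numeric(max_consolidate)
    used <- 0L
    streak <- 0L
    for (it in seq_len(max_consolidate)) {
      pa <- place_activation(acts, pm)
      pm <- hebbian_update(pm, pa, acts)
      extra[it] <- attr(pm, "delta")
      used <- it
      streak <- if (extra[it] < tol) streak + 1L else 0L
      if (streak >= hold) break
    }
    trace <- c(trace, extra[seq_len(used)])
  }
  below <- trace < tol
  run <- rle(below)
  converged <- any(run$values & run$lengths >= hold)
  converged_at <- NA_integer_
  if (converged) {
    ends <- cumsum(run$lengths)
    k <- which(run$values & run$lengths >= hold)[1]
    converged_at <- ends[k] - run$lengths[k] + hold
  }
  list(place = pm, stack = h$stack, trace = trace,
       converged = converged, converged_at = converged_at)
}

# unwrap a winner coordinate sequence on the torus by continuity
.unwrap_seq <- function(z, N) {
  d <- diff(z)
  d <- d - N * round(d / N)
  if (any(abs(d) > N / 2 - 1e-9))
    warning("unwrap failure: winner jumped more than half a sheet")
  cumsum(c(z[1], d))
}

#' Decode arena positions from place-cell winners
#'
#' Converts a recorded run to unwrapped sheet coordinates and calibrates
#' an affine map per axis against ground-truth positions over the first
#' part of the run. Winner-based decoding assumes all modules share one
#' path-integration gain (see [calibrate_stack()]) so the winner pattern
#' translates rigidly; the displacement method only needs per-module
#' continuity.
#'
#' @param history A [integrate_path()] result with winners (a place module
#'   was attached).
#' @param truth Data frame \code{t, x, y} of ground-truth positions
#'   (matched to \code{history$times} by nearest time).
#' @param calib_frac Leading fraction of the run used to fit the affine
#'   calibration.
#' @param method \code{"displacement"} (default) decodes from the mean
#'   grid-pattern displacement across modules, which is robust when
#'   residual gain mismatch between modules makes the winner hop between
#'   lattice-equivalent cells; \code{"winner"} unwraps the place-cell
#'   winner sequence by continuity, using the recorded mean pattern
#'   displacement between records as a motion prior for image selection.
#' @return Data frame \code{t, x, y} of decoded positions (class
#'   \code{"decoded_trajectory"}).
#' @export
decode_trajectory <- function(history, truth, calib_frac = 0.25,
                              method = c("displacement", "winner")) {
  method <- match.arg(method)
  N <- history$stack$N
  M <- ncol(history$disp) / 2
  mdx <- rowMeans(history$disp[, 2 * seq_len(M) - 1, drop = FALSE])
  mdy <- rowMeans(history$disp[, 2 * seq_len(M), drop = FALSE])
  if (method == "displacement") {
    ux <- mdx
    uy <- mdy
  } else {
    stopifnot(!is.null(history$winners))
    k0 <- history$winners - 1L
    row <- k0 %/% N
    col <- k0 %% N
    n <- length(k0)
    ux <- numeric(n)
    uy <- numeric(n)
    ux[1] <- col[1]
    uy[1] <- row[1]
    pdx <- c(0, diff(mdx))
    pdy <- c(0, diff(mdy))
    jumped <- FALSE
    for (k in seq_len(n)[-1]) {
      tx <- ux[k - 1] + pdx[k]
      ty <- uy[k - 1] + pdy[k]
      dx <- col[k] - tx
      dy <- row[k] - ty
      dx <- dx - N * round(dx / N)
      dy <- dy - N * round(dy / N)
      if (max(abs(dx), abs(dy)) > N / 4) jumped <- TRUE
      ux[k] <- tx + dx
      uy[k] <- ty + dy
    }
    if (jumped)
      warning("winner hopped between non-adjacent cells during decoding")
  }
  ti <- vapply(history$times, function(tt) which.min(abs(truth$t - tt)), 1L)
  tx <- truth$x[ti]
  ty <- truth$y[ti]
  n_cal <- max(2L, floor(length(ux) * calib_frac))
  # the sheet axes are aligned with the arena axes by construction; fit
  # offset and (signed) scale per axis, allowing for an axis swap
  fit_pair <- function(u, v, w) {
    if (stats::sd(u[1:n_cal]) < 1e-9 && stats::sd(v[1:n_cal]) < 1e-9)
      return(rep(mean(w[1:n_cal]), length(u)))  # stationary: no scale info
    r_direct <- abs(suppressWarnings(stats::cor(u[1:n_cal], w[1:n_cal])))
    r_swap <- abs(suppressWarnings(stats::cor(v[1:n_cal], w[1:n_cal])))
    src <- if (!is.na(r_swap) && (is.na(r_direct) || r_swap > r_direct)) v
           else u
    co <- stats::coef(stats::lm(w[1:n_cal] ~ src[1:n_cal]))
    if (any(is.na(co))) return(rep(mean(w[1:n_cal]), length(u)))
    co[1] + co[2] * src
  }
  out <- data.frame(t = history$times,
                    x = fit_pair(ux, uy, tx),
                    y = fit_pair(uy, ux, ty))
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}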