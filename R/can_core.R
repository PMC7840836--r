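#' Grid-module specification
#'
#' Bundles the parameters of one continuous-attractor grid module: an
#' \code{N x N} neural sheet on a torus whose recurrent difference-of-Gaussians
#' kernel selects a spatially periodic bump lattice with \code{n_m} periods
#' across the sheet.
#'
#' @param N Sheet side length in neurons; must be even (the sheet tiles into
#'   2x2 sub-units holding the four preferred directions).
#' @param n_m Number of bump periods across the sheet (grid period is
#'   approximately \code{N / n_m} neurons).
#' @param w0 Recurrent weight gain. \code{NULL} uses the shipped per-\code{N}
#'   calibration (see [default_w0()]).
#' @param c_sigma Sigma divisor: kernel width \code{sigma_m = N / (c_sigma *
#'   n_m)}; must lie in \[3, 4\].
#' @param b Inhibition-width ratio of the two Gaussians (> 1); 1.01 for all
#'   modules.
#' @param k_g Steepness of the sigmoidal transfer function.
#' @param alpha Velocity gain, sheet input units per m/s.
#' @param I0 Tonic excitatory drive added to every neuron's net input. The
#'   purely inhibitory recurrent kernel needs a constant excitatory operating
#'   current for bump lattices to form; the velocity input modulates around
#'   it.
#' @param tau Neural time constant in seconds.
#' @param l Outgoing-weight shift along the presynaptic preferred direction,
#'   in neurons.
#' @param dt Euler integration step in seconds; must satisfy
#'   \code{dt <= tau / 5}.
#' @param seed RNG seed for the module's random initial firing rates.
#' @return An object of class \code{"grid_module_spec"}.
#' @export
grid_module_spec <- function(N = 40L, n_m = 4L, w0 = NULL, c_sigma = 3.4,
                             b = 1.01, k_g = 18, alpha = 0.2, I0 = 1,
                             tau = 0.005, l = 2L, dt = 0.001, seed = 1L) {
  N <- as.integer(N)
  n_m <- as.integer(n_m)
  if (is.na(N) || N < 2L || N %% 2L != 0L)
    stop("invalid spec: N must be an even integer >= 2", call. = FALSE)
  if (is.na(n_m) || n_m < 1L)
    stop("invalid spec: n_m must be a positive integer", call. = FALSE)
  if (!is.numeric(b) || b <= 1)
    stop("invalid spec: b must exceed 1", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0)
    stop("invalid spec: tau must be positive", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || dt > tau / 5 + 1e-12)
    stop("invalid spec: dt must satisfy 0 < dt <= tau / 5", call. = FALSE)
  if (!is.numeric(c_sigma) || c_sigma < 3 || c_sigma > 4)
    stop("invalid spec: c_sigma must lie in [3, 4]", call. = FALSE)
  if (is.null(w0)) w0 <- default_w0(N)
  spec <- list(N = N, n_m = n_m, w0 = w0, c_sigma = c_sigma, b = b,
               k_g = k_g, alpha = alpha, I0 = I0, tau = tau,
               l = as.numeric(l), dt = dt, seed = as.integer(seed))
  class(spec) <- "grid_module_spec"
  spec
}

#' Default recurrent weight gain for a sheet size
#'
#' Larger sheets need a smaller weight gain for high-quality periodic
#' patterns. The shipped table was calibrated once by sweeping \code{w0}
#' and maximizing the sheet-snapshot gridness (see [tune_w0()]);
#' intermediate sizes are interpolated on a log-log scale.
#'
#' @param N Sheet side length in neurons.
#' @return A scalar weight gain.
#' @export
default_w0 <- function(N) {
  tab_N <- c(16, 24, 32, 40, 48, 64, 84)
  tab_w <- c(375, 167, 94, 60, 41.7, 23.4, 13.7)
  if (N <= tab_N[1]) return(tab_w[1])
  if (N >= tab_N[length(tab_N)]) return(tab_w[length(tab_w)])
  exp(stats::approx(log(tab_N), log(tab_w), xout = log(N))$y)
}

# canonical direction order used throughout: East, North, West, South
.dir_angles <- c(0, pi / 2, pi, 3 * pi / 2)
.dir_ex <- c(1, 0, -1, 0)
.dir_ey <- c(0, 1, 0, -1)

#' Preferred-direction assignment of the neural sheet
#'
#' Tiles the \code{N x N} sheet with 2x2 sub-units, each containing the four
#' preferred directions exactly once in the fixed layout
#' \code{rbind(c(pi/2, 0), c(pi, 3*pi/2))}.
#'
#' @param N Even sheet side length.
#' @return An \code{N x N} matrix of angles in radians.
#' @export
preferred_direction_map <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L || N %% 2L != 0L)
    stop("invalid spec: N must be even", call. = FALSE)
  block <- rbind(c(pi / 2, 0), c(pi, 3 * pi / 2))
  block[rep(1:2, length.out = N), rep(1:2, length.out = N)]
}

# separable form of the recurrent kernel consumed by the compiled fast
# path: each Gaussian factorizes over the torus axes (per-axis minimal
# image), so the per-direction convolution is Cy %*% g_d %*% Cx per
# Gaussian, with the direction's l-shift folded into the shifted axis.
# Slices per direction: [a*Cy_b, Cx_b, a*Cy_1, Cx_1].
.separable_kernels <- function(spec, n_max) {
  N <- spec$N
  sigma_m <- N / (spec$c_sigma * spec$n_m)
  a_m <- spec$w0 * spec$n_m / n_max
  idx <- 0:(N - 1)
  circ_left <- function(bfac, shift) {
    D <- .wrap_disp(outer(idx, idx, "-") - shift, N)
    exp(-bfac * D^2 / (2 * sigma_m^2))
  }
  Csep <- array(0, dim = c(N, N, 16))
  for (d in 1:4) {
    sx <- spec$l * .dir_ex[d]
    sy <- spec$l * .dir_ey[d]
    o <- 4 * (d - 1)
    Csep[, , o + 1] <- a_m * circ_left(spec$b, sy)
    Csep[, , o + 2] <- t(circ_left(spec$b, sx))
    Csep[, , o + 3] <- a_m * circ_left(1, sy)
    Csep[, , o + 4] <- t(circ_left(1, sx))
  }
  Csep
}

# per-neuron unit-vector components and per-direction 0/1 masks
.direction_geometry <- function(directions) {
  N <- nrow(directions)
  Ex <- matrix(0, N, N)
  Ey <- matrix(0, N, N)
  masks <- array(0, dim = c(N, N, 4))
  for (d in 1:4) {
    hit <- abs(directions - .dir_angles[d]) < 1e-9
    Ex[hit] <- .dir_ex[d]
    Ey[hit] <- .dir_ey[d]
    masks[, , d][hit] <- 1
  }
  list(Ex = Ex, Ey = Ey, masks = masks)
}

#' Feed-forward velocity input
#'
#' Each neuron receives \code{alpha * (e_theta . v)}: within one sub-unit
#' laid out as \code{[pi/2, 0; pi, 3*pi/2]} the inputs for velocity
#' \code{(vx, vy)} are \code{alpha * c(vy, vx, -vx, -vy)}.
#'
#' @param alpha Velocity gain.
#' @param directions Preferred-direction matrix from
#'   [preferred_direction_map()].
#' @param v Planar velocity \code{c(vx, vy)} in m/s.
#' @return Matrix of per-neuron inputs, same shape as \code{directions}.
#' @export
feedforward_input <- function(alpha, directions, v) {
  stopifnot(length(v) == 2, all(is.finite(v)))
  geo <- .direction_geometry(directions)
  alpha * (geo$Ex * v[1] + geo$Ey * v[2])
}

#' Sigmoidal transfer function
#'
#' \code{s(x) = 1 / (1 + exp(-k_g * x))}, mapping any finite net input into
#' (0, 1).
#'
#' @param x Net input (any numeric shape).
#' @param k_g Steepness.
#' @return Values in (0, 1), same shape as \code{x}.
#' @export
sigmoid_transfer <- function(x, k_g) {
  1 / (1 + exp(-k_g * x))
}

# wrap displacements to the minimal image [-N/2, N/2)
.wrap_disp <- function(z, N) {
  ((z + N / 2) %% N) - N / 2
}

#' Recurrent weight kernel of a grid module
#'
#' Builds the four direction-resolved kernel images
#' \deqn{W(x) = a_m (\exp(-b|x|^2 / 2\sigma_m^2) - \exp(-|x|^2 / 2\sigma_m^2))}
#' with \code{x} the torus displacement \code{x_i - x_j - l * e_theta_j}
#' (minimal image per axis), \code{sigma_m = N / (c_sigma * n_m)} and
#' \code{a_m = w0 * n_m / n_max}. With \code{b > 1} the kernel is everywhere
#' \code{<= 0} and vanishes only at \code{|x| = 0}.
#'
#' @param spec A [grid_module_spec()].
#' @param n_max Largest period count in the stack the module belongs to
#'   (sets the amplitude ratio \code{a_m = w0 * n_m / n_max}).
#' @return List with \code{K} (real \code{N x N x 4} kernel images indexed by
#'   displacement, one per presynaptic direction), \code{Khat} (their 2-D
#'   FFTs), \code{sigma_m}, \code{a_m}.
#' @export
grid_kernel <- function(spec, n_max = spec$n_m) {
  if (n_max < spec$n_m)
    stop("invalid stack: n_max must be >= n_m", call. = FALSE)
  N <- spec$N
  sigma_m <- N / (spec$c_sigma * spec$n_m)
  a_m <- spec$w0 * spec$n_m / n_max
  dxy <- 0:(N - 1)  # displacement grid, wrapped below
  K <- array(0, dim = c(N, N, 4))
  Khat <- array(complex(real = 0), dim = c(N, N, 4))
  for (d in 1:4) {
    ux <- .wrap_disp(outer(rep(1, N), dxy) - spec$l * .dir_ex[d], N)
    uy <- .wrap_disp(outer(dxy, rep(1, N)) - spec$l * .dir_ey[d], N)
    r2 <- ux^2 + uy^2
    K[, , d] <- a_m * (exp(-spec$b * r2 / (2 * sigma_m^2)) -
                         exp(-r2 / (2 * sigma_m^2)))
    Khat[, , d] <- fft(K[, , d])
  }
  list(K = K, Khat = Khat, sigma_m = sigma_m, a_m = a_m)
}

#' Dense recurrent weight matrix (reference form)
#'
#' Materializes the full \code{N^2 x N^2} weight matrix with neurons indexed
#' row-major (\code{i = (row - 1) * N + col}, position \code{(x, y) =
#' (col - 1, row - 1)}). Intended for small sheets; the simulator never uses
#' this form.
#'
#' @inheritParams grid_kernel
#' @return A dense numeric matrix \code{W} with \code{W[i, j]} the weight
#'   from neuron \code{j} to neuron \code{i}.
#' @export
dense_weight_matrix <- function(spec, n_max = spec$n_m) {
  N <- spec$N
  ker <- grid_kernel(spec, n_max)
  dirs <- preferred_direction_map(N)
  idx <- expand.grid(col = 0:(N - 1), row = 0:(N - 1))
  # row-major order: row varies slowest
  ord <- order(idx$row, idx$col)
  px <- idx$col[ord]
  py <- idx$row[ord]
  dnum <- matrix(0L, N, N)
  for (d in 1:4) dnum[abs(dirs - .dir_angles[d]) < 1e-9] <- d
  dj <- dnum[cbind(py + 1, px + 1)]
  n2 <- N * N
  W <- matrix(0, n2, n2)
  sigma_m <- ker$sigma_m
  a_m <- ker$a_m
  for (j in seq_len(n2)) {
    ux <- .wrap_disp(px - px[j] - spec$l * .dir_ex[dj[j]], N)
    uy <- .wrap_disp(py - py[j] - spec$l * .dir_ey[dj[j]], N)
    r2 <- ux^2 + uy^2
    W[, j] <- a_m * (exp(-spec$b * r2 / (2 * sigma_m^2)) -
                       exp(-r2 / (2 * sigma_m^2)))
  }
  W
}

#' Construct a grid module
#'
#' Assembles sheet geometry, recurrent kernel, and (optionally) settles the
#' attractor from random initial firing rates at zero velocity.
#'
#' @param spec A [grid_module_spec()].
#' @param n_max Largest period count of the enclosing stack.
#' @param settle_steps Settling iterations at zero velocity (0 skips
#'   settling).
#' @return An object of class \code{"grid_module"}.
#' @export
grid_module <- function(spec, n_max = spec$n_m, settle_steps = 500L) {
  stopifnot(inherits(spec, "grid_module_spec"))
  N <- spec$N
  directions <- preferred_direction_map(N)
  geo <- .direction_geometry(directions)
  ker <- grid_kernel(spec, n_max)
  mod <- list(spec = spec, n_max = n_max, directions = directions,
              Ex = geo$Ex, Ey = geo$Ey, masks = geo$masks,
              K = ker$K, Khat = ker$Khat,
              Csep = .separable_kernels(spec, n_max),
              sigma_m = ker$sigma_m, a_m = ker$a_m,
              g = matrix(0.5, N, N), settled = FALSE)
  class(mod) <- "grid_module"
  if (settle_steps > 0) mod <- settle_module(mod, steps = settle_steps)
  mod
}

#' Recurrent input to a module (R reference path)
#'
#' Computes \code{W . g} by FFT circular convolution of the four
#' direction-masked activity sheets with the direction kernels. Kept in R as
#' an independent check of the compiled integrator and of the dense-matrix
#' reference.
#'
#' @param module A \code{"grid_module"}.
#' @param g Activity matrix (defaults to the module state).
#' @return Matrix of recurrent drives.
#' @export
recurrent_input <- function(module, g = module$g) {
  N <- module$spec$N
  acc <- matrix(complex(real = 0), N, N)
  for (d in 1:4)
    acc <- acc + module$Khat[, , d] * fft(g * module$masks[, , d])
  Re(fft(acc, inverse = TRUE)) / (N * N)
}

#' One forward-Euler step of the attractor dynamics
#'
#' \code{g <- g + (dt / tau) * (-g + s(W g + I))} with the sigmoidal
#' transfer \code{s}.
#'
#' @param module A \code{"grid_module"}.
#' @param I Per-neuron feed-forward input matrix (default zero).
#' @param dt Step in seconds (defaults to the module spec's \code{dt}).
#' @return The module with updated activity.
#' @export
step_dynamics <- function(module, I = NULL, dt = module$spec$dt) {
  if (dt > module$spec$tau)
    stop("stability error: dt exceeds tau", call. = FALSE)
  if (is.null(I)) I <- matrix(0, module$spec$N, module$spec$N)
  u <- recurrent_input(module) + I + module$spec$I0
  s <- sigmoid_transfer(u, module$spec$k_g)
  module$g <- module$g + (dt / module$spec$tau) * (-module$g + s)
  module
}

#' Settle a module into its periodic bump state
#'
#' Initializes activities uniformly at random in (0, 1) from the module
#' seed and runs the dynamics at zero velocity until a stable periodic
#' pattern forms. Warns if no spatial structure emerges (activity variance
#' at the noise floor).
#'
#' @param module A \code{"grid_module"}.
#' @param steps Settling iterations.
#' @param seed RNG seed (defaults to the spec seed).
#' @return The settled module.
#' @export
settle_module <- function(module, steps = 500L, seed = module$spec$seed) {
  N <- module$spec$N
  set.seed(seed)
  module$g <- matrix(runif(N * N), N, N)
  res <- stack_run_cpp(array(module$g, dim = c(N, N, 1)),
                       module$Csep, module$masks, module$Ex, module$Ey,
                       rep(0, steps), rep(0, steps),
                       module$spec$alpha, module$spec$k_g, module$spec$I0,
                       module$spec$dt, module$spec$tau, module$spec$n_m,
                       numeric(0), -1, 0, 0L,
                       matrix(integer(0), 0, 2))
  module$g <- res$g[, , 1]
  if (sd(module$g) < 1e-4)
    warning("settle failure: no periodic pattern formed (variance at noise floor)")
  module$settled <- TRUE
  module
}

#' Construct a multi-scale grid-cell stack
#'
#' Builds \code{M} grid modules sharing one sheet size, one per period count
#' in \code{n}, all driven by the same velocity stream. Amplitudes follow
#' \code{a_m = w0 * n_m / max(n)}.
#'
#' @param n Strictly increasing integer vector of period counts.
#' @param N Shared sheet side length.
#' @param settle_steps Settling iterations per module.
#' @param seed Base seed; module \code{m} settles from \code{seed + m - 1}.
#' @param ... Further arguments passed to [grid_module_spec()] (shared by
#'   all modules).
#' @return An object of class \code{"grid_stack"}.
#' @export
grid_stack <- function(n = c(2L, 3L, 4L, 5L), N = 40L, settle_steps = 1500L,
                       seed = 1L, ...) {
  n <- as.integer(n)
  if (length(n) < 1L || any(diff(n) <= 0L))
    stop("invalid stack: n must be strictly increasing", call. = FALSE)
  modules <- lapply(seq_along(n), function(m) {
    spec <- grid_module_spec(N = N, n_m = n[m], seed = seed + m - 1L, ...)
    grid_module(spec, n_max = max(n), settle_steps = settle_steps)
  })
  structure(list(modules = modules, n = n, N = as.integer(N)),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("grid_stack: %d modules, N = %d, periods n = (%s)\n",
              length(x$modules), x$N, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
print.grid_module <- function(x, ...) {
  cat(sprintf(
    "grid_module: N = %d, n_m = %d, sigma_m = %.2f, a_m = %.2f, settled = %s\n",
    x$spec$N, x$spec$n_m, x$sigma_m, x$a_m, x$settled))
  invisible(x)
}

# gather the per-module cubes the compiled integrator consumes
.stack_tensors <- function(stack) {
  N <- stack$N
  M <- length(stack$modules)
  g <- array(0, dim = c(N, N, M))
  Csep <- array(0, dim = c(N, N, 16 * M))
  for (m in seq_len(M)) {
    g[, , m] <- stack$modules[[m]]$g
    Csep[, , (16 * m - 15):(16 * m)] <- stack$modules[[m]]$Csep
  }
  first <- stack$modules[[1]]
  list(g = g, Csep = Csep, masks = first$masks, Ex = first$Ex, Ey = first$Ey,
       alpha = vapply(stack$modules, function(m) m$spec$alpha, 0),
       kg = vapply(stack$modules, function(m) m$spec$k_g, 0),
       i0 = vapply(stack$modules, function(m) m$spec$I0, 0),
       tau = vapply(stack$modules, function(m) m$spec$tau, 0),
       nm = as.numeric(stack$n), dt = first$spec$dt)
}

#' Validate an odometry data frame
#'
#' @param odometry Data frame with columns \code{t} (s), \code{vx}, \code{vy}
#'   (m/s).
#' @return The validated data frame.
#' @export
as_odometry <- function(odometry) {
  need <- c("t", "vx", "vy")
  if (!all(need %in% names(odometry)))
    stop("odometry must have columns t, vx, vy", call. = FALSE)
  if (!all(is.finite(as.matrix(odometry[need]))))
    stop("odometry contains non-finite values", call. = FALSE)
  odometry
}

#' Drive a grid-cell stack along an odometry stream
#'
#' Advances every module's attractor dynamics with the shared velocity
#' sequence (path integration). Optionally drives an attached place-cell
#' module and applies competitive Hebbian learning to its per-module
#' weights.
#'
#' @param stack A settled [grid_stack()].
#' @param odometry Data frame \code{t, vx, vy}; one dynamics step of length
#'   \code{dt} per row.
#' @param record_every Record bump phases (and winners, tracked cells) every
#'   this many steps.
#' @param track_cells Optional data frame with columns \code{cell} (1-based
#'   column-major index into the sheet) and \code{module} (1-based) whose
#'   activities are recorded.
#' @param place Optional [place_module()] to co-simulate.
#' @param learn If \code{TRUE} (and \code{place} given) apply the Hebbian
#'   weight update each step.
#' @return A list of class \code{"grid_history"}: the updated \code{stack},
#'   recorded \code{times}, per-module unwrapped pattern displacement
#'   \code{disp} (columns \code{dx, dy} per module, in neurons, relative to
#'   the state at entry), place \code{winners} (1-based row-major index) and
#'   final activity \code{p} when a place module is attached, \code{tracked}
#'   activities, the updated \code{place} module, and the per-step weight
#'   change trace \code{dwtrace} when learning.
#' @export
integrate_path <- function(stack, odometry, record_every = 10L,
                           track_cells = NULL, place = NULL, learn = FALSE) {
  stopifnot(inherits(stack, "grid_stack"))
  if (!all(vapply(stack$modules, function(m) isTRUE(m$settled), TRUE)))
    stop("state error: stack has unsettled modules", call. = FALSE)
  odometry <- as_odometry(odometry)
  tens <- .stack_tensors(stack)
  track <- matrix(integer(0), 0, 2)
  if (!is.null(track_cells))
    track <- cbind(as.integer(track_cells$cell) - 1L,
                   as.integer(track_cells$module) - 1L)
  w <- numeric(0); kp <- -1; lr <- 0
  if (!is.null(place)) {
    stopifnot(inherits(place, "place_module"))
    w <- place$w
    kp <- place$k_p
    lr <- if (learn) place$lr else 0
  }
  res <- stack_run_cpp(tens$g, tens$Csep, tens$masks, tens$Ex, tens$Ey,
                       odometry$vx, odometry$vy, tens$alpha, tens$kg,
                       tens$i0, tens$dt, tens$tau, tens$nm, w, kp, lr,
                       as.integer(record_every), track)
  for (m in seq_along(stack$modules)) stack$modules[[m]]$g <- res$g[, , m]
  n_rec <- nrow(res$disp)
  times <- if (record_every > 0 && n_rec > 0)
    odometry$t[seq_len(n_rec) * record_every] else numeric(0)
  out <- list(stack = stack, times = times, disp = res$disp,
              tracked = res$tracked, dwtrace = as.numeric(res$dwtrace),
              p = NULL, winners = NULL, place = place)
  if (!is.null(place)) {
    place$w <- as.numeric(res$w)
    if (isTRUE(res$w_reinit))
      warning("place weights collapsed to zero; reinitialized to uniform")
    out$place <- place
    out$p <- res$p
    out$winners <- as.integer(res$winners) + 1L
  }
  class(out) <- "grid_history"
  out
}

#' Minimal phase distance on a periodic axis
#'
#' @param a,b Phases in neurons.
#' @param period Axis period in neurons.
#' @return Elementwise minimal wrapped distance.
#' @export
phase_distance <- function(a, b, period) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

#' Measure the path-integration gain of a stack
#'
#' Runs a constant-velocity episode and regresses the unwrapped pattern
#' displacement against distance travelled, returning sheet neurons per
#' meter (signed: the sheet flows opposite or along the motion depending on
#' the kernel shift convention). Modules share one gain when they share
#' \code{alpha}, \code{l}, and \code{k_g}.
#'
#' @param stack A settled [grid_stack()].
#' @param speed Probe speed in m/s.
#' @param duration Probe duration in seconds.
#' @return List with \code{gain} (mean over modules, neurons per meter) and
#'   \code{per_module}.
#' @export
calibrate_gain <- function(stack, speed = 0.25, duration = 2) {
  dt <- stack$modules[[1]]$spec$dt
  steps <- round(duration / dt)
  M <- length(stack$modules)
  est <- matrix(0, 4, M)
  probes <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (k in seq_along(probes)) {
    odo <- data.frame(t = seq_len(steps) * dt,
                      vx = speed * probes[[k]][1],
                      vy = speed * probes[[k]][2])
    hist <- integrate_path(stack, odo, record_every = 5L)
    dist <- hist$times * speed
    axis <- if (probes[[k]][1] != 0) 0L else 1L
    sgn <- sum(probes[[k]])
    for (m in seq_len(M))
      est[k, m] <- sgn *
        stats::coef(stats::lm(hist$disp[, 2 * m - 1 + axis] ~ dist))[[2]]
    stack <- hist$stack
  }
  per <- colMeans(est)
  list(gain = mean(per), per_module = per, per_probe = est, stack = stack)
}

# unwrap a phase sequence on a periodic axis by continuity
.unwrap_phase <- function(ph, period) {
  d <- diff(ph)
  d <- d - period * round(d / period)
  cumsum(c(ph[1], d))
}

#' Calibrate per-module velocity gains to a common path-integration gain
#'
#' The flow speed of a module's bump lattice per unit velocity input depends
#' on its kernel width, so modules driven with one shared \code{alpha}
#' integrate at different sheet-neurons-per-meter rates. Coherent place
#' decoding needs all modules to share one rate: this routine measures each
#' module's gain with a constant-velocity probe and rescales its
#' \code{alpha} toward \code{target_gain}, iterating to absorb the response
#' nonlinearity.
#'
#' @param stack A settled [grid_stack()].
#' @param target_gain Desired gain in sheet neurons per meter.
#' @param probe_speed Probe speed in m/s (use a speed typical of the
#'   trajectories the stack will integrate).
#' @param iters Calibration passes.
#' @return The stack with adjusted per-module \code{alpha}, with the
#'   achieved per-module gains in \code{attr(, "gains")}.
#' @export
calibrate_stack <- function(stack, target_gain = 150, probe_speed = 0.25,
                            iters = 3L) {
  for (it in seq_len(iters)) {
    g <- calibrate_gain(stack, speed = probe_speed, duration = 1.5)
    stack <- g$stack
    for (m in seq_along(stack$modules)) {
      ratio <- target_gain / g$per_module[m]
      ratio <- min(max(ratio, 0.2), 5)  # guard against probe noise
      stack$modules[[m]]$spec$alpha <- stack$modules[[m]]$spec$alpha * ratio
    }
  }
  g <- calibrate_gain(stack, speed = probe_speed, duration = 1.5)
  stack <- g$stack
  attr(stack, "gains") <- g$per_module
  stack
}

#' Sweep the weight gain for a sheet size
#'
#' Settles single modules over a grid of \code{w0} values and scores the
#' sheet-snapshot gridness, returning the sweep table and the best gain.
#'
#' @param N Sheet side length.
#' @param n_m Period count used for the probe module.
#' @param w0_grid Candidate gains.
#' @param settle_steps Settling iterations per candidate.
#' @param ... Passed to [grid_module_spec()].
#' @return List with \code{table} (w0, gridness, period) and \code{best}.
#' @export
tune_w0 <- function(N = 40L, n_m = 4L, w0_grid = c(5, 10, 15, 20, 30, 45, 60),
                    settle_steps = 500L, ...) {
  rows <- lapply(w0_grid, function(w0) {
    spec <- grid_module_spec(N = N, n_m = n_m, w0 = w0, ...)
    mod <- grid_module(spec, settle_steps = settle_steps)
    sc <- sheet_snapshot_score(mod$g)
    data.frame(w0 = w0, gridness = sc$gridness,
               period = ifelse(is.na(sc$period), NA_real_, sc$period))
  })
  tab <- do.call(rbind, rows)
  best <- tab$w0[which.max(ifelse(is.na(tab$gridness), -Inf, tab$gridness))]
  list(table = tab, best = best)
}
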