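#' Accumulate a firing-rate map over a trajectory
#'
#' Bins the arena into \code{B x B} spatial bins and averages the cell's
#' activity over all visits to each bin (the standard rate-map estimate:
#' accumulated firing divided by occupancy).
#'
#' @param activity Numeric activity series, one value per pose.
#' @param poses Data frame with columns \code{x}, \code{y} (meters), aligned
#'   with \code{activity}.
#' @param arena Arena extent: either a side length (square arena with origin
#'   0) or a vector \code{c(xmin, xmax, ymin, ymax)}.
#' @param B Number of bins per axis (>= 16).
#' @return An object of class \code{"rate_map"}: \code{rate} (\code{B x B},
#'   rows = y bins, \code{NA} where unvisited), \code{occupancy},
#'   \code{bin_size} (meters per bin).
#' @export
accumulate_rate_map <- function(activity, poses, arena, B = 50L) {
  if (length(activity) == 0L) stop("empty trajectory", call. = FALSE)
  if (length(activity) != nrow(poses))
    stop("activity and poses must be aligned", call. = FALSE)
  B <- as.integer(B)
  if (B < 16L) stop("B must be >= 16", call. = FALSE)
  if (length(arena) == 1L) arena <- c(0, arena, 0, arena)
  xb <- seq(arena[1], arena[2], length.out = B + 1L)
  yb <- seq(arena[3], arena[4], length.out = B + 1L)
  ix <- findInterval(poses$x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(poses$y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  occ <- matrix(0, B, B)
  acc <- matrix(0, B, B)
  for (k in seq_along(activity)) {
    occ[iy[k], ix[k]] <- occ[iy[k], ix[k]] + 1
    acc[iy[k], ix[k]] <- acc[iy[k], ix[k]] + activity[k]
  }
  rate <- acc / occ
  rate[occ == 0] <- NA_real_
  structure(list(rate = rate, occupancy = occ,
                 bin_size = (arena[2] - arena[1]) / B),
            class = "rate_map")
}

#' Smooth a rate map with a Gaussian kernel
#'
#' Standard occupancy-aware smoothing: both the rate (with unvisited bins
#' zeroed) and the visit indicator are blurred with the same Gaussian and
#' their ratio taken, so unvisited regions do not drag the estimate down.
#' Bins far from any visited bin stay \code{NA}.
#'
#' @param map A [accumulate_rate_map()] result.
#' @param sigma_bins Gaussian width in bins.
#' @return The map with smoothed \code{rate}.
#' @export
smooth_rate_map <- function(map, sigma_bins = 1.5) {
  stopifnot(inherits(map, "rate_map"))
  B <- nrow(map$rate)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(-half:half, sd = sigma_bins)
  blur <- function(m) {
    # separable convolution with edge renormalization via the indicator
    m2 <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
    t(apply(t(m2), 2, function(row) stats::filter(row, k, sides = 2)))
  }
  I <- ifelse(is.finite(map$rate), 1, 0)
  A <- ifelse(is.finite(map$rate), map$rate, 0)
  # zero-pad the filter boundary effects by treating NA as 0
  bA <- blur(A)
  bI <- blur(I)
  bA[is.na(bA)] <- 0
  bI[is.na(bI)] <- 0
  sm <- bA / bI
  sm[bI < 0.05 * sum(k)] <- NA_real_
  map$rate <- sm
  map
}

# masked cross-sums at every integer shift via zero-padded FFT correlation
.shift_sums <- function(A, I, P) {
  B <- nrow(A)
  pad <- function(m) {
    out <- matrix(0, P, P)
    out[1:B, 1:B] <- m
    out
  }
  xcorr <- function(a, b) {
    # sum over overlap of a[i] * b[i + shift]
    Re(fft(Conj(fft(pad(a))) * fft(pad(b)), inverse = TRUE)) / (P * P)
  }
  list(n = xcorr(I, I), sab = xcorr(A, A), sa = xcorr(A, I),
       sb = xcorr(I, A), saa = xcorr(A * A, I), sbb = xcorr(I, A * A))
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every integer bin shift,
#' using only bins where both copies are visited; shifts with fewer than
#' \code{min_overlap} overlapping bins are masked \code{NA}.
#'
#' @param map A [accumulate_rate_map()] result or a plain numeric matrix
#'   (\code{NA} marks invalid bins).
#' @param min_overlap Minimum overlapping valid bins per shift.
#' @return An object of class \code{"autocorrelogram"}: \code{corr} of size
#'   \code{(2B-1) x (2B-1)} (zero shift at the center), \code{n_overlap},
#'   and \code{center} (the zero-shift index).
#' @export
autocorrelogram <- function(map, min_overlap = 20L) {
  A <- if (inherits(map, "rate_map")) map$rate else map
  B <- nrow(A)
  if (sum(is.finite(A)) < 20L)
    stop("need at least 20 valid bins", call. = FALSE)
  I <- ifelse(is.finite(A), 1, 0)
  A0 <- ifelse(is.finite(A), A, 0)
  P <- 2L * B
  s <- .shift_sums(A0, I, P)
  # reorder FFT output so shift (dy, dx) in -(B-1)..(B-1) maps to
  # index (dy + B, dx + B)
  reorder <- function(m) {
    idx <- c((P - B + 2L):P, 1L:B)  # shifts -(B-1) .. (B-1)
    m[idx, idx]
  }
  n <- reorder(s$n)
  sab <- reorder(s$sab)
  sa <- reorder(s$sa)
  sb <- reorder(s$sb)
  saa <- reorder(s$saa)
  sbb <- reorder(s$sbb)
  num <- n * sab - sa * sb
  den <- sqrt(pmax(n * saa - sa^2, 0) * pmax(n * sbb - sb^2, 0))
  corr <- num / den
  corr[!is.finite(corr)] <- NA_real_
  corr[round(n) < min_overlap] <- NA_real_
  corr <- pmin(pmax(corr, -1), 1)
  structure(list(corr = corr, n_overlap = round(n), center = B),
            class = "autocorrelogram")
}

# angularly averaged profile of a SAC by integer radius
.radial_profile <- function(corr, center) {
  B2 <- nrow(corr)
  dy <- row(corr) - center
  dx <- col(corr) - center
  r <- round(sqrt(dy^2 + dx^2))
  rs <- 0:max(r)
  prof <- vapply(rs, function(rr) {
    v <- corr[r == rr]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  prof
}

# bilinear rotation of a matrix about the given center; outside -> NA
.rotate_about_center <- function(m, center, angle_deg) {
  B2 <- nrow(m)
  th <- angle_deg * pi / 180
  dy <- row(m) - center
  dx <- col(m) - center
  # sample source coordinates rotated by -angle
  sx <- cos(th) * dx + sin(th) * dy + center
  sy <- -sin(th) * dx + cos(th) * dy + center
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- matrix(NA_real_, B2, B2)
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= B2 & y0 + 1 <= B2
  gv <- function(yy, xx) {
    v <- matrix(NA_real_, B2, B2)
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

# local maxima above a floor with greedy non-maximum suppression
.sac_peaks <- function(corr, center, floor_corr, nms_radius) {
  B2 <- nrow(corr)
  cand <- which(!is.na(corr) & corr > floor_corr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    v <- corr[r, c]
    nb <- corr[max(1, r - 1):min(B2, r + 1), max(1, c - 1):min(B2, c + 1)]
    keep[k] <- v >= max(nb, na.rm = TRUE)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  d_center <- sqrt((cand[, 1] - center)^2 + (cand[, 2] - center)^2)
  cand <- cand[d_center >= nms_radius, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  ord <- order(corr[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  chosen <- matrix(0, 0, 2)
  for (k in seq_len(nrow(cand))) {
    if (nrow(chosen) == 0L ||
        all(sqrt((chosen[, 1] - cand[k, 1])^2 +
                   (chosen[, 2] - cand[k, 2])^2) >= nms_radius))
      chosen <- rbind(chosen, cand[k, ])
  }
  chosen
}

#' Gridness score of a spatial autocorrelogram
#'
#' Locates the annulus containing the six peaks nearest the origin of the
#' autocorrelogram, correlates the annulus with copies rotated by 30, 60,
#' 90, 120, and 150 degrees, and returns the six-fold symmetry statistic
#' \code{min(r60, r120) - max(r30, r90, r150)}. The grid period is the
#' median center distance of the six peaks.
#'
#' @param sac An [autocorrelogram()] (or a matrix, taken as the correlogram
#'   with its center at the middle bin).
#' @param bin_size Optional meters per bin, to convert the period.
#' @param peak_floor Minimum correlation for a candidate peak.
#' @return An object of class \code{"grid_score"}: \code{gridness} (NA with
#'   \code{status = "too-few-peaks"} when fewer than six peaks are found),
#'   \code{period} (bins), \code{period_m} (meters, if \code{bin_size}
#'   given), \code{peaks} (six peak offsets, bins), \code{rotations} (the
#'   five rotation correlations).
#' @export
gridness_score <- function(sac, bin_size = NULL, peak_floor = 0.1) {
  if (inherits(sac, "autocorrelogram")) {
    corr <- sac$corr
    center <- sac$center
  } else {
    corr <- sac
    center <- (nrow(sac) + 1L) %/% 2L
  }
  fail <- function(status) {
    structure(list(gridness = NA_real_, period = NA_real_,
                   period_m = NA_real_, peaks = NULL, rotations = NULL,
                   status = status), class = "grid_score")
  }
  prof <- .radial_profile(corr, center)
  # inner annulus radius: first local minimum of the radial profile
  r_in <- NA_integer_
  for (r in 2:(length(prof) - 1)) {
    if (!is.na(prof[r]) && !is.na(prof[r + 1]) && prof[r + 1] > prof[r]) {
      r_in <- r
      break
    }
  }
  if (is.na(r_in)) r_in <- 2L
  peaks <- .sac_peaks(corr, center, peak_floor, r_in)
  if (nrow(peaks) < 6L) return(fail("too-few-peaks"))
  d <- sqrt((peaks[, 1] - center)^2 + (peaks[, 2] - center)^2)
  ord <- order(d)[1:6]
  six <- peaks[ord, , drop = FALSE]
  d6 <- d[ord]
  r_out <- 1.25 * max(d6)
  dy <- row(corr) - center
  dx <- col(corr) - center
  rr <- sqrt(dy^2 + dx^2)
  annulus <- rr >= r_in & rr <= r_out
  angles <- c(30, 60, 90, 120, 150)
  rots <- vapply(angles, function(a) {
    rot <- .rotate_about_center(corr, center, a)
    ok <- annulus & !is.na(corr) & !is.na(rot)
    if (sum(ok) < 20L) return(NA_real_)
    stats::cor(corr[ok], rot[ok])
  }, 0)
  names(rots) <- paste0("r", angles)
  if (any(is.na(rots))) return(fail("rotation-overlap-too-small"))
  gridness <- min(rots["r60"], rots["r120"]) -
    max(rots["r30"], rots["r90"], rots["r150"])
  period <- stats::median(d6)
  structure(list(gridness = unname(gridness), period = period,
                 period_m = if (is.null(bin_size)) NA_real_
                            else period * bin_size,
                 peaks = cbind(dy = six[, 1] - center, dx = six[, 2] - center),
                 rotations = rots, status = "ok"),
            class = "grid_score")
}

#' @export
print.grid_score <- function(x, ...) {
  if (identical(x$status, "ok"))
    cat(sprintf("grid_score: gridness = %.3f, period = %.2f bins\n",
                x$gridness, x$period))
  else cat(sprintf("grid_score: undefined (%s)\n", x$status))
  invisible(x)
}

#' Ratio of the second-highest to highest firing-field peak
#'
#' Finds the local maxima of a rate map (8-neighborhood, above
#' \code{floor}) and returns the ratio of the second-highest peak to the
#' highest: 0 for a single dominant field, near 1 for periodic multi-field
#' maps.
#'
#' @param map A [accumulate_rate_map()] result (or matrix).
#' @param floor Minimum rate for a peak.
#' @return Scalar ratio in \[0, 1\] (0 when fewer than two peaks).
#' @export
rate_map_peak_ratio <- function(map, floor = 0.05) {
  r <- if (inherits(map, "rate_map")) map$rate else map
  r[is.na(r)] <- 0
  B1 <- nrow(r)
  B2 <- ncol(r)
  peaks <- numeric(0)
  for (i in 2:(B1 - 1)) for (j in 2:(B2 - 1)) {
    nb <- r[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (r[i, j] == max(nb) && r[i, j] > floor)
      peaks <- c(peaks, r[i, j])
  }
  if (length(peaks) < 2) return(0)
  peaks <- sort(peaks, decreasing = TRUE)
  peaks[2] / peaks[1]
}

#' Gridness of a neural-sheet activity snapshot
#'
#' Treats the settled \code{N x N} sheet activity as a fully visited rate
#' map and scores its periodicity; the returned period is in sheet neurons.
#'
#' @param g Activity matrix.
#' @param ... Passed to [gridness_score()].
#' @return A \code{"grid_score"}.
#' @export
sheet_snapshot_score <- function(g, ...) {
  sac <- autocorrelogram(g)
  gridness_score(sac, bin_size = 1, ...)
}
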