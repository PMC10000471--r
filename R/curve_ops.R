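#' Melting curve container
#'
#' @param temperatures numeric, strictly increasing, uniform step (degrees C).
#' @param fluorescence numeric, same length.
#' @param channel dye channel label.
#' @param subject_id sample identifier.
#' @return A `melting_curve` object (data.frame with attributes).
#' @export
melting_curve <- function(temperatures, fluorescence,
                          channel = "HEX", subject_id = NA_character_) {
  if (length(temperatures) != length(fluorescence)) {
    stop("temperatures and fluorescence must have equal length")
  }
  .check_uniform_grid(temperatures)
  structure(
    data.frame(temperature = temperatures, fluorescence = fluorescence),
    channel = channel, subject_id = subject_id,
    class = c("melting_curve", "data.frame")
  )
}

.check_uniform_grid <- function(tg) {
  d <- diff(tg)
  if (length(d) && (any(d <= 0) || max(abs(d - d[1L])) > 1e-6)) {
    stop("temperature grid must be strictly increasing with uniform step")
  }
  invisible(tg)
}

# Savitzky-Golay derivative filters are identical for every curve on the
# same grid; cache them per (order, window, step)
.sg_cache <- new.env(parent = emptyenv())
.sg_filter <- function(p, n, h) {
  key <- paste(p, n, h, sep = "_")
  if (is.null(.sg_cache[[key]])) {
    .sg_cache[[key]] <- signal::sgolay(p, n, m = 1L, ts = h)
  }
  .sg_cache[[key]]
}

# -dF/dT on a uniform grid via a Savitzky-Golay first-derivative filter
# (order-2 local polynomial fit over the window; its built-in endpoint
# filters handle the curve ends). With smoothing_window = 1 plain central
# differences are used, one-sided at the endpoints. Plain-vector core
# shared by the single-curve wrapper and the cohort caller.
.neg_deriv <- function(tg, f, smoothing_window) {
  w <- as.integer(smoothing_window)
  if (w != 1L && (w < 5L || w %% 2L == 0L || w >= length(f))) {
    stop("smoothing_window must be 1 or an odd integer in [5, n_points)")
  }
  n <- length(f)
  h <- tg[2L] - tg[1L]
  if (w == 1L) {
    d <- numeric(n)
    d[2:(n - 1L)] <- (f[3:n] - f[1:(n - 2L)]) / (2 * h)
    d[1L] <- (f[2L] - f[1L]) / h
    d[n] <- (f[n] - f[n - 1L]) / h
  } else {
    d <- as.numeric(signal::sgolayfilt(f, .sg_filter(2L, w, h)))
  }
  -d
}

# matrix form of .neg_deriv (one curve per column, shared grid): the same
# Savitzky-Golay derivative filter applied to all columns at once
.neg_deriv_mat <- function(tg, fm, smoothing_window) {
  w <- as.integer(smoothing_window)
  n <- nrow(fm)
  h <- tg[2L] - tg[1L]
  if (w == 1L) {
    d <- fm
    d[2:(n - 1L), ] <- (fm[3:n, ] - fm[1:(n - 2L), ]) / (2 * h)
    d[1L, ] <- (fm[2L, ] - fm[1L, ]) / h
    d[n, ] <- (fm[n, ] - fm[n - 1L, ]) / h
    return(-d)
  }
  if (w < 5L || w %% 2L == 0L || w >= n) {
    stop("smoothing_window must be 1 or an odd integer in [5, n_points)")
  }
  filt <- .sg_filter(2L, w, h)
  k <- w %/% 2L
  # interior: FIR convolution with the centre filter row; ends: the
  # asymmetric endpoint rows (mirrors signal::sgolayfilt arithmetic)
  z <- stats::filter(fm, filt[k + 1L, w:1], method = "convolution",
                     sides = 1L)
  -rbind(filt[1:k, , drop = FALSE] %*% fm[1:w, , drop = FALSE],
         z[w:n, , drop = FALSE],
         filt[(k + 2L):w, , drop = FALSE] %*%
           fm[(n - w + 1L):n, , drop = FALSE])
}

#' Negative derivative of a melting curve
#'
#' Smooths the fluorescence with a Savitzky-Golay local polynomial (order 2)
#' and returns -dF/dT on the same temperature grid via central differences
#' (one-sided at the endpoints). Probe dissociation appears as a positive
#' peak at the duplex melting temperature.
#'
#' @param curve a [melting_curve()], or any data.frame with `temperature`
#'   and `fluorescence` columns on a uniform grid.
#' @param smoothing_window odd integer window length in grid points
#'   (default 11, i.e. about 1.1 degrees C on the default grid); use 1 to
#'   disable smoothing.
#' @return A `derivative_curve` data.frame with columns `temperature`,
#'   `neg_dfdt`.
#' @export
negative_derivative <- function(curve, smoothing_window = 11L) {
  tg <- curve$temperature
  .check_uniform_grid(tg)
  structure(
    data.frame(temperature = tg,
               neg_dfdt = .neg_deriv(tg, curve$fluorescence,
                                     smoothing_window)),
    channel = attr(curve, "channel"), subject_id = attr(curve, "subject_id"),
    class = c("derivative_curve", "data.frame")
  )
}

# peak detection core: returns a matrix with columns tm, height, prominence
# sorted by descending tm (possibly 0 rows)
.find_peaks <- function(tg, y, min_prominence_fraction, tm_window) {
  n <- length(y)
  none <- matrix(numeric(0), ncol = 3L,
                 dimnames = list(NULL, c("tm", "height", "prominence")))
  if (n < 3L) return(none)
  # interior strict-left / weak-right maxima; plateau ties keep the left edge
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  # background level of the derivative: 10th percentile of -dF/dT (flat
  # inter-peak regions dominate the grid), so candidate heights track
  # dissociation amplitude, not baseline drift
  bg <- stats::quantile(y, 0.10, names = FALSE)
  # the absolute floor guards against floating-point ripple on flat or
  # baseline-only curves being read as structure
  cand <- cand[y[cand] - bg > 1e-9]
  if (!length(cand)) return(none)
  # screen on height and on topographic prominence, both relative to the
  # tallest candidate: the height floor rejects baseline noise bumps
  # (whose prominence is inflated by negative dips on either side), the
  # prominence screen rejects shoulder wiggles riding on a real peak.
  # Height is screened first so prominence walks run only for the few
  # surviving candidates.
  thr <- min_prominence_fraction * max(y[cand] - bg)
  cand <- cand[y[cand] - bg >= thr]
  prom <- vapply(cand, .prominence, y = y, numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(none)
  # parabolic vertex through the three points around each maximum
  h <- tg[2L] - tg[1L]
  y0 <- y[cand]
  ym <- y[cand - 1L]
  yp <- y[cand + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- ifelse(abs(denom) > 0, 0.5 * (ym - yp) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  tm <- tg[cand] + delta * h
  height <- y0 - 0.25 * (ym - yp) * delta - bg
  inside <- tm >= tm_window[1L] & tm <= tm_window[2L]
  ord <- order(-tm[inside])
  cbind(tm = tm[inside][ord], height = height[inside][ord],
        prominence = prom[inside][ord])
}

#' Detect melting peaks in a -dF/dT curve
#'
#' Local maxima are screened by topographic prominence relative to the
#' tallest candidate; surviving peak positions are refined below grid
#' resolution by fitting a parabola through the three points around each
#' maximum. A flat or empty curve yields an empty peak set, not an error.
#'
#' @param deriv a `derivative_curve` from [negative_derivative()].
#' @param min_prominence_fraction keep peaks whose prominence is at least
#'   this fraction of the tallest candidate's height (default 0.15).
#' @param tm_window numeric length-2: report only peaks inside this
#'   temperature interval (default `c(50, 80)`).
#' @return A `peak_set` data.frame with columns `tm`, `height`,
#'   `prominence`, sorted by descending `tm`.
#' @export
detect_peaks <- function(deriv, min_prominence_fraction = 0.15,
                         tm_window = c(50, 80)) {
  stopifnot(min_prominence_fraction > 0, min_prominence_fraction <= 1)
  m <- .find_peaks(deriv$temperature, deriv$neg_dfdt,
                   min_prominence_fraction, tm_window)
  structure(
    data.frame(tm = m[, "tm"], height = m[, "height"],
               prominence = m[, "prominence"]),
    channel = attr(deriv, "channel"),
    subject_id = attr(deriv, "subject_id"),
    class = c("peak_set", "data.frame")
  )
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (walk each side until a taller point or the
# boundary, tracking the minimum)
.prominence <- function(i, y) {
  peak <- y[i]
  left_min <- peak
  j <- i - 1L
  while (j >= 1L && y[j] <= peak) {
    if (y[j] < left_min) left_min <- y[j]
    j <- j - 1L
  }
  right_min <- peak
  j <- i + 1L
  n <- length(y)
  while (j <= n && y[j] <= peak) {
    if (y[j] < right_min) right_min <- y[j]
    j <- j + 1L
  }
  peak - max(left_min, right_min)
}
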