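#' Direction-resolved IR spectrum container
#'
#' Holds a wavenumber grid (cm^-1) and the three diagonal Cartesian
#' absorption components A_xx, A_yy, A_zz.  The normalization convention is
#' the discrete one-sided power spectral density of the dipole derivative:
#' for an unsmoothed spectrum, sum(A * dnu) over the full grid equals the
#' time-mean of the squared dipole derivative per component
#' (units (e Angstrom / fs)^2 per cm^-1).  Intensities carry no molar
#' absorption constant; spectra computed with the same convention are
#' mutually comparable to scale.
#'
#' @param nu strictly increasing wavenumber grid, cm^-1 (>= 0).
#' @param A numeric matrix with columns `xx`, `yy`, `zz`.
#' @param n_segments number of NVE segments averaged into `A`.
#' @param err optional matrix of per-component standard errors over segments.
#' @param allow_negative signed spectra (differences) skip the
#'   non-negativity check.
#' @return an object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(nu, A, n_segments = 1L, err = NULL,
                        allow_negative = FALSE) {
  nu <- as.numeric(nu)
  A <- as.matrix(A)
  if (ncol(A) != 3L) stop("A must have three components (xx, yy, zz)")
  colnames(A) <- c("xx", "yy", "zz")
  if (length(nu) != nrow(A)) stop("grid and component lengths differ")
  if (length(nu) > 1L && any(diff(nu) <= 0)) stop("nu must be strictly increasing")
  if (any(nu < 0)) stop("nu must be non-negative")
  if (!all(is.finite(A))) stop("non-finite absorption values")
  if (!allow_negative && any(A < -1e-12 * max(abs(A), 1)))
    stop("negative absorption values in a non-difference spectrum")
  if (!is.null(err)) {
    err <- as.matrix(err)
    colnames(err) <- c("xx", "yy", "zz")
    if (nrow(err) != length(nu)) stop("err length does not match grid")
  }
  structure(list(nu = nu, A = A, n_segments = as.integer(n_segments),
                 err = err),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat("ir_spectrum:", length(x$nu), "grid points,",
      sprintf("nu in [%.1f, %.1f] cm^-1", min(x$nu), max(x$nu)), "\n")
  cat("  segments averaged:", x$n_segments,
      if (!is.null(x$err)) "(with standard errors)" else "", "\n")
  bi <- apply(x$A, 2, function(a) sum(a) * mean(diff(x$nu)))
  cat(sprintf("  band integrals: xx %.4g  yy %.4g  zz %.4g\n", bi[1], bi[2], bi[3]))
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(nu = x$nu, A_xx = x$A[, 1L], A_yy = x$A[, 2L], A_zz = x$A[, 3L])
}

#' @export
plot.ir_spectrum <- function(x, main = "IR spectrum", ...) {
  graphics::matplot(x$nu, x$A, type = "l", lty = 1,
                    col = c("steelblue", "skyblue3", "firebrick"),
                    xlab = expression(paste(nu, " (", cm^-1, ")")),
                    ylab = "A (arb. units)", main = main, ...)
  graphics::legend("topright", c("xx", "yy", "zz"), lty = 1,
                   col = c("steelblue", "skyblue3", "firebrick"), bty = "n")
  invisible(x)
}

#' Spectral-estimation configuration
#'
#' @param dt sampling interval, fs.
#' @param sigma_nu Gaussian smoothing kernel width (standard deviation),
#'   cm^-1; 50 cm^-1 is the conventional visualization width for AIMD water
#'   spectra.
#' @param nu_max upper wavenumber cutoff of the output grid, cm^-1.
#' @param detrend remove the mean of the dipole derivative before the
#'   transform (suppresses the zero-frequency bin).
#' @param window taper applied to the dipole derivative (`"none"` keeps the
#'   plain periodogram, i.e. the biased autocovariance estimator).
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(dt = 0.5, sigma_nu = 50, nu_max = 4000,
                            detrend = TRUE, window = c("none", "hann")) {
  window <- match.arg(window)
  if (sigma_nu < 0) stop("sigma_nu must be >= 0")
  if (nu_max <= 0) stop("nu_max must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(dt = dt, sigma_nu = sigma_nu, nu_max = nu_max,
                 detrend = detrend, window = window),
            class = "spectral_config")
}

#' Time derivative of a dipole series
#'
#' Central differences on interior points, one-sided differences at the two
#' ends; length preserved.
#'
#' @param series a [dipole_series] of the dipole moment (e Angstrom).
#' @return a `dipole_series` of the derivative (e Angstrom / fs), with the
#'   same label and a `derivative` flag set.
#' @export
dipole_derivative <- function(series) {
  stopifnot(inherits(series, "dipole_series"))
  mu <- series$mu
  n <- nrow(mu)
  if (n < 3L) stop("need at least 3 frames to differentiate")
  dt <- series$dt
  d <- matrix(0, n, 3L)
  d[2:(n - 1L), ] <- (mu[3:n, ] - mu[1:(n - 2L), ]) / (2 * dt)
  d[1L, ] <- (mu[2L, ] - mu[1L, ]) / dt
  d[n, ] <- (mu[n, ] - mu[n - 1L, ]) / dt
  out <- series
  out$mu <- d
  out$derivative <- TRUE
  out
}

#' Direction-resolved IR spectrum from a dipole time series
#'
#' Implements the dipole-derivative autocorrelation route: per Cartesian
#' direction the one-sided Fourier cosine transform of the biased
#' autocovariance of the dipole derivative, evaluated as the periodogram of
#' the derivative (Wiener-Khinchin).  The frequency axis is mapped to
#' wavenumbers nu = f / (100 c).  The absolute scale is fixed by the
#' convention that the unsmoothed spectrum integrates (Riemann sum over the
#' untruncated grid) to the time-mean squared dipole derivative per
#' component.
#'
#' @param series a [dipole_series]; interpreted as the dipole moment mu(t)
#'   and differentiated internally unless its `derivative` flag is set.
#' @param config a [spectral_config]; smoothing is *not* applied here (see
#'   [smooth_gaussian]), only dt/grid/detrend/window are used.
#' @return an [ir_spectrum] on the grid `0 .. nu_max`.
#' @export
spectrum_from_dipole <- function(series, config = spectral_config(dt = series$dt)) {
  stopifnot(inherits(series, "dipole_series"))
  n <- nrow(series$mu)
  if (n < 16L) stop("need at least 16 samples for a spectrum")
  if (!is.null(series$times)) {
    dtimes <- diff(series$times)
    if (any(abs(dtimes - series$dt) > 1e-8 * series$dt))
      stop("non-uniform sampling times in dipole series")
  }
  dt <- config$dt
  md <- if (isTRUE(series$derivative)) series$mu else dipole_derivative(series)$mu
  if (config$detrend) md <- sweep(md, 2L, colMeans(md))
  w <- switch(config$window,
              none = rep(1, n),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  wnorm <- sqrt(mean(w^2))
  ft <- stats::mvfft(md * (w / wnorm))
  pw <- Mod(ft)^2
  nk <- floor(n / 2) + 1L               # one-sided bins k = 0 .. floor(n/2)
  dnu <- 1 / (n * dt * .c_cmfs)
  scale <- rep(2, nk)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[nk] <- 1     # Nyquist bin not doubled
  A <- pw[seq_len(nk), , drop = FALSE] * (scale / (n^2 * dnu))
  nu <- (seq_len(nk) - 1L) * dnu
  keep <- nu <= config$nu_max
  ir_spectrum(nu[keep], A[keep, , drop = FALSE])
}

#' Gaussian smoothing of a spectrum
#'
#' Convolves each component on the wavenumber grid with a normalized
#' Gaussian kernel (truncated at 6 standard deviations, reflective edge
#' handling), preserving the band integral.  `sigma_nu = 0` is the identity.
#'
#' @param spectrum an [ir_spectrum].
#' @param sigma_nu kernel standard deviation, cm^-1.
#' @return the smoothed `ir_spectrum` (errors smoothed with the same kernel).
#' @export
smooth_gaussian <- function(spectrum, sigma_nu = 50) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (sigma_nu < 0) stop("sigma_nu must be >= 0")
  if (sigma_nu == 0) return(spectrum)
  nu <- spectrum$nu
  dnu <- mean(diff(nu))
  half <- max(1L, ceiling(6 * sigma_nu / dnu))
  kern <- stats::dnorm(seq(-half, half) * dnu, sd = sigma_nu)
  kern <- kern / sum(kern)
  sm <- function(y) {
    n <- length(y)
    # whole-sample reflection pads conserve total mass under a symmetric kernel
    ypad <- c(rev(y[seq_len(min(half, n))]),
              y,
              rev(y[seq.int(n, by = -1, length.out = min(half, n))]))
    if (half > n) { # very wide kernel relative to grid: tile reflections
      ypad <- y
      while (length(ypad) < n + 2 * half) ypad <- c(rev(y), ypad, rev(y))
      mid <- (length(ypad) - n) %/% 2
      ypad <- ypad[(mid - half + 1):(mid + n + half)]
    }
    as.numeric(stats::filter(ypad, kern, sides = 2))[(half + 1):(half + n)]
  }
  out <- spectrum
  out$A <- apply(spectrum$A, 2L, sm)
  colnames(out$A) <- c("xx", "yy", "zz")
  if (!is.null(spectrum$err)) {
    out$err <- apply(spectrum$err, 2L, sm)
    colnames(out$err) <- c("xx", "yy", "zz")
  }
  out
}

#' Average spectra over NVE segments
#'
#' Componentwise mean over segment spectra on a shared grid, with the
#' per-grid-point standard error over segments as the statistical error.
#'
#' @param spectra list of [ir_spectrum] objects with identical grids.
#' @return an `ir_spectrum` with `n_segments` and (for >= 2 segments) `err` set.
#' @export
average_segments <- function(spectra) {
  if (!length(spectra)) stop("need at least one spectrum")
  stopifnot(all(vapply(spectra, inherits, logical(1), "ir_spectrum")))
  nu <- spectra[[1L]]$nu
  for (s in spectra)
    if (length(s$nu) != length(nu) || any(abs(s$nu - nu) > 1e-9 * (nu[2] %||% 1)))
      stop("segment spectra are not on a common wavenumber grid")
  m <- length(spectra)
  if (m == 1L) return(spectra[[1L]])
  acc <- Reduce(`+`, lapply(spectra, `[[`, "A")) / m
  dev2 <- Reduce(`+`, lapply(spectra, function(s) (s$A - acc)^2))
  err <- sqrt(dev2 / (m - 1L) / m)
  ir_spectrum(nu, acc, n_segments = m, err = err, allow_negative = TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Segment-pooled equivalent-direction error of the axial/radial difference
#'
#' The per-point half-difference |A_xx - A_yy|/2 of a single averaged
#' spectrum is a one-degree-of-freedom noise estimate, so thresholding on it
#' produces Cauchy-like ratios.  Pooling the x/y half-differences over
#' segments gives a stable estimate: with per-segment, per-component noise
#' variance s2 estimated from mean_s (A_xx,s - A_yy,s)^2 / 2, the variance
#' of A_zz - (A_xx + A_yy)/2 of the M-segment average is 1.5 s2 / M.
#'
#' @param spectra list of per-segment [ir_spectrum] objects (smoothed or
#'   raw, but consistently so).
#' @return per-grid-point standard error of `A_z - A_xy` of the segment
#'   average, attributable purely to statistical noise under x/y
#'   equivalence.
#' @export
equivalent_direction_error <- function(spectra) {
  stopifnot(length(spectra) >= 2L)
  M <- length(spectra)
  d2 <- Reduce(`+`, lapply(spectra, function(s) (s$A[, 1L] - s$A[, 2L])^2)) / M
  sqrt(1.5 * (d2 / 2) / M)
}

#' Radial (xy) average and equivalent-direction error
#'
#' For uniaxial clusters x and y are statistically equivalent, so their
#' half-difference estimates the statistical error of the radial average.
#'
#' @param spectrum an [ir_spectrum].
#' @return list with `nu`, `A_z`, `A_xy = (A_xx + A_yy)/2`, and
#'   `anisotropy_error = |A_xx - A_yy|/2` per grid point.
#' @export
radial_average <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  list(nu = spectrum$nu,
       A_z = spectrum$A[, 3L],
       A_xy = (spectrum$A[, 1L] + spectrum$A[, 2L]) / 2,
       anisotropy_error = abs(spectrum$A[, 1L] - spectrum$A[, 2L]) / 2)
}

#' Protonated-minus-unprotonated difference spectrum
#'
#' @param protonated,unprotonated [ir_spectrum] objects on the same grid.
#' @return a signed `ir_spectrum`; segment errors are combined in quadrature
#'   when both inputs carry them.
#' @export
difference_spectrum <- function(protonated, unprotonated) {
  stopifnot(inherits(protonated, "ir_spectrum"),
            inherits(unprotonated, "ir_spectrum"))
  if (length(protonated$nu) != length(unprotonated$nu) ||
      any(abs(protonated$nu - unprotonated$nu) >
          1e-9 * max(protonated$nu, 1)))
    stop("difference spectrum requires a common wavenumber grid")
  err <- NULL
  if (!is.null(protonated$err) && !is.null(unprotonated$err))
    err <- sqrt(protonated$err^2 + unprotonated$err^2)
  ir_spectrum(protonated$nu, protonated$A - unprotonated$A,
              n_segments = min(protonated$n_segments, unprotonated$n_segments),
              err = err, allow_negative = TRUE)
}

#' Band-integrated axial/radial anisotropy ratio
#'
#' Trapezoidal integrals of A_zz and A_xy = (A_xx + A_yy)/2 over
#' `[nu_lo, nu_hi]`; the continuum-band window conventionally used for
#' bR-like systems is 1800--2200 cm^-1.
#'
#' @param spectrum an [ir_spectrum].
#' @param nu_lo,nu_hi band limits, cm^-1.
#' @return list with `ratio` (Inf when the radial integral vanishes while the
#'   axial one does not), `I_z`, `I_xy`, and `infinite` flag.
#' @export
band_anisotropy <- function(spectrum, nu_lo = 1800, nu_hi = 2200) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (nu_lo >= nu_hi) stop("nu_lo must be below nu_hi")
  sel <- spectrum$nu >= nu_lo & spectrum$nu <= nu_hi
  if (sum(sel) < 2L) stop("band [", nu_lo, ", ", nu_hi, "] contains fewer ",
                          "than two grid points")
  trapz <- function(x, y) {
    n <- length(x)
    sum(diff(x) * (y[-n] + y[-1L]) / 2)
  }
  nu <- spectrum$nu[sel]
  I_z <- trapz(nu, spectrum$A[sel, 3L])
  I_xy <- trapz(nu, (spectrum$A[sel, 1L] + spectrum$A[sel, 2L]) / 2)
  inf <- I_xy == 0 && I_z > 0
  list(ratio = if (inf) Inf else I_z / I_xy, I_z = I_z, I_xy = I_xy,
       infinite = inf)
}
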