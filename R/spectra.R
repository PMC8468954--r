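#' Velocity autocorrelation function
#'
#' Normalized velocity autocorrelation
#' \eqn{C(k) = \langle v(t)\cdot v(t+k\,dt)\rangle / \langle |v|^2 \rangle},
#' averaged over all time origins and over the Cartesian components of
#' the selected atoms.  The sum over origins is evaluated with FFTs, so
#' long trajectories are cheap.
#'
#' @param traj A [trajectory()] carrying velocities (see
#'   [derive_velocities()] when only positions are stored), or a plain
#'   numeric matrix \code{frames x components} of velocity components.
#' @param atoms Atom indices to include (ignored for matrix input).
#'   For spectra of the bridge protons, select the proton atoms only.
#' @param max_lag Largest lag in frames; defaults to
#'   \code{min(2048, floor(n/2))}.
#' @param dt Frame spacing in fs (taken from the trajectory when given).
#' @return An object of class \code{"vacf"}: \code{lag} (fs), \code{C}
#'   (dimensionless, \code{C[1] = C(0) = 1}), \code{dt}, \code{n_frames}.
#' @export
velocity_autocorrelation <- function(traj, atoms = NULL, max_lag = NULL,
                                     dt = NULL) {
  if (inherits(traj, "trajectory")) {
    if (is.null(traj$velocities))
      stop("trajectory has no velocities; use derive_velocities() first")
    if (is.null(atoms)) atoms <- seq_along(traj$labels)
    v <- traj$velocities[, atoms, , drop = FALSE]
    n <- dim(v)[1]
    V <- matrix(v, nrow = n)
    dt <- traj$dt
  } else {
    V <- as.matrix(traj)
    n <- nrow(V)
    if (is.null(dt)) stop("'dt' is required for matrix input")
  }
  if (is.null(max_lag)) max_lag <- min(2048L, n %/% 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("'max_lag' must be in [1, n_frames - 1]")
  # FFT-based raw autocovariance, summed over components
  npad <- stats::nextn(2L * n, 2)
  acf_raw <- numeric(max_lag + 1L)
  for (j in seq_len(ncol(V))) {
    f <- fft(c(V[, j], numeric(npad - n)))
    s <- Re(fft(f * Conj(f), inverse = TRUE)) / npad
    acf_raw <- acf_raw + s[seq_len(max_lag + 1L)]
  }
  acf_raw <- acf_raw / (n - 0:max_lag)   # unbiased origin average
  if (acf_raw[1] <= 0)
    stop("zero-variance velocities: normalization undefined")
  structure(list(lag = (0:max_lag) * dt, C = acf_raw / acf_raw[1],
                 dt = dt, n_frames = n),
            class = "vacf")
}

#' @export
plot.vacf <- function(x, ...) {
  plot(x$lag, x$C, type = "l", xlab = "lag (fs)", ylab = "C(t)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

.spectral_windows <- list(
  hann = function(k, L) 0.5 * (1 + cos(pi * k / L)),
  hamming = function(k, L) 0.54 + 0.46 * cos(pi * k / L),
  blackman = function(k, L) 0.42 + 0.5 * cos(pi * k / L) +
    0.08 * cos(2 * pi * k / L),
  rectangular = function(k, L) rep(1, length(k))
)

#' Power spectrum of a velocity autocorrelation function
#'
#' One-sided cosine transform of the (real, time-even) VACF after
#' application of a lag window.  This is the classical vibrational power
#' spectrum; the wavenumber axis is
#' \eqn{\tilde\nu_j = j / (c\,L\,dt)} and the resolution one bin,
#' \eqn{1/(c\,L\,dt)}.  Tiny negative leakage values are clipped to zero
#' and counted in attribute \code{n_clipped}.
#'
#' @param vacf A [velocity_autocorrelation()] result.
#' @param window Lag window name: \code{"hann"} (default),
#'   \code{"hamming"}, \code{"blackman"} or \code{"rectangular"}.
#' @return An object of class \code{"spectrum"}: \code{wavenumber}
#'   (cm^-1, up to the Nyquist limit), \code{intensity} (arbitrary
#'   units, >= 0), \code{resolution} (cm^-1), plus the window name and
#'   lag count as metadata.
#' @export
power_spectrum <- function(vacf, window = "hann") {
  stopifnot(inherits(vacf, "vacf"))
  if (!window %in% names(.spectral_windows))
    stop("unknown window '", window, "'; available: ",
         paste(names(.spectral_windows), collapse = ", "))
  C <- vacf$C
  L <- length(C)
  if (L == 0L) stop("empty VACF")
  k <- 0:(L - 1L)
  w <- .spectral_windows[[window]](k, L)
  wc <- w * C
  n_half <- L %/% 2L
  j <- 0:n_half
  # S_j = w0*C0 + 2 * sum_{k>=1} w_k C_k cos(2 pi j k / L)
  #     = 2 * Re(DFT(wc))_j - w0*C0
  S <- (2 * Re(fft(wc)) - wc[1])[j + 1L]
  n_clipped <- sum(S < 0)
  S[S < 0] <- 0
  res <- 1 / (.C_CM_FS * L * vacf$dt)
  structure(list(wavenumber = j * res, intensity = S, resolution = res,
                 window = window, n_lags = L, dt = vacf$dt),
            class = "spectrum", n_clipped = n_clipped)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot(x$wavenumber, x$intensity, type = "l",
       xlab = expression(tilde(nu) ~ (cm^-1)), ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Extract contiguous absorption-band regions from a spectrum
#'
#' Reports the maximal contiguous wavenumber runs whose intensity
#' reaches \code{rel_threshold} times the spectrum maximum; runs
#' separated by sub-threshold gaps no wider than \code{merge_gap} are
#' merged.  Useful for quoting broad band extents such as an O-H stretch
#' region.
#'
#' @param spec A [power_spectrum()] result.
#' @param rel_threshold Relative intensity threshold, in (0, 1).
#' @param merge_gap Maximum gap to bridge, cm^-1.
#' @return Data frame with columns \code{lo} and \code{hi} (cm^-1),
#'   sorted ascending; zero rows for an all-zero spectrum.
#' @export
band_regions <- function(spec, rel_threshold = 0.05, merge_gap = 50) {
  stopifnot(inherits(spec, "spectrum"))
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("'rel_threshold' must be strictly between 0 and 1")
  empty <- data.frame(lo = numeric(0), hi = numeric(0))
  mx <- max(spec$intensity)
  if (mx == 0) return(empty)
  mask <- spec$intensity >= rel_threshold * mx
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- which(runs$values)
  if (length(on) == 0L) return(empty)
  lo <- spec$wavenumber[starts[on]]
  hi <- spec$wavenumber[ends[on]]
  # merge across small gaps
  i <- 1L
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(on) > 1L) {
    for (r in 2:length(on)) {
      if (lo[r] - out_hi[length(out_hi)] <= merge_gap) {
        out_hi[length(out_hi)] <- hi[r]
      } else {
        out_lo <- c(out_lo, lo[r]); out_hi <- c(out_hi, hi[r])
      }
    }
  }
  data.frame(lo = out_lo, hi = out_hi)
}
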