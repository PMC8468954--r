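#' Hydrogen-bridge distance time series
#'
#' Per-frame Euclidean distances of one O-H...O bridge: donor-acceptor
#' (\code{d_OO}), donor-proton (\code{d_DH}) and proton-acceptor
#' (\code{d_HA}).
#'
#' @param traj A [trajectory()].
#' @param bridge A [bridge_definition()].
#' @return A data frame of class \code{"bridge_series"} with columns
#'   \code{time} (fs), \code{d_OO}, \code{d_DH}, \code{d_HA} (Angstrom).
#' @export
compute_bridge_series <- function(traj, bridge) {
  at <- bridge_atoms(traj, bridge)
  dist <- function(a, b) sqrt(rowSums((a - b)^2))
  out <- data.frame(time = frame_times(traj),
                    d_OO = dist(at$donor, at$acceptor),
                    d_DH = dist(at$donor, at$proton),
                    d_HA = dist(at$proton, at$acceptor))
  attr(out, "label") <- bridge$label
  class(out) <- c("bridge_series", "data.frame")
  out
}

#' @export
plot.bridge_series <- function(x, ...) {
  matplot(x$time / 1000, cbind(x$d_OO, x$d_DH, x$d_HA), type = "l",
          lty = 1, col = c("black", "red", "darkgreen"),
          xlab = "time (ps)", ylab = "distance (Å)", ...)
  legend("topright", c("O...O", "O-H (donor)", "H...O (acceptor)"),
         lty = 1, col = c("black", "red", "darkgreen"), bty = "n")
  invisible(x)
}

#' Voronoi proton-possession statistics
#'
#' Fraction of frames the bridge proton spends at the donor or acceptor
#' site, assigned by the Voronoi geometric criterion (comparison of the
#' donor-proton and proton-acceptor distances).  Exact ties are counted
#' as donor frames and reported separately; the two percentages sum to
#' 100 exactly.
#'
#' @param series A [compute_bridge_series()] result.
#' @return List of class \code{"possession_stats"}: \code{donor_fraction}
#'   and \code{acceptor_fraction} (percent), frame counts
#'   \code{n_donor}, \code{n_acceptor}, \code{n_tie}, \code{n_frames}.
#' @export
possession_statistics <- function(series) {
  stopifnot(inherits(series, "bridge_series"))
  n <- nrow(series)
  if (n == 0L) stop("empty bridge series")
  acceptor <- series$d_DH > series$d_HA
  tie <- series$d_DH == series$d_HA
  n_acc <- sum(acceptor)
  donor_fraction <- 100 * (n - n_acc) / n
  out <- list(donor_fraction = donor_fraction,
              acceptor_fraction = 100 - donor_fraction,
              n_donor = n - n_acc, n_acceptor = n_acc,
              n_tie = sum(tie), n_frames = n)
  class(out) <- "possession_stats"
  out
}

#' @export
print.possession_stats <- function(x, ...) {
  cat(sprintf("Proton possession (Voronoi criterion, %d frames):\n", x$n_frames))
  cat(sprintf("  donor    %5.1f%%  (%d frames)\n", x$donor_fraction, x$n_donor))
  cat(sprintf("  acceptor %5.1f%%  (%d frames)\n", x$acceptor_fraction,
              x$n_acceptor))
  if (x$n_tie > 0)
    cat(sprintf("  (%d exact ties counted as donor)\n", x$n_tie))
  invisible(x)
}

#' Detect proton-transfer events
#'
#' A transfer event is a sign change of the Voronoi coordinate
#' \eqn{s(t) = d_{DH} - d_{HA}} whose new sign persists for at least
#' \code{min_dwell}; shorter recrossings of the barrier top are
#' discarded.  Ties (\eqn{s = 0}) count as donor side.  The dwell filter
#' is this package's operationalization of a "proton-sharing event";
#' raw sign changes overcount barrier recrossings.
#'
#' @param series A [compute_bridge_series()] result.
#' @param min_dwell Minimum persistence of the new possession state, fs.
#' @return Data frame with one row per event: \code{onset_time} (fs),
#'   \code{direction} (\code{"donor_to_acceptor"} or
#'   \code{"acceptor_to_donor"}), \code{dwell} (fs, time until the next
#'   event or the end of the series).  Directions alternate.
#' @export
detect_transfer_events <- function(series, min_dwell = 10) {
  stopifnot(inherits(series, "bridge_series"), min_dwell >= 0)
  n <- nrow(series)
  if (n == 0L) stop("empty bridge series")
  dt <- if (n > 1L) series$time[2] - series$time[1] else 0
  state <- ifelse(series$d_DH > series$d_HA, 1L, -1L)
  runs <- rle(state)
  len <- runs$lengths
  starts <- cumsum(c(1L, len[-length(len)]))
  confirmed <- which(len * dt >= min_dwell)
  empty <- data.frame(onset_time = numeric(0), direction = character(0),
                      dwell = numeric(0))
  if (length(confirmed) == 0L) return(empty)
  vals <- runs$values[confirmed]
  keep <- c(TRUE, vals[-1L] != vals[-length(vals)])
  vals <- vals[keep]
  onset_idx <- starts[confirmed][keep]
  if (length(vals) < 2L) return(empty)
  onset <- series$time[onset_idx][-1L]
  direction <- ifelse(vals[-1L] == 1L, "donor_to_acceptor", "acceptor_to_donor")
  dwell <- c(diff(onset), series$time[n] - onset[length(onset)])
  data.frame(onset_time = onset, direction = direction, dwell = dwell)
}

#' Joint donor-proton distance histogram of the two bridges
#'
#' Two-dimensional probability density of the donor-proton distances of
#' two bridges, normalized so that the density integrates to one
#' (units 1/Angstrom^2).  Samples outside the range accumulate in the
#' edge bins and their number is reported in attribute
#' \code{n_clamped} (with a message).
#'
#' @param series1,series2 [compute_bridge_series()] results of equal
#'   length.
#' @param bin_width Bin width, Angstrom.
#' @param range Common axis range, Angstrom.
#' @return An object of class \code{"density2d"}: \code{x_edges},
#'   \code{y_edges} and the \code{density} matrix (bridge 1 on rows).
#' @export
joint_histogram <- function(series1, series2, bin_width = 0.02,
                            range = c(0.8, 1.8)) {
  stopifnot(inherits(series1, "bridge_series"),
            inherits(series2, "bridge_series"))
  if (nrow(series1) != nrow(series2))
    stop("bridge series lengths differ")
  if (bin_width <= 0) stop("'bin_width' must be positive")
  edges <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  clamp <- function(x) pmin(pmax(x, 1L), nb)
  ix <- findInterval(series1$d_DH, edges, rightmost.closed = TRUE)
  iy <- findInterval(series2$d_DH, edges, rightmost.closed = TRUE)
  n_clamped <- sum(ix < 1L | ix > nb | iy < 1L | iy > nb)
  ix <- clamp(ix); iy <- clamp(iy)
  counts <- matrix(0, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)),
               factor(iy, levels = seq_len(nb)))
  counts[] <- as.numeric(tab)
  n <- nrow(series1)
  dens <- counts / (n * bin_width^2)
  if (n_clamped > 0)
    message(n_clamped, " out-of-range samples accumulated in edge bins")
  structure(list(x_edges = edges, y_edges = edges, density = dens,
                 bin_width = bin_width),
            class = "density2d", n_clamped = n_clamped)
}

#' @export
plot.density2d <- function(x, ...) {
  xm <- (x$x_edges[-1L] + x$x_edges[-length(x$x_edges)]) / 2
  ym <- (x$y_edges[-1L] + x$y_edges[-length(x$y_edges)]) / 2
  image(xm, ym, x$density, xlab = "d(O-H) bridge 1 (Å)",
        ylab = "d(O-H) bridge 2 (Å)", ...)
  invisible(x)
}

#' Double proton-transfer synchronicity summary
#'
#' Classifies every frame into the four possession quadrants of the two
#' bridges (DD, DA, AD, AA, by the Voronoi sign of each bridge; first
#' letter is bridge 1, D = donor) and additionally reports the occupancy
#' of the central region where both protons sit within \code{eps} of the
#' bridge midpoint criterion \eqn{|d_{DH} - d_{HA}| < \epsilon} --- a
#' populated center would indicate synchronous double transfer.
#'
#' @param series1,series2 [compute_bridge_series()] results of equal
#'   length.
#' @param eps Half-width of the central region, Angstrom.
#' @return List of class \code{"synchronicity_summary"} with percentage
#'   occupancies \code{DD}, \code{DA}, \code{AD}, \code{AA} (summing to
#'   100) and \code{center}.
#' @export
synchronicity_summary <- function(series1, series2, eps = 0.05) {
  stopifnot(inherits(series1, "bridge_series"),
            inherits(series2, "bridge_series"), eps > 0)
  if (nrow(series1) != nrow(series2))
    stop("bridge series lengths differ")
  q1 <- series1$d_DH - series1$d_HA
  q2 <- series2$d_DH - series2$d_HA
  d1 <- q1 <= 0; d2 <- q2 <= 0
  n <- length(q1)
  out <- list(DD = 100 * sum(d1 & d2) / n,
              DA = 100 * sum(d1 & !d2) / n,
              AD = 100 * sum(!d1 & d2) / n,
              AA = 100 * sum(!d1 & !d2) / n,
              center = 100 * sum(abs(q1) < eps & abs(q2) < eps) / n,
              eps = eps, n_frames = n)
  class(out) <- "synchronicity_summary"
  out
}

#' @export
print.synchronicity_summary <- function(x, ...) {
  cat(sprintf("Quadrant occupancies over %d frames (bridge1/bridge2):\n",
              x$n_frames))
  cat(sprintf("  DD %5.1f%%   DA %5.1f%%\n  AD %5.1f%%   AA %5.1f%%\n",
              x$DD, x$DA, x$AD, x$AA))
  cat(sprintf("  center (both |d_DH - d_HA| < %g A): %.2f%%\n",
              x$eps, x$center))
  invisible(x)
}
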