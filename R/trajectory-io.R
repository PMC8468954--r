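#' Molecular trajectory container
#'
#' Holds an ordered sequence of frames of labelled atomic positions, with
#' optional matching velocities and a uniform inter-frame spacing.
#'
#' @param labels Character vector of element symbols, one per atom.
#' @param xyz Numeric array \code{frames x atoms x 3}, Angstrom.
#' @param dt Inter-frame spacing, fs (supplied by the producer; it is not
#'   parsed from file comments).
#' @param t0 Time stamp of the first frame, fs.
#' @param velocities Optional array with the same dimensions as
#'   \code{xyz}, A/fs.
#' @return An object of class \code{"trajectory"}.
#' @export
trajectory <- function(labels, xyz, dt, t0 = 0, velocities = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("'xyz' must be a frames x atoms x 3 array")
  if (dim(xyz)[2] != length(labels))
    stop("number of labels does not match atom count")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.null(velocities) && !identical(dim(velocities), dim(xyz)))
    stop("'velocities' dimensions must match 'xyz'")
  structure(list(labels = as.character(labels), xyz = xyz,
                 velocities = velocities, dt = dt, t0 = t0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$xyz)
  cat(sprintf("Trajectory: %d frames x %d atoms (%s), dt = %g fs%s\n",
              d[1], d[2], paste(x$labels, collapse = " "), x$dt,
              if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Frame time stamps
#' @param traj A [trajectory()].
#' @return Numeric vector of times in fs.
#' @export
frame_times <- function(traj) traj$t0 + (seq_len(n_frames(traj)) - 1) * traj$dt

# parse one XYZ-format file into list(labels, xyz, times)
.parse_xyz <- function(path) {
  lines <- readLines(path)
  n_lines <- length(lines)
  pos <- 1L
  frames <- list()
  times <- numeric()
  labels0 <- NULL
  f <- 0L
  while (pos <= n_lines) {
    if (!nzchar(trimws(lines[pos])) && pos == n_lines) break
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0)
      stop(sprintf("parse error at line %d: expected an atom count, got '%s'",
                   pos, lines[pos]))
    if (pos + 1L + nat > n_lines)
      stop(sprintf("truncated frame %d: expected %d atom lines", f + 1L, nat))
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexpr("t=\\s*[-+0-9.eE]+", comment))
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad))
      stop(sprintf("parse error at line %d: fewer than 4 fields",
                   pos + 1L + bad[1]))
    lab <- vapply(toks, `[[`, "", 1L)
    co <- vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3))
    nonnum <- which(colSums(is.na(co)) > 0)
    if (length(nonnum))
      stop(sprintf("parse error at line %d: non-numeric coordinate",
                   pos + 1L + nonnum[1]))
    f <- f + 1L
    if (is.null(labels0)) {
      labels0 <- lab
    } else {
      if (nat != length(labels0))
        stop(sprintf("inconsistent atom count in frame %d: %d (expected %d)",
                     f, nat, length(labels0)))
      if (!identical(lab, labels0))
        stop(sprintf("atom labels in frame %d do not match the first frame", f))
    }
    frames[[f]] <- t(co)
    times[f] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    pos <- pos + 2L + nat
    while (pos <= n_lines && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (f == 0L) stop("file contains no frames: ", path)
  xyz <- array(0, dim = c(f, length(labels0), 3L))
  for (i in seq_len(f)) xyz[i, , ] <- frames[[i]]
  list(labels = labels0, xyz = xyz, times = times)
}

#' Read an XYZ-format trajectory
#'
#' Reads a standard (multi-frame) XYZ file.  Frames appear in file order;
#' atom labels are taken from the first frame and later frames must
#' match.  If the comment lines carry \code{t=} time stamps, their
#' spacing is checked against \code{dt} and a warning is issued on
#' mismatch (the supplied \code{dt} always wins).
#'
#' @param path XYZ file path.
#' @param dt Inter-frame spacing, fs.
#' @param velocity_path Optional companion file in identical XYZ layout
#'   whose "coordinates" are velocities in A/fs.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, dt, velocity_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- .parse_xyz(path)
  if (sum(!is.na(px$times)) >= 2) {
    steps <- diff(px$times[!is.na(px$times)])
    if (any(abs(steps - dt) > 1e-6 * max(1, dt)))
      warning(sprintf("comment-line time spacing (%.6g fs) differs from dt = %g fs",
                      steps[1], dt))
  }
  t0 <- if (!is.na(px$times[1])) px$times[1] else 0
  vel <- NULL
  if (!is.null(velocity_path)) {
    pv <- .parse_xyz(velocity_path)
    if (!identical(dim(pv$xyz), dim(px$xyz)))
      stop("velocity file frame/atom layout does not match the position file")
    vel <- pv$xyz
  }
  trajectory(px$labels, px$xyz, dt = dt, t0 = t0, velocities = vel)
}

#' Write an XYZ-format trajectory
#'
#' Writes standard XYZ records (atom-count line, comment line carrying
#' \code{t= <fs>}, one \code{label x y z} line per atom) with nine
#' decimal digits per coordinate.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param what Write atomic \code{"positions"} (default) or
#'   \code{"velocities"} in the same layout.
#' @export
write_xyz_trajectory <- function(traj, path, what = c("positions", "velocities")) {
  stopifnot(inherits(traj, "trajectory"))
  what <- match.arg(what)
  dat <- if (what == "positions") traj$xyz else traj$velocities
  if (is.null(dat)) stop("trajectory has no velocities to write")
  nf <- dim(dat)[1]; na <- dim(dat)[2]
  if (nf == 0L) stop("refusing to write a trajectory with zero frames")
  times <- frame_times(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nf)) {
    cat(na, "\n", file = con, sep = "")
    cat(sprintf("t= %.6f\n", times[i]), file = con)
    cat(sprintf("%-3s %17.9f %17.9f %17.9f\n", traj$labels,
                dat[i, , 1], dat[i, , 2], dat[i, , 3]),
        file = con, sep = "")
  }
  invisible(path)
}

#' Finite-difference velocities from positions
#'
#' Fills in velocities by central differences
#' \eqn{v(t_i) = (x(t_{i+1}) - x(t_{i-1})) / (2\,dt)} at interior frames
#' and one-sided differences at both ends, keeping the series length
#' aligned with the frame count (the end-frame bias of the one-sided
#' stencil is accepted).
#'
#' @param traj A [trajectory()] with at least 3 frames.
#' @return The trajectory with a \code{velocities} array in A/fs.
#' @export
derive_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 3L) stop("need at least 3 frames to derive velocities")
  x <- traj$xyz
  v <- array(0, dim = dim(x))
  v[2:(nf - 1), , ] <- (x[3:nf, , , drop = FALSE] -
                          x[1:(nf - 2), , , drop = FALSE]) / (2 * traj$dt)
  v[1, , ] <- (x[2, , ] - x[1, , ]) / traj$dt
  v[nf, , ] <- (x[nf, , ] - x[nf - 1, , ]) / traj$dt
  traj$velocities <- v
  traj
}

#' Define a donor / proton / acceptor atom selection
#'
#' @param donor_index,proton_index,acceptor_index Atom indices (1-based,
#'   as everywhere in R).  Reports may additionally carry the chemical
#'   atom names through \code{label}.
#' @param label Free-text label, e.g. \code{"O8-HBP1...O1"}.
#' @return An object of class \code{"bridge_definition"}.
#' @export
bridge_definition <- function(donor_index, proton_index, acceptor_index,
                              label = "") {
  idx <- c(donor_index, proton_index, acceptor_index)
  if (any(idx != round(idx)) || any(idx < 1))
    stop("atom indices must be positive integers")
  if (anyDuplicated(idx))
    stop("donor, proton and acceptor indices must be distinct")
  structure(list(donor = as.integer(donor_index),
                 proton = as.integer(proton_index),
                 acceptor = as.integer(acceptor_index),
                 label = label),
            class = "bridge_definition")
}

#' Extract per-frame donor, proton and acceptor coordinates
#'
#' @param traj A [trajectory()].
#' @param bridge A [bridge_definition()].
#' @return List of three \code{frames x 3} matrices: \code{donor},
#'   \code{proton}, \code{acceptor}.
#' @export
bridge_atoms <- function(traj, bridge) {
  stopifnot(inherits(traj, "trajectory"), inherits(bridge, "bridge_definition"))
  na <- dim(traj$xyz)[2]
  for (role in c("donor", "proton", "acceptor"))
    if (bridge[[role]] > na)
      stop(sprintf("%s index %d out of range (trajectory has %d atoms)",
                   role, bridge[[role]], na))
  sel <- function(i) {
    m <- traj$xyz[, i, , drop = FALSE]
    dim(m) <- c(dim(m)[1], 3L)
    m
  }
  list(donor = sel(bridge$donor), proton = sel(bridge$proton),
       acceptor = sel(bridge$acceptor))
}
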