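#' Generate scan positions at fixed increment
#'
#' Arithmetic sequence of O-H distances for a proton-potential scan.
#' The customary increment for such scans is 0.05 Angstrom.
#'
#' @param start First O-H distance, Angstrom.
#' @param count Number of positions (>= 1).
#' @param increment Step, Angstrom (> 0).
#' @return Numeric vector of distances.
#' @export
scan_positions <- function(start, count, increment = 0.05) {
  if (count < 1) stop("'count' must be at least 1")
  if (increment <= 0) stop("'increment' must be positive")
  start + (seq_len(count) - 1) * increment
}

#' Energy backends for proton-potential evaluation
#'
#' A backend maps proton positions (O-H distances) to energies in
#' kcal/mol.  Two implementations are provided: the builtin surrogate
#' model potential, and a CSV table of externally computed energies
#' (e.g. ab initio single points) in the dialect
#' \code{"distance_A,energy_kcal_mol"}.
#'
#' @param params A [model_params()] object.
#' @param R_fixed Donor-acceptor distance at which the model profile is
#'   taken; may be left \code{NULL} and supplied per call (as the NQE
#'   pipeline does, where each snapshot has its own bridge length).
#' @return An object inheriting from class \code{"energy_backend"}.
#' @rdname energy_backend
#' @export
model_energy_backend <- function(params, R_fixed = NULL) {
  stopifnot(inherits(params, "model_params"))
  structure(list(params = params, R_fixed = R_fixed, tag = "model"),
            class = c("model_energy_backend", "energy_backend"))
}

#' @param path CSV file with header \code{distance_A,energy_kcal_mol}.
#'   Rows are sorted by distance on read (with a warning if the file was
#'   unsorted).
#' @rdname energy_backend
#' @export
csv_energy_backend <- function(path) {
  tab <- read.csv(path)
  if (!all(c("distance_A", "energy_kcal_mol") %in% names(tab)))
    stop("CSV must have columns 'distance_A' and 'energy_kcal_mol'")
  if (is.unsorted(tab$distance_A, strictly = TRUE)) {
    warning("CSV distances were not sorted; sorting on read")
    tab <- tab[order(tab$distance_A), ]
  }
  if (any(!is.finite(tab$energy_kcal_mol)))
    stop("CSV contains non-finite energies")
  structure(list(table = tab, tag = paste0("csv:", basename(path))),
            class = c("csv_energy_backend", "energy_backend"))
}

#' Evaluate a backend at given distances
#'
#' @param backend An \code{"energy_backend"}.
#' @param distances O-H distances, Angstrom.
#' @param R Donor-acceptor distance for the model backend when it was
#'   constructed without a fixed one.
#' @return Energies, kcal/mol (one finite value per input point).
#' @export
backend_energies <- function(backend, distances, R = NULL) {
  UseMethod("backend_energies")
}

#' @export
backend_energies.model_energy_backend <- function(backend, distances, R = NULL) {
  Ruse <- if (!is.null(R)) R else backend$R_fixed
  if (is.null(Ruse))
    stop("model backend needs a donor-acceptor distance ('R_fixed' or 'R')")
  evaluate_model_potential(backend$params, distances, Ruse)
}

#' @export
backend_energies.csv_energy_backend <- function(backend, distances, R = NULL) {
  idx <- match(round(distances, 6), round(backend$table$distance_A, 6))
  if (anyNA(idx)) {
    miss <- distances[is.na(idx)]
    stop("backend failure: no tabulated energy at distance(s) ",
         paste(format(miss), collapse = ", "))
  }
  backend$table$energy_kcal_mol[idx]
}

#' Build a discrete proton-potential profile
#'
#' Evaluates a backend on a uniformly spaced distance grid and shifts
#' the energies so the minimum is zero (the original offset is kept in
#' attribute \code{offset}).
#'
#' @param backend An \code{"energy_backend"}.
#' @param distances Strictly increasing, uniformly spaced O-H distances
#'   (Angstrom), at least 3; see [scan_positions()].
#' @param R Optional donor-acceptor distance passed through to the
#'   backend.
#' @return A data frame of class \code{"potential_profile"} with columns
#'   \code{distance} and \code{energy}, attributes \code{increment},
#'   \code{offset} and \code{backend}.
#' @export
evaluate_profile <- function(backend, distances, R = NULL) {
  if (length(distances) < 3L) stop("a profile needs at least 3 points")
  steps <- diff(distances)
  if (any(steps <= 0)) stop("'distances' must be strictly increasing")
  if (max(steps) - min(steps) > 1e-9)
    stop("'distances' must be uniformly spaced (to 1e-9 A)")
  E <- backend_energies(backend, distances, R = R)
  if (any(!is.finite(E)))
    stop("backend failure: non-finite energy at distance(s) ",
         paste(format(distances[!is.finite(E)]), collapse = ", "))
  offset <- min(E)
  out <- data.frame(distance = distances, energy = E - offset)
  attr(out, "increment") <- mean(steps)
  attr(out, "offset") <- offset
  attr(out, "backend") <- if (is.list(backend)) backend$tag else "function"
  class(out) <- c("potential_profile", "data.frame")
  out
}

#' Read / write profile CSV files
#'
#' The on-disk dialect is \code{distance_A,energy_kcal_mol}, the same
#' exchange format accepted by [csv_energy_backend()].
#'
#' @param profile A \code{"potential_profile"}.
#' @param path File path.
#' @rdname profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "potential_profile"))
  write.csv(data.frame(distance_A = profile$distance,
                       energy_kcal_mol = profile$energy),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname profile_csv
#' @export
read_profile_csv <- function(path) {
  be <- csv_energy_backend(path)
  evaluate_profile(be, be$table$distance_A)
}

#' Two-minimum and barrier analysis of a discrete proton profile
#'
#' Locates the deep (global) minimum, the lowest secondary local
#' minimum, and the intervening discrete maximum of a scanned proton
#' potential.  The barrier is reported from the discrete points only ---
#' no interpolation --- together with a discretization uncertainty equal
#' to half the largest energy step between the discrete maximum and its
#' two neighbours; this mirrors how barrier accuracy is limited by the
#' energy steps near the transition state in scan-based protocols.  An
#' optional parabolic refinement of the three points around the top is
#' also reported (clearly labelled, and never used for the primary
#' value).
#'
#' @param profile A [evaluate_profile()] result (>= 5 points), or any
#'   data frame with \code{distance} and \code{energy} columns.
#' @param refine Also report a three-point parabolic estimate of the
#'   barrier top.
#' @return List of class \code{"profile_analysis"}: \code{r_deep},
#'   \code{E_deep}, \code{r_shallow}, \code{E_shallow}, \code{r_max},
#'   \code{barrier}, \code{uncertainty}, \code{asymmetry},
#'   \code{single_minimum} flag, \code{relative_energy} curve and
#'   (optionally) \code{barrier_refined}.  Energies are relative to the
#'   deep minimum, kcal/mol.
#' @export
analyze_profile <- function(profile, refine = FALSE) {
  d <- profile$distance
  E <- profile$energy
  n <- length(E)
  if (n < 5L) stop("need at least 5 points to analyze a profile")
  E <- E - min(E)
  i_deep <- which.min(E)
  # interior local minima
  is_min <- c(FALSE, E[2:(n - 1)] < E[1:(n - 2)] & E[2:(n - 1)] <= E[3:n],
              FALSE)
  cand <- setdiff(which(is_min), i_deep)
  single <- function() {
    structure(list(r_deep = d[i_deep], E_deep = 0,
                   r_shallow = NA_real_, E_shallow = NA_real_,
                   r_max = NA_real_, barrier = NA_real_,
                   uncertainty = NA_real_, asymmetry = NA_real_,
                   single_minimum = TRUE, relative_energy = E),
              class = "profile_analysis")
  }
  if (length(cand) == 0L) return(single())
  i_shallow <- cand[which.min(E[cand])]
  span <- if (i_shallow > i_deep) (i_deep:i_shallow) else (i_shallow:i_deep)
  i_max <- span[which.max(E[span])]
  if (i_max == i_deep || i_max == i_shallow) return(single())
  barrier <- E[i_max]
  unc <- max(abs(E[i_max] - E[i_max - 1L]), abs(E[i_max] - E[i_max + 1L])) / 2
  out <- list(r_deep = d[i_deep], E_deep = 0,
              r_shallow = d[i_shallow], E_shallow = E[i_shallow],
              r_max = d[i_max], barrier = barrier, uncertainty = unc,
              asymmetry = E[i_shallow],
              single_minimum = FALSE, relative_energy = E)
  if (refine) {
    i3 <- (i_max - 1L):(i_max + 1L)
    fit <- stats::lm.fit(cbind(1, d[i3], d[i3]^2), E[i3])
    cf <- fit$coefficients
    out$barrier_refined <- if (cf[3] < 0) {
      r_top <- -cf[2] / (2 * cf[3])
      cf[1] + cf[2] * r_top + cf[3] * r_top^2
    } else barrier
  }
  class(out) <- "profile_analysis"
  out
}

#' @export
print.profile_analysis <- function(x, ...) {
  if (x$single_minimum) {
    cat(sprintf("Single-minimum profile; minimum at %.4f A\n", x$r_deep))
  } else {
    cat(sprintf("Deep minimum at %.3f A; shallow minimum at %.3f A (asymmetry %.3f kcal/mol)\n",
                x$r_deep, x$r_shallow, x$asymmetry))
    cat(sprintf("Barrier: (%.2f +- %.2f) kcal/mol at %.3f A\n",
                x$barrier, x$uncertainty, x$r_max))
    if (!is.null(x$barrier_refined))
      cat(sprintf("  [parabolic 3-point refinement: %.3f kcal/mol]\n",
                  x$barrier_refined))
  }
  invisible(x)
}

#' @export
backend_energies.function <- function(backend, distances, R = NULL) {
  E <- backend(distances)
  if (length(E) != length(distances))
    stop("backend function must return one energy per distance")
  E
}
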