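#' Extract equally spaced snapshots from a trajectory
#'
#' Endpoint-inclusive selection of \code{n} frames at constant intervals:
#' frame indices \code{1 + round(k*(F-1)/(n-1))} for \code{k = 0..n-1};
#' a single snapshot takes the last frame.
#'
#' @param traj A [trajectory()].
#' @param bridge A [bridge_definition()].
#' @param n Number of snapshots.
#' @return List of \code{"snapshot"} objects, each with \code{frame},
#'   \code{time} (fs), \code{donor}/\code{proton}/\code{acceptor}
#'   coordinates (Angstrom), \code{d_OO} and classical \code{d_DH}.
#' @export
extract_snapshots <- function(traj, bridge, n = 5) {
  stopifnot(inherits(traj, "trajectory"))
  Fc <- n_frames(traj)
  if (n < 1) stop("'n' must be at least 1")
  if (n > Fc) stop(sprintf("requested %d snapshots from %d frames", n, Fc))
  idx <- if (n == 1L) Fc
         else as.integer(1 + round((0:(n - 1)) * (Fc - 1) / (n - 1)))
  at <- bridge_atoms(traj, bridge)
  times <- frame_times(traj)
  lapply(idx, function(i) {
    don <- at$donor[i, ]; pro <- at$proton[i, ]; acc <- at$acceptor[i, ]
    structure(list(frame = i, time = times[i], donor = don, proton = pro,
                   acceptor = acc,
                   d_OO = sqrt(sum((acc - don)^2)),
                   d_DH = sqrt(sum((pro - don)^2))),
              class = "snapshot")
  })
}

#' Proton positions along the donor-proton-acceptor arc
#'
#' Generates candidate proton positions on the unique circle through the
#' donor, proton and acceptor coordinates (a straight donor-acceptor
#' segment when the three points are colinear to within 1e-6 Angstrom of
#' the chord).  Positions are parameterized by their distance from the
#' donor, uniformly spaced from \code{margin} to \code{d_OO - margin};
#' the number of positions grows with the bridge length as
#' \code{base_count + clamp(round((d_OO - 2.40)/0.05), 0, 4)}, staying
#' within 16 to 20 points for typical O...O separations.
#'
#' @param donor,proton,acceptor Length-3 coordinate vectors, Angstrom.
#' @param margin Distance margin kept from both heavy atoms, Angstrom.
#' @param base_count Count at the shortest bridges.
#' @return List with \code{positions} (N x 3 matrix), \code{distances}
#'   (donor-proton distance of each position) and \code{d_OO}.
#' @export
arc_positions <- function(donor, proton, acceptor, margin = 0.80,
                          base_count = 16L) {
  donor <- as.numeric(donor); proton <- as.numeric(proton)
  acceptor <- as.numeric(acceptor)
  if (max(sqrt(sum((donor - proton)^2)), sqrt(sum((donor - acceptor)^2)),
          sqrt(sum((proton - acceptor)^2))) < 1e-9)
    stop("degenerate geometry: coincident points")
  d_OO <- sqrt(sum((acceptor - donor)^2))
  if (d_OO <= 2 * margin)
    stop("bridge too short for the requested margins")
  N <- base_count + min(max(round((d_OO - 2.40) / 0.05), 0), 4)
  dist <- seq(margin, d_OO - margin, length.out = N)

  u_da <- (acceptor - donor) / d_OO
  hp <- proton - donor
  off <- hp - sum(hp * u_da) * u_da       # proton offset from the chord
  if (sqrt(sum(off^2)) < 1e-6) {
    pos <- donor + outer(dist, u_da)
    return(list(positions = pos, distances = dist, d_OO = d_OO))
  }
  # circumcenter of the three points (intersection of bisector planes)
  a <- donor - proton; b <- acceptor - proton
  n_ <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  M <- rbind(a, b, n_)
  rhs <- c(sum(a * (donor + proton)) / 2, sum(b * (acceptor + proton)) / 2,
           sum(n_ * proton))
  center <- solve(M, rhs)
  rho <- sqrt(sum((donor - center)^2))
  u <- (donor - center) / rho
  w0 <- (proton - center) - sum((proton - center) * u) * u
  w <- w0 / sqrt(sum(w0^2))              # in-plane direction towards the proton
  theta <- 2 * asin(pmin(dist / (2 * rho), 1))
  pos <- t(vapply(theta, function(th)
    center + rho * (cos(th) * u + sin(th) * w), numeric(3)))
  list(positions = pos, distances = dist, d_OO = d_OO)
}

#' Fit a polynomial proton potential with confining continuation
#'
#' Least-squares fit of a degree-\code{degree} polynomial (default 9) to
#' sampled (distance, energy) points, performed in the shifted and
#' scaled coordinate \eqn{u = (d - d_{mid}) / \textrm{halfrange}} for
#' conditioning.  Outside the sampled range the potential continues as a
#' quadratic wall \eqn{V(\textrm{endpoint}) + \kappa (d - \textrm{endpoint})^2},
#' which keeps the solver domain confining where a high-degree
#' polynomial would otherwise diverge.
#'
#' @param distances,energies Sampled points (Angstrom, kcal/mol); needs
#'   more points than \code{degree}.
#' @param degree Polynomial degree.
#' @param kappa Wall stiffness, kcal mol^-1 A^-2.
#' @return Object of class \code{"proton_potential_1d"} with the
#'   coefficients, the sampled range and the fit RMS residual.
#' @export
fit_potential <- function(distances, energies, degree = 9, kappa = 200) {
  if (length(distances) != length(energies))
    stop("'distances' and 'energies' lengths differ")
  if (length(distances) <= degree)
    stop(sprintf("need more than %d points for a degree-%d fit; lower the degree",
                 degree, degree))
  d_min <- min(distances); d_max <- max(distances)
  mid <- (d_min + d_max) / 2
  half <- (d_max - d_min) / 2
  u <- (distances - mid) / half
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, energies)
  resid_rms <- sqrt(mean(fit$residuals^2))
  structure(list(coef = unname(fit$coefficients), degree = degree,
                 d_min = d_min, d_max = d_max, mid = mid, half = half,
                 kappa = kappa, rms = resid_rms),
            class = "proton_potential_1d")
}

#' @export
print.proton_potential_1d <- function(x, ...) {
  cat(sprintf("Degree-%d proton potential on [%.3f, %.3f] A (fit RMS %.2e kcal/mol)\n",
              x$degree, x$d_min, x$d_max, x$rms))
  cat(sprintf("  quadratic wall continuation, kappa = %g kcal/mol/A^2\n", x$kappa))
  invisible(x)
}

#' Evaluate a fitted proton potential
#'
#' @param object A [fit_potential()] result.
#' @param d Distances, Angstrom.
#' @param ... Unused.
#' @return Energies, kcal/mol; continuous across the sampled-range
#'   boundaries.
#' @export
predict.proton_potential_1d <- function(object, d, ...) {
  poly_at <- function(dd) {
    u <- (dd - object$mid) / object$half
    drop(outer(u, 0:object$degree, `^`) %*% object$coef)
  }
  v <- numeric(length(d))
  lo <- d < object$d_min
  hi <- d > object$d_max
  mid <- !lo & !hi
  v[mid] <- poly_at(d[mid])
  if (any(lo))
    v[lo] <- poly_at(object$d_min) + object$kappa * (d[lo] - object$d_min)^2
  if (any(hi))
    v[hi] <- poly_at(object$d_max) + object$kappa * (d[hi] - object$d_max)^2
  v
}

#' Settings for the 1D vibrational grid solver
#'
#' @param n_grid Number of grid points (>= 16); default 400.
#' @param domain Solver domain, Angstrom; default 0.7 to 2.0.
#' @param mass Particle mass, amu; default the bare proton mass (a
#'   plausible alternative is the O-H reduced mass, which is exposed
#'   here rather than hard-wired).
#' @param temperature Temperature for thermal averaging, K.
#' @param levels Number of vibrational levels entering the thermal
#'   average.
#' @return Object of class \code{"solver_settings"}.
#' @export
solver_settings <- function(n_grid = 400, domain = c(0.7, 2.0),
                            mass = 1.0078, temperature = 295, levels = 3) {
  if (n_grid < 16) stop("'n_grid' must be at least 16")
  if (domain[1] >= domain[2]) stop("'domain' lower bound must be below upper")
  if (levels < 1) stop("'levels' must be at least 1")
  if (mass <= 0) stop("'mass' must be positive")
  structure(list(n_grid = as.integer(n_grid), domain = domain, mass = mass,
                 temperature = temperature, levels = as.integer(levels)),
            class = "solver_settings")
}

#' Solve the 1D vibrational Schroedinger equation on a grid
#'
#' Sine-DVR (particle-in-a-box discrete variable representation) with
#' Dirichlet boundaries: the kinetic operator is represented exactly in
#' the sine basis of the solver domain and transformed to the uniform
#' interior grid, giving spectral accuracy for potentials that confine
#' the wavefunction inside the domain.  Internally the problem is solved
#' in Hartree atomic units.
#'
#' @param potential A [fit_potential()] object, or any function mapping
#'   distance (Angstrom) to energy (kcal/mol).
#' @param settings A [solver_settings()] object.
#' @return Object of class \code{"vibrational_solution"}: \code{grid}
#'   (Angstrom), \code{energies_kcal} and \code{energies_cm} (relative
#'   zero at the potential's minimum as supplied), normalized
#'   \code{wavefunctions} (columns; \eqn{\sum \psi^2 \Delta x = 1}),
#'   per-state \code{r_expect} (Angstrom) and the settings used.
#'   A warning is raised if the ground state leaks into the outermost
#'   grid cells (non-confining potential).
#' @export
solve_bound_states <- function(potential, settings = solver_settings()) {
  stopifnot(inherits(settings, "solver_settings"))
  Vfun <- if (is.function(potential)) potential
          else function(d) predict(potential, d)
  N <- settings$n_grid
  a <- settings$domain[1]; b <- settings$domain[2]
  h <- (b - a) / (N + 1)
  x <- a + h * seq_len(N)                      # interior grid, Angstrom
  V_kcal <- Vfun(x)
  if (any(is.na(V_kcal))) stop("potential evaluated to NaN on the grid")
  # atomic units
  L_au <- (b - a) / .BOHR_ANG
  m_au <- settings$mass * .AMU_ME
  V_au <- V_kcal / .HARTREE_KCAL
  n <- seq_len(N)
  U <- sqrt(2 / (N + 1)) * sin(pi * outer(n, n) / (N + 1))
  t_n <- (n * pi / L_au)^2 / (2 * m_au)        # sine-basis kinetic eigenvalues
  H <- U %*% (t_n * U) + diag(V_au)
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  n_keep <- min(N, max(settings$levels + 2L, 8L))
  ord <- N:1                                    # eigen() returns decreasing
  Evals <- eig$values[ord][seq_len(n_keep)]
  psi <- eig$vectors[, ord, drop = FALSE][, seq_len(n_keep), drop = FALSE]
  # unit-norm DVR vectors -> continuum normalization
  edge_mass <- colSums(psi[c(1, 2, N - 1, N), 1, drop = FALSE]^2)
  if (sum(edge_mass) > 1e-3)
    warning("potential is not confining: ground state has weight at the domain edge")
  psi <- psi / sqrt(h)
  # fix sign convention: positive mean amplitude
  s <- sign(colSums(psi^3))
  s[s == 0] <- 1
  psi <- sweep(psi, 2, s, `*`)
  r_exp <- colSums(psi^2 * x) * h
  structure(list(grid = x, energies_kcal = Evals * .HARTREE_KCAL,
                 energies_cm = Evals * .HARTREE_CM,
                 wavefunctions = psi, r_expect = r_exp,
                 settings = settings),
            class = "vibrational_solution")
}

#' @export
print.vibrational_solution <- function(x, ...) {
  k <- min(length(x$energies_cm), 5L)
  cat(sprintf("Vibrational solution (%d grid points on [%.2f, %.2f] A, m = %.4f amu)\n",
              x$settings$n_grid, x$settings$domain[1], x$settings$domain[2],
              x$settings$mass))
  for (i in seq_len(k))
    cat(sprintf("  level %d: E = %9.2f cm^-1,  <r> = %.4f A\n",
                i - 1L, x$energies_cm[i] - x$energies_cm[1], x$r_expect[i]))
  invisible(x)
}

#' Thermal expectation of the donor-proton distance
#'
#' Boltzmann average \eqn{\langle r\rangle = \sum_n w_n \langle\psi_n|r|\psi_n\rangle}
#' over the lowest vibrational levels, with weights
#' \eqn{w_n \propto e^{-(E_n - E_0)/k_B T}} normalized to one.  At
#' \eqn{T = 0} only the ground state contributes.  Invariant under an
#' additive shift of all energies.
#'
#' @param x A [solve_bound_states()] solution, or a numeric vector of
#'   level energies in kcal/mol (then supply \code{r_values}).
#' @param ... Passed to methods.
#' @return The thermal \eqn{\langle r\rangle} in Angstrom, with the
#'   Boltzmann weights attached as attribute \code{weights}.
#' @export
thermal_expectation <- function(x, ...) UseMethod("thermal_expectation")

#' @param r_values Per-state position expectations, Angstrom.
#' @param temperature Temperature, K.
#' @param levels Number of levels in the average.
#' @rdname thermal_expectation
#' @export
thermal_expectation.default <- function(x, r_values, temperature = 295,
                                        levels = min(3L, length(x)), ...) {
  if (levels > length(x) || levels > length(r_values))
    stop(sprintf("%d levels requested but only %d available", levels,
                 min(length(x), length(r_values))))
  E <- x[seq_len(levels)] - x[1]
  r <- r_values[seq_len(levels)]
  w <- if (temperature == 0) c(1, numeric(levels - 1L))
       else exp(-E / (.kB * temperature))
  w <- w / sum(w)
  structure(sum(w * r), weights = w)
}

#' @rdname thermal_expectation
#' @export
thermal_expectation.vibrational_solution <- function(x, temperature = x$settings$temperature,
                                                     levels = x$settings$levels, ...) {
  thermal_expectation(x$energies_kcal, x$r_expect, temperature = temperature,
                      levels = levels)
}

#' Nuclear-quantum-effects report for a trajectory
#'
#' Runs the full a posteriori NQE pipeline: extract equally spaced
#' snapshots, build arc proton paths from the donor/proton/acceptor
#' coordinates, score them with an energy backend, fit the degree-9
#' polynomial potential, solve the 1D vibrational Schroedinger equation
#' on the grid, and Boltzmann-average the donor-proton distance operator
#' over the lowest levels.  One row per snapshot compares the classical
#' proton position with its quantum expectation.
#'
#' @param traj A [trajectory()].
#' @param bridge A [bridge_definition()].
#' @param backend An \code{"energy_backend"}; the model backend is
#'   evaluated at each snapshot's own donor-acceptor distance.
#' @param n_snapshots Number of snapshots.
#' @param solver A [solver_settings()] object.
#' @param arc_margin,degree,kappa Arc margin (Angstrom), polynomial
#'   degree and wall stiffness, passed to the pipeline stages.
#' @return Data frame of class \code{"nqe_report"} with columns
#'   \code{frame}, \code{time}, \code{d_OO}, \code{d_DH_classical},
#'   \code{r_classical_min} (minimum of the fitted potential) and
#'   \code{r_quantum} (thermal expectation), all distances in Angstrom.
#' @export
nqe_report <- function(traj, bridge, backend, n_snapshots = 5,
                       solver = solver_settings(), arc_margin = 0.80,
                       degree = 9, kappa = 200) {
  snaps <- extract_snapshots(traj, bridge, n_snapshots)
  rows <- lapply(seq_along(snaps), function(i) {
    s <- snaps[[i]]
    res <- tryCatch({
      arc <- arc_positions(s$donor, s$proton, s$acceptor, margin = arc_margin)
      E <- backend_energies(backend, arc$distances, R = s$d_OO)
      pot <- fit_potential(arc$distances, E, degree = degree, kappa = kappa)
      sol <- solve_bound_states(pot, solver)
      rq <- thermal_expectation(sol)
      dd <- seq(pot$d_min, pot$d_max, length.out = 2001)
      i0 <- which.min(predict(pot, dd))
      rcl <- optimize(function(d) predict(pot, d),
                      c(dd[max(i0 - 1L, 1L)], dd[min(i0 + 1L, 2001L)]))$minimum
      data.frame(frame = s$frame, time = s$time, d_OO = s$d_OO,
                 d_DH_classical = s$d_DH, r_classical_min = rcl,
                 r_quantum = as.numeric(rq))
    }, error = function(e) {
      stop(sprintf("snapshot %d (frame %d): %s", i, s$frame,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nqe_report", "data.frame")
  out
}

#' @export
plot.nqe_report <- function(x, ...) {
  plot(x$d_OO, x$d_DH_classical, pch = 1, col = "darkgreen",
       xlab = "d(O...O) (Å)", ylab = "d(O-H) (Å)",
       ylim = range(c(x$d_DH_classical, x$r_quantum, x$d_OO / 2)), ...)
  points(x$d_OO, x$r_quantum, pch = 4, col = "red")
  lines(sort(x$d_OO), sort(x$d_OO) / 2, lty = 2)
  legend("topleft", c("classical", "quantum <r>", "bridge midpoint"),
         pch = c(1, 4, NA), lty = c(NA, NA, 2),
         col = c("darkgreen", "red", "black"), bty = "n")
  invisible(x)
}
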