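#' Parameters of the surrogate two-bridge proton Hamiltonian
#'
#' Defines the reduced-dimensional model used to generate surrogate
#' trajectories of two coupled intramolecular O-H...O bridges.  Each bridge
#' carries a proton coordinate \eqn{r} (donor-proton distance) and a
#' breathing donor-acceptor coordinate \eqn{R}, with per-bridge potential
#' \deqn{V(r,R) = D_d [1 - e^{-a_d (r-\rho)}]^2 +
#'               D_a [1 - e^{-a_a (R-r-\rho)}]^2 +
#'               \tfrac{1}{2} k_R (R-R_0)^2}
#' and a bilinear inter-bridge coupling \eqn{\lambda\, q_1 q_2} in the
#' signed Voronoi coordinates \eqn{q_b = r_b - R_b/2}.  The opposed Morse
#' wells produce a double-well proton profile whose deep (donor-side)
#' minimum sits near 1 Angstrom; the harmonic term restrains the
#' donor-acceptor distance against the inward pull of the acceptor well.
#'
#' The default parameter set is calibrated so that, at 295 K, the thermal
#' mean donor-acceptor distance is close to 2.55 Angstrom, the fixed-R
#' proton profile at 2.55 Angstrom is a double well with a barrier of
#' roughly 5 kcal/mol, the donor-site residence is about 90 percent, and
#' the O-H stretch falls near 3400 cm^-1.  The \code{"solid"} preset
#' equalises the two Morse depths, giving a symmetric well and an
#' approximately 50/50 proton partition, emulating a strongly shared,
#' condensed-phase regime.  The \code{"lowbarrier"} preset softens the
#' Morse range so the barrier drops to about 3 kcal/mol and decouples the
#' two bridges; it is intended for ergodicity checks, where frequent
#' barrier crossings make simulated statistics converge quickly to their
#' Boltzmann limits.
#'
#' @param D_d,D_a Morse well depths of the donor and acceptor wells
#'   (kcal/mol).
#' @param a_d,a_a Morse range parameters (1/Angstrom).
#' @param rho Equilibrium covalent O-H distance (Angstrom).
#' @param k_R Harmonic donor-acceptor force constant (kcal mol^-1 A^-2).
#' @param R_0 Rest length of the harmonic donor-acceptor restraint
#'   (Angstrom).  Note this is the skeletal rest length, not the observed
#'   mean O...O distance: the acceptor Morse well pulls the bridge inward,
#'   and the defaults are chosen so the dynamical mean lands near 2.55.
#' @param lambda_c Bilinear inter-bridge coupling constant
#'   (kcal mol^-1 A^-2); negative values favour concerted double-well
#'   occupation (both protons donor-side or both acceptor-side).
#' @param m_H Proton mass (amu).
#' @param m_R Effective donor-acceptor reduced mass (amu).
#' @param preset Optional named preset: \code{"default"}, \code{"solid"}
#'   or \code{"lowbarrier"}.  Explicit arguments override preset values.
#' @return An object of class \code{"model_params"}.
#' @examples
#' p <- model_params()
#' evaluate_model_potential(p, r = 1.0, R = 2.55)
#' characterize_model(p, R_fixed = 2.55)
#' @export
model_params <- function(D_d = 48, D_a = 46, a_d = 3.2, a_a = 3.2,
                         rho = 0.95, k_R = 300, R_0 = 2.68,
                         lambda_c = -2, m_H = 1.0078, m_R = 7.9997,
                         preset = c("default", "solid", "lowbarrier")) {
  preset <- match.arg(preset)
  given <- names(match.call())[-1L]
  override <- function(name, value) if (name %in% given) get(name) else value
  if (preset == "solid") {
    D_a <- override("D_a", 48)
  } else if (preset == "lowbarrier") {
    a_d <- override("a_d", 3.0)
    a_a <- override("a_a", 3.0)
    D_a <- override("D_a", 46.5)
    lambda_c <- override("lambda_c", 0)
  }
  p <- list(D_d = D_d, D_a = D_a, a_d = a_d, a_a = a_a, rho = rho,
            k_R = k_R, R_0 = R_0, lambda_c = lambda_c,
            m_H = m_H, m_R = m_R, preset = preset)
  for (nm in c("D_d", "D_a", "a_d", "a_a", "k_R", "m_H", "m_R"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  if (2 * p$rho >= p$R_0)
    stop("2*rho must be smaller than R_0 (wells must fit inside the bridge)")
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-bridge double-well model parameters (preset:", x$preset, ")\n")
  cat(sprintf("  donor Morse:    D_d = %g kcal/mol, a_d = %g 1/A\n", x$D_d, x$a_d))
  cat(sprintf("  acceptor Morse: D_a = %g kcal/mol, a_a = %g 1/A\n", x$D_a, x$a_a))
  cat(sprintf("  rho = %g A,  k_R = %g kcal/mol/A^2,  R_0 = %g A\n",
              x$rho, x$k_R, x$R_0))
  cat(sprintf("  coupling lambda_c = %g kcal/mol/A^2;  m_H = %g amu, m_R = %g amu\n",
              x$lambda_c, x$m_H, x$m_R))
  invisible(x)
}

# single-bridge potential, vectorized over r and/or R
.bridge_potential <- function(p, r, R) {
  p$D_d * (1 - exp(-p$a_d * (r - p$rho)))^2 +
    p$D_a * (1 - exp(-p$a_a * (R - r - p$rho)))^2 +
    0.5 * p$k_R * (R - p$R_0)^2
}

#' Evaluate the surrogate bridge potential
#'
#' Potential energy of a single O-H...O bridge of the surrogate model at
#' donor-proton distance \code{r} and donor-acceptor distance \code{R}
#' (no inter-bridge coupling term).
#'
#' @param params A [model_params()] object.
#' @param r Donor-proton distance(s), Angstrom; must be positive.
#' @param R Donor-acceptor distance(s), Angstrom; must exceed \code{r}.
#' @return Energy in kcal/mol, vectorized over \code{r}/\code{R}.
#' @export
evaluate_model_potential <- function(params, r, R) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(r)) || any(!is.finite(R)))
    stop("'r' and 'R' must be finite")
  if (any(r <= 0)) stop("non-physical geometry: r must be positive")
  if (any(R <= r)) stop("non-physical geometry: R must exceed r")
  .bridge_potential(params, r, R)
}

#' Locate the double-well structure of the model at fixed bridge length
#'
#' Scans the proton coordinate at fixed donor-acceptor distance and
#' reports the deep and shallow minima, the intervening barrier and the
#' well asymmetry.  Minima are refined from a dense grid scan by local
#' parabolic-free golden-section optimization, so the reported positions
#' are resolution-independent.
#'
#' @param params A [model_params()] object.
#' @param R_fixed Donor-acceptor distance at which the profile is taken
#'   (Angstrom).
#' @param n_grid Number of scan points used to bracket the stationary
#'   points.
#' @return A list of class \code{"model_characterization"} with elements
#'   \code{r_min_deep}, \code{r_min_shallow}, \code{r_max},
#'   \code{barrier} (E_max - E_deep, kcal/mol), \code{asymmetry}
#'   (E_shallow - E_deep, kcal/mol) and \code{double_well} (logical).
#'   For a single-minimum profile \code{double_well} is \code{FALSE} and
#'   the shallow-minimum and barrier entries are \code{NA}.
#' @export
characterize_model <- function(params, R_fixed = params$R_0, n_grid = 4000) {
  stopifnot(inherits(params, "model_params"))
  margin <- 0.35
  if (R_fixed <= 2 * margin) stop("R_fixed too short to scan")
  r <- seq(margin, R_fixed - margin, length.out = n_grid)
  E <- .bridge_potential(params, r, R_fixed)
  dE <- diff(sign(diff(E)))
  i_min <- which(dE > 0) + 1L
  i_max <- which(dE < 0) + 1L
  f <- function(x) .bridge_potential(params, x, R_fixed)
  refine <- function(i, maximum = FALSE) {
    lo <- r[max(i - 1L, 1L)]; hi <- r[min(i + 1L, n_grid)]
    opt <- optimize(f, c(lo, hi), maximum = maximum, tol = 1e-10)
    if (maximum) c(opt$maximum, opt$objective) else c(opt$minimum, opt$objective)
  }
  if (length(i_min) < 2L || length(i_max) < 1L) {
    i0 <- if (length(i_min) >= 1L) i_min[which.min(E[i_min])] else which.min(E)
    m <- refine(i0)
    out <- list(r_min_deep = m[1], E_deep = m[2], r_min_shallow = NA_real_,
                E_shallow = NA_real_, r_max = NA_real_, barrier = NA_real_,
                asymmetry = NA_real_, double_well = FALSE, R_fixed = R_fixed)
    class(out) <- "model_characterization"
    return(out)
  }
  mins <- t(vapply(i_min, refine, numeric(2)))
  ord <- order(mins[, 2])
  deep <- mins[ord[1], ]; shallow <- mins[ord[2], ]
  between <- i_max[r[i_max] > min(deep[1], shallow[1]) &
                   r[i_max] < max(deep[1], shallow[1])]
  i_bar <- between[which.max(E[between])]
  bar <- refine(i_bar, maximum = TRUE)
  out <- list(r_min_deep = deep[1], E_deep = deep[2],
              r_min_shallow = shallow[1], E_shallow = shallow[2],
              r_max = bar[1],
              barrier = bar[2] - deep[2],
              asymmetry = shallow[2] - deep[2],
              double_well = TRUE, R_fixed = R_fixed)
  class(out) <- "model_characterization"
  out
}

#' @export
print.model_characterization <- function(x, ...) {
  cat(sprintf("Proton profile at fixed R = %.4g A:\n", x$R_fixed))
  if (!x$double_well) {
    cat(sprintf("  single minimum at r = %.4f A\n", x$r_min_deep))
  } else {
    cat(sprintf("  deep minimum    r = %.4f A\n", x$r_min_deep))
    cat(sprintf("  shallow minimum r = %.4f A (asymmetry %.3f kcal/mol)\n",
                x$r_min_shallow, x$asymmetry))
    cat(sprintf("  barrier         %.3f kcal/mol at r = %.4f A\n",
                x$barrier, x$r_max))
  }
  invisible(x)
}

#' Boltzmann quadrature reference statistics for one bridge
#'
#' Computes equilibrium configurational statistics of a single,
#' uncoupled bridge of the surrogate model by direct 2D numerical
#' quadrature of \eqn{e^{-V(r,R)/k_B T}}.  Serves as the stationary-state
#' reference against which long Langevin trajectories can be validated.
#'
#' @param params A [model_params()] object (the inter-bridge coupling is
#'   ignored; it is exact for \code{lambda_c = 0}).
#' @param temperature Temperature in Kelvin.
#' @param n_r,n_R Quadrature grid sizes for the proton and bridge
#'   coordinates.
#' @return List with \code{donor_fraction} (percent of configurational
#'   weight with \code{r < R/2}), \code{mean_R}, \code{sd_R} and
#'   \code{mean_r} (Angstrom).
#' @export
boltzmann_bridge_stats <- function(params, temperature = 295,
                                   n_r = 1200, n_R = 500) {
  stopifnot(inherits(params, "model_params"), temperature > 0)
  kT <- .kB * temperature
  R <- seq(max(2 * params$rho + 0.05, params$R_0 - 0.6), params$R_0 + 0.55,
           length.out = n_R)
  r <- seq(0.3, max(R) - 0.3, length.out = n_r)
  logw <- outer(r, R, function(r, R) {
    v <- .bridge_potential(params, r, R)
    ifelse(r > 0.25 & r < R - 0.25, -v / kT, -Inf)
  })
  w <- exp(logw - max(logw))
  Rm <- matrix(R, nrow = n_r, ncol = n_R, byrow = TRUE)
  rm_ <- matrix(r, nrow = n_r, ncol = n_R)
  Z <- sum(w)
  mean_R <- sum(w * Rm) / Z
  list(donor_fraction = 100 * sum(w[rm_ < Rm / 2]) / Z,
       mean_R = mean_R,
       sd_R = sqrt(sum(w * (Rm - mean_R)^2) / Z),
       mean_r = sum(w * rm_) / Z)
}

#' Boltzmann quadrature reference for the joint bridge-bridge quadrants
#'
#' Quadrant occupancies (both-donor DD, mixed DA/AD, both-acceptor AA) of
#' the coupled two-bridge Boltzmann density.  The 4D configurational
#' integral factorizes through the signed Voronoi coordinates
#' \eqn{q_b = r_b - R_b/2}: each bridge contributes a 1D marginal density
#' \eqn{f_b(q)}, and the bilinear coupling reweights the product with
#' \eqn{e^{-\lambda q_1 q_2 / k_B T}}.
#'
#' @inheritParams boltzmann_bridge_stats
#' @param n_q Number of bins for the q marginals.
#' @return List with percentage occupancies \code{DD}, \code{DA},
#'   \code{AD}, \code{AA} (bridge-1 letter first; D means \eqn{q \le 0}).
#' @export
boltzmann_quadrant_stats <- function(params, temperature = 295,
                                     n_r = 900, n_R = 400, n_q = 400) {
  stopifnot(inherits(params, "model_params"), temperature > 0)
  kT <- .kB * temperature
  R <- seq(max(2 * params$rho + 0.05, params$R_0 - 0.6), params$R_0 + 0.55,
           length.out = n_R)
  r <- seq(0.3, max(R) - 0.3, length.out = n_r)
  logw <- outer(r, R, function(r, R) {
    v <- .bridge_potential(params, r, R)
    ifelse(r > 0.25 & r < R - 0.25, -v / kT, -Inf)
  })
  w <- exp(logw - max(logw))
  q <- outer(r, R, function(r, R) r - R / 2)
  q_edges <- seq(min(q) - 1e-9, max(q) + 1e-9, length.out = n_q + 1L)
  bin <- findInterval(as.vector(q), q_edges, rightmost.closed = TRUE)
  fq <- vapply(seq_len(n_q), function(b) sum(w[bin == b]), numeric(1))
  q_mid <- (q_edges[-1L] + q_edges[-(n_q + 1L)]) / 2
  # both bridges share the same marginal under identical parameters
  W2 <- outer(fq, fq) * exp(-params$lambda_c * outer(q_mid, q_mid) / kT)
  don <- q_mid <= 0
  Z <- sum(W2)
  list(DD = 100 * sum(W2[don, don]) / Z,
       DA = 100 * sum(W2[don, !don]) / Z,
       AD = 100 * sum(W2[!don, don]) / Z,
       AA = 100 * sum(W2[!don, !don]) / Z)
}

#' Harmonic normal modes of one bridge at its minimum
#'
#' Mass-weighted normal-mode analysis of the two reduced coordinates
#' (r, R) of a single uncoupled bridge, linearized at the relaxed
#' minimum.  The high-frequency, proton-dominated mode is the analytic
#' reference for the O-H stretch position in power spectra of
#' small-amplitude surrogate trajectories.
#'
#' @param params A [model_params()] object.
#' @param delta Finite-difference step for the Hessian, Angstrom.
#' @return List with \code{minimum} (r, R in Angstrom),
#'   \code{wavenumbers} (cm^-1, decreasing) and \code{modes}
#'   (mass-weighted eigenvectors as columns, rows ordered r, R).
#' @export
model_normal_modes <- function(params, delta = 1e-4) {
  stopifnot(inherits(params, "model_params"))
  x0 <- .bridge_minimum(params)
  f <- function(z) .bridge_potential(params, z[1], z[2])
  Hm <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- delta; ej[j] <- delta
    Hm[i, j] <- (f(x0 + ei + ej) - f(x0 + ei - ej) -
                 f(x0 - ei + ej) + f(x0 - ei - ej)) / (4 * delta^2)
  }
  m <- c(params$m_H, params$m_R)
  W <- Hm * .KCAL_TO_INT / sqrt(outer(m, m))   # internal units, mass-weighted
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE)
  omega <- sqrt(pmax(ev$values, 0))            # fs^-1
  list(minimum = x0, wavenumbers = omega / (2 * pi * .C_CM_FS),
       modes = ev$vectors)
}
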