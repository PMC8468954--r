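# Independent oracles used across the suite.  These re-derive reference
# values from first principles (closed forms, dense quadrature, plain
# finite differences) and never call the code paths they check.

# independent evaluation of the single-bridge surrogate potential
oracle_potential <- function(p, r, R) {
  p$D_d * (1 - exp(-p$a_d * (r - p$rho)))^2 +
    p$D_a * (1 - exp(-p$a_a * (R - r - p$rho)))^2 +
    0.5 * p$k_R * (R - p$R_0)^2
}

# dense 1D grid scan of the profile at fixed R: minima, maxima, barrier
oracle_profile_scan <- function(p, R_fixed, n = 10000) {
  r <- seq(0.4, R_fixed - 0.4, length.out = n)
  E <- oracle_potential(p, r, R_fixed)
  E <- E - min(E)
  d2 <- diff(sign(diff(E)))
  i_min <- which(d2 > 0) + 1L
  i_max <- which(d2 < 0) + 1L
  list(r = r, E = E, r_min = r[i_min], E_min = E[i_min],
       r_max = r[i_max], E_max = E[i_max],
       barrier = if (length(i_max)) max(E[i_max]) - min(E[i_min]) else NA_real_)
}

# 2D midpoint-rule Boltzmann quadrature for one uncoupled bridge
oracle_bridge_boltzmann <- function(p, temperature = 295,
                                    n_r = 1000, n_R = 400) {
  kB <- 0.0019872041
  R <- seq(p$R_0 - 0.6, p$R_0 + 0.55, length.out = n_R)
  r <- seq(0.35, max(R) - 0.3, length.out = n_r)
  lw <- outer(r, R, function(r, R) {
    v <- oracle_potential(p, r, R)
    ifelse(r < R - 0.28, -v / (kB * temperature), -Inf)
  })
  w <- exp(lw - max(lw))
  Rm <- matrix(R, n_r, n_R, byrow = TRUE)
  rm_ <- matrix(r, n_r, n_R)
  list(donor_fraction = 100 * sum(w[rm_ < Rm / 2]) / sum(w),
       mean_R = sum(w * Rm) / sum(w))
}

# dense-grid second-order finite-difference eigensolver (Dirichlet)
oracle_fd_levels <- function(Vfun_kcal, mass_amu, domain, n = 1200, k = 3) {
  HARTREE_KCAL <- 627.509474
  HARTREE_CM <- 219474.6313632
  BOHR <- 0.529177210903
  AMU_ME <- 1822.888486
  h <- (domain[2] - domain[1]) / (n + 1)
  x <- domain[1] + h * seq_len(n)
  h_au <- h / BOHR
  m_au <- mass_amu * AMU_ME
  V <- Vfun_kcal(x) / HARTREE_KCAL
  t0 <- 1 / (2 * m_au * h_au^2)
  H <- diag(2 * t0 + V)
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  H[idx] <- -t0
  H[idx[, 2:1]] <- -t0
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  ev[seq_len(k)] * HARTREE_CM
}

# minimal bridge_series construction for unit tests
mk_series <- function(d_DH, d_HA, d_OO = d_DH + d_HA, dt = 1) {
  out <- data.frame(time = (seq_along(d_DH) - 1) * dt, d_OO = d_OO,
                    d_DH = d_DH, d_HA = d_HA)
  class(out) <- c("bridge_series", "data.frame")
  out
}

# single-frame 3-atom trajectory holding one bridge geometry
mk_snapshot_traj <- function(proton, d_OO = 2.55) {
  xyz <- array(0, dim = c(1, 3, 3))
  xyz[1, 2, ] <- proton
  xyz[1, 3, 1] <- d_OO
  trajectory(c("O", "H", "O"), xyz, dt = 1)
}

# harmonic potential (kcal/mol) with fundamental nu_cm at minimum x0
mk_harmonic_kcal <- function(nu_cm, x0, mass_amu = 1.0078) {
  HARTREE_KCAL <- 627.509474
  HARTREE_CM <- 219474.6313632
  BOHR <- 0.529177210903
  AMU_ME <- 1822.888486
  omega_au <- nu_cm / HARTREE_CM
  m_au <- mass_amu * AMU_ME
  function(d) 0.5 * m_au * omega_au^2 * ((d - x0) / BOHR)^2 * HARTREE_KCAL
}
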