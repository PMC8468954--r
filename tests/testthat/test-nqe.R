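test_that("snapshot extraction is endpoint-inclusive at constant intervals", {
  xyz <- array(0, dim = c(101, 3, 3))
  xyz[, 2, 1] <- 1; xyz[, 3, 1] <- 2.55
  tr <- trajectory(c("O", "H", "O"), xyz, dt = 2)
  bd <- bridge_definition(1, 2, 3)
  sn <- extract_snapshots(tr, bd, 5)
  expect_equal(vapply(sn, `[[`, 0L, "frame"), c(1L, 26L, 51L, 76L, 101L))
  expect_equal(sn[[2]]$time, 25 * 2)
  expect_equal(sn[[1]]$d_OO, 2.55)
  expect_equal(extract_snapshots(tr, bd, 1)[[1]]$frame, 101L)
  expect_error(extract_snapshots(tr, bd, 0), "at least 1")
  expect_error(extract_snapshots(tr, bd, 500), "500 snapshots")
})

test_that("colinear geometries give a straight scan with exact distances", {
  arc <- arc_positions(c(0, 0, 0), c(1.0, 3e-7, 0), c(2.55, 0, 0))
  expect_equal(arc$d_OO, 2.55)
  d_back <- sqrt(rowSums(arc$positions^2))
  expect_equal(d_back, arc$distances, tolerance = 1e-12)
  expect_true(all(abs(arc$positions[, 2]) < 1e-12))  # on the chord
  expect_equal(arc$distances[1], 0.80)
  expect_equal(arc$distances[length(arc$distances)], 2.55 - 0.80)
})

test_that("non-colinear points lie on the circumcircle of the defining triple", {
  don <- c(0.1, -0.2, 0.3); pro <- c(1.05, 0.31, 0.1); acc <- c(2.5, 0.15, 0.4)
  arc <- arc_positions(don, pro, acc)
  # circumcenter found independently: equidistance from the three points
  p <- arc$positions
  d_don <- sqrt(colSums((t(p) - don)^2))
  expect_equal(d_don, arc$distances, tolerance = 1e-9)
  # all points and the generating atoms share a common center
  mid <- function(a, b) (a + b) / 2
  # distance of every arc point to donor/proton/acceptor circumcenter:
  A <- rbind(2 * (pro - don), 2 * (acc - don))
  # solve in the plane: center = don + alpha*(pro-don) + beta*(acc-don)
  base <- cbind(pro - don, acc - don)
  G <- crossprod(base)
  rhs <- c(sum((pro - don)^2), sum((acc - don)^2)) / 2
  ab <- solve(G, rhs)
  center <- don + as.vector(base %*% ab)
  rr <- sqrt(sum((don - center)^2))
  radii <- sqrt(colSums((t(p) - center)^2))
  expect_lt(max(abs(radii - rr)), 1e-9)
})

test_that("arc position counts respect the bridge-length rule", {
  mk <- function(dOO) arc_positions(c(0, 0, 0), c(1, 0.2, 0), c(dOO, 0, 0))
  expect_length(mk(2.55)$distances, 19L)
  counts <- vapply(seq(2.35, 2.75, by = 0.05),
                   function(dOO) length(mk(dOO)$distances), 0L)
  expect_true(all(counts >= 16L & counts <= 20L))
  expect_error(arc_positions(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               "degenerate")
})

test_that("degree-9 data are reproduced exactly and walls confine the domain", {
  set.seed(8)
  cf <- rnorm(10)
  d <- seq(0.80, 1.75, length.out = 20)
  u <- (d - mean(range(d))) / (diff(range(d)) / 2)
  E <- drop(outer(u, 0:9, `^`) %*% cf)
  pot <- fit_potential(d, E, degree = 9)
  expect_lt(max(abs(predict(pot, d) - E)), 1e-8)
  expect_lt(pot$rms, 1e-10)

  # constant energies fit exactly
  pc <- fit_potential(d, rep(2.5, 20))
  expect_equal(predict(pc, c(0.9, 1.3)), c(2.5, 2.5), tolerance = 1e-9)
  expect_equal(pc$rms, 0, tolerance = 1e-12)

  # below the sampled range the quadratic wall keeps values above V(d_min)
  expect_gte(predict(pot, 0.7), predict(pot, pot$d_min))
  # continuity at the boundary
  expect_equal(predict(pot, pot$d_min - 1e-9), predict(pot, pot$d_min),
               tolerance = 1e-6)
  expect_error(fit_potential(d[1:8], E[1:8], degree = 9), "lower the degree")
})

test_that("the grid solver reproduces particle-in-a-box levels", {
  L <- 1.3  # box 0.7..2.0 Angstrom
  sol <- solve_bound_states(function(d) rep(0, length(d)),
                            solver_settings())
  # E_n = n^2 h^2 / (8 m L^2) in atomic units: n^2 pi^2 / (2 m L_au^2)
  L_au <- L / 0.529177210903
  m_au <- 1.0078 * 1822.888486
  E_true <- (1:3)^2 * pi^2 / (2 * m_au * L_au^2) * 219474.6313632
  got <- sol$energies_cm[1:3]
  expect_lt(max(abs(got - E_true) / E_true), 1e-3)
})

test_that("a potential piling density onto the wall triggers a warning", {
  # on a coarse grid a well hugging the boundary leaks into the edge cells
  expect_warning(
    solve_bound_states(mk_harmonic_kcal(3000, 1.97),
                       solver_settings(n_grid = 16)),
    "not confining")
})

test_that("a 3000 cm^-1 harmonic well gives the exact fundamental", {
  V <- mk_harmonic_kcal(3000, x0 = 1.35)
  sol <- solve_bound_states(V, solver_settings())
  expect_lt(abs((sol$energies_cm[2] - sol$energies_cm[1]) - 3000), 0.1)
  # eigenvalue ordering and normalization
  expect_true(all(diff(sol$energies_cm) > 0))
  h <- diff(sol$grid)[1]
  norms <- colSums(sol$wavefunctions^2) * h
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-10)
  # <r> = minimum for every state of a symmetric well
  expect_lt(max(abs(sol$r_expect[1:3] - 1.35)), 1e-6)
})

test_that("Morse levels match the closed-form anharmonic spectrum", {
  D_kcal <- 35; a_ang <- 2.5; xe <- 1.1; m <- 1.0078
  V <- function(d) D_kcal * (1 - exp(-a_ang * (d - xe)))^2
  sol <- solve_bound_states(V, solver_settings(mass = m))
  D_au <- D_kcal / 627.509474
  a_au <- a_ang * 0.529177210903
  m_au <- m * 1822.888486
  w0 <- a_au * sqrt(2 * D_au / m_au)
  n <- 0:2
  E_true <- (w0 * (n + 0.5) - (w0 * (n + 0.5))^2 / (4 * D_au)) * 219474.6313632
  expect_lt(max(abs(sol$energies_cm[1:3] - E_true)), 1)
})

test_that("doubling the grid changes the low levels by less than 0.01 cm^-1", {
  V <- function(d) 35 * (1 - exp(-2.5 * (d - 1.1)))^2
  s400 <- solve_bound_states(V, solver_settings(n_grid = 400))
  s800 <- solve_bound_states(V, solver_settings(n_grid = 800))
  expect_lt(max(abs(s400$energies_cm[1:3] - s800$energies_cm[1:3])), 0.01)
})

test_that("the solver agrees with an independent finite-difference oracle", {
  tests <- list(
    function(d) 35 * (1 - exp(-2.5 * (d - 1.1)))^2,
    mk_harmonic_kcal(2800, x0 = 1.3),
    function(d) 1500 * ((d - 1.3)^2 - 0.25^2)^2 / 0.25^4 * 0.005  # double well
  )
  for (V in tests) {
    sol <- solve_bound_states(V, solver_settings())
    ref <- oracle_fd_levels(V, 1.0078, c(0.7, 2.0), n = 2400, k = 3)
    expect_lt(max(abs(sol$energies_cm[1:3] - ref)), 1)
  }
})

test_that("NaN potentials are rejected", {
  expect_error(solve_bound_states(function(d) ifelse(d > 1, NaN, 0),
                                  solver_settings()), "NaN")
})

test_that("thermal expectations follow Boltzmann weighting", {
  kB <- 0.0019872041
  # hand-evaluated two-level case: gap = kB T ln 2 -> weights 2/3, 1/3
  E <- c(0, kB * 295 * log(2))
  r <- thermal_expectation(E, c(1.0, 1.3), temperature = 295, levels = 2)
  expect_equal(as.numeric(r), 1.1, tolerance = 1e-9)
  expect_equal(attr(r, "weights"), c(2, 1) / 3, tolerance = 1e-12)

  # energy-shift invariance
  r2 <- thermal_expectation(E + 57.3, c(1.0, 1.3), temperature = 295,
                            levels = 2)
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-12)

  # a gap much larger than kB T leaves only the ground state
  r3 <- thermal_expectation(c(0, 10), c(1.0, 1.3), temperature = 295,
                            levels = 2)
  expect_lt(abs(as.numeric(r3) - 1.0), 1e-6)

  # T = 0: ground state only
  r4 <- thermal_expectation(c(0, 1e-9), c(1.0, 1.3), temperature = 0,
                            levels = 2)
  expect_equal(as.numeric(r4), 1.0)

  expect_error(thermal_expectation(c(0, 1), c(1, 1.2), levels = 5),
               "levels requested")
})

test_that("harmonic thermal expectation equals the well minimum", {
  sol <- solve_bound_states(mk_harmonic_kcal(3000, 1.35), solver_settings())
  r <- thermal_expectation(sol)
  expect_lt(abs(as.numeric(r) - 1.35), 1e-6)
})

test_that("the NQE pipeline quantifies proton delocalization per snapshot", {
  bd <- bridge_definition(1, 2, 3)
  # symmetric double well: quantum <r> is closer to the midpoint than the
  # classical minimum
  sym <- model_params(preset = "solid", lambda_c = 0)
  tr <- mk_snapshot_traj(c(1.0, 0.12, 0))
  rep1 <- nqe_report(tr, bd, model_energy_backend(sym), n_snapshots = 1)
  expect_equal(nrow(rep1), 1L)
  mid <- rep1$d_OO / 2
  expect_lt(abs(rep1$r_quantum - mid), abs(rep1$r_classical_min - mid))

  # acceptor-biased potential, proton caught on the acceptor side: the
  # quantum expectation moves back towards the donor
  acc <- model_params(D_d = 46, D_a = 48, lambda_c = 0)
  tr2 <- mk_snapshot_traj(c(1.58, 0.10, 0))
  rep2 <- nqe_report(tr2, bd, model_energy_backend(acc), n_snapshots = 1)
  expect_gt(rep2$d_DH_classical, 1.5)
  expect_lt(rep2$r_quantum, rep2$d_DH_classical)
})

test_that("full NQE reports are deterministic and one row per snapshot", {
  xyz <- array(0, dim = c(11, 3, 3))
  xyz[, 2, 1] <- seq(0.98, 1.05, length.out = 11)
  xyz[, 2, 2] <- 0.15
  xyz[, 3, 1] <- seq(2.50, 2.60, length.out = 11)
  tr <- trajectory(c("O", "H", "O"), xyz, dt = 10)
  bd <- bridge_definition(1, 2, 3)
  be <- model_energy_backend(model_params())
  r1 <- nqe_report(tr, bd, be, n_snapshots = 5)
  r2 <- nqe_report(tr, bd, be, n_snapshots = 5)
  expect_equal(nrow(r1), 5L)
  expect_identical(r1, r2)
  expect_true(all(r1$r_quantum > 0.7 & r1$r_quantum < 2.0))
})
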