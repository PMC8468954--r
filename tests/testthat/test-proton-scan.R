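test_that("scan positions are an arithmetic sequence at the set increment", {
  d <- scan_positions(0.95, 12, 0.05)
  expect_length(d, 12L)
  expect_equal(d[1], 0.95)
  expect_equal(d[12], 1.50)
  expect_equal(unique(round(diff(d), 12)), 0.05)
  expect_equal(scan_positions(1.1, 1), 1.1)
  expect_error(scan_positions(0.95, 5, 0), "positive")
  expect_error(scan_positions(0.95, 0), "at least 1")
})

test_that("model-backend profiles agree with the model characterization", {
  p <- model_params()
  be <- model_energy_backend(p, R_fixed = 2.55)
  prof <- evaluate_profile(be, scan_positions(0.40, 341, 0.005))
  an <- analyze_profile(prof)
  ch <- characterize_model(p, 2.55)
  expect_false(an$single_minimum)
  expect_equal(an$r_deep, ch$r_min_deep, tolerance = 0.005)
  expect_equal(an$barrier, ch$barrier, tolerance = an$uncertainty + 1e-6)
  expect_equal(an$asymmetry, ch$asymmetry, tolerance = 0.02)
})

test_that("profile CSV round trips and unsorted files are repaired loudly", {
  p <- model_params()
  prof <- evaluate_profile(model_energy_backend(p, 2.55),
                           scan_positions(0.95, 15, 0.05))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  rt <- read_profile_csv(f)
  expect_equal(rt$distance, prof$distance)
  expect_equal(rt$energy, prof$energy, tolerance = 1e-12)

  tab <- read.csv(f)
  write.csv(tab[rev(seq_len(nrow(tab))), ], f, row.names = FALSE)
  expect_warning(rt2 <- read_profile_csv(f), "not sorted")
  expect_equal(rt2$distance, prof$distance)

  # missing tabulated point is a backend failure
  be <- suppressWarnings(csv_energy_backend(f))
  expect_error(backend_energies(be, 0.9617), "no tabulated energy")
})

test_that("profiles must be uniformly spaced and long enough", {
  be <- model_energy_backend(model_params(), 2.55)
  expect_error(evaluate_profile(be, c(0.9, 1.0)), "at least 3")
  expect_error(evaluate_profile(be, c(0.9, 1.0, 1.2)), "uniformly spaced")
  expect_error(evaluate_profile(be, c(1.0, 0.9, 1.1)), "increasing")
})

test_that("symmetric quartic barriers are recovered within the half-step uncertainty", {
  A <- 1000; x0 <- 0.25; ctr <- 1.25
  f <- function(x) A * ((x - ctr)^2 - x0^2)^2
  d <- seq(0.95, 1.55, by = 0.05)
  prof <- evaluate_profile(function(dd) f(dd), d)
  an <- analyze_profile(prof)
  expect_false(an$single_minimum)
  expect_equal(an$asymmetry, 0, tolerance = 1e-9)
  expect_lt(abs(an$barrier - A * x0^4), an$uncertainty + 1e-9)
})

test_that("tilted quartic barriers match a root-finding oracle", {
  A <- 1000; x0 <- 0.25; ctr <- 1.25; B <- 1.0
  f <- function(x) A * ((x - ctr)^2 - x0^2)^2 + B * (x - ctr)
  d <- seq(0.95, 1.55, by = 0.05)
  an <- analyze_profile(evaluate_profile(function(dd) f(dd), d))
  # stationary points of the cubic derivative, independently of the package
  y <- sort(Re(polyroot(c(B, -4 * A * x0^2, 0, 4 * A))))
  E <- f(ctr + y)
  barrier_true <- max(E) - min(E)
  asym_true <- abs(E[3] - E[1])
  expect_lt(abs(an$barrier - barrier_true), an$uncertainty + 1e-9)
  expect_equal(an$asymmetry, asym_true, tolerance = 0.05)
  expect_gte(an$barrier, an$asymmetry)
})

test_that("refining the increment shrinks the uncertainty and converges the barrier", {
  A <- 800; x0 <- 0.22; ctr <- 1.2; B <- 0.8
  f <- function(x) A * ((x - ctr)^2 - x0^2)^2 + B * (x - ctr)
  y <- sort(Re(polyroot(c(B, -4 * A * x0^2, 0, 4 * A))))
  barrier_true <- max(f(ctr + y)) - min(f(ctr + y))
  incs <- c(0.05, 0.025, 0.0125, 0.00625)
  res <- t(vapply(incs, function(h) {
    d <- seq(0.9, 1.5, by = h)
    an <- analyze_profile(evaluate_profile(function(dd) f(dd), d))
    c(an$barrier, an$uncertainty)
  }, numeric(2)))
  expect_true(all(diff(res[, 2]) < 0))                 # monotone shrink
  expect_lt(abs(res[4, 1] - barrier_true), res[4, 2] + 1e-9)
  expect_lt(abs(res[4, 1] - barrier_true), abs(res[1, 1] - barrier_true) + 1e-9)
})

test_that("analysis is invariant under a constant energy shift", {
  f <- function(x) 500 * ((x - 1.2)^2 - 0.04)^2
  d <- seq(0.9, 1.5, by = 0.05)
  a1 <- analyze_profile(evaluate_profile(function(dd) f(dd), d))
  a2 <- analyze_profile(evaluate_profile(function(dd) f(dd) + 123.456, d))
  expect_equal(a1$barrier, a2$barrier)
  expect_equal(a1$r_deep, a2$r_deep)
  expect_equal(a1$relative_energy, a2$relative_energy, tolerance = 1e-9)
})

test_that("monotone profiles are flagged as single-minimum", {
  d <- scan_positions(0.9, 10, 0.05)
  prof <- evaluate_profile(function(dd) 10 * dd, d)
  an <- analyze_profile(prof)
  expect_true(an$single_minimum)
  expect_true(is.na(an$barrier))
})
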