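test_that("bridge distances are plain Euclidean geometry", {
  xyz <- array(0, dim = c(2, 3, 3))
  # frame 1: colinear O-H...O; frame 2: right angle at the proton
  xyz[1, 2, 1] <- 1.0; xyz[1, 3, 1] <- 2.55
  xyz[2, 2, 1] <- 1.0; xyz[2, 3, ] <- c(1.0, 1.2, 0)
  tr <- trajectory(c("O", "H", "O"), xyz, dt = 1)
  ser <- compute_bridge_series(tr, bridge_definition(1, 2, 3))
  expect_equal(nrow(ser), 2L)
  expect_equal(unlist(ser[1, c("d_OO", "d_DH", "d_HA")], use.names = FALSE),
               c(2.55, 1.0, 1.55))
  expect_equal(unlist(ser[2, c("d_OO", "d_DH", "d_HA")], use.names = FALSE),
               c(sqrt(2.44), 1.0, 1.2))
  # triangle inequality holds by construction
  expect_true(all(abs(ser$d_DH - ser$d_HA) <= ser$d_OO + 1e-12))
  expect_true(all(ser$d_OO <= ser$d_DH + ser$d_HA + 1e-12))
})

test_that("possession fractions count the Voronoi criterion with donor ties", {
  s <- mk_series(d_DH = c(1.0, 1.0, 1.6), d_HA = c(1.5, 1.5, 1.0))
  ps <- possession_statistics(s)
  expect_equal(ps$donor_fraction, 100 * 2 / 3)
  expect_equal(ps$donor_fraction + ps$acceptor_fraction, 100)
  expect_equal(ps$n_tie, 0L)

  all_donor <- possession_statistics(mk_series(rep(1, 5), rep(1.5, 5)))
  expect_equal(all_donor$donor_fraction, 100)
  expect_equal(all_donor$acceptor_fraction, 0)

  with_tie <- possession_statistics(mk_series(c(1.2, 1.0), c(1.2, 1.5)))
  expect_equal(with_tie$n_tie, 1L)
  expect_equal(with_tie$donor_fraction, 100)

  expect_error(possession_statistics(mk_series(numeric(0), numeric(0))),
               "empty")
})

test_that("possession statistics are invariant under frame reordering", {
  set.seed(21)
  s <- mk_series(runif(200, 0.9, 1.7), runif(200, 0.9, 1.7))
  perm <- sample(nrow(s))
  s2 <- s[perm, ]; class(s2) <- class(s)
  expect_equal(possession_statistics(s2)$donor_fraction,
               possession_statistics(s)$donor_fraction)
})

test_that("transfer events are dwell-filtered sign changes", {
  # one persistent crossing
  s <- mk_series(d_DH = c(rep(1.0, 10), rep(1.6, 10)),
                 d_HA = c(rep(1.6, 10), rep(1.0, 10)), dt = 5)
  ev <- detect_transfer_events(s, min_dwell = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "donor_to_acceptor")
  expect_equal(ev$onset_time, 50)

  # a recrossing shorter than the dwell is discarded
  s2 <- mk_series(d_DH = c(rep(1.0, 10), 1.6, rep(1.0, 10)),
                  d_HA = c(rep(1.6, 10), 1.0, rep(1.6, 10)), dt = 5)
  expect_equal(nrow(detect_transfer_events(s2, min_dwell = 10)), 0L)

  # constant sign: nothing
  s3 <- mk_series(rep(1, 50), rep(1.5, 50))
  expect_equal(nrow(detect_transfer_events(s3, min_dwell = 0)), 0L)

  # directions alternate and counts are translation invariant
  dh <- rep(c(1.0, 1.6), each = 20, times = 3)
  s4 <- mk_series(dh, rev(dh), dt = 2)
  ev4 <- detect_transfer_events(s4, min_dwell = 10)
  expect_gt(nrow(ev4), 1L)
  expect_true(all(ev4$direction[-1] != ev4$direction[-nrow(ev4)]))
  s5 <- s4; s5$time <- s5$time + 1e4
  ev5 <- detect_transfer_events(s5, min_dwell = 10)
  expect_equal(nrow(ev5), nrow(ev4))
})

test_that("joint histograms conserve probability mass exactly", {
  set.seed(31)
  n <- 5000
  s1 <- mk_series(runif(n, 0.85, 1.75), rep(1.2, n))
  s2 <- mk_series(runif(n, 0.85, 1.75), rep(1.2, n))
  h <- joint_histogram(s1, s2, bin_width = 0.02)
  expect_equal(sum(h$density) * 0.02^2, 1, tolerance = 1e-12)
  expect_true(all(h$density >= 0))

  # all frames identical -> single occupied bin with density 1/width^2
  s3 <- mk_series(rep(1.111, 50), rep(1.4, 50))
  h3 <- joint_histogram(s3, s3, bin_width = 0.05)
  expect_equal(max(h3$density), 1 / 0.05^2)
  expect_equal(sum(h3$density > 0), 1L)

  expect_error(joint_histogram(s1, mk_series(1, 2)), "lengths differ")
})

test_that("uniform samples give a flat histogram within multinomial error", {
  set.seed(41)
  n <- 40000
  s1 <- mk_series(runif(n, 0.8, 1.8), rep(1.2, n))
  s2 <- mk_series(runif(n, 0.8, 1.8), rep(1.2, n))
  h <- joint_histogram(s1, s2, bin_width = 0.1)
  # expected density 1 everywhere; per-bin 5-sigma multinomial band
  p <- 0.01
  se <- sqrt(n * p * (1 - p)) / (n * 0.1^2)
  expect_lt(max(abs(h$density - 1)), 5 * se)
})

test_that("out-of-range samples are clamped into edge bins and reported", {
  s1 <- mk_series(c(0.5, 1.2, 2.5), rep(1.2, 3))
  s2 <- mk_series(rep(1.2, 3), rep(1.3, 3))
  expect_message(h <- joint_histogram(s1, s2), "out-of-range")
  expect_equal(attr(h, "n_clamped"), 2L)
  expect_equal(sum(h$density) * h$bin_width^2, 1, tolerance = 1e-12)
})

test_that("synchronicity quadrants sum to 100 and detect trivial cases", {
  both_donor <- mk_series(rep(1, 10), rep(1.5, 10))
  sy <- synchronicity_summary(both_donor, both_donor)
  expect_equal(sy$DD, 100)
  expect_equal(sy$DD + sy$DA + sy$AD + sy$AA, 100)
  expect_equal(sy$center, 0)

  # all |q| > eps -> empty center
  far <- mk_series(c(1, 1.6), c(1.5, 1.0))
  expect_equal(synchronicity_summary(far, far, eps = 0.05)$center, 0)
  # both near the midpoint -> full center
  near <- mk_series(rep(1.2, 4), rep(1.21, 4))
  expect_equal(synchronicity_summary(near, near, eps = 0.05)$center, 100)
})

test_that("negative coupling favours concerted quadrants as in quadrature", {
  p <- model_params(preset = "lowbarrier", lambda_c = -2)
  out <- simulate_bridges(p, simulation_settings(production_length = 100,
                                                 output_stride = 5, seed = 11))
  tr <- embed_trajectory(out)
  bd <- embedded_bridge_definitions()
  sy <- synchronicity_summary(compute_bridge_series(tr, bd[[1]]),
                              compute_bridge_series(tr, bd[[2]]))
  expect_gt(sy$DD + sy$AA, sy$DA + sy$AD)
  q <- boltzmann_quadrant_stats(p)
  expect_gt(q$DD + q$AA, q$DA + q$AD)
  # simulated and quadrature concertedness agree reasonably
  expect_equal(sy$DD + sy$AA, q$DD + q$AA, tolerance = 0.1)
})
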