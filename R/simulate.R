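#' Settings for the surrogate Langevin simulation
#'
#' @param temperature Bath temperature, Kelvin.
#' @param time_step Integration time step, fs.  The default 0.25 fs
#'   resolves a 3400 cm^-1 O-H stretch with more than 30 samples per
#'   period.
#' @param friction Langevin friction, 1/ps.
#' @param n_equilibration_steps Number of initial steps discarded before
#'   frames are recorded.
#' @param production_length Length of the recorded production run, ps.
#' @param output_stride Record every \code{output_stride}-th step.
#' @param seed Integer seed; the run is bitwise reproducible given the
#'   seed.  \code{NULL} leaves the R random-number state untouched.
#' @return An object of class \code{"simulation_settings"}.
#' @export
simulation_settings <- function(temperature = 295, time_step = 0.25,
                                friction = 1.0,
                                n_equilibration_steps = 10000,
                                production_length = 21,
                                output_stride = 1L, seed = NULL) {
  if (time_step <= 0) stop("'time_step' must be positive")
  if (production_length <= 0) stop("'production_length' must be positive")
  if (temperature < 0) stop("'temperature' must be non-negative")
  if (friction < 0) stop("'friction' must be non-negative")
  if (n_equilibration_steps < 0) stop("'n_equilibration_steps' must be >= 0")
  if (output_stride < 1) stop("'output_stride' must be >= 1")
  s <- list(temperature = temperature, time_step = time_step,
            friction = friction,
            n_equilibration_steps = as.integer(n_equilibration_steps),
            production_length = production_length,
            output_stride = as.integer(output_stride),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(s) <- "simulation_settings"
  s
}

# analytic gradient of the single-bridge potential
.bridge_gradient <- function(p, r, R) {
  ed <- exp(-p$a_d * (r - p$rho))
  ea <- exp(-p$a_a * (R - r - p$rho))
  c(2 * p$D_d * p$a_d * ed * (1 - ed) - 2 * p$D_a * p$a_a * ea * (1 - ea),
    2 * p$D_a * p$a_a * ea * (1 - ea) + p$k_R * (R - p$R_0))
}

# relaxed (r, R) minimum of one uncoupled bridge; Newton-polished so the
# residual gradient is at machine-precision level (a clean stationary
# start makes zero-temperature runs exact fixed points)
.bridge_minimum <- function(params) {
  obj <- function(z) .bridge_potential(params, z[1], z[2])
  fit <- stats::optim(c(params$rho + 0.05, params$R_0 - 0.1), obj,
                      method = "L-BFGS-B",
                      lower = c(0.5, 2 * params$rho + 0.1),
                      upper = c(2.0, params$R_0 + 0.8))
  z <- fit$par
  h <- 1e-5
  for (it in 1:8) {
    g <- .bridge_gradient(params, z[1], z[2])
    if (max(abs(g)) < 1e-11) break
    H <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      H[, j] <- (.bridge_gradient(params, z[1] + e[1], z[2] + e[2]) -
                 .bridge_gradient(params, z[1] - e[1], z[2] - e[2])) / (2 * h)
    }
    step <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) g * 0)
    if (any(!is.finite(step))) break
    z <- z - step
  }
  z
}

#' Propagate the two-bridge model with Langevin dynamics
#'
#' Runs BAOAB-split Langevin dynamics (velocity half-kicks, half-drifts
#' and an exact Ornstein-Uhlenbeck noise step) on the four reduced
#' coordinates of the surrogate model, starting from the relaxed geometry
#' with zero velocities.  Equilibration frames are discarded; production
#' frames are stored every \code{output_stride} steps with absolute time
#' stamps (time zero is the start of equilibration).
#'
#' @param params A [model_params()] object.
#' @param settings A [simulation_settings()] object.
#' @return An object of class \code{"bridge_states"}: a list with
#'   \code{time} (fs), matrices \code{r}, \code{R}, \code{v_r},
#'   \code{v_R} (frames x 2 bridges, Angstrom and A/fs), and the
#'   generating \code{params}/\code{settings}.
#' @seealso [embed_trajectory()] to convert to labelled atomic
#'   coordinates, [boltzmann_bridge_stats()] for the stationary reference.
#' @export
simulate_bridges <- function(params = model_params(),
                             settings = simulation_settings()) {
  stopifnot(inherits(params, "model_params"),
            inherits(settings, "simulation_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  n_prod <- as.integer(round(settings$production_length * 1000 /
                               settings$time_step))
  x0 <- .bridge_minimum(params)
  state0 <- c(x0[1], x0[2], x0[1], x0[2], rep(0, 4))
  gamma_fs <- settings$friction * 1e-3
  res <- langevin_baoab_cpp(state0, unclass(params),
                            settings$n_equilibration_steps, n_prod,
                            settings$output_stride, settings$time_step,
                            gamma_fs, .kB * settings$temperature)
  if (!isTRUE(res$ok))
    stop(sprintf("integrator diverged (non-finite energy or coordinate) at step %d",
                 res$step))
  fr <- res$frames
  r <- fr[, c(1, 3), drop = FALSE]
  R <- fr[, c(2, 4), drop = FALSE]
  if (any(r <= 0) || any(r >= R))
    stop("invariant violation: a stored frame has r <= 0 or r >= R")
  out <- list(time = res$time, r = r, R = R,
              v_r = fr[, c(5, 7), drop = FALSE],
              v_R = fr[, c(6, 8), drop = FALSE],
              params = params, settings = settings)
  class(out) <- "bridge_states"
  out
}

#' @export
print.bridge_states <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("Surrogate bridge trajectory: %d frames, dt = %g fs (stride %d)\n",
              n, x$settings$time_step * x$settings$output_stride,
              x$settings$output_stride))
  cat(sprintf("  t = %.1f .. %.1f fs, T = %g K\n",
              x$time[1], x$time[n], x$settings$temperature))
  for (b in 1:2)
    cat(sprintf("  bridge %d: mean r = %.3f A, mean R = %.3f A\n",
                b, mean(x$r[, b]), mean(x$R[, b])))
  invisible(x)
}

#' Embed reduced bridge states as a labelled atomic trajectory
#'
#' Places each bridge on its own line parallel to the x axis: bridge 1 at
#' y = 0 with donor O at the origin, H at (r1, 0, 0) and acceptor O at
#' (R1, 0, 0); bridge 2 identically at y = 5 Angstrom.  Velocities are
#' embedded the same way.
#'
#' @param states A \code{"bridge_states"} object from
#'   [simulate_bridges()].
#' @return A [trajectory()] with six atoms (O, H, O, O, H, O) per frame.
#' @export
embed_trajectory <- function(states) {
  stopifnot(inherits(states, "bridge_states"))
  n <- length(states$time)
  xyz <- array(0, dim = c(n, 6L, 3L))
  vel <- array(0, dim = c(n, 6L, 3L))
  for (b in 1:2) {
    a0 <- 3L * (b - 1L)
    y <- 5.0 * (b - 1L)
    xyz[, a0 + 1L, 2] <- y
    xyz[, a0 + 2L, 1] <- states$r[, b]
    xyz[, a0 + 2L, 2] <- y
    xyz[, a0 + 3L, 1] <- states$R[, b]
    xyz[, a0 + 3L, 2] <- y
    vel[, a0 + 2L, 1] <- states$v_r[, b]
    vel[, a0 + 3L, 1] <- states$v_R[, b]
  }
  dt <- states$settings$time_step * states$settings$output_stride
  trajectory(labels = c("O", "H", "O", "O", "H", "O"), xyz = xyz,
             dt = dt, t0 = states$time[1], velocities = vel)
}

#' Bridge definitions for the embedded surrogate trajectory
#'
#' @return A list of two [bridge_definition()] objects matching the atom
#'   layout produced by [embed_trajectory()].
#' @export
embedded_bridge_definitions <- function() {
  list(bridge_definition(1L, 2L, 3L, label = "bridge 1"),
       bridge_definition(4L, 5L, 6L, label = "bridge 2"))
}

#' Write a key-value run manifest
#'
#' Records the full parameter set, settings and seed of a simulation in a
#' plain-text \code{key = value} file so a run can be reproduced exactly.
#'
#' @param states A \code{"bridge_states"} object.
#' @param path Output file path.
#' @export
write_run_manifest <- function(states, path) {
  stopifnot(inherits(states, "bridge_states"))
  p <- states$params; s <- states$settings
  kv <- c(
    vapply(setdiff(names(unclass(p)), "preset"),
           function(nm) sprintf("%s = %.17g", nm, p[[nm]]), character(1)),
    sprintf("preset = %s", p$preset),
    sprintf("temperature = %.17g", s$temperature),
    sprintf("time_step = %.17g", s$time_step),
    sprintf("friction = %.17g", s$friction),
    sprintf("n_equilibration_steps = %d", s$n_equilibration_steps),
    sprintf("production_length = %.17g", s$production_length),
    sprintf("output_stride = %d", s$output_stride),
    sprintf("seed = %s", if (is.null(s$seed)) "NA" else as.character(s$seed)))
  writeLines(kv, path)
  invisible(path)
}

#' Read a key-value configuration file
#'
#' Parses a minimal INI-style file (\code{key = value} lines, \code{#}
#' comments) into [model_params()] and [simulation_settings()] objects.
#' Unknown keys are an error, so typos do not silently fall back to
#' defaults.
#'
#' @param path Configuration file path.
#' @return List with elements \code{params} and \code{settings}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  par_keys <- c("D_d", "D_a", "a_d", "a_a", "rho", "k_R", "R_0",
                "lambda_c", "m_H", "m_R", "preset")
  set_keys <- c("temperature", "time_step", "friction",
                "n_equilibration_steps", "production_length",
                "output_stride", "seed")
  unknown <- setdiff(keys, c(par_keys, set_keys))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  pick <- function(valid) {
    sel <- keys %in% valid
    args <- as.list(vals[sel])
    names(args) <- keys[sel]
    num <- names(args) != "preset"
    args[num] <- lapply(args[num], as.numeric)
    args
  }
  sargs <- pick(set_keys)
  if (!is.null(sargs$seed) && is.na(sargs$seed)) sargs$seed <- NULL
  list(params = do.call(model_params, pick(par_keys)),
       settings = do.call(simulation_settings, sargs))
}
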