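#' Solver options
#'
#' Options for the adaptive stiff integrator. The default relative tolerance
#' is 1e-12 (tight enough that halving it moves endpoints by far less than
#' 1e-6 relative); the absolute tolerance floor is far below the smallest
#' meaningful concentration in the model.
#'
#' @param rtol Relative local error tolerance.
#' @param atol Absolute local error tolerance, mmol/ml.
#' @param save_dt Output cadence, s.
#' @param h_init Initial step size, s.
#' @param max_steps Step budget per input segment.
#' @return A list of class `solver_opts`.
#' @export
solver_opts <- function(rtol = 1e-12, atol = 1e-26, save_dt = 60,
                        h_init = 1e-2, max_steps = 5e7) {
  stopifnot(rtol > 0, atol >= 0, save_dt != 0, h_init > 0)
  structure(list(rtol = rtol, atol = atol, save_dt = save_dt,
                 h_init = h_init, max_steps = max_steps),
            class = "solver_opts")
}

#' Integrate the consortium over an input schedule
#'
#' Adaptive integration of the 13-component consortium ODE, restarted at
#' every input breakpoint so that step-size control never straddles a
#' discontinuity. Every breakpoint appears exactly in the returned time
#' grid; between breakpoints states are saved on the `save_dt` cadence.
#'
#' @param params A `circuit_params` object.
#' @param schedule An `input_schedule`.
#' @param init Initial state (length 13, non-negative). Defaults to
#'   [pre_equilibrate()] of `params`.
#' @param opts Solver options from [solver_opts()].
#' @return An object of class `trajectory`: list with `time` (s), `states`
#'   (matrix, one row per time point, columns [state_names()]), `schedule`,
#'   `params`, and `solver` (tolerances and step statistics).
#' @export
integrate_circuit <- function(params, schedule, init = NULL,
                              opts = solver_opts()) {
  validate_params(params)
  stopifnot(inherits(schedule, "input_schedule"))
  if (is.null(init)) init <- pre_equilibrate(params, opts = opts)
  init <- as.numeric(init)
  if (length(init) != 13L) stop("init must have 13 components")
  if (any(!is.finite(init)) || any(init < 0))
    stop("init must be finite and non-negative")
  pv <- expand_params(params)
  bp <- attr(schedule, "breakpoints_s")
  y <- init
  times <- numeric(0)
  states <- NULL
  nsteps <- 0
  nreject <- 0
  for (i in seq_len(nrow(schedule))) {
    res <- rosenbrock_segment(y, bp[i], bp[i + 1], pv,
                              schedule$R[i] * params$input_conc,
                              schedule$S[i] * params$input_conc,
                              clamp_medium = FALSE,
                              rtol = opts$rtol, atol = opts$atol,
                              save_dt = opts$save_dt, h_init = opts$h_init,
                              max_steps = opts$max_steps)
    keep <- if (i == 1) seq_along(res$time) else seq_along(res$time)[-1]
    times <- c(times, res$time[keep])
    states <- rbind(states, res$states[keep, , drop = FALSE])
    y <- res$states[nrow(res$states), ]
    nsteps <- nsteps + res$nsteps
    nreject <- nreject + res$nreject
  }
  colnames(states) <- state_names()
  structure(list(time = times, states = states, schedule = schedule,
                 params = params,
                 solver = list(rtol = opts$rtol, atol = opts$atol,
                               save_dt = opts$save_dt, nsteps = nsteps,
                               nreject = nreject)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %.2f h, %d accepted steps\n",
              length(x$time), max(x$time) / 3600, x$solver$nsteps))
  invisible(x)
}

#' Flip-flop readout series
#'
#' Extracts the circuit readout Phi(t) = phi_x(t) - phi_y(t) (the difference
#' between the prepro alpha-factor concentrations of the two NOT cells)
#' together with the schedule breakpoints and the amplitude extrema
#' m = min Phi, M = max Phi over the run.
#'
#' @param trajectory A `trajectory` from [integrate_circuit()].
#' @return An object of class `phi_series`: list with `time` (s), `phi`
#'   (mmol/ml), `breakpoints` (s), `m`, `M`.
#' @export
phi_of <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  phi <- trajectory$states[, "phi_x"] - trajectory$states[, "phi_y"]
  phi_series(trajectory$time, phi,
             attr(trajectory$schedule, "breakpoints_s"))
}

#' Construct a readout series directly
#'
#' Low-level constructor used by [phi_of()] and the fixture generator.
#'
#' @param time Time grid, s (strictly increasing).
#' @param phi Readout values, mmol/ml.
#' @param breakpoints Segment boundaries, s (must be covered by `time`).
#' @return A `phi_series` object.
#' @export
phi_series <- function(time, phi, breakpoints) {
  if (length(time) != length(phi)) stop("time and phi lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (min(breakpoints) < min(time) - 1e-9 ||
      max(breakpoints) > max(time) + 1e-9)
    stop("phi series does not cover the breakpoints")
  structure(list(time = time, phi = phi,
                 breakpoints = as.numeric(breakpoints),
                 m = min(phi), M = max(phi)),
            class = "phi_series")
}

#' @export
print.phi_series <- function(x, ...) {
  cat(sprintf("<phi_series> %d points, m = %.3g, M = %.3g mmol/ml\n",
              length(x$time), x$m, x$M))
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' One row per saved time point; columns `time_s` plus every state
#' component named as in [state_names()].
#'
#' @param trajectory A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time_s = trajectory$time, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a readout series as CSV
#'
#' Two columns: `time_min`, `phi`.
#'
#' @param phi A `phi_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phi_csv <- function(phi, path) {
  utils::write.csv(data.frame(time_min = phi$time / 60, phi = phi$phi),
                   path, row.names = FALSE)
  invisible(path)
}
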