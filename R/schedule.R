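#' Piecewise-constant input schedule
#'
#' An input schedule is an ordered list of contiguous segments starting at
#' t = 0, each holding the logical input pair (R, S) constant for a positive
#' duration. The invalid SR-latch combination R = S = 1 is rejected.
#'
#' @param durations_s Numeric vector of segment durations, s (> 0).
#' @param R,S Integer vectors of logical input levels (0/1), one per
#'   segment.
#' @return An object of class `input_schedule`: a data frame with columns
#'   `duration_s`, `R`, `S` and attribute `breakpoints_s` (cumulative
#'   segment boundaries including 0).
#' @export
input_schedule <- function(durations_s, R, S) {
  if (length(durations_s) == 0) stop("schedule needs at least one segment")
  if (length(R) != length(durations_s) || length(S) != length(durations_s))
    stop("durations, R and S must have equal length")
  if (any(!is.finite(durations_s)) || any(durations_s <= 0))
    stop("durations must be positive and finite")
  if (!all(R %in% c(0, 1)) || !all(S %in% c(0, 1)))
    stop("R and S levels must be 0 or 1")
  if (any(R == 1 & S == 1))
    stop("R = S = 1 is an invalid flip-flop input")
  sch <- data.frame(duration_s = as.numeric(durations_s),
                    R = as.integer(R), S = as.integer(S))
  attr(sch, "breakpoints_s") <- c(0, cumsum(sch$duration_s))
  class(sch) <- c("input_schedule", "data.frame")
  sch
}

#' Canonical write/hold protocol
#'
#' The canonical SR protocol: write 1 with (1,0) for `activation_h` hours,
#' hold with (0,0) for `memory_h` hours, write 0 with (0,1), hold again,
#' repeated `repeats` times. With the defaults (3 h, 12 h, 1 repeat) the
#' breakpoints fall at 0, 180, 900, 1080 and 1800 min; with (3 h, 20 h, 3
#' repeats) the total span is 138 h.
#'
#' @param activation_h Duration of each write segment, hours.
#' @param memory_h Duration of each hold segment, hours.
#' @param repeats Number of write-1/hold/write-0/hold cycles.
#' @return An `input_schedule`.
#' @export
canonical_sequence <- function(activation_h = 3, memory_h = 12, repeats = 1) {
  if (activation_h <= 0 || memory_h <= 0) stop("durations must be > 0")
  if (repeats < 1) stop("repeats must be >= 1")
  act <- activation_h * 3600
  mem <- memory_h * 3600
  input_schedule(rep(c(act, mem, act, mem), repeats),
                 R = rep(c(1, 0, 0, 0), repeats),
                 S = rep(c(0, 0, 1, 0), repeats))
}

#' Total schedule duration
#'
#' @param schedule An `input_schedule`.
#' @return Total duration, s.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "input_schedule"))
  sum(schedule$duration_s)
}

#' Input concentrations at a time point
#'
#' Looks up the segment containing `t` and scales its logical levels by
#' `input_conc`. Breakpoints are right-continuous: at a segment boundary the
#' new segment's levels apply.
#'
#' @param schedule An `input_schedule`.
#' @param t Time, s; must lie in `[0, schedule_duration(schedule)]`.
#' @param input_conc Concentration of a logical 1, ug/ml.
#' @return Named numeric pair `c(R = , S = )`, ug/ml.
#' @export
inputs_at <- function(schedule, t, input_conc) {
  stopifnot(inherits(schedule, "input_schedule"))
  bp <- attr(schedule, "breakpoints_s")
  if (t < 0 || t > bp[length(bp)])
    stop("t = ", t, " s outside schedule [0, ", bp[length(bp)], "]")
  # right-continuous: segment i covers [bp[i], bp[i+1])
  i <- findInterval(t, bp, rightmost.closed = TRUE)
  i <- min(i, nrow(schedule))
  c(R = schedule$R[i] * input_conc, S = schedule$S[i] * input_conc)
}

#' Pre-equilibrate the consortium without communication
#'
#' Runs each cell type to its internal equilibrium with medium coupling
#' severed: the medium pools are clamped at zero (NOT cells see no ligand)
#' and inputs are held at (0, 0) for `hours` hours. The returned state is
#' the combined consortium state with the clock reset to 0 and the medium
#' pools empty, the standard initial condition before the first write input.
#'
#' @param params A `circuit_params` object.
#' @param hours Equilibration horizon, hours.
#' @param init Optional starting state (defaults to the zero state; feeding
#'   a pre-equilibrated state back reproduces it, up to solver tolerance).
#' @param opts Solver options from [solver_opts()].
#' @return Named state vector of length 13.
#' @export
pre_equilibrate <- function(params, hours = 7, init = NULL,
                            opts = solver_opts()) {
  validate_params(params)
  pv <- expand_params(params)
  y0 <- if (is.null(init)) numeric(13) else as.numeric(init)
  if (length(y0) != 13L || any(y0 < 0)) stop("init must be a non-negative state")
  res <- rosenbrock_segment(y0, 0, hours * 3600, pv, 0, 0,
                            clamp_medium = TRUE, rtol = opts$rtol,
                            atol = opts$atol, save_dt = -1,
                            h_init = opts$h_init, max_steps = opts$max_steps)
  s <- res$states[nrow(res$states), ]
  s[11:12] <- 0
  s[s < 0 & s > -1e-30] <- 0
  names(s) <- state_names()
  s
}
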