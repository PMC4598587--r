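# Shared fixtures. Tests use reduced tolerances/grids where the contract
# under test does not depend on them; the acceptance tests use the full
# settings.

fast_opts <- function(rtol = 1e-10, save_dt = 60)
  solver_opts(rtol = rtol, save_dt = save_dt)

# a random non-negative state on the scales the model actually visits
random_state <- function() {
  sc <- c(1e-7, 1e-8, 1e-7, 1e-8, 1e-9, 1e-10, 1e-9, 1e-9, 1e-10, 1e-9,
          1e-11, 1e-11, 1e-9)
  stats::runif(13) * sc
}

# piecewise-constant phi series; jumps encoded with double samples so
# trapezoidal quadrature resolves them (mirrors ideal_signal's encoding)
step_phi <- function(values, times_s, breakpoints = canonical_breakpoints(),
                     dt_s = 60) {
  stopifnot(length(values) == length(times_s))
  grid <- sort(unique(c(seq(breakpoints[1], breakpoints[5], by = dt_s),
                        breakpoints, times_s, times_s + 1e-6)))
  f <- stats::stepfun(times_s[-1] + 1e-7, values)
  phi_series(grid, f(grid), breakpoints)
}

canonical_30h <- function() canonical_sequence(3, 12, 1)
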