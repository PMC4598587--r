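# Simulation-based stability classification, as in the source phase
# portraits: integrate a grid of medium-pheromone initial conditions to a
# long horizon under (0,0) inputs and cluster the terminal points.

#' Default initial-condition grid for stability runs
#'
#' Log-spaced pairs of medium pheromone concentrations spanning the range
#' the trajectories actually visit. Exactly-diagonal pairs (X = Y) are
#' excluded: in the bistable regime they converge to the symmetric saddle
#' and would contaminate the equilibrium clustering with a third terminal
#' point.
#'
#' @param n Grid points per axis.
#' @param lo,hi Range of each coordinate, mmol/ml.
#' @return A matrix with columns `X_med`, `Y_med`.
#' @export
default_ic_grid <- function(n = 5, lo = 1e-15, hi = 1e-5) {
  g <- 10^seq(log10(lo), log10(hi), length.out = n)
  grid <- expand.grid(X_med = g, Y_med = g)
  grid <- grid[grid$X_med != grid$Y_med, , drop = FALSE]
  as.matrix(grid)
}

#' Classify the circuit as bistable or monostable
#'
#' Integrates every initial condition under sustained (0, 0) inputs to the
#' horizon, starting from the pre-equilibrated intracellular state with the
#' medium pools set to the grid point. Terminal `(X_med, Y_med)` points are
#' clustered by single linkage in log space; two clusters separated by at
#' least `separation_factor` in either coordinate mean bistable. Runs whose
#' right-hand side has not decayed at the horizon are flagged inconclusive
#' rather than silently classified.
#'
#' @param params A `circuit_params` object.
#' @param ic_grid Matrix of `(X_med, Y_med)` initial conditions;
#'   default [default_ic_grid()].
#' @param horizon_h Integration horizon, hours (default 300).
#' @param separation_factor Fold-separation defining distinct equilibria.
#' @param conv_rate Convergence criterion: a run counts as converged when
#'   every component's relative rate of change at the horizon is below this
#'   value (1/s), i.e. the residual relaxation time far exceeds the
#'   horizon. Near the bistability boundary runs slow down critically and
#'   are honestly flagged inconclusive.
#' @param opts Solver options; stability runs default to a looser tolerance
#'   than trajectory scoring since only the attractor is needed.
#' @return An object of class `stability_report`: list with
#'   `classification` (`"bistable"`, `"monostable"` or `"inconclusive"`),
#'   `equilibria` (matrix of cluster centroids in `(X_med, Y_med)`),
#'   `basin` (cluster index per initial condition), `terminal` (matrix of
#'   terminal points), `converged` (logical per run), and `memory_time_min`
#'   (`Inf` for bistable, `NA` here; see [memory_time()]).
#' @export
classify_stability <- function(params, ic_grid = default_ic_grid(),
                               horizon_h = 300, separation_factor = 3,
                               conv_rate = 1e-8,
                               opts = solver_opts(rtol = 1e-8, atol = 1e-28,
                                                  save_dt = -1)) {
  validate_params(params)
  ic_grid <- as.matrix(ic_grid)
  if (ncol(ic_grid) != 2L || nrow(ic_grid) < 1L)
    stop("ic_grid must be a matrix with columns X_med, Y_med")
  pv <- expand_params(params)
  base <- pre_equilibrate(params, opts = solver_opts(rtol = 1e-10))
  horizon_s <- horizon_h * 3600
  nruns <- nrow(ic_grid)
  terminal <- matrix(NA_real_, nruns, 2,
                     dimnames = list(NULL, c("X_med", "Y_med")))
  converged <- logical(nruns)
  for (i in seq_len(nruns)) {
    y0 <- base
    y0[11] <- ic_grid[i, 1]
    y0[12] <- ic_grid[i, 2]
    res <- rosenbrock_segment(y0, 0, horizon_s, pv, 0, 0, FALSE,
                              opts$rtol, opts$atol, -1, opts$h_init,
                              opts$max_steps)
    yend <- res$states[nrow(res$states), ]
    terminal[i, ] <- yend[11:12]
    dy <- circuit_rhs_cpp(yend, pv, 0, 0, FALSE)
    scale <- pmax(abs(yend), 1e-6 * max(abs(yend)), 1e-30)
    converged[i] <- max(abs(dy) / scale) < conv_rate
  }

  floor_c <- 1e-30
  lg <- log10(pmax(terminal, floor_c))
  thr <- log10(separation_factor)
  # single-linkage clustering under Chebyshev distance in log coordinates
  cl <- stats::cutree(stats::hclust(stats::dist(lg, method = "maximum"),
                                    method = "single"), h = thr)
  if (nruns == 1L) cl <- 1L
  ncl <- length(unique(cl))
  centro <- t(vapply(sort(unique(cl)), function(k)
    10^colMeans(lg[cl == k, , drop = FALSE]), numeric(2)))
  colnames(centro) <- c("X_med", "Y_med")

  classification <- if (!all(converged)) "inconclusive"
  else if (ncl >= 2) "bistable" else "monostable"
  structure(list(classification = classification, equilibria = centro,
                 basin = cl, terminal = terminal, converged = converged,
                 separation_factor = separation_factor,
                 horizon_h = horizon_h),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (%d equilibria, %d/%d runs converged)\n",
              x$classification, nrow(x$equilibria), sum(x$converged),
              length(x$converged)))
  invisible(x)
}

#' Transient memory time
#'
#' Duration for which the readout stays negative during the first hold
#' window after a (1, 0) write, the standard measure of transient memory.
#' If the readout never returns to zero within the window (persistent
#' memory), the full window length is returned.
#'
#' @param params A `circuit_params` object.
#' A symmetric monostable circuit relaxes toward the diagonal with the
#' readout approaching 0 from below but never crossing it, so the memory
#' time is measured up to a small relative threshold: memory ends when the
#' readout first exceeds `-rel_threshold * |min(phi)|`.
#'
#' @param schedule An `input_schedule` starting with a (1, 0) segment
#'   followed by a (0, 0) segment; default 3 h write + 12 h hold.
#' @param rel_threshold Fraction of the write-depth at which the state is
#'   considered erased.
#' @param opts Solver options.
#' @return Memory time in minutes.
#' @export
memory_time <- function(params, schedule = NULL, rel_threshold = 1e-3,
                        opts = solver_opts(rtol = 1e-10, save_dt = 60)) {
  if (is.null(schedule))
    schedule <- input_schedule(c(3, 12) * 3600, R = c(1, 0), S = c(0, 0))
  stopifnot(inherits(schedule, "input_schedule"))
  if (!(schedule$R[1] == 1 && schedule$S[1] == 0) ||
      nrow(schedule) < 2 ||
      !(schedule$R[2] == 0 && schedule$S[2] == 0))
    stop("schedule must start with a (1,0) write followed by a (0,0) hold")
  traj <- integrate_circuit(params, schedule, opts = opts)
  phi <- phi_of(traj)
  bp <- attr(schedule, "breakpoints_s")
  w <- .phi_window(phi, bp[2], bp[3])
  thr <- -rel_threshold * abs(min(phi$phi))
  neg <- w$v < thr
  if (!neg[1]) return(0)
  if (all(neg)) return((bp[3] - bp[2]) / 60)
  i <- which(!neg)[1]
  # linear interpolation of the threshold crossing between grid points
  t0 <- w$t[i - 1]; t1 <- w$t[i]
  v0 <- w$v[i - 1]; v1 <- w$v[i]
  tc <- if (v1 == v0) t1 else t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
  (tc - bp[2]) / 60
}

#' Locate the bistability boundary in the medium clearance rate
#'
#' Bisection on `k_alpha_deg` (in log space) between two rates with
#' different stability classifications, until the bracket is narrower than
#' `tol` relative.
#'
#' The bracket endpoints are classified with [classify_stability()]; the
#' refinement probes the sign of the diagonal instability instead (whether
#' a small X/Y asymmetry grows or shrinks over the late part of a long
#' run). Both criteria agree away from the boundary, but the instability
#' sign stays decisive arbitrarily close to it, where full equilibration
#' slows down critically and terminal-point clustering becomes
#' inconclusive.
#'
#' @param params Base `circuit_params`.
#' @param k_low,k_high Bracket endpoints, 1/s; their classifications must
#'   differ.
#' @param tol Relative bracket width at termination.
#' @param horizon_h Probe horizon, hours.
#' @param ... Passed to [classify_stability()] for the endpoint checks
#'   (e.g. a reduced `ic_grid` for speed).
#' @return The boundary estimate (bracket midpoint in log space), 1/s.
#' @export
bistability_boundary <- function(params, k_low, k_high, tol = 0.01,
                                 horizon_h = 300, ...) {
  cls <- function(k)
    classify_stability(set_param(params, "k_alpha_deg", k),
                       horizon_h = horizon_h, ...)$classification
  c_lo <- cls(k_low)
  c_hi <- cls(k_high)
  if (c_lo == "inconclusive" || c_hi == "inconclusive")
    stop("inconclusive classification at a bracket endpoint")
  if (c_lo == c_hi)
    stop("bracket endpoints have the same classification (", c_lo, ")")
  probe <- function(k) {
    if (.diagonal_unstable(set_param(params, "k_alpha_deg", k), horizon_h))
      "bistable" else "monostable"
  }
  lo <- log10(k_low); hi <- log10(k_high)
  while ((10^hi - 10^lo) / 10^lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(10^mid) == c_lo) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

# Is the symmetric (diagonal) state unstable? Integrates one slightly
# asymmetric initial condition and inspects the medium-pheromone asymmetry
# |log10(X/Y)| over the late part of the run: a latched (saturated, large)
# or still-growing asymmetry means the diagonal is unstable; a shrinking
# one means it is stable. The medium pools are fast, so the seeded
# asymmetry is carried by the slow intracellular variables and grows or
# decays exponentially with the dominant transverse eigenvalue.
.diagonal_unstable <- function(params, horizon_h = 300) {
  pv <- expand_params(params)
  base <- pre_equilibrate(params, opts = solver_opts(rtol = 1e-10))
  y0 <- base
  y0[11] <- 1e-12
  y0[12] <- 2e-12
  horizon_s <- horizon_h * 3600
  res <- rosenbrock_segment(y0, 0, horizon_s, pv, 0, 0, FALSE,
                            1e-10, 1e-30, horizon_s / 4, 1e-2, 5e7)
  st <- res$states
  n <- nrow(st)
  asym <- function(r) abs(log10(pmax(st[r, 11], 1e-300) /
                                  pmax(st[r, 12], 1e-300)))
  asym(n) >= 1 || asym(n) > asym(n - 1) * 1.001
}
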