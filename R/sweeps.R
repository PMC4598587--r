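# Parameter-sweep drivers: 2-D quality maps and lambda scans with
# sweep-wide amplitude normalization.

.score_point <- function(params, schedule, lam, opts, init_hours = 7) {
  init <- pre_equilibrate(params, hours = init_hours, opts = opts)
  traj <- integrate_circuit(params, schedule, init = init, opts = opts)
  theta_S(phi_of(traj), lam)
}

#' Two-dimensional quality sweep
#'
#' Scores the canonical protocol on a grid over two parameters. Each grid
#' point is pre-equilibrated, simulated and scored independently
#' (deterministic, embarrassingly parallel in principle); the
#' amplitude-normalized quality uses the sweep-wide extrema
#' `m_T = min m`, `M_T = max M` over all points, so `theta_A <= theta_S`
#' point-wise. Failed integrations are recorded as zero quality with a
#' failure flag rather than aborting the sweep.
#'
#' @param param_x,param_y Names of `circuit_params` fields to vary.
#' @param grid_x,grid_y Numeric grids of values.
#' @param base Base `circuit_params`.
#' @param lam Pareto weight lambda.
#' @param schedule Input schedule to score (default canonical 30 h).
#' @param opts Solver options.
#' @return An object of class `quality_map`: data frame with columns `x`,
#'   `y`, `S_r`, `S_m`, `theta_S`, `theta_A`, `m`, `M`, `failed`, plus
#'   attributes `m_T`, `M_T`, `lambda`, `param_x`, `param_y`.
#' @export
sweep2d <- function(param_x, grid_x, param_y, grid_y, base = default_params(),
                    lam = 0.4, schedule = canonical_sequence(),
                    opts = solver_opts(rtol = 1e-10)) {
  stopifnot(length(grid_x) >= 1, length(grid_y) >= 1)
  pts <- expand.grid(x = grid_x, y = grid_y)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- set_param(set_param(base, param_x, pts$x[i]), param_y, pts$y[i])
    sc <- tryCatch(.score_point(p, schedule, lam, opts), error = identity)
    rows[[i]] <- if (inherits(sc, "error"))
      data.frame(x = pts$x[i], y = pts$y[i], S_r = 0, S_m = 0, theta_S = 0,
                 theta_A = NA_real_, m = NA_real_, M = NA_real_,
                 failed = TRUE)
    else
      data.frame(x = pts$x[i], y = pts$y[i], S_r = sc$S_r, S_m = sc$S_m,
                 theta_S = sc$theta_S, theta_A = NA_real_, m = sc$m,
                 M = sc$M, failed = FALSE)
  }
  map <- do.call(rbind, rows)
  .normalize_map(map, lam, param_x, param_y)
}

.normalize_map <- function(map, lam, param_x, param_y) {
  ok <- !map$failed & is.finite(map$m) & is.finite(map$M)
  m_T <- if (any(ok)) min(map$m[ok]) else NA_real_
  M_T <- if (any(ok)) max(map$M[ok]) else NA_real_
  if (any(ok) && is.finite(m_T) && is.finite(M_T) && m_T < 0 && M_T > 0) {
    map$theta_A[ok] <- map$theta_S[ok] * (map$m[ok] * map$M[ok]) / (m_T * M_T)
  } else {
    map$theta_A[ok] <- 0
  }
  structure(map, m_T = m_T, M_T = M_T, lambda = lam,
            param_x = param_x, param_y = param_y,
            class = c("quality_map", "data.frame"))
}

#' One-dimensional sweep scored across a lambda grid
#'
#' Simulates once per parameter value and rescores across `lambda_grid`
#' without re-integration: the shape quality is affine in lambda between
#' its memory (`lambda = 0`) and response (`lambda = 1`) endpoints, so it
#' is recomputed from the cached `S_r`, `S_m` (zero-quality rules are
#' lambda-independent and preserved).
#'
#' @param param Name of the `circuit_params` field to vary.
#' @param grid Numeric grid of parameter values.
#' @param base Base `circuit_params`.
#' @param lambda_grid Lambda values in \[0, 1\].
#' @param schedule Input schedule to score.
#' @param opts Solver options.
#' @return A `quality_map` data frame with columns `x` (parameter value),
#'   `y` (lambda), `S_r`, `S_m`, `theta_S`, `theta_A`, `m`, `M`, `failed`;
#'   normalizers are computed over the parameter grid (one amplitude per
#'   parameter value, shared across lambdas).
#' @export
lambda_scan <- function(param, grid, base = default_params(),
                        lambda_grid = seq(0, 1, by = 0.25),
                        schedule = canonical_sequence(),
                        opts = solver_opts(rtol = 1e-10)) {
  stopifnot(length(grid) >= 1, all(lambda_grid >= 0 & lambda_grid <= 1))
  rows <- vector("list", 0L)
  for (v in grid) {
    p <- set_param(base, param, v)
    sc <- tryCatch(.score_point(p, schedule, lambda_grid[1], opts),
                   error = identity)
    for (lam in lambda_grid) {
      rows[[length(rows) + 1L]] <- if (inherits(sc, "error"))
        data.frame(x = v, y = lam, S_r = 0, S_m = 0, theta_S = 0,
                   theta_A = NA_real_, m = NA_real_, M = NA_real_,
                   failed = TRUE)
      else
        data.frame(x = v, y = lam, S_r = sc$S_r, S_m = sc$S_m,
                   theta_S = if (sc$zero_rule != "none") 0 else
                     .clamp01(lam * sc$S_r + (1 - lam) * sc$S_m),
                   theta_A = NA_real_, m = sc$m, M = sc$M, failed = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  .normalize_map(map, NA_real_, param, "lambda")
}

#' Export a quality map as CSV
#'
#' Columns: `x`, `y`, `theta_S`, `theta_A`, `S_r`, `S_m`, `m`, `M`,
#' `failed`.
#'
#' @param map A `quality_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(
    map[, c("x", "y", "theta_S", "theta_A", "S_r", "S_m", "m", "M",
            "failed")],
    path, row.names = FALSE)
  invisible(path)
}
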