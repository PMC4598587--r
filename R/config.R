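# Run configuration: JSON config loading with strict key validation,
# default filling, canonical serialization, and the top-level pipeline.

.config_keys <- c("params_file", "params", "protocol", "lambda", "solver",
                  "tasks", "sweep", "stability", "seed")
.solver_keys <- c("rtol", "atol", "save_dt", "h_init", "max_steps")

#' Parse a protocol specification
#'
#' Accepts either the shorthand `"canonical:3h,12h,x1"` (activation hours,
#' memory hours, repeats) or a list of `(duration_s, R, S)` segment rows.
#'
#' @param spec Character shorthand or list of 3-element segment rows.
#' @return An `input_schedule`.
#' @export
parse_protocol <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!grepl("^canonical:", spec))
      stop("unknown protocol shorthand: ", spec)
    body <- sub("^canonical:", "", spec)
    parts <- strsplit(body, ",")[[1]]
    if (length(parts) != 3L)
      stop("canonical protocol needs 'canonical:<act>h,<mem>h,x<repeats>'")
    act <- as.numeric(sub("h$", "", parts[1]))
    mem <- as.numeric(sub("h$", "", parts[2]))
    rep <- as.integer(sub("^x", "", parts[3]))
    if (any(is.na(c(act, mem, rep))))
      stop("could not parse protocol: ", spec)
    return(canonical_sequence(act, mem, rep))
  }
  if (is.list(spec) || is.matrix(spec)) {
    rows <- if (is.matrix(spec)) split(spec, row(spec)) else spec
    seg <- t(vapply(rows, function(r) as.numeric(unlist(r)), numeric(3)))
    return(input_schedule(seg[, 1], seg[, 2], seg[, 3]))
  }
  stop("protocol must be a shorthand string or a list of (duration_s, R, S)")
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, fills defaults
#' (canonical 3 h / 12 h protocol, lambda = 0.4, default solver options),
#' resolves the parameter file, and validates the resulting parameter set
#' and protocol (the invalid input R = S = 1 is rejected at load time).
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- default_params()
  if (!is.null(raw$params_file)) {
    pf <- raw$params_file
    if (!file.exists(pf))
      pf <- file.path(dirname(path), raw$params_file)
    params <- read_params_json(pf)
  }
  if (!is.null(raw$params)) {
    unknown <- setdiff(names(raw$params), setdiff(names(params), "overrides"))
    unknown <- setdiff(unknown, "overrides")
    if (length(unknown))
      stop("unknown parameter key(s) in config: params.",
           paste(unknown, collapse = ", params."))
    for (k in setdiff(names(raw$params), "overrides"))
      params[[k]] <- as.numeric(raw$params[[k]])
    if (!is.null(raw$params$overrides))
      params$overrides <- lapply(raw$params$overrides,
                                 function(cc) lapply(cc, as.numeric))
    validate_params(params)
  }
  solver <- do.call(solver_opts, lapply(
    stats::setNames(.solver_keys, .solver_keys), function(k) {
      v <- raw$solver[[k]]
      if (is.null(v)) formals(solver_opts)[[k]] else as.numeric(v)
    }))
  if (!is.null(raw$solver)) {
    unknown <- setdiff(names(raw$solver), .solver_keys)
    if (length(unknown))
      stop("unknown solver key(s): solver.", paste(unknown, collapse = ", solver."))
  }
  protocol <- if (is.null(raw$protocol)) canonical_sequence()
              else parse_protocol(raw$protocol)
  lam <- if (is.null(raw$lambda)) 0.4 else as.numeric(raw$lambda)
  if (lam < 0 || lam > 1) stop("config error at key lambda: not in [0, 1]")
  tasks <- if (is.null(raw$tasks)) c("simulate", "score")
           else unlist(raw$tasks)
  bad <- setdiff(tasks, c("simulate", "score", "stability", "sweep"))
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "))
  cfg <- list(params = params, protocol = protocol, lambda = lam,
              solver = solver, tasks = tasks,
              sweep = raw$sweep, stability = raw$stability,
              seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed))
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration back to canonical JSON
#'
#' Serializes a `run_config` so that `load_config(write_config(cfg))`
#' reproduces it (canonical round trip).
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(
    params = cfg$params[setdiff(names(cfg$params), "overrides")],
    protocol = lapply(seq_len(nrow(cfg$protocol)), function(i)
      c(cfg$protocol$duration_s[i], cfg$protocol$R[i], cfg$protocol$S[i])),
    lambda = cfg$lambda,
    solver = cfg$solver[.solver_keys],
    tasks = as.list(cfg$tasks))
  if (!is.null(cfg$params$overrides))
    out$params$overrides <- cfg$params$overrides
  if (!is.null(cfg$sweep)) out$sweep <- cfg$sweep
  if (!is.null(cfg$stability)) out$stability <- cfg$stability
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flat parameter file
#'
#' JSON key/value file whose keys match `circuit_params` field names; an
#' optional `overrides` object carries per-cell replacements.
#'
#' @param path Path to the JSON parameter file.
#' @return A `circuit_params` object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- default_params()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  for (k in setdiff(names(raw), "overrides"))
    base[[k]] <- as.numeric(raw[[k]])
  if (!is.null(raw$overrides))
    base$overrides <- lapply(raw$overrides, function(cc) lapply(cc, as.numeric))
  validate_params(base)
  base
}

#' Write a parameter set to a flat JSON file
#'
#' @param params A `circuit_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  out <- params[setdiff(names(params), "overrides")]
  if (!is.null(params$overrides)) out$overrides <- params$overrides
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Execute a configured run
#'
#' Runs the tasks named in the configuration and writes their artifacts
#' under `outdir`: `traj.csv` and `phi.csv` (simulate), `score.json`
#' (score), `stability.json` (stability), `map.csv` (sweep), plus a
#' `manifest.json` with the canonical config hash, package version and
#' wall time. Deterministic: identical configurations produce
#' byte-identical score files.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(...)
  artifacts <- list()

  need_traj <- any(c("simulate", "score") %in% cfg$tasks)
  if (need_traj) {
    say("simulate: ", nrow(cfg$protocol), " segments, ",
        schedule_duration(cfg$protocol) / 3600, " h")
    init <- pre_equilibrate(cfg$params, opts = cfg$solver)
    traj <- integrate_circuit(cfg$params, cfg$protocol, init = init,
                              opts = cfg$solver)
    say("simulate: ", traj$solver$nsteps, " accepted steps, ",
        traj$solver$nreject, " rejected")
    phi <- phi_of(traj)
    artifacts$traj <- write_trajectory_csv(traj, file.path(outdir, "traj.csv"))
    artifacts$phi <- write_phi_csv(phi, file.path(outdir, "phi.csv"))
    if ("score" %in% cfg$tasks) {
      sc <- theta_S(phi, cfg$lambda)
      sc$theta_A <- sc$theta_S * 1 # self-normalized single run
      artifacts$score <- write_score_json(sc, file.path(outdir, "score.json"))
      say(sprintf("score: theta_S = %.4f (S_r = %.4f, S_m = %.4f)",
                  sc$theta_S, sc$S_r, sc$S_m))
    }
  }
  if ("stability" %in% cfg$tasks) {
    sp <- cfg$stability
    unknown <- setdiff(names(sp), c("n_ic", "horizon_h"))
    if (length(unknown))
      stop("unknown stability key(s): stability.",
           paste(unknown, collapse = ", stability."))
    rep <- classify_stability(
      cfg$params,
      ic_grid = if (is.null(sp$n_ic)) default_ic_grid()
                else default_ic_grid(n = as.integer(sp$n_ic)),
      horizon_h = if (is.null(sp$horizon_h)) 300 else as.numeric(sp$horizon_h))
    say("stability: ", rep$classification)
    artifacts$stability <- file.path(outdir, "stability.json")
    jsonlite::write_json(
      list(classification = rep$classification,
           equilibria = as.data.frame(rep$equilibria),
           converged = all(rep$converged)),
      artifacts$stability, auto_unbox = TRUE, digits = NA)
  }
  if ("sweep" %in% cfg$tasks) {
    sw <- cfg$sweep
    if (is.null(sw)) stop("task 'sweep' requires a sweep spec in the config")
    unknown <- setdiff(names(sw), c("x", "y", "lambda_grid"))
    if (length(unknown))
      stop("unknown sweep key(s): sweep.", paste(unknown, collapse = ", sweep."))
    gx <- .parse_axis(sw$x)
    map <- if (!is.null(sw$lambda_grid)) {
      lambda_scan(gx$name, gx$grid, base = cfg$params,
                  lambda_grid = unlist(sw$lambda_grid),
                  schedule = cfg$protocol, opts = cfg$solver)
    } else {
      gy <- .parse_axis(sw$y)
      sweep2d(gx$name, gx$grid, gy$name, gy$grid, base = cfg$params,
              lam = cfg$lambda, schedule = cfg$protocol, opts = cfg$solver)
    }
    artifacts$map <- write_map_csv(map, file.path(outdir, "map.csv"))
    say("sweep: ", nrow(map), " points, max theta_S = ",
        sprintf("%.3f", max(map$theta_S)))
  }

  cfg_path <- file.path(outdir, "config_canonical.json")
  write_config(cfg, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("srlatch")),
    wall_time_s = proc.time()[["elapsed"]] - t_start)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts$manifest <- file.path(outdir, "manifest.json")
  invisible(artifacts)
}

# axis spec "k_alpha_deg:0.005:500:log:30" or list(name, from, to, scale, n)
.parse_axis <- function(ax) {
  if (is.character(ax) && length(ax) == 1L) {
    parts <- strsplit(ax, ":")[[1]]
    if (length(parts) != 5L)
      stop("axis spec must be name:from:to:lin|log:n, got ", ax)
    ax <- list(name = parts[1], from = as.numeric(parts[2]),
               to = as.numeric(parts[3]), scale = parts[4],
               n = as.integer(parts[5]))
  }
  grid <- if (identical(ax$scale, "log"))
    10^seq(log10(as.numeric(ax$from)), log10(as.numeric(ax$to)),
           length.out = as.integer(ax$n))
  else seq(as.numeric(ax$from), as.numeric(ax$to),
           length.out = as.integer(ax$n))
  list(name = ax$name, grid = grid)
}
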