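## Experiment orchestration: single runs and seed sweeps over the compiled
## (or reference R) RK4 core, producing unwrapped centroid trajectories,
## diagnostics and optional field snapshots.

#' Assemble an experiment configuration
#'
#' @param grid a [makeGrid()] grid (default 128 x 128, spacing 1).
#' @param params [modelParams()].
#' @param substrate_kind,E_ref,slope,axis substrate specification passed to
#'   [makeSubstrate()]; `E_ref` is the stiffness at the domain centre, i.e.
#'   at the initial cell centroid.
#' @param n_steps number of RK4 steps.
#' @param record_every record the centroid and diagnostics every this many
#'   steps.
#' @param snapshot_every save full field snapshots every this many steps
#'   (0 = none).
#' @param seed RNG seed for the random initial polarity.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference implementation).
#' @param freeze_flow keep the flow frozen at zero (passive runs).
#' @return classed configuration list.
#' @export
experimentConfig <- function(grid = makeGrid(128, 128),
                             params = modelParams(),
                             substrate_kind = c("gradient", "uniform"),
                             E_ref = 70, slope = 0.8, axis = "y",
                             n_steps = 1000, record_every = 10,
                             snapshot_every = 0, seed = 1L,
                             engine = c("cpp", "r"), freeze_flow = FALSE) {
  substrate_kind <- match.arg(substrate_kind)
  engine <- match.arg(engine)
  stopifnot(n_steps >= 1, record_every >= 1)
  structure(list(grid = grid, params = params,
                 substrate_kind = substrate_kind, E_ref = E_ref,
                 slope = slope, axis = axis,
                 n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every),
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed), engine = engine,
                 freeze_flow = isTRUE(freeze_flow)),
            class = "dg_config")
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [experimentConfig()],
#' [modelParams()] and the parameter constructors; unspecified values keep
#' the package defaults. Top-level keys: `grid: {nx, ny, dx, dy}`,
#' `substrate: {kind, E_ref, slope, axis}`, `params:` (with nested `energy`,
#' `flow`, `mech`), `run: {n_steps, record_every, snapshot_every, seed,
#' engine, freeze_flow}`.
#'
#' @param path YAML file path.
#' @return a `dg_config`.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  g <- do.call(makeGrid, modifyList(list(nx = 128, ny = 128), as.list(y$grid)))
  pargs <- as.list(y$params)
  for (nm in c("energy", "flow", "mech")) {
    ctor <- switch(nm, energy = energyParams, flow = flowParams,
                   mech = mechanosenseParams)
    pargs[[nm]] <- do.call(ctor, as.list(y$params[[nm]]))
  }
  params <- do.call(modelParams, pargs)
  run <- as.list(y$run)
  sub <- modifyList(list(kind = "gradient", E_ref = 70, slope = 0.8, axis = "y"),
                    as.list(y$substrate))
  do.call(experimentConfig,
          c(list(grid = g, params = params, substrate_kind = sub$kind,
                 E_ref = sub$E_ref, slope = sub$slope, axis = sub$axis),
            run))
}

#' Write a resolved configuration to YAML
#'
#' @param config a `dg_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  p <- config$params
  y <- list(
    grid = config$grid[c("nx", "ny", "dx", "dy")],
    substrate = list(kind = config$substrate_kind, E_ref = config$E_ref,
                     slope = config$slope, axis = config$axis),
    params = list(energy = unclass(p$energy), flow = unclass(p$flow),
                  mech = unclass(p$mech),
                  M = p$M, w = p$w, Gamma_P = p$Gamma_P, Gamma_m = p$Gamma_m,
                  alpha_m = p$alpha_m, m0 = p$m0, R = p$R,
                  eps_int = p$eps_int, eps_n = p$eps_n, dt = p$dt,
                  fickian = p$fickian),
    run = config[c("n_steps", "record_every", "snapshot_every", "seed",
                   "engine", "freeze_flow")]
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

## build the substrate object described by a config
configSubstrate <- function(config) {
  if (config$substrate_kind == "uniform")
    makeSubstrate(config$grid, "uniform", E_ref = config$E_ref)
  else
    makeSubstrate(config$grid, "gradient", E_ref = config$E_ref,
                  slope = config$slope, axis = config$axis)
}

#' Run one simulation experiment
#'
#' Initializes the droplet (deterministically from `config$seed`), advances
#' the coupled model for `n_steps` RK4 steps, and records the unwrapped cell
#' centroid (minimal-image accumulation across the periodic boundary) plus
#' step diagnostics. Identical configuration and seed reproduce the
#' trajectory bit-for-bit.
#'
#' @param config an [experimentConfig()].
#' @return list with elements
#'   `trajectory` (data.frame `track_id`, `t`, `x`, `y`; unwrapped, length
#'   units), `diagnostics` (data.frame with total actin `mass`, `max_div` of
#'   the velocity, `m_max`, `m_polarization`, free `energy`, `npolar_len` at
#'   each record), `final` (the final `dg_state`), `snapshots` (list of field
#'   snapshot lists, if requested), `m_clamped` (count of clamped negative
#'   myosin values) and the resolved `config`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "dg_config"))
  grid <- config$grid
  params <- config$params
  sub <- configSubstrate(config)
  state <- initializeState(grid, params, seed = config$seed)
  if (config$engine == "cpp") {
    ctrl <- list(dx = grid$dx, dy = grid$dy, n_steps = config$n_steps,
                 record_every = config$record_every,
                 snapshot_every = config$snapshot_every,
                 freeze_flow = config$freeze_flow)
    res <- .dg_engine_run(state$c, state$m, state$P$x, state$P$y, state$omega,
                          sub$E, unclass(params), ctrl)
    final <- structure(list(t = config$n_steps * params$dt,
                            c = res$final$c, m = res$final$m,
                            P = list(x = res$final$Px, y = res$final$Py),
                            omega = res$final$omega, psi = res$final$psi,
                            v = list(x = res$final$vx, y = res$final$vy)),
                       class = "dg_state")
    traj <- data.frame(track_id = 1L, t = as.numeric(res$t),
                       x = as.numeric(res$x), y = as.numeric(res$y))
    diag <- data.frame(t = as.numeric(res$t), mass = as.numeric(res$mass),
                       max_div = as.numeric(res$max_div),
                       m_max = as.numeric(res$m_max),
                       m_polarization = as.numeric(res$m_polarization),
                       energy = as.numeric(res$energy),
                       npolar_len = as.numeric(res$npolar_len))
    snaps <- if (length(res$snapshots)) res$snapshots else NULL
    list(trajectory = traj, diagnostics = diag, final = final,
         snapshots = snaps, m_clamped = res$m_clamped, config = config)
  } else {
    runExperimentR(config, state, sub)
  }
}

## pure-R experiment loop (reference path; slow, used on small problems)
runExperimentR <- function(config, state, sub) {
  grid <- config$grid; params <- config$params
  recs <- list(); snaps <- list(); clamped <- 0
  prev <- NULL; ux <- uy <- 0
  recordState <- function(s) {
    mask <- s$c >= params$energy$c0 / 2
    cc <- periodicCentroid(ifelse(mask, s$c, 0), grid)
    if (is.null(prev)) { ux <<- cc[1]; uy <<- cc[2] }
    else {
      ux <<- ux + torusDiff(cc[1], prev[1], grid$Lx)
      uy <<- uy + torusDiff(cc[2], prev[2], grid$Ly)
    }
    prev <<- cc
    div <- fieldDivergence(s$v, grid, "fd")
    np <- computeNpolar(s, grid, params$energy$c0, eps_n = 0)
    data.frame(t = s$t, x = ux, y = uy,
               mass = sum(s$c) * grid$dx * grid$dy,
               max_div = max(abs(div)), m_max = max(s$m),
               m_polarization = -np$offset[2], npolar_len = np$length,
               energy = freeEnergy(s$c, s$P, grid, params$energy, "fd"))
  }
  recs[[1]] <- recordState(state)
  for (step in seq_len(config$n_steps)) {
    state <- rk4Step(state, params, sub, grid, scheme = "fd",
                     freeze_flow = config$freeze_flow)
    clamped <- clamped + attr(state, "m_clamped")
    if (step %% config$record_every == 0)
      recs[[length(recs) + 1]] <- recordState(state)
    if (config$snapshot_every > 0 && step %% config$snapshot_every == 0)
      snaps[[length(snaps) + 1]] <-
        list(t = state$t, c = state$c, m = state$m,
             Px = state$P$x, Py = state$P$y, psi = state$psi,
             omega = state$omega, vx = state$v$x, vy = state$v$y)
  }
  rec <- do.call(rbind, recs)
  list(trajectory = data.frame(track_id = 1L, t = rec$t, x = rec$x, y = rec$y),
       diagnostics = rec[, c("t", "mass", "max_div", "m_max",
                             "m_polarization", "energy", "npolar_len")],
       final = state, snapshots = if (length(snaps)) snaps else NULL,
       m_clamped = clamped, config = config)
}

#' Run a seeded ensemble of experiments
#'
#' Repeats [runExperiment()] over `n_seeds` seeds derived from `master_seed`
#' by a fixed stride (runs are mutually independent and individually
#' reproducible), pooling the trajectories into one track table.
#'
#' @param config an [experimentConfig()]; its `seed` field is ignored.
#' @param n_seeds number of runs.
#' @param master_seed base seed; run `i` uses `master_seed + 1000 * (i - 1)`.
#' @return list with `tracks` (pooled trajectory data.frame), `stats`
#'   (per-track migration statistics via [summarizeTracks()]), and
#'   `m_polarization` (per-run time-averaged myosin polarization over the
#'   second half of each run).
#' @export
runEnsemble <- function(config, n_seeds = 10, master_seed = 1L) {
  tracks <- list(); mpol <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(master_seed + 1000 * (i - 1))
    res <- runExperiment(cfg)
    tr <- res$trajectory
    tr$track_id <- i
    tracks[[i]] <- tr
    d <- res$diagnostics
    half <- d$t >= max(d$t) / 2
    mpol[i] <- mean(d$m_polarization[half])
  }
  tracks <- do.call(rbind, tracks)
  list(tracks = tracks, stats = summarizeTracks(tracks),
       m_polarization = mpol)
}
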