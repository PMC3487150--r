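# Configuration, serialization, and the top-level experiment runner.

#' Serialize a discrete model to JSON
#'
#' Writes the model as dense row-major arrays with explicit shape headers, so
#' the file is self-describing and editable by hand. `model_from_json`
#' validates on load through [discrete_model()]. Indices in the file are
#' 1-based, matching the R interface.
#'
#' @param model a [discrete_model()].
#' @param path file path; `model_to_json` with `path = NULL` returns the JSON
#'   string.
#' @return `model_from_json` returns a [discrete_model()].
#' @export
model_to_json <- function(model, path = NULL) {
  dense <- function(M) list(shape = dim(M), order = "row-major",
                            values = as.numeric(t(M)))
  obj <- list(
    type = "discrete_model", index_base = 1L,
    n_states = model$n_states, n_obs = model$n_obs,
    n_controls = model$n_controls, horizon = model$horizon,
    A = dense(model$A), B = lapply(model$B, dense),
    c = model$c, d = model$d
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  undense <- function(d) {
    matrix(as.numeric(d$values), d$shape[1], d$shape[2], byrow = TRUE)
  }
  discrete_model(A = undense(obj$A), B = lapply(obj$B, undense),
                 c = as.numeric(obj$c), d = as.numeric(obj$d),
                 horizon = obj$horizon)
}

#' Export an episode trace as CSV
#'
#' Writes the per-step record (time, state index, continuous coordinates,
#' observation, action, free energy) and, optionally, the final belief
#' matrices as separate CSV files.
#'
#' @param trace an `episode_trace` from [run_episode()].
#' @param path CSV path for the per-step record.
#' @param beliefs_prefix if non-`NULL`, writes `<prefix>_alpha.csv` and
#'   `<prefix>_beta.csv`.
#' @return `path`, invisibly.
#' @export
write_episode_csv <- function(trace, path, beliefs_prefix = NULL) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  if (!is.null(beliefs_prefix)) {
    utils::write.csv(trace$beliefs$alpha, paste0(beliefs_prefix, "_alpha.csv"),
                     row.names = FALSE)
    utils::write.csv(trace$beliefs$beta, paste0(beliefs_prefix, "_beta.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

config_schema <- function() {
  list(
    experiment = "mountain_car",
    seed = 1L,
    out = NULL,
    mountain_car = list(
      n_pos = 32L, n_vel = 32L,
      pos_range = c(-2, 2), vel_range = c(-3, 3),
      control_values = c(-2, -1, 0, 1, 2),
      dt = 2, horizon = 16L, sweeps_per_step = 8L,
      smoothing_sigma = 0.5, action_gain = 0.5, friction = 0.15,
      goal = c(1, 0), start = c(0, 0), mode = "modal"
    ),
    saccade = list(
      n_saccades = 8L, bins_per_saccade = 16L,
      retina_n_side = 16L, salience_grid = 32L,
      n_orders = 3L, noise = TRUE,
      glyph_seed = 7L, glyph_size = 128L, scene = "upright"
    ),
    toy_mdp = list(
      n_states = 4L, n_actions = 3L, horizon = 3L,
      deterministic = TRUE, mode = "modal"
    )
  )
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(sprintf("config key '%s' must be a mapping", paste(path, collapse = ".")),
         call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", ")),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.null(user[[k]])) next  # explicit null: keep the default
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration, fills every missing key with the default
#' settings of the simulated experiments (the mountain-car and visual-search
#' defaults mirror the package's standard demonstrations: a 32 x 32 state
#' grid with 5 control levels and 8 variational sweeps per step; a 16 x 16
#' retina, 32 x 32 salience grid, and 8 saccades of 16 bins), and rejects
#' unknown keys with their key path. An empty or missing file yields the full
#' default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
  }
  cfg <- merge_config(config_schema(), user)
  if (!cfg$experiment %in% c("mountain_car", "saccade", "toy_mdp")) {
    stop(sprintf("unknown experiment '%s'", cfg$experiment), call. = FALSE)
  }
  if (!is.null(cfg$mountain_car$mode) &&
      !cfg$mountain_car$mode %in% c("modal", "sampled")) {
    stop("mountain_car.mode must be 'modal' or 'sampled'", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches to the experiment named in the configuration, runs it with the
#' configured seed, and writes traces, maps, a JSON summary, the fully
#' resolved configuration, and a manifest with MD5 hashes of every artifact
#' into the output directory.
#'
#' @param config a `run_config` from [load_config()] (or `NULL` for
#'   defaults).
#' @param out output directory (overrides `config$out`).
#' @return The manifest (named list of files and hashes), invisibly.
#' @export
run_experiment <- function(config = NULL, out = NULL) {
  if (is.null(config)) config <- load_config(NULL)
  if (!inherits(config, "run_config")) stop("config must come from load_config()", call. = FALSE)
  out <- out %||% config$out %||% stop("no output directory given", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  summary <- switch(
    config$experiment,
    mountain_car = run_experiment_mountain_car(config, out),
    saccade = run_experiment_saccade(config, out),
    toy_mdp = run_experiment_toy_mdp(config, out)
  )
  summary$experiment <- config$experiment
  summary$seed <- config$seed
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(config, file.path(out, "config_resolved.yaml"))

  # artifacts are a pure function of config and seed; the runtime lives only
  # in the (unhashed) manifest
  files <- sort(list.files(out, full.names = TRUE))
  manifest <- list(files = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   seed = config$seed,
                   runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

run_experiment_mountain_car <- function(config, out) {
  p <- config$mountain_car
  grid <- grid_spec(n_pos = p$n_pos, pos_range = p$pos_range,
                    n_vel = p$n_vel, vel_range = p$vel_range,
                    control_values = p$control_values)
  dyn <- car_dynamics(action_gain = p$action_gain, friction = p$friction,
                      dt = p$dt)
  mc <- make_mountain_car_model(grid, dyn, goal = p$goal,
                                smoothing_sigma = p$smoothing_sigma,
                                horizon = p$horizon)
  start <- nearest_state(grid, p$start[1], p$start[2])
  trace <- run_episode(mc$model, mc$R, start,
                       n_sweeps_per_step = p$sweeps_per_step,
                       mode = p$mode, seed = config$seed, coords = mc$coords)
  write_episode_csv(trace, file.path(out, "episode.csv"),
                    beliefs_prefix = file.path(out, "beliefs"))
  final <- state_coords(grid, trace$states[p$horizon + 1L])
  list(final_position = final[[1]], final_velocity = final[[2]],
       goal_state = mc$goal_state, goal_hit = trace$states[p$horizon + 1L] == mc$goal_state)
}

run_experiment_saccade <- function(config, out) {
  p <- config$saccade
  gl <- make_glyph_hypotheses(size = p$glyph_size, seed = p$glyph_seed)
  scene <- gl$scenes[[p$scene]]
  if (is.null(scene)) stop("saccade.scene must be upright, inverted, or rotated", call. = FALSE)
  retina <- retina_spec(n_side = p$retina_n_side)
  tr <- saccade_search(scene, gl$hypotheses, n_saccades = p$n_saccades,
                       bins_per_saccade = p$bins_per_saccade, retina = retina,
                       seed = config$seed, noise = p$noise,
                       grid_side = p$salience_grid, n_orders = p$n_orders)
  utils::write.csv(as.data.frame(tr), file.path(out, "trace.csv"), row.names = FALSE)
  for (i in seq_along(tr$salience_maps)) {
    write_pgm(salience_as_image(tr$salience_maps[[i]]),
              file.path(out, sprintf("salience_%02d.pgm", i)))
    utils::write.csv(salience_as_image(tr$salience_maps[[i]])$values,
                     file.path(out, sprintf("salience_%02d.csv", i)),
                     row.names = FALSE)
  }
  ior_img <- scene_image(matrix(tr$ior_memory, p$salience_grid, p$salience_grid))
  write_pgm(ior_img, file.path(out, "ior_memory.pgm"))
  utils::write.csv(ior_img$values, file.path(out, "ior_memory.csv"),
                   row.names = FALSE)
  utils::write.csv(tr$fixations, file.path(out, "fixations.csv"), row.names = FALSE)
  n <- nrow(tr$posterior)
  list(fixations = unname(split(tr$fixations, seq_len(nrow(tr$fixations)))),
       final_posterior = tr$posterior[n, ],
       entropy_per_saccade = tr$entropy,
       winner = which.max(tr$posterior[n, ]))
}

run_experiment_toy_mdp <- function(config, out) {
  p <- config$toy_mdp
  toy <- make_toy_mdp(n_states = p$n_states, n_actions = p$n_actions,
                      horizon = p$horizon, deterministic = p$deterministic,
                      seed = config$seed)
  vi <- value_iteration(toy$Tr, toy$reward, p$horizon)
  trace <- run_episode(toy$model, toy$R, start_state = 1L,
                       mode = p$mode, seed = config$seed)
  utils::write.csv(as.data.frame(trace), file.path(out, "episode.csv"),
                   row.names = FALSE)
  # agency-free actions along the visited states, against the Bellman policy
  agree <- vapply(seq_len(p$horizon), function(t) {
    post <- numeric(p$n_states); post[trace$states[t]] <- 1
    a <- agency_free_action(post, vi$policy[t, ], toy$Tr, toy$model$A, toy$R,
                            trace$observations[t])
    a == vi$policy[t, trace$states[t]]
  }, logical(1))
  list(value_t0 = vi$V[1, ], bellman_agreement = all(agree),
       states_visited = trace$states)
}
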