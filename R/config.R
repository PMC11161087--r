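config_defaults <- function() {
  list(
    grid = list(width_x = 15, width_y = 25, nx = 120L, ny = 200L),
    kinetics = list(a = 0.3, b = 0.8, D_u = 1, D_v = 40),
    solver = list(dt = 0.05, scheme = "imex", stationarity_tol = 1e-4,
                  record_every = 10),
    schedule = list(n_systems = 5L,
                    durations = c(500, 1000, 1000, 1000, 1000),
                    scenario = "full", seed = 1L),
    init = list(amplitude = 0.01),
    masks = list(threshold_fraction = 0.5, margin = 0.5,
                 min_area_cells = 4L),
    horseshoe = list(),
    metrics = list(detection_threshold = 0.5, interbud_radius = NULL,
                   anterior_direction = 0, anterior_half_angle = 30,
                   lateral_max = 90, posterior_lateral_max = 150),
    output = list(dir = ".", verbosity = 1L)
  )
}

check_unknown_keys <- function(cfg, defaults, path = "") {
  errs <- character(0)
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra))
    errs <- c(errs, paste0("unknown key(s) ",
                           paste0(path, extra, collapse = ", ")))
  for (k in intersect(names(cfg), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "horseshoe") {
      if (is.list(cfg[[k]]))
        errs <- c(errs, check_unknown_keys(cfg[[k]], defaults[[k]],
                                           paste0(path, k, ".")))
    }
  }
  errs
}

validate_config <- function(cfg) {
  errs <- character(0)
  add <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  g <- cfg$grid; k <- cfg$kinetics; s <- cfg$solver; sc <- cfg$schedule
  add(g$width_x > 0 && g$width_y > 0, "grid extents must be positive")
  add(g$nx >= 8 && g$ny >= 8, "grid must have at least 8 cells per direction")
  add(k$a >= 0, "kinetics.a must be >= 0")
  add(k$b > 0, "kinetics.b must be > 0")
  add(k$D_u > 0 && k$D_v > 0, "diffusion coefficients must be > 0")
  add(s$dt > 0, "solver.dt must be > 0")
  add(s$scheme %in% c("imex", "euler"), "solver.scheme must be imex or euler")
  add(sc$n_systems >= 1, "schedule.n_systems must be >= 1")
  add(length(sc$durations) == sc$n_systems,
      sprintf("schedule.durations has length %d but n_systems = %d",
              length(sc$durations), sc$n_systems))
  add(all(sc$durations > 0), "all schedule.durations must be > 0")
  add(sc$scenario %in% c("full", "remove_bud2", "horseshoe"),
      "schedule.scenario must be full, remove_bud2 or horseshoe")
  add(cfg$init$amplitude >= 0 && cfg$init$amplitude < 1,
      "init.amplitude must be in [0, 1)")
  add(cfg$masks$threshold_fraction > 0 && cfg$masks$threshold_fraction < 1,
      "masks.threshold_fraction must be in (0, 1)")
  add(cfg$masks$margin >= 0, "masks.margin must be >= 0")
  errs
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills in the model defaults (kinetic
#' constants 0.3 and 0.8, domain 15 x 25, five systems with the 500 +
#' 4 x 1000 schedule), and validates the result.  An empty or missing-key
#' file therefore yields the canonical run.  Unknown keys and every violated
#' constraint are reported together.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` (nested named list).
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  errs <- check_unknown_keys(user, defaults)
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  # modifyList drops NULL defaults that stay NULL; normalise types
  cfg$grid$nx <- as.integer(cfg$grid$nx); cfg$grid$ny <- as.integer(cfg$grid$ny)
  cfg$schedule$n_systems <- as.integer(cfg$schedule$n_systems)
  cfg$schedule$seed <- as.integer(cfg$schedule$seed)
  cfg$schedule$durations <- as.numeric(unlist(cfg$schedule$durations))
  errs <- c(errs, validate_config(cfg))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' The written file reloads into an equal configuration via
#' [load_config()].
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_to_objects <- function(cfg) {
  p <- kinetic_params(cfg$kinetics$a, cfg$kinetics$b,
                      cfg$kinetics$D_u, cfg$kinetics$D_v)
  list(
    grid = rd_grid(cfg$grid$width_x, cfg$grid$width_y,
                   cfg$grid$nx, cfg$grid$ny),
    params = p,
    settings = solver_settings(cfg$solver$dt, duration = 1,
                               scheme = cfg$solver$scheme,
                               stationarity_tol = cfg$solver$stationarity_tol,
                               record_every = cfg$solver$record_every),
    schedule = simulation_schedule(cfg$schedule$n_systems,
                                   cfg$schedule$durations,
                                   cfg$schedule$scenario,
                                   p, cfg$schedule$seed))
}
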