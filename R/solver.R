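#' Time-stepping settings for the reaction-diffusion solver
#'
#' @param dt time step (time units).  The default 0.05 targets the
#'   semi-implicit scheme; the explicit reference scheme needs
#'   `dt <= spacing^2 / (4 * max(D))` and is intended for small oracle runs.
#' @param duration total integration time.
#' @param scheme `"imex"` (Peaceman-Rachford alternating-direction
#'   semi-implicit step: each diffusion direction is implicit in one
#'   half-step, the gated kinetics are explicit; unconditionally stable in
#'   the diffusion and second-order in the splitting) or `"euler"` (fully
#'   explicit reference scheme).
#' @param stationarity_tol threshold on `max |field change| / dt` below
#'   which the pattern is declared stationary (1/time).
#' @param record_every interval between recorded trace samples and
#'   snapshots (time units).
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(dt = 0.05, duration = 500, scheme = c("imex", "euler"),
                            stationarity_tol = 1e-4, record_every = 10) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, duration >= 0, stationarity_tol >= 0, record_every > 0)
  structure(list(dt = dt, duration = duration, scheme = scheme,
                 stationarity_tol = stationarity_tol,
                 record_every = record_every),
            class = "solver_settings")
}

#' Randomly perturbed homogeneous initial condition
#'
#' The Turing initial condition: the homogeneous steady state `(u*, v*)`
#' with independent uniform multiplicative noise,
#' `u = u* (1 + amplitude * eta)` with `eta ~ U[-1, 1]` per cell, and
#' likewise for `v`.  Reproducible from `seed`.
#'
#' @param grid an [rd_grid()].
#' @param p a [kinetic_params()].
#' @param amplitude perturbation amplitude as a fraction of the steady
#'   state, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return List with `scalar_field`s `u` and `v`.
#' @export
make_initial_condition <- function(grid, p, amplitude = 0.01, seed = 1L) {
  stopifnot(amplitude >= 0, amplitude < 1)
  ss <- homogeneous_steady_state(p)
  n <- grid$nx * grid$ny
  eta <- withr_seed(seed, function() {
    list(u = runif(n, -1, 1), v = runif(n, -1, 1))
  })
  u <- matrix(ss[["u"]] * (1 + amplitude * eta$u), grid$nx, grid$ny)
  v <- matrix(ss[["v"]] * (1 + amplitude * eta$v), grid$nx, grid$ny)
  list(u = scalar_field(grid, u, "activator"),
       v = scalar_field(grid, v, "inhibitor"))
}

# run fn() under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

#' Discrete Laplacian with the model's mixed boundary conditions
#'
#' 5-point finite-difference Laplacian on the simulation grid: the y
#' direction (top/bottom) wraps periodically, the x direction (left/right)
#' uses mirror ghost cells (zero flux).
#'
#' @param field a `scalar_field` (or plain matrix with a `grid` attribute).
#' @return A `scalar_field` of the same shape.
#' @export
laplacian <- function(field) {
  g <- field_grid(field)
  out <- laplacian_cpp(unclass_matrix(field), g$dx, g$dy)
  scalar_field(g, out, attr(field, "species") %||% "activator",
               attr(field, "system_index") %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_matrix <- function(f) {
  m <- unclass(f)
  attributes(m) <- list(dim = dim(m))
  m
}

mask_matrix <- function(mask, grid) {
  if (is.null(mask)) return(matrix(1, grid$nx, grid$ny))
  m <- unclass_matrix(mask)
  storage.mode(m) <- "double"
  m
}

#' Advance the masked reaction-diffusion system by one time step
#'
#' Diffusion acts on the whole domain; the Schnakenberg kinetics are
#' multiplied by the competence mask `S(x, y)` and therefore act only where
#' the mask is 1.
#'
#' @param u,v activator and inhibitor `scalar_field`s on one grid.
#' @param mask a [competence_mask()] (or `NULL` for an all-ones mask).
#' @param p a [kinetic_params()].
#' @param settings a [solver_settings()]; only `dt` and `scheme` are used.
#' @return List with updated fields `u` and `v`.
#' @export
rd_step <- function(u, v, mask = NULL, p = kinetic_params(),
                    settings = solver_settings()) {
  run_masked_system(u, v, mask, p, settings, n_steps = 1L)[c("u", "v")]
}

run_masked_system <- function(u, v, mask, p, settings, n_steps,
                              t0 = 0, snapshot_every_steps = 0L) {
  g <- field_grid(u)
  gv <- field_grid(v)
  if (!grid_compatible(g, gv)) stop("u and v live on different grids")
  if (!is.null(mask) && !grid_compatible(g, attr(mask, "grid") %||% g))
    stop("mask grid does not match the field grid")
  trace_every <- max(1L, as.integer(round(settings$record_every / settings$dt)))
  res <- rd_run_cpp(unclass_matrix(u), unclass_matrix(v),
                    mask_matrix(mask, g),
                    p$a, p$b, p$D_u, p$D_v, g$dx, g$dy,
                    settings$dt, as.integer(n_steps), settings$scheme,
                    1e-9, t0, trace_every, as.integer(snapshot_every_steps))
  res$u <- scalar_field(g, res$u, "activator", attr(u, "system_index") %||% 1L)
  res$v <- scalar_field(g, res$v, "inhibitor", attr(v, "system_index") %||% 1L)
  res
}

#' Integrate a masked system for a fixed duration
#'
#' Runs the gated Schnakenberg system for `settings$duration` time units and
#' reports whether the final pattern is stationary: `converged = TRUE` when
#' the final `max |field change| / dt` falls below
#' `settings$stationarity_tol`.
#'
#' @param u0,v0 initial `scalar_field`s.
#' @param mask a [competence_mask()] or `NULL` (kinetics active everywhere).
#' @param p a [kinetic_params()].
#' @param settings a [solver_settings()].
#' @param snapshots if `TRUE`, field snapshots are recorded every
#'   `record_every` time units and returned as `nx x ny x n_snap` arrays.
#' @return List with `u`, `v` (final fields), `trace` (data.frame of `time`
#'   and `max_change_rate`), `converged`, and optionally `snapshots_u`,
#'   `snapshots_v`, `snapshot_times`.
#' @export
#' @examples
#' g <- rd_grid(nx = 30, ny = 50)
#' p <- kinetic_params()
#' ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 7)
#' out <- run_to_stationarity(ic$u, ic$v, NULL, p,
#'                            solver_settings(duration = 5))
#' out$converged
run_to_stationarity <- function(u0, v0, mask = NULL, p = kinetic_params(),
                                settings = solver_settings(),
                                snapshots = FALSE) {
  n_steps <- as.integer(round(settings$duration / settings$dt))
  if (n_steps == 0L) {
    # no integration: report the instantaneous change rate at the input
    rate <- instantaneous_change_rate(u0, v0, mask, p)
    return(list(u = u0, v = v0,
                trace = data.frame(time = 0, max_change_rate = rate),
                converged = rate < settings$stationarity_tol))
  }
  snap_every <- if (snapshots)
    max(1L, as.integer(round(settings$record_every / settings$dt))) else 0L
  res <- run_masked_system(u0, v0, mask, p, settings, n_steps,
                           snapshot_every_steps = snap_every)
  rate <- res$trace_rate[length(res$trace_rate)]
  out <- list(u = res$u, v = res$v,
              trace = data.frame(time = res$trace_time,
                                 max_change_rate = res$trace_rate),
              converged = rate < settings$stationarity_tol)
  if (snapshots) {
    out$snapshots_u <- res$snapshots_u
    out$snapshots_v <- res$snapshots_v
    out$snapshot_times <- res$snapshot_times
  }
  out
}

instantaneous_change_rate <- function(u, v, mask, p) {
  g <- field_grid(u)
  S <- mask_matrix(mask, g)
  kin <- evaluate_kinetics(p, pmax(unclass_matrix(u), 0), pmax(unclass_matrix(v), 0))
  du <- p$D_u * unclass_matrix(laplacian(u)) + S * kin$f
  dv <- p$D_v * unclass_matrix(laplacian(v)) + S * kin$g
  max(abs(du), abs(dv))
}
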