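#' Schedule for the consecutive Turing systems
#'
#' Defines the ordered sequence of masked reaction-diffusion systems: 5
#' morphogen pairs by default, the first integrated for 500 time units on
#' the fully competent domain, each subsequent one for 1,000 time units on
#' the region not yet patterned.
#'
#' @param n_systems number of sequential systems (default 5).
#' @param durations per-system integration times; default `c(500, 1000,
#'   1000, ...)` matching `n_systems`.
#' @param scenario `"full"` (every earlier system restricts the next),
#'   `"remove_bud2"` (system 2 still runs but its condensations never
#'   restrict later systems), or `"horseshoe"` (systems 3+ are confined to a
#'   horseshoe ring around the primary bud, independent of system 2).
#' @param per_system_params a single [kinetic_params()] used for every
#'   system, or a list of length `n_systems`.
#' @param seed integer master seed; per-system seeds are derived from it
#'   deterministically.
#' @return A `simulation_schedule` object.
#' @export
simulation_schedule <- function(n_systems = 5L,
                                durations = NULL,
                                scenario = c("full", "remove_bud2", "horseshoe"),
                                per_system_params = kinetic_params(),
                                seed = 1L) {
  scenario <- match.arg(scenario)
  n_systems <- as.integer(n_systems)
  stopifnot(n_systems >= 1L)
  if (is.null(durations))
    durations <- c(500, rep(1000, n_systems - 1L))
  if (length(durations) != n_systems)
    stop("durations has length ", length(durations),
         " but n_systems = ", n_systems)
  if (any(durations <= 0)) stop("all durations must be > 0")
  if (inherits(per_system_params, "kinetic_params"))
    per_system_params <- rep(list(per_system_params), n_systems)
  if (length(per_system_params) != n_systems)
    stop("per_system_params must have one entry per system")
  structure(list(n_systems = n_systems, durations = durations,
                 scenario = scenario, per_system_params = per_system_params,
                 seed = as.integer(seed)),
            class = "simulation_schedule")
}

#' @export
print.simulation_schedule <- function(x, ...) {
  cat(sprintf("<simulation_schedule> %d systems, scenario '%s', seed %d\n",
              x$n_systems, x$scenario, x$seed))
  cat("  durations:", paste(x$durations, collapse = ", "), "\n")
  invisible(x)
}

derive_system_seeds <- function(seed, n) {
  withr_seed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}

# union of dilated condensations of the given systems, as an exclusion mask
exclusion_mask <- function(grid, condensations_by_system, systems, margin) {
  m <- competence_mask(grid, 1L)
  for (s in systems) {
    m <- shrink_competence(m, condensations_by_system[[s]], margin)
  }
  competence_mask(grid, unclass_matrix(m), 1L)
}

#' Scenario-specific competence rule
#'
#' Rewrites the candidate competence mask of system `i` according to the
#' scenario: `"full"` leaves it unchanged; `"remove_bud2"` rebuilds it from
#' the condensations of system 1 and systems 3..(i-1) only, so the second
#' bud never restricts later systems; `"horseshoe"` intersects the mask
#' built from system-1 exclusions with the horseshoe ring (systems 3+).
#'
#' @param scenario scenario tag.
#' @param i system index (>= 2).
#' @param mask_candidate the mask produced by the default (full) rule.
#' @param context list with `grid`, `condensations` (per-system list so
#'   far), `margin`, and for the horseshoe scenario `horseshoe` (a
#'   `competence_mask`).
#' @return A `competence_mask` for system `i`.
#' @export
apply_scenario <- function(scenario, i, mask_candidate, context) {
  stopifnot(i >= 2L)
  g <- context$grid
  switch(scenario,
    full = mask_candidate,
    remove_bud2 = {
      if (i <= 2L) return(mask_candidate)
      keep <- setdiff(seq_len(i - 1L), 2L)
      m <- exclusion_mask(g, context$condensations, keep, context$margin)
      competence_mask(g, unclass_matrix(m), i)
    },
    horseshoe = {
      if (i <= 2L) return(mask_candidate)
      if (is.null(context$horseshoe))
        stop("horseshoe scenario needs a horseshoe mask in the context")
      m1 <- exclusion_mask(g, context$condensations, 1L, context$margin)
      m <- compose_scenario_mask(m1, context$horseshoe)
      competence_mask(g, unclass_matrix(m), i)
    },
    stop("unknown scenario '", scenario, "'"))
}

#' Run the consecutive masked Turing systems
#'
#' Implements the sequential patterning scheme: system 1 runs on the fully
#' competent domain; each subsequent system runs on the domain minus the
#' dilated condensations of the systems before it (modified by the
#' scenario).  Every system starts from its own freshly perturbed
#' homogeneous state; noise seeds are derived deterministically from
#' `schedule$seed`.
#'
#' @param schedule a [simulation_schedule()].
#' @param grid an [rd_grid()].
#' @param settings a [solver_settings()]; `duration` is overridden per
#'   system by the schedule.
#' @param threshold_fraction,min_area_cells condensation extraction
#'   parameters (see [extract_condensations()]).
#' @param margin exclusion dilation radius (length units).
#' @param amplitude initial perturbation amplitude.
#' @param horseshoe either `NULL` (defaults derived from the primary spot:
#'   `r_inner` = 1.2 x primary-spot radius, `r_outer = r_inner + 2.5`,
#'   60-degree half-angle opening facing posterior) or a list overriding
#'   `center`, `r_inner`, `r_outer`, `opening_half_angle`,
#'   `opening_direction`.
#' @return A `sequential_result`: per-system entries (`u`, `v`, `mask`,
#'   `condensations`, `converged`, `seed`), the schedule, grid, settings,
#'   and an event log.
#' @export
#' @examples
#' \donttest{
#' sched <- simulation_schedule(n_systems = 2, durations = c(60, 60), seed = 3)
#' res <- run_sequence(sched, rd_grid(nx = 48, ny = 80),
#'                     solver_settings(dt = 0.1))
#' lengths(lapply(res$systems, `[[`, "condensations"))
#' }
run_sequence <- function(schedule, grid = rd_grid(),
                         settings = solver_settings(),
                         threshold_fraction = 0.5, min_area_cells = 4L,
                         margin = 0.5, amplitude = 0.01, horseshoe = NULL) {
  n <- schedule$n_systems
  seeds <- derive_system_seeds(schedule$seed, n)
  systems <- vector("list", n)
  condensations <- vector("list", n)
  log <- character(0)
  horseshoe_mask_obj <- NULL
  say <- function(...) log <<- c(log, sprintf(...))

  for (i in seq_len(n)) {
    p <- schedule$per_system_params[[i]]
    # competence mask: full-rule candidate, then scenario modification
    if (i == 1L) {
      mask <- competence_mask(grid, 1L, 1L)
    } else {
      cand <- exclusion_mask(grid, condensations, seq_len(i - 1L), margin)
      cand <- competence_mask(grid, unclass_matrix(cand), i)
      ctx <- list(grid = grid, condensations = condensations,
                  margin = margin, horseshoe = horseshoe_mask_obj)
      mask <- apply_scenario(schedule$scenario, i, cand, ctx)
    }
    say("system %d: %.1f%% of the domain competent, seed %d",
        i, 100 * mean(mask == 1L), seeds[i])

    ic <- make_initial_condition(grid, p, amplitude, seeds[i])
    set_i <- settings
    set_i$duration <- schedule$durations[i]
    out <- run_to_stationarity(ic$u, ic$v, mask, p, set_i)
    attr(out$u, "system_index") <- i
    attr(out$v, "system_index") <- i
    cond <- extract_condensations(out$u, p, threshold_fraction, min_area_cells,
                                  mask = mask)
    for (k in seq_along(cond)) cond[[k]]$system_index <- i
    condensations[[i]] <- cond
    say("system %d: %d condensation(s), converged = %s",
        i, length(cond), out$converged)
    if (length(cond) == 0L)
      warning("system ", i, " produced no condensations")

    if (i == 1L && schedule$scenario == "horseshoe") {
      horseshoe_mask_obj <- build_horseshoe(grid, cond, horseshoe)
      say("horseshoe ring covers %.1f%% of the domain",
          100 * mean(horseshoe_mask_obj == 1L))
    }

    systems[[i]] <- list(u = out$u, v = out$v, mask = mask,
                         condensations = cond, converged = out$converged,
                         seed = seeds[i], duration = schedule$durations[i],
                         params = p)
  }

  structure(list(systems = systems, schedule = schedule, grid = grid,
                 settings = settings,
                 threshold_fraction = threshold_fraction,
                 min_area_cells = min_area_cells, margin = margin,
                 amplitude = amplitude,
                 horseshoe_mask = horseshoe_mask_obj,
                 event_log = log),
            class = "sequential_result")
}

build_horseshoe <- function(grid, system1_condensations, override) {
  if (length(system1_condensations) == 0L)
    stop("cannot place the horseshoe: system 1 produced no condensation")
  areas <- vapply(system1_condensations, `[[`, numeric(1), "area")
  primary <- system1_condensations[[which.max(areas)]]
  r_spot <- sqrt(primary$area / pi)
  defaults <- list(center = primary$centroid,
                   r_inner = 1.2 * r_spot,
                   r_outer = 1.2 * r_spot + 2.5,
                   opening_half_angle = 60,
                   opening_direction = 180)
  cfg <- modifyList(defaults, override %||% list())
  horseshoe_mask(grid, cfg$center, cfg$r_inner, cfg$r_outer,
                 cfg$opening_half_angle, cfg$opening_direction)
}

#' @export
print.sequential_result <- function(x, ...) {
  cat(sprintf("<sequential_result> %d systems, scenario '%s', seed %d\n",
              x$schedule$n_systems, x$schedule$scenario, x$schedule$seed))
  for (i in seq_along(x$systems)) {
    s <- x$systems[[i]]
    cat(sprintf("  system %d: %d condensation(s), converged = %s\n",
                i, length(s$condensations), s$converged))
  }
  invisible(x)
}

#' Merge the per-system patterns into one composite field
#'
#' Produces the composite "final pattern": per cell, the maximum over
#' systems of the normalised activator excess
#' `(u_i - u*_i) / max(u_i - u*_i)`, clipped at 0, together with a per-cell
#' label of the dominating system (0 where no system exceeds its steady
#' state).  Systems with a flat field contribute zeros.
#'
#' @param result a `sequential_result`.
#' @return List with `field` (a `scalar_field` in `[0, 1]`) and
#'   `system_label` (integer matrix).
#' @export
merge_patterns <- function(result) {
  g <- result$grid
  best <- matrix(0, g$nx, g$ny)
  label <- matrix(0L, g$nx, g$ny)
  for (i in seq_along(result$systems)) {
    s <- result$systems[[i]]
    us <- homogeneous_steady_state(s$params)[["u"]]
    excess <- unclass_matrix(s$u) - us
    m <- max(excess)
    if (m <= 0) next
    norm <- pmax(excess / m, 0)
    take <- norm > best
    best[take] <- norm[take]
    label[take] <- i
  }
  list(field = scalar_field(g, best, "activator"), system_label = label)
}
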