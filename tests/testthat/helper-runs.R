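# shared grids and memoised simulation runs (helpers are sourced once per
# test session, so expensive runs are reused across test files)
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.run_cache[[key]])) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

coarse_grid <- function() rd_grid(nx = 60, ny = 100)
tiny_grid <- function(nx = 30, ny = 50) rd_grid(nx = nx, ny = ny)

# a complete 5-system run at the coarse desk grid
scenario_run <- function(scenario = "full", seed = 11) {
  cached(paste0("run60-", scenario, "-", seed), function() {
    suppressWarnings(run_sequence(
      simulation_schedule(seed = seed, scenario = scenario), coarse_grid()))
  })
}

# hand-built sequential_result from planted-bump fields (no PDE run)
planted_result <- function(grid = coarse_grid(), p = kinetic_params()) {
  us <- homogeneous_steady_state(p)[["u"]]
  mk_system <- function(centers, idx) {
    fx <- generate_fixture(
      fixture_spec("planted_bumps", grid, centers = centers,
                   amplitudes = 2, widths = 0.8), p)
    u <- fx$u
    attr(u, "system_index") <- idx
    mask <- competence_mask(grid, 1L, idx)
    cond <- extract_condensations(u, p, 0.5, 4L, mask = mask)
    for (k in seq_along(cond)) cond[[k]]$system_index <- idx
    list(u = u, v = scalar_field(grid, 1, "inhibitor", idx), mask = mask,
         condensations = cond, converged = TRUE, params = p,
         centers = centers)
  }
  sys1 <- mk_system(rbind(c(7.5, 12.5)), 1L)
  sys2 <- mk_system(rbind(c(3, 4), c(12, 4), c(7.5, 20)), 2L)
  structure(list(systems = list(sys1, sys2),
                 schedule = simulation_schedule(n_systems = 2,
                                                durations = c(1, 1)),
                 grid = grid, threshold_fraction = 0.5,
                 min_area_cells = 4L, margin = 0.5,
                 event_log = character(0)),
            class = "sequential_result")
}

periodic_dist <- function(a, b, period = 25) {
  sqrt((a[1] - b[1])^2 + ((((a[2] - b[2]) + period / 2) %% period) - period / 2)^2)
}
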