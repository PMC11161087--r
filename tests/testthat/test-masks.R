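p_default <- kinetic_params()

test_that("condensation extraction recovers planted bumps", {
  g <- coarse_grid()
  centers <- rbind(c(4, 5), c(11, 12), c(6, 20))
  fx <- generate_fixture(
    fixture_spec("planted_bumps", g, centers = centers, amplitudes = 2,
                 widths = 1), p_default)
  cond <- extract_condensations(fx$u, p_default, 0.5)
  expect_length(cond, 3)
  got <- t(vapply(cond, function(cd) cd$centroid, numeric(2)))
  for (k in 1:3) {
    d <- apply(got, 1, function(ct) periodic_dist(ct, centers[k, ]))
    expect_lt(min(d), 0.5)
  }
  expect_true(all(vapply(cond, `[[`, numeric(1), "area") > 0))

  # homogeneous field: nothing above the steady state
  flat <- scalar_field(g, homogeneous_steady_state(p_default)[["u"]])
  expect_length(extract_condensations(flat, p_default, 0.5), 0)
})

test_that("a bump straddling the periodic seam is one component", {
  g <- coarse_grid()
  fx <- generate_fixture(
    fixture_spec("planted_bumps", g, centers = rbind(c(7, 0.2)),
                 amplitudes = 2, widths = 1.2), p_default)
  cond <- extract_condensations(fx$u, p_default, 0.5)
  expect_length(cond, 1)

  # oracle: label a y-rolled copy (seam moved to the interior) and compare
  roll_by <- g$ny %/% 2
  rolled <- unclass(fx$u)[, c((roll_by + 1):g$ny, 1:roll_by)]
  cond_r <- extract_condensations(scalar_field(g, rolled), p_default, 0.5)
  expect_length(cond_r, 1)
  expect_equal(cond_r[[1]]$n_cells, cond[[1]]$n_cells)
  shifted_back <- (cond_r[[1]]$centroid[["y"]] + roll_by * g$dy) %% g$width_y
  expect_lt(abs(shifted_back - cond[[1]]$centroid[["y"]]), 1e-6)
})

test_that("periodic-wrap labelling agrees with labelling a tiled field", {
  g <- coarse_grid()
  fx <- generate_fixture(
    fixture_spec("planted_bumps", g,
                 centers = rbind(c(7, 0.2), c(3, 10), c(12, 17)),
                 amplitudes = 2, widths = 1), p_default)
  us <- homogeneous_steady_state(p_default)[["u"]]
  m <- unclass(fx$u)
  cut <- us + 0.5 * (max(m) - us)
  above <- m > cut

  lab_wrap <- label_components_cpp(above, TRUE)
  # oracle: tile twice in y, label without wrap, and take a window of one
  # period positioned so that its edges cut no bump (bumps and their
  # copies lie at y = 10, 17, 25.2 of the doubled field)
  lab_tile <- label_components_cpp(cbind(above, above), FALSE)
  y_tiled <- (seq_len(2 * g$ny) - 0.5) * g$dy
  mid <- lab_tile[, y_tiled > 5 & y_tiled <= 30]
  expect_identical(max(lab_wrap), length(unique(mid[mid > 0])))
  expect_equal(as.integer(sort(table(lab_wrap[lab_wrap > 0]))),
               as.integer(sort(table(mid[mid > 0]))))
})

test_that("extraction ignores sub-threshold background shifts", {
  g <- coarse_grid()
  fx <- generate_fixture(
    fixture_spec("planted_bumps", g, centers = rbind(c(4, 5), c(11, 18)),
                 amplitudes = 2, widths = 1), p_default)
  cond <- extract_condensations(fx$u, p_default, 0.5)
  us <- homogeneous_steady_state(p_default)[["u"]]
  m <- unclass(fx$u)
  cut <- us + 0.5 * (max(m) - us)
  shifted <- m
  low <- m <= cut - 0.3  # background cells staying below the cut after +0.2
  shifted[low] <- shifted[low] + 0.2
  cond2 <- extract_condensations(scalar_field(g, shifted), p_default, 0.5)
  expect_identical(lapply(cond2, `[[`, "cells"), lapply(cond, `[[`, "cells"))
})

test_that("shrink_competence removes dilated condensations monotonically", {
  g <- coarse_grid()
  ones <- competence_mask(g, 1L)
  expect_equal(unclass(shrink_competence(ones, list(), 0.5)),
               unclass(ones), ignore_attr = TRUE)

  fx <- generate_fixture(
    fixture_spec("planted_bumps", g, centers = rbind(c(7, 12)),
                 amplitudes = 2, widths = 1), p_default)
  cond <- extract_condensations(fx$u, p_default, 0.5)

  # margin 0: exactly the component cells are zeroed
  m0 <- shrink_competence(ones, cond, 0)
  expect_identical(which(unclass(m0) == 0L), sort(cond[[1]]$cells))

  # positive margin: a superset of the component is zeroed; subset invariant
  m1 <- shrink_competence(ones, cond, 0.5)
  expect_true(all(m1[cond[[1]]$cells] == 0L))
  expect_gt(sum(m0), sum(m1))
  expect_true(all(unclass(m1) <= unclass(ones)))

  # idempotence for a fixed condensation list
  m2 <- shrink_competence(m1, cond, 0.5)
  expect_equal(unclass(m2), unclass(m1), ignore_attr = TRUE)

  # removing everything leaves S == 0, so kinetics are off everywhere
  all_cells <- list(condensation_like <- list(cells = seq_len(g$nx * g$ny)))
  m_empty <- shrink_competence(ones, all_cells, 0)
  expect_true(all(m_empty == 0L))
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 4)
  out <- run_to_stationarity(ic$u, ic$v, m_empty, p,
                             solver_settings(dt = 0.05, duration = 20))
  expect_length(extract_condensations(out$u, p, 0.5, mask = m_empty), 0)
})

test_that("horseshoe mask geometry matches its definition", {
  g <- rd_grid(nx = 150, ny = 250)  # fine grid for the area comparison
  ctr <- c(7.5, 12.5)

  # full annulus: rasterised area within 5% of pi (r_out^2 - r_in^2)
  ann <- horseshoe_mask(g, ctr, r_inner = 2, r_outer = 5,
                        opening_half_angle = 0)
  expect_equal(sum(ann) * g$dx * g$dy, pi * (25 - 4), tolerance = 0.05)

  # opening of 180 degrees excludes everything
  empty <- horseshoe_mask(g, ctr, 2, 5, opening_half_angle = 180)
  expect_true(all(empty == 0L))

  # ring body opposite the opening is competent
  hs <- horseshoe_mask(g, ctr, 2, 5, opening_half_angle = 60,
                       opening_direction = 180)
  probe <- c(7.5, 12.5 - 3.5)  # anterior of center, mid-ring
  i <- which.min(abs(g$x - probe[1])); j <- which.min(abs(g$y - probe[2]))
  expect_identical(hs[i, j], 1L)
  # a point inside the opening wedge is not
  jp <- which.min(abs(g$y - (12.5 + 3.5)))
  expect_identical(hs[i, jp], 0L)

  expect_error(horseshoe_mask(g, ctr, 2, 13, 0), "periodic extent")
})

test_that("scenario overlay composition is an elementwise AND", {
  g <- coarse_grid()
  base <- competence_mask(g, 1L)
  expect_identical(unclass(compose_scenario_mask(base, NULL)), unclass(base))
  expect_identical(unclass(compose_scenario_mask(base, competence_mask(g, 1L))),
                   unclass(base))
  hs <- horseshoe_mask(g, c(7.5, 12.5), 2, 5, 60)
  expect_identical(unclass(compose_scenario_mask(base, hs)), unclass(hs))
  g2 <- rd_grid(nx = 40, ny = 64)
  expect_error(compose_scenario_mask(base, competence_mask(g2, 1L)),
               "different grids")
})

test_that("masks round-trip exactly through the field container", {
  run <- planted_result()
  path <- withr::local_tempfile(fileext = ".rds")
  write_fields_container(run, path)
  back <- read_fields_container(path)
  for (i in seq_along(run$systems)) {
    expect_identical(unclass(back$systems[[i]]$mask),
                     unclass(run$systems[[i]]$mask))
    expect_equal(unclass(back$systems[[i]]$u), unclass(run$systems[[i]]$u),
                 ignore_attr = TRUE)
  }
})
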