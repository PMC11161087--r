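test_that("laplacian reproduces boundary-condition eigenfunctions", {
  g <- rd_grid(nx = 120, ny = 200)
  p <- kinetic_params()

  # constant field
  f0 <- scalar_field(g, 2.5)
  expect_true(all(abs(laplacian(f0)) < 1e-12))

  # periodic eigenfunction in y
  ky <- 2 * pi / g$width_y
  fy <- scalar_field(g, outer(rep(1, g$nx), cos(ky * g$y)))
  err <- max(abs(laplacian(fy) + ky^2 * fy))
  expect_lt(err, ky^2 * (ky * g$dy)^2 / 10)  # O(spacing^2)

  # zero-flux (Neumann) eigenfunction in x
  kx <- pi / g$width_x
  fx <- scalar_field(g, outer(cos(kx * g$x), rep(1, g$ny)))
  err <- max(abs(laplacian(fx) + kx^2 * fx))
  expect_lt(err, kx^2 * (kx * g$dx)^2 / 10)

  expect_error(laplacian_cpp(matrix(0, 2, 10), 1, 1), "at least 3 cells")
})

test_that("perturbed initial conditions honour amplitude and seed", {
  g <- tiny_grid()
  p <- kinetic_params()
  ss <- homogeneous_steady_state(p)

  ic0 <- make_initial_condition(g, p, amplitude = 0, seed = 9)
  expect_true(all(ic0$u == ss[["u"]]))
  expect_true(all(ic0$v == ss[["v"]]))

  a <- make_initial_condition(g, p, amplitude = 0.01, seed = 42)
  b <- make_initial_condition(g, p, amplitude = 0.01, seed = 42)
  expect_identical(unclass(a$u), unclass(b$u))
  expect_identical(unclass(a$v), unclass(b$v))
  c_ <- make_initial_condition(g, p, amplitude = 0.01, seed = 43)
  expect_false(identical(unclass(a$u), unclass(c_$u)))

  expect_true(all(a$u >= 0.99 * ss[["u"]] & a$u <= 1.01 * ss[["u"]]))
  expect_true(all(a$v >= 0.99 * ss[["v"]] & a$v <= 1.01 * ss[["v"]]))
})

test_that("the homogeneous steady state is a fixed point of the solver", {
  g <- tiny_grid()
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0, seed = 1)
  out <- run_to_stationarity(ic$u, ic$v, NULL, p,
                             solver_settings(dt = 0.05, duration = 50))
  ss <- homogeneous_steady_state(p)
  expect_lt(max(abs(out$u - ss[["u"]])), 1e-10)
  expect_lt(max(abs(out$v - ss[["v"]])), 1e-10)
  expect_true(out$converged)
})

test_that("pure diffusion conserves mass under the mixed boundaries", {
  g <- tiny_grid(nx = 32, ny = 48)
  p <- kinetic_params()
  off <- competence_mask(g, 0L)
  pulse <- matrix(0, g$nx, g$ny)
  pulse[10, 17] <- 1
  u <- scalar_field(g, pulse + 0.1)
  v <- scalar_field(g, pulse + 0.1, "inhibitor")
  m0 <- sum(u)
  out <- run_to_stationarity(u, v, off, p,
                             solver_settings(dt = 0.05, duration = 50))
  expect_lt(abs(sum(out$u) - m0) / m0, 1e-8)
  expect_lt(abs(sum(out$v) - m0) / m0, 1e-8)
})

test_that("dynamics are equivariant under translation by the y period", {
  g <- rd_grid(nx = 40, ny = 64)
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 5)
  roll <- function(m, k) m[, c((ncol(m) - k + 1):ncol(m), 1:(ncol(m) - k))]
  st <- solver_settings(dt = 0.05, duration = 20)
  out1 <- run_to_stationarity(ic$u, ic$v, NULL, p, st)
  out2 <- run_to_stationarity(scalar_field(g, roll(unclass(ic$u), 16)),
                              scalar_field(g, roll(unclass(ic$v), 16),
                                           "inhibitor"),
                              NULL, p, st)
  expect_lt(max(abs(roll(unclass(out1$u), 16) - unclass(out2$u))), 1e-9)
})

test_that("no-flux boundary: the x-gradient vanishes at the walls", {
  run <- scenario_run("full", seed = 11)
  u <- unclass(run$systems[[1]]$u)
  g <- run$grid
  boundary_grad <- max(abs(u[2, ] - u[1, ]), abs(u[g$nx, ] - u[g$nx - 1, ])) / g$dx
  interior_grad <- max(abs(diff(u))) / g$dx
  expect_lt(boundary_grad, 0.25 * interior_grad)
})

test_that("semi-implicit and explicit schemes integrate the same dynamics", {
  g <- rd_grid(nx = 20, ny = 30)
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 2)
  dt <- 0.002  # inside the explicit stability bound dx^2/(4 max(D))
  a <- run_to_stationarity(ic$u, ic$v, NULL, p,
                           solver_settings(dt = dt, duration = 2, scheme = "imex"))
  b <- run_to_stationarity(ic$u, ic$v, NULL, p,
                           solver_settings(dt = dt, duration = 2, scheme = "euler"))
  expect_lt(max(abs(a$u - b$u)), 5e-3)
  expect_lt(max(abs(a$v - b$v)), 5e-3)
})

test_that("a seeded admissible mode grows at the dispersion-relation rate", {
  p <- kinetic_params()
  g <- coarse_grid()
  fx <- generate_fixture(fixture_spec("single_mode", g, mode_x = 2,
                                      mode_y = 0, amplitude = 1e-4), p)
  lam <- with(list(J = jacobian_at_steady_state(p)), {
    k2 <- fx$truth$k^2
    A <- J - k2 * diag(c(p$D_u, p$D_v))
    max(Re(eigen(A)$values))
  })
  ss <- homogeneous_steady_state(p)
  out <- run_to_stationarity(fx$u, scalar_field(g, ss[["v"]], "inhibitor"),
                             NULL, p,
                             solver_settings(dt = 0.005, duration = 60,
                                             record_every = 2),
                             snapshots = TRUE)
  amp <- apply(out$snapshots_u, 3,
               function(f) sum((f - mean(f)) * fx$truth$mode) /
                           sum(fx$truth$mode^2))
  tt <- out$snapshot_times
  sel <- tt >= 20 & amp > 0
  slope <- unname(coef(lm(log(amp[sel]) ~ tt[sel]))[2])
  expect_equal(slope, lam, tolerance = 0.05)
})

test_that("zero duration returns the inputs with an instantaneous verdict", {
  g <- tiny_grid()
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0, seed = 1)
  out <- run_to_stationarity(ic$u, ic$v, NULL, p,
                             solver_settings(duration = 0))
  expect_identical(unclass(out$u), unclass(ic$u))
  expect_true(out$converged)  # exact steady state: zero change rate

  icp <- make_initial_condition(g, p, amplitude = 0.05, seed = 1)
  outp <- run_to_stationarity(icp$u, icp$v, NULL, p,
                              solver_settings(duration = 0,
                                              stationarity_tol = 1e-12))
  expect_false(outp$converged)
})

test_that("equal diffusion relaxes a perturbation back to homogeneity", {
  g <- coarse_grid()
  p <- kinetic_params(D_u = 1, D_v = 1)
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 3)
  out <- run_to_stationarity(ic$u, ic$v, NULL, p,
                             solver_settings(dt = 0.05, duration = 100))
  expect_lt(max(out$u) - min(out$u), 1e-3 * homogeneous_steady_state(p)[["u"]])
  expect_true(out$converged)
})

test_that("the explicit scheme reports integration failure on blow-up", {
  g <- tiny_grid()
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 1)
  expect_error(
    run_to_stationarity(ic$u, ic$v, NULL, p,
                        solver_settings(dt = 5, duration = 50,
                                        scheme = "euler")),
    "integration failure")
})

test_that("halving dt leaves the converged pattern unchanged within 1%", {
  g <- rd_grid(nx = 48, ny = 80)
  p <- kinetic_params()
  ic <- make_initial_condition(g, p, amplitude = 0.01, seed = 8)
  a <- run_to_stationarity(ic$u, ic$v, NULL, p,
                           solver_settings(dt = 0.05, duration = 400))
  b <- run_to_stationarity(ic$u, ic$v, NULL, p,
                           solver_settings(dt = 0.025, duration = 400))
  rng <- max(a$u) - min(a$u)
  expect_gt(rng, 0.5 * homogeneous_steady_state(p)[["u"]])  # patterned
  expect_lt(max(abs(a$u - b$u)) / rng, 0.01)
})
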