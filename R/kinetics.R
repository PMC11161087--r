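#' Schnakenberg kinetic parameters
#'
#' Bundles the kinetic constants of the activator-inhibitor pair
#' `f(u, v) = a - u + u^2 v`, `g(u, v) = b - u^2 v` together with the two
#' diffusion coefficients.  The defaults `a = 0.3`, `b = 0.8` are the
#' constants printed in the model equations; `D_u = 1`, `D_v = 40` place the
#' system comfortably inside the Turing (spot-forming) regime, whose
#' critical diffusion ratio for these kinetics is about 28.5.
#'
#' @param a activator basal production rate (dimensionless, >= 0).
#' @param b inhibitor-side production rate (dimensionless, > 0).
#' @param D_u activator diffusion coefficient (length^2/time, > 0).
#' @param D_v inhibitor diffusion coefficient (length^2/time, > 0).
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' p <- kinetic_params()
#' homogeneous_steady_state(p)
kinetic_params <- function(a = 0.3, b = 0.8, D_u = 1, D_v = 40) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(D_u), is.numeric(D_v))
  if (a < 0) stop("a must be >= 0 (got ", a, ")")
  if (b <= 0) stop("b must be > 0 (got ", b, ")")
  if (D_u <= 0) stop("D_u must be > 0 (got ", D_u, ")")
  if (D_v <= 0) stop("D_v must be > 0 (got ", D_v, ")")
  if (a + b <= 0) stop("a + b must be > 0 for the steady state to exist")
  structure(list(a = a, b = b, D_u = D_u, D_v = D_v),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> a = %g, b = %g, D_u = %g, D_v = %g (D_v/D_u = %g)\n",
              x$a, x$b, x$D_u, x$D_v, x$D_v / x$D_u))
  invisible(x)
}

#' Evaluate the Schnakenberg reaction terms
#'
#' Returns the reaction rates `f = a - u + u^2 v` (activator) and
#' `g = b - u^2 v` (inhibitor) at the given concentrations.  Vectorised over
#' `u` and `v`.
#'
#' @param p a [kinetic_params()].
#' @param u,v non-negative concentrations (scalars, vectors or matrices of
#'   equal shape).
#' @return A list with components `f` and `g`.
#' @export
evaluate_kinetics <- function(p, u, v) {
  if (any(u < 0)) stop("negative activator concentration u = ", min(u))
  if (any(v < 0)) stop("negative inhibitor concentration v = ", min(v))
  uuv <- u * u * v
  list(f = p$a - u + uuv, g = p$b - uuv)
}

#' Homogeneous steady state of the Schnakenberg kinetics
#'
#' Setting `f = g = 0` and adding the two equations gives `u* = a + b`;
#' substituting back gives `v* = b / (a + b)^2`.
#'
#' @param p a [kinetic_params()].
#' @return Named numeric vector `c(u = u_star, v = v_star)`.
#' @export
homogeneous_steady_state <- function(p) {
  if (p$a + p$b <= 0) stop("singular parameters: a + b must be > 0")
  u_star <- p$a + p$b
  c(u = u_star, v = p$b / u_star^2)
}

#' Jacobian of the kinetics at the homogeneous steady state
#'
#' Partial derivatives of `(f, g)` with respect to `(u, v)` evaluated at
#' `(u*, v*)`:
#' `[[ -1 + 2 u* v*, u*^2 ], [ -2 u* v*, -u*^2 ]]`.
#'
#' @param p a [kinetic_params()].
#' @return A 2 x 2 numeric matrix with dimnames `(f, g) x (u, v)`.
#' @export
jacobian_at_steady_state <- function(p) {
  ss <- homogeneous_steady_state(p)
  us <- ss[["u"]]; vs <- ss[["v"]]
  matrix(c(-1 + 2 * us * vs, -2 * us * vs, us^2, -us^2), 2, 2,
         dimnames = list(c("f", "g"), c("u", "v")))
}

# largest real part of the eigenvalues of J - q * diag(D_u, D_v), q = k^2,
# via the closed-form 2x2 characteristic polynomial
growth_rate_at <- function(J, D_u, D_v, q) {
  tr <- (J[1, 1] - q * D_u) + (J[2, 2] - q * D_v)
  det <- (J[1, 1] - q * D_u) * (J[2, 2] - q * D_v) - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
}

#' Critical diffusion ratio for Turing instability
#'
#' Solves the marginal-instability condition
#' `D_v f_u + D_u g_v = 2 sqrt(D_u D_v det J)` for the ratio `d = D_v/D_u`.
#' With `s = sqrt(d)` this is the quadratic `f_u s^2 - 2 sqrt(det J) s + g_v
#' = 0`; the larger root gives the threshold above which a band of
#' wavenumbers grows.
#'
#' @param p a [kinetic_params()] (only `a`, `b` matter).
#' @return The critical ratio `D_v/D_u` (dimensionless), or `Inf` when the
#'   activator is not self-enhancing at the steady state (`f_u <= 0`), in
#'   which case no diffusion ratio destabilises the state.
#' @export
critical_diffusion_ratio <- function(p) {
  J <- jacobian_at_steady_state(p)
  fu <- J[1, 1]; gv <- J[2, 2]
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (detJ <= 0) stop("det J <= 0: steady state is a saddle, no Turing analysis")
  if (fu <= 0) return(Inf)
  s <- (sqrt(detJ) + sqrt(detJ - fu * gv)) / fu
  s^2
}

#' Turing dispersion relation
#'
#' Growth rate of a spatial perturbation with wavenumber `k`: the largest
#' real part of the eigenvalues of `J - k^2 diag(D_u, D_v)`, computed from
#' the closed-form 2 x 2 characteristic polynomial on a uniform grid of
#' wavenumbers.  Diffusion-driven (Turing) instability requires the
#' steady state to be stable without diffusion (`tr J < 0 < det J`) while
#' some `k > 0` grows.
#'
#' @param p a [kinetic_params()].
#' @param k_max largest wavenumber sampled (1/length).
#' @param n_samples number of uniformly spaced samples (>= 2), including 0
#'   and `k_max`.
#' @param grid optional [rd_grid()]; when supplied, the admissible modes of
#'   the rectangle (cosine modes `pi * p / width_x` in the zero-flux x
#'   direction, integer modes `2 * pi * m / width_y` in the periodic y
#'   direction) are evaluated and the one nearest to `k_crit` is reported.
#' @return A `dispersion_result` list: `wavenumbers`, `growth_rates`,
#'   `k_crit` (continuous maximiser of the growth rate), `max_growth_rate`,
#'   `is_turing_unstable`, `d_crit` (critical `D_v/D_u`), `warning_code`
#'   (`"unstable_without_diffusion"` when `tr J >= 0` or `det J <= 0`, else
#'   `NA`), and when `grid` is given, `k_admissible` (the nearest admissible
#'   mode) and `admissible_modes` (all admissible wavenumbers <= `k_max`).
#' @export
#' @examples
#' d <- dispersion_relation(kinetic_params(), k_max = 2, n_samples = 201)
#' d$is_turing_unstable
#' 2 * pi / d$k_crit  # predicted pattern wavelength
dispersion_relation <- function(p, k_max = 2, n_samples = 401, grid = NULL) {
  stopifnot(k_max > 0, n_samples >= 2)
  J <- jacobian_at_steady_state(p)
  trJ <- J[1, 1] + J[2, 2]
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  stable_k0 <- (trJ < 0 && detJ > 0)
  warning_code <- if (!stable_k0) "unstable_without_diffusion" else NA_character_

  k <- seq(0, k_max, length.out = n_samples)
  growth <- growth_rate_at(J, p$D_u, p$D_v, k^2)

  # continuous maximiser of the growth rate over q = k^2
  opt <- stats::optimize(function(q) growth_rate_at(J, p$D_u, p$D_v, q),
                         interval = c(0, k_max^2), maximum = TRUE,
                         tol = 1e-12)
  g0 <- growth_rate_at(J, p$D_u, p$D_v, 0)
  k_crit <- if (opt$objective > g0) sqrt(opt$maximum) else 0
  max_growth <- max(opt$objective, growth)

  positive_band <- any(growth[k > 0] > 0) || (opt$objective > 0 && opt$maximum > 0)
  res <- list(
    wavenumbers = k,
    growth_rates = growth,
    k_crit = k_crit,
    max_growth_rate = max_growth,
    is_turing_unstable = stable_k0 && positive_band,
    d_crit = if (detJ > 0) critical_diffusion_ratio(p) else NA_real_,
    trace_J = trJ, det_J = detJ,
    warning_code = warning_code)

  if (!is.null(grid)) {
    px <- 0:ceiling(k_max * grid$width_x / pi)
    my <- 0:ceiling(k_max * grid$width_y / (2 * pi))
    modes <- sqrt(outer((pi * px / grid$width_x)^2,
                        (2 * pi * my / grid$width_y)^2, `+`))
    modes <- sort(unique(as.vector(modes)))
    modes <- modes[modes <= k_max]
    res$admissible_modes <- modes
    nonzero <- modes[modes > 0]
    res$k_admissible <- if (length(nonzero))
      nonzero[which.min(abs(nonzero - k_crit))] else NA_real_
  }
  class(res) <- "dispersion_result"
  res
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> %s; k_crit = %.4g (wavelength %.4g), max growth = %.4g\n",
              if (x$is_turing_unstable) "Turing unstable" else "no Turing instability",
              x$k_crit, 2 * pi / x$k_crit, x$max_growth_rate))
  if (!is.na(x$warning_code)) cat("  warning:", x$warning_code, "\n")
  cat(sprintf("  d_crit (D_v/D_u at margin) = %.4g\n", x$d_crit))
  invisible(x)
}

#' Export a dispersion curve as a two-column CSV
#'
#' @param d a `dispersion_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(d, path) {
  write.csv(data.frame(k = d$wavenumbers, growth_rate = d$growth_rates),
            path, row.names = FALSE)
  invisible(path)
}
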