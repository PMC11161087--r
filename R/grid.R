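#' Construct the simulation grid
#'
#' Defines a regular finite-difference grid on the rectangular tissue domain
#' `[0, width_x] x [0, width_y]`.  The x direction (left/right) carries
#' zero-flux boundaries, the y direction (top/bottom) is periodic; y is the
#' axis to which the anterior-posterior polarity is assigned after
#' simulation.  Cell centers sit at `(i + 1/2) * spacing` with 0-based `i`.
#'
#' @param width_x,width_y domain extents (length units); defaults 15 x 25.
#' @param nx,ny number of cells in x and y; both must be >= 8.
#' @param k_crit optional fastest-growing wavenumber; if supplied, a warning
#'   is issued when the grid under-resolves the predicted pattern wavelength
#'   (`2*pi/k_crit < 6 * max(spacing)`).
#'
#' @return An object of class `rd_grid`: a list with fields `width_x`,
#'   `width_y`, `nx`, `ny`, `dx`, `dy` and cell-center coordinate vectors
#'   `x`, `y`.
#' @export
#' @examples
#' g <- rd_grid(nx = 60, ny = 100)
#' g$dx
rd_grid <- function(width_x = 15, width_y = 25, nx = 120, ny = 200,
                    k_crit = NULL) {
  stopifnot(width_x > 0, width_y > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L)
    stop("grid must have at least 8 cells in each direction (got ",
         nx, " x ", ny, ")")
  dx <- width_x / nx
  dy <- width_y / ny
  if (!is.null(k_crit) && is.finite(k_crit) && k_crit > 0) {
    if (2 * pi / k_crit < 6 * max(dx, dy))
      warning("grid spacing under-resolves the pattern wavelength 2*pi/k_crit")
  }
  structure(
    list(width_x = width_x, width_y = width_y, nx = nx, ny = ny,
         dx = dx, dy = dy,
         x = (seq_len(nx) - 0.5) * dx,
         y = (seq_len(ny) - 0.5) * dy),
    class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("<rd_grid> [0, %g] x [0, %g], %d x %d cells (dx = %g, dy = %g)\n",
              x$width_x, x$width_y, x$nx, x$ny, x$dx, x$dy))
  cat("  x: zero-flux boundaries; y: periodic\n")
  invisible(x)
}

grid_compatible <- function(g1, g2) {
  isTRUE(all.equal(g1[c("width_x", "width_y", "nx", "ny")],
                   g2[c("width_x", "width_y", "nx", "ny")]))
}

#' Construct a scalar concentration field on a grid
#'
#' A `scalar_field` is a numeric `nx x ny` matrix (rows index x, columns
#' index y) with its grid and provenance attached.
#'
#' @param grid an [rd_grid()].
#' @param values a numeric matrix of dimension `nx x ny`, or a single number
#'   recycled over the grid.
#' @param species `"activator"` or `"inhibitor"`.
#' @param system_index which sequential system the field belongs to.
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(grid, values, species = c("activator", "inhibitor"),
                         system_index = 1L) {
  species <- match.arg(species)
  if (length(values) == 1L) values <- matrix(values, grid$nx, grid$ny)
  values <- as.matrix(values)
  if (nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("values must be a ", grid$nx, " x ", grid$ny, " matrix")
  if (!all(is.finite(values)))
    stop("field values must be finite everywhere")
  structure(values, grid = grid, species = species,
            system_index = as.integer(system_index),
            class = c("scalar_field", "matrix", "array"))
}

#' @export
print.scalar_field <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<scalar_field> %s (system %d) on %d x %d grid; range [%.4g, %.4g]\n",
              attr(x, "species"), attr(x, "system_index"),
              g$nx, g$ny, min(x), max(x)))
  invisible(x)
}

field_grid <- function(f) {
  g <- attr(f, "grid")
  if (is.null(g)) stop("field carries no grid; build it with scalar_field()")
  g
}

# periodic displacement y2 - y1 mapped into (-period/2, period/2]
wrap_dy <- function(dy, period) {
  ((dy + period / 2) %% period) - period / 2
}

# Euclidean distance with periodic y metric
periodic_distance <- function(x1, y1, x2, y2, period) {
  sqrt((x2 - x1)^2 + wrap_dy(y2 - y1, period)^2)
}
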