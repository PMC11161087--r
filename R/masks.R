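#' Binary competence mask
#'
#' The indicator `S(x, y)` of the competence region Omega: reactions of a
#' given system are active only where the mask is 1.  Morphogens diffuse
#' everywhere regardless of the mask.
#'
#' @param grid an [rd_grid()].
#' @param values matrix of 0/1 (or logical) of dimension `nx x ny`, or a
#'   single value recycled; defaults to all-ones (competent everywhere).
#' @param system_index which sequential system this mask gates.
#' @return A `competence_mask` object (integer 0/1 matrix with grid
#'   attached).
#' @export
competence_mask <- function(grid, values = 1L, system_index = 1L) {
  if (length(values) == 1L) values <- matrix(values, grid$nx, grid$ny)
  values <- as.matrix(values)
  if (is.logical(values)) values <- values * 1L
  if (nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("mask values must be a ", grid$nx, " x ", grid$ny, " matrix")
  if (!all(values %in% c(0L, 1L)))
    stop("mask values must be exactly 0 or 1")
  storage.mode(values) <- "integer"
  structure(values, grid = grid, system_index = as.integer(system_index),
            class = c("competence_mask", "matrix", "array"))
}

#' @export
print.competence_mask <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<competence_mask> system %d on %d x %d grid; %.1f%% competent\n",
              attr(x, "system_index"), g$nx, g$ny, 100 * mean(x == 1L)))
  invisible(x)
}

#' Extract activator condensations from a stationary field
#'
#' Cells whose activator concentration exceeds
#' `u* + threshold_fraction * (max(u) - u*)` are grouped into 4-connected
#' components, wrapping across the periodic y boundary; components smaller
#' than `min_area_cells` cells are discarded.  Each retained component is a
#' condensation (a model feather primordium).
#'
#' @param u stationary activator `scalar_field`.
#' @param p the [kinetic_params()] of the system that produced `u` (for the
#'   steady-state baseline `u*`).
#' @param threshold_fraction fraction of the above-steady-state amplitude
#'   used as the cut, in (0, 1); default 0.5 (half maximum).
#' @param min_area_cells smallest component kept, in cells.
#' @param mask optional [competence_mask()]: when given, condensation
#'   membership is restricted to competent cells.  Outside the competence
#'   region the kinetics are off, so above-threshold activator there is
#'   residual morphogen that diffused out of a bud, not bud tissue itself.
#' @return A list of `condensation` objects, each with `cells` (linear cell
#'   indices), `centroid` (`c(x, y)`, y via the periodic circular mean),
#'   `area` (cells times cell area), `peak_value`, `n_cells` and
#'   `system_index`.  A field with no cell above `u*` yields an empty list.
#' @export
extract_condensations <- function(u, p, threshold_fraction = 0.5,
                                  min_area_cells = 4L, mask = NULL) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  g <- field_grid(u)
  us <- homogeneous_steady_state(p)[["u"]]
  m <- unclass_matrix(u)
  if (max(m) <= us) return(list())
  cut <- us + threshold_fraction * (max(m) - us)
  above <- m > cut
  if (!is.null(mask)) above <- above & (unclass_matrix(mask) == 1L)
  if (!any(above)) return(list())
  lab <- label_components_cpp(above, TRUE)
  out <- list()
  for (id in seq_len(max(lab))) {
    cells <- which(lab == id)
    if (length(cells) < min_area_cells) next
    out[[length(out) + 1L]] <- condensation_from_cells(
      g, cells, m, attr(u, "system_index") %||% 1L)
  }
  out
}

condensation_from_cells <- function(grid, cells, values, system_index) {
  i <- ((cells - 1L) %% grid$nx) + 1L
  j <- ((cells - 1L) %/% grid$nx) + 1L
  w <- values[cells]
  cx <- sum(grid$x[i] * w) / sum(w)
  # circular (periodic) weighted mean in y
  th <- 2 * pi * grid$y[j] / grid$width_y
  cy <- atan2(sum(sin(th) * w), sum(cos(th) * w)) * grid$width_y / (2 * pi)
  cy <- cy %% grid$width_y
  structure(list(cells = cells,
                 centroid = c(x = cx, y = cy),
                 area = length(cells) * grid$dx * grid$dy,
                 peak_value = max(w),
                 n_cells = length(cells),
                 system_index = as.integer(system_index)),
            class = "condensation")
}

#' @export
print.condensation <- function(x, ...) {
  cat(sprintf("<condensation> system %d at (%.2f, %.2f), area %.2f, peak %.3f\n",
              x$system_index, x$centroid[["x"]], x$centroid[["y"]],
              x$area, x$peak_value))
  invisible(x)
}

# logical matrix of cells within `margin` of any listed cell
# (Euclidean disc, periodic in y, clipped in x)
dilate_cells <- function(grid, cells, margin) {
  base <- matrix(FALSE, grid$nx, grid$ny)
  base[cells] <- TRUE
  if (margin <= 0) return(base)
  ri <- floor(margin / grid$dx)
  rj <- floor(margin / grid$dy)
  acc <- base
  for (di in -ri:ri) {
    for (dj in -rj:rj) {
      if (di == 0 && dj == 0) next
      if ((di * grid$dx)^2 + (dj * grid$dy)^2 > margin^2) next
      sh <- matrix(FALSE, grid$nx, grid$ny)
      src_i <- seq_len(grid$nx) - di
      keep <- src_i >= 1L & src_i <= grid$nx
      jj <- ((seq_len(grid$ny) - 1L - dj) %% grid$ny) + 1L
      sh[keep, ] <- base[src_i[keep], jj]
      acc <- acc | sh
    }
  }
  acc
}

#' Shrink a competence region around new condensations
#'
#' Produces the competence mask of the next system: the previous mask minus
#' every condensation dilated by a disc of radius `margin` (periodic in y).
#' The result is always a subset of `prev_mask`.
#'
#' @param prev_mask the current [competence_mask()].
#' @param condensations list of condensations from [extract_condensations()].
#' @param margin dilation radius (length units, >= 0); default 0.5.
#' @return A new `competence_mask` for `system_index + 1`.
#' @export
shrink_competence <- function(prev_mask, condensations, margin = 0.5) {
  stopifnot(margin >= 0)
  g <- attr(prev_mask, "grid")
  vals <- unclass_matrix(prev_mask)
  if (length(condensations)) {
    cells <- unlist(lapply(condensations, `[[`, "cells"))
    excl <- dilate_cells(g, cells, margin)
    vals[excl] <- 0L
  }
  competence_mask(g, vals, attr(prev_mask, "system_index") + 1L)
}

# bearing in degrees from a reference point: 0 = anterior (-y),
# positive toward +x (right); result in (-180, 180]
bearing_from <- function(dx_, dy_) {
  th <- atan2(dx_, -dy_) * 180 / pi
  ifelse(th <= -180, th + 360, th)
}

#' Horseshoe competence region
#'
#' Ring (annulus) around a center with an angular opening: cells whose
#' distance from the center (periodic in y) lies in `[r_inner, r_outer]` and
#' whose bearing is outside the opening wedge are competent.  Bearings are
#' measured from the anterior direction (0 degrees = -y), positive toward
#' +x.
#'
#' @param grid an [rd_grid()].
#' @param center `c(x, y)` of the ring center (length units).
#' @param r_inner,r_outer inner/outer radii, `0 < r_inner < r_outer`.
#' @param opening_half_angle half-width of the opening wedge in degrees,
#'   `[0, 180]`; 0 gives a full annulus, 180 an empty mask.
#' @param opening_direction bearing of the middle of the opening (degrees);
#'   default 180 (posterior, +y).
#' @param system_index stored on the resulting mask.
#' @return A `competence_mask`.
#' @export
horseshoe_mask <- function(grid, center, r_inner, r_outer,
                           opening_half_angle = 60, opening_direction = 180,
                           system_index = 1L) {
  stopifnot(r_inner > 0, r_outer > r_inner,
            opening_half_angle >= 0, opening_half_angle <= 180)
  if (2 * r_outer > grid$width_y)
    stop("annulus diameter ", 2 * r_outer,
         " exceeds the periodic extent ", grid$width_y,
         " (would self-overlap through the wrap)")
  dxm <- outer(grid$x - center[[1]], rep(1, grid$ny))
  dym <- outer(rep(1, grid$nx), wrap_dy(grid$y - center[[2]], grid$width_y))
  r <- sqrt(dxm^2 + dym^2)
  th <- bearing_from(dxm, dym)
  ang_dist <- abs(wrap_dy(th - opening_direction, 360))
  inside <- (r >= r_inner) & (r <= r_outer) & (ang_dist > opening_half_angle)
  competence_mask(grid, inside, system_index)
}

#' Intersect a competence mask with a scenario overlay
#'
#' Elementwise AND of the base competence with an overlay mask (for example
#' the horseshoe region).  A `NULL` overlay returns the base unchanged.
#'
#' @param base a [competence_mask()].
#' @param scenario_overlay a `competence_mask` on the same grid, or `NULL`.
#' @return A `competence_mask`.
#' @export
compose_scenario_mask <- function(base, scenario_overlay = NULL) {
  if (is.null(scenario_overlay)) return(base)
  gb <- attr(base, "grid"); go <- attr(scenario_overlay, "grid")
  if (!grid_compatible(gb, go)) stop("base and overlay masks live on different grids")
  competence_mask(gb, unclass_matrix(base) * unclass_matrix(scenario_overlay),
                  attr(base, "system_index"))
}
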