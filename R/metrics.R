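#' Detect spots across a finished sequential run
#'
#' Re-extracts the activator condensations of every system at the given
#' detection threshold and pools them into one spot table.  The primary bud
#' is the largest-area spot of system 1.
#'
#' @param result a `sequential_result` from [run_sequence()].
#' @param detection_threshold threshold fraction passed to
#'   [extract_condensations()].
#' @param min_area_cells smallest component kept.
#' @return A `spot_set`: a data.frame with columns `spot_id`, `system`, `x`,
#'   `y`, `area`, `peak`, `n_cells`, plus attributes `primary_index` (row of
#'   the primary spot) and `grid`.
#' @export
detect_spots <- function(result, detection_threshold = 0.5,
                         min_area_cells = 4L) {
  rows <- list()
  for (i in seq_along(result$systems)) {
    s <- result$systems[[i]]
    cond <- extract_condensations(s$u, s$params, detection_threshold,
                                  min_area_cells, mask = s$mask)
    for (cd in cond) {
      rows[[length(rows) + 1L]] <- data.frame(
        system = i, x = cd$centroid[["x"]], y = cd$centroid[["y"]],
        area = cd$area, peak = cd$peak_value, n_cells = cd$n_cells)
    }
  }
  if (length(rows) == 0L || !any(vapply(rows, function(r) r$system == 1L, logical(1))))
    stop("system 1 produced no spot: no primary bud to reference")
  df <- do.call(rbind, rows)
  df <- cbind(spot_id = seq_len(nrow(df)), df)
  sys1 <- which(df$system == 1L)
  primary <- sys1[which.max(df$area[sys1])]
  spot_set(df, primary, result$grid)
}

#' Construct a spot set from a spot table
#'
#' @param df data.frame with at least `system`, `x`, `y`, `area` columns.
#' @param primary_index row index of the primary bud (must be a system-1
#'   spot).
#' @param grid the [rd_grid()] the coordinates refer to.
#' @return A `spot_set`.
#' @export
spot_set <- function(df, primary_index, grid) {
  if (!"spot_id" %in% names(df)) df <- cbind(spot_id = seq_len(nrow(df)), df)
  if (!"peak" %in% names(df)) df$peak <- NA_real_
  if (!"n_cells" %in% names(df)) df$n_cells <- NA_integer_
  if (df$system[primary_index] != 1L)
    stop("the primary spot must belong to system 1")
  structure(df, primary_index = as.integer(primary_index), grid = grid,
            class = c("spot_set", "data.frame"))
}

#' Nearest-neighbour spacing statistics of a spot set
#'
#' Distances use the periodic metric in y (the top/bottom wrap of the
#' domain).
#'
#' @param spots a `spot_set` (or data.frame with `x`, `y` and a `grid`
#'   attribute).
#' @param grid optional [rd_grid()] override.
#' @return List with `mean_nn` (mean nearest-neighbour distance),
#'   `min_distance` and `count`.
#' @export
spacing_statistics <- function(spots, grid = NULL) {
  g <- grid %||% attr(spots, "grid")
  n <- nrow(spots)
  if (n < 2L) stop("spacing statistics need at least 2 spots (got ", n, ")")
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- periodic_distance(spots$x[i], spots$y[i],
                                              spots$x[j], spots$y[j],
                                              g$width_y)
    }
  }
  nn <- apply(d, 1L, min)
  list(mean_nn = mean(nn), min_distance = min(nn), count = n)
}

default_sector_config <- function() {
  list(anterior_direction = 0,     # bearing of the anterior (-y) direction
       anterior_half_angle = 30,   # class 3 wedge: |bearing| < 30
       lateral_max = 90,           # classes 4/4': 30 <= |bearing| < 90
       posterior_lateral_max = 150)# classes 5/5': 90 <= |bearing| < 150
}

#' Classify ectopic spot positions relative to the primary bud
#'
#' Applies the spatial taxonomy of ectopic buds: class 2 lies in the
#' interbud region (distance from the primary beyond `interbud_radius`);
#' closer spots are classified by bearing from the primary bud into
#' anterior (3), lateral (4 right / 4' left), posterior-lateral (5/5'), or
#' `unclassified` for the posterior wedge, where no ectopic buds are
#' observed.  Bearings are measured from the anterior direction (0 degrees =
#' -y), positive toward +x; sectors are half-open on their upper edge.
#'
#' @param spots a `spot_set`.
#' @param sector_config list overriding `anterior_direction`,
#'   `anterior_half_angle`, `lateral_max`, `posterior_lateral_max`
#'   (degrees).
#' @param interbud_radius distance separating near-field classes from the
#'   interbud class 2; default 0.6 x the system-1 nearest-neighbour spacing
#'   when several system-1 spots exist, else 0.6 x min(domain extents)/2.
#' @return A data.frame: `spot_id`, `system`, `label` (factor with levels
#'   1, 2, 3, 4, 4', 5, 5', unclassified), `bearing` (degrees), `distance`.
#' @export
classify_positions <- function(spots, sector_config = list(),
                               interbud_radius = NULL) {
  g <- attr(spots, "grid")
  cfg <- modifyList(default_sector_config(), sector_config)
  pi_ <- attr(spots, "primary_index")
  px <- spots$x[pi_]; py <- spots$y[pi_]

  if (is.null(interbud_radius)) {
    sys1 <- spots[spots$system == 1L, , drop = FALSE]
    interbud_radius <- if (nrow(sys1) >= 2L)
      0.6 * spacing_statistics(sys1, g)$mean_nn
    else 0.6 * min(g$width_x, g$width_y) / 2
  }

  levels_ <- c("1", "2", "3", "4", "4'", "5", "5'", "unclassified")
  n <- nrow(spots)
  label <- character(n); bearing <- numeric(n); distance <- numeric(n)
  for (r in seq_len(n)) {
    dx_ <- spots$x[r] - px
    dy_ <- wrap_dy(spots$y[r] - py, g$width_y)
    distance[r] <- sqrt(dx_^2 + dy_^2)
    th <- wrap_dy(bearing_from(dx_, dy_) - cfg$anterior_direction, 360)
    bearing[r] <- th
    if (r == pi_) { label[r] <- "1"; next }
    if (distance[r] > interbud_radius) { label[r] <- "2"; next }
    ath <- abs(th)
    label[r] <-
      if (ath < cfg$anterior_half_angle) "3"
      else if (ath < cfg$lateral_max) { if (th >= 0) "4" else "4'" }
      else if (ath < cfg$posterior_lateral_max) { if (th >= 0) "5" else "5'" }
      else "unclassified"
  }
  data.frame(spot_id = spots$spot_id, system = spots$system,
             label = factor(label, levels = levels_),
             bearing = bearing, distance = distance)
}

#' Canonical bud-combination code
#'
#' Collapses the classified spot labels into the canonical combination
#' string used for bud-pattern tallies, e.g. `"1+2+3+4'"`.  The primary
#' class 1 is always included; `unclassified` spots are not part of the
#' vocabulary and are omitted.
#'
#' @param classes the data.frame from [classify_positions()], or a character
#'   vector of labels.
#' @return A single string.
#' @export
combination_code <- function(classes) {
  labs <- if (is.data.frame(classes)) as.character(classes$label) else as.character(classes)
  order_ <- c("1", "2", "3", "4", "4'", "5", "5'")
  present <- union("1", intersect(order_, labs))
  paste(order_[order_ %in% present], collapse = "+")
}

#' Write a classified spot table as CSV
#'
#' @param spots a `spot_set`.
#' @param classes matching output of [classify_positions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spot_csv <- function(spots, classes, path) {
  df <- data.frame(spot_id = spots$spot_id, system = spots$system,
                   x = spots$x, y = spots$y, area = spots$area,
                   peak = spots$peak, class = as.character(classes$label),
                   bearing_deg = classes$bearing,
                   distance = classes$distance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
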