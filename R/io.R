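#' Save a sequential run as a self-describing field container
#'
#' Stores all final fields and masks as one named-dimension array stack
#' (dimensions x, y, species, system) together with the grid, kinetic
#' parameters and schedule metadata, so the file can be re-analysed without
#' re-simulation.
#'
#' @param result a `sequential_result`.
#' @param path output file (conventionally `fields.rds`).
#' @return `path`, invisibly.
#' @export
write_fields_container <- function(result, path) {
  g <- result$grid
  n <- length(result$systems)
  fields <- array(NA_real_, c(g$nx, g$ny, 2L, n),
                  dimnames = list(NULL, NULL, c("u", "v"), NULL))
  masks <- array(NA_integer_, c(g$nx, g$ny, n))
  for (i in seq_len(n)) {
    s <- result$systems[[i]]
    fields[, , "u", i] <- unclass_matrix(s$u)
    fields[, , "v", i] <- unclass_matrix(s$v)
    masks[, , i] <- unclass_matrix(s$mask)
  }
  obj <- list(
    format = "turingbuds-fields-v1",
    dims = c("x", "y", "species", "system"),
    grid = g,
    fields = fields,
    masks = masks,
    params = result$schedule$per_system_params,
    schedule = result$schedule,
    threshold_fraction = result$threshold_fraction,
    min_area_cells = result$min_area_cells,
    margin = result$margin,
    converged = vapply(result$systems, `[[`, logical(1), "converged"),
    event_log = result$event_log)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a field container back as a re-analysable result
#'
#' @param path file written by [write_fields_container()].
#' @return A `sequential_result` (without solver traces).
#' @export
read_fields_container <- function(path) {
  if (!file.exists(path)) stop("field container not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("garbled field container ", path, ": ", conditionMessage(e)))
  if (!identical(obj$format, "turingbuds-fields-v1"))
    stop("file ", path, " is not a turingbuds field container")
  g <- obj$grid
  n <- dim(obj$fields)[4]
  systems <- vector("list", n)
  for (i in seq_len(n)) {
    p <- obj$params[[i]]
    u <- scalar_field(g, obj$fields[, , "u", i], "activator", i)
    v <- scalar_field(g, obj$fields[, , "v", i], "inhibitor", i)
    mask_i <- competence_mask(g, obj$masks[, , i], i)
    cond <- extract_condensations(u, p, obj$threshold_fraction,
                                  obj$min_area_cells, mask = mask_i)
    for (k in seq_along(cond)) cond[[k]]$system_index <- i
    systems[[i]] <- list(u = u, v = v,
                         mask = mask_i,
                         condensations = cond,
                         converged = obj$converged[i],
                         params = p)
  }
  structure(list(systems = systems, schedule = obj$schedule, grid = g,
                 threshold_fraction = obj$threshold_fraction,
                 min_area_cells = obj$min_area_cells, margin = obj$margin,
                 event_log = obj$event_log),
            class = "sequential_result")
}

field_palette <- function(n = 64) grDevices::hcl.colors(n, "viridis")

#' Write a field (or mask) as a PNG heatmap
#'
#' Masks are rendered white = competent on black, matching the convention
#' that the region with competence to undergo patterning is shown in white.
#'
#' @param field a `scalar_field` or `competence_mask`.
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
write_field_png <- function(field, path, width = 480, height = 800) {
  g <- field_grid(field)
  vals <- unclass_matrix(field)
  storage.mode(vals) <- "double"
  grDevices::png(path, width = width, height = height)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  col <- if (inherits(field, "competence_mask"))
    c("black", "white") else field_palette()
  graphics::image(g$x, g$y, vals, col = col, useRaster = TRUE,
                  axes = FALSE, xlab = "", ylab = "")
  invisible(path)
}

#' Write the progressive animation frames of a sequential run
#'
#' Frame `i` shows the merged pattern of systems `1..i`, mirroring the
#' stepwise appearance of new buds.
#'
#' @param result a `sequential_result`.
#' @param dir output directory (created if needed).
#' @return Character vector of frame paths, invisibly.
#' @export
write_animation_frames <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(result$systems)
  paths <- character(n)
  for (i in seq_len(n)) {
    partial <- result
    partial$systems <- result$systems[seq_len(i)]
    mg <- merge_patterns(partial)
    paths[i] <- file.path(dir, sprintf("frame_%02d.png", i))
    write_field_png(mg$field, paths[i])
  }
  invisible(paths)
}
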