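# Gridded habitat projection: prediction grid, layer interpolation,
# probability maps, climate-scenario difference maps, high-value areas.

#' Build a regular prediction grid over a bounding box
#'
#' An `nx` x `ny` lattice of longitude/latitude nodes spanning the box
#' inclusively, with planar UTM coordinates and a water mask (depth > 0)
#' attached.
#'
#' @param bbox Named vector/list with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` (degrees).
#' @param nx,ny Nodes per axis (>= 2).
#' @param depth Optional depth [env_field()]; nodes with depth <= 0 or
#'   outside the layer are masked as land. Without it all nodes are water.
#' @return Object of class `pred_grid`: `$nodes` (data.frame `lon`, `lat`,
#'   `x`, `y`, `water`), `$nx`, `$ny`. Node count is always `nx * ny`.
#' @export
make_prediction_grid <- function(bbox, nx = 101, ny = 101, depth = NULL) {
  bb <- as.list(bbox)
  if (bb$lon_max <= bb$lon_min || bb$lat_max <= bb$lat_min) {
    stop("inverted bounding box")
  }
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  lon <- seq(bb$lon_min, bb$lon_max, length.out = nx)
  lat <- seq(bb$lat_min, bb$lat_max, length.out = ny)
  nodes <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  pl <- project_to_plane(nodes$lon, nodes$lat)
  nodes$x <- pl$x
  nodes$y <- pl$y
  if (is.null(depth)) {
    nodes$water <- TRUE
  } else {
    d <- rep(NA_real_, nrow(nodes))
    inside <- nodes$lon >= min(depth$lon) & nodes$lon <= max(depth$lon) &
      nodes$lat >= min(depth$lat) & nodes$lat <= max(depth$lat)
    d[inside] <- field_lookup(depth, nodes$lon[inside], nodes$lat[inside])
    nodes$water <- !is.na(d) & d > 0
    nodes$depth_m <- d
  }
  structure(
    list(nodes = nodes, lon = lon, lat = lat, nx = nx, ny = ny,
         zone = attr(pl, "zone"), bbox = bb),
    class = "pred_grid"
  )
}

#' @export
print.pred_grid <- function(x, ...) {
  cat(sprintf("Prediction grid: %d x %d = %d nodes (%d water)\n",
              x$nx, x$ny, nrow(x$nodes), sum(x$nodes$water)))
  invisible(x)
}

#' Interpolate environmental layers onto a prediction grid
#'
#' Bilinear interpolation of each layer at the grid nodes; nodes outside a
#' layer's support get NA and are removed from the water mask.
#'
#' @param grid A [make_prediction_grid()] object.
#' @param layers List of [env_field()]s; each contributes a covariate
#'   column named after the field.
#' @return The grid with covariate columns added to `$nodes`.
#' @export
interpolate_layers <- function(grid, layers) {
  stopifnot(inherits(grid, "pred_grid"))
  nodes <- grid$nodes
  for (layer in layers) {
    inside <- nodes$lon >= min(layer$lon) & nodes$lon <= max(layer$lon) &
      nodes$lat >= min(layer$lat) & nodes$lat <= max(layer$lat)
    if (!any(inside)) stop(sprintf("layer %s does not overlap the grid", layer$name))
    v <- rep(NA_real_, nrow(nodes))
    v[inside] <- field_lookup(layer, nodes$lon[inside], nodes$lat[inside])
    nodes[[layer$name]] <- v
    nodes$water <- nodes$water & !is.na(v)
  }
  grid$nodes <- nodes
  grid
}

#' Predict an occurrence probability map on a grid
#'
#' Applies the fitted model node-wise on water nodes; land/masked nodes
#' stay NA.
#'
#' @param model A converged `sdm_fit` (or a `pooling_result`, predicted via
#'   [predict_pooled()]).
#' @param grid A covariate-carrying [make_prediction_grid()] object.
#' @param label Map label (season, scenario/decade, ...).
#' @param date_index Time index passed to spatiotemporal predictions.
#' @return Object of class `prob_map`: grid axes, `$values` (length
#'   `nx * ny`, NA off water), `$label`.
#' @export
project_map <- function(model, grid, label = "", date_index = NULL) {
  stopifnot(inherits(grid, "pred_grid"))
  if (inherits(model, "sdm_fit") && !model$converged) {
    stop("refusing to project a non-converged model")
  }
  nodes <- grid$nodes
  if (!is.null(date_index)) nodes$date_index <- date_index
  wet <- which(nodes$water)
  vals <- rep(NA_real_, nrow(nodes))
  nd <- nodes[wet, , drop = FALSE]
  vals[wet] <- if (inherits(model, "pooling_result")) {
    predict_pooled(model, nd)
  } else {
    predict(model, nd)
  }
  structure(
    list(lon = grid$lon, lat = grid$lat, nx = grid$nx, ny = grid$ny,
         water = nodes$water, values = vals, label = label),
    class = "prob_map"
  )
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat)) &&
    identical(a$water, b$water)
}

#' Future-minus-current difference map
#'
#' @param future,current Two [project_map()] maps on the same grid.
#' @return Object of class `delta_map` with node-wise `future - current`
#'   (in [-1, 1] on water nodes).
#' @export
scenario_difference <- function(future, current) {
  if (!.same_grid(future, current)) stop("maps are on different grids")
  structure(
    list(lon = future$lon, lat = future$lat, nx = future$nx, ny = future$ny,
         water = future$water, values = future$values - current$values,
         label = paste(future$label, "-", current$label)),
    class = "delta_map"
  )
}

#' High-value (probability > threshold) area of a map
#'
#' @param map A [project_map()] probability map.
#' @param threshold Probability threshold in (0, 1); strictly exceeded.
#' @return List with logical `mask` (NA off water) and `fraction` (flagged
#'   water nodes / water nodes).
#' @export
high_value_mask <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mask <- map$values > threshold
  list(mask = mask, fraction = sum(mask[map$water]) / sum(map$water),
       threshold = threshold)
}

#' Average several probability maps (e.g. seasons into an annual map)
#'
#' @param maps List of [project_map()] maps on one grid.
#' @param label Label of the averaged map.
#' @return A `prob_map` with node-wise mean values.
#' @export
average_maps <- function(maps, label = "annual") {
  for (m in maps[-1]) {
    if (!.same_grid(maps[[1]], m)) stop("maps are on different grids")
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out <- maps[[1]]
  out$values <- vals
  out$label <- label
  out
}

#' Write a map as long-format CSV (lon, lat, value, label)
#'
#' @param map A `prob_map` or `delta_map`.
#' @param path Output path.
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(
    lon = rep(map$lon, times = length(map$lat)),
    lat = rep(map$lat, each = length(map$lon)),
    value = map$values, label = map$label
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
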