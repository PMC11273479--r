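# Spatial discretisation: regular lattice mesh, SPDE Matern precision,
# bilinear projector. The lattice plays the role a triangulated mesh plays in
# the usual SPDE workflow; with piecewise-(bi)linear elements and a lumped
# mass matrix the resulting precision is the standard Matern (smoothness 1)
# GMRF approximation.

#' Matern correlation (smoothness 1)
#'
#' `corr(d) = kappa*d * K_1(kappa*d)` with `kappa = sqrt(8)/range`, so that
#' correlation at `d = range` has dropped to about 0.14 (the conventional
#' "decorrelation range").
#'
#' @param d Distances (same units as `range`).
#' @param range Decorrelation range (> 0).
#' @return Correlation values in [0, 1]; 1 at d = 0.
#' @export
matern_correlation <- function(d, range) {
  if (range <= 0) stop("range must be positive")
  kd <- sqrt(8) * d / range
  out <- ifelse(kd == 0, 1, kd * besselK(kd, 1))
  # besselK underflows to 0 for large arguments, which is the right limit
  out[!is.finite(out)] <- 0
  out
}

#' Build a regular lattice mesh over station locations
#'
#' Creates the discrete spatial domain on which the Matern GMRF lives: a
#' rectangular lattice of nodes covering the stations' planar bounding box
#' plus a buffer (the buffer keeps boundary artefacts of the SPDE
#' approximation away from the data).
#'
#' @param coords Station coordinates: a data.frame with planar `x`, `y`
#'   columns in kilometres (see [project_to_plane()]), or with `lon`, `lat`
#'   columns in degrees (projected internally; the UTM zone is stored).
#' @param spacing_km Target node spacing in kilometres.
#' @param buffer_km Buffer width beyond the station bounding box (km).
#' @return An object of class `sdm_mesh`: node axes, node coordinates, and
#'   the projection metadata needed to map longitude/latitude data onto it.
#' @export
build_mesh <- function(coords, spacing_km, buffer_km = 2 * spacing_km) {
  if (spacing_km <= 0) stop("spacing_km must be positive")
  zone <- NULL
  if (all(c("lon", "lat") %in% names(coords))) {
    pl <- project_to_plane(coords$lon, coords$lat)
    zone <- attr(pl, "zone")
    xy <- pl
  } else if (all(c("x", "y") %in% names(coords))) {
    xy <- coords[, c("x", "y")]
  } else {
    stop("coords must have columns lon/lat or x/y")
  }
  uxy <- unique(xy)
  if (nrow(uxy) < 3) stop("need at least 3 distinct station locations")
  # collinearity check via the cross product of spanning vectors
  v1 <- c(uxy$x[2] - uxy$x[1], uxy$y[2] - uxy$y[1])
  cross <- abs((uxy$x - uxy$x[1]) * v1[2] - (uxy$y - uxy$y[1]) * v1[1])
  if (max(cross) < 1e-9) stop("stations are collinear; cannot build a 2-D mesh")

  ax <- function(lo, hi) {
    lo <- lo - buffer_km
    hi <- hi + buffer_km
    k <- max(1L, ceiling((hi - lo) / spacing_km))
    seq(lo, lo + k * spacing_km, by = spacing_km)
  }
  xs <- ax(min(xy$x), max(xy$x))
  ys <- ax(min(xy$y), max(xy$y))
  nodes <- cbind(
    x = rep(xs, times = length(ys)),
    y = rep(ys, each = length(xs))
  )
  structure(
    list(
      x = xs, y = ys, nodes = nodes,
      nx = length(xs), ny = length(ys), n = length(xs) * length(ys),
      spacing_km = spacing_km, buffer_km = buffer_km, zone = zone
    ),
    class = "sdm_mesh"
  )
}

#' @export
print.sdm_mesh <- function(x, ...) {
  cat(sprintf(
    "Lattice mesh: %d x %d = %d nodes, spacing %.1f km, buffer %.1f km\n",
    x$nx, x$ny, x$n, x$spacing_km, x$buffer_km
  ))
  invisible(x)
}

# node index helper (column-major over x then y)
.mesh_index <- function(mesh, i, j) (j - 1L) * mesh$nx + i

#' SPDE precision matrix of a Matern GMRF on a lattice mesh
#'
#' Builds the sparse precision `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)`
#' of the smoothness-1 Matern field on the mesh nodes, with `kappa =
#' sqrt(8)/range` and `tau` chosen so the marginal standard deviation at
#' interior nodes is `sd` (`sigma^2 = 1/(4 pi kappa^2 tau^2)`). `C` is the
#' lumped mass matrix, `G` the stiffness matrix of linear elements.
#'
#' @param mesh An [build_mesh()] lattice.
#' @param range_km Decorrelation range in kilometres (> 0).
#' @param sd Marginal standard deviation (> 0).
#' @return A sparse symmetric positive-definite `Matrix` of dimension
#'   `mesh$n`.
#' @export
spde_precision <- function(mesh, range_km, sd) {
  if (range_km <= 0) stop("range_km must be positive")
  if (sd <= 0) stop("sd must be positive")
  Q <- .assemble_Q(.spde_parts(mesh), range_km, sd)
  ch <- tryCatch(Matrix::Cholesky(Q, LDL = FALSE), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf(
      "precision not positive definite (range_km = %g, sd = %g)", range_km, sd
    ))
  }
  attr(Q, "range_km") <- range_km
  attr(Q, "sd") <- sd
  Q
}

#' Bilinear projector from mesh nodes to point locations
#'
#' @param mesh An [build_mesh()] lattice.
#' @param points data.frame/matrix with planar `x`, `y` in kilometres.
#' @return Sparse matrix `A` (`npoints` x `mesh$n`) with nonnegative rows
#'   summing to one; `A %*% u` evaluates nodal values `u` at the points.
#' @export
interpolation_matrix <- function(mesh, points) {
  x <- points[, "x"]
  y <- points[, "y"]
  eps <- 1e-9
  if (any(x < mesh$x[1] - eps | x > mesh$x[mesh$nx] + eps |
          y < mesh$y[1] - eps | y > mesh$y[mesh$ny] + eps)) {
    stop("points outside the mesh extent; enlarge the buffer")
  }
  hx <- mesh$x[2] - mesh$x[1]
  hy <- mesh$y[2] - mesh$y[1]
  fx <- pmin(pmax((x - mesh$x[1]) / hx, 0), mesh$nx - 1 - 1e-12)
  fy <- pmin(pmax((y - mesh$y[1]) / hy, 0), mesh$ny - 1 - 1e-12)
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  np <- length(x)
  rows <- rep(seq_len(np), 4)
  cols <- c(
    .mesh_index(mesh, i0, j0), .mesh_index(mesh, i0 + 1L, j0),
    .mesh_index(mesh, i0, j0 + 1L), .mesh_index(mesh, i0 + 1L, j0 + 1L)
  )
  vals <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(np, mesh$n))
}
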