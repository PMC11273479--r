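# Synthetic trawl-survey generator.
#
# Emulates a four-season bottom-trawl survey of the southern Yellow Sea /
# East China Sea shelf (0.5 x 0.5 degree station grid, ~111-141 stations per
# cruise, 1-h tows) together with gridded environmental layers and
# climate-scenario variants, using the same statistical structure the
# estimator assumes: smooth (Gaussian-bump) niche responses on environmental
# covariates plus correlated Matern spatial fields, Bernoulli presence
# sampling, and a simple catch-size model on top. Every downstream module is
# exercised against this generator, whose latent truth is returned for
# recovery tests.

#' Survey design
#'
#' @param bbox Named list or vector with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` in degrees.
#' @param station_spacing Station grid spacing in degrees.
#' @param seasons Character vector of season labels in chronological order.
#' @param stations_per_season Integer vector, one count per season.
#' @param tow_hours Fixed tow duration (h) or a length-2 range to draw from.
#' @return Object of class `survey_design`. Defaults reproduce the study
#'   design: 120-127 E, 26.5-35 N at 0.5 degree spacing; autumn, winter,
#'   spring, summer cruises with 127, 111, 141 and 140 stations and 1-h tows.
#' @export
survey_design <- function(bbox = c(lon_min = 120, lon_max = 127,
                                   lat_min = 26.5, lat_max = 35),
                          station_spacing = 0.5,
                          seasons = c("autumn", "winter", "spring", "summer"),
                          stations_per_season = c(127L, 111L, 141L, 140L),
                          tow_hours = 1) {
  bbox <- as.list(bbox)
  if (bbox$lon_max <= bbox$lon_min || bbox$lat_max <= bbox$lat_min) {
    stop("degenerate bbox")
  }
  if (station_spacing <= 0) stop("station_spacing must be positive")
  if (length(seasons) != length(stations_per_season)) {
    stop("one station count per season required")
  }
  if (any(stations_per_season <= 0)) stop("station counts must be positive")
  if (!(length(tow_hours) %in% c(1, 2)) || any(tow_hours <= 0)) {
    stop("tow_hours must be a positive value or range")
  }
  structure(
    list(
      bbox = bbox, station_spacing = station_spacing,
      seasons = seasons, date_index = seq_along(seasons),
      stations_per_season = as.integer(stations_per_season),
      tow_hours = tow_hours
    ),
    class = "survey_design"
  )
}

#' Gridded environmental layer
#'
#' @param name Covariate name (station-column dialect, e.g. `"sst_c"`).
#' @param season Season label or `"all"` for static layers.
#' @param lon,lat Strictly increasing axis vectors (degrees).
#' @param values Matrix `length(lon) x length(lat)`.
#' @param units Unit string.
#' @return Object of class `env_field`.
#' @export
env_field <- function(name, season, lon, lat, values, units = "") {
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop("grid axes must be strictly increasing")
  }
  if (!is.matrix(values) ||
      !all(dim(values) == c(length(lon), length(lat)))) {
    stop("values must be a length(lon) x length(lat) matrix")
  }
  structure(
    list(name = name, season = season, lon = lon, lat = lat,
         values = values, units = units),
    class = "env_field"
  )
}

#' Bilinear lookup in an environmental layer
#'
#' @param field An [env_field()].
#' @param lon,lat Query coordinates (must lie inside the layer extent).
#' @return Numeric vector of interpolated values.
#' @export
field_lookup <- function(field, lon, lat) {
  fx <- approx(field$lon, seq_along(field$lon), xout = lon, rule = 1)$y
  fy <- approx(field$lat, seq_along(field$lat), xout = lat, rule = 1)$y
  if (any(is.na(fx)) || any(is.na(fy))) {
    stop("query points outside the layer extent")
  }
  i0 <- pmin(floor(fx), length(field$lon) - 1)
  j0 <- pmin(floor(fy), length(field$lat) - 1)
  tx <- fx - i0
  ty <- fy - j0
  v <- field$values
  idx <- cbind(i0, j0)
  v[idx] * (1 - tx) * (1 - ty) +
    v[cbind(i0 + 1, j0)] * tx * (1 - ty) +
    v[cbind(i0, j0 + 1)] * (1 - tx) * ty +
    v[cbind(i0 + 1, j0 + 1)] * tx * ty
}

# internal lattice-mesh constructor from axis vectors (km)
.lattice_mesh <- function(xs, ys) {
  structure(
    list(
      x = xs, y = ys,
      nodes = cbind(x = rep(xs, times = length(ys)),
                    y = rep(ys, each = length(xs))),
      nx = length(xs), ny = length(ys), n = length(xs) * length(ys),
      spacing_km = xs[2] - xs[1], buffer_km = 0, zone = NULL
    ),
    class = "sdm_mesh"
  )
}

#' Sample a Matern (smoothness 1) Gaussian random field on a lattice
#'
#' Draws zero-mean stationary fields with Matern nu = 1 covariance via the
#' SPDE/GMRF construction: the lattice is extended by a buffer of 1.5 times
#' the range (so the bounded-domain artefacts stay outside the requested
#' grid), the sparse precision is factorised once, and samples are obtained
#' by back-substitution.
#'
#' @param grid Either `list(lon=, lat=)` axis vectors in degrees (converted
#'   to kilometres with a local equirectangular scale) or `list(x=, y=)`
#'   axis vectors already in kilometres.
#' @param range_km Decorrelation range in km (must be > 0 when `sd > 0`).
#' @param sd Marginal standard deviation (>= 0; `sd = 0` returns zeros).
#' @param seed Integer seed; identical inputs give identical fields.
#' @param n Number of independent replicate fields.
#' @return Matrix `nx x ny` for `n = 1`, else an array `nx x ny x n`.
#' @export
sample_matern_field <- function(grid, range_km, sd, seed, n = 1) {
  if (sd < 0) stop("sd must be nonnegative")
  if (!is.null(grid$lon)) {
    midlat <- mean(range(grid$lat))
    xs <- grid$lon * 111.320 * cos(midlat * pi / 180)
    ys <- grid$lat * 110.574
  } else {
    xs <- grid$x
    ys <- grid$y
  }
  nx <- length(xs)
  ny <- length(ys)
  if (nx < 1 || ny < 1) stop("grid must have at least one node")
  if (sd == 0) {
    out <- array(0, dim = c(nx, ny, n))
    return(if (n == 1) out[, , 1, drop = TRUE] else out)
  }
  if (range_km <= 0) stop("range_km must be positive when sd > 0")
  hx <- if (nx > 1) mean(diff(xs)) else range_km / 4
  hy <- if (ny > 1) mean(diff(ys)) else range_km / 4
  bx <- ceiling(1.5 * range_km / hx)
  by <- ceiling(1.5 * range_km / hy)
  ex <- c(xs[1] - rev(seq_len(bx)) * hx, xs, xs[nx] + seq_len(bx) * hx)
  ey <- c(ys[1] - rev(seq_len(by)) * hy, ys, ys[ny] + seq_len(by) * hy)
  mesh <- .lattice_mesh(ex, ey)
  Q <- spde_precision(mesh, range_km = range_km, sd = sd)
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  z <- with_seed(seed, matrix(stats::rnorm(mesh$n * n), mesh$n, n))
  u <- as.matrix(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                               system = "Pt"))
  keep_x <- bx + seq_len(nx)
  keep_y <- by + seq_len(ny)
  out <- array(u, dim = c(length(ex), length(ey), n))[keep_x, keep_y, , drop = FALSE]
  if (n == 1) out[, , 1, drop = TRUE] else out
}

# deterministic gradient component of each covariate; u = normalised
# latitude (0 south -> 1 north), v = normalised offshore (west -> east)
.env_gradients <- list(
  sst_south = c(autumn = 23.5, winter = 17.0, spring = 25.0, summer = 29.5),
  sst_north = c(autumn = 17.5, winter = 8.5, spring = 13.0, summer = 24.5),
  strat_t   = c(autumn = 10, winter = 1, spring = 6, summer = 14),
  plume     = c(autumn = 3.5, winter = 2.5, spring = 5.5, summer = 4.5),
  do_extra  = c(autumn = NA, winter = 0, spring = 0.1, summer = 1.5),
  strat_do  = c(autumn = NA, winter = 0.1, spring = 0.3, summer = 2.2)
)

#' Generate gridded environmental layers for a survey design
#'
#' Builds depth (static) and seasonal SST/SBT/SSS/SBS/DO layers as smooth
#' latitudinal + offshore gradients (a warm south, a cool north, summer
#' stratification, a coastal low-salinity plume) plus Matern noise. The
#' default parameterisation spans the in-situ seasonal envelopes reported
#' for this shelf (e.g. summer SST roughly 25-29 C, winter SST roughly
#' 9-16 C). Dissolved-oxygen layers are not produced for autumn, mirroring
#' surveys in which the autumn DO sensor record is missing.
#'
#' @param design A [survey_design()].
#' @param seed Integer seed.
#' @param resolution Grid resolution in degrees.
#' @param noise_scale Multiplier on all Matern noise standard deviations;
#'   0 gives the purely deterministic gradients.
#' @return Object of class `env_set`: a list of [env_field()]s indexed as
#'   `name.season` (depth as `depth_m.all`).
#' @export
generate_environment <- function(design, seed, resolution = 0.25,
                                 noise_scale = 1) {
  stopifnot(inherits(design, "survey_design"))
  bb <- design$bbox
  lon <- seq(bb$lon_min, bb$lon_max, by = resolution)
  lat <- seq(bb$lat_min, bb$lat_max, by = resolution)
  u <- outer(rep(1, length(lon)), (lat - bb$lat_min) / (bb$lat_max - bb$lat_min))
  v <- outer((lon - bb$lon_min) / (bb$lon_max - bb$lon_min), rep(1, length(lat)))
  g <- .env_gradients
  noise <- function(sd, sub) {
    if (sd == 0 || noise_scale == 0) {
      matrix(0, length(lon), length(lat))
    } else {
      sample_matern_field(list(lon = lon, lat = lat), range_km = 80,
                          sd = sd * noise_scale,
                          seed = derive_seed(seed, sub))
    }
  }
  fields <- list()
  add <- function(name, season, values, units) {
    fields[[paste(name, season, sep = ".")]] <<-
      env_field(name, season, lon, lat, values, units)
  }
  depth <- pmax(12 + 95 * v + 8 * u * v + noise(4, 1), 5)
  add("depth_m", "all", depth, "m")
  fdep <- pmin(pmax((depth - 15) / 85, 0), 1)
  plume_lat <- exp(-((outer(rep(1, length(lon)), lat) - 31.5) / 2.5)^2)
  for (k in seq_along(design$seasons)) {
    s <- design$seasons[k]
    sst <- g$sst_south[s] - (g$sst_south[s] - g$sst_north[s]) * u +
      noise(0.5, 10 + k)
    sbt <- sst - g$strat_t[s] * fdep + noise(0.5, 20 + k)
    sss <- 34.3 - g$plume[s] * (1 - v)^1.5 * plume_lat + noise(0.25, 30 + k)
    sbs <- sss + 0.5 * fdep + noise(0.2, 40 + k)
    add("sst_c", s, sst, "degC")
    add("sbt_c", s, sbt, "degC")
    add("sss_psu", s, sss, "psu")
    add("sbs_psu", s, sbs, "psu")
    if (!is.na(g$do_extra[s])) {
      ssdo <- 10.3 - 0.146 * sst - g$do_extra[s] + noise(0.15, 50 + k)
      sbdo <- ssdo + 0.4 - g$strat_do[s] * fdep + noise(0.15, 60 + k)
      add("ssdo_mgl", s, ssdo, "mg/L")
      add("sbdo_mgl", s, sbdo, "mg/L")
    }
  }
  structure(
    list(fields = fields, seasons = design$seasons, resolution = resolution,
         bbox = bb, lon = lon, lat = lat),
    class = "env_set"
  )
}

# fetch a layer for a season, falling back to the static "all" layer
env_layer <- function(env, name, season) {
  env$fields[[paste(name, season, sep = ".")]] %||%
    env$fields[[paste(name, "all", sep = ".")]]
}

#' Niche parameters for one species
#'
#' Occurrence follows inverse-logit(intercept + sum of Gaussian bump
#' responses + spatial field): each response contributes
#' `height * exp(-(x - optimum)^2 / (2 tolerance^2))`.
#'
#' @param intercept Logit-scale intercept.
#' @param responses Named list of responses, one per covariate column name,
#'   each `list(optimum=, tolerance=, height=)`.
#' @param field_range_km,field_sd Matern parameters of the species' latent
#'   spatial field.
#' @param mean_count Mean catch count given presence (shifted Poisson).
#' @param weight_meanlog,weight_sdlog Lognormal per-individual weight (g).
#' @return Object of class `niche_params`.
#' @export
niche_params <- function(intercept,
                         responses = list(),
                         field_range_km = 150, field_sd = 0.8,
                         mean_count = 20,
                         weight_meanlog = log(8), weight_sdlog = 0.5) {
  for (r in responses) {
    if (r$tolerance <= 0) stop("response tolerance must be positive")
  }
  if (field_sd < 0) stop("field_sd must be nonnegative")
  structure(
    list(intercept = intercept, responses = responses,
         field_range_km = field_range_km, field_sd = field_sd,
         mean_count = mean_count, weight_meanlog = weight_meanlog,
         weight_sdlog = weight_sdlog),
    class = "niche_params"
  )
}

#' Default niche pair for the two squid species
#'
#' Two overlapping demersal niches on the shelf: both prefer mid-shelf
#' depths; one tracks bottom temperature, the other salinity, giving
#' partially shared environmental responses whose overlap is controlled by
#' `rho` (the correlation of their latent spatial fields).
#'
#' @param rho Inter-species field correlation in [-1, 1].
#' @return List with elements `beka`, `uyii` ([niche_params()]) and `rho`.
#' @export
default_niche_pair <- function(rho = 0.6) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  list(
    beka = niche_params(
      intercept = -3.2,
      responses = list(
        depth_m = list(optimum = 45, tolerance = 28, height = 1.6),
        sss_psu = list(optimum = 32, tolerance = 1.6, height = 1.4)
      ),
      field_range_km = 150, field_sd = 0.8,
      mean_count = 25, weight_meanlog = log(7), weight_sdlog = 0.5
    ),
    uyii = niche_params(
      intercept = -3.4,
      responses = list(
        depth_m = list(optimum = 55, tolerance = 30, height = 1.5),
        sbt_c = list(optimum = 14, tolerance = 5, height = 1.5)
      ),
      field_range_km = 150, field_sd = 0.8,
      mean_count = 8, weight_meanlog = log(12), weight_sdlog = 0.5
    ),
    rho = rho
  )
}

#' Generate a synthetic trawl survey
#'
#' Draws station locations from the design's station lattice for each
#' season, looks up environmental covariates, computes each species' latent
#' occurrence probability (niche responses + correlated Matern fields),
#' samples Bernoulli presence and, where present, catch counts (shifted
#' Poisson) and weights (count times lognormal individual weight).
#'
#' @param design A [survey_design()].
#' @param niche A niche pair as from [default_niche_pair()]: elements
#'   `beka`, `uyii`, `rho`.
#' @param env An [generate_environment()] `env_set` (generated from
#'   `design` if `NULL`).
#' @param seed Integer seed.
#' @return data.frame, one row per station x season, in the station-CSV
#'   dialect (`station_id`, `season`, `date_index`, `lon`, `lat`,
#'   `tow_hours`, covariates, per-species counts/weights, and the latent
#'   `true_p_*` probabilities for recovery tests). The per-species latent
#'   field matrices on the environment grid are attached as attribute
#'   `"latent_fields"`.
#' @export
generate_survey <- function(design, niche = default_niche_pair(), env = NULL,
                            seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  if (is.null(env)) env <- generate_environment(design, seed = derive_seed(seed, 99))
  bb <- design$bbox
  lon_pts <- seq(bb$lon_min, bb$lon_max, by = design$station_spacing)
  lat_pts <- seq(bb$lat_min, bb$lat_max, by = design$station_spacing)
  lattice <- expand.grid(lon = lon_pts, lat = lat_pts)
  if (any(design$stations_per_season > nrow(lattice))) {
    stop("station count exceeds the station lattice size")
  }
  rho <- niche$rho
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  grid <- list(lon = env$lon, lat = env$lat)
  sp_names <- c("beka", "uyii")
  rng <- niche$beka$field_range_km
  base <- lapply(1:3, function(i) {
    sample_matern_field(grid, range_km = rng, sd = 1,
                        seed = derive_seed(seed, 200 + i))
  })
  a <- sqrt(abs(rho))
  b <- sqrt(1 - abs(rho))
  latent <- list(
    beka = niche$beka$field_sd * (a * base[[1]] + b * base[[2]]),
    uyii = niche$uyii$field_sd * (sign(rho + 1e-300) * a * base[[1]] + b * base[[3]])
  )
  if (rho == 0) {
    latent$uyii <- niche$uyii$field_sd * base[[3]]
  }
  field_f <- lapply(latent, function(m) {
    env_field("latent", "all", env$lon, env$lat, m)
  })

  cov_names <- c("depth_m", "sst_c", "sbt_c", "sss_psu", "sbs_psu",
                 "ssdo_mgl", "sbdo_mgl")
  rows <- list()
  for (k in seq_along(design$seasons)) {
    s <- design$seasons[k]
    n_s <- design$stations_per_season[k]
    idx <- with_seed(derive_seed(seed, 300 + k),
                     sample.int(nrow(lattice), n_s))
    st <- lattice[idx, , drop = FALSE]
    tow <- if (length(design$tow_hours) == 1) {
      rep(design$tow_hours, n_s)
    } else {
      with_seed(derive_seed(seed, 400 + k),
                stats::runif(n_s, design$tow_hours[1], design$tow_hours[2]))
    }
    df <- data.frame(
      station_id = sprintf("%s-%03d", s, seq_len(n_s)),
      season = s, date_index = design$date_index[k],
      lon = st$lon, lat = st$lat, tow_hours = tow
    )
    for (cv in cov_names) {
      layer <- env_layer(env, cv, s)
      df[[cv]] <- if (is.null(layer)) NA_real_ else field_lookup(layer, st$lon, st$lat)
    }
    for (sp in sp_names) {
      np <- niche[[sp]]
      eta <- rep(np$intercept, n_s)
      for (cv in names(np$responses)) {
        r <- np$responses[[cv]]
        x <- df[[cv]]
        if (all(is.na(x))) stop(sprintf("niche covariate %s missing from environment", cv))
        eta <- eta + r$height * exp(-(x - r$optimum)^2 / (2 * r$tolerance^2))
      }
      eta <- eta + field_lookup(field_f[[sp]], st$lon, st$lat)
      p <- inv_logit(eta)
      draw <- with_seed(derive_seed(seed, 500 + k, match(sp, sp_names)), {
        pres <- stats::rbinom(n_s, 1, p)
        cnt <- ifelse(pres == 1,
                      1L + stats::rpois(n_s, max(np$mean_count - 1, 0)), 0L)
        iw <- stats::rlnorm(n_s, np$weight_meanlog, np$weight_sdlog)
        list(cnt = cnt, wt = ifelse(cnt > 0, round(cnt * iw, 1), 0))
      })
      df[[paste0("count_", sp)]] <- draw$cnt
      df[[paste0("weight_", sp, "_g")]] <- draw$wt
      df[[paste0("true_p_", sp)]] <- p
    }
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "latent_fields") <- latent
  attr(out, "env") <- env
  out
}

#' Simulate presence/absence directly from the spatial model
#'
#' Draws station locations from a lattice over the default survey domain,
#' one standardised environmental covariate with a linear (monotone smooth)
#' effect, a Matern spatial field, and Bernoulli outcomes — the exact
#' data-generating process the estimator assumes. Used for parameter
#' recovery experiments.
#'
#' @param n Number of stations.
#' @param range_km,sd Matern field parameters.
#' @param intercept,effect Logit-scale intercept and covariate coefficient.
#' @param seed Integer seed.
#' @return data.frame with `lon`, `lat`, `date_index`, covariate `x`,
#'   response `y`, and latent `true_p`.
#' @export
simulate_occurrence <- function(n, range_km = 100, sd = 1.0,
                                intercept = -0.3, effect = 1.2, seed = 1) {
  design <- survey_design()
  env <- generate_environment(design, seed = derive_seed(seed, 7))
  lon_pts <- seq(design$bbox$lon_min, design$bbox$lon_max, by = 0.25)
  lat_pts <- seq(design$bbox$lat_min, design$bbox$lat_max, by = 0.25)
  lattice <- expand.grid(lon = lon_pts, lat = lat_pts)
  if (n > nrow(lattice)) stop("n exceeds the station lattice size")
  idx <- with_seed(derive_seed(seed, 1), sample.int(nrow(lattice), n))
  st <- lattice[idx, , drop = FALSE]
  x <- field_lookup(env$fields[["sst_c.spring"]], st$lon, st$lat)
  xs <- (x - mean(x)) / stats::sd(x)
  eta <- intercept + effect * xs
  if (sd > 0) {
    fld <- sample_matern_field(list(lon = env$lon, lat = env$lat),
                               range_km, sd, seed = derive_seed(seed, 2))
    ff <- env_field("latent", "all", env$lon, env$lat, fld)
    eta <- eta + field_lookup(ff, st$lon, st$lat)
  }
  p <- inv_logit(eta)
  y <- with_seed(derive_seed(seed, 3), stats::rbinom(n, 1, p))
  data.frame(lon = st$lon, lat = st$lat, date_index = 1L,
             x = xs, y = y, true_p = p)
}

.default_warming <- data.frame(
  scenario = rep(c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"), each = 2),
  decade = rep(c("2050s", "2090s"), 3),
  d_sst = c(0.8, 1.2, 1.2, 2.2, 1.8, 3.8),
  d_sss = c(-0.10, -0.15, -0.15, -0.30, -0.20, -0.50),
  stringsAsFactors = FALSE
)

#' Generate climate-scenario SST/SSS layer sets
#'
#' The baseline ("current") layer is the across-season mean of the seasonal
#' SST and SSS fields, standing in for a 2010-2020 decadal mean; each future
#' layer adds a scenario- and decade-specific uniform warming/freshening
#' delta. SST deltas must be ordered SSP1-2.6 <= SSP2-4.5 <= SSP5-8.5 within
#' each decade.
#'
#' @param env An [generate_environment()] `env_set`.
#' @param warming data.frame with columns `scenario`, `decade`, `d_sst`
#'   (degC), `d_sss` (psu). Default: mild/moderate/strong warming for the
#'   2050s and 2090s.
#' @return List with `baseline` (named list of `env_field`s: `sst_c`,
#'   `sss_psu`) and `futures`, a list of scenario layer sets each carrying
#'   `scenario`, `decade`, `sst_c`, `sss_psu`.
#' @export
generate_scenario_layers <- function(env, warming = .default_warming) {
  stopifnot(inherits(env, "env_set"))
  if (any(!is.finite(warming$d_sst)) || any(!is.finite(warming$d_sss))) {
    stop("scenario deltas must be finite")
  }
  sev <- c("SSP1-2.6" = 1, "SSP2-4.5" = 2, "SSP5-8.5" = 3)
  for (dec in unique(warming$decade)) {
    w <- warming[warming$decade == dec, ]
    w <- w[order(sev[w$scenario]), ]
    if (is.unsorted(w$d_sst)) {
      stop(sprintf("SST deltas for %s violate scenario ordering", dec))
    }
  }
  mean_field <- function(name, units) {
    mats <- lapply(env$seasons, function(s) env_layer(env, name, s)$values)
    env_field(name, "baseline-2010-2020", env$lon, env$lat,
              Reduce(`+`, mats) / length(mats), units)
  }
  baseline <- list(
    sst_c = mean_field("sst_c", "degC"),
    sss_psu = mean_field("sss_psu", "psu")
  )
  futures <- lapply(seq_len(nrow(warming)), function(i) {
    w <- warming[i, ]
    list(
      scenario = w$scenario, decade = w$decade,
      sst_c = env_field("sst_c", paste(w$scenario, w$decade), env$lon, env$lat,
                        baseline$sst_c$values + w$d_sst, "degC"),
      sss_psu = env_field("sss_psu", paste(w$scenario, w$decade), env$lon,
                          env$lat, baseline$sss_psu$values + w$d_sss, "psu")
    )
  })
  list(baseline = baseline, futures = futures)
}

#' Write station records to CSV
#'
#' @param records Survey data.frame from [generate_survey()].
#' @param path Output file path.
#' @export
write_station_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
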