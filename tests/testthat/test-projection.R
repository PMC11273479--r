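grid_bbox <- c(lon_min = 119.5, lon_max = 127, lat_min = 26, lat_max = 35.5)

test_that("the survey-area prediction grid has 101 x 101 = 10,201 nodes", {
  g <- make_prediction_grid(grid_bbox, nx = 101, ny = 101)
  expect_equal(nrow(g$nodes), 10201L)
  expect_equal(length(unique(g$nodes$lon)), 101)
  # inclusive corners
  g2 <- make_prediction_grid(grid_bbox, nx = 2, ny = 2)
  expect_equal(nrow(g2$nodes), 4L)
  expect_setequal(g2$nodes$lon, c(119.5, 127))
  expect_setequal(g2$nodes$lat, c(26, 35.5))
  expect_error(make_prediction_grid(c(lon_min = 5, lon_max = 1,
                                      lat_min = 0, lat_max = 1), 3, 3),
               "inverted")
})

test_that("the water mask follows depth > 0 and masking keeps the node count", {
  env <- fx_env()
  dep <- env$fields[["depth_m.all"]]
  g <- make_prediction_grid(grid_bbox, 21, 21, depth = dep)
  expect_equal(nrow(g$nodes), 441L)
  inside <- g$nodes$lon >= 120 & g$nodes$lon <= 127 &
    g$nodes$lat >= 26.5 & g$nodes$lat <= 35
  # generator depth is positive everywhere on its support
  expect_true(all(g$nodes$water[inside]))
  expect_false(any(g$nodes$water[!inside]))
  # uniform positive depth (no layer) -> nothing masked
  g0 <- make_prediction_grid(grid_bbox, 11, 11)
  expect_true(all(g0$nodes$water))
})

test_that("layer interpolation is exact for cell centres, constants and linear fields", {
  env <- fx_env()
  sst <- env$fields[["sst_c.spring"]]
  # node coincident with a layer grid point
  g <- make_prediction_grid(c(lon_min = 121, lon_max = 125,
                              lat_min = 27, lat_max = 33), 5, 7)
  gi <- interpolate_layers(g, list(sst))
  i <- which(gi$nodes$lon == 122 & gi$nodes$lat == 30)
  expect_equal(gi$nodes$sst_c[i],
               sst$values[which(sst$lon == 122), which(sst$lat == 30)])
  # constant and linear-in-lon layers are reproduced exactly
  cfield <- env_field("cst", "all", sst$lon, sst$lat,
                      matrix(7.5, length(sst$lon), length(sst$lat)))
  lfield <- env_field("lin", "all", sst$lon, sst$lat,
                      outer(2 * sst$lon - 10, rep(1, length(sst$lat))))
  gi2 <- interpolate_layers(g, list(cfield, lfield))
  expect_equal(gi2$nodes$cst, rep(7.5, nrow(gi2$nodes)))
  expect_equal(gi2$nodes$lin, 2 * gi2$nodes$lon - 10, tolerance = 1e-12)
  far <- make_prediction_grid(c(lon_min = 0, lon_max = 1,
                                lat_min = 0, lat_max = 1), 3, 3)
  expect_error(interpolate_layers(far, list(sst)), "overlap")
})

test_that("probability maps propagate masks and match station predictions", {
  sv <- fx_survey()
  env <- fx_env()
  fit <- fit_model(model_spec("beka", smooths = "depth_m"), sv)
  g <- make_prediction_grid(grid_bbox, 21, 21, depth = env$fields[["depth_m.all"]])
  g <- interpolate_layers(g, list(env$fields[["depth_m.all"]]))
  mp <- project_map(fit, g, "spring")
  expect_true(all(is.na(mp$values[!mp$water])))
  wet <- mp$water
  expect_true(all(mp$values[wet] >= 0 & mp$values[wet] <= 1))
  # a node's value equals the station-level prediction with that covariate
  i <- which(wet)[1]
  nd <- g$nodes[i, ]
  expect_equal(mp$values[i], predict(fit, nd))
  # intercept-only model: constant map at inverse-logit(intercept)
  fit0 <- fit_model(model_spec("beka"), sv)
  mp0 <- project_map(fit0, g, "flat")
  expect_equal(unique(round(mp0$values[wet], 12)),
               round(plogis(unname(fit0$beta[1])), 12))
})

test_that("scenario differences are antisymmetric and zero-delta is exact", {
  sv <- fx_survey()
  env <- fx_env()
  fit <- fit_model(model_spec("beka", smooths = c("sst_c", "depth_m")), sv)
  zero <- data.frame(
    scenario = rep(c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"), each = 2),
    decade = rep(c("2050s", "2090s"), 3), d_sst = 0, d_sss = 0
  )
  sc <- generate_scenario_layers(env, zero)
  g <- make_prediction_grid(grid_bbox, 15, 15, depth = env$fields[["depth_m.all"]])
  g_base <- interpolate_layers(g, list(sc$baseline$sst_c,
                                       env$fields[["depth_m.all"]]))
  g_fut <- interpolate_layers(g, list(sc$futures[[6]]$sst_c,
                                      env$fields[["depth_m.all"]]))
  m_base <- project_map(fit, g_base, "baseline")
  m_fut <- project_map(fit, g_fut, "SSP5-8.5 2090s")
  expect_identical(m_fut$values, m_base$values) # bit-for-bit
  d <- scenario_difference(m_fut, m_base)
  expect_true(all(d$values[d$water] == 0))
  d_ab <- scenario_difference(m_base, m_fut)
  expect_equal(d$values, -d_ab$values)
  other <- make_prediction_grid(grid_bbox, 14, 14)
  expect_error(scenario_difference(m_base, project_map(fit,
    interpolate_layers(other, list(sc$baseline$sst_c,
                                   env$fields[["depth_m.all"]])), "x")),
    "different grids")
})

test_that("high-value masks use a strict threshold and a counting oracle", {
  g <- make_prediction_grid(grid_bbox, 5, 5)
  mk_map <- function(v) structure(list(lon = g$lon, lat = g$lat, nx = 5,
                                       ny = 5, water = rep(TRUE, 25),
                                       values = v, label = "t"),
                                  class = "prob_map")
  expect_equal(high_value_mask(mk_map(rep(0.6, 25)))$fraction, 1)
  expect_equal(high_value_mask(mk_map(rep(0.5, 25)))$fraction, 0)
  set.seed(41)
  v <- runif(25)
  hv <- high_value_mask(mk_map(v), 0.37)
  expect_equal(hv$fraction, sum(v > 0.37) / 25)
  expect_error(high_value_mask(mk_map(v), 1.2), "threshold")
})

test_that("averaging seasonal maps gives the node-wise mean", {
  g <- make_prediction_grid(grid_bbox, 4, 4)
  mk_map <- function(v) structure(list(lon = g$lon, lat = g$lat, nx = 4,
                                       ny = 4, water = rep(TRUE, 16),
                                       values = v, label = "s"),
                                  class = "prob_map")
  m1 <- mk_map(rep(0.2, 16))
  m2 <- mk_map(rep(0.6, 16))
  avg <- average_maps(list(m1, m2), "annual")
  expect_equal(avg$values, rep(0.4, 16))
  expect_equal(avg$label, "annual")
})

test_that("fitted high-value area tracks the generator's latent truth", {
  # single strong-niche species on a dense survey; compare the map's
  # high-value fraction with the latent truth's fraction
  d <- survey_design(station_spacing = 0.25, seasons = "spring",
                     stations_per_season = 1000)
  env <- generate_environment(survey_design(), seed = 55)
  niche <- default_niche_pair()
  niche$beka$responses <- list(depth_m = list(optimum = 45, tolerance = 25,
                                              height = 3.2))
  niche$beka$intercept <- -1.8
  niche$beka$field_sd <- 0.3
  sv <- generate_survey(d, niche, env, seed = 56)
  fit <- fit_model(model_spec("beka", smooths = "depth_m"), sv)
  g <- make_prediction_grid(grid_bbox, 41, 41, depth = env$fields[["depth_m.all"]])
  g <- interpolate_layers(g, list(env$fields[["depth_m.all"]]))
  mp <- project_map(fit, g, "spring")
  truth <- mp
  dep <- g$nodes$depth_m
  lf <- attr(sv, "latent_fields")$beka
  ff <- env_field("f", "all", env$lon, env$lat, lf)
  wet <- g$nodes$water
  tv <- rep(NA_real_, nrow(g$nodes))
  tv[wet] <- plogis(-1.8 +
    3.2 * exp(-(dep[wet] - 45)^2 / (2 * 25^2)) +
    field_lookup(ff, g$nodes$lon[wet], g$nodes$lat[wet]))
  truth$values <- tv
  f_fit <- high_value_mask(mp)$fraction
  f_true <- high_value_mask(truth)$fraction
  expect_lt(abs(f_fit - f_true), 0.1)
})
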