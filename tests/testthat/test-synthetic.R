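test_that("matern sampler honours degenerate variance and determinism", {
  grid <- list(x = seq(0, 200, 25), y = seq(0, 200, 25))
  z <- sample_matern_field(grid, range_km = 50, sd = 0, seed = 1)
  expect_true(all(z == 0))
  a <- sample_matern_field(grid, 50, 1, seed = 9)
  b <- sample_matern_field(grid, 50, 1, seed = 9)
  expect_identical(a, b)
  c <- sample_matern_field(grid, 50, 1, seed = 10)
  expect_false(identical(a, c))
  expect_error(sample_matern_field(grid, -1, 1, seed = 1), "positive")
})

test_that("sampled fields match the Matern marginal variance and range correlation", {
  # 60x60 grid, range 100 km, sd 1, 200 replicates; the expected lag-range
  # correlation comes from the closed-form Matern (nu = 1) value
  grid <- list(x = seq(0, 590, 10), y = seq(0, 590, 10))
  f <- sample_matern_field(grid, range_km = 100, sd = 1, seed = 4, n = 200)
  vars <- apply(f, c(1, 2), var)
  expect_lt(abs(mean(vars) - 1), 0.15)
  # correlation at lag = range along the x axis (10 cells = 100 km)
  lag <- 10
  a <- f[1:(60 - lag), , ]
  b <- f[(lag + 1):60, , ]
  emp <- cor(as.vector(a), as.vector(b))
  expect_lt(abs(emp - matern_correlation(100, 100)), 0.1)
})

test_that("environment layers follow the design contracts", {
  d <- fx_design()
  env <- fx_env()
  # winter bottom temperature spans a narrower range than the annual one
  sbt <- lapply(d$seasons, function(s) range(env$fields[[paste0("sbt_c.", s)]]$values))
  winter_span <- diff(sbt[[which(d$seasons == "winter")]])
  annual_span <- diff(range(unlist(sbt)))
  expect_lt(winter_span, annual_span)
  # summer SST warm, winter SST cold (envelope-compatible spans)
  expect_gt(min(env$fields[["sst_c.summer"]]$values), 22)
  expect_lt(max(env$fields[["sst_c.winter"]]$values), 19)
  # depth static and positive
  expect_true(all(env$fields[["depth_m.all"]]$values > 0))
  # autumn has no dissolved-oxygen layers
  expect_null(env$fields[["ssdo_mgl.autumn"]])
  # zero-noise configuration is purely deterministic
  e1 <- generate_environment(d, seed = 1, noise_scale = 0)
  e2 <- generate_environment(d, seed = 2, noise_scale = 0)
  expect_equal(e1$fields, e2$fields)
  # different seeds differ in values but share grid axes
  e3 <- generate_environment(d, seed = 1)
  e4 <- generate_environment(d, seed = 2)
  expect_identical(e3$lon, e4$lon)
  expect_identical(e3$lat, e4$lat)
  expect_false(identical(e3$fields, e4$fields))
})

test_that("survey reproduces the four-cruise station counts and basic invariants", {
  sv <- fx_survey()
  expect_equal(as.integer(table(sv$date_index)), c(127L, 111L, 141L, 140L))
  expect_equal(unique(sv$season[order(sv$date_index)]),
               c("autumn", "winter", "spring", "summer"))
  for (sp in c("beka", "uyii")) {
    cnt <- sv[[paste0("count_", sp)]]
    wt <- sv[[paste0("weight_", sp, "_g")]]
    p <- sv[[paste0("true_p_", sp)]]
    expect_true(all((wt > 0) == (cnt > 0)))
    expect_true(all(p > 0 & p < 1))
  }
  expect_true(all(sv$tow_hours > 0))
  expect_true(all(sv$lon >= 120 & sv$lon <= 127 & sv$lat >= 26.5 & sv$lat <= 35))
  expect_error(
    generate_survey(survey_design(stations_per_season = c(10000, 1, 1, 1)),
                    seed = 1),
    "exceeds"
  )
})

test_that("flat niche with logit(0.5) intercept yields ~50% presence", {
  niche <- default_niche_pair()
  niche$beka$responses <- list()
  niche$uyii$responses <- list()
  niche$beka$intercept <- 0
  niche$uyii$intercept <- 0
  niche$beka$field_sd <- 0
  niche$uyii$field_sd <- 0
  sv <- generate_survey(fx_design(), niche, fx_env(), seed = 21)
  n <- nrow(sv)
  rate <- mean(sv$count_beka > 0)
  # binomial 99% bounds around 0.5
  half_width <- qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(rate - 0.5), half_width)
  expect_equal(unique(sv$true_p_beka), 0.5)
})

test_that("field correlation rho controls the inter-species latent correlation", {
  niche1 <- default_niche_pair(rho = 1)
  niche1$uyii <- niche1$beka
  sv1 <- generate_survey(fx_design(), niche1, fx_env(), seed = 8)
  expect_equal(sv1$true_p_beka, sv1$true_p_uyii)
  # short-range fields give enough effectively independent grid patches
  # for the sample correlation to resolve rho
  niche0 <- default_niche_pair(rho = 0)
  for (sp in c("beka", "uyii")) niche0[[sp]]$field_range_km <- 25
  lf <- attr(generate_survey(fx_design(), niche0, fx_env(), seed = 8),
             "latent_fields")
  expect_lt(abs(cor(as.vector(lf$beka), as.vector(lf$uyii))), 0.1)
  lf1 <- attr(sv1, "latent_fields")
  expect_gt(cor(as.vector(lf1$beka), as.vector(lf1$uyii)), 0.99)
})

test_that("empirical presence frequency tracks the configured response curve", {
  # dense one-season survey, no spatial field, single depth response;
  # empirical presence per depth bin must converge to the bump curve
  d <- survey_design(station_spacing = 0.05, seasons = "spring",
                     stations_per_season = 20000)
  env <- generate_environment(d, seed = 2, resolution = 0.5, noise_scale = 0)
  niche <- default_niche_pair()
  resp <- list(depth_m = list(optimum = 50, tolerance = 25, height = 2))
  for (sp in c("beka", "uyii")) {
    niche[[sp]]$responses <- resp
    niche[[sp]]$intercept <- -2
    niche[[sp]]$field_sd <- 0
  }
  sv <- generate_survey(d, niche, env, seed = 14)
  bins <- cut(sv$depth_m, breaks = seq(10, 110, by = 10))
  emp <- tapply(sv$count_beka > 0, bins, mean)
  theo <- tapply(plogis(-2 + 2 * exp(-(sv$depth_m - 50)^2 / (2 * 25^2))),
                 bins, mean)
  big <- !is.na(emp) & table(bins) > 500
  expect_lt(max(abs(emp[big] - theo[big])), 0.05)
})

test_that("scenario layers obey identity, uniform-shift and ordering contracts", {
  env <- fx_env()
  zero <- data.frame(
    scenario = rep(c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"), each = 2),
    decade = rep(c("2050s", "2090s"), 3), d_sst = 0, d_sss = 0
  )
  sc0 <- generate_scenario_layers(env, zero)
  for (fu in sc0$futures) {
    expect_equal(fu$sst_c$values, sc0$baseline$sst_c$values)
    expect_equal(fu$sss_psu$values, sc0$baseline$sss_psu$values)
  }
  sc <- generate_scenario_layers(env)
  expect_length(sc$futures, 6)
  plus3 <- zero
  plus3$d_sst[plus3$scenario == "SSP5-8.5" & plus3$decade == "2090s"] <- 3
  sc3 <- generate_scenario_layers(env, plus3)
  fu <- sc3$futures[[6]]
  expect_equal(mean(fu$sst_c$values) - mean(sc3$baseline$sst_c$values), 3)
  bad <- zero
  bad$d_sst <- c(2, 2, 1, 1, 0.5, 0.5) # severity ordering inverted
  expect_error(generate_scenario_layers(env, bad), "ordering")
})
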