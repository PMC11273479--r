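test_that("field-free fits match the IRLS logistic oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 250
    dat <- data.frame(
      lon = runif(n, 120, 127), lat = runif(n, 26.5, 35), date_index = 1L,
      x1 = rnorm(n), x2 = rnorm(n)
    )
    eta <- rnorm(1) + rnorm(1) * dat$x1 + rnorm(1) * dat$x2
    dat$y <- rbinom(n, 1, plogis(eta))
    fit <- fit_model(model_spec("y", linear = c("x1", "x2")), dat)
    orc <- glm(y ~ x1 + x2, binomial(), dat)
    expect_lt(max(abs(fit$beta - coef(orc))), 1e-4)
    expect_equal(fit$loglik, as.numeric(logLik(orc)), tolerance = 1e-6)
  }
})

test_that("intercept-only fit with balanced labels gives a zero intercept", {
  dat <- data.frame(lon = runif(500, 120, 127), lat = runif(500, 26.5, 35),
                    date_index = 1L, y = rep(c(0, 1), 250))
  fit <- fit_model(model_spec("y"), dat)
  expect_lt(abs(fit$beta[1]), 1e-6)
})

test_that("single-class responses are rejected", {
  dat <- data.frame(lon = 121:124, lat = 27:30, date_index = 1L, y = c(1, 1, 1, 1))
  expect_error(fit_model(model_spec("y"), dat), "single class")
})

test_that("AIC identity and logLik method hold for converged fits", {
  dat <- fx_logistic_data()
  fit <- fit_model(model_spec("y", smooths = "x1", df = 3), dat)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(AIC(fit), fit$aic)
  sv <- fx_survey()
  sfit <- fit_model(model_spec("beka", smooths = "depth_m", spatial = TRUE),
                    sv, fx_mesh())
  expect_true(sfit$converged)
  expect_equal(sfit$k, 1 + 3 + 2)
  expect_equal(sfit$aic, 2 * sfit$k - 2 * sfit$loglik)
})

test_that("adding the generating covariate never lowers the training likelihood", {
  dat <- fx_logistic_data()
  f0 <- fit_model(model_spec("y"), dat)
  f1 <- fit_model(model_spec("y", smooths = "x1"), dat)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("predictions are self-consistent, bounded and monotone where fitted so", {
  dat <- fx_logistic_data()
  fit <- fit_model(model_spec("y", linear = "x1"), dat)
  # linear predictor 0 -> p = 0.5
  x0 <- -fit$beta[1] / fit$beta[2]
  p0 <- predict(fit, data.frame(x1 = x0, lon = 123, lat = 30, date_index = 1L))
  expect_equal(unname(p0), 0.5, tolerance = 1e-12)
  p <- predict(fit, dat)
  eta <- predict(fit, dat, type = "link")
  expect_equal(p, plogis(eta), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  # monotone fitted effect preserves ordering along the covariate
  ord <- order(dat$x1)
  expect_true(all(diff(p[ord]) * sign(fit$beta[2]) >= 0))
})

test_that("spatial predictions at training stations reproduce fitted values", {
  sv <- fx_survey()
  fit <- fit_model(model_spec("beka", smooths = "depth_m", spatial = TRUE),
                   sv, fx_mesh())
  p1 <- predict(fit, sv)
  p2 <- predict(fit, sv)
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("the SD -> 0 limit recovers the field-free coefficients", {
  sv <- fx_survey()
  sp <- model_spec("beka", smooths = "depth_m", spatial = TRUE)
  tiny <- fit_model(sp, sv, fx_mesh(),
                    fit_control(fix_range = 100, fix_sd = 1e-8))
  free <- fit_model(model_spec("beka", smooths = "depth_m"), sv)
  expect_lt(max(abs(tiny$beta - free$beta)), 1e-3)
  expect_equal(tiny$loglik, free$loglik, tolerance = 1e-4)
})

test_that("spatiotemporal fields are estimated and vanish for unseen times", {
  sv <- fx_survey()
  sp <- model_spec("beka", smooths = "depth_m", spatial = TRUE,
                   spatiotemporal = TRUE)
  fit <- fit_model(sp, sv, fx_mesh())
  expect_equal(ncol(fit$eps_hat), 4)
  nd <- sv[1:5, ]
  nd$date_index <- 99L
  p_unseen <- predict(fit, nd, type = "link")
  nd0 <- nd
  eps_contrib <- local({
    nd1 <- sv[1:5, ]
    predict(fit, nd1, type = "link")
  })
  # unseen time = smooth + omega only; must differ from the in-sample
  # linear predictor by exactly the epsilon contribution
  A <- interpolation_matrix(fit$mesh,
                            project_to_plane(nd$lon, nd$lat, fit$mesh$zone))
  eps1 <- as.vector(A %*% fit$eps_hat[, paste0("t", sv$date_index[1])])
  expect_lt(max(abs((eps_contrib - p_unseen) - eps1)), 1e-10)
  expect_error(fit_model(sp, sv[sv$date_index == 1, ], fx_mesh()), ">= 2 time")
})

test_that("hyperparameters are recovered from model-generated data", {
  # single replicate sanity check (the acceptance suite runs the full
  # 20-seed recovery experiment)
  dat <- simulate_occurrence(1000, range_km = 100, sd = 1, seed = 1)
  mesh <- build_mesh(dat, spacing_km = 25, buffer_km = 125)
  fit <- fit_model(model_spec("y", smooths = "x", spatial = TRUE), dat, mesh)
  expect_true(fit$converged)
  expect_lt(abs(fit$fields$spatial$range_km - 100) / 100, 0.5)
  expect_lt(abs(fit$fields$spatial$sd - 1), 0.5)
})
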