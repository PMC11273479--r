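# shared fixtures, built once per test run

.fx <- new.env()

fx_design <- function() {
  if (is.null(.fx$design)) .fx$design <- survey_design()
  .fx$design
}

fx_survey <- function() {
  if (is.null(.fx$survey)) .fx$survey <- generate_survey(fx_design(), seed = 3)
  .fx$survey
}

fx_env <- function() {
  if (is.null(.fx$env)) .fx$env <- attr(fx_survey(), "env")
  .fx$env
}

fx_mesh <- function() {
  if (is.null(.fx$mesh)) {
    .fx$mesh <- build_mesh(fx_survey(), spacing_km = 50, buffer_km = 100)
  }
  .fx$mesh
}

# small logistic dataset with a known smooth signal
fx_logistic_data <- function(n = 300, seed = 11) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta <- -0.4 + 1.1 * x1 - 0.7 * x2
  data.frame(
    lon = runif(n, 120, 127), lat = runif(n, 26.5, 35),
    date_index = 1L, x1 = x1, x2 = x2,
    y = rbinom(n, 1, plogis(eta))
  )
}

# textbook natural cubic spline basis (truncated power construction),
# independent of splines::ns; spans the same function space
ncs_textbook_basis <- function(x, knots, boundary) {
  kk <- sort(c(boundary[1], knots, boundary[2]))
  K <- length(kk)
  d <- function(z, j) {
    (pmax(z - kk[j], 0)^3 - pmax(z - kk[K], 0)^3) / (kk[K] - kk[j])
  }
  B <- cbind(x, sapply(seq_len(K - 2), function(j) d(x, j) - d(x, K - 1)))
  B
}
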