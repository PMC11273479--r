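# Model selection and cross-validated evaluation: AIC stepwise covariate
# selection with spatial-effect toggling, k-fold CV and leave-future-out CV
# scored by summed test log-likelihood.

#' Akaike information criterion
#'
#' `AIC = 2k - 2 lnL`.
#'
#' @param k Number of parameters (>= 0).
#' @param loglik Maximised log-likelihood.
#' @return AIC value.
#' @export
aic <- function(k, loglik) {
  if (k < 0) stop("k must be nonnegative")
  2 * k - 2 * loglik
}

.safe_fit <- function(spec, data, mesh, control) {
  tryCatch(fit_model(spec, data, mesh, control), error = function(e) NULL)
}

#' AIC stepwise covariate selection
#'
#' Stage 1 fits the intercept-only model with spatial effects off and on and
#' keeps the better (lower-AIC) random-effect configuration. Stage 2 then
#' greedily adds or drops single smooth terms, at each round accepting the
#' move that most decreases AIC, until no move decreases it. Non-converged
#' fits are recorded with an `NA` AIC and skipped.
#'
#' @param candidates Character vector of candidate smooth covariates.
#' @param data Station data.frame.
#' @param mesh A [build_mesh()] lattice (used when spatial effects are
#'   considered).
#' @param response Response passed to [model_spec()].
#' @param df Basis dimension for candidate smooths.
#' @param try_spatial Consider the spatial random effect at stage 1? If
#'   `FALSE` only the fields-off intercept row is fitted and fields stay off.
#' @param spatiotemporal Carry a spatiotemporal field in every model.
#' @param control [fit_control()] list.
#' @param cv_repeats If > 0, also report the k-fold CV summed test
#'   log-likelihood (mean over this many repeats) for each converged row.
#' @param cv_k,cv_seed k and seed for that CV column.
#' @return Object of class `selection_trace`: `$trace` (data.frame with
#'   `formula`, `spatial`, `aic`, `cv_loglik`), `$spec` (the chosen
#'   specification) and `$fit` (its fitted model).
#' @export
stepwise_select <- function(candidates, data, mesh = NULL,
                            response = "pooled", df = 3,
                            try_spatial = TRUE, spatiotemporal = FALSE,
                            control = fit_control(),
                            cv_repeats = 0, cv_k = 5, cv_seed = 1) {
  if (length(candidates) < 1) stop("need at least one candidate covariate")
  trace <- data.frame(formula = character(), spatial = character(),
                      aic = numeric(), cv_loglik = numeric(),
                      stringsAsFactors = FALSE)
  fits <- list()
  record <- function(spec, fit) {
    key <- paste(spec_formula(spec), ifelse(spec$spatial, "on", "off"))
    cvll <- NA_real_
    if (!is.null(fit) && fit$converged && cv_repeats > 0) {
      cvll <- tryCatch(
        kfold_cv(spec, data, mesh, k = cv_k, repeats = cv_repeats,
                 seed = cv_seed, control = control),
        error = function(e) NA_real_
      )
    }
    trace[nrow(trace) + 1, ] <<- list(
      spec_formula(spec), ifelse(spec$spatial, "on", "off"),
      if (!is.null(fit) && fit$converged) fit$aic else NA_real_, cvll
    )
    fits[[key]] <<- list(spec = spec, fit = fit)
    key
  }
  mk <- function(smooths, spatial) {
    model_spec(response, smooths = smooths, df = df, spatial = spatial,
               spatiotemporal = spatiotemporal)
  }

  # stage 1: intercept-only, fields off then (optionally) on
  s_off <- mk(character(), FALSE)
  k_off <- record(s_off, .safe_fit(s_off, data, mesh, control))
  keys <- k_off
  if (try_spatial) {
    s_on <- mk(character(), TRUE)
    keys <- c(keys, record(s_on, .safe_fit(s_on, data, mesh, control)))
  }
  aics <- trace$aic[seq_along(keys)]
  if (all(is.na(aics))) stop("all intercept fits failed to converge")
  best_key <- keys[which.min(aics)]
  cur <- fits[[best_key]]
  use_spatial <- cur$spec$spatial

  # stage 2: greedy add/drop of single smooth terms
  repeat {
    have <- names(cur$spec$smooths)
    moves <- c(setdiff(candidates, have),
               if (length(have)) paste0("-", have))
    if (!length(moves)) break
    best_move <- NULL
    best_aic <- cur$fit$aic
    for (mv in moves) {
      sm <- if (startsWith(mv, "-")) setdiff(have, substring(mv, 2)) else c(have, mv)
      spec_try <- mk(sm, use_spatial)
      key <- paste(spec_formula(spec_try), ifelse(use_spatial, "on", "off"))
      if (!is.null(fits[[key]])) next
      fit_try <- .safe_fit(spec_try, data, mesh, control)
      record(spec_try, fit_try)
      if (!is.null(fit_try) && fit_try$converged && fit_try$aic < best_aic) {
        best_aic <- fit_try$aic
        best_move <- key
      }
    }
    if (is.null(best_move)) break
    cur <- fits[[best_move]]
  }
  structure(
    list(trace = trace, spec = cur$spec, fit = cur$fit),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  tr <- x$trace
  tr$aic <- ifelse(is.na(tr$aic), "-", sprintf("%.2f", tr$aic))
  tr$cv_loglik <- ifelse(is.na(tr$cv_loglik), "-", sprintf("%.2f", tr$cv_loglik))
  print(tr, row.names = FALSE)
  cat("chosen:", spec_formula(x$spec), "| spatial",
      ifelse(x$spec$spatial, "on", "off"), "\n")
  invisible(x)
}

.bernoulli_loglik <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# stratified k-fold partition; returns fold id per row. k = n degenerates
# to leave-one-out (one observation per fold).
.stratified_folds <- function(y, k) {
  if (k == length(y)) return(sample(length(y)))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(sample(k), length(idx)))
  }
  fold
}

#' Repeated k-fold cross-validation scored by summed test log-likelihood
#'
#' For each repeat the data are partitioned into `k` outcome-stratified
#' folds; each fold in turn is held out, the model refitted on the rest,
#' and the Bernoulli log-likelihood of the held-out observations summed
#' across folds. The mean over repeats is returned (values are <= 0;
#' closer to 0 is better).
#'
#' @param spec A [model_spec()].
#' @param data Station data.frame.
#' @param mesh Mesh for field-carrying specs.
#' @param k Number of folds (k = n gives leave-one-out).
#' @param repeats Number of independent repartitions.
#' @param seed Seed; per-repeat sub-seeds are derived deterministically.
#' @param control [fit_control()].
#' @return Mean summed test log-likelihood; per-repeat values in attribute
#'   `"repeats"`.
#' @export
kfold_cv <- function(spec, data, mesh = NULL, k = 5, repeats = 100,
                     seed = 1, control = fit_control()) {
  if (k < 2) stop("k must be >= 2")
  y <- .response_vector(spec, data)
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of records")
  vals <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- NULL
    ok <- FALSE
    with_seed(derive_seed(seed, r), {
      for (try in 1:100) {
        fold <- .stratified_folds(y, k)
        ok <- all(vapply(seq_len(k), function(f) {
          yy <- y[fold != f]
          length(unique(yy)) == 2
        }, logical(1)))
        if (ok) break
      }
    })
    if (!ok) stop("could not build folds with both classes in every training set")
    tot <- 0
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      fit <- fit_model(spec, train, mesh, control)
      p <- predict(fit, test)
      tot <- tot + .bernoulli_loglik(p, y[fold == f])
    }
    vals[r] <- tot
  }
  structure(mean(vals), repeats = vals)
}

#' Leave-future-out cross-validation over chronological survey seasons
#'
#' For each time index t (from the first to the next-to-last), the model is
#' trained on all records with `date_index <= t` and scored on the records
#' at `t + 1` (the chronologically next index); the summed Bernoulli test
#' log-likelihood across folds is returned.
#'
#' @param spec A [model_spec()] (typically with a spatiotemporal field).
#' @param data Station data.frame with >= 2 distinct `date_index` values.
#' @param mesh Mesh for field-carrying specs.
#' @param control [fit_control()].
#' @return Total summed test log-likelihood; per-fold data.frame in
#'   attribute `"folds"`.
#' @export
lfocv <- function(spec, data, mesh = NULL, control = fit_control()) {
  times <- sort(unique(data$date_index))
  if (length(times) < 2) stop("LFOCV needs at least 2 time indices")
  y <- .response_vector(spec, data)
  folds <- data.frame(train_through = numeric(), test_index = numeric(),
                      n_test = integer(), loglik = numeric())
  tot <- 0
  for (i in seq_len(length(times) - 1)) {
    t_tr <- times[i]
    t_te <- times[i + 1]
    train <- data[data$date_index <= t_tr, , drop = FALSE]
    test <- data[data$date_index == t_te, , drop = FALSE]
    spec_t <- spec
    # a single training season cannot support a by-season field
    if (spec$spatiotemporal && length(unique(train$date_index)) < 2) {
      spec_t$spatiotemporal <- FALSE
    }
    fit <- fit_model(spec_t, train, mesh, control)
    p <- predict(fit, test)
    ll <- .bernoulli_loglik(p, y[data$date_index == t_te])
    folds[nrow(folds) + 1, ] <- list(t_tr, t_te, nrow(test), ll)
    tot <- tot + ll
  }
  structure(tot, folds = folds)
}
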