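# Binomial (logit) spatial GLMM estimated by maximising the
# Laplace-approximated marginal likelihood, mirroring the TMB machinery:
# an inner Newton optimisation over the latent field node values (with the
# fixed effects profiled at the joint mode) nested inside an outer
# quasi-Newton search over the field hyperparameters (log range, log SD).

#' Model specification
#'
#' @param response Name of a 0/1 column in the data, or a species suffix
#'   (e.g. `"beka"`) for which presence is derived from `count_<species>`.
#' @param smooths Covariates entering as natural-spline smooths: either a
#'   character vector of column names (all with basis dimension `df`) or a
#'   named integer vector mapping column name to basis dimension.
#' @param df Default basis dimension for smooths.
#' @param linear Covariates entering linearly (no basis expansion).
#' @param spatial Include the spatial Matern random field `omega_s`?
#' @param spatiotemporal Include independent-by-season spatiotemporal
#'   fields `epsilon_{s,t}` (requires >= 2 time indices in the data)?
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response, smooths = character(), df = 3,
                       linear = character(),
                       spatial = FALSE, spatiotemporal = FALSE) {
  if (is.character(smooths)) {
    smooths <- stats::setNames(rep(as.integer(df), length(smooths)), smooths)
  }
  if (anyDuplicated(c(names(smooths), linear))) {
    stop("duplicate covariates across smooth/linear terms")
  }
  structure(
    list(response = response, smooths = smooths, linear = linear,
         spatial = isTRUE(spatial), spatiotemporal = isTRUE(spatiotemporal)),
    class = "model_spec"
  )
}

#' Formula-style label of a specification
#' @param spec A [model_spec()].
#' @return Character like `"y ~ s(depth_m) + s(sss_psu)"`.
#' @export
spec_formula <- function(spec) {
  terms <- c(spec$linear, sprintf("s(%s)", names(spec$smooths)))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  paste("y ~", rhs)
}

#' Fitting control parameters
#'
#' @param maxit_outer Outer iteration cap for the hyperparameter search.
#' @param grad_tol Convergence tolerance on the outer gradient (inf-norm).
#' @param inner_maxit,inner_tol Inner Newton cap and gradient tolerance.
#' @param ridge Ridge on fixed-effect coefficients guarding against
#'   complete separation.
#' @param fix_range,fix_sd Optional fixed values (km, SD) for the spatial
#'   field hyperparameters instead of estimating them.
#' @param fix_range_eps,fix_sd_eps Same for the spatiotemporal field.
#' @return List of control values.
#' @export
fit_control <- function(maxit_outer = 200, grad_tol = 1e-3,
                        inner_maxit = 50, inner_tol = 1e-6, ridge = 1e-4,
                        fix_range = NULL, fix_sd = NULL,
                        fix_range_eps = NULL, fix_sd_eps = NULL) {
  as.list(environment())
}

.response_vector <- function(spec, data) {
  y <- data[[spec$response]]
  if (is.null(y)) {
    cc <- paste0("count_", spec$response)
    if (!is.null(data[[cc]])) y <- as.integer(data[[cc]] > 0)
  }
  if (is.null(y)) stop(sprintf("response '%s' not found", spec$response))
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  as.numeric(y)
}

.design_matrix <- function(spec, data, bases = NULL) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in spec$linear) {
    x <- data[[cv]]
    if (is.null(x)) stop(sprintf("covariate '%s' missing from data", cv))
    if (any(!is.finite(x))) stop(sprintf("covariate '%s' has missing values", cv))
    m <- matrix(x, ncol = 1, dimnames = list(NULL, cv))
    cols[[cv]] <- m
  }
  new_bases <- list()
  for (cv in names(spec$smooths)) {
    x <- data[[cv]]
    if (is.null(x)) stop(sprintf("covariate '%s' missing from data", cv))
    if (any(!is.finite(x))) stop(sprintf("covariate '%s' has missing values", cv))
    if (is.null(bases)) {
      b <- spline_basis(x, df = spec$smooths[[cv]])
      new_bases[[cv]] <- b
      B <- b$basis
    } else {
      B <- predict(bases[[cv]], x)
    }
    colnames(B) <- sprintf("s(%s).%d", cv, seq_len(ncol(B)))
    cols[[cv]] <- B
  }
  X <- do.call(cbind, cols)
  list(X = X, bases = if (is.null(bases)) new_bases else bases)
}

# ridge-penalised logistic Newton fit (dense, small p)
.logistic_fit <- function(X, y, ridge, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * ridge * sum(b^2)
  }
  f0 <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - ridge * beta
    if (max(abs(g)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(ridge, p)
    step <- solve(H, g)
    t_ <- 1
    repeat {
      f1 <- obj(beta + t_ * step)
      if (f1 >= f0 - 1e-12 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    beta <- beta + t_ * step
    f0 <- obj(beta)
  }
  eta <- drop(X %*% beta)
  list(beta = beta, loglik = sum(y * eta - log1p(exp(eta))), iters = it)
}

# shared C/G parts of the SPDE precision, cached on the mesh by the caller
.spde_parts <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  hx <- mesh$x[2] - mesh$x[1]; hy <- mesh$y[2] - mesh$y[1]
  n <- nx * ny
  wx <- rep(1, nx); wx[c(1, nx)] <- 0.5
  wy <- rep(1, ny); wy[c(1, ny)] <- 0.5
  cdiag <- as.vector(outer(wx, wy)) * hx * hy
  i <- rep(seq_len(nx - 1), times = ny)
  j <- rep(seq_len(ny), each = nx - 1)
  a1 <- .mesh_index(mesh, i, j); b1 <- .mesh_index(mesh, i + 1L, j)
  i <- rep(seq_len(nx), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx)
  a2 <- .mesh_index(mesh, i, j); b2 <- .mesh_index(mesh, i, j + 1L)
  ii <- c(a1, b1, a2, b2); jj <- c(b1, a1, b2, a2)
  vv <- c(rep(-hy / hx, 2 * length(a1)), rep(-hx / hy, 2 * length(a2)))
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  Matrix::diag(G) <- -Matrix::rowSums(G)
  list(C = Matrix::Diagonal(n, cdiag), G = G,
       Cinv = Matrix::Diagonal(n, 1 / cdiag), GCG = G %*% Matrix::Diagonal(n, 1 / cdiag) %*% G)
}

.assemble_Q <- function(parts, range_km, sd) {
  kappa <- sqrt(8) / range_km
  tau2 <- 1 / (4 * pi * kappa^2 * sd^2)
  Matrix::forceSymmetric(
    tau2 * (kappa^4 * parts$C + 2 * kappa^2 * parts$G + parts$GCG)
  )
}

.chol_logdet <- function(M) {
  ch <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
  c(2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

#' Fit the spatial binomial GLMM
#'
#' Maximises the Laplace-approximated marginal Bernoulli likelihood over the
#' fixed/basis coefficients and, when fields are active, the Matern
#' hyperparameters (decorrelation range in km and marginal SD) of the
#' spatial field `omega_s` and/or the by-season spatiotemporal fields
#' `epsilon_{s,t}`. Without fields this reduces to (ridge-stabilised)
#' logistic regression.
#'
#' @param spec A [model_spec()].
#' @param data Station data.frame with `lon`, `lat`, `date_index`, the
#'   response and all smooth covariates.
#' @param mesh A [build_mesh()] lattice covering the stations (required
#'   when any field is active).
#' @param control A [fit_control()] list.
#' @return Object of class `sdm_fit` with elements `beta`, `fields`
#'   (hyperparameter estimates), `omega_hat`/`eps_hat` (posterior modes of
#'   node values), `loglik` (marginal), `k`, `aic` (`NA` unless converged),
#'   `converged` and `diagnostics`.
#' @export
fit_model <- function(spec, data, mesh = NULL, control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"))
  y <- .response_vector(spec, data)
  if (length(unique(y)) < 2) {
    stop(sprintf("response '%s' has a single class; cannot fit", spec$response))
  }
  dm <- .design_matrix(spec, data)
  X <- dm$X
  p <- ncol(X)
  use_om <- spec$spatial
  use_eps <- spec$spatiotemporal
  times <- sort(unique(data$date_index))
  if (use_eps && length(times) < 2) {
    stop("spatiotemporal field requires >= 2 time indices")
  }

  if (!use_om && !use_eps) {
    lf <- .logistic_fit(X, y, control$ridge)
    fit <- list(
      spec = spec, beta = stats::setNames(lf$beta, colnames(X)),
      bases = dm$bases, mesh = mesh, fields = list(),
      omega_hat = NULL, eps_hat = NULL, times = times,
      loglik = lf$loglik, k = p, aic = 2 * p - 2 * lf$loglik,
      converged = TRUE,
      diagnostics = list(inner_iters = lf$iters, outer_grad = 0)
    )
    class(fit) <- "sdm_fit"
    return(fit)
  }

  if (is.null(mesh)) stop("mesh required when spatial fields are active")
  pl <- project_to_plane(data$lon, data$lat, zone = mesh$zone)
  A <- interpolation_matrix(mesh, pl)
  nm <- mesh$n
  Tn <- length(times)
  blocks <- list(methods::as(X, "CsparseMatrix"))
  if (use_om) blocks <- c(blocks, list(A))
  if (use_eps) {
    for (t in times) {
      At <- A
      At[data$date_index != t, ] <- 0
      blocks <- c(blocks, list(Matrix::drop0(At)))
    }
  }
  M <- do.call(cbind, blocks)
  n_u <- (if (use_om) nm else 0) + (if (use_eps) nm * Tn else 0)
  u_idx <- p + seq_len(n_u)
  parts <- .spde_parts(mesh)

  # outer parameter vector: (log range, log sd) per active field, minus fixed
  par_names <- character(0)
  if (use_om) par_names <- c(par_names, "lr_om", "ls_om")
  if (use_eps) par_names <- c(par_names, "lr_eps", "ls_eps")
  diam <- sqrt(diff(range(mesh$x))^2 + diff(range(mesh$y))^2)
  init <- c(
    lr_om = log(diam / 4), ls_om = 0,
    lr_eps = log(diam / 4), ls_eps = 0
  )[par_names]
  fixed <- c(
    lr_om = if (!is.null(control$fix_range)) log(control$fix_range) else NA,
    ls_om = if (!is.null(control$fix_sd)) log(control$fix_sd) else NA,
    lr_eps = if (!is.null(control$fix_range_eps)) log(control$fix_range_eps) else NA,
    ls_eps = if (!is.null(control$fix_sd_eps)) log(control$fix_sd_eps) else NA
  )[par_names]
  free <- is.na(fixed)
  lower <- c(lr_om = log(mesh$spacing_km / 2), ls_om = log(1e-9),
             lr_eps = log(mesh$spacing_km / 2), ls_eps = log(1e-9))[par_names]
  upper <- c(lr_om = log(20 * diam), ls_om = log(50),
             lr_eps = log(20 * diam), ls_eps = log(50))[par_names]

  beta0 <- .logistic_fit(X, y, control$ridge)$beta
  z_warm <- c(beta0, rep(0, n_u))

  build_P <- function(th) {
    Qs <- list(Matrix::Diagonal(p, control$ridge))
    logdetQ <- 0
    if (use_om) {
      Q_om <- .assemble_Q(parts, exp(th[["lr_om"]]), exp(th[["ls_om"]]))
      Qs <- c(Qs, list(Q_om))
      logdetQ <- logdetQ + .chol_logdet(Q_om)
    }
    if (use_eps) {
      Q_eps <- .assemble_Q(parts, exp(th[["lr_eps"]]), exp(th[["ls_eps"]]))
      Qs <- c(Qs, rep(list(Q_eps), Tn))
      logdetQ <- logdetQ + Tn * .chol_logdet(Q_eps)
    }
    list(P = Matrix::bdiag(Qs), logdetQ = logdetQ)
  }

  inner <- function(th) {
    bp <- build_P(th)
    P <- bp$P
    z <- z_warm
    obj <- function(z, eta) sum(y * eta - log1p(exp(eta))) -
      0.5 * sum(z * as.vector(P %*% z))
    eta <- as.vector(M %*% z)
    f0 <- obj(z, eta)
    iters <- 0
    for (it in seq_len(control$inner_maxit)) {
      iters <- it
      mu <- stats::plogis(eta)
      g <- as.vector(Matrix::crossprod(M, y - mu)) - as.vector(P %*% z)
      if (max(abs(g)) < control$inner_tol) break
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- Matrix::forceSymmetric(
        Matrix::crossprod(M, Matrix::Diagonal(x = w) %*% M) + P
      )
      step <- as.vector(Matrix::solve(H, g))
      t_ <- 1
      repeat {
        z1 <- z + t_ * step
        eta1 <- as.vector(M %*% z1)
        f1 <- obj(z1, eta1)
        if (is.finite(f1) && (f1 >= f0 - 1e-12)) break
        t_ <- t_ / 2
        if (t_ < 1e-10) break
      }
      z <- z + t_ * step
      eta <- as.vector(M %*% z)
      f0 <- obj(z, eta)
    }
    z_warm <<- z
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- Matrix::forceSymmetric(
      Matrix::crossprod(M, Matrix::Diagonal(x = w) %*% M) + P
    )
    Huu <- H[u_idx, u_idx, drop = FALSE]
    ll <- sum(y * eta - log1p(exp(eta)))
    u <- z[u_idx]
    quad <- sum(u * as.vector((P %*% z)[u_idx]))
    lap <- ll - 0.5 * quad + 0.5 * bp$logdetQ - 0.5 * .chol_logdet(Huu)
    list(lap = lap, z = z, iters = iters)
  }

  nll <- function(par_free) {
    th <- fixed
    th[free] <- par_free
    names(th) <- par_names
    -inner(th)$lap
  }

  th_hat <- fixed
  opt_iters <- 0
  if (any(free)) {
    opt <- stats::nlminb(
      init[free], nll,
      lower = lower[free], upper = upper[free],
      control = list(iter.max = control$maxit_outer,
                     eval.max = 4 * control$maxit_outer)
    )
    th_hat[free] <- opt$par
    opt_iters <- opt$iterations
  }
  names(th_hat) <- par_names
  fin <- inner(th_hat)

  # outer gradient (central differences) for the convergence diagnostic
  grad <- rep(0, sum(free))
  if (any(free)) {
    h <- 1e-4
    pf <- th_hat[free]
    for (i in seq_along(pf)) {
      e <- rep(0, length(pf)); e[i] <- h
      at_bound <- pf[i] <= lower[free][i] + 1e-8 || pf[i] >= upper[free][i] - 1e-8
      grad[i] <- if (at_bound) 0 else (nll(pf + e) - nll(pf - e)) / (2 * h)
    }
  }
  converged <- all(is.finite(grad)) && max(abs(grad), 0) < control$grad_tol &&
    is.finite(fin$lap)

  z <- fin$z
  beta <- stats::setNames(z[seq_len(p)], colnames(X))
  omega_hat <- NULL
  eps_hat <- NULL
  off <- p
  if (use_om) {
    omega_hat <- z[off + seq_len(nm)]
    off <- off + nm
  }
  if (use_eps) {
    eps_hat <- matrix(z[off + seq_len(nm * Tn)], nm, Tn,
                      dimnames = list(NULL, paste0("t", times)))
  }
  fields <- list()
  if (use_om) {
    fields$spatial <- list(range_km = exp(th_hat[["lr_om"]]),
                           sd = exp(th_hat[["ls_om"]]))
  }
  if (use_eps) {
    fields$spatiotemporal <- list(range_km = exp(th_hat[["lr_eps"]]),
                                  sd = exp(th_hat[["ls_eps"]]))
  }
  k <- p + 2 * length(fields)
  fit <- list(
    spec = spec, beta = beta, bases = dm$bases, mesh = mesh,
    fields = fields, omega_hat = omega_hat, eps_hat = eps_hat,
    times = times, loglik = fin$lap, k = k,
    aic = if (converged) 2 * k - 2 * fin$lap else NA_real_,
    converged = converged,
    diagnostics = list(outer_iters = opt_iters, inner_iters = fin$iters,
                       outer_grad = if (length(grad)) max(abs(grad)) else 0)
  )
  class(fit) <- "sdm_fit"
  fit
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("Spatial binomial GLMM: %s\n", spec_formula(x$spec)))
  cat(sprintf("  fields: spatial %s, spatiotemporal %s\n",
              ifelse(x$spec$spatial, "on", "off"),
              ifelse(x$spec$spatiotemporal, "on", "off")))
  for (nm in names(x$fields)) {
    cat(sprintf("  %s field: range %.1f km, SD %.3f\n",
                nm, x$fields[[nm]]$range_km, x$fields[[nm]]$sd))
  }
  cat(sprintf("  marginal lnL %.3f, k %d, AIC %s, converged: %s\n",
              x$loglik, x$k,
              ifelse(is.na(x$aic), "-", sprintf("%.2f", x$aic)),
              x$converged))
  invisible(x)
}

#' @export
logLik.sdm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Predict occurrence probability at new locations
#'
#' Evaluates `p = inverse-logit(basis(covariates) beta + interpolated
#' omega_hat (+ epsilon_hat for the row's time index))`. Spatiotemporal
#' fields contribute zero (their prior mean) for time indices not seen in
#' training.
#'
#' @param object A fitted `sdm_fit`.
#' @param newdata data.frame with the spec's covariates and, when fields
#'   are active, `lon`/`lat` (and `date_index` for spatiotemporal fields).
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.sdm_fit <- function(object, newdata, type = c("response", "link"),
                            ...) {
  type <- match.arg(type)
  dm <- .design_matrix(object$spec, newdata, bases = object$bases)
  eta <- drop(dm$X %*% object$beta)
  if (object$spec$spatial || object$spec$spatiotemporal) {
    pl <- project_to_plane(newdata$lon, newdata$lat, zone = object$mesh$zone)
    A <- interpolation_matrix(object$mesh, pl)
    if (object$spec$spatial) {
      eta <- eta + as.vector(A %*% object$omega_hat)
    }
    if (object$spec$spatiotemporal) {
      ti <- newdata$date_index
      if (is.null(ti)) stop("newdata needs date_index for spatiotemporal fields")
      for (t in intersect(unique(ti), object$times)) {
        rows <- which(ti == t)
        eps <- object$eps_hat[, paste0("t", t)]
        eta[rows] <- eta[rows] + as.vector(A[rows, , drop = FALSE] %*% eps)
      }
    }
  }
  if (type == "link") eta else inv_logit(eta)
}

#' @rdname predict.sdm_fit
#' @param model Fitted model.
#' @param newdata See [predict.sdm_fit()].
#' @export
predict_probability <- function(model, newdata) {
  predict(model, newdata, type = "response")
}
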