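## From-scratch REML engine for the four individual-tree model families:
##   B    control | pedigree + replicate + iblock:rep + iid residual
##   BA   control | pedigree + AR1xAR1 residual + units (nugget)
##   BC   B  + standardized competition covariate
##   BAC  BA + standardized competition covariate
## The competition covariate is fixed by default ("covariate" reading) or a
## one-column random regression with its own variance (`competition =
## "random"`).

#' Specify one of the B / BA / BC / BAC models
#'
#' @param family `"B"`, `"BA"`, `"BC"`, or `"BAC"`.
#' @param trait trait column name in the data (e.g. `"H"`).
#' @param ci_column column holding the standardized competition index
#'   (required for BC/BAC).
#' @param ci_label human-readable label of the competition configuration,
#'   carried into reports.
#' @param competition `"fixed"` (covariate, default) or `"random"`
#'   (one-column random regression).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("B", "BA", "BC", "BAC"), trait,
                       ci_column = "ci_std", ci_label = NULL,
                       competition = c("fixed", "random")) {
  family <- match.arg(family)
  competition <- match.arg(competition)
  if (missing(trait) || !is.character(trait))
    stop("`trait` must name a data column", call. = FALSE)
  has_ci <- family %in% c("BC", "BAC")
  structure(list(family = family, trait = trait,
                 ci_column = if (has_ci) ci_column else NULL,
                 ci_label = if (has_ci) ci_label %||% ci_column else NULL,
                 competition = competition,
                 spatial = family %in% c("BA", "BAC")),
            class = "model_spec")
}

#' Optimizer options for [fit_ace()]
#'
#' @param n_starts number of deterministic multi-starts (>= 1).
#' @param maxit iteration cap per optimizer stage.
#' @param reltol convergence tolerance on -2LL.
#' @param rho_max bound on |rho|.
#' @param boundary_tol variances below this are treated as boundary
#'   estimates (their SEs are reported `NA`).
#' @param compute_se set `FALSE` to skip the Hessian (faster when only LL
#'   or point estimates are needed, e.g. in ranking studies).
#' @return list of options.
#' @export
fit_options <- function(n_starts = 3, maxit = 500, reltol = 1e-8,
                        rho_max = 0.999, boundary_tol = 1e-6,
                        compute_se = TRUE) {
  list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
       reltol = reltol, rho_max = rho_max, boundary_tol = boundary_tol,
       compute_se = isTRUE(compute_se))
}

#' REML -2 log-likelihood for a given covariance
#'
#' `-2LL = log|V| + log|X'V^-1 X| + y'Py + (n - p) log 2pi` with
#' `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`, evaluated via Cholesky
#' factorisations. Translation of `y` along the columns of `X` leaves the
#' value unchanged.
#'
#' @param y response vector. @param X full-column-rank fixed-effect matrix.
#' @param V positive-definite covariance matrix.
#' @return scalar -2 REML log-likelihood.
#' @export
reml_neg2ll <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  L <- t(chol(V))
  z <- forwardsolve(L, cbind(X, y))
  zX <- z[, seq_len(p), drop = FALSE]; zy <- z[, p + 1L]
  XtViX <- crossprod(zX)
  Lx <- t(chol(XtViX))
  w <- forwardsolve(Lx, crossprod(zX, zy))
  yPy <- sum(zy^2) - sum(w^2)
  2 * sum(log(diag(L))) + 2 * sum(log(diag(Lx))) + yPy +
    (n - p) * log(2 * pi)
}

## Assemble the model structures once per dataset; returns closures used by
## the optimizer. `data` rows must be the observed (non-missing) records.
build_structures <- function(data, spec, A) {
  n <- nrow(data)
  K <- list()
  ids <- as.character(data$tree_id)
  if (!all(ids %in% rownames(A)))
    stop("phenotyped trees missing from the relationship matrix",
         call. = FALSE)
  K$A <- A[ids, ids]
  terms <- "A"
  if (!spec$spatial) {
    if (length(unique(data$rep)) > 1L) {
      K$rep <- outer(data$rep, data$rep, "==") * 1
      terms <- c(terms, "rep")
    }
    ib <- paste(data$rep, data$iblock)
    if (length(unique(ib)) > 1L) {
      K$ib <- outer(ib, ib, "==") * 1
      terms <- c(terms, "ib")
    }
  }
  if (!is.null(spec$ci_column) && spec$competition == "random") {
    ci <- data[[spec$ci_column]]
    K$comp <- tcrossprod(ci)
    terms <- c(terms, "comp")
  }
  Dr <- Dc <- NULL
  if (spec$spatial) {
    if (anyDuplicated(cbind(data$row, data$col)))
      stop("duplicate (row, col) grid cells among observations",
           call. = FALSE)
    Dr <- abs(outer(data$row, data$row, "-"))
    Dc <- abs(outer(data$col, data$col, "-"))
  }
  list(K = K, terms = terms, Dr = Dr, Dc = Dc, n = n)
}

## Parameter layout (natural scale): variances for each K term, then
## (sigma2_xi, rho_row, rho_col) if spatial, then the residual variance
## ("eta" nugget for spatial models, "e" otherwise).
param_names <- function(st, spec) {
  c(st$terms, if (spec$spatial) c("xi", "rho_row", "rho_col"),
    if (spec$spatial) "eta" else "e")
}

assemble_V <- function(par, st, spec) {
  V <- matrix(0, st$n, st$n)
  for (i in seq_along(st$terms)) V <- V + par[[st$terms[i]]] * st$K[[i]]
  if (spec$spatial)
    V <- V + par[["xi"]] * (par[["rho_row"]]^st$Dr * par[["rho_col"]]^st$Dc)
  res <- if (spec$spatial) par[["eta"]] else par[["e"]]
  V + diag(rep(res, st$n))
}

## transformed (unbounded) <-> natural parameters
to_natural <- function(theta, nms, rho_max) {
  out <- numeric(length(theta)); names(out) <- nms
  for (i in seq_along(nms))
    out[i] <- if (startsWith(nms[i], "rho")) rho_max * tanh(theta[i])
              else exp(theta[i])
  out
}
to_transformed <- function(par, nms, rho_max) {
  out <- numeric(length(par)); names(out) <- nms
  for (i in seq_along(nms))
    out[i] <- if (startsWith(nms[i], "rho")) atanh(pmin(0.999, pmax(-0.999,
                par[i] / rho_max)))
              else log(max(par[i], 1e-10))
  out
}

#' Fit an individual-tree REML mixed model
#'
#' Maximises the REML log-likelihood of the chosen model family over
#' log-variances and atanh-correlations by Nelder-Mead search with BFGS
#' refinement from several deterministic starting points. Standard errors
#' come from the central-difference Hessian of -2LL at the optimum
#' (covariance = 2 H^-1); variance estimates at the zero boundary get `NA`
#' SEs. Missing phenotypes are dropped from the response while their grid
#' cells simply never enter the AR1 index set (the grid stays conceptually
#' complete; distances are in grid steps).
#'
#' @param data data frame with columns `tree_id`, `rep`, `iblock`, `row`,
#'   `col`, the trait, and the competition column for BC/BAC. Rows with a
#'   missing trait value are dropped.
#' @param spec a [model_spec()].
#' @param pedigree pedigree data frame (used if `A` is not given).
#' @param A optional precomputed additive relationship matrix with ids as
#'   dimnames (saves repeated tabular passes across fits).
#' @param options a [fit_options()] list.
#' @return an object of class `ace_fit`: `vc` (named variance parameters),
#'   `vc_se`, `vc_cov`, `fixed` (estimates, SEs), `LL`, `neg2ll`, `t`
#'   (variance parameter count), `nu` (n - p), `n`, `h2`, `h2_se`,
#'   `converged`, `spec`, `starts` (per-start -2LL trace).
#' @export
fit_ace <- function(data, spec, pedigree = NULL, A = NULL,
                    options = fit_options()) {
  if (!inherits(spec, "model_spec"))
    stop("`spec` must come from model_spec()", call. = FALSE)
  if (is.null(A)) {
    if (is.null(pedigree)) stop("supply `pedigree` or `A`", call. = FALSE)
    A <- additive_matrix(pedigree)
  }
  y_all <- data[[spec$trait]]
  if (is.null(y_all)) stop("trait column `", spec$trait, "` not found",
                           call. = FALSE)
  keep <- !is.na(y_all)
  if (!is.null(spec$ci_column)) {
    if (is.null(data[[spec$ci_column]]))
      stop("competition column `", spec$ci_column, "` not found",
           call. = FALSE)
    keep <- keep & !is.na(data[[spec$ci_column]])
  }
  obs <- data[keep, , drop = FALSE]
  y <- obs[[spec$trait]]
  n <- length(y)

  X <- cbind(`(Intercept)` = 1,
             control = as.numeric(obs$control))
  if (!is.null(spec$ci_column) && spec$competition == "fixed")
    X <- cbind(X, competition = obs[[spec$ci_column]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)

  st <- build_structures(obs, spec, A)
  nms <- param_names(st, spec)

  fn <- function(theta) {
    par <- to_natural(theta, nms, options$rho_max)
    V <- assemble_V(par, st, spec)
    val <- tryCatch(reml_neg2ll(y, X, V), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 + sum(theta^2) else val
  }

  v0 <- stats::var(y)
  n_var <- sum(!startsWith(nms, "rho"))
  # moment-based primary start: half-sib ANOVA for sigma2_A, neighbour
  # correlation of the centred response for the spatial split
  sA0 <- 0.3 * v0
  if (!is.null(obs$family) && length(unique(obs$family)) > 2) {
    k <- mean(table(obs$family))
    msb <- stats::var(tapply(y, obs$family, mean))
    msw <- mean(tapply(y, obs$family, stats::var), na.rm = TRUE)
    sf <- max(msb - msw / k, 0.01 * v0)
    sA0 <- min(4 * sf, 0.8 * v0)
  }
  ac0 <- 0.3
  if (spec$spatial) {
    key <- paste(obs$row, obs$col)
    idx <- match(paste(obs$row, obs$col + 1L), key)
    ok <- !is.na(idx)
    e0 <- y - mean(y)
    if (sum(ok) > 30)
      ac0 <- min(max(stats::cor(e0[ok], e0[idx[ok]]), 0.05), 0.9)
  }
  rest <- max(v0 - sA0, 0.2 * v0)
  par_primary <- stats::setNames(rep(rest / max(n_var - 1, 1), length(nms)),
                                 nms)
  par_primary["A"] <- sA0
  if (spec$spatial) {
    par_primary["xi"] <- rest / 2
    par_primary["eta"] <- rest / 2
    par_primary[c("rho_row", "rho_col")] <- min(0.9, 2 * ac0)
  }
  start_sets <- list(par_primary,
                     stats::setNames(rep(v0 / n_var, length(nms)), nms),
                     stats::setNames(rep(v0 / n_var, length(nms)), nms))
  start_sets[[3]]["A"] <- 0.6 * v0
  rho_starts <- c(NA, 0.2, 0.6)   # NA = keep the moment-based value
  best <- NULL; trace <- numeric(0)
  for (s in seq_len(min(options$n_starts, 3L))) {
    par0 <- start_sets[[s]]
    if (spec$spatial && !is.na(rho_starts[s]))
      par0[c("rho_row", "rho_col")] <- rho_starts[s]
    th0 <- to_transformed(par0, nms, options$rho_max)
    o1 <- tryCatch(
      stats::optim(th0, fn, method = "BFGS",
                   control = list(maxit = 150, reltol = options$reltol)),
      error = function(e) list(par = th0, value = fn(th0)))
    o2 <- stats::optim(o1$par, fn, method = "Nelder-Mead",
                       control = list(maxit = options$maxit,
                                      reltol = options$reltol))
    o <- if (o2$value <= o1$value) o2 else o1
    trace <- c(trace, o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- is.finite(best$value) && best$value < 1e9
  par_hat <- to_natural(best$par, nms, options$rho_max)

  # central-difference Hessian of -2LL on the natural scale
  free <- !startsWith(nms, "rho") & par_hat > options$boundary_tol |
          startsWith(nms, "rho") & abs(par_hat) < options$rho_max * 0.995
  vc_cov <- matrix(NA_real_, length(nms), length(nms),
                   dimnames = list(nms, nms))
  if (converged && any(free) && options$compute_se) {
    f_nat <- function(q) {
      par <- par_hat; par[free] <- q
      if (any(par[!startsWith(nms, "rho")] < 0)) return(NA_real_)
      V <- assemble_V(par, st, spec)
      tryCatch(reml_neg2ll(y, X, V), error = function(e) NA_real_)
    }
    q0 <- par_hat[free]
    h <- pmax(1e-4, 5e-3 * abs(q0))
    m <- length(q0)
    H <- matrix(NA_real_, m, m)
    fpp <- fmm <- fpm <- fmp <- matrix(NA_real_, m, m)
    f0 <- f_nat(q0)
    for (i in seq_len(m)) for (j in i:m) {
      ei <- ej <- numeric(m); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f_nat(q0 + ei) - 2 * f0 + f_nat(q0 - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f_nat(q0 + ei + ej) - f_nat(q0 + ei - ej) -
           f_nat(q0 - ei + ej) + f_nat(q0 - ei - ej)) / (4 * h[i] * h[j])
      }
    }
    cov_free <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_free) && all(is.finite(diag(cov_free))) &&
        all(diag(cov_free) > 0))
      vc_cov[free, free] <- cov_free
  }
  vc_se <- sqrt(pmax(diag(vc_cov), 0))

  # GLS fixed effects at the optimum
  V <- assemble_V(par_hat, st, spec)
  L <- t(chol(V))
  z <- forwardsolve(L, cbind(X, y))
  zX <- z[, seq_len(p), drop = FALSE]
  XtViX_inv <- solve(crossprod(zX))
  beta <- drop(XtViX_inv %*% crossprod(zX, z[, p + 1L]))
  fixed <- data.frame(term = colnames(X), estimate = beta,
                      se = sqrt(diag(XtViX_inv)))

  fit <- structure(list(vc = par_hat, vc_se = vc_se, vc_cov = vc_cov,
                        fixed = fixed,
                        neg2ll = best$value, LL = -best$value / 2,
                        t = length(nms), nu = n - p, n = n, p = p,
                        converged = converged, spec = spec,
                        starts = trace),
                   class = "ace_fit")
  h2 <- tryCatch(heritability(fit), error = function(e) c(NA_real_, NA_real_))
  fit$h2 <- unname(h2[1]); fit$h2_se <- unname(h2[2])
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("<ace_fit %s> trait %s  LL = %.3f  (n = %d, t = %d, nu = %d)%s\n",
              x$spec$family, x$spec$trait, x$LL, x$n, x$t, x$nu,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  vc <- data.frame(component = names(x$vc), estimate = unname(x$vc),
                   se = unname(x$vc_se))
  print(vc, row.names = FALSE, digits = 4)
  cat(sprintf("h2 = %.4f (SE %.4f)\n", x$h2, x$h2_se))
  invisible(x)
}

#' Narrow-sense heritability of a fit
#'
#' `h2 = sigma2_A / (sigma2_A + sigma2_E)` where the residual variance
#' `sigma2_E` is the iid residual for B/BC models and the units (nugget)
#' component for models with an AR1 term; the spatially correlated
#' component and design variances are excluded from the denominator. The SE
#' is by the delta method from the variance-parameter covariance.
#'
#' @param fit an `ace_fit`.
#' @return named numeric `c(h2, se)`.
#' @export
heritability <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  res_nm <- if (fit$spec$spatial) "eta" else "e"
  sA <- fit$vc[["A"]]; sE <- fit$vc[[res_nm]]
  if (sA + sE <= 0) stop("h2 undefined: sigma2_A + sigma2_E = 0",
                         call. = FALSE)
  h2 <- sA / (sA + sE)
  se <- NA_real_
  cov2 <- fit$vc_cov[c("A", res_nm), c("A", res_nm)]
  if (all(is.finite(cov2))) {
    g <- c(sE, -sA) / (sA + sE)^2
    v <- drop(t(g) %*% cov2 %*% g)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  c(h2 = h2, se = se)
}
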