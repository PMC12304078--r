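#' Model specification for the pipeline's mixed models
#'
#' All models in the pipeline are generalised linear mixed models with one of
#' two families -- Gamma with log link (contrast and cone-catch responses) or
#' binomial with logit link (choice success) -- and at most a single random
#' intercept (photo ID or fish ID).
#'
#' @param response name of the response column.
#' @param family `"gamma_log"` or `"binomial_logit"`.
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ species * treatment`.
#' @param random_group name of the grouping column for the random intercept,
#'   or `NULL` for an ordinary GLM.
#' @return An object of class `glmm_spec`.
#' @export
glmm_spec <- function(response, family = c("gamma_log", "binomial_logit"),
                      fixed = ~1, random_group = NULL) {
  family <- match.arg(family)
  if (!inherits(fixed, "formula")) stop("fixed must be a one-sided formula")
  structure(list(response = response, family = family, fixed = fixed,
                 random_group = random_group),
            class = "glmm_spec")
}

# family log-density and derivatives with respect to the linear predictor.
# aux is the Gamma shape (ignored by the binomial family).
glmm_family <- function(family) {
  if (family == "binomial_logit") {
    list(
      logf = function(y, eta, aux) y * eta - ifelse(eta > 30, eta, log1p(exp(eta))),
      d1 = function(y, eta, aux) y - stats::plogis(eta),
      d2 = function(y, eta, aux) { p <- stats::plogis(eta); -p * (1 - p) },
      invlink = stats::plogis,
      has_shape = FALSE
    )
  } else {
    list(
      logf = function(y, eta, nu) {
        nu * (log(nu) - eta - y * exp(-eta)) - lgamma(nu) + (nu - 1) * log(y)
      },
      d1 = function(y, eta, nu) nu * (y * exp(-eta) - 1),
      d2 = function(y, eta, nu) -nu * y * exp(-eta),
      invlink = exp,
      has_shape = TRUE
    )
  }
}

# penalised profile of the random intercepts: vectorised Newton maximisation
# of h_i(b) = sum_j log f(y_j | eta_j + b) + log phi(b; 0, sigma^2), one b per
# group. Returns the modes, the per-group h values and curvatures.
glmm_inner_modes <- function(y, eta_fix, gi, G, fam, aux, sigma, b_start) {
  b <- b_start
  sig2 <- sigma^2
  for (it in seq_len(100)) {
    eta <- eta_fix + b[gi]
    g1 <- drop(rowsum(fam$d1(y, eta, aux), gi)) - b / sig2
    g2 <- drop(rowsum(fam$d2(y, eta, aux), gi)) - 1 / sig2
    step <- g1 / g2
    step <- pmax(pmin(step, 5), -5)
    b <- b - step
    if (max(abs(g1)) < 1e-10) break
  }
  eta <- eta_fix + b[gi]
  h <- drop(rowsum(fam$logf(y, eta, aux), gi)) +
    stats::dnorm(b, 0, sigma, log = TRUE)
  hpp <- drop(rowsum(fam$d2(y, eta, aux), gi)) - 1 / sig2
  list(b = b, h = h, hpp = hpp)
}

glmm_nll_factory <- function(y, X, gi, G, family, agq_nodes, ridge_var) {
  fam <- glmm_family(family)
  p <- ncol(X)
  has_random <- !is.null(gi)
  gh <- if (has_random && family == "binomial_logit") {
    pracma::gaussHermite(agq_nodes)
  } else NULL
  warm <- new.env(parent = emptyenv())
  warm$b <- if (has_random) numeric(G) else NULL

  function(theta) {
    beta <- theta[seq_len(p)]
    k <- p
    sigma <- if (has_random) { k <- k + 1; exp(theta[k]) } else 0
    aux <- if (fam$has_shape) { k <- k + 1; exp(theta[k]) } else 1
    if (!all(is.finite(beta)) || !is.finite(sigma) || !is.finite(aux)) return(1e10)
    eta_fix <- drop(X %*% beta)
    pen <- if (is.finite(ridge_var)) sum(beta^2) / (2 * ridge_var) else 0
    if (!has_random) {
      ll <- sum(fam$logf(y, eta_fix, aux))
      return(if (is.finite(ll)) -ll + pen else 1e10)
    }
    inner <- glmm_inner_modes(y, eta_fix, gi, G, fam, aux, sigma, warm$b)
    warm$b <- inner$b
    if (any(!is.finite(inner$h)) || any(inner$hpp >= 0)) return(1e10)
    if (is.null(gh)) {
      # Laplace approximation
      ll_i <- inner$h + 0.5 * log(2 * pi) - 0.5 * log(-inner$hpp)
    } else {
      # adaptive Gauss-Hermite centred on the conditional modes
      s <- 1 / sqrt(-inner$hpp)
      terms <- matrix(NA_real_, G, length(gh$x))
      for (kq in seq_along(gh$x)) {
        bk <- inner$b + sqrt(2) * s * gh$x[kq]
        hk <- drop(rowsum(fam$logf(y, eta_fix + bk[gi], aux), gi)) +
          stats::dnorm(bk, 0, sigma, log = TRUE)
        terms[, kq] <- hk + gh$x[kq]^2 + log(gh$w[kq])
      }
      m <- apply(terms, 1, max)
      ll_i <- m + log(rowSums(exp(terms - m))) + log(sqrt(2) * s)
    }
    ll <- sum(ll_i)
    if (!is.finite(ll)) return(1e10)
    -ll + pen
  }
}

#' Fit a generalised linear mixed model
#'
#' Maximum-likelihood fit of a Gamma (log link) or binomial (logit link) model
#' with an optional single random intercept. The random intercept is
#' integrated out by adaptive Gauss--Hermite quadrature (15 nodes per group by
#' default) for the binomial family and by the Laplace approximation for the
#' Gamma family. Fixed-effect uncertainty is summarised by the Wald
#' covariance, i.e. the fixed-effect block of the inverse observed information
#' over all parameters. With `random_group = NULL` the fit is an ordinary
#' maximum-likelihood GLM.
#'
#' @param data data frame containing the response, fixed-effect factors and
#'   (if any) the grouping column.
#' @param spec a [glmm_spec()].
#' @param ridge_var optional Gaussian ridge variance on the fixed effects
#'   (logit scale), used to stabilise complete separation in binomial fits;
#'   `Inf` (default) disables it.
#' @param agq_nodes Gauss--Hermite node count for the binomial family.
#' @param control list overriding `nlminb` control values (`rel.tol = 1e-10`,
#'   `iter.max = 500`).
#' @return An object of class `camo_glmm` with elements `coefficients`,
#'   `covariance`, `dispersion_or_shape` (Gamma shape; 1 for binomial),
#'   `random_sd`, `loglik`, `spec`, and the design ingredients used by the
#'   posterior and residual tools.
#' @seealso [posterior_draws()], [predict_levels()], [response_ratio()],
#'   [r_squared()], [quantile_residuals()]
#' @export
fit_glmm <- function(data, spec, ridge_var = Inf, agq_nodes = 15,
                     control = list()) {
  stopifnot(inherits(spec, "glmm_spec"))
  if (!spec$response %in% names(data)) {
    stop("response column '", spec$response, "' not found in the data")
  }
  y <- data[[spec$response]]
  if (anyNA(y)) stop("response contains missing values")
  if (spec$family == "gamma_log" && any(y <= 0)) {
    stop("Gamma responses must be strictly positive")
  }
  if (spec$family == "binomial_logit" && !all(y %in% c(0, 1))) {
    stop("binomial responses must be coded 0/1")
  }
  mf <- stats::model.frame(spec$fixed, data = data, na.action = stats::na.fail,
                           drop.unused.levels = TRUE)
  for (v in names(mf)) {
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]]) && nlevels(droplevels(mf[[v]])) < 2) {
      stop("fixed factor '", v, "' has fewer than 2 observed levels")
    }
  }
  trms <- stats::terms(mf)
  X <- stats::model.matrix(trms, mf)
  p <- ncol(X)
  gi <- NULL; G <- 0L; group_levels <- NULL
  if (!is.null(spec$random_group)) {
    if (!spec$random_group %in% names(data)) {
      stop("random grouping column '", spec$random_group, "' not found")
    }
    gf <- factor(data[[spec$random_group]])
    gi <- as.integer(gf)
    G <- nlevels(gf)
    group_levels <- levels(gf)
  }

  # starting values: least squares on the link-transformed response
  ylink <- if (spec$family == "gamma_log") log(y) else stats::qlogis((y + 0.5) / 2)
  beta0 <- tryCatch(qr.solve(X, ylink), error = function(e) numeric(p))
  if (!all(is.finite(beta0))) beta0 <- numeric(p)
  theta0 <- beta0
  if (!is.null(gi)) theta0 <- c(theta0, log(0.3))
  if (spec$family == "gamma_log") {
    r <- y / pmax(exp(drop(X %*% beta0)), 1e-12)
    nu0 <- 1 / max(stats::var(log(r)), 0.02)
    theta0 <- c(theta0, log(min(max(nu0, 0.1), 100)))
  }

  nll <- glmm_nll_factory(y, X, gi, G, spec$family, agq_nodes, ridge_var)
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500, eval.max = 2000),
                            control)
  opt <- stats::nlminb(theta0, nll, control = ctrl)
  if (!opt$convergence %in% c(0L) &&
      !grepl("relative convergence|both X|singular convergence", opt$message)) {
    # a flat likelihood plateau (e.g. complete separation) triggers "false
    # convergence"; accept it only when the gradient really is negligible,
    # so the separation diagnostics downstream can deal with it
    h <- 1e-5
    grad <- vapply(seq_along(opt$par), function(j) {
      e <- numeric(length(opt$par)); e[j] <- h
      (nll(opt$par + e) - nll(opt$par - e)) / (2 * h)
    }, numeric(1))
    if (!all(is.finite(grad)) || max(abs(grad)) > 1e-3 * (1 + abs(opt$objective))) {
      stop("model fit did not converge: ", opt$message,
           " (objective ", signif(opt$objective, 6), ")")
    }
  }
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    stop("model fit failed: non-finite likelihood at the optimum")
  }
  if (is.null(gi)) {
    # polish the GLM route to machine precision with Newton steps on beta
    # (and a 1-d shape refit for the Gamma family)
    fam <- glmm_family(spec$family)
    beta <- opt$par[seq_len(p)]
    aux <- if (fam$has_shape) exp(opt$par[p + 1]) else 1
    for (round in 1:3) {
      for (it in 1:50) {
        eta <- drop(X %*% beta)
        gvec <- drop(crossprod(X, fam$d1(y, eta, aux)))
        Hm <- crossprod(X, X * fam$d2(y, eta, aux))
        if (is.finite(ridge_var)) {
          gvec <- gvec - beta / ridge_var
          Hm <- Hm - diag(1 / ridge_var, p)
        }
        step <- tryCatch(solve(Hm, gvec), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step)) || max(abs(beta)) > 30) break
        beta <- beta - step
        if (max(abs(gvec)) < 1e-10) break
      }
      if (!fam$has_shape) break
      eta <- drop(X %*% beta)
      o <- stats::optimize(function(ln) -sum(fam$logf(y, eta, exp(ln))),
                           c(-5, 8), tol = 1e-12)
      aux <- exp(o$minimum)
    }
    cand <- opt$par
    cand[seq_len(p)] <- beta
    if (fam$has_shape) cand[p + 1] <- log(aux)
    if (all(is.finite(cand)) && nll(cand) <= opt$objective + 1e-8) {
      opt$par <- cand
      opt$objective <- nll(cand)
    }
  }

  H <- stats::optimHess(opt$par, nll)
  V_full <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V_full) || any(!is.finite(V_full))) {
    ev <- eigen(H, symmetric = TRUE)
    vals <- pmax(ev$values, max(abs(ev$values)) * 1e-10)
    V_full <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  }
  V <- (V_full[seq_len(p), seq_len(p), drop = FALSE] +
        t(V_full[seq_len(p), seq_len(p), drop = FALSE])) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  k <- p
  random_sd <- if (!is.null(gi)) { k <- k + 1; unname(exp(opt$par[k])) } else 0
  shape <- if (spec$family == "gamma_log") { k <- k + 1; unname(exp(opt$par[k])) } else 1

  structure(list(coefficients = beta, covariance = V,
                 dispersion_or_shape = shape, random_sd = random_sd,
                 loglik = -opt$objective, spec = spec,
                 terms = stats::delete.response(trms),
                 xlevels = stats::.getXlevels(trms, mf),
                 contrasts = attr(X, "contrasts"),
                 X = X, y = y, group_index = gi, group_levels = group_levels,
                 ridge_var = ridge_var, message = opt$message),
            class = "camo_glmm")
}

#' @export
print.camo_glmm <- function(x, ...) {
  cat(sprintf("GLMM (%s), %d fixed effects, random SD %.4g%s, logLik %.3f\n",
              x$spec$family, length(x$coefficients), x$random_sd,
              if (x$spec$family == "gamma_log")
                sprintf(", shape %.3g", x$dispersion_or_shape) else "",
              x$loglik))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Detect complete separation in a binomial fit
#'
#' Flags fits whose estimates or standard errors have drifted to the scale
#' typical of separated data (|coefficient| > 10 or SE > 10 on the logit
#' scale), in which case a weak ridge penalty keeps estimates finite.
#'
#' @param fit a `camo_glmm`.
#' @export
detect_separation <- function(fit) {
  stopifnot(inherits(fit, "camo_glmm"))
  if (fit$spec$family != "binomial_logit") return(FALSE)
  se <- sqrt(pmax(diag(fit$covariance), 0))
  any(!is.finite(fit$coefficients)) || any(abs(fit$coefficients) > 10) ||
    any(!is.finite(se)) || any(se > 10)
}

#' Simulate from the posterior of the fixed effects
#'
#' Draws parameter sets from the multivariate normal distribution centred on
#' the fixed-effect estimates with the Wald covariance, the standard
#' simulation route for compatibility intervals of model predictions.
#' Random-effect uncertainty is not propagated.
#'
#' @param fit a `camo_glmm`.
#' @param n number of draws (default 10,000, the pipeline's convention).
#' @param seed integer seed; identical seeds give identical draws.
#' @return Numeric matrix `n x p` of coefficient draws.
#' @export
posterior_draws <- function(fit, n = 10000, seed = 1) {
  stopifnot(inherits(fit, "camo_glmm"))
  if (n < 1) stop("need at least one draw")
  V <- fit$covariance
  p <- ncol(V)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(V, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
      warning("covariance not positive semi-definite; negative eigenvalues clipped")
    }
    vals <- pmax(ev$values, 0)
    R <- diag(sqrt(vals), p) %*% t(ev$vectors)
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  draws <- Z %*% R
  draws <- sweep(draws, 2, fit$coefficients, "+")
  colnames(draws) <- names(fit$coefficients)
  draws
}

level_model_matrix <- function(fit, levels) {
  mf <- stats::model.frame(fit$terms, levels, xlev = fit$xlevels,
                           na.action = stats::na.fail)
  stats::model.matrix(fit$terms, mf, contrasts.arg = fit$contrasts)
}

#' Predicted medians and compatibility intervals per factor level
#'
#' For each requested factor combination, transforms the simulated linear
#' predictors through the inverse link and reports the median and the 2.5/97.5
#' percentiles (95\% compatibility interval) across draws.
#'
#' @param fit a `camo_glmm`.
#' @param draws a matrix from [posterior_draws()].
#' @param levels data frame of factor combinations (one row per prediction).
#' @return `levels` with columns `median`, `ci_low`, `ci_high`, `n_draws`
#'   appended.
#' @export
predict_levels <- function(fit, draws, levels) {
  stopifnot(inherits(fit, "camo_glmm"))
  Xn <- tryCatch(level_model_matrix(fit, levels),
                 error = function(e) stop("level not in the model design: ",
                                          conditionMessage(e)))
  fam <- glmm_family(fit$spec$family)
  lin <- Xn %*% t(draws)                     # levels x draws
  resp <- fam$invlink(lin)
  qs <- t(apply(resp, 1, stats::quantile, probs = c(0.5, 0.025, 0.975),
                names = FALSE))
  out <- cbind(levels,
               data.frame(median = qs[, 1], ci_low = qs[, 2], ci_high = qs[, 3],
                          n_draws = nrow(draws)))
  rownames(out) <- NULL
  out
}

#' Posterior response ratio between two factor levels
#'
#' Median and 95\% compatibility interval of
#' \eqn{\exp(\eta_a - \eta_b)} across posterior draws: for the Gamma log link
#' this is the ratio of predicted means (the response-ratio effect size); for
#' the binomial logit it is an odds ratio. Ratios whose CI excludes one are
#' flagged.
#'
#' @param fit a `camo_glmm`.
#' @param draws a matrix from [posterior_draws()].
#' @param level_a,level_b one-row data frames naming the two factor
#'   combinations (numerator, denominator).
#' @return One-row data frame: `ratio_median`, `ci_low`, `ci_high`,
#'   `excludes_one`, `n_draws`.
#' @export
response_ratio <- function(fit, draws, level_a, level_b) {
  Xa <- level_model_matrix(fit, level_a)
  Xb <- level_model_matrix(fit, level_b)
  if (nrow(Xa) != 1 || nrow(Xb) != 1) stop("level_a and level_b must be single rows")
  r <- exp(drop((Xa - Xb) %*% t(draws)))
  q <- stats::quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(ratio_median = q[1], ci_low = q[2], ci_high = q[3],
             excludes_one = q[2] > 1 || q[3] < 1, n_draws = length(r))
}

#' Marginal and conditional R-squared
#'
#' Nakagawa--Schielzeth variance decomposition on the link scale: the marginal
#' R2 is the fixed-effect variance share, the conditional R2 adds the random
#' intercept variance. The residual variance is the family-specific
#' distribution variance on the link scale: \eqn{\pi^2/3} for the logit, and
#' the trigamma of the shape parameter for the Gamma log link.
#'
#' @param fit a `camo_glmm`.
#' @return Named vector `c(marginal, conditional)`.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "camo_glmm"))
  var_f <- stats::var(drop(fit$X %*% fit$coefficients))
  var_r <- fit$random_sd^2
  var_e <- if (fit$spec$family == "binomial_logit") pi^2 / 3
           else trigamma(fit$dispersion_or_shape)
  denom <- var_f + var_r + var_e
  c(marginal = var_f / denom, conditional = (var_f + var_r) / denom)
}

#' Randomised quantile residuals
#'
#' Simulation-based residuals in the DHARMa style: each observation's residual
#' is its rank position within `n_sim` responses simulated from the fitted
#' model (new random intercepts each simulation), jittered uniformly within
#' ties. Under a well-specified model the residuals are Uniform(0, 1).
#'
#' @param fit a `camo_glmm`.
#' @param n_sim simulations per observation (>= 20).
#' @param seed integer seed.
#' @return Numeric vector of residuals in (0, 1), one per observation.
#' @export
quantile_residuals <- function(fit, n_sim = 250, seed = 1) {
  stopifnot(inherits(fit, "camo_glmm"))
  if (n_sim < 20) stop("n_sim below 20 gives residuals too coarse to interpret")
  set.seed(seed)
  n <- length(fit$y)
  eta_fix <- drop(fit$X %*% fit$coefficients)
  fam <- glmm_family(fit$spec$family)
  below <- integer(n); equal <- integer(n)
  for (s in seq_len(n_sim)) {
    eta <- eta_fix
    if (!is.null(fit$group_index)) {
      b <- stats::rnorm(length(fit$group_levels), 0, fit$random_sd)
      eta <- eta + b[fit$group_index]
    }
    mu <- fam$invlink(eta)
    ysim <- if (fit$spec$family == "binomial_logit") {
      stats::rbinom(n, 1, mu)
    } else {
      nu <- fit$dispersion_or_shape
      stats::rgamma(n, shape = nu, rate = nu / mu)
    }
    below <- below + (ysim < fit$y)
    equal <- equal + (ysim == fit$y)
  }
  (below + stats::runif(n) * (1 + equal)) / (n_sim + 1)
}
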