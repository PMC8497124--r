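#' Type-II censored sample container
#'
#' Wraps the first `k` order statistics of `n` units.  `k = n` (the default)
#' is a complete sample.  Values are sorted ascending on construction.
#'
#' @param values nonnegative observations (the observed failures).
#' @param n_total number of units on test, `>= length(values)`.
#' @return An object of class `"tgl_sample"` with components `values`
#'   (sorted), `n` and `k`.
#' @examples
#' s <- tgl_censored(c(0.3, 0.1, 0.7), n_total = 5)
#' s$k; s$n
#' @export
tgl_censored <- function(values, n_total = length(values)) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must be nonempty")
  if (any(!is.finite(values)) || any(values < 0))
    stop("'values' must be finite and nonnegative")
  if (n_total < length(values))
    stop("'n_total' cannot be smaller than the number of observed values")
  structure(list(values = sort(values), n = as.integer(n_total),
                 k = length(values)),
            class = "tgl_sample")
}

as_tgl_sample <- function(x, n_total = NULL) {
  if (inherits(x, "tgl_sample")) return(x)
  tgl_censored(x, n_total = if (is.null(n_total)) length(x) else n_total)
}

#' Log-likelihood of the TGL model
#'
#' `tgl_loglik` evaluates the complete-sample log-likelihood (the sum of
#' log-densities).  `tgl_loglik_typeII` evaluates the Type-II censored
#' log-likelihood for the first `k` of `n` order statistics.  The
#' `"canonical"` variant uses the standard censored form
#' \deqn{\ell_2 = \sum_{i=1}^k \log f(x_{(i)}) + (n-k)\log S(x_{(k)}),}
#' while `"paper_literal"` multiplies the summed log-survival of *every*
#' observed order statistic by `(n-k)`,
#' \eqn{\sum_i \log f(x_{(i)}) + (n-k)\sum_i \log S(x_{(i)})}, an
#' alternative algebra that some published accounts of this family print.
#' Both coincide with the complete-sample log-likelihood when `k = n`.
#'
#' @param x numeric vector of observations (complete sample).
#' @param sample a [tgl_censored()] object (or a plain vector, treated as
#'   complete).
#' @param params a [tgl_params()] object.
#' @param variant `"canonical"` (default) or `"paper_literal"`.
#' @return The log-likelihood (`-Inf` if any observation has zero density
#'   or the survival term vanishes).
#' @export
tgl_loglik <- function(x, params) {
  sum(dtgl(x, params, log = TRUE))
}

#' @rdname tgl_loglik
#' @export
tgl_loglik_typeII <- function(sample, params,
                              variant = c("canonical", "paper_literal")) {
  variant <- match.arg(variant)
  sample <- as_tgl_sample(sample)
  ll <- sum(dtgl(sample$values, params, log = TRUE))
  if (sample$k < sample$n) {
    lS <- ptgl(sample$values, params, lower.tail = FALSE, log.p = TRUE)
    ll <- ll + if (variant == "canonical") {
      (sample$n - sample$k) * lS[sample$k]
    } else {
      (sample$n - sample$k) * sum(lS)
    }
  }
  ll
}

#' Analytic score of the complete-sample log-likelihood
#'
#' The gradient of [tgl_loglik()] in the original parameterization, in the
#' order `(delta, gamma, vartheta, pi, beta)`.  Derived by differentiating
#' the log-density; agrees with central finite differences to high relative
#' accuracy, which the test suite asserts.
#'
#' @param x numeric vector of observations.
#' @param params a [tgl_params()] object.
#' @return A named numeric 5-vector.
#' @export
tgl_score <- function(x, params) {
  params <- as_tgl_params(params)
  delta <- params$delta; gam <- params$gamma
  vth <- params$vartheta; pis <- params$pi; beta <- params$beta
  n <- length(x)
  lg <- log1p(gam * x)
  A <- exp(delta * pis * lg)            # (1 + gamma x)^(delta pi)
  psi <- 1 - A
  w <- exp((vth / pis) * psi)
  D <- 1 - beta + 2 * beta * w
  xr <- x / (1 + gam * x)
  A1 <- exp((delta * pis - 1) * lg)
  g_delta <- n / delta + pis * sum(lg) - vth * sum(A * lg) -
    sum(2 * beta * vth * A * lg * w / D)
  g_gamma <- n / gam + (delta * pis - 1) * sum(xr) -
    delta * vth * sum(x * A1) -
    sum(2 * beta * delta * vth * w * x * A1 / D)
  g_vth <- n / vth + sum(psi) / pis + sum(2 * beta * (psi / pis) * w / D)
  g_pi <- delta * sum(lg) -
    (vth / pis^2) * sum(pis * delta * A * lg + psi) -
    sum(2 * beta * w * vth * (delta * A * lg / pis + psi / pis^2) / D)
  g_beta <- sum((2 * w - 1) / D)
  c(delta = g_delta, gamma = g_gamma, vartheta = g_vth,
    pi = g_pi, beta = g_beta)
}

## ------------------------------------------------------------------
## internal optimization machinery
##
## Working parameterization: th = (log delta, log gamma, log vartheta,
## log pi, atanh(beta)), which makes the positivity and |beta| < 1
## constraints implicit.
## ------------------------------------------------------------------

BETA_EPS <- 1e-6

tgl_to_theta <- function(p) {
  p <- unname(tgl_par_vec(p))
  b <- min(max(p[5], -1 + BETA_EPS), 1 - BETA_EPS)
  c(log(p[1:4]), atanh(b))
}

tgl_from_theta <- function(th) {
  c(exp(th[1:4]), tanh(th[5]))
}

# negative log-likelihood as a function of the raw parameter vector
# p = (delta, gamma, vartheta, pi, beta); returns a large finite penalty
# outside the domain so finite-difference probes never see NaN
tgl_nll_raw <- function(p, sample, variant) {
  if (any(!is.finite(p)) || any(p[1:4] <= 0) || abs(p[5]) > 1) return(1e10)
  a <- p[1] * p[4]; b <- p[3] / p[4]
  x <- sample$values
  lg <- log1p(p[2] * x)
  psi <- -expm1(a * lg)
  w <- exp(b * psi)
  mix <- 1 - p[5] + 2 * p[5] * w
  if (any(!is.finite(c(psi, w, mix))) || any(mix <= 0)) return(1e10)
  ll <- sum(log(p[1] * p[3] * p[2]) + (a - 1) * lg + b * psi + log(mix))
  if (sample$k < sample$n) {
    sw <- w * (1 - p[5] + p[5] * w)
    if (any(sw <= 0)) return(1e10)
    ll <- ll + if (variant == "canonical") {
      (sample$n - sample$k) * log(sw[sample$k])
    } else {
      (sample$n - sample$k) * sum(log(sw))
    }
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

tgl_nll_theta <- function(th, sample, variant) {
  tgl_nll_raw(tgl_from_theta(th), sample, variant)
}

fd_gradient <- function(f, th, ..., h = 1e-7) {
  vapply(seq_along(th), function(i) {
    e <- rep(0, length(th)); e[i] <- h
    (f(th + e, ...) - f(th - e, ...)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, th, ..., h) {
  k <- length(th)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- rep(0, k); ej <- rep(0, k)
      ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(th + ei + ej, ...) - f(th + ei - ej, ...) -
           f(th - ei + ej, ...) + f(th - ei - ej, ...)) / (4 * h[i] * h[j])
    }
  }
  H
}

# symmetric pseudo-inverse; drops eigenvalues below rtol * max|eigenvalue|
pinv_sym <- function(H, rtol = 1e-7) {
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  keep <- ev$values > max(abs(ev$values)) * rtol
  if (!any(keep)) return(list(cov = matrix(NA_real_, nrow(H), ncol(H)),
                              rank = 0L, dropped = ncol(H)))
  V <- ev$vectors[, keep, drop = FALSE]
  list(cov = V %*% (t(V) / ev$values[keep]),
       rank = sum(keep), dropped = sum(!keep))
}

# damped minimum-norm (Moore-Penrose) Newton descent on the working scale;
# the canonical resolution of the exactly flat (delta, vartheta, pi) ridge:
# steps have no component along null directions of the Hessian
scoring_optim <- function(th, sample, variant, maxit = 60L,
                          obj.tol = 1e-10, step.tol = 1e-9) {
  f0 <- tgl_nll_theta(th, sample, variant)
  it <- 0L
  repeat {
    it <- it + 1L
    g <- fd_gradient(tgl_nll_theta, th, sample = sample, variant = variant)
    H <- fd_hessian(tgl_nll_theta, th, sample = sample, variant = variant,
                    h = rep(1e-4, length(th)))
    P <- pinv_sym(H)
    if (P$rank == 0L) break
    step <- -as.numeric(P$cov %*% g)
    lam <- 1
    repeat {
      thn <- th + lam * step
      f1 <- tgl_nll_theta(thn, sample, variant)
      if (f1 < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (f1 >= f0 - obj.tol * (1 + abs(f0))) break
    th <- thn; f0 <- f1
    if (sqrt(sum((lam * step)^2)) < step.tol) break
    if (it >= maxit) break
  }
  g <- fd_gradient(tgl_nll_theta, th, sample = sample, variant = variant)
  list(par = th, objective = f0, iterations = it,
       grad_norm = sqrt(sum(g^2)), converged = it < maxit)
}

# deterministic multistart set: heuristic start, GoLom-constrained warm
# start, and seeded log-normal perturbations of the heuristic
tgl_start_set <- function(sample, n_starts, seed, variant) {
  x <- sample$values
  m <- mean(x)
  heur <- c(delta = 1, gamma = 1 / m, vartheta = 1, pi = 1, beta = 0)
  starts <- list(heur)
  # GoLom warm start: 4-parameter fit with beta pinned at 0
  g0 <- tryCatch({
    obj <- function(th4) tgl_nll_raw(c(exp(th4), 0), sample, variant)
    o <- stats::nlminb(log(heur[1:4]), obj,
                       control = list(iter.max = 500L, rel.tol = 1e-10))
    c(exp(o$par), beta = 0)
  }, error = function(e) NULL)
  if (!is.null(g0)) starts <- c(starts, list(g0))
  n_extra <- max(n_starts - length(starts), 0L)
  if (n_extra > 0L) {
    pert <- withr_seed(seed, {
      lapply(seq_len(n_extra), function(i) {
        c(heur[1:4] * exp(stats::rnorm(4, 0, 0.75)),
          beta = stats::runif(1, -0.9, 0.9))
      })
    })
    starts <- c(starts, pert)
  }
  starts[seq_len(min(length(starts), max(n_starts, 1L)))]
}

# evaluate expr with a local RNG state seeded by `seed` (NULL = use current)
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Maximum-likelihood fit of the TGL distribution
#'
#' Maximizes the complete or Type-II censored log-likelihood over the
#' constrained parameter space via an unconstrained working scale (log for
#' the four positive parameters, `atanh` for `beta`).  Two optimizers are
#' available:
#'
#' * `"multistart"` (default): [stats::nlminb()] quasi-Newton runs from a
#'   deterministic start set — a moment-flavored heuristic, a
#'   GoLom-constrained (`beta = 0`) warm start, and seeded perturbations —
#'   keeping the best objective.
#' * `"scoring"`: damped Newton iteration whose step uses the Moore-Penrose
#'   pseudo-inverse of the finite-difference Hessian.  Because the TGL
#'   parameterization carries an exactly flat `(delta, vartheta, pi)` ridge,
#'   the pseudo-inverse step has no component along the ridge, making the
#'   fitted coordinates the minimum-movement representative relative to the
#'   starting point.  This is the optimizer the Monte Carlo harness uses.
#'
#' The covariance matrix is the pseudo-inverse of the observed information
#' (negative finite-difference Hessian in the original parameterization).
#' The information matrix of this family is singular by construction, so
#' `singular_info` is reported alongside; Wald intervals are
#' `est +/- z * SE` from the retained eigenspace.
#'
#' @param x observations: a numeric vector (complete sample) or a
#'   [tgl_censored()] object.
#' @param n_total total units on test when `x` is a plain vector from a
#'   Type-II censored experiment.
#' @param variant censored likelihood variant, see [tgl_loglik_typeII()].
#' @param method `"multistart"` or `"scoring"`.
#' @param start optional [tgl_params()] (or 5-vector) used as the first
#'   start (multistart) or the anchor point (scoring).
#' @param n_starts number of multistart launches (ignored by scoring).
#' @param alpha Wald interval level is `1 - alpha`.
#' @param seed integer seed for the perturbation starts; `NULL` uses the
#'   current RNG state.
#' @return An object of class `"tgl_fit"`: a list with `params` (a
#'   [tgl_params()]), `estimates` (named 5-vector), `loglik`, `cov`, `se`,
#'   `acis` (data frame of Wald intervals), `converged`, `grad_norm`,
#'   `n_starts_used`, `singular_info`, `beta_boundary`, `variant`,
#'   `sample`, and `alpha`.
#' @examples
#' set.seed(1)
#' x <- rtgl(200, tgl_params(0.5, 0.6, 0.5, 0.3, 0.3))
#' fit <- tgl_fit(x, n_starts = 4, seed = 1)
#' fit$estimates
#' @export
tgl_fit <- function(x, n_total = NULL,
                    variant = c("canonical", "paper_literal"),
                    method = c("multistart", "scoring"),
                    start = NULL, n_starts = 10L, alpha = 0.05,
                    seed = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  sample <- as_tgl_sample(x, n_total)
  if (sample$k < 6L)
    stop("need at least 6 observed values to fit five parameters")
  if (length(unique(sample$values)) == 1L)
    stop("degenerate sample: all observed values are identical")

  if (method == "scoring") {
    if (is.null(start))
      stop("method = \"scoring\" needs an explicit 'start' anchor")
    th0 <- tgl_to_theta(start)
    best <- scoring_optim(th0, sample, variant)
    n_used <- 1L
  } else {
    starts <- tgl_start_set(sample, n_starts, seed, variant)
    if (!is.null(start)) starts <- c(list(unname(tgl_par_vec(start))), starts)
    best <- NULL
    n_used <- 0L
    for (s in starts) {
      th0 <- tryCatch(tgl_to_theta(s), error = function(e) NULL)
      if (is.null(th0)) next
      o <- tryCatch(
        stats::nlminb(th0, tgl_nll_theta, sample = sample, variant = variant,
                      control = list(iter.max = 2000L, rel.tol = 1e-10)),
        error = function(e) NULL)
      if (is.null(o) || !is.finite(o$objective)) next
      n_used <- n_used + 1L
      g <- fd_gradient(tgl_nll_theta, o$par, sample = sample,
                       variant = variant)
      cand <- list(par = o$par, objective = o$objective,
                   grad_norm = sqrt(sum(g^2)),
                   converged = o$convergence == 0L || o$objective < 1e9)
      if (is.null(best) || cand$objective < best$objective) best <- cand
    }
    if (is.null(best)) stop("all optimization starts failed")
  }

  est <- tgl_from_theta(best$par)
  est[5] <- min(max(est[5], -1 + BETA_EPS), 1 - BETA_EPS)
  names(est) <- c("delta", "gamma", "vartheta", "pi", "beta")
  params <- tgl_params(est[1], est[2], est[3], est[4], est[5])
  loglik <- -tgl_nll_raw(est, sample, variant)

  info <- tgl_observed_info(sample, params, variant = variant)
  P <- pinv_sym(info)
  se <- sqrt(pmax(diag(P$cov), 0))
  names(se) <- names(est)

  fit <- structure(list(
    params = params, estimates = est, loglik = loglik,
    cov = P$cov, se = se, converged = isTRUE(best$converged),
    grad_norm = best$grad_norm, n_starts_used = n_used,
    singular_info = P$dropped > 0L,
    beta_boundary = abs(est[5]) >= 1 - 10 * BETA_EPS,
    variant = variant, sample = sample, alpha = alpha, method = method
  ), class = "tgl_fit")
  fit$acis <- tgl_aci(fit, alpha)
  fit
}

#' Observed information matrix of a TGL fit
#'
#' The negative Hessian of the (complete or censored) log-likelihood with
#' respect to the original parameters `(delta, gamma, vartheta, pi, beta)`,
#' by central finite differences with per-coordinate step
#' `h = max(1e-5, 1e-4 |theta|)` (the `beta` step is shrunk near the
#' `|beta| = 1` boundary so probes stay inside the domain).
#'
#' @param sample a [tgl_censored()] object or numeric vector.
#' @param params a [tgl_params()] object (normally the MLE).
#' @param variant censored likelihood variant.
#' @return A symmetric 5x5 matrix.  For this family one eigenvalue is zero
#'   up to finite-difference noise (the flat reparameterization ridge).
#' @export
tgl_observed_info <- function(sample, params,
                              variant = c("canonical", "paper_literal")) {
  variant <- match.arg(variant)
  sample <- as_tgl_sample(sample)
  p <- unname(tgl_par_vec(params))
  h <- pmax(1e-5, 1e-4 * abs(p))
  h[5] <- min(h[5], max((1 - abs(p[5])) / 2, 1e-8))
  H <- fd_hessian(tgl_nll_raw, p, sample = sample, variant = variant, h = h)
  dimnames(H) <- rep(list(c("delta", "gamma", "vartheta", "pi", "beta")), 2)
  H   # negative Hessian of the log-likelihood = Hessian of the nll
}

#' Wald (asymptotic-normal) confidence intervals from a TGL fit
#'
#' `est +/- z_{1-alpha/2} * SE` with standard errors from the diagonal of
#' the pseudo-inverse observed information.
#'
#' @param fit a [tgl_fit()] object.
#' @param alpha one minus the confidence level.
#' @return A data frame with columns `parameter`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
tgl_aci <- function(fit, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se),
             lower = unname(fit$estimates - z * fit$se),
             upper = unname(fit$estimates + z * fit$se),
             row.names = NULL)
}

#' @export
print.tgl_fit <- function(x, ...) {
  cat(sprintf("TGL maximum-likelihood fit (%s, %s)\n", x$method, x$variant))
  cat(sprintf("  n = %d, k = %d, log-likelihood = %.4f\n",
              x$sample$n, x$sample$k, x$loglik))
  print(x$acis, digits = 5)
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$singular_info)
    cat("  note: observed information singular (flat ridge); SEs use the\n",
        "        pseudo-inverse and intervals are approximate\n", sep = "")
  if (x$beta_boundary)
    cat("  note: beta estimate at the boundary; its interval is unreliable\n")
  invisible(x)
}
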