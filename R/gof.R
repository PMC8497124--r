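#' Goodness-of-fit statistics for a fitted TGL (or any) distribution
#'
#' With `u_(i) = F(x_(i))` the fitted distribution function at the sorted
#' data, computes
#' \itemize{
#'   \item Kolmogorov-Smirnov:
#'     \eqn{KS = \max_i \max(i/n - u_{(i)},\, u_{(i)} - (i-1)/n)}, with an
#'     asymptotic p-value from the Kolmogorov series at \eqn{\sqrt{n}\,KS};
#'   \item Cramer-von Mises:
#'     \eqn{W^* = 1/(12n) + \sum_i (u_{(i)} - (2i-1)/(2n))^2};
#'   \item Anderson-Darling:
#'     \eqn{A^* = -n - \frac{1}{n}\sum_i (2i-1)[\log u_{(i)} +
#'       \log(1-u_{(n+1-i)})]}.
#' }
#' Fitted probabilities equal to 0 or 1 are clipped away from the boundary
#' (with a warning) so the log terms stay finite.
#'
#' @param x numeric sample (any order; sorted internally).
#' @param params a [tgl_params()] object, or a function `F(x)` returning
#'   fitted probabilities (so externally supplied models plug in).
#' @return An object of class `"tgl_gof"`: list with `ks`, `ks_pvalue`,
#'   `w_star`, `a_star`, `n`.
#' @examples
#' fr <- tgl_covid_data("france")
#' tgl_gof(fr$values, tgl_published_fit("france"))
#' @export
tgl_gof <- function(x, params) {
  if (length(x) < 1L) stop("'x' must be nonempty")
  x <- sort(x)
  n <- length(x)
  Fx <- if (is.function(params)) params else function(q) ptgl(q, params)
  u <- Fx(x)
  if (any(u <= 0 | u >= 1)) {
    warning("fitted probabilities at the data boundary were clipped")
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  w_star <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  a_star <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  structure(list(ks = ks, ks_pvalue = kolmogorov_pvalue(sqrt(n) * ks),
                 w_star = w_star, a_star = a_star, n = n),
            class = "tgl_gof")
}

# asymptotic Kolmogorov tail probability P(K > lambda)
kolmogorov_pvalue <- function(lambda, terms = 100L) {
  if (lambda <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.tgl_gof <- function(x, ...) {
  cat(sprintf("n = %d  KS = %.4f (p = %.4f)  W* = %.4f  A* = %.4f\n",
              x$n, x$ks, x$ks_pvalue, x$w_star, x$a_star))
  invisible(x)
}

#' Ranked goodness-of-fit comparison of candidate models
#'
#' Fits each candidate to the sample by its own maximum likelihood and ranks
#' the models by their Kolmogorov-Smirnov statistic.  Native models are
#' `"tgl"` (the full five-parameter family) and `"golom"` (the `beta = 0`
#' Gompertz Lomax submodel, fitted with the transmutation weight pinned at
#' zero).  Externally fitted competitors plug in as a named list entry
#' holding a fitted cdf, `function(q) -> probability`.
#'
#' @param x numeric sample.
#' @param models character vector among `"tgl"`, `"golom"`, and/or a named
#'   list mixing those strings with fitted cdf functions.
#' @param n_starts,seed forwarded to [tgl_fit()] for the native fits.
#' @return A data frame ranked by `ks`, with columns `model`, `ks`,
#'   `ks_pvalue`, `w_star`, `a_star`, and `loglik` (`NA` for plug-in cdfs);
#'   failed fits are recorded with `NA` statistics and excluded from the
#'   ranking order.
#' @export
tgl_compare <- function(x, models = c("tgl", "golom"), n_starts = 10L,
                        seed = 1L) {
  if (!is.list(models)) {
    models <- stats::setNames(as.list(models), models)
  }
  if (is.null(names(models)) || any(names(models) == ""))
    stop("every model must be named")
  rows <- lapply(names(models), function(nm) {
    spec <- models[[nm]]
    out <- data.frame(model = nm, ks = NA_real_, ks_pvalue = NA_real_,
                      w_star = NA_real_, a_star = NA_real_,
                      loglik = NA_real_)
    g <- tryCatch({
      if (is.function(spec)) {
        list(gof = tgl_gof(x, spec), loglik = NA_real_)
      } else if (identical(spec, "tgl")) {
        fit <- tgl_fit(x, n_starts = n_starts, seed = seed)
        list(gof = tgl_gof(x, fit$params), loglik = fit$loglik)
      } else if (identical(spec, "golom")) {
        fit <- golom_fit(x)
        list(gof = tgl_gof(x, fit$params), loglik = fit$loglik)
      } else stop("unknown model spec: ", nm)
    }, error = function(e) NULL)
    if (!is.null(g)) {
      out$ks <- g$gof$ks; out$ks_pvalue <- g$gof$ks_pvalue
      out$w_star <- g$gof$w_star; out$a_star <- g$gof$a_star
      out$loglik <- g$loglik
    }
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(is.na(res$ks), res$ks), , drop = FALSE]
  res$rank <- ifelse(is.na(res$ks), NA_integer_, seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

# beta = 0 (GoLom) constrained maximum-likelihood fit
golom_fit <- function(x) {
  s <- as_tgl_sample(x)
  obj <- function(th4) tgl_nll_raw(c(exp(th4), 0), s, "canonical")
  starts <- list(c(0, log(1 / mean(s$values)), 0, 0),
                 c(log(2), log(1 / stats::median(s$values)), log(0.5), 0),
                 c(log(0.5), log(1 / mean(s$values)), log(2), log(2)))
  best <- NULL
  for (th0 in starts) {
    o <- tryCatch(stats::nlminb(th0, obj,
                                control = list(iter.max = 1000L,
                                               rel.tol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("GoLom fit failed")
  p <- exp(best$par)
  list(params = tgl_params(p[1], p[2], p[3], p[4], 0),
       loglik = -best$objective)
}

#' Probability-probability plot coordinates
#'
#' Pairs the plotting positions `(i - 1/2)/n` with the fitted probabilities
#' `u_(i)` at the sorted sample, for PP-plot diagnostics of a fitted model.
#'
#' @inheritParams tgl_gof
#' @return A data frame with columns `empirical` and `fitted`, one row per
#'   observation.
#' @export
tgl_pp_points <- function(x, params) {
  if (length(x) < 1L) stop("'x' must be nonempty")
  x <- sort(x)
  n <- length(x)
  Fx <- if (is.function(params)) params else function(q) ptgl(q, params)
  data.frame(empirical = (seq_len(n) - 0.5) / n, fitted = Fx(x))
}
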