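#' Parameter vector of the transmuted generalized Lomax distribution
#'
#' Constructs and validates the five-parameter vector of the TGL family.
#' `delta` and `gamma` are the shape and scale-rate of the Lomax baseline,
#' `vartheta` and `pi` the rate and shape of the Gompertz generator, and
#' `beta` the transmutation weight.  The density is nonnegative for every
#' `x >= 0` exactly when `beta` lies in `[-1, 1]`, which is therefore the
#' admissible transmutation range.
#'
#' Note that the family is over-parameterized: the distribution depends on
#' the five parameters only through the four identifiable combinations
#' `a = delta * pi`, `b = vartheta / pi`, `gamma` and `beta`, so
#' `(delta, vartheta, pi)` and `(t * delta, vartheta / t, pi / t)` describe
#' the same distribution for any `t > 0`.  See the package vignette for the
#' inferential consequences.
#'
#' @param delta Lomax shape, `> 0`.
#' @param gamma Lomax scale rate per unit of `x`, `> 0`.
#' @param vartheta Gompertz rate, `> 0`.
#' @param pi Gompertz shape, `> 0`.
#' @param beta transmutation weight in `[-1, 1]` (dimensionless);
#'   `beta = 0` recovers the Gompertz Lomax (GoLom) submodel.
#'
#' @return An object of class `"tgl_params"`: a named list with the five
#'   validated components.
#' @examples
#' p <- tgl_params(delta = 0.5, gamma = 0.6, vartheta = 0.5, pi = 0.3, beta = 0.3)
#' p
#' @export
tgl_params <- function(delta, gamma, vartheta, pi, beta) {
  p <- list(delta = delta, gamma = gamma, vartheta = vartheta,
            pi = pi, beta = beta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("delta", "gamma", "vartheta", "pi"))
    if (p[[nm]] <= 0)
      stop("'", nm, "' must be strictly positive (got ", p[[nm]], ")",
           call. = FALSE)
  if (beta < -1 || beta > 1)
    stop("'beta' must lie in [-1, 1] (got ", beta,
         "); outside this range the density goes negative near x = 0",
         call. = FALSE)
  structure(p, class = "tgl_params")
}

#' @export
print.tgl_params <- function(x, ...) {
  cat("TGL parameters:\n")
  print(unlist(x[c("delta", "gamma", "vartheta", "pi", "beta")]))
  cat(sprintf("identifiable combinations: a = delta*pi = %.6g, b = vartheta/pi = %.6g\n",
              x$delta * x$pi, x$vartheta / x$pi))
  invisible(x)
}

# coerce a length-5 vector (delta, gamma, vartheta, pi, beta) or a
# tgl_params object, validating either way
as_tgl_params <- function(p) {
  if (inherits(p, "tgl_params")) {
    return(tgl_params(p$delta, p$gamma, p$vartheta, p$pi, p$beta))
  }
  if (is.numeric(p) && length(p) == 5L) {
    nm <- names(p)
    if (!is.null(nm) && all(c("delta", "gamma", "vartheta", "pi", "beta") %in% nm))
      return(tgl_params(p[["delta"]], p[["gamma"]], p[["vartheta"]],
                        p[["pi"]], p[["beta"]]))
    return(tgl_params(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]]))
  }
  stop("expected a 'tgl_params' object or a numeric vector of length 5",
       call. = FALSE)
}

# named parameter vector in canonical order
tgl_par_vec <- function(p) {
  p <- as_tgl_params(p)
  c(delta = p$delta, gamma = p$gamma, vartheta = p$vartheta,
    pi = p$pi, beta = p$beta)
}

#' Per-observation link transforms of the TGL family
#'
#' Every TGL formula is written in terms of the two monotone transforms
#' `psi(x) = 1 - (1 + gamma*x)^(delta*pi)` (nonpositive, decreasing) and
#' `w(x) = exp((vartheta/pi) * psi(x))` (in `(0, 1]`, decreasing).  Both are
#' computed in log space, `psi = -expm1(delta*pi*log1p(gamma*x))`, so that
#' large `gamma*x` does not overflow.
#'
#' @param x nonnegative numeric vector.
#' @param params a [tgl_params()] object.
#' @return A list with numeric components `psi` and `w`, each the length of
#'   `x`.
#' @examples
#' tgl_link(c(0, 1, 10), tgl_params(0.5, 0.6, 0.5, 0.3, 0.3))
#' @export
tgl_link <- function(x, params) {
  params <- as_tgl_params(params)
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  a <- params$delta * params$pi
  b <- params$vartheta / params$pi
  psi <- -expm1(a * log1p(params$gamma * x))
  w <- pmin(exp(b * psi), 1)
  # clip against hard underflow so that log(w)-based formulas stay finite
  w <- pmax(w, 1e-300)
  list(psi = psi, w = w)
}
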