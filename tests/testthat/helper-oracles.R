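# Independent reference implementations used as oracles.  These are written
# directly from the published closed forms, deliberately NOT sharing code
# with the package internals.

# Gompertz Lomax cdf/pdf (the beta = 0 baseline), plain-power form
golom_cdf_oracle <- function(x, delta, gamma, vartheta, pi_s) {
  1 - exp((vartheta / pi_s) * (1 - (1 + gamma * x)^(delta * pi_s)))
}
golom_pdf_oracle <- function(x, delta, gamma, vartheta, pi_s) {
  vartheta * delta * gamma * (1 + gamma * x)^(delta * pi_s - 1) *
    exp((vartheta / pi_s) * (1 - (1 + gamma * x)^(delta * pi_s)))
}

# transmuted map applied to an arbitrary baseline cdf
transmute_cdf_oracle <- function(G, beta) G * (1 + beta - beta * G)

# quantile by bisection on the cdf (independent of the closed-form root)
quantile_bisect <- function(q, params, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (ptgl(hi, params) < q) hi <- hi * 2
  while (hi - lo > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (ptgl(mid, params) < q) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# the four reference simulation cases
case_list <- function() lapply(1:4, tgl_case_params)
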