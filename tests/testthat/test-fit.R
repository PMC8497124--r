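test_that("complete log-likelihood is the sum of log densities and matches its expansion", {
  p <- tgl_case_params(1)
  set.seed(51)
  x <- rtgl(40, p)
  expect_equal(tgl_loglik(x[1], p), dtgl(x[1], p, log = TRUE))
  # printed expansion: n log(th d g) + (dp-1) sum log(1+gx) + (th/pi) sum psi
  #                    + sum log(1 - b + 2 b w)
  l <- tgl_link(x, p)
  expansion <- length(x) * log(p$vartheta * p$delta * p$gamma) +
    (p$delta * p$pi - 1) * sum(log1p(p$gamma * x)) +
    (p$vartheta / p$pi) * sum(l$psi) +
    sum(log(1 - p$beta + 2 * p$beta * l$w))
  expect_equal(tgl_loglik(x, p), expansion, tolerance = 1e-10)
})

test_that("Type-II likelihood reduces to the complete one at k = n and variants differ otherwise", {
  p <- tgl_case_params(2)
  set.seed(52)
  x <- sort(rtgl(30, p))
  full <- tgl_censored(x, 30)
  expect_equal(tgl_loglik_typeII(full, p, "canonical"), tgl_loglik(x, p),
               tolerance = 1e-10)
  expect_equal(tgl_loglik_typeII(full, p, "paper_literal"), tgl_loglik(x, p),
               tolerance = 1e-10)
  cens <- tgl_censored(x[1:20], 30)
  can <- tgl_loglik_typeII(cens, p, "canonical")
  lit <- tgl_loglik_typeII(cens, p, "paper_literal")
  expect_false(isTRUE(all.equal(can, lit)))
  # canonical form written out directly
  direct <- sum(dtgl(x[1:20], p, log = TRUE)) + 10 * log(stgl(x[20], p))
  expect_equal(can, direct, tolerance = 1e-10)
})

test_that("analytic score matches central finite differences", {
  set.seed(53)
  for (i in 1:20) {
    p <- tgl_params(runif(1, 0.2, 2), runif(1, 0.2, 2), runif(1, 0.2, 2),
                    runif(1, 0.2, 2), runif(1, -0.9, 0.9))
    x <- rtgl(25, p)
    s <- tgl_score(x, p)
    pv <- c(p$delta, p$gamma, p$vartheta, p$pi, p$beta)
    fd <- vapply(1:5, function(j) {
      h <- 1e-6 * max(abs(pv[j]), 1)
      up <- pv; dn <- pv
      up[j] <- up[j] + h; dn[j] <- dn[j] - h
      (tgl_loglik(x, tgl_params(up[1], up[2], up[3], up[4], up[5])) -
         tgl_loglik(x, tgl_params(dn[1], dn[2], dn[3], dn[4], dn[5]))) / (2 * h)
    }, numeric(1))
    expect_equal(unname(s), fd, tolerance = 1e-5)
  }
})

test_that("the beta score component collapses to sum(2w - 1) at beta = 0", {
  p0 <- tgl_case_params(1)
  p <- tgl_params(p0$delta, p0$gamma, p0$vartheta, p0$pi, 0)
  set.seed(54)
  x <- rtgl(30, p)
  expect_equal(unname(tgl_score(x, p)["beta"]),
               sum(2 * tgl_link(x, p)$w - 1), tolerance = 1e-12)
})

test_that("the score vanishes at an interior maximum-likelihood estimate", {
  p <- tgl_case_params(1)
  set.seed(55)
  x <- rtgl(300, p)
  fit <- tgl_fit(x, method = "scoring", start = p)
  s <- tgl_score(x, fit$params)
  # gradient on the log/atanh working scale (scale-free comparison)
  est <- fit$estimates
  work <- c(s[1:4] * est[1:4], s[5] * (1 - est[5]^2))
  expect_lt(max(abs(work)), 0.02)
})

test_that("identifiable parameter combinations are recovered in large samples", {
  # the family depends on (delta*pi, vartheta/pi, gamma, beta) only, so
  # recovery is asserted for those combinations rather than raw coordinates
  p <- tgl_case_params(1)
  set.seed(56)
  x <- rtgl(1000, p)
  fit <- tgl_fit(x, method = "scoring", start = p)
  expect_true(fit$converged)
  est <- fit$estimates
  a_hat <- est["delta"] * est["pi"]; a_true <- p$delta * p$pi
  b_hat <- est["vartheta"] / est["pi"]; b_true <- p$vartheta / p$pi
  expect_lt(abs(a_hat - a_true) / a_true, 0.25)
  expect_lt(abs(log(b_hat / b_true)), 0.6)
  expect_lt(abs(est["beta"] - p$beta), 0.6)
  # the fitted cdf is close to the truth where it matters
  qs <- qtgl(seq(0.1, 0.9, by = 0.1), p)
  expect_lt(max(abs(ptgl(qs, fit$params) - ptgl(qs, p))), 0.05)
})

test_that("multistart fitting attains at least the warm-start likelihood", {
  p <- tgl_case_params(1)
  set.seed(57)
  x <- rtgl(120, p)
  fit_ms <- tgl_fit(x, n_starts = 5, seed = 3)
  expect_gte(fit_ms$loglik, tgl_loglik(x, p) - 1e-6)
  fit_warm <- tgl_fit(x, method = "scoring", start = p)
  expect_gte(fit_ms$loglik + 1e-6, fit_warm$loglik - 0.5)
})

test_that("refitting data generated at fitted values reproduces the distribution", {
  p <- tgl_case_params(2)
  set.seed(58)
  x <- rtgl(400, p)
  fit1 <- tgl_fit(x, method = "scoring", start = p)
  set.seed(59)
  y <- rtgl(400, fit1$params)
  fit2 <- tgl_fit(y, method = "scoring", start = fit1$params)
  qs <- qtgl(seq(0.1, 0.9, by = 0.1), fit1$params)
  expect_lt(max(abs(ptgl(qs, fit2$params) - ptgl(qs, fit1$params))), 0.06)
})

test_that("observed information is singular along the flat ridge and ACIs are Wald", {
  p <- tgl_case_params(1)
  set.seed(60)
  x <- rtgl(150, p)
  fit <- tgl_fit(x, method = "scoring", start = p)
  # at the MLE the flat (delta, vartheta, pi) ridge shows up as a null
  # eigenvalue of the observed information (only there: at non-stationary
  # points the ridge tangent picks up gradient curvature)
  H <- tgl_observed_info(x, fit$params)
  expect_equal(H, t(H), tolerance = 1e-8)
  ev <- eigen(H, symmetric = TRUE)$values
  expect_lt(abs(ev[5]) / max(abs(ev)), 1e-3)
  expect_gt(ev[4] / max(abs(ev)), 1e-6)
  expect_true(fit$singular_info)
  ac <- tgl_aci(fit, alpha = 0.05)
  z <- qnorm(0.975)
  expect_equal(ac$upper - ac$lower, 2 * z * fit$se, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(ac$lower <= ac$estimate & ac$estimate <= ac$upper))
})

test_that("information scales linearly with the sample size", {
  p <- tgl_case_params(1)
  set.seed(61)
  x <- rtgl(2000, p)
  H_full <- tgl_observed_info(x, p)
  H_half <- tgl_observed_info(x[1:1000], p)
  # dominant curvature doubles, up to sampling noise
  r <- max(eigen(H_full, symmetric = TRUE)$values) /
    max(eigen(H_half, symmetric = TRUE)$values)
  expect_gt(r, 1.5); expect_lt(r, 2.6)
})

test_that("degenerate and undersized samples are refused", {
  expect_error(tgl_fit(rep(1, 20)), "degenerate")
  expect_error(tgl_fit(c(0.1, 0.2, 0.3)), "at least 6")
})
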