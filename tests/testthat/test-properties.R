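test_that("raw moments: order zero is one and quadrature matches Monte Carlo", {
  p <- tgl_case_params(1)
  expect_identical(tgl_moment(p, 0), 1)
  m1 <- tgl_moment(p, 1)
  set.seed(21)
  draws <- rtgl(1e6, p)
  mc <- mean(draws)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(m1 - mc), 3 * se)
})

test_that("beta = 0 moments match the same quadrature applied to the GoLom pdf", {
  p0 <- tgl_case_params(2)
  p <- tgl_params(p0$delta, p0$gamma, p0$vartheta, p0$pi, 0)
  direct <- integrate(function(x)
    x^2 * golom_pdf_oracle(x, p$delta, p$gamma, p$vartheta, p$pi),
    0, Inf, rel.tol = 1e-10)$value
  expect_equal(tgl_moment(p, 2), direct, tolerance = 1e-8)
})

test_that("series moments are exact when the binomial series terminates", {
  # delta * pi = 1 makes every inner exponent an integer: finite sum
  p <- tgl_params(delta = 2, gamma = 1.3, vartheta = 0.8, pi = 0.5,
                  beta = 0.4)
  for (r in 1:3) {
    s <- tgl_moment(p, r, method = "series")
    expect_true(attr(s, "converged"))
    expect_equal(as.numeric(s), tgl_moment(p, r), tolerance = 1e-7)
  }
})

test_that("a divergent series is reported, not silently returned", {
  p <- tgl_case_params(1)   # delta*pi = 0.15, fractional exponents
  expect_warning(tgl_moment(p, 2, method = "series"), "Cauchy")
})

test_that("variance is nonnegative across the reference cases", {
  for (p in case_list()) {
    m1 <- tgl_moment(p, 1); m2 <- tgl_moment(p, 2)
    expect_gte(m2 - m1^2, 0)
  }
})

test_that("incomplete moments grow to the full moment", {
  p <- tgl_case_params(2)
  expect_identical(tgl_incomplete_moment(p, 1, 0), 0)
  med <- qtgl(0.5, p)
  im <- tgl_incomplete_moment(p, 1, med)
  direct <- integrate(function(x) x * dtgl(x, p), 0, med,
                      rel.tol = 1e-11)$value
  expect_equal(im, direct, tolerance = 1e-9)
  expect_gt(tgl_incomplete_moment(p, 1, med * 2), im)
  expect_equal(tgl_incomplete_moment(p, 1, qtgl(1 - 1e-12, p)),
               tgl_moment(p, 1), tolerance = 1e-6)
})

test_that("beta = 1 closed-form median agrees with the generic quantile", {
  for (p0 in case_list()) {
    p <- tgl_params(p0$delta, p0$gamma, p0$vartheta, p0$pi, 1)
    m <- tgl_median_beta1(p)
    expect_equal(m, qtgl(0.5, p), tolerance = 1e-12)
    expect_equal(ptgl(m, p), 0.5, tolerance = 1e-12)
  }
  expect_error(tgl_median_beta1(tgl_case_params(1)), "beta = 1")
})

test_that("beta = 1 median reduces correctly under delta*pi = 1", {
  # with a = delta*pi = 1 and gamma = 1 the median is (pi/(2 vartheta)) log 2
  p <- tgl_params(delta = 4, gamma = 1, vartheta = 1, pi = 0.25, beta = 1)
  expect_equal(tgl_median_beta1(p), 0.25 * log(2) / 2, tolerance = 1e-12)
})

test_that("mode finder locates interior modes and flags J-shaped densities", {
  # delta*pi > 1 produces a hump: Case 4 has an interior mode
  p4 <- tgl_case_params(4)
  m <- tgl_mode(p4)
  expect_false(m$boundary)
  # the log-density derivative vanishes and changes sign there
  h <- 1e-6
  dl <- (dtgl(m$mode + h, p4, log = TRUE) -
           dtgl(m$mode - h, p4, log = TRUE)) / (2 * h)
  expect_lt(abs(dl), 1e-2)
  expect_gte(dtgl(m$mode, p4), dtgl(m$mode + 1e-4, p4))
  expect_gte(dtgl(m$mode, p4), dtgl(max(m$mode - 1e-4, 0), p4))
  # Cases 1 and 2 have decreasing densities: supremum at the origin
  for (cid in 1:2) {
    m0 <- tgl_mode(tgl_case_params(cid))
    expect_true(m0$boundary)
    expect_identical(m0$mode, 0)
  }
})

test_that("Renyi entropy brackets the differential entropy near order one", {
  p <- tgl_case_params(2)
  shannon <- -integrate(function(x) {
    fx <- dtgl(x, p)
    ifelse(fx > 0, fx * log(fx), 0)
  }, 0, Inf, rel.tol = 1e-10)$value
  lo <- tgl_renyi_entropy(p, 1.001)
  hi <- tgl_renyi_entropy(p, 0.999)
  expect_lt(lo, shannon + 1e-2)
  expect_gt(hi, shannon - 1e-2)
  expect_lt(abs((lo + hi) / 2 - shannon), 1e-3)
  expect_error(tgl_renyi_entropy(p, 1), "psi_order")
  expect_error(tgl_renyi_entropy(p, -2), "psi_order")
})

test_that("Renyi order 2 matches a Monte Carlo estimate of E[f(X)]", {
  p <- tgl_case_params(1)
  set.seed(31)
  draws <- rtgl(1e6, p)
  fd <- dtgl(draws, p)
  mc <- -log(mean(fd))
  se_log <- sd(fd) / sqrt(length(fd)) / mean(fd)
  expect_lt(abs(tgl_renyi_entropy(p, 2) - mc), 3 * se_log)
})

test_that("beta = 0 entropy equals the functional on the GoLom density", {
  p0 <- tgl_case_params(3)
  p <- tgl_params(p0$delta, p0$gamma, p0$vartheta, p0$pi, 0)
  direct <- -log(integrate(function(x)
    golom_pdf_oracle(x, p$delta, p$gamma, p$vartheta, p$pi)^2,
    0, Inf, rel.tol = 1e-10)$value)
  expect_equal(tgl_renyi_entropy(p, 2), direct, tolerance = 1e-7)
})

test_that("order-statistic densities normalize and collapse correctly", {
  p <- tgl_case_params(1)
  expect_equal(tgl_order_stat_pdf(c(0.4, 2), p, n = 1, r = 1),
               dtgl(c(0.4, 2), p), tolerance = 1e-12)
  val <- integrate(function(x) tgl_order_stat_pdf(x, p, n = 5, r = 3),
                   0, Inf, rel.tol = 1e-9)$value
  expect_equal(val, 1, tolerance = 1e-7)
  # minimum of n has the closed collapse n f (1-F)^(n-1)
  xs <- qtgl(seq(0.05, 0.95, length.out = 20), p)
  expect_equal(tgl_order_stat_pdf(xs, p, n = 7, r = 1),
               7 * dtgl(xs, p) * stgl(xs, p)^6, tolerance = 1e-10)
  expect_error(tgl_order_stat_pdf(1, p, n = 3, r = 4), "r <= n")
})

test_that("order-statistic moments match simulation and increase with rank", {
  p <- tgl_case_params(1)
  expect_equal(tgl_order_stat_moment(p, 1, 1, 1), tgl_moment(p, 1),
               tolerance = 1e-7)
  set.seed(41)
  mins <- matrix(rtgl(5 * 1e5, p), ncol = 5)
  mn <- apply(mins, 1, min)
  mc <- mean(mn); se <- sd(mn) / sqrt(length(mn))
  expect_lt(abs(tgl_order_stat_moment(p, 5, 1, 1) - mc), 3 * se)
  means <- vapply(1:5, function(r) tgl_order_stat_moment(p, 5, r, 1),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("averaging order-statistic densities over ranks recovers the marginal", {
  p <- tgl_case_params(3)
  xs <- qtgl(c(0.1, 0.35, 0.6, 0.85), p)
  avg <- Reduce(`+`, lapply(1:4, function(r)
    tgl_order_stat_pdf(xs, p, n = 4, r = r))) / 4
  expect_equal(avg, dtgl(xs, p), tolerance = 1e-10)
})
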