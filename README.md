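# tglomax

Inference for the five-parameter **transmuted generalized Lomax (TGL)**
lifetime distribution — a heavy-tailed model for nonnegative rate data such
as daily epidemic mortality-rate series — for survival/reliability
analysts and epidemiological modelers who need the full pipeline around
this family: simulation, maximum likelihood under complete and Type-II
censored sampling, confidence intervals, and goodness-of-fit comparison.

## The model

Starting from the Lomax (Pareto II) baseline with shape δ and rate γ, the
Gompertz generator (rate ϑ, shape π) produces the Gompertz Lomax cdf
*G*(x) = 1 − exp[(ϑ/π)(1 − (1+γx)^{δπ})], and the quadratic transmutation
map with weight β ∈ [−1, 1] yields

    F(x) = G(x) [1 + β − β G(x)] = (1 − w)(1 + βw),
    w(x) = exp[(ϑ/π)(1 − (1+γx)^{δπ})],

with density f(x) = δϑγ (1+γx)^{δπ−1} w (1 − β + 2βw) on x ≥ 0.
β = 0 recovers Gompertz Lomax.  The family is over-parameterized — only
(δπ, ϑ/π, γ, β) are identifiable — which has real inferential
consequences (singular information, optimizer-dependent coordinates); the
package handles this explicitly via pseudo-inverse covariances and a
minimum-norm scoring optimizer, and the methods vignette
(`vignettes/tgl-methods.Rmd`) explains the details.

The package provides:

* `dtgl` / `ptgl` / `qtgl` / `rtgl` / `stgl` / `htgl` — distribution
  primitives with closed-form quantile inversion;
* `tgl_moment`, `tgl_incomplete_moment`, `tgl_mode`, `tgl_median_beta1`,
  `tgl_renyi_entropy`, `tgl_order_stat_pdf`, `tgl_order_stat_moment` —
  structural properties by adaptive quadrature (series forms as
  diagnostics);
* `tgl_fit`, `tgl_score`, `tgl_observed_info`, `tgl_aci` — maximum
  likelihood for complete and Type-II censored samples
  (`tgl_censored`), with Wald intervals;
* `tgl_boot` — percentile and studentized parametric bootstrap intervals;
* `tgl_sim_cell`, `tgl_sim_table` — a reproducible Monte Carlo harness
  (bias, MSE, interval lengths, coverage);
* `tgl_gof`, `tgl_compare`, `tgl_pp_points` — Kolmogorov–Smirnov,
  Cramér–von Mises and Anderson–Darling statistics and ranked model
  comparison;
* `tgl_covid_data`, `tgl_published_fit`, `tgl_build_series` — two embedded
  daily COVID-19 mortality-rate series (France, 108 days; United Kingdom,
  82 days) with the published TGL estimates for each.

A thin command-line front end ships in `exec/tgl`
(`tgl fit data.csv`, `tgl gof data.csv --params fit.json`,
`tgl simulate --case 1 --n 100 ...`).

## Worked example

```r
library(tglomax)

fr <- tgl_covid_data("france")
#> COVID-19 mortality-rate series 'france': 108 daily values, 2021-03-01 to 2021-06-16

tgl_gof(fr$values, tgl_published_fit("france"))
#> n = 108  KS = 0.0657 (p = 0.7404)  W* = 0.0820  A* = 0.5007

tgl_compare(fr$values, c("tgl", "golom"), seed = 1)
#>   model      ks ks_pvalue  w_star a_star loglik rank
#> 1   tgl 0.06556    0.7421 0.08185 0.4999  232.5    1
#> 2 golom 0.07084    0.6504 0.09836 0.6456  231.6    2
```

The KS distance of 0.0657 (p = 0.74) says the fitted TGL cdf never strays
more than about 6.6 percentage points from the empirical cdf of the 108
French daily rates — a fit the sample cannot reject — and the comparison
ranks the five-parameter TGL ahead of its β = 0 Gompertz Lomax submodel on
all three statistics.

Fitting simulated data:

```r
set.seed(1)
x <- rtgl(200, tgl_case_params(1))
tgl_fit(x, method = "scoring", start = tgl_params(1, 1/mean(x), 1, 1, 0))
#> TGL maximum-likelihood fit (scoring, canonical)
#>   n = 200, k = 200, log-likelihood = -957.4910
#>   parameter estimate       se    lower    upper
#> 1     delta  0.33582 0.084882  0.16945  0.50218
#> 2     gamma  1.37341 1.155320 -0.89098  3.63779
#> 3  vartheta  1.07830 0.095071  0.89197  1.26464
#> 4        pi  0.31144 0.240892 -0.16070  0.78358
#> 5      beta -0.88582 0.206856 -1.29125 -0.48039
#>   note: observed information singular (flat ridge); SEs use the
#>         pseudo-inverse and intervals are approximate
```

The singular-information note is expected — it is a structural property of
this family, not a numerical accident (see the vignette).

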