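---
title: "The transmuted generalized Lomax model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The transmuted generalized Lomax model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tglomax)
```

## The model

The transmuted generalized Lomax (TGL) distribution is built in two steps
from the Lomax (Pareto type II) baseline with shape $\delta$ and scale rate
$\gamma$.  First the Gompertz generator with rate $\vartheta$ and shape
$\pi$ maps the Lomax cdf into the Gompertz Lomax (GoLom) family,

$$G(x) = 1 - e^{(\vartheta/\pi)\,\psi(x)}, \qquad
  \psi(x) = 1 - (1+\gamma x)^{\delta\pi},$$

and then the quadratic transmutation map with weight $\beta \in [-1, 1]$
bends it further:

$$F(x) = G(x)\,[1 + \beta - \beta\,G(x)]
       = (1 - w)(1 + \beta w), \qquad
  w(x) = e^{(\vartheta/\pi)\,\psi(x)}.$$

The density is
$f(x) = \delta\vartheta\gamma\,(1+\gamma x)^{\delta\pi-1}\,w\,(1-\beta+2\beta w)$,
nonnegative on $[0,\infty)$ exactly when $|\beta| \le 1$, which is why the
package enforces that range.  At the origin $f(0) = \delta\vartheta\gamma(1+\beta)$,
generally nonzero; the density is J-shaped (supremum at 0) whenever
$\delta\pi \le 1$ and humped otherwise, and the hazard
$f/(1-F) \propto (1+\gamma x)^{\delta\pi - 1}$ in the far tail, so it
*decays* for $\delta\pi < 1$ and grows without bound for $\delta\pi > 1$.
The survival function is implemented as $1 - F = w(1-\beta+\beta w)$, the
algebraic complement of the cdf, and the hazard through its closed-form
ratio, which stays well defined far beyond the point where $f$ and $1-F$
individually underflow.

Setting $\beta = 0$ recovers GoLom exactly, and every primitive reduces
accordingly; this is asserted in the test suite against an independently
coded GoLom implementation.  A claimed further reduction of this family to
the plain Lomax at $(\vartheta, \pi, \beta) = (1, 1, 0)$ does not hold
algebraically and is not asserted.

## A flat ridge: the five parameters are not identifiable

The distribution depends on $(\delta, \gamma, \vartheta, \pi, \beta)$ only
through the four combinations

$$a = \delta\pi, \qquad b = \vartheta/\pi, \qquad \gamma, \qquad \beta,$$

so $(\delta, \vartheta, \pi) \mapsto (t\delta, \vartheta/t, \pi/t)$ leaves
the model invariant for every $t > 0$.  The likelihood surface therefore
carries an exactly flat one-dimensional ridge, the observed information
matrix is singular *at any maximum*, and per-coordinate point estimates are
only defined relative to how an optimizer resolves the ridge.  This single
fact drives most of the package's design decisions:

* **Covariance.** Standard errors come from the Moore–Penrose
  pseudo-inverse of the finite-difference observed information (eigenvalues
  below $10^{-7}$ of the dominant one are dropped); fits flag
  `singular_info` so users know the Wald intervals live in the retained
  eigenspace.
* **Fitting.** `tgl_fit()` offers two optimizers.  The default
  `"multistart"` mode runs `nlminb` quasi-Newton from ten deterministic
  starts (a moment-flavored heuristic, a GoLom-constrained warm start with
  $\beta = 0$, and eight seeded perturbations) on a working scale (log for
  the positive parameters, $\tanh^{-1}$ for $\beta$), keeping the best
  objective; ties along the ridge are broken by first-found.  The
  `"scoring"` mode is a damped Newton iteration whose step uses the
  pseudo-inverse Hessian: the step has no component along the null
  direction, so the answer is the *minimum-movement* representative of the
  optimum relative to the supplied anchor.  Stopping rules: relative
  objective improvement below $10^{-10}$, step norm below $10^{-9}$, or 60
  iterations.
* **Monte Carlo summaries.** The simulation harness reports bias and mean
  squared error of the five raw coordinates, so those summaries are only
  meaningful under a fixed ridge resolution; the harness therefore
  warm-starts every replicate at the true parameter vector and fits by
  scoring.  A quasi-Newton optimizer free to wander the ridge produces
  arbitrary per-coordinate values at identical likelihoods.

## Estimation

The complete-sample log-likelihood is the sum of log densities; the
analytic score (`tgl_score()`) was re-derived from the log-density and is
verified against central finite differences in the tests — two printed
forms of these derivatives in circulation contain typos (a missing $2\beta$
factor in the $\vartheta$ component and a mis-scaled $\psi$ term in the
$\pi$ component), so the derivation, not any printed equation, is the
contract.

For Type-II censoring (observation stops at the $k$-th of $n$ ordered
failures) the canonical likelihood is

$$\ell_2 = \sum_{i=1}^{k}\log f(x_{(i)}) + (n-k)\log S(x_{(k)}),$$

the standard form in reliability theory.  An alternative algebra that
multiplies the *summed* log survival of all observed order statistics by
$(n-k)$ circulates in print for this family; it is available as
`variant = "paper_literal"` so that its numbers can be reproduced, but it is
not the default because it does not describe the Type-II sampling density.
Both coincide at $k = n$, which the tests assert to $10^{-10}$.

Wald intervals are $\hat\theta \pm z_{1-\alpha/2}\,\mathrm{SE}$.  $\beta$
estimates are pinned to $[-1+10^{-6},\, 1-10^{-6}]$ and boundary hits are
flagged, since Wald theory fails on the boundary.

## Bootstrap intervals

Both interval types are parametric: resamples are drawn from the fitted
model (for censored fits, $n$ variates drawn, sorted, first $k$ kept —
mirroring the data mechanism) and refit by scoring warm-started at the
original estimates.  Boot-P takes per-parameter order statistics of the
replicate estimates at the ceiling indices $\lceil B\gamma/2\rceil$ and
$\lceil B(1-\gamma/2)\rceil$; no interpolation is used, and the convention
is fixed and documented (for four replicates $\{1,2,3,4\}$ at level 50% it
yields $(1, 3)$).  Boot-t studentizes each replicate by its own
pseudo-inverse information SE.  Replicates whose refit fails are dropped
and counted; more than 20% failures raises an error.

## The Monte Carlo harness

`tgl_sim_cell()` reproduces one cell of the study design: four true
parameter cases

| case | $\delta$ | $\gamma$ | $\vartheta$ | $\pi$ | $\beta$ |
|------|------|------|------|------|------|
| 1 | 0.50 | 0.60 | 0.50 | 0.30 | 0.3 |
| 2 | 0.80 | 0.75 | 1.90 | 1.20 | 0.4 |
| 3 | 0.45 | 0.75 | 0.85 | 0.35 | −0.4 |
| 4 | 1.40 | 2.70 | 1.80 | 1.50 | −0.6 |

crossed with $n \in \{30, 50, 100\}$ and observed-failure counts
$k \in \{30,25,20\}$, $\{50,40,30\}$, $\{100,90,70\}$.  Replicate seeds
derive from the master seed by one `set.seed(seed)` call followed by
`sample.int`, so every cell is bit-reproducible.  Reported columns are
per-parameter bias, MSE, mean Wald/Boot-P/Boot-t interval lengths, and the
Wald coverage probability in percent.

Two replicate-screening rules apply, both counted and reported: fits that
error or fail convergence (more than 10% aborts the cell), and
*boundary-divergent* fits — replicates whose identifiable combinations
$(a, b, \gamma)$ end more than 7 nats (a factor $e^7 \approx 1100$) from
the truth anchor.  For such samples the likelihood supremum sits on the
boundary of the parameter space (typically $a \to 0$ or
$\gamma \to \infty$) and no interior MLE exists, so no meaningful
finite-parameter summary can include them.  At $n = 100$ under Case 1 they
are rare (well under 1%); at $n = 30$ a few percent.

Default replication is 1000 with bootstrap $B = 200$ inside cells
(`boot_B = 0` disables the bootstrap columns); the published study quotes
10000 iterations, which desk-scale runs trade away because the acceptance
comparisons are within Monte Carlo error, not digit-exact.  The test suite
uses 60–300 replicates per cell and the acceptance script 1000.

What the generator emulates — i.i.d. inverse-transform draws from the exact
model, truncated by Type-II censoring — is precisely the published design.
What it does not emulate: real mortality-rate series are serially dependent
and nonstationary, so passing simulation checks demonstrate correctness of
the estimator pipeline under the model, not fitness of the model for any
particular data set.

## Goodness of fit

With $u_{(i)} = F(x_{(i)})$ at the sorted sample, `tgl_gof()` computes the
Kolmogorov–Smirnov sup-distance with asymptotic p-value
$2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2 n D_n^2}$, the Cramér–von Mises statistic
$W^* = 1/(12n) + \sum_i (u_{(i)} - (2i-1)/(2n))^2$, and the
Anderson–Darling statistic
$A^* = -n - \tfrac1n\sum_i (2i-1)[\log u_{(i)} + \log(1-u_{(n+1-i)})]$.
The unmodified forms are used (no small-sample multipliers); fitted
probabilities that land exactly on 0 or 1 are clipped with a warning before
the logarithms.  `tgl_compare()` fits each candidate by its own MLE (the
$\beta = 0$ submodel via a constrained four-parameter fit) and ranks by KS;
externally fitted cdfs plug in as functions.

On the embedded France series the package reproduces the published TGL row
closely (KS 0.0657 vs 0.0660 printed; the published estimates are a genuine
stationary point of the likelihood).  On the UK series the published
estimates are *not* a stationary point and the likelihood improves without
bound along the ridge, so only the published KS reproduces from the printed
row; the printed $W^*$ and $A^*$ there cannot be recovered either at the
printed estimates or by refitting, and the package reports what it
computes.

## Structural properties

Quadrature is canonical for every property; series expansions are
diagnostics only.  The heavy tails here (for $\delta\pi = 0.15$, Case 1,
the *mean* is 541 and the second moment $1.7\times10^8$) defeat naive
$x$-space integration, so moments use the exact substitution
$y = (\vartheta/\pi)[(1+\gamma x)^{\delta\pi}-1]$, giving

$$\mu_r' = \gamma^{-r}\left[(1-\beta) I\!\left(\tfrac{\pi}{\vartheta}\right)
  + \beta I\!\left(\tfrac{\pi}{2\vartheta}\right)\right], \qquad
  I(c) = \int_0^\infty \left[(1+cy)^{1/(\delta\pi)} - 1\right]^r e^{-y}\,dy,$$

whose exponential weight tames the tail; other functionals integrate in
probability space via the quantile function.  The series form expands
$(1+cy)^{(r-i)/(\delta\pi)}$ binomially: it terminates (and is then exact,
which the tests exploit) when every exponent is a nonnegative integer, and
is otherwise a divergent asymptotic series — the implementation truncates
by a Cauchy criterion (three consecutive terms below $10^{-12}$ of the
partial sum, cap 200) and *warns* rather than silently returning.

Rényi entropy uses the standard sign convention
$I_R(\psi) = \log\!\int f^\psi / (1-\psi)$, under which $\psi \to 1$
recovers Shannon entropy (verified by bracketing at $\psi = 0.999, 1.001$);
a printed form with the opposite sign contradicts that limit.  The
quantile function inverts the transmutation quadratic in closed form, the
$\beta = 1$ median has its own closed form (checked to $10^{-12}$ against
the generic inversion), and the mode is located numerically — 512
log-spaced grid points between the $10^{-4}$ and $1-10^{-4}$ quantiles
followed by bracketed refinement, with a boundary flag for J-shaped cases.
A printed mode equation for this family contains an undefined symbol and
does not match $d\log f/dx = 0$; the numerical mode is canonical here.
Order-statistic moments use $X_{(r)} = Q(U_{(r)})$ with
$U_{(r)} \sim \mathrm{Beta}(r, n-r+1)$.

## Data

The two embedded series are daily COVID-19 mortality-rate proxies,
$x_i = \mathrm{ND}_i / (\mathrm{CC}_i - \mathrm{CD}_{i-1}) \times 1000$
(new deaths over cases not yet resolved by death, per mille): France,
108 days (2021-03-01 to 2021-06-16), and the United Kingdom, 82 days
(2021-05-01 to 2021-07-16).  Values are stored as printed decimal text with
four decimals and parsed on load, so checksums are platform-stable
(France sums to 5.2893, UK to 2.9286).  `tgl_build_series()` applies the
construction formula to raw count series, with the previous day's
cumulative deaths in the denominator and the day-zero value supplied by the
caller.  `tgl_published_fit()` returns the published TGL point estimates
for each series, read in the published column order
$(\pi, \beta, \delta, \gamma, \vartheta)$ — the alternative reading was
checked and produces nonsense (KS above 0.5).

## Numerical choices, in one place

* All powers of $1+\gamma x$ go through `exp(c * log1p(gamma*x))`; $w$ is
  clipped to $[10^{-300}, 1]$ so log-density terms stay finite.
* Quantile: the root of $\beta w^2 + (1-\beta)w - (1-q) = 0$ in $(0,1]$,
  with the $\beta \to 0$ branch taken below $|\beta| < 10^{-12}$.
* Negative arguments: cdf returns 0, survival 1, density 0 — convenient
  for goodness-of-fit plumbing — while the quantile function rejects
  probabilities outside $(0,1)$.
* Finite-difference Hessians use per-coordinate steps
  $h = \max(10^{-5}, 10^{-4}|\theta|)$, with the $\beta$ step shrunk near
  the boundary so probes stay inside the domain.
* Quadrature tolerances: $10^{-9}$–$10^{-10}$ relative, 1000 subdivisions.

## Known limitations

* Per-coordinate estimates, intervals and Monte Carlo summaries for
  $(\delta, \vartheta, \pi)$ are anchor-dependent because of the flat
  ridge; the identifiable objects are $(\delta\pi, \vartheta/\pi, \gamma,
  \beta)$ and any functional of the cdf.
* On some samples (small $n$, heavy censoring) the MLE does not exist in
  the interior; such fits are flagged (harness) or surface as runaway
  estimates (direct use).
* The Boot-t interval inherits the instability of replicate-level
  pseudo-inverse standard errors and can be very wide; Boot-P is the
  robust default.
* Competitor families from the published comparison tables (Weibull-Lomax
  and the various Marshall–Olkin alpha-power families) are out of scope;
  the plug-in cdf slot of `tgl_compare()` accepts externally fitted ones.
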