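---
title: "Methods: equivalence testing for goodness-of-fit of continuous distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivalence testing for goodness-of-fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqgof)
```

## Why equivalence, not lack-of-fit

A lack-of-fit test (Kolmogorov–Smirnov, chi-square) can only ever refute a
distributional model; failing to refute it proves nothing, because the type
II error of that failure is uncontrolled. When the scientific goal is to
*certify* a model — "these data are compatible with standard normality to
within a stated tolerance" — the logic must be inverted: the tolerance
region around the model becomes the alternative hypothesis, and rejecting
the complementary null establishes fit with the type I error capped at
`alpha`. That inversion is the entire content of this package; every
procedure in it rejects in favor of *fit*.

## The Lehmann indifference zone

Deviations from the hypothesized cdf $F_0$ are modeled as Lehmann
alternatives $F = F_0^\theta$, $\theta > 0$ — the cdf-scale sibling of the
proportional-hazards model, with $\log\theta$ playing the role of the
log-hazard-ratio. Within this family the Kolmogorov distance has the closed
form (implemented in `sup_distance()`)
$$\|F_0^\theta - F_0\| = \bigl|\theta^{1/(1-\theta)} -
\theta^{\theta/(1-\theta)}\bigr|,$$
which is continuous at $\theta = 1$ with value $0$ (numerically, the
first-order expansion $e^{-1}|\theta-1|$ is used for
$|\theta - 1| < 10^{-8}$). Consequently "‖F − F₀‖ < δ" and
"$1/(1+\varepsilon) < \theta < 1+\varepsilon$" describe the same region
once $\varepsilon$ solves
$(1+\varepsilon)^{-1/\varepsilon} - (1+\varepsilon)^{-(1+\varepsilon)/\varepsilon} = \delta$.
The left side is strictly increasing in $\varepsilon$, so
`epsilon_from_delta()` uses a bracketed root search (upper bracket doubled
until it encloses the root, `uniroot` at tolerance 1e-14); powers are
evaluated as `exp(-a*log1p(eps))` to keep extreme margins stable. The
round-trip is exact to about 1e-12 over $\varepsilon \in [0.01, 10]$.

An honest limitation: the indifference zone lives *inside* the Lehmann
family. A distribution can be within sup-distance $\delta$ of $F_0$ without
being any $F_0^\theta$; failure to establish equivalence does not certify
misfit in that wider sense.

## The exact UMP test

Under $F_0^\theta$, $-\log F_0(X_i)$ is exponential with rate $\theta$
(probability-integral transform), so $2\theta n/\hat\theta_n \sim
\chi^2_{2n}$ exactly, where $\hat\theta_n = -n/\sum_i \log F_0(X_i)$ is the
ML estimator. The sample enters the test only through $\hat\theta_n$, and
the whole procedure — constants, power, size — is distribution-free in
$F_0$. Because the Lehmann family is a one-parameter exponential family, a
uniformly most powerful level-$\alpha$ test of the interval hypothesis
exists; its critical interval $(C_1, C_2)$ equalizes the rejection
probability at the two boundary values of $\theta$.

**Numerics of the critical constants.** In the variables $a = 2n/C_2 < b =
2n/C_1$ both level equations are monotone in one variable given the other:
for trial $b$ the upper-boundary equation is solved for $a$ by `uniroot`
(tolerance 1e-13), and the lower-boundary defect is then driven to zero in
$b$, bracketed between the smallest feasible value
$q_{\chi^2_{2n}}(\alpha)/(1+\varepsilon)$ (defect negative) and an
adaptively enlarged upper bound (defect positive). A final two-dimensional
Newton polish with the analytic Jacobian (chi-square densities) takes both
defects to machine precision; the residual is stored in the result and a
residual above 1e-9 is an error, never a silent return. The test suite
verifies all thirty boundary rejection probabilities to 1e-9.

**Conventions.** `alpha` is restricted to $(0, 0.5)$ — an equivalence test
at $\alpha \ge 0.5$ is degenerate (the "critical interval" logic inverts).
The critical interval is open: $\hat\theta_n$ exactly equal to a constant
(a probability-zero event) does not reject. The sample-size search doubles
$n$ until the target power is bracketed, then bisects on integers, which is
valid because power is monotone in $n$.

## The grouped-data counterpart

Partitioning the support at the $F_0$-quantiles $j/k$ gives classes of
model probability $1/k$ each (`equal_prob_partition()`; classes are
left-open/right-closed). Under $F_0^\theta$ the class masses are
$(j/k)^\theta - ((j-1)/k)^\theta$ — again distribution-free. The margin
carried over from the continuous problem is the Euclidean distance
$\varepsilon_* = \|\pi^{(1+\varepsilon)} - \pi^\circ\|_2$; with $k = 5$ and
$\varepsilon = 0.5077$ this is $0.1548$.

The test rejects its null $d(\pi, \pi^\circ) \ge \varepsilon_*$ when
$d^2(\hat\pi, \pi^\circ) < \varepsilon_*^2 - z_{1-\alpha}
v_n(\hat\pi)/\sqrt{n}$. The delta-method variance
$v_n^2 = 4[\sum_j a_j^2\hat\pi_j - (\sum_j a_j\hat\pi_j)^2]$,
$a_j = \hat\pi_j - \pi^\circ_j$, is implemented in this moment form, which
is algebraically identical to the expanded double-sum form (the suite
checks the identity on random vectors to 1e-12) and never divides by an
empty class frequency. Two numerical edge cases have documented
conventions:

* $v_n = 0$ (e.g. $\hat\pi = \pi^\circ$ exactly): the bound degenerates to
  comparing $d^2$ with $\varepsilon_*^2$. That comparison is honored only
  for $n \ge 30$; below it the asymptotic argument backing the rule has no
  force, and the test does not reject. Such results carry a `degenerate`
  flag.
* Exact power: all $\binom{n+k-1}{k-1}$ count vectors are enumerated
  (chunked over the first class to bound memory, guarded at $2\times 10^7$
  compositions), each is pushed through the same decision function the
  test itself uses, and multinomial probabilities are summed; the summed
  total mass is returned as an attribute and checked to equal 1.

At matched margins the grouped test is decisively weaker than the exact
test — the suite verifies the strict inequality at $n = 50$ and $100$
(Monte Carlo with $10^4$ replicates against the exact power $0.7869$ and
$0.9857$). Grouping squanders most of the information the exact statistic
extracts from the tails.

## The location-scale (TOST) score test

To test for normal *shape* — $F = [F_0((\cdot-\mu)/\sigma)]^\theta$ with
$(\mu, \sigma)$ unknown — no UMP theory is available, and the
log-likelihood can fail to attain an interior maximum in $\theta$, ruling
out Wald-type constructions. The package instead splits the interval
hypothesis into two one-sided problems at the boundary values
$\theta_b \in \{1/(1+\varepsilon), 1+\varepsilon\}$ and combines the two
score tests (TOST): fit is established iff
$U(1/(1+\varepsilon))/\tilde v_l > z_{1-\alpha}$ *and*
$U(1+\varepsilon)/\tilde v_r < z_\alpha$.

**Restricted fits.** $(\tilde\mu(\theta_b), \tilde\sigma(\theta_b))$ solve
the nuisance score equations at fixed $\theta_b$ by Newton–Raphson with a
differenced Jacobian. The line search accepts a step if it increases the
likelihood, or — once likelihood gains fall below floating-point
resolution — if it at least halves the score norm without materially
decreasing the likelihood. Pure score-norm acceptance is deliberately
avoided: the nuisance scores also vanish along the degenerate
$\sigma \to \infty$ ray, where there is no likelihood peak, and a
score-only criterion can drift there for small $\theta_b$. Steps proposing
$\sigma \le 0$ are halved away; non-convergence after 50 iterations is an
error carrying the trace, and convergence requires the maximum nuisance
score below $10^{-8} n$. Fits are verified in the suite against
`stats::optim` on the same likelihood.

**Variance of the efficient score.** $U(\theta_b)$ is the total
$\theta$-score at the restricted fit. Its variance estimate uses the
*expected* (not observed) covariance matrix of the score vector — the
standard guard against the Freedman inconsistency of observed-information
standardization under misspecification. With $V$ the full-sample expected
covariance ($n$ times the per-observation matrix), the standardizer is the
partial information $\tilde v^2 = 1/[(V^{-1})_{11}]$ — the variance of the
$\theta$-score with the nuisance directions projected out. The scale
matrix cancels in the $(1,1)$ element of the inverse, so $\tilde v^2$
depends only on $(\theta_b, n)$; at $n = 100$, $\varepsilon = 0.5077$ the
two values are $1.636889$ and $0.276968$. Their smallness *is* the story:
the effective information about $\theta$ left after profiling out
$(\mu, \sigma)$ is two orders of magnitude below the fully-specified case
($n/\theta_b^2$), which is why the suite's power check finds a rejection
rate far below 50% even at $n = 500$, $\theta = 1$ — certifying a
distributional *shape* needs samples in the thousands.

**Quadrature.** The expectations behind $V$ have no closed form. They are
integrals over the probability scale, $E[g(Z)] = \int_0^1
g(F_0^{-1}(u))\,\theta u^{\theta-1}\,du$; the substitution $v = u^\theta$
removes the power singularity, leaving logarithmic singularities at both
endpoints (from $\log F_0$ on the left, from $z^2$-type terms on the
right). Composite Gauss–Legendre quadrature (default 16 nodes per panel)
on panels geometrically refined toward both endpoints ($2^{-60}$ on the
left, $2^{-45}$ on the right, the right tail parameterized by $1-v$
because $v$ itself is not representable near 1 in double precision)
handles these to near machine precision; a single global rule would stall
around 1e-6 on the $(\log u)^2$ terms. Every matrix is recomputed with
doubled nodes and the maximum entrywise change attached as a `self_check`
attribute (typically below 1e-12). The suite cross-checks the matrices
against Monte-Carlo score covariances ($10^6$ draws, 3-SE bands) and
against the Gaussian closed forms at $\theta = 1$.

## The synthetic-data generator

`rlehmann()` draws $F_0^{-1}(U^{1/\theta})$ with $U$ uniform — exact
inverse-transform sampling from the Lehmann alternative; uniform draws
hitting 0 or 1 at machine level are redrawn so observations stay strictly
inside the support. `write_fixture()` makes seeded, byte-reproducible
sample files with a JSON sidecar recording the generator truth. The
packaged worked-example sample (`synthetic_norm100.txt`) is such a
fixture: $n = 100$ standard-normal observations ($\theta = 1$, seed 106),
mirroring the canonical use case of certifying standard normality on a
hundred observations.

What the generator emulates is exactly the model's sampling assumptions:
i.i.d. draws from a continuous $F_0^\theta$. Real data deviate in ways the
generator deliberately does not imitate — ties and rounding (which make
$F_0(X_i)$ collide), measurement error, dependence, censoring. Passing
tests therefore certify the *procedures* under their stated assumptions,
not robustness to those violations; observations at the support boundary,
the most common symptom of a mismatched data/model pairing, are a hard
error naming the offending index rather than something the code silently
clamps.

## Default parameters at a glance

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 0.05 | one-sided error of falsely certifying fit; restricted to (0, 0.5) |
| `delta` / `epsilon` | none — user must choose | the scientific tolerance; δ = 0.15 (ε = 0.5077) is a moderate, customary sup-distance margin |
| `k` | 5 (CLI) | classes for grouping; equal-probability cuts at F₀-quantiles |
| `nodes` | 16 per panel | quadrature density; doubling self-check attached to every matrix |
| degenerate-variance minimum `n` | 30 | below it the asymptotic grouped rule is not trusted |
| MC problem sizes in the suite | $10^4$–$10^5$ reps, $n \le 500$ | keep the full suite around a minute while leaving 3-SE bands decisive |

## Known limitations

* The equivalence region is Lehmann-shaped; distances to arbitrary
  non-Lehmann neighbors of $F_0$ are out of scope.
* The grouped and score tests are asymptotic (the score test warns below
  $n = 50$); only the UMP test is exact at any $n$.
* Right-censored data and two-sample problems are not supported.
* The score test is implemented for location-scale families with smooth
  standard densities (normal and logistic in the catalogue); its power at
  practical sample sizes is poor — that is a property of the problem, not
  of the implementation, and the package reports it honestly.
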