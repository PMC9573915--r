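---
title: "Laplace-approximated maximum likelihood for Poisson-ICAR disease mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplace-approximated maximum likelihood for Poisson-ICAR disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icarlap)
```

## The model

Counts of disease cases in $n$ small areas are modelled as

$$y_i \sim \mathrm{Pois}(E_i \lambda_i), \qquad
  \log \lambda_i = \beta_0 + x_i'\beta + s_i,$$

with $E_i > 0$ the expected count (offset) and $\lambda_i$ the relative
risk. The spatial field $s$ follows the Besag intrinsic conditional
autoregressive (ICAR) distribution on the first-order contiguity graph:
each $s_i$, conditional on its neighbours, is normal with mean the
neighbour average and variance inversely proportional to the neighbour
count $n_i$. Jointly,

$$p(s \mid \tau) \propto
  \exp\!\Big( -\tfrac{1}{2\tau^2}\, s' Q s \Big), \qquad
  Q = D_w - W,$$

where $W$ is the binary symmetric contiguity matrix and $D_w =
\mathrm{diag}(n_i)$. The quadratic form equals the sum of squared
differences across edges, so $Q\mathbf{1} = 0$: $Q$ is singular with
rank $n - k$ ($k$ = number of connected components), the density is
improper, and the field is identified only after constraining each
component's effects to sum to zero. The conditional mean level of the
field is fixed at zero and absorbed into the free intercept; a separate
mean parameter would not be identifiable.

The joint negative log-likelihood (dropping the data-constant
$\log y_i!$ throughout, so reported values differ from the full Poisson
likelihood by a constant) is

$$\mathrm{nll}(\theta, s) =
  -\sum_i \big\{ y_i \eta_i - E_i e^{\beta_0 + x_i'\beta + s_i} \big\}
  + \frac{s'Qs}{2\tau^2} - c(\tau),$$

with $\eta_i = \log E_i + \beta_0 + x_i'\beta + s_i$ and
$\theta = (\beta_0, \beta, \log\tau)$.

### The normalizing constant matters

$c(\tau)$ is the generalized normalizing constant of the constrained
ICAR density,

$$c(\tau) = -\tfrac{n-k}{2}\log 2\pi
            + \tfrac12 \log \mathrm{pdet}(Q) - (n-k)\log\tau,$$

with $\mathrm{pdet}$ the product of the $n-k$ positive eigenvalues of
$Q$. The improper density is usually written only up to
proportionality, but the $-(n-k)\log\tau$ term **must** enter the
marginal likelihood: without it the likelihood is monotone in $\tau$ and
the dispersion MLE diverges. The $\tau$-free part
($\log \mathrm{pdet} Q$, computed once per graph by dense
eigendecomposition) only shifts the likelihood and is included so
reported values are proper log-densities.

## Laplace-approximated marginal likelihood

The latent field is integrated out over the constrained subspace:

$$\mathrm{nll}^*(\theta)
 = -\log \int e^{-\mathrm{nll}(\theta, s)}\, ds
 \approx \mathrm{nll}(\theta, \hat s_\theta)
   + \tfrac12 \log\det H(\hat s_\theta) - \tfrac m2 \log 2\pi,$$

where $\hat s_\theta$ minimizes the joint nll in $s$, $H = A'\,[
\mathrm{diag}(E_i e^{\eta_i}) + Q/\tau^2\,] A$ is the Hessian in the
working coordinates, and $m$ is the integrated dimension. The Poisson
log-likelihood is concave in $\eta$ and the prior quadratic convex, so
the inner problem is strictly convex: undamped Newton with step-halving
converges monotonically in a handful of iterations (warm-started across
outer evaluations).

### Constraint handling

Two interchangeable implementations are provided
(`constraint_spec()`):

* **hard_reparameterize** (default): write $s = A u$ with $A$ an
  $n \times (n-k)$ orthonormal basis of the per-component sum-to-zero
  subspace, built blockwise from normalized Helmert contrasts
  (deterministic; no QR pivoting), and optimize/integrate over $u$
  ($m = n-k$). Because $A$ is orthonormal,
  $\det(A'QA) = \mathrm{pdet}(Q)$ and the subspace measure is the
  natural one. Components of size one (zero-neighbour islands)
  contribute no columns: their effect is fixed at zero.
* **soft_penalty**: keep all $n$ coordinates and add
  $\tfrac\kappa2 (\sum_{i \in c} s_i)^2$ per component
  ($\kappa \ge 10^4$, default $10^6$), folded into a *proper* prior
  whose normalizing constant includes
  $\tfrac12\sum_c \log(\kappa n_c)$; then $m = n$. As
  $\kappa \to \infty$ the two marginal likelihoods agree exactly term
  by term (the $\kappa$ contributions cancel between prior constant and
  $\log\det H$), which the test-suite verifies at $\kappa = 10^6$ to
  about $10^{-4}$.

The hard mode is the default because it needs no tuning constant and
keeps the outer problem well-conditioned; the soft mode exists as an
independent cross-check. The basis is dense, so the inner algebra is
dense $O(n(n-k)^2)$ per Newton step — entirely adequate for the
hundreds-of-regions scale this model targets (a 225-cell lattice fit
takes ~1-2 s); the sparse-penalized soft route is the escape hatch for
much larger graphs.

### Outer optimization and uncertainty

`fit_mle()` minimizes $\mathrm{nll}^*$ by BFGS with central
finite-difference gradients (step $10^{-5}(1+|\theta_j|)$), started at
the moment-matched intercept $\log(\sum y / \sum E)$, $\beta = 0$,
$\log\tau = 0$. BFGS's relative-decrease stopping rule can halt while
the gradient is still above tolerance when $|\mathrm{nll}^*|$ is large,
so a Newton polish (finite-difference Hessian, step-halving, accepted
only when the gradient norm falls) runs until the sup-norm outer
gradient is below $5\times10^{-5}$; a fit is reported `converged` only
if the final gradient is $\le 10^{-4}$ (the inner tolerance, $10^{-8}$,
is deliberately much tighter so finite differences of the profiled
objective are stable). Standard errors come from the inverse
finite-difference Hessian of $\mathrm{nll}^*$ at $\hat\theta$; if that
observed information is not positive definite, SEs are reported missing
with a warning rather than silently.

**Reporting scale.** $\tau$ enters as $1/(2\tau^2)$, so $\tau^2$ is the
variance-scale quantity ($\sigma_s^2$, with conditional variances
$\tau^2/n_i$); published tables for these models label that variance
"spatial $\tau$". The default report scale is therefore `tau2`, with
`tau` available, and SEs transfer by the delta method
($\mathrm{se}(\tau^2) = 2\tau^2\,\mathrm{se}(\log\tau)$).

**Boundary.** With no spatial signal the dispersion MLE collapses
toward zero along a flat profile; the fit flags `boundary = TRUE` when
$\hat\tau^2 < 10^{-3}$ instead of erroring, since the information matrix
is singular there.

**Latent estimates.** `plug_in_latent()` returns the empirical-Bayes
plug-in field $\hat s(\hat\theta)$ with conditional SDs from the
diagonal of $A H^{-1} A'$; it refuses unconverged fits.

## Contiguity graphs

`polygons_to_graph()` derives first-order contiguity from polygon
shapefiles: **queen** (any shared boundary point; the convention of the
WinBUGS/GeoBUGS county-map tooling, hence the default) or **rook**
(a shared segment of positive length). Shared points are matched by
exact coordinate equality after vertex deduplication — deliberately no
snapping tolerance, because snapping thresholds are data cleaning, not
method; shapefiles produced from a common boundary topology (the normal
case for county maps) match exactly. Vertex order follows shapefile
record order so latent-field vectors align with input rows.
Zero-neighbour polygons are permitted, become their own component (with
$s_i = 0$), and are loudly warned about. No R shapefile reader is
assumed: a minimal `.shp`/`.dbf` polygon parser is included, plus GAL
and plain two-column edge-list readers, and audit CSV writers for the
derived edges and degrees.

## The synthetic world

`simulate_counts()` draws from exactly the model above: a rook (or
queen) lattice, $s = \tau \sum_{\lambda_\ell > 0} v_\ell
z_\ell/\sqrt{\lambda_\ell}$ from the spectral decomposition of $Q$ (so
component sums are zero exactly, not just in expectation — conditional
Gibbs sweeps would only satisfy the constraint stochastically), standard
normal covariates when requested, and Poisson counts. The reference
scenario — 15×15 rook lattice, $\beta_0 = 0.5$, $\tau = 0.5$, $E = 50$
— was chosen once to bracket the information content of county case
studies (tens to hundreds of expected cases per area, moderate spatial
variance) and is what the 200-replicate recovery criterion runs at;
offsets of 10/50/200 bracket sparser and richer registries in the unit
tests. What a green recovery test establishes: near-unbiasedness of
$\hat\beta_0$ and $\hat\tau^2$ and honest Wald coverage *under the
model*. What it does not: robustness to non-Poisson overdispersion,
misspecified neighbourhoods, or covariate measurement error — real
registries deviate in all three ways, and only the $\tau = 0$
degenerate case is simulated as misspecification.

## Oracles: how the Laplace machinery is adjudicated

Because the Laplace approximation is uncontrolled in general, the
package carries independent brute-force routes on tiny graphs
(`brute_force_marginal`, dimension capped at 4):

* **adaptive quadrature** (dimension ≤ 2 by default): nested
  `stats::integrate` in the eigenbasis of $Q$, relative tolerance
  $10^{-8}$, stability asserted by halving the tolerance;
* **importance sampling** (dimension 3–4): product-t proposal (7 df)
  centred at a Nelder-Mead pilot mode with finite-difference curvature
  scales, $6\times10^5$ draws, Monte-Carlo SE reported. Nested adaptive
  quadrature in pure R needs ~30 s per 3-D point, which is why sampling
  takes over above dimension 2; the two methods agree within the
  Monte-Carlo error wherever both run, and a one-off full-quadrature
  pass over the whole fixture grid reproduced the sampled values.

The fixture set (`oracle_fixtures()`) is versioned: single edge, path-3,
4-cycle, and a two-component $n=5$ graph (exercising the $k = 2$
normalizing constant), each over a 3×3 grid of
$(\beta_0, \log\tau)$. Observed Laplace error is ≤ 0.05 on these
small-count instances and shrinks as counts grow (verified on a
×1/×10/×100 scaling ladder), which is the expected large-count
behaviour. Replacing the Poisson term by its second-order expansion
makes the integrand Gaussian; the Laplace value then matches an
independently coded complete-the-square evidence to $10^{-10}$,
isolating the optimizer/determinant plumbing from approximation error.

A self-contained Metropolis-within-Gibbs sampler (`mcmc_crosscheck`,
flat priors on coefficients, N(0, 10²) on $\log\tau$, per-component
recentring each sweep with the removed mean transferred to the intercept
on connected graphs, split-chain R-hat with a 1.1 gate) provides the
Bayesian comparison at realistic sizes: MLEs land within two posterior
SDs of posterior means on simulated lattices, mirroring how these models
are usually validated against their MCMC implementations.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| inner Newton tolerance | $10^{-8}$ sup-norm | must be ≪ outer so FD outer gradients are stable |
| outer gradient tolerance | $10^{-4}$ | the "maximum gradient ≈ 0" convergence contract |
| FD gradient step | $10^{-5}(1+|\theta|)$ | central differences; objective noise is $O(10^{-12})$ |
| soft penalty $\kappa$ | $10^{6}$ (min $10^4$) | agreement with hard mode to ~4 decimals |
| quadrature rel. tol | $10^{-8}$ | oracle must be far below the 0.05 comparison band |
| IS draws / df | $6\times10^5$ / 7 | MC SE ~$10^{-3}$ on the log scale; heavy tails dominate the integrand's |
| boundary flag | $\hat\tau^2 < 10^{-3}$ | flat profile, singular information |
| dense-eigen guard | $n \le 5000$ | spectral sampler and pdet are dense |
| initialization | $\beta_0 = \log(\sum y/\sum E)$, $\beta=0$, $\log\tau=0$, $s=0$ | moment-matched null mode |

Ties/degenerates: duplicate and reversed edges collapse; self-pairs are
errors; empty graphs are rejected; a fully disconnected graph has $m=0$
and the marginal likelihood degenerates to the independent Poisson GLM,
which is also the exact $\tau \to 0$ limit.

## Limitations

* Poisson likelihood and binary first-order weights only — no
  proper-CAR $\rho$, no BYM convolution, no negative-binomial or
  binomial variants, no row-standardized or distance weights.
* The Laplace error is only certified (≤ 0.05 in nll) on the small
  fixture graphs; at realistic counts it is far smaller (the scaling
  ladder and the MCMC agreement are the evidence), but no analytic
  bound is computed.
* Outer derivatives are finite differences, not automatic
  differentiation; adequate at ≤ a few hundred regions and ≤ 5
  parameters, increasingly wasteful beyond.
* The dense eigendecomposition/basis limits graphs to a few thousand
  regions; truly large lattices would need a sparse-Cholesky soft-mode
  path throughout.
* Exact-coordinate contiguity matching assumes topologically clean
  shapefiles; digitization noise requires upstream cleaning.
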