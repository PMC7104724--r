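---
title: "Modeling coverage depth on circular chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coverage depth on circular chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circptr)
```

## The model

Most bacteria and many archaea replicate a circular chromosome
bidirectionally from a replication origin. In a growing population a
sequencing library therefore over-represents positions near the origin: the
coverage-depth profile along the chromosome is a wave with its peak at the
origin and its trough at the terminus, and the peak-to-trough ratio (PTR)
rises with replication activity.

circptr models this wave probabilistically. Position $i$ of a replicon
binned into $I$ bins maps to the angle $\theta_i = \tfrac{i}{I}2\pi$, and
each sequenced base is treated as an independent draw of a position from a
circular probability distribution $P(\theta \mid \omega)$. The binned depths
$d_{i,s}$ of sample $s$ are then stacking counts of angles, giving the
weighted log-likelihood

$$\log L(\omega \mid \theta, d) = \sum_s \sum_i d_{i,s}
  \log L_{\mathrm{dist}}(\omega_s \mid \theta_i),$$

which is exactly the parameter-dependent term of the full multinomial
likelihood of the bin counts (`coverage_loglik_multinomial()` adds the
data-only combinatorial constant). Equivalently, the depth at a single bin
is $d_{i,s}\sim\mathrm{Binomial}(T_s, p_i)$ with
$p_i = f(\theta_i)\cdot 2\pi/I$ — the view used by `binomial_depth_predictive()`
and by the simulator. The paper-facing estimand is the **probabilistic PTR**

$$\mathrm{pPTR} = \frac{\max_\theta f(\theta)}{\min_\theta f(\theta)},$$

the latent observation bias at the origin relative to the terminus. Unlike a
ratio of raw depths it is defined at arbitrarily low coverage, because it is
a property of the fitted density.

The location parameter $\mu$ (the origin) is shared across samples mapped to
the same reference; the concentration parameter — and any shape, peakedness
or skewness parameter — is per sample, since it carries the growth signal.

## Families and their closed-form pPTR

Six circular families are supported (`dist_spec()`), chosen to span
different peak shapes while keeping closed-form peak-to-trough ratios:

| family | concentration | pPTR |
|---|---|---|
| von Mises | $\kappa \ge 0$ | $e^{2\kappa}$ |
| cardioid | $0 \le \rho < 1/2$ | $(1+2\rho)/(1-2\rho)$ |
| wrapped Cauchy | $0 \le \rho < 1$ | $((1+\rho)/(1-\rho))^2$ |
| Jones–Pewsey ($\psi$ shape) | $\kappa \ge 0$ | $e^{2\kappa}$ |
| linear cardioid | $0 \le \rho < 1/\pi$ | $(1+\pi\rho)/(1-\pi\rho)$ |
| exp. linear cardioid | $0 \le \rho < 1/\pi$ | $e^{2\pi\rho}$ |

Bounds are enforced strictly with an $10^{-8}$ margin at the poles. Two
printed forms needed an implementation decision:

* the **Jones–Pewsey kernel** is implemented as
  $(\cosh\kappa\psi + \sinh\kappa\psi\cos(\theta-\mu))^{1/\psi}$ — the
  argument of the cosine is $\theta-\mu$, so the location acts as in every
  other family — and its constant is computed by Simpson quadrature rather
  than through the associated Legendre function, which avoids
  special-function edge cases near $\psi = 0$ ($\psi = 0$ itself is treated
  as exactly von Mises). Any real $\psi$ is admitted; the quadrature is
  sign-agnostic.
* the **exponential linear cardioid** exponent is grouped as
  $2\rho(\lvert\lvert\theta-\mu\rvert-\pi\rvert - \pi/2)$; under this
  grouping the density normalizes to
  $\rho/(e^{\pi\rho}-e^{-\pi\rho})$ and the pPTR $e^{2\pi\rho}$ holds.

## Peakedness and skewness extensions

Four argument transformations reshape a base family (all operate on the
deviation $x = \theta - \mu$, wrapped to $(-\pi,\pi]$):

* **SE** (Batschelet): $x \mapsto x + \lambda\sin x$, renormalized
  numerically.
* **InvSE** (inverse Batschelet):
  $g_\lambda(x) = \tfrac{1-\lambda}{1+\lambda}x +
  \tfrac{2\lambda}{1+\lambda}t_{1,\lambda}^{-1}(x)$ with
  $t_{1,\lambda}(u) = u - \tfrac12(1+\lambda)\sin u$. A note on
  normalization: substituting any odd bijection of $(-\pi,\pi]$ into a
  symmetric density changes its integral unless the map is the identity
  (the inverse Jacobian of an odd map is even, and only the identity keeps
  its even part at 1), so this composite map is *not* measure-preserving —
  numerically the von Mises ($\kappa=1$, $\lambda=0.4$) case integrates to
  0.81. circptr therefore renormalizes the InvSE density explicitly, like SE
  and MIAE. The constant cancels in the peak-to-trough ratio, so pPTR is
  unaffected.
* **MIAE**: $x \mapsto x - \nu\sin^2 x$, renormalized. The $\sin^2$ form is
  the only coherent reading: an odd modifier such as $\sin 2x$ would leave
  every symmetric density symmetric and could not express skewness, whereas
  $x - \nu\sin^2 x$ is strictly increasing for $\lvert\nu\rvert<1$, keeps
  the mode exactly at $\mu$, and is the forward counterpart of the InvMIAE
  map below.
* **InvMIAE**: $x \mapsto s_\nu^{-1}(x)$ with $s_\nu(u) = u + \nu\sin^2 u$.
  Here normalization invariance is exact ($s_\nu' = 1 + \nu\sin 2u$ has odd
  deviation from 1, which integrates to zero against any symmetric base),
  the mode stays at $\mu$, and the pPTR is unchanged for any $\nu$.

Skewness enters asymmetry without moving the peak — the biological
requirement, since replication starts at the origin regardless of growth
rate. $\lambda$ and $\nu$ are kept in $(-1,1)$, the largest interval on
which the maps remain monotone; inverse maps are solved by Newton iteration
when $\lvert\lambda\rvert$ or $\lvert\nu\rvert < 0.8$ (tolerance
$1.19\times10^{-7}$, the single-precision epsilon, at most 30 iterations)
and by the Illinois method otherwise (tolerance $10^{-13}$, at most 100
iterations); exactly 0.8 goes to Illinois, the conservative choice.

## Priors

* Concentrations: half-Student-t with 2.5 degrees of freedom, location 0,
  and family-specific scale (0.2 von Mises / Jones–Pewsey, 0.1 cardioid,
  0.17 wrapped Cauchy, 0.105 linear cardioid, 0.1103 exponential linear
  cardioid). These scales put the prior CDF near 0.8 at the concentration
  whose pPTR is 2.0 — encoding that most growth signals in a community fall
  between pPTR 1 and 2 (`phalf_t(log(2)/2, 2.5, 0.2)` is 0.8005).
* Shape/peakedness/skewness: standard Gaussian, to damp overfitting.
* Mixture weights: symmetric Dirichlet with per-component mass $A = 50/M$,
  encoding that multiple origins tend to fire with similar activity.
* Location: uniform on the circle.

## Estimation

Both modes work on unconstrained reparameterized variables: the location as
a 2-vector through $\mu = \mathrm{atan2}(y, x)$ (no wrap-around boundary for
the optimizer or sampler to fall over), $\log\kappa$ or a logistic-scaled
$\rho$ against its family bound, $\tanh$-scaled $\lambda,\nu$, and a
softmax for mixture weights. The location vector carries a soft Gaussian
tether on its radius around 1 — a pure normal prior on the components would
make the optimizing-mode radius collapse to zero — which leaves the angle
marginal uniform.

**Optimizing mode** maximizes the joint posterior in the constrained space
(the convention of posterior-optimization software: no Jacobian terms, so
flat priors reproduce maximum likelihood exactly) with BFGS, restarting from
`n_seeds` random initializations (`seed + 0..n_seeds-1`; default 1 for a
single origin, 30 for mixtures, where the likelihood is multimodal) and
keeping the highest posterior. Analytic gradients are used for the von Mises
family (single origin and mixtures); other families use finite differences
over their handful of parameters.

**Sampling mode** runs Hamiltonian Monte Carlo on the Jacobian-adjusted
posterior: one chain, 500 iterations with 300 warm-up for a single origin
and 1500/1000 for mixtures; leapfrog trajectories of 5–15 steps (15–30 for
mixtures, whose weight/concentration ridge needs longer paths); step size
adapted by dual averaging toward 0.8 acceptance, and a diagonal mass matrix
estimated from the draws halfway through warm-up. The chain is initialized
at the optimizing-mode solution. The point estimate is the expected a
posteriori (EAP) over post-warm-up draws, with the location averaged as a
mean unit vector (a circular mean). Convergence is summarized by
split-chain rank-normalized Rhat on every coordinate plus the log posterior;
the fit is flagged `accepted` only when all Rhat $\le 1.1$. A rejected fit
is returned, flagged, rather than raised as an error. Trajectories with
non-finite energies count as divergences and are reported.

Model comparison: AIC $=2k - 2\log L$ and BIC $=k\log(\sum_s T_s) - 2\log L$
with $k = 1 + S$ for vanilla non-Jones–Pewsey models, $1 + 2S$ for
Jones–Pewsey, one extra per-sample parameter under an extension, and
$M + MS + (M-1)$ for mixtures (locations, concentrations, free weights —
the count the mixture actually adds; the sources do not state one). The
per-sample treatment of $\psi$, $\lambda$ and $\nu$ follows the
Jones–Pewsey count $1 + 2S$, which is only consistent with a per-sample
shape. BIC's sample size is the total observation count $\sum_s T_s$,
i.e. the number of angular draws the multinomial view implies. WAIC is
computed from pointwise (per-bin, depth-weighted) log-likelihood draws in
sampling mode only; in optimizing mode it is an error, not an `NA`.
Nested families are compared by the likelihood-ratio test with Wilks'
chi-squared reference (Jones–Pewsey against von Mises; an extension against
its base).

For multi-origin chromosomes, `select_origin_count()` fits $M = 1..4$
(MAP with 30 restarts, then HMC for WAIC), reports best-by-AIC and
best-by-WAIC, and chooses the smaller of the two when they disagree — the
mixture is a singular model, so ties and conflicts break toward fewer
origins. Components are sorted by location after fitting to resolve label
switching. Per-origin activity is the weighted PTR
$\mathrm{wPTR}_m = e^{2\alpha_m\kappa_m}$ (von Mises mixture), and the
chromosome-level score mwPTR is the arithmetic mean over origins.

## Preprocessing and quality control

`make_track()` runs the standard pipeline on per-base depth: a moving
median filter (window 100 nt, stride 100 nt — denoising and 100-fold
compression in one step; a shorter tail window uses the positions present;
windows do not wrap across the origin), optional blanking of the top 1% of
*bins* of the binned track (conserved-region pileups; ties at the cutoff
break by position; blanked bins become 0, i.e. no observations), and the
angle mapping using each bin's upper index per $\theta = \tfrac{i}{I}2\pi$.
Medians of even windows are means of the middle pair, so binned depths may
be half-integers; the likelihood only needs non-negative weights.

`lander_waterman_check()` guards against non-random coverage: with average
coverage $a$, uniform sequencing predicts a zero-coverage fraction
$\hat f = e^{-a}$. For samples with $a < 5$, the sample is flagged when
$\log f > 0.56\,\log\hat f$ — substantially more empty bins than random
sampling allows (both logs are negative; the published rule is ambiguous
about whether 0.56 multiplies the log or the raw theoretical score, so the
raw-scale literal reading is available behind `log_scale = FALSE`, though it
essentially never fires). Fitted PTRs of 3.0 or more are flagged as residual
noise, and coverage at or below 0.01x fails outright.

## The simulator and what passing tests mean

`generate_coverage()` draws $T = \bar d \cdot I$ observation events and
spreads them over bins with a single multinomial whose probabilities follow
the chosen density — exactly the observation model, at the bin level.
Defaults reproduce the conditions used throughout the package's own checks:
a 1 Mnt chromosome binned at 100 nt ($I = 10^4$) at 20x depth. Robustness
checks (rarefaction to 0.01x, injected 100-bin pileups at +50x with the
top-1% filter) use a 4 Mnt chromosome — the scale of *E. coli*, the
canonical culture organism for PTR validation — because the error of a
rarefied estimate is governed by the absolute number of surviving
observations, and a realistic genome length is the honest setting for that
check. The parameter-recovery sweep uses a discrete length of 1000 bins and
coverages 0.5–16x over a grid of locations and concentrations, with the fit
quality measured as the Kullback–Leibler divergence to the true density on
a 10,000-point grid.

What the simulator does *not* emulate: read-level structure (adjacent-bin
correlation from read length), GC-content bias, strand asymmetry, mutations
against the reference, or contamination by close relatives. Passing the
simulation-based checks therefore demonstrates correctness of the model,
estimator and pipeline mechanics under the model's own assumptions — not
performance on real libraries, for which the preprocessing filters and the
Lander–Waterman screen exist.

`rarefy()` thins each bin binomially (the bin-level image of read
subsampling), `add_peak_noise()` adds uniform depth boosts over random
regions, and `sorted_profile()` reproduces the diagnostic that even
noise-free multinomial sampling distorts both tails of the sorted depth
profile relative to the sorted density quantiles — heavy sorted-profile
tails alone are not evidence of artifacts.

## Numerical choices and degenerate inputs

* Integrals over the circle use composite Simpson quadrature; the
  user-facing default is 20 subintervals (sufficient for the smooth,
  moderately concentrated densities the model targets), while internal
  normalization constants use at least 400 subintervals so that densities
  are normalized to well below $10^{-5}$ across the admissible parameter
  range.
* The discrete-normalization constants ($N/(2\pi)$ cardioid,
  $(N+2)/(2\pi)$ linear cardioid, direct sums for von Mises and wrapped
  Cauchy) belong to the opt-in discretized variant of the likelihood; the
  default model treats $\theta$ as continuous.
* All-zero tracks are rejected (`degenerate-input`); a flat track shrinks
  $\kappa$ to almost 0 under the prior (pPTR $\to$ 1). Concentrations at a
  family pole raise an invalid-parameter error naming the bound.
* Optimizer failure on every restart raises a fit-failure error; single
  restarts that fail are skipped silently.
* Problem sizes in the package's own test suite (chosen to keep the checks
  sharp but fast): $I = 10^4$ for the simulation realism checks,
  $I = 10^3$ for the recovery sweep, $I = 4\times10^4$ for robustness,
  and $I = 3\times10^3$ at 20x for the three-origin selection check, whose
  ground truth uses the weighted-PTR profile of a three-origin archaeon in
  exponential growth (wPTRs 3.59, 3.18, 2.66 at equal weights, irregularly
  spaced origins). Equally spaced origins with equal concentrations are
  deliberately avoided as a truth: by symmetry their first circular
  harmonics cancel and the mixture density is nearly uniform, which makes
  the origin count unidentifiable in principle, not just in practice.

## Known limitations

* Taxonomic resolution is whatever the alignment gives: mixed coverage from
  close relatives mixes PTR signals.
* The pPTR is a growth *proxy*; converting it to a doubling time requires
  the replication-period correction, which is out of scope, so estimates
  should not be compared across species.
* GC-content correction is omitted; strongly biased libraries should be
  corrected upstream.
* The Rhat diagnostic uses a split single chain by default (the sampling
  defaults use one chain); it cannot detect a chain that never leaves a
  minor mode — the multi-seed MAP initialization mitigates this.
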