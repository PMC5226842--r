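---
title: "Exchange-algorithm sampling for item response posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exchange-algorithm sampling for item response posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Bayesian inference for a person's latent ability $\theta$ in an item
response model needs draws from the posterior
$\pi(\theta \mid x) \propto \pi(x \mid \theta)\,\pi(\theta)$. For models in
the exponential family,

$$\pi(x \mid \theta) = \frac{h(x)}{Z_\theta} \exp\{\theta\, t(x)\},$$

the likelihood is known only up to the normalizing constant $Z_\theta$, and
for many related models (network models, random fields) $Z_\theta$ is
outright intractable. What is almost always easy, however, is *simulating*
from the model: draw $\theta^* \sim \pi(\theta)$, then data
$x^* \sim \pi(x \mid \theta^*)$. The pair is a draw from the joint
$\pi(\theta)\pi(x \mid \theta) = \pi(x)\pi(\theta \mid x)$, so $\theta^*$
is an *exact* posterior draw — but from the posterior given the simulated
data $x^*$, not the observed data $x$.

The Single-Variable-Exchange (SVE) algorithm turns this into a sampler for
the observed-data posterior: use $\pi(\theta \mid x^*)$ as the proposal in
an independence Metropolis chain. For exponential-family models the
acceptance probability collapses to

$$\phi = \min\bigl\{1, \exp[(\theta^* - \theta')(t(x) - t(x^*))]\bigr\},$$

in which $Z_\theta$ cancels: only the current value $\theta'$, the
proposal $\theta^*$, and the observed and simulated sufficient statistics
appear. `svexchange` implements this kernel and a family of
generalizations for the two workhorse binary item response models:

* **Rasch**: $P(X_i = 1 \mid \theta) = \mathrm{logit}^{-1}(\theta -
  \delta_i)$, sufficient statistic the test score $x_+ = \sum_i x_i$;
* **2PL**: $P(X_i = 1 \mid \theta) = \mathrm{logit}^{-1}(\alpha_i \theta -
  \delta_i)$, sufficient statistic the weighted score $\sum_i \alpha_i
  x_i$.

Item parameters are treated as fixed and known throughout; only person
posteriors are sampled.

## A mixture of kernels, and why the plain algorithm is slow

Each realized statistic $t(x^*)$ indexes one Metropolis transition kernel;
the algorithm is a mixture of kernels weighted by the *mixing
distribution* $\pi(t(x^*))$, the prior-predictive law of the statistic.
Every kernel leaves $\pi(\theta \mid x)$ invariant, so any scheme that
reweights kernels *using the statistics alone* — never the current state
$\theta'$ or the proposed $\theta^*$ — keeps the correct invariant
distribution. The plain algorithm is inefficient precisely because the
mixing distribution puts much of its mass on kernels with $t(x^*)$ far
from $t(x)$, which almost never move the chain
(`mixing_distribution()` and `tail_mass()` quantify this).

All generalizations below exploit that one degree of freedom.

```{r}
library(svexchange)
model <- rasch_model(reference_difficulties(20))
mix <- mixing_distribution(model, normal_prior(), n_draws = 2e4)
tail_mass(mix, center = 9, radius = 4) # kernels unlikely to move a score-9 chain
```

## The kernels

**Oversampling** (`kernel = "oversample"`, parameter `m`): draw $m$
proposals, forward the one with statistic closest to $t(x)$ (ties broken
uniformly at random). The minimum distance $\min_m |t(x^*) - t(x)|$ is
non-increasing in $m$, so acceptance rises monotonically; $m = 1$ *is* the
plain algorithm. The $m$ draws are mutually independent, so this trades
raw simulation effort for statistical efficiency.

**Rank matching** (`kernel = "match"`): with $n$ simultaneous targets
(independent posteriors of $n$ persons), generate $n$ proposals and assign
them by rank: sort targets by their matching statistic, sort proposals
likewise, pair first with first, and accept each pair independently. The
sorted pairing minimizes $\sum |t(x^*) - t(x)|$ over all $n!$ assignments
for this one-dimensional statistic (a rearrangement argument), at
$n \log n$ cost. When a proposal drawn from person $q$'s prior is offered
to person $p$'s posterior, the priors no longer cancel and the acceptance
ratio carries the factor
$\pi_p(\theta^*)\pi_q(\theta')/[\pi_p(\theta')\pi_q(\theta^*)]$
(`accept_probability_cross_prior()`). Under a latent regression prior
$\theta_p \sim N(y_p^\top\beta, \sigma^2)$ the whole ratio folds into a
shifted statistic $x_{p+} + y_p^\top\beta/\sigma^2$, which is therefore
also the right statistic to sort on (`matching_statistic()`).

**Recycling rejection** (`kernel = "recycle"`): when the statistic is
discrete with few values (a test score takes $k+1$ values), a proposal
whose statistic *exactly* matches an outstanding observed score is an
exact posterior draw — no Metropolis step at all. Pooling $n$ persons by
score multiplicity and recycling every proposal into whichever score still
needs draws, the expected cost falls from $n\,E[1/\pi(x_+)]$ proposals to
roughly $n$ as $n$ grows; at $n = 1$ it is the classical rejection
sampler. The cost stays above one proposal per draw at finite $n$ because
the rarest observed score still dominates the waiting time.

**Binning** (`kernel = "bin"`, parameter `half_width` $= a$): for
continuous or many-valued statistics (the 2PL weighted score takes up to
$2^k$ values) exact matching is hopeless. Instead, regenerate proposals
until $t(x^*)$ lands in the open interval $(t(x) - a,\, t(x) + a)$, then
apply the usual exchange accept step. Any $a > 0$ leaves the posterior
invariant — unlike ABC-style acceptance of everything in the window,
exactness here does not require a small $a$; $a$ only tunes the tradeoff
between acceptance rate and proposals per iteration. $a = \infty$ is plain
SVE. An unreachable bin is reported (`capped = TRUE` after `max_tries`
draws) rather than looping forever. For many targets,
`binned_recycling_sweep()` composes binning with recycling: proposals are
recycled across non-overlapping bins of observed statistics and each
assignment then passes through the exchange correction.

**Augmented-variable proposals** (`kernel = "augment"`, Rasch with a
common prior): the Rasch response can be written with logistic latent
variables, $x_i = 1 \iff z_i + \delta_i < \theta$. Draw the joint vector
$w = (z_1 + \delta_1, \ldots, z_k + \delta_k,\ \theta)$ *once*; every
component $w_j$ is then a candidate proposal with realized statistic
$s_j = \#\{i \ne j : w_i < w_j\}$. For distinct components the $s_j$ are a
permutation of $\{0, \ldots, k\}$, so a candidate with $s_j$ exactly equal
to the observed score always exists and is offered with exchange ratio
$\exp[(\theta^* - \theta')(x_+ - s_j)] = 1$. One joint draw thus yields a
near-certain move however large $k$ is, while plain SVE degrades as the
posterior concentrates.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `m` | proposals per oversampled update | 1 | 1 = plain SVE; 5–20 gives most of the gain for a 20-item test |
| `half_width` (`a`) | bin half-width on the statistic scale | `Inf` | `Inf` = plain SVE; 2–5 score units suits a 20-item weighted score |
| `iterations` | sweeps (or i.i.d. draws for `"recycle"`) | 10^4 | acceptance-rate SE below half a point at typical rates |
| `burn` | fraction of sweeps the summaries discard | 0.1 | independence proposals converge fast; 10% is conservative |
| `max_tries` | cap per binned proposal | 10^5 | surfaces unreachable bins instead of hanging |
| prior | common $N(0,1)$ unless specified | `normal_prior()` | the conventional latent-ability scale |

## The synthetic-data generator and the packaged scenarios

`generate_fixture()` draws persons from the prior and responses from the
model — exactly the composite scheme behind the proposals — so fixtures
are by construction consistent with the sampler's assumptions. The
packaged scenarios (`run_scenario()`, `"fig1"`–`"fig6"`) probe the six
regimes of interest: the mixing distribution and plain-SVE acceptance at a
mid-range score; oversampling over $m \in \{1, 5, 20\}$; matching against
independent updates over a grid of $n$; recycling cost over a grid of $n$;
binning under the 2PL for $a \in \{\infty, 5, 3, 2\}$; and augmented
proposals against plain SVE over $k \in \{10, 20, 50\}$.

The reference design fixes $k = 20$ items, a standard normal prior, and an
observed score of 9. Item difficulties are equally spaced on
$[-1.5, 1.5]$ (`reference_difficulties()`). The spread was fixed once, by
quadrature on the prior-predictive score law, so that the design sits in
the regime these scenarios are about: a single mid-range score captures
roughly 8–10% of the proposal mass and about a third of the mass lies more
than four score points away — a moderately informative test whose plain-SVE
acceptance is mediocre and leaves the generalizations visible headroom. A
flat design ($\delta_i = 0$) overdisperses the score distribution and
makes direct hits noticeably rarer; difficulties are configurable
everywhere, and the scenario drivers accept any design. The 2PL scenario
draws its discriminations $\alpha_i \sim U(0, 4)$ once under a fixed,
documented seed (`reference_discriminations()`), and picks a deterministic
observed pattern with raw score 9 and weighted score as close as possible
to 19 (`observed_pattern_2pl()`); the realized $\alpha$ are persisted with
the scenario output since all weighted-score results depend on them.

What the fixtures do *not* emulate: misfit between data and model (the
responses really are Rasch/2PL), uncertainty in item parameters (fixed by
design), missingness, and local dependence between items. Passing tests
therefore demonstrate correctness of the samplers under the model, not
robustness of the Rasch model to real data.

## Numerical and design choices

* All acceptance computations run on the log scale; the exponent is
  clipped at 0 before exponentiation, so no overflow for extreme
  statistic gaps.
* The binned interval is open on both ends, $(t(x) - a, t(x) + a)$.
* Ties — among oversampled candidates at equal distance, among equal
  matching statistics in the sort, among tied augmented candidates — are
  broken uniformly at random with the step's own RNG stream, so no result
  depends on input ordering.
* Randomness uses R's native global RNG: every function is deterministic
  under `set.seed()`, and `sve(..., seed =)` seeds internally. This is
  the R idiom (and what makes `identical()`-level reproducibility tests
  possible); no generator objects are passed around, and nothing is
  parallelized.
* Chain initialization defaults to the prior mean; with independence
  proposals the effect of the start dies out within a handful of accepted
  moves, and summaries discard a 10% burn-in by default.
* `recycling_rejection()` validates that every requested score lies in
  the support $\{0, \ldots, k\}$ before looping, and counts only the
  proposals up to the draw that filled the last outstanding slot.
* Degenerate inputs: saturated items ($|\delta_i|$ huge) give
  deterministic responses; a constant chain reports `NA`
  autocorrelation beyond lag 0 and an effective sample size of 1.

**The augmented correction hook.** For the exact-match candidate the
exchange exponent is zero and the move is accepted outright; this path is
taken with probability one for continuous draws and fully determines the
kernel's headline behavior. Candidates with $s_j \ne x_+$ (reachable only
through the measure-zero tie fallback) formally target a companion model
in which one likelihood factor trades places with the prior, and their
acceptance needs a model-swap correction factor. `augmented_sve_step()`
isolates that factor behind the `log_correction` hook (default 0). A
consequence worth stating plainly: with the default hook the stationary
law of the augmented kernel is the mixture of the candidate conditionals,
which coincides with the target posterior in mean for symmetric designs
(equal items, central score) — the case the test suite checks — but is
not guaranteed distribution-exact for asymmetric ones. Users needing
exactness under asymmetry should supply the correction or use the
`"recycle"` kernel, which is exact by construction for the Rasch score.

## Problem sizes used by the test suite

The stationarity checks run each kernel variant for $2 \times 10^5$
sweeps on a 3-item test against adaptive-quadrature posterior moments
(batch-means standard errors, 3-SE bands); the exact-draw law is checked
by a Kolmogorov–Smirnov test on $10^4$ recycled draws against the
quadrature CDF; acceptance-rate reproductions use $10^4$-sweep chains,
with the $n = 25$ multi-target rates averaged over several fixture
replicates because the realized score multiset, not the chain noise,
dominates their variability. These sizes keep every check's Monte-Carlo
error well inside its tolerance band.

## Known limitations

* Item parameters ($\delta$, $\alpha$, $\beta$, $\sigma^2$) are inputs,
  never estimated.
* Binary responses only; no partial-credit or multinomial constructions.
* The augmented kernel covers the Rasch model under a common prior; its
  non-exact-match correction defaults to unity (see above).
* `m` and `a` are fixed for a run — adapting them on the fly would break
  the fixed-kernel invariance argument.
* Single-chain diagnostics only (acceptance, direct hits,
  autocorrelation, ESS); no cross-chain convergence statistics.
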