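---
title: "Scoring and classifying binary technical replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying binary technical replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binreps)
```

## The model and its assumptions

Each individual $i$ carries a latent binary status $T_i \in \{0,1\}$
(diseased/healthy, contaminated/clean, resistant/susceptible) and is
measured $n_i$ times by the same binary assay. The model assumes:

* $T_i \sim \mathrm{Bernoulli}(\theta_T)$ independently, with
  $\theta_T$ the prevalence;
* given $T_i$, the replicates are independent flips of the truth with
  false-positivity rate $p = P(X = 1 \mid T = 0)$ and false-negativity
  rate $q = P(X = 0 \mid T = 1)$, so that the positive count satisfies
  $S_i \mid T_i \sim \mathrm{Binomial}(n_i,\; T_i(1-q) + (1-T_i)p)$;
* $p, q \in (0, 1/2)$: a replicate is more often right than wrong.
  Besides being the only regime in which replication is worth doing,
  this constraint is what identifies the mixture — without it, the
  relabelled solution $(1-\theta_T,\, 1-q,\, 1-p)$ fits the data
  identically. `model_params()` enforces it, and both fitting routines
  keep their iterates inside it, so label switching never needs
  post-hoc resolution.

Replicates within an individual are exchangeable, so $(n_i, S_i)$ is
sufficient; `replicate_data` objects store nothing else (plus an
optional gold-standard status). Missing replicate values and
individual-level covariates are out of scope.

## The four scores

* $Y_{A,i} = S_i/n_i$ and the replicate median
  $Y_{M,i} \in \{0, 1/2, 1\}$ (with $1/2$ at even-$n$ ties) need no
  model. They coincide whenever $n_i \le 2$.
* The likelihood-based score at known parameters is the posterior
  probability of the positive status,
  $$Y_{L,i}(\theta_T, p, q) = \frac{\theta_T\, q^{\,n_i-s_i}(1-q)^{s_i}}
    {\theta_T\, q^{\,n_i-s_i}(1-q)^{s_i} + (1-\theta_T)\, p^{s_i}(1-p)^{\,n_i-s_i}},$$
  strictly increasing in $s_i$ at fixed $n_i$.
* The MAP score plugs the penalized-likelihood estimate from
  `fit_map()` into $Y_L$; the Bayesian score from `fit_bayes()`
  integrates $Y_L$ over the posterior of $(\theta_T, p, q)$, which is
  the posterior probability $P(T_i = 1 \mid S_1,\dots,S_N)$ given the
  whole dataset.

The median is itself a limit of the Bayesian score: a prior
concentrated near $(\theta_T, p, q) = (1/2, 0, 0)$ makes
$Y_B \approx Y_L(1/2, 0, 0)$, which equals the median score (the test
suite demonstrates this with the prior
$a_T = b_T = 200$, $a_{FP} = a_{FN} = 2$, $b_{FP} = b_{FN} = 200$).

## Penalized likelihood and the EM algorithm

The observed-data likelihood
$L(\theta_T, p, q) = \prod_i \{\theta_T (1-q)^{s_i} q^{n_i-s_i} +
(1-\theta_T) p^{s_i} (1-p)^{n_i-s_i}\}$ admits degenerate maxima at
$p = 0$ or $q = 0$; independent $\mathrm{Beta}(2,2)$ penalties on $p$
and $q$ remove them. There is deliberately **no** penalty on
$\theta_T$. The EM steps are then closed-form: the E-step sets the
responsibilities $\gamma_i = Y_{L,i}$ at the current parameters, and
the M-step is the weighted-MAP update in which each Beta(2,2) penalty
contributes one pseudo-success and one pseudo-failure:
$$\theta_T = \tfrac{1}{N}\sum_i \gamma_i,\qquad
  q = \frac{\sum_i \gamma_i (n_i - s_i) + 1}{\sum_i \gamma_i n_i + 2},\qquad
  p = \frac{\sum_i (1-\gamma_i) s_i + 1}{\sum_i (1-\gamma_i) n_i + 2},$$
with $p, q$ clipped into $[\varepsilon, 1/2-\varepsilon]$,
$\varepsilon = 10^{-6}$. Because the clipped point is still the
constrained maximizer of the concave M-step objective, the penalized
log-likelihood is non-decreasing across iterations even when clipping
triggers — a property the test suite asserts on every run.

Defaults and why:

* `tol = 1e-8` on the change in penalized log-likelihood,
  `max_iter = 500` — the objective is cheap, so a tight tolerance costs
  little.
* `n_starts = 8`: one moment-based start (prevalence from the mean
  median score; error rates from the ratio estimators evaluated at the
  median scores) plus seven random starts. Mixture likelihoods have
  local optima; on the datasets in the test suite the moment start
  almost always wins, but the random restarts are kept as insurance.
* At least one $n_i \ge 3$ is needed for the three parameters to be
  well identified; `fit_map()` warns (does not fail) when all
  $n_i \le 2$.

The EM optimum is validated in the tests against brute-force
maximization of the same objective on a $0.01$ grid.

## The Bayesian model and the Gibbs sampler

Priors: $\theta_T \sim \mathrm{Beta}(a_T, b_T)$ on $(0,1)$;
$p \sim \mathrm{Beta}(a_{FP}, b_{FP})$ and
$q \sim \mathrm{Beta}(a_{FN}, b_{FN})$, both truncated to $(0, 1/2)$.
The defaults are $a_T = b_T = 1/2$ (Jeffreys-style, minimally
informative about prevalence) and $a_{FP} = b_{FP} = a_{FN} = b_{FN} = 2$
for the error rates: replication exists because measurements are noisy,
so mass near $p = 0$ or $q = 0$ — where likelihood-based scoring
degenerates — is deliberately down-weighted relative to a uniform or
Jeffreys prior.

Augmenting with the latent statuses makes every full conditional
conjugate:

1. $T_i \mid \text{rest} \sim \mathrm{Bernoulli}(Y_{L,i})$;
2. $\theta_T \mid T \sim \mathrm{Beta}(a_T + \sum T_i,\; b_T + N - \sum T_i)$;
3. $p \mid \text{rest} \sim \mathrm{Beta}(a_{FP} + \sum_{T_i=0} s_i,\;
   b_{FP} + \sum_{T_i=0}(n_i - s_i))$ truncated to $(0, 1/2)$;
4. $q \mid \text{rest}$ likewise with the roles of positives and
   negatives for the $T_i = 1$ group.

Truncated-Beta draws use exact inverse-CDF sampling on
$(0, F(1/2))$ — no rejection loop, so a fixed seed yields a
bit-identical draw sequence of fixed length. Chains are initialized
with $T$ set from the median scores and parameters drawn from the
prior. Defaults `n_iter = 6000`, `burn_in = 1000`, `thin = 1`,
`chains = 4` give 20000 kept draws in well under a second at
$N \le 200$; split-chain potential-scale-reduction above 1.01 raises a
warning, never an error. Seeded calls save and restore the caller's
RNG state, so a fit inside a replication loop does not derail the
loop's own stream.

Bayesian per-individual scores use the Rao–Blackwellized form — the
average of $Y_{L,i}$ over the kept parameter draws — rather than the
raw frequency of $T_i = 1$ among the latent draws; both are available
and agree within Monte-Carlo error, but the Rao–Blackwellized version
has smaller variance.

**The quadrature oracle.** `grid_posterior()` integrates the posterior
on a midpoint grid over $(\theta_T, p, q)$ with the latent statuses
summed out analytically through the mixture likelihood. It is
deterministic and Monte-Carlo-free, which makes it the independent
reference the Gibbs sampler is tested against (agreement within 0.02 on
all posterior means and all per-individual scores for small datasets).
One numerical caveat: the default Beta(1/2, 1/2) prevalence prior has
integrable endpoint singularities, so midpoint quadrature converges
more slowly under it ($\sim 10^{-3}$ shifts when halving a 0.01 step)
than under smooth priors ($< 10^{-4}$); both regimes are well inside
the 0.02 comparison tolerance. The node count is capped at $10^7$.

## Decisions with an indecision response

Scores become decisions through
$\Phi(y) = 0,\ 1/2,\ 1$ for $y < v_L$, $v_L \le y \le v_U$, $y > v_U$.
The indecision band is **closed**: average scores hit rational
thresholds exactly, and a score sitting on the cut is, by construction,
a case where the evidence equals the cost-indifference point, so the
cautious response is returned. Ties in expected risk are resolved the
same way (toward $1/2$).

Given the loss table (indecision costs $a$ under truth 0 and $d$ under
truth 1; misclassification costs $b$, $c$), indecision is ever optimal
iff $bc/(b+c) > a + (d-a)b/(b+c)$ and $-b < d-a < c$
(`indecision_condition()`), and then the risk-minimizing cuts are
$v_L = a/(c-(d-a))$, $v_U = (b-a)/((d-a)+b)$. For the symmetric loss
$\ell_a$ ($b = c = 1$, $d = a$) this is $(a, 1-a)$, requiring
$a < 1/2$. The test suite verifies the formulas against brute-force
risk minimization over a fine grid of $P(T=1)$ for random valid loss
tables.

Under indecision, sensitivity and specificity count only committed
correct decisions — an indecision is an error whichever the truth — and
the empirical risk is exposed on both the per-individual mean scale and
the dataset sum scale ($N$ times the mean); reported risks on real
datasets are sometimes quoted on the sum scale, so neither is
privileged.

With $n_0$ the largest replicate count,
$\delta_0 = 1/(2n_0)$ ($n_0$ odd) or $1/(2(n_0-1))$ ($n_0$ even)
bounds the agreement band: thresholds inside
$(1/2-\delta_0,\, 1/2+\delta_0)$ make the average- and median-based
classifiers provably identical, because no attainable average score
separates them there (`agreement_band()`).

## Estimation and prediction

Prevalence: the mean score for A/M/MAP, the posterior mean of
$\theta_T$ for B. The average-based estimator has exact bias
$p - \theta_T(p+q)$, independent of the $n_i$; the median-based bias is
computed exactly from binomial tails
($E[Y_M \mid n] = P(S > n/2) + \tfrac12 P(S = n/2)$ in each mixture
component, averaged over the replicate-count distribution) and decays
to zero as replicate counts grow (`bias_average()`, `bias_median()`).
These closed forms double as the deterministic reference curves for the
simulation studies, replacing derivations that would otherwise be
needed for the variance of the estimators — which this package covers
empirically, by replication, rather than analytically.

Error rates are estimated by the ratio estimators
$\hat p = \sum S_i(1-Y_i) / \sum n_i(1-Y_i)$,
$\hat q = \sum (n_i-S_i)Y_i / \sum n_i Y_i$; when every score is 0 or
every score is 1 the corresponding estimator is reported as missing
with an explanatory flag rather than silently returning 0/0. With a
gold standard, the same formulas at $Y = T$ give the latent-status
estimates (`latent_estimates()`), an identity the tests assert exactly.

Prediction for a new individual evaluates $Y_L$ at plug-in estimates
(A/M/MAP) or averages it over posterior draws (B); the latter carries
parameter uncertainty and is therefore less over-confident.
`prediction_table()` renders the practitioner-facing rule: one decision
per (replicate count, positive count) pair.

## The synthetic-data generator

`simulate_replicates()` draws from the model itself: statuses
$\mathrm{Bernoulli}(\theta_T)$, counts $n_i$ uniform on $\{2,\dots,6\}$
by default, and $S_i$ binomial with success probability $1-q$ or $p$.
The default study conditions used throughout the tests are
$p = 0.1$, $q = 0.05$, $n_i \sim U\{2,\dots,6\}$, with $N = 200$
individuals per dataset for the replication studies. Two stress
scenarios extend it:

* `f_single`: a fixed fraction of individuals observed once —
  the regime where scores carry almost no information and only the
  model-based methods can borrow strength across individuals;
* `sigma > 0`: heterogeneous error rates
  $p_i = 0.5\,\mathrm{logistic}(v_i)$, $v_i \sim N(0, \sigma^2)$,
  independently for $p$ and $q$ — every rate stays in $(0, 1/2)$, and
  the fitted model remains the homogeneous one, so the sweep measures
  robustness to misspecification. The sweep default is 10 log-spaced
  $\sigma$ values from 0.01 to 1.

What the generator does **not** emulate: within-individual correlation
beyond the shared latent status, covariate-driven error rates,
rater-specific effects (each replicate is exchangeable), or missing
replicates. Tests passing on this generator therefore certify the
methods under the stated model and its two controlled departures — not
under arbitrary real-world error structures.

Boundary note: the generator accepts $p = q = 0$ (noiseless limit,
useful for sanity checks), which the inference-side `model_params()`
deliberately rejects.

## Problem sizes and numerical choices

The bundled studies run at desk scale, chosen so the whole suite
finishes in about two minutes: 50 datasets per grid point for the bias
and risk sweeps (with a leaner sampler configuration of 1500
iterations, single chain, inside loops), $N = 10^4$ for the
sensitivity/specificity comparison, and 0.01 grids for the quadrature
and maximization oracles. All mixture likelihood evaluations go through
log-sum-exp; scores are never clipped for reporting. One empirical
finding from the risk sweep is worth recording: with 90% singleton
individuals and the symmetric cost $a = 0.45$, all four methods make
identical decisions on the singletons (every score lands on the same
side of the narrow band), so their classification risks coincide up to
Monte-Carlo noise even though the MAP and Bayesian prevalence estimates
remain markedly less biased — the advertised advantage of the
model-based methods in that regime is in estimation, not in
classification risk at these settings.

## Known limitations

* Homogeneous $p, q$ are assumed by all fitted models; heterogeneity is
  only simulated, matching the methods' intended scope.
* The non-Bayesian estimators ship without analytic standard errors;
  uncertainty quantification is the Bayesian module's job.
* The quadrature oracle scales as $(1/\text{step})^3$ and is meant for
  validation at small $N$, not for routine inference.
* No covariates, no missing data, no per-replicate weights.
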