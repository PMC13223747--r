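---
title: "Estimating selection from allele-frequency time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection from allele-frequency time series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplselect)
```

## The inference problem

A bi-allelic locus evolves in a population of constant size $N$. The mutant
allele has Wrightian fitness $1+s$ and alleles mutate symmetrically with
probability $\mu$ per generation. We observe the population at generations
$t_0 < t_1 < \dots < t_K$, but only through finite samples: at $t_k$ we draw
$n_s(t_k)$ individuals and count mutants, so the observed frequency
$\hat{x}(t_k) = c(t_k)/n_s(t_k)$ carries binomial noise on top of the
genetic drift that perturbs the true frequency $x(t_k)$. The goal is to
estimate $s$, and — just as importantly — to understand how precision
depends on the sampling effort $n_s$, the population size $N$, and the
length and shape of the trajectory.

## The estimator

Under the diffusion approximation of the Wright–Fisher process, the
probability of a frequency path factorises into per-interval Gaussian
transition densities with mean displacement
$\Delta t_k\,[s\,v(t_k) + \mu(1-2x(t_k))]$ and variance
$\Delta t_k\, v(t_k)/N$, where $v(t)=x(t)(1-x(t))$ is the allele variance.
Maximising this path likelihood in $s$ has a closed form:

$$
\hat{s}_{\mathrm{MPL}}
 = \frac{x(t_K)-x(t_0)-\mu\sum_{k=0}^{K-1}\Delta t_k\,(1-2x(t_k))}
        {\sum_{k=0}^{K-1}\Delta t_k\, v(t_k)} .
$$

The numerator is the net frequency change with the mutation flux removed;
the denominator is the *integrated variance* $V$, the quantity that
ultimately controls precision. `s_mpl()` implements this on population
frequencies.

With sampled data, substituting $\hat{x}$ for $x$ biases the denominator:
$E[\hat{x}(1-\hat{x})] = v\,(n_s-1)/n_s$ under binomial sampling. Each
denominator term is therefore rescaled by $n_s(t_k)/(n_s(t_k)-1)$
(`estimate_s()`, with `bias_correction = FALSE` recovering the uncorrected
variant). This is why every sample size must be at least 2.

Because the path log-likelihood is *exactly* quadratic in $s$ with
curvature $-N\sum_k \Delta t_k v(t_k)$, the likelihood-ratio confidence
interval is available in closed form:
$\hat{s} \pm \sqrt{\chi^2_{1,\alpha} / (N V_{\mathrm{raw}})}$, centred at
the likelihood argmax on the observed frequencies with the *raw*
(uncorrected) integrated sample variance — the corrected denominator
belongs to the point estimate, not to the likelihood. We use
`qchisq(level, 1)` rather than a rounded 3.84. The interval reflects drift
uncertainty only, since the path likelihood does not model sampling; this
is the same approximation made when the interval is applied to real data.

## Performance theory

For a fixed population trajectory observed with constant $n_s$ and
$\Delta t$, the numerator $\hat{D}$ and corrected denominator $\hat{V}$
have *exact* first and second moments under binomial sampling — the
formulas implemented in `var_D()`, `cov_DV()` and `var_V()` are not
asymptotic, a fact the test suite verifies by exhaustively enumerating all
count outcomes for small designs. The printed form of the `var_V()`
coefficient is $4 - 2/(n_s-1)$; enumeration pins down this reading
unambiguously.

The ratio $\hat{s} = \hat{D}/\hat{V}$ is then handled by a first-order
Taylor expansion about the means (`var_s_sampling()`), giving the
sampling-only variance with scale $O(n_s^{-1} V^{-2})$. Under drift, the
estimator applied to perfectly-read Wright–Fisher paths is unbiased to
first order, its Fisher information is $N V$, and the Cramér–Rao bound
$1/(NV)$ (`crlb_drift()`) is close to attained for moderate $N$. The two
noise sources behave as uncorrelated, so
`var_total()` $= \sigma_s^2 + 1/(NV)$ tracks the joint-noise Monte-Carlo
variance; `theory_report()` assembles all components.

Two practical consequences follow. First, sampling noise fades as
$V^{-2}$ but drift only as $V^{-1}$: on long polymorphic trajectories
drift dominates, and heavy per-time-point sampling buys little. Second,
the theory turns into a detection-power statement: under the Gaussian
approximation of the estimator distribution (`gaussian_approx()`), the
smallest coefficient detectable at the 5% level solves
$\mathrm{Var}[\hat{s}] = (s_{\min}/2)^2$, a fixed-point problem because
the trajectory — and hence $V$ — depends on the candidate $s$.
`min_detectable_s()` solves it on the exact deterministic trajectory; at
$N=1000$, $n_s=20$, $\Delta t=10$, $x_0=0.1$, $\mu=10^{-3}$ it returns
about 4.2% for $T=50$ generations and about 1.5% for $T=150$ (the
acceptance script recomputes both).

### Accuracy limits of the first-order theory

The identities $E[\hat{s}] = \hat{s}_{\mathrm{MPL}} = s$ hold to first
order only, and three distinct higher-order effects are visible at desk
scale. They are worth being precise about, because a Monte-Carlo run with
$10^4$–$10^5$ replicates has a standard error *smaller* than these
systematic terms:

* **Model curvature.** The exact per-generation recursion differs from its
  linearisation at relative order $s x$; on the standard study trajectory
  ($s=0.02$, $x_0=0.1$, $T=450$) $\hat{s}_{\mathrm{MPL}}$ of the exact
  deterministic path sampled at $\Delta t = 10$ is 0.0195, about 2.5%
  below the generating value. Exact recovery (to machine precision) holds
  on the linearised path sampled at every generation — that is the regime
  in which the estimator is derived.
* **Ratio curvature.** $E[\hat{D}/\hat{V}]$ exceeds
  $E[\hat{D}]/E[\hat{V}]$ by
  $(\hat{s}_{\mathrm{MPL}}\mathrm{Var}[\hat{V}] -
  \mathrm{Cov}[\hat{D},\hat{V}])/V^2$; the theory tests verify that adding
  this second-order term reconciles the analytic mean with the Monte-Carlo
  mean to within its standard error.
* **Order-statement drift.** The $V^{-2}$ and $V^{-1}$ scalings are
  asymptotic orders, not fitted slopes: across $T = 50,\dots,450$ the
  endpoint variances in $\mathrm{Var}[\hat{D}]$ change with $T$ and the
  CRLB tightness improves from roughly 1.35× to 1.07×, so finite-range
  log–log slopes come out near $-2.2$ and $-1.1$ rather than exactly
  $-2$ and $-1$.

None of this changes the practical message — the bias is a couple of
percent *of s* under the hardest settings — but tests comparing the
first-order formulas to large simulations must budget for these terms,
and ours do so explicitly.

## The simulators (what the synthetic data does and does not emulate)

`sim_trajectory()` provides the stochastic Wright–Fisher model (binomial
reproduction with the selection–mutation success probability; the state is
kept as an integer count internally so frequencies are exact multiples of
$1/N$) and the deterministic model in exact and linearised variants.
`observe()` adds binomial sampling at chosen times, with fixed or
Poisson-distributed sample sizes; Poisson draws below 2 are redrawn, since
a sample of 0 or 1 leaves both the observed frequency uninformative and
the bias correction undefined. Sampling is binomial even when $n_s$
approaches $N$ — i.e. sampling with replacement — which is the standard
observation model here; we document rather than "fix" this.

Defaults throughout ($N=1000$, $s=0.02$, $\mu=10^{-3}$, $x_0=0.1$,
$T=450$, $\Delta t=10$, $n_s=20$) are the canonical study conditions for
this estimator family. What the generator does *not* emulate: population
structure, time-varying $N$ or $s$, asymmetric mutation, linked or
epistatic loci, and overdispersed (non-binomial) sequencing noise. Passing
tests therefore certify the estimator under the model it is derived for,
not robustness to these violations.

Every stochastic entry point takes a single integer `seed`; ensembles are
advanced one generation at a time across all replicates by vectorised
binomial draws, so one root seed deterministically governs the whole
ensemble and reruns are bit-identical. `mc_sampling_only()`,
`mc_drift_only()` and `mc_joint()` report the replicate count, mean,
variance, both Monte-Carlo standard errors (the SE of the variance via the
fourth central moment) and `n_failed`, the replicates whose observed
integrated variance was zero (lost or fixed trajectories observed at the
boundary); such replicates are excluded from moments and always counted.
At the default conditions losses are rare and this exclusion moves moments
by less than one standard error.

## The HMM benchmark

`fit_s_ls()` implements the estimator that *does* model sampling: hidden
states are the $D=100$ midpoints of a uniform frequency grid, transitions
discretise the same Gaussian path density (rows renormalised — the
discretised density does not sum to one by itself), emissions are binomial
pmfs, and the likelihood is computed by the forward algorithm. We use the
scaled form of the forward recursion (normalising the forward vector each
step and accumulating log normalisers), which is algebraically the
log-space computation and cannot underflow. The 1-D Nelder–Mead maximiser
runs at tolerance $10^{-4}$ (both parameter and objective), initialised at
the closed-form estimate.

The initial hidden state deserves care: the likelihood conditions on the
initial frequency. With real data only $\hat{x}(t_0)$ is available, so the
default places a point mass on its bin (`init_prior = "uniform"` is the
agnostic alternative). In simulation benchmarks the true $x_0$ is known
and should be supplied via the `x0` argument — anchoring the HMM at a
noisy first observation instead puts it at a substantial artificial
disadvantage in paired comparisons with the closed-form estimator, which
treats all time points symmetrically. With the faithful initialisation the
two estimators' RMSEs agree within about 1% on long ($T=450$)
trajectories.

## Numerical choices and degenerate inputs

* **Boundary time points.** In the closed-form estimator, terms with
  $v(t_k)=0$ contribute zero and need no special treatment; an error is
  raised only when the whole denominator vanishes ("uninformative
  observation" for sampled data, "monomorphic trajectory" for population
  data). In the log-likelihood a boundary time point would divide by zero,
  so those transitions are dropped with a warning naming the generations,
  erroring only if nothing remains.
* **Quantisation constant.** The path density's frequency-quantisation
  factor is omitted from `mpl_loglik()`; it does not depend on $s$, so
  argmaxes and likelihood ratios are unchanged.
* **Detection-limit root.** `min_detectable_s()` scans 80 log-spaced
  candidates for the first sign change of $\mathrm{var\_total}(s)-(s/2)^2$
  and bisects inside that subinterval (tolerance $10^{-5}$). The scan
  exists because the full variance expression keeps the
  $\hat{s}_{\mathrm{MPL}}^2\mathrm{Var}[\hat{V}]/V^2$ term, which makes
  the objective non-monotone near $s \approx 1$; the smallest root is the
  scientifically meaningful one.
* **Linearised update clipping.** The linear deterministic step can exit
  $[0,1]$ for extreme parameters; it is clipped with a warning so that
  downstream variance terms stay defined.
* **KL estimator.** `kl_to_standard_normal()` standardises the sample and
  uses Scott's-rule histogram bins against exact normal bin masses
  (far-tail masses computed in the matching tail of `pnorm` to avoid
  cancellation). Its seed-to-seed spread is about $10^{-4}$ nats at
  $10^5$ samples — comparisons between settings whose true divergences
  differ by less than that are not resolvable at that scale.
* **Heterogeneous steps.** All estimator formulas accept per-interval
  $\Delta t_k$; the HMM rebuilds the transition matrix per step when steps
  differ.

## Problem sizes

The shipped tests run the full pipeline at the standard study conditions
with $10^4$ replicates for means, the CRLB check and scaling regressions,
$10^5$ for distribution-shape checks, 1000 paired replicates for the
HMM-vs-closed-form comparison, and exhaustive enumeration (all
$(n_s+1)^{K+1}$ outcomes, $n_s \le 6$, $K \le 3$) for the moment
formulas. These sizes resolve all first-order effects and the
second-order corrections discussed above.

## Known limitations

The estimator and its theory inherit the diffusion regime: $s$ and $\mu$
of order $1/N$, moderate $\Delta t$, and trajectories away from fixation.
Once the mutant fixes, $V$ plateaus and further observations add no
information. The confidence interval ignores sampling noise by
construction and is therefore slightly anticonservative for very small
$n_s$. The codominant-diploid mapping (`diploid_adapter()`) covers
additive fitness (1, $1+s$, $1+2s$) only — dominance requires a different
dynamic and is out of scope, as are multi-locus systems with linkage or
epistasis.
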