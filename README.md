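# mplselect

Selection-coefficient inference from allele-frequency time series, for
population geneticists and evolve-and-resequence analysts who observe a
locus repeatedly over generations through finite samples.

Two noise sources confound such inference: **limited sampling** (only
`ns(t_k)` of the `N` individuals are genotyped at each time point, making
the observed frequency a binomial draw around the truth) and **genetic
drift** (the true frequency itself fluctuates because `N` is finite).
`mplselect` implements a closed-form estimator derived from the marginal
path likelihood (MPL) — the Gaussian path approximation of the
Wright–Fisher diffusion — together with the analytical machinery needed to
understand and predict its precision under both noise sources.

## The estimator

For frequencies `x(t_0), ..., x(t_K)` with allele variance
`v(t) = x(t)(1 − x(t))` and sampling steps `Δt_k`:

```
        x(t_K) − x(t_0) − μ Σ_k Δt_k (1 − 2 x(t_k))
ŝ_MPL = ────────────────────────────────────────────
                  Σ_k Δt_k v(t_k)
```

— the net frequency change minus the mutation flux, divided by the
*integrated variance* `V = Σ_k Δt_k v(t_k)`. With sampled counts, each
denominator term gets the unbiasing factor `ns/(ns − 1)` (the sample
allele variance is biased low under binomial sampling). Key results
implemented here:

* the sampling-noise moments of numerator and denominator are **exact**
  closed forms, and the sampling-only estimator variance scales as
  `O(ns⁻¹ V⁻²)`;
* under drift the Fisher information is `N·V`, so the drift-only variance
  is bounded by (and nearly attains) the Cramér–Rao bound `1/(N·V)`;
* total variance ≈ sampling-only + drift-only, so on long polymorphic
  trajectories drift dominates — sampling harder per time point buys
  little compared with sampling longer;
* the likelihood-ratio 95% confidence interval is
  `ŝ ± sqrt(qchisq(.95, 1)/(N·V_raw))` (the path log-likelihood is exactly
  quadratic in `s`);
* the minimum detectable selection coefficient solves
  `Var[ŝ] = (s_min/2)²`;
* a grid-HMM benchmark estimator (Gaussian transitions on a 100-bin
  frequency grid, binomial emissions, forward algorithm, Nelder–Mead)
  that *does* model sampling, for head-to-head comparisons.

## Worked example

```r
library(mplselect)

# one Wright-Fisher trajectory (N = 1000, s = 0.02), observed every 10
# generations with 20 sampled individuals per time point
traj <- sim_trajectory(N = 1000, s = 0.02, mu = 1e-3, x0 = 0.1,
                       generations = 450, model = "wf", seed = 1)
obs  <- observe(traj, dt = 10, ns = 20, seed = 36)

estimate_s(obs, mu = 1e-3, N = 1000)
#> MPL selection-coefficient estimate
#>   s_hat       :  0.019952 (bias-corrected)
#>   95% CI      : ( 0.012228,  0.029776)   [likelihood ratio, N = 1000]
#>   numerator D :  1.048000
#>   denominator V: 52.526316
#>   time points : 46 (generations 0-450), mu = 0.001

fit_s_ls(obs, N = 1000, mu = 1e-3, x0 = 0.1)   # HMM benchmark
#> Grid-HMM selection-coefficient estimate
#>   s_ls      :  0.020451
#>   loglik    : -79.7102  (6 evaluations, converged)
#>   grid bins : 100, N = 1000, mu = 0.001, init = point
```

From 920 binomially sampled alleles (46 × 20) the estimator recovers the
generating coefficient 0.02 to the third decimal, with a likelihood-ratio
interval of roughly ±0.009 reflecting drift uncertainty at `N = 1000`;
the sampling-aware HMM lands on essentially the same value. The analytic
side predicts this precision without simulation:

```r
det <- sim_trajectory(s = 0.02, mu = 1e-3, x0 = 0.1, generations = 450,
                      model = "det_exact")
theory_report(det, dt = 10, ns = 20, N = 1000, mu = 1e-3)
#> # A tibble: 1 x 8
#>   mean_s   var_D  cov_DV var_V var_s_sampling crlb_drift var_total     V
#> 1 0.0195 0.00677 -0.0495  9.85     0.00000423  0.0000184 0.0000227  54.3
```

i.e. a predicted standard deviation of `sqrt(2.27e-5) ≈ 0.0048`, of which
drift (`1/(N·V) = 1.84e-5`) contributes four times the share of sampling
noise. Power analysis is one call:

```r
min_detectable_s(N = 1000, ns = 20, dt = 10, T = 50)    # 0.0415
min_detectable_s(N = 1000, ns = 20, dt = 10, T = 150)   # 0.0149
```

Tripling the observation window more than halves the detectable effect.

A thin command-line front end wraps the same functions
(`exec/mplselect` with subcommands `simulate`, `observe`, `estimate`,
`hmm-estimate`, `theory`, `power`, `mc`); TSV schemas are
`generation / frequency` for trajectories and
`generation / sample_size / mutant_count` for observations.

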