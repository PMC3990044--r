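---
title: "Functional vs. statistical G×G: models, simulations and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional vs. statistical GxG: models, simulations and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxgcoev)
```

## The problem

Coevolution between hosts and parasites requires *functional*
genotype-by-genotype (G×G) interactions: the outcome of an encounter must
depend jointly on both genotypes, so that evolutionary change in one species
reshapes selection on the other. Empiricists, however, usually measure
*statistical* G×G — the host×parasite interaction variance component of a
factorial reciprocal cross-infection experiment. Statistical G×G is a
population-level quantity: it depends on the genotype frequencies at the
moment of sampling, not only on the infection mechanism. This package
simulates the full chain — mechanism, coevolutionary dynamics, sampling
design, ANOVA — so the two notions can be connected quantitatively, and
implements a likelihood-based alternative that confronts candidate
mechanistic models with the cross-infection data directly.

## Functional models of infection

A functional model is a $K \times K$ matrix $\alpha$ of infection
probabilities, host genotypes in rows, parasite genotypes in columns
(`infection_matrix()`):

* **MA** (matching alleles): $\alpha = I$; a parasite infects only the host
  genotype it matches.
* **IMA** (inverse matching alleles): $\alpha = 1 - I$; molecular
  recognition of a matching parasite triggers defense, so infection succeeds
  everywhere *except* the diagonal.
* **GFG** (gene-for-gene): implemented in the nested multi-level form — host
  genotype $i$ carries resistance level $r_i = i-1$, parasite genotype $j$
  virulence level $v_j = j-1$, and infection succeeds iff $v_j \ge r_i$.
  This is the standard multi-level GFG geometry with exactly $K$ genotypes
  per species from a single locus, and levels carry multiplicative fitness
  costs $(1-\tau_h)^{r_i}$ and $(1-\tau_p)^{v_j}$.
* **CONST** and **ADDITIVE**: controls without functional G×G. `CONST` is a
  flat matrix; `ADDITIVE` is $\mathrm{clamp}(\beta_i + \gamma_j, 0, 1)$,
  which has main effects but (absent clamping) no interaction.

$\alpha$ is stored as probabilities rather than binary outcomes so that an
assay error rate can be layered on by the experiment module without touching
the model definitions. The model registry is deliberately open: any
probability matrix can be passed wherever an `infection_matrix` is accepted,
so alternative GFG parameterizations drop in without changes elsewhere.

The analytic bridge between mechanism and measurement is the
frequency-weighted two-way decomposition
(`interaction_variance_components()`): with host frequencies $p$ and
parasite frequencies $q$,
$$\mu = \textstyle\sum_{ij} p_i q_j \alpha_{ij},\qquad
a_i = \textstyle\sum_j q_j \alpha_{ij} - \mu,\qquad
b_j = \textstyle\sum_i p_i \alpha_{ij} - \mu,$$
$$e_{ij} = \alpha_{ij} - \mu - a_i - b_j,\qquad
\sigma^2_{G\times G} = \textstyle\sum_{ij} p_i q_j\, e_{ij}^2 .$$
The decomposition is exact and the weighted main effects average to zero.
It makes the central point analytic: for IMA with $K=2$,
$\sigma^2_{G\times G} = 0.25$ at even parasite frequencies but nearly 0 at
$q = (0.99, 0.01)$ — same mechanism, different population.

```{r decomposition}
ima <- infection_matrix("IMA", 2)
interaction_variance_components(ima, c(.5, .5), c(.5, .5))$var_interaction
interaction_variance_components(ima, c(.5, .5), c(.99, .01))$var_interaction
```

## Coevolutionary dynamics

`run_simulation()` iterates a discrete-generation recursion per species:
selection, then symmetric mutation, then (optionally) drift as one
multinomial draw of $N$ individuals. Fitness is mean-field — each individual
meets the partner population in proportion to its genotype frequencies:
$$w_h[i] = \Big(1 - s_h \sum_j q_j \alpha_{ij}\Big)(1-\tau_h)^{r_i},\qquad
w_p[j] = \Big(1 - s_p \sum_i p_i (1-\alpha_{ij})\Big)(1-\tau_p)^{v_j}.$$
The parasite is penalized for *failing* to infect. The scheme is the
standard Wright–Fisher-with-selection construction; mean-field fitness is
the usual choice at $N = 10^5$ and is what makes 1000-generation runs cheap.

Defaults (all overridable in `sim_params()`): $N = 100{,}000$,
$\mu = 10^{-5}$, $K = 3$, strong selection $s_h = 0.67$, $s_p = 0.69$
(moderate: $0.37/0.39$), GFG costs $\tau_h = 0.12$, $\tau_p = 0.09$
(moderate: $0.08/0.05$), 1000 generations. `selection = FALSE` zeroes all
fitness effects (the no-coevolution control); `drift = FALSE` gives the
deterministic infinite-population recursion. Both modes are provided because
either could underlie a study at this $N$; drift is the default. Initial
frequencies are uniform $1/K$ plus a seeded perturbation of magnitude 0.01,
so deterministic runs leave the unstable symmetric equilibrium; numerical
negatives below $10^{-12}$ are clamped and renormalized.

Under MA/IMA with strong selection, negative frequency-dependent selection
drives large-amplitude cycles in which genotypes repeatedly approach
fixation — the dynamical regime that decouples statistical from functional
G×G.

## The simulated experiment

`longitudinal_survey()` mimics the empiricist: every 20 generations
(inclusive of generation 0), sample 30 host and 30 parasite isolates,
challenge all pairs with 5 trial exposures, replicate the factorial 5
times. Isolates are drawn with replacement from the genotype frequencies
(the infinite-population approximation; at 30 of 100,000 the error is
negligible) and the five replicates share isolates — replication is the
within-cell error stratum, not a fresh sample. Each cell count is
$\mathrm{Binomial}(5, \pi')$ with
$\pi' = \pi(1-\varepsilon) + (1-\pi)\varepsilon$, where $\varepsilon$ is the
assay misclassification rate.

`experiment_design()` defaults to $\varepsilon = 0$, which with 0/1
matrices makes cells deterministic. The *study* scenarios instead use
$\varepsilon = 0.1$: a non-trivial assay error is what produces the
empirically ubiquitous situation in which the error component dominates the
interaction component, and 10% misclassification is a realistic figure for
scoring infection phenotypes. This is a fixed property of the study
conditions, not a tuning knob.

## Variance partitioning

`anova_decompose()` solves the balanced two-way random-effects
expected-mean-squares equations in closed form
($\hat\sigma^2_e = MS_E$, $\hat\sigma^2_{G\times G} = (MS_{AB}-MS_E)/n$,
etc.), truncating negative solutions at zero while retaining the raw values
— truncation bias is itself part of the detection story. REML (via lme4) is
available as a cross-check. Two response scales are exposed:

* `"count"` (default): the per-cell number of infections in 5 trials,
  matching how such experiments are usually scored;
* `"binary"`: one 0/1 outcome per trial. On this scale the error component
  is the within-cell Bernoulli variance $\approx \varepsilon(1-\varepsilon)$
  and component magnitudes are comparable across designs. The count scale
  multiplies interaction variance by $t^2$ but error variance only by $t$,
  so cross-component comparisons (e.g. error vs. interaction dominance) are
  made on the binary, infect-vs-resist scale.

`expected_components()` is the infinite-sample oracle: isolates are i.i.d.
genotype draws, so the expected host/parasite/interaction components are the
frequency-weighted decomposition of $t\,\pi'$ and the expected error
component is the mean within-cell binomial variance. The test suite checks
the estimator against this bridge and against a brute-force sums-of-squares
oracle (agreement to $10^{-10}$).

## Likelihood-based inference

`log_likelihood_exact()` evaluates, for a candidate hypothesis
(model family, $K$, frequencies $f, g$, error rate $\varepsilon$),
$$L = \sum_{z} \prod_g f_{z_g} \prod_h g_{z_h}
\prod_{g,h,r} \mathrm{Binom}(y_{ghr};\, t,\ \pi'_{z_g z_h}),$$
the sum running over all joint assignments of latent genotypes to isolates.
It is exact but exponential; the guard $K^{G+H} \le 10^7$ restricts it to
small instances (internally one margin is marginalized analytically, which
is algebraically identical and much faster). $\varepsilon > 0$ keeps $L$
finite on data containing outcomes a 0/1 matrix forbids; the default is
0.01.

`fit_model()` maximizes over $f$ and $g$ (optionally $\varepsilon$) with a
mean-field variational EM: each isolate carries a posterior over the $K$
genotypes; host posteriors are updated holding parasite posteriors fixed and
vice versa, frequencies are refreshed from posterior means, and every
coordinate update provably cannot decrease the evidence lower bound (ELBO),
which is asserted at each iteration. Exact EM is intractable here because
row and column assignments couple; the coordinate scheme is the natural
variational relaxation, and exact enumeration remains available as the
small-instance oracle. Ten restarts (first uniform, rest random) with
absolute ELBO tolerance $10^{-8}$ are the defaults. On instances inside the
enumeration guard the reported `logLik` is the exact likelihood at the
fitted parameters; otherwise it is the ELBO, a lower bound, and the fit is
flagged accordingly — comparisons within one table therefore use a
consistent objective.

`compare_models()` ranks hypotheses by $AIC = 2k - 2\log L$; the number of
segregating genotypes is selected by fitting each candidate $K$ and
comparing AIC, without trans-dimensional machinery. Parameter counts:
$2(K-1)$ for matrix models, 1 for `CONST` (its constant infection
probability has a closed-form MLE; genotype frequencies are not
identifiable under it and are not counted), $+1$ when $\varepsilon$ is
estimated. Likelihood-ratio statistics are reported only for hard-coded
nested pairs — identical hypotheses and same-family pairs with smaller
$K$ — since the 0/1 families cannot represent one another's patterns for
$K \ge 2$; cross-family comparison rests on AIC. AIC ties are broken by
fewer parameters, then input order.

## The study pipeline

`run_study()` orchestrates all scenarios of `default_scenarios()` (MA, IMA,
GFG each at strong and moderate selection, plus the `CONST` and
selection-off controls) from one `study_config()`: simulate, survey,
partition, optionally model-compare; write trajectory and component CSVs
and a manifest JSON holding every seed and parameter. Per-scenario seeds
derive deterministically from the master seed, so reruns are
byte-identical. `summarize_gxg_detection()` reports, per scenario, the
fraction of sampled generations whose $\hat\sigma^2_{G\times G}$ falls
below 5% of the scenario's mean error variance — a scale-free
"detection-failure" threshold tied to the component that dominates every
scenario; the threshold fraction is configurable.

```{r study, eval = FALSE}
cfg <- study_config(seed = 1, N = 10000,
                    design = experiment_design(30, 30, 5, 5,
                                               sampling_interval = 20,
                                               error_rate = 0.1),
                    out_dir = "study_out")
report <- run_study(cfg)
summarize_gxg_detection(report)
plot_scenario(report, "ma_strong")
```

## Problem sizes, numerical choices, and what the tests show

The package's own validation runs the study at $N = 10{,}000$ with 20
replicate studies per comparison — large enough that drift does not disrupt
the selection-driven cycles, small enough that the full suite completes in
minutes. Under those conditions the simulations reproduce, and the tests
assert: (i) strong-selection MA trajectories cycle each genotype above 0.9
and below 0.1; (ii) a substantial fraction of sampled generations shows
negligible statistical G×G, and that fraction is *larger* under strong than
under moderate selection; (iii) the error component exceeds the interaction
component on the binary scale in every coevolution scenario; (iv) the
selection-off control still shows strong statistical G×G. Likelihood-based
model selection recovers the generating model in $\ge 90\%$ of 50
replicates at the 30×30 design.

What the generator does *not* emulate: multi-locus or diploid genetics,
overlapping generations, gene flow, escalatory sweep dynamics, unbalanced
or multi-population designs, and environmental (G×G×E) structure. Passing
tests therefore demonstrate internal consistency of the chain from
mechanism to measurement under these idealizations, not that any particular
empirical system behaves this way.

Numerical conventions collected in one place: frequencies are renormalized
after mutation with negatives below $10^{-12}$ clamped; the ANOVA requires
a complete balanced factorial and $\ge 2$ replicates; negative component
estimates are truncated at zero (raw values retained); likelihood terms at
probability 0 are floored at $e^{-10^{300}}$ so impossible data surface as
$-\infty$ rather than NaN; EM convergence is absolute ELBO change
$< 10^{-8}$ with a 500-iteration cap; the enumeration guard is
$K^{G+H} \le 10^7$.
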