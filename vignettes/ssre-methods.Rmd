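---
title: "Methods: single-sample inference of RNA synthesis, processing and degradation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sample inference of RNA synthesis, processing and degradation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssre)
```

## The kinetic model

A transcript's premature (intron-containing) RNA $p$ and mature RNA $m$
follow the two-stage linear system

$$\dot p = \alpha - \beta p, \qquad \dot m = \beta p - \gamma m,$$

with synthesis rate $\alpha$, processing rate $\beta$ and degradation
rate $\gamma$. During a metabolic-labeling pulse of duration $T$ the RNA
separates into two pools with the same kinetics but different boundary
conditions:

* the **unlabeled** (pre-existing) pool starts at the steady state
  $(\alpha/\beta,\ \alpha/\gamma)$ and decays with no new synthesis;
* the **labeled** (new) pool starts at $(0, 0)$ and grows toward steady
  state.

Both have closed-form solutions (`unlabeled_pool()`,
`labeled_pool()`), verified in the package against numerical
integration (`ode_pool_oracle()`) to $10^{-8}$, and their sum conserves
the steady state to $10^{-10}$.

## The observables

Sequencing yields, per pool, an intronic abundance $\iota$ (premature
only) and an exonic abundance $\chi$ (premature + mature). The two
intron-to-exon ratios

$$a = \iota_u/\chi_u, \qquad b = \iota_l/\chi_l$$

are scale-free: they depend only on $k = \beta/\gamma$ and the
dimensionless time $x = \gamma T$,

$$a(k, x) = \frac{1-k}{1 - k^2 e^{(k-1)x}}, \qquad
  b(k, x) = \frac{(1 - e^{-kx})/k}
                 {(1 - e^{-kx})/k + 1/k\,\bigl(\ldots\bigr)},$$

(`ratio_unlabeled()`, `ratio_labeled()`; the $k = 1$ limits are
removable and implemented by series). For fixed $k$ the pair
$(a(k,x), b(k,x))$ traces a trajectory in the unit square from
$(1/(1+k),\ 1)$ at $x \to 0$ to $(\max(1-k, 0),\ 1/(1+k))$ as
$x \to \infty$ (`trajectory()`).

## Inversion

Model-compatible observations satisfy $a < b < 1$. Solving the
$b$-relation for $x$ and substituting into the $a$-relation leaves one
equation in $k$ (`reduced_equation()`),

$$\frac{k}{k-1}\log\frac{k+a-1}{k^2 a}
  \;=\; \log\frac{b-a}{a\,(bk + b - 1)},$$

whose admissible domain is the open interval
$\max(1/b - 1,\ 1 - a) < k < 1/a - 1$ (`admissible_domain()`). Above
the curve $b = 1/(2-a)$ the root is unique; at or below it up to two
roots exist — both reproduce the observables exactly, a genuine
two-branch ambiguity (`classify_region()`). Given a root $k$,

$$\gamma = \frac{1}{kT}\log\frac{b-a}{a(bk+b-1)}, \qquad \beta = k\gamma,$$

and $\alpha$ follows from the absolute abundances of either pool
(`gamma_from_k()`, `alpha_from_unlabeled()`, `alpha_from_labeled()`).

```{r worked-example}
a <- ratio_unlabeled(0.5, 1)   # generate from k = 0.5, x = 1
b <- ratio_labeled(0.5, 1)
solve_k(a, b)                  # recovers k = 0.5
gamma_from_k(solve_k(a, b), a, b, labeling_time = 1)
```

## Numerical decisions

**Root finding.** The residual diverges at both domain endpoints, and
genuine roots can sit within a few ulps of them (saturated
observables). `solve_k()` therefore scans a dense log-spaced grid
augmented with geometric endpoint ladders, brackets sign changes, and
refines with `uniroot()` — switching to sign-only bisection where the
residual is infinite at an endpoint. Every root is **validated** by
recomputing both observables from $(k, x)$ and requiring agreement to
$10^{-6}$ relative; spurious brackets are discarded.

**$k = 1$.** The factor $k/(k-1)$ times a vanishing logarithm is a
removable singularity, evaluated by a second-order series for
$|k - 1| < 10^{-4}$.

**No-root data.** Noisy observations may admit no exact root. The
estimator then minimizes the squared log-distance between observed and
model ratios over the domain (`objective_reduced()`), reported as
`fallback_optimized`.

**Ambiguity under noise.** Near the $b = 1/(2-a)$ curve, noise can
leave only one branch as an exact root while the *other* branch
survives as a near-exact local minimum of the objective. Local minima
whose squared log-misfit is below $10^{-12}$ (the root-validation
tolerance squared) are therefore pooled with the exact roots as
competing explanations. Multi-candidate cases are resolved in a second
pass against the run's own unambiguous population: the candidate whose
$\log k$ is nearest the population median wins
(`resolve_ambiguity()`), since processing-to-degradation ratios are far
more conserved across transcripts than the rates themselves. On exact
data the minima coincide with the roots and deduplicate away, so
noise-free behavior is unchanged.

**Which pool for $\alpha$.** The unlabeled mature abundance decays like
$e^{-\min(\beta,\gamma) T}$, so reconstructing $\alpha$ from it
amplifies errors in the estimated rates exponentially for fast
transcripts (log-condition number $\sim \beta T$). The labeled pool
approaches the steady state $\alpha/\gamma$ and stays polynomially
conditioned. Benchmarks therefore default to the labeled pool; on real
data, where unlabeled RNA is usually quantified more precisely,
`estimate_rates()` defaults to the unlabeled pool
(`alpha_source = "unlabeled"`).

## Benchmark behavior

```{r benchmark, eval = FALSE}
cfg <- benchmark_config(n_transcripts = 50000, noise_sigma = 0.1, seed = 1)
run_recovery(cfg)
```

With rate triplets log-uniform on $[e^{-5}, e^5]$ and $T = 1$:

* **Noise-free**, unique-root transcripts recover $\beta$ and $\gamma$
  within $10^{-6}$ relative in $\ge 99\%$ of cases; the remainder have
  fully saturated observables ($\gamma T \sim 100$) at the double
  precision floor.
* **Noise sd 0.10**: 64.4% estimable. This is a *protocol ceiling*, not
  a solver property — with four independent $e^{N(0, 0.1)}$ factors,
  35.6% of observations land at $b \ge 1$ or $b \le a$ and are
  rejected before any root finding. Log-rate correlations:
  $\alpha$ 0.96, $\beta$ 0.83, $\gamma$ 0.50. The $\gamma$ tail is
  data-forced: wrong-branch resolutions where both branches fit the
  noisy observables exactly (the simulated $k$ has no population
  clustering to exploit), and honest unique roots in hypersensitive
  regimes where $\partial \log\gamma / \partial \log b$ reaches the
  tens.
* **Noise sd 0.05**: 69.2% estimable, minimum correlation 0.62.

`scripts/acceptance.R` regenerates these numbers from a seed.
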