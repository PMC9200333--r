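---
title: "Methods: multi-agent max-margin reinforcement learning for strain design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-agent max-margin reinforcement learning for strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(strainrl)
```

## The problem

Metabolic engineering tunes the expression of a handful of enzymes so that a
microbe over-produces a target compound. Each Design–Build–Test–Learn (DBTL)
round is expensive — a strain must be built and cultivated before its
production level is known — so the optimizer must learn from dozens, not
thousands, of experiments, typically run in small parallel batches.

`strainrl` implements a model-free multi-agent reinforcement-learning
optimizer for this setting. Each *agent* is a parallel cultivation slot. At
round $t$ agent $i$ holds a design $e^i_t$ (a vector of transformed enzyme
levels), executes it, observes a state vector $s^i_t$ (e.g. a metabolite or
flux readout) and a scalar response $y^i_t$ (production), and receives the
reward $r^i_t = y^i_t - y^i_{t-1}$. Agents are partitioned into groups;
each group pools its members' `(state, action, reward)` triplets into one
history and learns a joint policy from it.

## Design space: the enzyme-level transform

Normalized enzyme pools $\hat e \in [0.1, 10]$ (10-fold down- to 10-fold
up-regulation around the wild type at 1) are mapped through

$$f(\hat e) = \frac{\hat e - 1}{\hat e + 1},$$

which sends the wild type to 0, a knock-out ($\hat e = 0$) to $-1$, and makes
the up- and down-regulation ranges nearly symmetric:

```{r}
transform_enzyme(c(0, 0.1, 1, 10))
```

All optimization happens in the transformed box
$[f(0.1), f(10)]^n \approx [-0.818, 0.818]^n$.

## The learner: Maximum Margin Regression

The policy is an SVM-like kernel machine over triplets. Rewards are mapped
to margins $M(r) = \log_2(r + 1)$ (clamped at $-1 + 10^{-6}$ since rewards
are response deltas and can fall below $-1$), and each triplet demands that
the learned reward surrogate exceed its margin. In the kernelized dual this
is the box-constrained quadratic program

$$\min_\beta \; \tfrac12 \beta^\top K_{SA} \beta - M^\top \beta,
  \qquad 0 \le \beta \le C_\xi,$$

where $K_{SA} = K_S \circ K_A$ is the Hadamard product of Gaussian kernel
matrices over states and actions (positive semidefinite by the Schur product
theorem). High-reward triplets are pushed toward becoming support vectors.
The solver is a deterministic cyclic coordinate-descent routine
(`solve_box_qp()`, tolerance $10^{-8}$, with an objective-decrease stop for
numerically singular kernels); tests certify its objective against an
independent projected-gradient oracle and `kernlab::ipop`.

```{r}
h <- mmr_history(states  = rbind(c(0, 0), c(1, 0), c(0, 1)),
                 actions = rbind(c(1, 0), c(0, 1), c(-1, 0)),
                 rewards = c(2, 0.5, -0.8))
fit <- mmr(h, sigma_s = 1, sigma_a = 1)
summary(fit)
```

### Action prediction and the pre-image problem

A fitted policy recommends an action for a query state $s$ by (approximately)
solving the *pre-image problem*: find the action maximizing the learned
surrogate $g(a) = \sum_i \beta_i K_S(s, s_i) K_A(a, a_i)$. Three solutions
are offered by `predict.mmr()`:

* `"sum"` (default): the closed form $\sum_i \beta_i a_i K_S(s, s_i)$ — the
  kernel-weighted combination of training actions.
* `"normalized"`: the same sum divided by $\sum_i \beta_i K_S(s, s_i)$,
  a convex re-weighting.
* `"preimage"`: a numeric solution by multi-start mean-shift (fixed-point)
  iteration on $g$, started from the weighted action mean and the
  highest-weight support actions.

The closed form is kept as the default for continuity with the published
method, but it has a structural weakness that matters in optimization loops:
its terms can *cancel*. On a response plateau rewards shrink, margins and
hence $\beta$ go to zero, and opposing support actions annihilate, so the
predicted step norm collapses and exploration stalls. The numeric pre-image
does not suffer cancellation (it seeks a mode, not a mean) and empirically
recommends larger, better-directed steps; see the benchmark note below.
It is available throughout the run loop via
`marl_config(predict = "preimage")`.

## The multi-agent loop

`run_marl()` implements the full DBTL loop:

1. **Warm-up** — each agent executes `tau` (default 5) Latin-hypercube
   designs (`latin_hypercube()`, stratified per dimension); its first reward
   is measured against the wild-type baseline response.
2. **Initialization** — agent 1 starts from the coordinate-wise median of
   the warm-up designs whose responses lie in the top
   $1 - \texttt{upper\_quantile}$ fraction (default top 25%); the remaining
   agents restart from fresh Latin-hypercube draws to keep exploring.
3. **Iterate** (default 40 rounds): every agent executes its design; each
   group appends its members' triplets to the group history, refits the MMR
   policy, and predicts one action per member.
4. **Perturbation** (`perturb_agents()`): within a group the predicted
   actions are blended with their Gram–Schmidt orthonormalization,
   $\tilde a_i = (1 - c)\,a_i + c\,v_i$ with $c = 0.8$, then restored to
   their original norms. This provably does not shrink the Gram determinant
   of the action set — the volume of the parallelotope the group explores —
   so parallel experiments stay diverse.
5. **Update** — $e_{t+1} = \mathrm{clip}(e_t + \tilde a_t)$ to the design
   box.
6. **Replacement** — every `replace_every_k` (default 5) rounds the agent
   with the lowest median response restarts from a copy of a uniformly
   chosen other agent's design.

Every random draw flows from one root seed through named substreams
(`derive_seed()`), so any run is bit-reproducible.

```{r}
env <- make_surface_env(n_enzymes = 4, seed = 1)
cfg <- marl_config(n_agents = 4, tau = 5, n_iterations = 15, seed = 1)
run <- run_marl(env, cfg)
summary(run)
```

## Environments

Both of the paper-style testbeds are bundled as deterministic, seeded
surrogates behind one pluggable contract (`strain_env()`): a design goes in,
a state vector and a response come out. External simulators can be attached
by implementing the same contract.

* `make_surface_env()` stands in for a genome-scale kinetic simulation: a
  single smooth peak $y(d) = y_{max} \exp(-(d - f^*)^\top Q (d - f^*))$ in
  the transformed enzyme space, with seeded optimum $f^*$, random SPD
  curvature $Q$, and a state readout $s = \tanh(Bd)$ through a random linear
  map (the optimizer never sees $f^*$; it is exposed for verification only).
* `make_synthetic_library()` + `make_library_env()` emulate a combinatorial
  promoter library: the $6^5$ grid of coded strengths, a seeded `coverage`
  fraction of which exists, scored by a concave quadratic with pairwise
  gene–gene interactions under multiplicative log-normal measurement noise
  ($\sigma_{\log} = 0.1$). A proposed design is matched to the nearest
  library strain within an element-wise tolerance (default 0.2, the grid
  spacing); designs matching no strain score zero — the strain simply does
  not exist.
* `with_noise()` wraps any environment with the three observation-noise
  channels (state, executed action, response), each scaled as a percentage
  of the signal as in the noise-robustness protocol.

## Baselines and evaluation

`random_search()` and `bo_gp()` (Gaussian-process surrogate with expected
improvement and constant-liar batching) consume exactly the same
environment-call budget as `run_marl()` and can share its warm-up
experiments (`compare_methods()`), so comparisons are experiment-for-
experiment fair. `aggregate_trajectories()` pools per-(agent, seed)
best-found responses per round (median and 25th/75th percentiles);
`rsd_stability()` measures a design's robustness to construction error as
the relative standard deviation of responses in a fold-change neighborhood;
`noise_degradation()` summarizes the cost of observation noise at the final
round.

## Benchmark note: where the method stands on the bundled surrogates

An honest accounting of the scaled-down benchmark protocol (6-enzyme
surface environment, seed 1; 4 agents in 2 groups, $\tau = 5$, 40
iterations, 5 seeds, shared warm-ups; pooled per-(agent, seed) final-round
medians), as encoded in the acceptance test suite:

| method | pooled final median |
|---|---|
| MARL, default `"sum"` prediction | 6.09 |
| random search | 7.39 |
| MARL, `predict = "preimage"` | 8.33 |
| BO-GP | 9.06 |
| target (90% of $y_{max}$) | 9.00 |

Two acceptance criteria are deliberately left failing rather than met by
protocol adjustments. With the default closed-form prediction the optimizer
stalls (the cancellation collapse described above) and trails random
search. The numeric pre-image option recovers a clear lead over random
search but still plateaus near 8.3: the $c = 0.8$ perturbation keeps the
executed step mostly orthogonal to the prediction at full norm, and the
update $e_{t+1} = e_t + \tilde a_t$ is applied unconditionally (no
elitism), so agents orbit the peak at roughly one step-radius. Even the
BO-GP reference misses the 90% bar on some environment seeds at this
budget. On the coverage-0.5 library protocol MARL (11.09) beats both random
search (10.29) and BO-GP (10.65) but misses 95% of the library's *realized*
maximum — a lucky log-normal measurement draw ~35% above the deterministic
optimum, i.e. an extreme-tail target for any 180-query method. Two findings
generalize: channel noise can *help* (it substitutes for the exploration
the policy loses on plateaus), and the pre-image implementation of Eq-2
prediction is the single most effective improvement available within the
method's structure.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| `n_agents` | 4 | four parallel cultivations |
| `n_groups` | 2 | two groups of two: joint learning with diversity |
| `tau` | 5 | warm-up rounds per agent |
| `n_iterations` | 40 | sequential DBTL iterations |
| `perturb_c` | 0.8 | perturbation coefficient of Algorithm 2 |
| `replace_every_k` | 5 | worst-agent replacement period |
| `upper_quantile` | 0.75 | warm-up quantile seeding agent 1 |
| `sigma_s`, `sigma_a` | median heuristic | no published values |
| `c_xi` | 1.0 | box bound of the dual |
| `predict` | `"sum"` | closed-form Eq-2 prediction (see above) |

## Limitations

* The bundled environments are smooth/quadratic surrogates, not kinetic
  models; absolute performance numbers do not transfer to real organisms.
* The algorithm has no elitism or step-size adaptation; on unimodal
  landscapes it converges to a neighborhood of the optimum whose radius is
  set by the learned action norms.
* The GP baseline uses a fixed-form squared-exponential kernel with the
  median-heuristic length scale, adequate for the bundled problem sizes
  (up to ~200 observations, ≤ 13 dimensions) but not tuned beyond that.
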