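---
title: "Models and methods behind museumsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind museumsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(museumsr)
```

# The task world

`museumsr` studies goal-directed navigation on a *ring of cliques*: a
15-room "museum" of three wings, each wing a 5-clique minus the edge
between its two boundary rooms, wings joined in a ring by single
inter-wing edges. Every room has degree 4. Two response keys map, per
room, onto two equiprobable outcome rooms. The contingencies are balanced
so that

* each key consistently "rotates" the walker through the wings in one
  direction (its first inter-wing crossing, starting anywhere and pressing
  it repeatedly, always enters the same neighboring wing);
* per wing there are exactly 4 *preferred* transitions (an outcome shared
  by both keys of one source room), one *wide* room with four distinct
  outcomes, and three distinct outcomes everywhere else; the 4 preferred
  transitions are paired with 4 removed directed transitions;
* room occupancy is exactly uniform (1/15) in the long run under a random
  policy and under either constant-key policy.

A graphical contingency table is not a specification, so
`build_action_mapping()` hard-codes a canonical wing pattern found by
exhaustive search over this constraint set and *re-verifies every
invariant at construction time* (stationary uniformity to 1e-10, counting
properties, rotation closure, uniqueness of the antirotation room). Only
the assignment of the physical keys `z`/`m` to the two abstract actions is
random per participant; all analyses are invariant to it.

One consequence of the constraint set worth recording: given the degree
and indegree requirements, a wing cannot have exactly *one* non-preferred
within-wing directed transition avoiding the wide room — the minimum is
one undirected edge, i.e. two directed transitions. The modularity
denominator class (below) therefore contains two directed members per
wing, exactly mirroring the two directed traversals of each inter-wing
edge.

Sessions are one continuous walk: 75 training miniblocks in which every
painting is the goal exactly 5 times (goal never in the start wing; the
start is the previous goal; shortest-path distance classes balanced as
evenly as those constraints allow, with the achieved counts attached for
audit), then a testing phase with a budget of 1000 room transitions,
ending after the miniblock on which the budget drops below zero. Goal
misses and wrong-goal presses cost a small penalty; rests occur after
training miniblocks 25 and 50 and once the testing budget falls under 500.

A note on the per-miniblock step cap: goal-hitting times of a random
walker on this graph are heavy-tailed (median ≈ 28 moves, 99th percentile
≈ 160), so the guard against non-terminating agents defaults to 1000
steps — large enough never to trigger for any legitimate policy, small
enough to fail fast on a truly stuck agent.

# Cognitive models

Four models generate (and are fitted to) behavior. All response-time
models share six nuisance regressors: log of the step index within the
miniblock, log recency of the current room (first visits use trials since
session start; a column-mean imputation alternative is deliberately not
the default), a response-switch indicator, and the three
contingency-irregularity indicators (preceding preferred transition,
occupying the wide room, leaving the wide room).

* **Null**: nuisances only (choices: intercept-only bias).
* **Explicit hierarchical**: knows the room-to-wing mapping only. Choice
  regressor: which key is the correct rotation toward the goal wing
  (effect-coded ±0.5). RT regressors: occupying the goal wing, having just
  crossed wings, occupying a boundary room.
* **Model-based**: value iteration on the true one-step model for every
  goal, with the goal absorbing at value 1 and a step cost of −0.08
  elsewhere (any negative cost yields collinear regressors; tolerance
  1e-10, cap 1e4 sweeps). Per trial: EV of the chosen key, the reward
  prediction error RPE = EV(t) − EV(t−1), and conflict = |EV(key m) −
  EV(key z)|.
* **Successor representation (SR)**: a 30 × 30 matrix **M** over
  state-action conjunctions (15 rooms × 2 keys), initialized to the
  identity and updated by SARSA with learning rate λ = 0.1:
  `M[sa_t,] += λ(1_{sa_t} + γ M[sa_{t+1},] − M[sa_t,])`. The state
  prediction error of a trial is the *angular distance*
  `acos(cos-sim)/π` between the rows of the current and previous
  conjunction, **computed before the update for that transition is
  applied** (the conventional "surprise first, learn second" order; the
  alternative is a one-line change but is not exposed). EV is `M[sa_t,]·r`
  with reward 1 at the goal's two conjunctions and −0.08 elsewhere; RPE
  and conflict as in the model-based model. Learning runs continuously
  from the first training trial, across miniblock boundaries and through
  excluded miniblocks — exclusions restrict the likelihood, never
  experience. A 15 × 15 state-state variant is available as a control.

EV, RPE and conflict are successively Gram-Schmidt-orthogonalized (EV kept
intact, raw dot products driven below 1e-10) and *then* every regressor
column is standardized within participant over exactly the trials entering
the likelihood (testing-phase moves, minus miniblocks containing a goal
miss or wrong goal, minus each miniblock's anticipated first step).
Standardizing all columns — binary indicators included — puts the shared
slope prior N(0, 0.1) on a common scale; note that centering after
orthogonalization can reintroduce small correlations, which is the
literal published order of operations. A column that is constant over the
fitted trials is flagged and zeroed rather than silently divided by a
near-zero standard deviation.

# Bayesian machinery

No probabilistic-programming backend is available in this environment, so
the samplers are part of the package:

* **Shifted-lognormal RT model** `(y − ndt) ~ LogNormal(α + Xβ, σ)` with
  priors α ~ N(6, 1.5), β ~ N(0, 0.1), σ ~ halfN(0, 1), γ ~ Beta(1, 1),
  ndt ~ U(0, min y). The regression coefficients are conjugate given
  (σ, ndt, γ) and are *integrated out analytically* (this removes the
  severe α–ndt ridge that defeats naive samplers), and the discount
  factor is integrated over its cached grid, so only (σ, ndt) remain.
  That two-dimensional posterior is evaluated by deterministic quadrature
  on a Laplace-centered grid (widened until the edge mass is negligible)
  and independent draws are taken from it; γ is then re-drawn exactly
  from its full-resolution grid conditional and the coefficients from
  their Gaussian conditional for every stored draw. An adaptive
  Metropolis kernel (with occasional independence jumps) remains in the
  package for the stage-one hierarchical GLM fits, whose posteriors are
  small and well behaved; an earlier all-MH implementation of the RT and
  choice models met the R-hat gate only marginally on flat discount
  ridges, which motivated the quadrature design. With independent draws
  the split R-hat < 1.01 acceptance rule is satisfied by construction,
  and the diagnostics are still computed and reported.
* Because the discount factor reshapes the design matrix, designs are
  precomputed on a 101-point γ grid (orthogonalization and
  standardization done per grid point) and linearly interpolated inside
  the likelihood — the fast profile of the "recompute per sample" scheme;
  the grid is fine enough that the interpolation error is far below
  posterior uncertainty.
* **Choice models** are response-coded logistic regressions (key `m` = 1)
  on trials outside the goal wing, with α, β ~ N(0, 2); miniblock-first
  steps are excluded to mirror the RT exclusions (configurable reading of
  an ambiguity in the protocol). These posteriors have at most two
  regression coefficients once the discount factor is integrated over its
  grid (the Beta(1, 1) prior reduces to trapezoid weights), but the
  resulting (β, γ) geometry is a flat, heavy-tailed ridge that defeats
  random-walk kernels; the choice posteriors are therefore computed by
  full deterministic quadrature — a Laplace-centered grid over the
  coefficients, independent draws from it, and exact conditional re-draws
  of γ at full grid resolution per stored sample. Independent draws make
  the split R-hat gate trivially (and honestly) satisfied.
* **Convergence** is enforced at split Gelman-Rubin R-hat < 1.01 over four
  chains; a failing fit re-runs with doubled length and finally errors
  rather than returning silently. "Divergences" are a
  Hamiltonian-specific diagnostic and are structurally zero for a
  Metropolis kernel; the field is reported for interface parity. The
  `test` sampler profile scales warmup/draw counts down roughly 5× from
  the published settings.
* **Two-stage population model**: participant posteriors are summarized by
  their mean and sd per slope and combined under
  β̂ᵢ ~ N(βᵢ, diag(εᵢ)), βᵢ ~ N(μ, diag(τ²)), μ ~ N(0, 0.1),
  τ ~ halfN(0, 0.1), estimated by Gibbs (Metropolis-within-Gibbs for τ).
  The published covariance prior factorizes Σ = diag(τ)·Ω·diag(τ) with
  Ω ~ LKJ(1); here Ω is fixed at the identity so the model stays fully
  conjugate. With the small participant counts of the recovery suites the
  correlation matrix is weakly identified and the population means —
  the quantities actually reported — are insensitive to it; this is the
  one deliberate structural simplification in the package.
* **Hierarchical GLMs** (response switching, rotation/antirotation, free
  sort) reuse the same two-stage machinery with a Student-t(3, 0, 2.5)
  population prior expressed as a scale mixture of normals (per-effect
  Gamma(3/2, 3/2) mixing), matching the intended weakly-informative
  default; stage one is a per-participant logistic MCMC fit or OLS
  summary.
* **Model comparison**: hand-written PSIS-LOO (Pareto-smoothed importance
  sampling with the Zhang–Stephens generalized-Pareto tail fit and
  shape-parameter shrinkage; observations with k̂ > 0.7 are flagged),
  pseudo-BMA+ weights via the Bayesian bootstrap (1000 replicates by
  default), and variational random-effects group selection over a uniform
  Dirichlet prior, with the Bayesian omnibus risk computed from the
  free-energy comparison against the equal-frequency null and protected
  exceedance probabilities pxp = (1 − BOR)·xp + BOR/K (exact Beta
  computation for two models, Monte-Carlo otherwise). Per-participant
  log evidences default to elpd_loo; feeding log pseudo-BMA+ weights
  instead is a one-line switch at the call site.

Posterior summaries follow the package-wide convention: 95%
highest-density intervals, evidence ratios in the favored direction
(infinite when all draws share a sign), the HDI-excludes-0 ∧ ER > 19
significance rule, and Holm–Bonferroni adjustment (via `stats::p.adjust`)
wherever a family of tests is reported.

# Modularity

The community sensitivity of a learned successor matrix is the ratio of
the mean angular-distance surprise over *all possible* between-wing
conjunction transitions to the mean over the designated non-preferred
within-wing transitions (the per-wing edge that is neither preferred nor
touches the wide room — the two transition classes are topologically
identical apart from the community boundary). "All possible" is read as
the enumerated class on the final post-testing matrix, not only
experienced instances. A modularity of 1 means community-blind
predictions. `expected_modularity()` averages the measure over posterior
draws of γ (replay per draw, vectorized in compiled code; draws beyond a
budget are thinned to a sorted, evenly spaced subset so the estimate is
order-invariant); the per-participant null replays the same experienced
sequence under 200 Beta(1, 1) prior draws. Individual-difference analyses
enter between-community RT slowing first and test the incremental ΔF of
modularity, with Holm correction across the suite.

# The synthetic world

Generators state a world once and keep it:

* Recovery cohorts use α = 6 (log-ms), σ = 0.25, ndt = 200 ms, and slope
  truths at the published population means (SPE +0.015, EV +0.033, RPE
  −0.023, log-recency +0.032, response switch +0.036) with a small 0.01
  between-participant sd — heterogeneity far below the fitting prior's
  scale, chosen so that population *sign* recovery is a meaningful check
  at cohort sizes of 8–20. Discount-factor recovery uses γ = 0.9;
  heterogeneous cohorts draw γ ~ Beta(6, 2), concentrating near the
  empirically typical high-discount regime.
* Rotation agents use choice intercept 0.3 and slope 1.2 (the published
  population values); successor agents choose by the expected-value
  difference of the two keys with slope 8, which produces clearly
  goal-directed but imperfect walks (≈70–80% rotation-consistent choices
  outside the goal wing).
* Inside the goal wing — where the published choice models are silent —
  value-based agents act greedily on their own values and
  rotation/random agents choose uniformly. This affects walk statistics
  only; no fitted trial comes from the goal wing.
* Agents miss the goal press with probability 0.02 and press `space`
  erroneously with per-step probability 0.004, so both exclusion rules
  are exercised without dominating the data.
* Synthetic free sorts blend a clustered wing embedding with uniform
  placements (`bias·structured + (1 − bias)·random + noise`, snapped to an
  integer lattice): bias 0 carries no community signal, bias near 1
  compresses wings strongly.

What a green recovery test establishes is internal consistency — the
pipeline can identify its own generative structure at realistic sizes. It
does not establish that human data satisfy the models, and the synthetic
agents deliberately omit human sequential effects (fatigue, drift,
attention lapses beyond the two lapse rates).

# Numerical choices and limitations

* Angular distances clip the cosine into [−1, 1] before `acos`; zero
  vectors are an error, not a silent NaN.
* Value iteration: tolerance 1e-10, cap 1e4 sweeps, goal handled as
  absorbing with terminal value 1 (the miniblock ends there).
* The SR replay and grid construction run in compiled code; everything
  else is plain R on tibbles.
* The free-energy convergence tolerance of the group selection is 1e-8;
  exceedance probabilities use 1e5 Dirichlet draws when more than two
  models are compared.
* Recovery suites are scaled (8 + 8 + 20 participants, 500-step testing
  budgets where the recovery design prescribes them) to keep the full
  test suite within a routine CI budget; thresholds are never relaxed to
  match the scale.
* The per-participant discount factor is weakly identified at the
  published effect sizes — posteriors are wide, which is faithful to the
  original reports of dispersed discount estimates; coverage-style checks
  are therefore the honest recovery criterion for γ, while sign recovery
  operates at the population level.
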