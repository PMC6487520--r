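---
title: "Methods: closed-loop Bayesian optimization of germination conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop Bayesian optimization of germination conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germBO)
```

`germBO` tunes the controllable conditions of seed-germination trials —
multi-day temperature schedules and daily water supply in climatic
chambers — by Bayesian optimization over a Gaussian-process surrogate.
This vignette is the package's own account of the method: the score and
its noise model, the surrogate and acquisition machinery, the simulator
used for testing, and the numerical and design choices made where the
method left room.

## The germination score and its noise model

A run places N seeds at condition **x**. Counting `N_g` germinated seeds
(radicle emerged; this count *includes* the well-germinated) and `N_wg`
well-germinated seeds (stricter criterion: hypocotyl emerged, or radicle
beyond a length threshold) gives the target

$$y(\mathbf{x}) = \frac{N_g + N_{wg}}{N} \in [0, 2].$$

The inclusive counting convention matters: with it, 73 germinated + 18
well-germinated of 100 seeds scores 0.91, and 80 + 33 scores 1.13, the
arithmetic the session report and the bundled trial tables rely on.
*Efficiency* is y as a percent of the maximum 2; reports round
efficiencies to one decimal and relative improvements to the nearest
integer, using decimal half-up rounding (`roundHalfUp`) so that values
that are exact decimals round the way they read (95.15 → 95.2 rather
than the banker's 95.1).

Seed stochasticity is modeled as a two-stage Bernoulli trial:
germination with probability p(**x**), then well-germination with
probability q(**x**). One seed's score contribution Z ∈ {0, 1, 2} has

$$\mu = p(1+q), \qquad
  \sigma^2 = \mathbb{E}Z^2 - \mu^2 = p(1+3q) - p^2(1+q)^2,$$

so for a run, y ≈ N(μ, σ²/N). Two noise floors follow:

* **global**: max σ² over the unit square is exactly 1, attained at
  (p, q) = (½, 1), so σ²/N ≤ 1/N always — with N = 100 this motivates
  the 0.01 lower bound on the white-noise hyperparameter;
* **per-observation**: among all (p, q) consistent with an observed mean
  y, the variance supremum is y(2−y) (the gap y(2−y) − σ² equals
  p(1−q) ≥ 0, vanishing at q = 1, p = y/2), giving the sharper bound
  y(2−y)/N.

Both floors are implemented; the default couples the global floor into
the kernel bounds (`defaultHyperBounds(N)`), the `"per-obs"` mode instead
sets the GP noise diagonal to max(σ², y(2−y)/N) per observation. The
default is `"global"` because the per-observation floor vanishes at
y = 0 and the corner pseudo-observations (below) are *not* actually
noiseless; using both at once would double-count. The normal
approximation is not gated on N: the exact sampler (`sampleScore`) is
exposed alongside, and the test suite checks the moments agree at
N = 100 to Monte-Carlo precision.

## Parameter scaling and initialization

The kernel is isotropic, so units must be made commensurate before
modeling. Each parameter is mapped linearly from its physical range to a
configurable scaled interval: temperatures 0–40 °C → [0, 1] and water
0–250 ml → [0, 0.5], which declares 1 °C exchangeable with 12.5 ml (both
steps are 0.025 scaled). For temperature-only spaces the natural default
is [0, 1] per dimension; `germBO` scales these too rather than leaving
raw units, purely for numerical conditioning — with a single unit the
choice is a harmless reparameterization.

Suggestions are reported in physical units rounded to the device
precision (0.1 °C, 1 ml), and the *rounded* point is what is logged and
re-checked against the constraints — chambers cannot execute finer
settings, so the model should never be told otherwise.

Optimization needs data to start: `cornerInitPoints` pins pseudo-
observations with y = 0 at the extreme box vertices (all 0/40 °C
combinations, zero water — 2⁴ = 16 points for the pea space), encoding
the domain knowledge that extreme conditions germinate nothing. These
carry provenance `"init"` and are excluded from the exploration-anchor
subset by default.

## Surrogate model

The score surface gets a GP prior with constant mean and covariance
α·C₅/₂(‖xᵢ−xⱼ‖/ρ) + σ²δᵢⱼ. The constant mean is fixed to the mean of the
observed targets (not jointly optimized); hyperparameters (α, ρ, σ²) are
fitted by maximizing the log marginal likelihood in log space with
L-BFGS-B from 30 log-uniform restarts inside the bounds α, ρ ∈ [10⁻⁵,
10⁵], σ² ∈ [1/N, 10⁵]. A 10⁻¹⁰ diagonal jitter stabilizes the Cholesky
factorization; predictive variances are clipped at zero against
round-off. Predictions use the standard conditional-Gaussian equations;
the predictive variance at a far query reverts to the prior amplitude α.
Hyperparameters are re-optimized once per ingestion of real results —
never inside a batch, where fantasy points (below) would otherwise drag
them.

With only tens of observations, dense Cholesky algebra is exact and
cheap; no sparse or approximate GP machinery is warranted, and no ARD
(the isotropy is deliberate — it is what the unit scaling is for).

## Acquisition and constraints

The acquisition is the upper confidence bound μ̂(x) + κσ̂(x). Two
distance constraints shape its maximizer, with per-parameter thresholds
normalized so the constraint boundary is 1 in both cases:

* exploitation, `min_i max_d |x_d − x_{i,d}|/ε_d ≥ 1` over all tested
  conditions — rules out sub-precision repeats of what was already run;
* exploration, `min_i Σ_d |x_d − x_{i,d}|/ε_d ≤ 1` over a trusted subset
  — keeps suggestions within reach of conditions known to work.

The thresholds are stated per quantity (0.1 °C and 1 ml; 10 °C and
100 ml), so the norms divide each coordinate difference by its own ε
before applying the ∞- or 1-norm; when all dimensions share one unit
this reduces to the scalar-ε form. The trusted subset defaults to all
non-`"init"` rows: the corner pseudo-points are synthetic and should not
anchor exploration.

The constrained maximization is a multi-start penalty method: a
vectorized random screen over the scaled box (biased toward the trusted
subset where the exploration ball lives) picks the most promising
starts, each is refined by L-BFGS-B on −UCB plus quadratic hinge
penalties (weights 10², 10⁴), and a deterministic repair step then
projects near-feasible candidates exactly onto the feasible set —
pushing the blocking coordinate just past ε away from its nearest tested
condition, or contracting toward the nearest trusted point. Feasibility
is re-verified after device rounding (tolerance 10⁻⁶ on the normalized
metrics, re-repairing by at most a few precision steps). Ties among
equal-value candidates break to the lexicographically smallest scaled
point, for determinism. If nothing feasible is found the best candidate
is returned flagged infeasible with its constraint slacks, never
silently.

An SQP-style constrained solver is the classical choice here; the
penalty-plus-repair construction used instead is gradient-based,
box-native, robust to the nonsmooth min/max constraint surfaces, and
guarantees exact post-rounding feasibility, which a smooth-tolerance
solver does not.

### Choosing κ, and batches

`selectKappa` automates the exploration weight: scan an ascending grid
(default 0 to 10 by 0.25) and return the first κ whose constrained
maximizer is feasible — the smallest workable κ, i.e. as exploitative as
the exploitation constraint allows. `suggestBatch` fills B concurrent
chambers sequentially: maximize, then "observe" the pick at its current
predictive mean (a *fantasy* observation with the global 1/N noise
floor, hyperparameters frozen, constant mean recomputed over the
augmented targets), repeat. Fantasies make successive picks mutually
exploit-separated; they are fully retracted on return — the caller's fit
is untouched and fantasies never reach the ledger. Whether the original
procedure retracted or kept fantasy points until results arrived is an
interpretation; retraction is the cleaner contract (the ledger only ever
contains real measurements) and is asserted bit-exactly in the tests.

## The simulator

`builtinSurface` provides three declared-fixture response surfaces —
smooth Gaussian compositions with constants fixed in code (documented on
the help page): `pea7d` (7-dim; mid-20s daily temperatures and ~370 ml
cumulative water optimal, maximum mean score 1.36), `radish4d` (4-dim
temperature-only, broad optimum ≈1.90), and `unimodal_1d` (closed-form
optimum at s = 0.6, mean score 1.53, for grid-oracle tests). They
emulate the qualitative structure of real germination response —
smoothness, interior optima, barren box corners, two-stage Bernoulli
sampling noise — and none of its mechanistic biology (no dormancy
dynamics, no triphasic water-uptake kinetics, no inter-seed competition,
no chamber drift). Passing closed-loop tests therefore demonstrates that
the optimizer works on landscapes of this character at germination-trial
noise levels, not that it reproduces any particular organism's response.

`simulateTrial` draws G ~ Bin(N, p), W ~ Bin(G, q). `runClosedLoop`
replays the full protocol: corner init, a simulated expert condition,
then rounds of fit → batch suggestion → simulated runs (optionally
repeated per condition) → ingestion. One session seed fans out into
per-trial/per-chamber child streams by a fixed arithmetic rule, so
ledgers are bit-reproducible and chamber order is immaterial.

One policy choice deserves its own paragraph: the closed-loop driver
defaults to a *fixed* κ = 2 rather than the automatic first-feasible
rule. With ε_xploit at the device precision (0.1 °C), the κ = 0
maximizer is nearly always feasible — a 0.1 °C step satisfies the
exploitation constraint — so the automatic rule degenerates into pure
local exploitation and the loop crawls. In the laboratory workflow this
is precisely the situation where an operator raises κ by hand; a
moderate fixed κ = 2 is the stand-in for that operator judgment in
unattended simulation. The automatic rule remains the default for
interactive sessions (`newSession`), where a human reviews each batch.

## Problem sizes used in testing

The test suite validates the analytic noise model against 10⁵–10⁶-draw
Monte-Carlo oracles (tolerance 3–4 standard errors), GP predictions
against a dense `solve()` oracle on 20 random instances of n ≤ 30
(relative 10⁻⁸), hyperparameter recovery on n = 40 GP draws (factor-of-2
brackets), the acquisition maximizer against a 10⁴-point grid in 1-d,
and the closed loop on `pea7d` with the full protocol shape — 16 corner
points, 1 expert point, 11 trials × 3 chambers, N = 100 — over 10 seeds
(expecting improvement over the expert draw in ≥ 8), plus an 8-trial
sequential run on `unimodal_1d` reaching 95% of the known optimum.
These sizes keep the whole suite within a few minutes on one core while
leaving each statistical check several standard errors of headroom.

## Known limitations

* The Bernoulli noise model treats seeds as exchangeable and independent;
  batch effects between chambers or dishes are not modeled.
* The isotropic kernel means the declared unit equivalence (1 °C ≙
  12.5 ml) is a modeling commitment, not something fitted from data.
* First-feasible κ selection inherits the granularity of its grid, and —
  as discussed — degenerates to exploitation when ε_xploit is at device
  precision.
* Beyond roughly ten dimensions the approach is expected to degrade, as
  plain GP-UCB machinery does; nothing here addresses high-dimensional
  structure.
* The built-in surfaces are test fixtures; conclusions about real crops
  require real trials.
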