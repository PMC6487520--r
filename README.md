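# germBO — Bayesian optimization of seed germination conditions

Fine-tuning the environmental schedule of a germination experiment —
chamber temperatures over several days, how much water to give on each
day — is a black-box optimization problem: every evaluation costs a
multi-day trial in a climatic chamber, the response is noisy (seeds are
stochastic), and the parameter space is too large to sweep. `germBO`
implements a closed-loop Bayesian-optimization workflow for exactly this
setting, for agronomists and lab scientists running sequential
germination (or similar plant-growth) trials.

## The model

Each of the N seeds in a run germinates with probability p(**x**) and,
given germination, is *well*-germinated with probability q(**x**), where
**x** is the vector of controllable conditions. The observed target is

    y(x) = (N_g + N_wg) / N  ∈ [0, 2],

with N_g the germinated count (inclusive of well-germinated) and N_wg the
well-germinated count. For one seed the score contribution has mean
μ = p(1+q) and variance σ² = p(1+3q) − p²(1+q)², so y is approximately
N(μ, σ²/N). Since max σ² over the unit square is 1 (at p = ½, q = 1),
1/N is a global lower bound for the observation noise — 0.01 for
N = 100 — and y(2−y)/N is a sharper per-observation bound.

The latent score surface gets a Gaussian-process prior with constant mean
(the mean of the observations) and covariance

    k(x_i, x_j) = α · C_{5/2}(x_i/ρ, x_j/ρ) + σ² δ_ij,

an amplitude-scaled isotropic Matérn-5/2 plus white noise, fitted by
maximum marginal likelihood with 30 multi-start restarts. Physical units
are made commensurate by linear scaling (temperatures 0–40 °C → [0, 1],
water 0–250 ml → [0, 0.5], so 1 °C ≙ 12.5 ml). The next condition
maximizes the upper confidence bound a(x) = μ̂(x) + κ·σ̂(x) subject to two
distance constraints with per-parameter thresholds ε:

* **exploitation** (min-separation, ∞-norm): at least one parameter must
  move at least ε_xploit (0.1 °C / 1 ml) away from every tested condition
  — no sub-precision repeats;
* **exploration** (max-departure, 1-norm): the suggestion must stay
  within a total distance ε_xplore (10 °C / 100 ml) of the nearest
  trusted condition — no leaps into regions known to be barren.

Batches for B concurrent chambers are assembled sequentially with
*fantasy observations*: each pick is provisionally "observed" at its GP
predictive mean (hyperparameters frozen) so the next pick is pushed
elsewhere; fantasies are discarded once the batch is fixed. A κ grid scan
(smallest feasible κ wins) automates the exploration weight, and a
two-stage-Bernoulli simulator with built-in response surfaces lets the
whole loop run and be tested without a laboratory.

## Worked example

Replay the bundled 33-trial pea ledger (7 parameters: t1–t4 in °C, w1–w3
in ml; 100 seeds per run), then ask for the next batch:

```r
library(germBO)

targetScore(germinationCount(100, 80, 33))
#> [1] 1.13
efficiencyPercent(c(0.73, 1.13), digits = 1)
#> [1] 36.5 56.5

sess <- newSession(peaParameterSpace(), N = 100)
pea <- peaTrials()
counts <- round(pea$target * 100)
for (i in seq_len(nrow(pea))) {
  ng <- min(counts[i], 100)
  sess <- ingestObservation(
    sess, sprintf("trial%02d", (i - 1) %/% 3 + 1),
    sprintf("c%d", (i - 1) %% 3 + 1), as.numeric(pea[i, 1:7]),
    germinationCount(100, ng, counts[i] - ng),
    provenance = if (i == 1) "expert" else "bo")
}
rep <- sessionReport(sess)
rep$improvementPercent
#> [1] 55
c(rep$initEfficiency, rep$bestEfficiency)
#> [1] 36.5 56.5

sess <- fitSession(sess)
sess@fit
#> GPFit: n = 33, d = 7, noise mode 'global'
#>   alpha = 0.01063, rho = 0.1023, sigma2 = 0.0167, mean = 0.7552, logLik = 14.75

sug <- suggest(sess, B = 3)
sug[[1]]
#> Suggestion (kappa = 0, UCB = 0.941, feasible)
#>   physical: 25.4, 23.3, 29.7, 25.3, 165, 40, 165
#>   slacks: exploit = 8 (>=1), explore = 0.22 (<=1)
```

The expert starting condition scored y = 0.73 (36.5% of the metric
maximum 2); the best condition found scored 1.13 (56.5%), a 55% relative
improvement — and the model's next suggestion sits right beside the best
tested schedule (a warm mid-20s cycle peaking on day 3 with a
high–low–high watering pattern).

A thin command-line wrapper (`inst/scripts/germbo`) exposes the same
workflow as `init` / `observe` / `suggest` / `report` / `export` /
`simulate` subcommands over a YAML configuration and a CSV trial ledger.

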