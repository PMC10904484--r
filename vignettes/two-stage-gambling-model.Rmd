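---
title: "A two-stage model of gambling participation and harm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage model of gambling participation and harm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamblesim)
```

## Why two stages

Standard utility models struggle with gambling twice over: risk-averse
agents facing an expected monetary loss should not gamble at all, and yet
some people not only gamble but keep gambling when it demonstrably makes
them worse off. This package implements a model that separates the two
phenomena. *Stage 1* — whether someone ever gambles — is governed by the
linear utility coefficients: net pleasure from gambling and (possibly
biased) beliefs about the monetary outcome. *Stage 2* — whether gambling
drifts to a level where experienced utility turns negative — is governed
by cravings and by how fast the quadratic terms punish large amounts.
Parameters that drive stage 2 (craving propensity, craving persistence,
curvature) have no effect on stage 1, which is what makes the model useful
for thinking about interventions that reduce harm without prohibiting
participation.

## The model

An agent `i` gambles an amount `A ≥ 0` per session (one period). Utility
has three ingredients.

**Baseline gamble utility.** Psychological effects
`U_P(A) = α_P A + (α_PP/2) A²` with `α_PP < 0` (pleasure is concave and
eventually negative for excessive amounts), and monetary effects
`U_M(A) = α_M A + (α_MM/2) A²` with `α_MM < 0` and objectively `α_M < 0`
(risk aversion plus the house edge). Their sum, with `b = α_P + α_M` and
`c = α_PP + α_MM < 0`, is the utility of a gamble for someone with no
gambling history.

**Cravings.** Past gambling leaves a stock `S` that evolves as
`S' = (1 − d) S + A`, `d ∈ (0, 1)`; the craving level is `α_C S` with
`α_C > 0`. Gambling less than the satisfaction amount
`A_sat(S) = −(b + α_C S)/c` costs `α_C S (A_sat − A)` in unsatisfied
cravings, clipped at zero so satisfied cravings never *add* utility. The
functional form makes cravings exactly satisfied at the myopic optimum,
and it delivers the intended qualitative behaviour: the loss is
non-negative, weakly decreasing in the amount gambled, steeper at higher
craving levels, larger for people with a more attractive baseline, and
persistent-but-fading under abstinence.

**Two belief frames.** Subjective coefficients (superscript `S`) drive
decisions; objective ones (`O`) drive experience. Optimism — about winning
or about how gambling will feel — means subjective coefficients weakly
exceed objective ones, which makes decision utility exceed experienced
utility by the wedge `(b^S − b^O) A + ((c^S − c^O)/2) A²`, a quantity
independent of the stock because the (inherently subjective) craving term
cancels. Only `α_M^O < 0` is imposed; a biased agent may believe
`α_M^S > 0`.

**Myopia.** Agents maximise current-period decision utility only
(they do not anticipate that gambling today raises cravings tomorrow), so
each period they choose `A*(S) = max{0, −(b^S + α_C S)/c^S}`, truncated by
available income and any external cap; a constrained agent gambles the
whole budget and carries unsatisfied cravings. Lifetime utility
`Σ (1 − δ)^t u_t` is computed for reporting, never optimised.

## Closed-form results and how they are verified

Substituting `A*(S)` into the stock recursion gives an affine map with
slope `1 − d + α_C/|c^S|`:

* **Convergence** iff `|c^S| > α_C/d` (strictly). The fixed point is
  `Ā = −b^S/(c^S + α_C/d)`, `S̄ = Ā/d`. The knife-edge
  `|c^S| = α_C/d` has slope exactly one and drifts upward linearly
  whenever the agent participates, so it is classified as divergent.
* **Harm** iff the objective baseline at `Ā` is negative, i.e.
  `b^O Ā + (c^O/2) Ā² < 0`; divergent participants always become harmful.
  The package evaluates this sign directly and also exposes the
  equivalent threshold form `2 α_C/d > |c^S| − ((b^S/b^O)|c^O| − |c^S|)`
  (`harm_condition_inequality`), which is algebraically identical for
  `b^O > 0`; because the ratio `b^S/b^O` flips sign when `b^O < 0`, the
  direct sign evaluation is treated as authoritative and any disagreement
  (none observed) would raise a warning rather than be silently resolved.
* **Harm thresholds.** Experienced baseline utility changes sign at the
  amount `2 b^O/|c^O|`; inverting the myopic rule gives the stock
  `S* = (|c^S| · 2b^O/|c^O| − b^S)/α_C` at which the indirect
  experienced-utility curve (utility as a function of stock when gambling
  myopically) crosses zero. When `b^O ≤ 0` any positive amount harms and
  the thresholds are reported as 0 with a flag. The same is true under
  bias so strong that the *first* gamble already overshoots the harm
  amount — the indirect curve then starts negative even though
  `b^O > 0`; the curve's textbook shape (positive at zero stock, one sign
  change) applies when `S* > 0`.

Every closed form is cross-checked by an independent numerical route in
the test suite: grid-search maximisation of decision utility against the
myopic formula, forward iteration of the recursion against `Ā` and `S̄`,
bisection on the indirect utility curve against `S*`, the sign of
simulated long-run experienced utility against the analytic harm flag, and
a literal transcription of the utility equations against the vectorised
implementation.

## Simulation semantics

Within a period the order is: observe start-of-period stock, choose the
amount (optimum truncated by income and cap), record decision and
experienced utility and the craving loss at the *realised* amount, update
gambler status, then update the stock using the realised amount (stock is
past gambling actually done, not desired). Status moves
non-gambler → current gambler on the first positive amount, and current →
ex-gambler in the first abstaining period afterwards; under pure myopic
optimisation an ex-gambler with positive stock and `b^S + α_C S > 0`
always relapses, so durable abstinence is only producible through an
explicit zero cap — this is a property of the model, not a bug. A
trajectory is deemed converged when consecutive amounts differ by less
than `1e-9` (configurable) for five consecutive periods; divergent agents
are flagged and their long-run experienced utility reported as `−Inf`.

## The synthetic cohort generator

The model has no canonical calibration — its parameters are latent utility
coefficients, not measured quantities — so `default_cohort_spec()` defines
a stylised reference population chosen once to exercise every regime while
keeping the majority of gamblers benign:

| parameter | distribution | rationale |
|---|---|---|
| `α_P^O` | Normal(0.75, 0.5) | most people get some pleasure; a left tail does not |
| `α_PP^O`, `α_MM^O` | Uniform(−1.5, −0.5) | moderate, heterogeneous curvature |
| `α_M^O` | Uniform(−1.0, −0.1) | universal objective expected loss |
| `α_C` | Lognormal(log 0.08, 0.8) | skewed craving propensity; most small, a long right tail |
| `d` | Uniform(0.2, 0.8) | persistence varies widely across people |
| `δ` | Uniform(0, 0.2) | light discounting |
| income | 10 per period | rarely binding; constraint effects are opt-in |
| bias wedges on `α_P`, `α_M` | Normal(0.08, 0.08), truncated ≥ 0 | mild average optimism |

Objective coefficients are sampled first and subjective ones derived by
adding non-negative wedges, so the decision–experienced wedge is
non-negative by construction; draws outside a parameter's legal range are
rejected and redrawn (capped at 1000 attempts, then an error naming the
parameter). A root seed derives one sub-seed per agent, so agent `i` is
reproducible regardless of batch size or order. Under these defaults
roughly three quarters of agents participate and a bit under half of the
participants end in a harmful regime — deliberately concentrated compared
with survey prevalence of gambling problems, because the generator's job
is to give the regime classifier and the intervention machinery a
population worth summarising, not to emulate any real survey. What passing
cohort tests show is therefore internal consistency (classification,
simulation and interventions agree on heterogeneous agents), not fidelity
to real gambling data: real populations have correlated parameters,
measurement error, income dynamics and strategic behaviour this generator
does not attempt.

For property-style tests the package's random-agent generator constructs
draws whose contraction ratio `1 − d(1 − α_C/(d |c^S|))` is bounded by
about 0.94, so a 500-period trajectory provably settles to within `1e-6`
of the closed-form equilibrium; divergent test draws keep the expansion
ratio below 1.5 so 500 periods of unbounded growth stay inside double
precision. These are choices about the test population's numerical
conditioning, not about the model.

## Numerical and design choices

* Amounts, stock, utility and income are dimensionless model units.
* Negative amounts or stock are rejected loudly, never clipped.
* Coefficients are stored as the four raw `α`'s; `b` and `c` are computed
  on demand (`net_slope`, `net_curvature`), never stored.
* The corner at `A* = 0` exactly is closed: the agent does not gamble.
* The boundary case of *exactly zero* long-run experienced utility counts
  as benign (harm requires strictly negative utility).
* Interventions compose, re-validate all invariants, and are designed for
  paired comparisons on the same sampled cohort (common random numbers):
  `scale_alpha_C` (craving reduction), `shift_alpha_PP` (both frames,
  more negative curvature), `amount_cap`, `income_limit`. No default
  magnitudes are endorsed — the model offers no calibration for them.
* CSV output uses 17 significant digits (round-trip exact), LF endings and
  a fixed column order; JSON serialises `±Inf` as string markers. All
  writes are atomic. Identical configs and seeds yield byte-identical
  files.

## Limitations

Sessions are deterministic (the outcome of a gamble equals its expectation),
bets within a session are not modelled, win probability is not a choice
variable, and agents never learn or plan ahead; lifetime utility is
descriptive. Parameters are exogenous inputs: the mapping from psychosocial
factors (mood moderation, loss chasing, advertising exposure, venue
proximity) to coefficient values is qualitative background, not code.
Utility is the individual's own; externalities to others are out of scope.

## Problem sizes

The shipped tests run cohorts of 15–80 agents over 40–400 periods and
property loops of 10–60 random agents; the acceptance script uses 100
grid-search draws, 50 + 50 convergence/divergence draws at 500 periods,
200 harm-sign draws at 600 periods and a 200-agent default cohort. A full
run of suite plus script takes on the order of a minute on a single core.
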