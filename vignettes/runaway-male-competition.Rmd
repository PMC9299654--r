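---
title: "Runaway evolution from male contests: model, simulator and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runaway evolution from male contests: model, simulator and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contestevo)
```

## The model and its assumptions

`contestevo` models three male traits: a signal $S$ used to advertise
threat in contests, body size $B$ (a stand-in for fighting ability), and
aggression $A$. Signal and body size are ordinary metric traits,
$z_i = a_i + e_i$, with breeding values $a_i$ multivariate normal and
environmental deviations independent of them. Aggression is *socially
contingent*: within a dyad the focal male expresses

$$z_A = a_A + e_A + \delta_{AS}\,(z_S - z_S'),$$

escalating against rivals with smaller signals and withdrawing from rivals
with larger ones. Because the shift depends on the opponent's heritable
signal, it is an indirect genetic effect, and $\delta_{AS}$ plays the role
of the interaction coefficient $\psi$ of interacting-phenotype models
(with the difference that it acts on the *relative* signal). Structural
assumptions, fixed by construction rather than defaulted:

* breeding values of aggression are uncorrelated with those of signal and
  body size ($G_{SA} = G_{BA} = 0$) — conservative, since positive
  covariance would only speed elaboration;
* signal and body size are fixed before a contest and unchanged by it;
* males meet in pairwise duels, drawn at random, one duel per male per
  generation.

Signal honesty is the genetic covariance $G_{SB}$: it is what makes a big
signal a reliable predictor of a dangerous opponent.

Contest fitness is a local (first/second-order) model derived from
hawk–dove payoff logic:

$$w = w_0 + b_A (z_A - z_A') - c_A z_A z_A' - c_B z_A' z_B'
      - c_S(\bar z_S - \theta_S) z_S .$$

The benefit $b_A$ of out-aggressing a rival is zero-sum across the dyad;
mutual escalation costs $c_A z_A z_A'$; the *threat of the opponent*
$c_B z_A' z_B'$ scales with how aggressive **and** how large the rival is;
and stabilising natural selection $c_S$ pulls the signal towards an
optimum $\theta_S$ with strength proportional to how far the population
mean has been dragged from it.

Differentiating $w$ at the population means gives the selection gradients
(`selection_gradients()`): notably $\beta_{NB} = 0$ and $\beta_{SS} = 0$
identically — body size is never a direct target of nonsocial selection,
and a rival's signal costs nothing *per se*; it matters only through the
behaviour it provokes. The test suite checks the analytic gradients
against central-difference derivatives of the fitness surface across
random parameter draws.

## Deterministic dynamics

With selection on males only, the response equations are

$$\Delta\bar z_S = \tfrac12 G_{SS}\left[\beta_{NS} +
  \delta_{AS}(\beta_{NA}-\beta_{SA})\right] + \tfrac12 G_{SB}\beta_{NB},$$

and analogously for $B$ (weights swapped) and
$\Delta\bar z_A = \tfrac12 G_{AA}\beta_{NA}$. Substituting the analytic
gradients collapses this to closed form (`response_mechanistic()`); the
two routes agree to machine precision, and both are exposed because the
gradient route accepts *estimated* gradients too.

Numerical choices:

* **Discrete, additive generations.** Updates are
  $\bar z \leftarrow \bar z + \Delta\bar z$ with non-overlapping
  generations. Whether canonical trajectories of this kind of model are
  produced by discrete iteration or by integrating the continuous-time
  analogue is usually unstated; discrete iteration matches the
  response-to-selection framework and a generation axis, so it is what
  `simulate_trajectory()` does, documented here once.
* **Constant $G$ and constant coefficients** across generations, in the
  Lande tradition. Eroding or evolving $G$ is out of scope.
* **Termination.** Convergence when every $|\Delta\bar z| <$ `tol`
  (default $10^{-10}$); divergence — the numerical signature of a runaway
  — when any mean exceeds `divergence_bound` (default $10^6$); otherwise a
  cap of `max_generations` (default $10^4$). At the reference parameter
  scales these defaults separate the two regimes unambiguously: the
  stable regime converges in a few thousand generations, the runaway hits
  the bound.
* **Exact coupling.** $\Delta\bar z_S$ and $\Delta\bar z_B$ are computed
  from one shared bracket so that
  $\Delta\bar z_B\,G_{SS} = \Delta\bar z_S\,G_{SB}$ holds to the last ulp
  along any trajectory, and the $B/S$ ratio of changes is exactly
  $G_{SB}/G_{SS}$.
* **Initial means** default to $(0,0,0)$ and are always recorded in the
  resolved run configuration, because equilibria on a *line* depend on
  where you start.

## Equilibria and stability

Aggression equilibrates at $\hat{\bar z}_A = b_A/c_A$ whenever $c_A > 0$
(with $c_A = 0$ the model has no finite aggression equilibrium and the
function says so). Signal and body size share a line of equilibria

$$\hat{\bar z}_S = \theta_S + \frac{2\delta_{AS} b_A}{c_S}
  + \frac{\delta_{AS} c_B}{c_S}\,\hat{\bar z}_B,$$

whose slope is the predicted evolutionary allometry of signal on body
size across populations. The inverse form (body on signal) is *derived*
from this line rather than implemented independently; the derivation
reproduces the printed closed form
$\hat{\bar z}_B = \frac{c_S}{\delta_{AS} c_B}(\hat{\bar z}_S - \theta_S)
- \frac{2 b_A}{c_B}$ exactly, so there is no sign ambiguity between the
two, and a test asserts their consistency.

The $(S, B)$ update map has a rank-one Jacobian: one eigenvalue is always
0 (neutral motion along the line), the other is
$\tfrac12(G_{SB}\delta_{AS} c_B - G_{SS} c_S)$. The runaway condition

$$\frac{G_{SB}}{G_{SS}}\,\delta_{AS}\,c_B > c_S$$

is equivalent to that eigenvalue being positive, and both are equivalent
to `simulate_trajectory()` diverging — the package tests all three
diagnostics against each other on random parameter sweeps. Two
implementation details:

* The Jacobian is restricted to the $(S, B)$ subsystem. The aggression
  recursion is autonomous and contracting whenever
  $0 < \tfrac12 G_{AA} c_A < 2$, so it cannot change the classification;
  this is stated in the report rather than silently assumed.
* **Dead band.** Within $10^{-9}$ of a zero margin the case is reported
  as `"marginal"` instead of being classified: the knife edge is not
  numerically decidable, and pretending otherwise would make the
  classification seed-dependent.
* The margin is computed with the grouping (covariance ratio) ×
  (responsiveness × threat), bit-identical to the female-choice
  comparator below.

## What the individual-based simulator emulates — and what it does not

`sample_males()`, `run_contests()` and `next_generation_means()` realise
the model generatively: breeding values from the trivariate normal with
covariance `G_matrix()`, independent environmental deviations, a random
perfect matching into dyads, context-dependent aggression, fitness plus
mean-zero Gaussian noise, within-sample normalisation to relative
fitness, and reproduction by multinomially sampling sires in proportion
to non-negative relative fitness, each offspring inheriting
$\tfrac12 a_{sire} + \tfrac12 \bar a$ (dams are unselected and carried at
the population mean — the minimal machinery that realises the $\tfrac12$
male-limited multiplier).

Chosen-once defaults, with reasoning:

* **Environmental variances** $E_{SS}=E_{BB}=E_{AA}=1$ against unit
  genetic variances, i.e. $h^2 = 0.5$ — the conventional round figure for
  morphological and behavioural traits; $E_{SB} = 0$ so that honesty is
  purely genetic unless a user says otherwise.
* **Fitness noise** $\varepsilon \sim N(0,\, 0.01\,w_0^2)$. The model is
  silent on the distribution of $\varepsilon$; normality is assumed and
  the variance kept small relative to the intercept.
* **Intercept calibration.** The fitness surface is a relative-fitness
  model, so its expectation should be 1 at the generating state. Because
  the quadratic cost terms have nonzero Gaussian expectations
  ($E[z_A z_A'] = \bar z_A^2 - 2\delta_{AS}^2\sigma_S^2$,
  $E[z_A' z_B'] = \bar z_A \bar z_B + \delta_{AS}(G_{SB}+E_{SB})$), a
  fixed $w_0$ leaves $E[w]$ far from 1 — even negative — at displaced
  states such as $\bar z_B = 10$. `calibrate_w0()` solves $E[w] = 1$ in
  closed form, and `make_contest_table()` applies it by default, which
  keeps the within-sample normalisation asymptotically inert and the
  regression estimators on the analytic scale. $w_0$ remains an ordinary
  user-settable parameter.
* **Seed substreams.** One user seed expands deterministically into
  independent seeds for sampling, pairing, noise and reproduction
  (Lehmer step modulo $2^{31}-1$), so each phase is separately
  reproducible and a table regenerates bit-identically.

Features of real data the generator deliberately does **not** emulate:
finite-population drift in the deterministic layer, mutation, linkage and
$G$-matrix evolution, overlapping generations, repeated or assortative
contests, female trait evolution, and any non-Gaussian trait
architecture. Passing tests therefore certify the *model arithmetic* and
the estimators under the model's own assumptions — they do not certify
that natural populations behave this way.

### The truncation boundary of the local fitness model

One limitation deserves its own section, because the test suite measures
it rather than hiding it. The quadratic fitness surface is a *local*
model. Realising it as reproduction requires non-negative weights at mean
relative fitness 1, yet with the reference coefficient scales the
standard deviation of $w$ is already a substantial fraction of 1 at the
origin — so a visible share of males draws negative fitness and is
truncated to zero weight (`truncation_count` reports how many). Three
verified consequences:

* In a weak-selection regime (coefficients scaled down until truncation
  is negligible) the replicate-averaged one-generation response is an
  unbiased realisation of the deterministic recursion, within
  Monte-Carlo error.
* At the full reference coefficient scale, truncation damps the realised
  one-generation response by a few percent — small, but larger than the
  Monte-Carlo precision of a large experiment, so exact-scale agreement
  should not be expected there and the suite asserts the damping
  explicitly instead.
* Along a runaway the means grow, the quadratic terms inflate
  $\mathrm{Var}(w)$, the truncated share grows with them, and the
  individual-based runaway becomes sub-exponential: aggression still
  plateaus at $b_A/c_A$ and signal and body size keep elaborating in the
  exact $G_{SB}/G_{SS}$ ratio, but the *acceleration* of the
  deterministic recursion is progressively eaten by truncation. Users
  should treat the individual-based layer as quantitatively faithful
  near the origin and qualitatively faithful far from it.

## Estimation layer

`estimate_gradients()` is the standard selection analysis: OLS of
relative fitness on the six focal/opponent traits. Because the
generator's traits are jointly Gaussian, the partial-regression slopes
equal the average derivatives of the quadratic fitness surface (Stein's
lemma), which is exactly the condition under which gradient regression
recovers the analytic gradients — worth remembering before applying the
same regression to strongly non-Gaussian field data. Details:

* **Standard errors.** Relative fitness is raw fitness divided by its
  *estimated* sample mean. That scale estimate carries sampling variance,
  and for large gradients it dominates the coefficient uncertainty, so
  reported standard errors add the delta-method term
  $\hat\beta^2\,\widehat{\mathrm{Var}}(w)/n$ to the OLS variance. A
  Monte-Carlo test in the suite confirms the combined SE tracks the
  empirical spread of the estimator while the bare OLS SE understates it
  severalfold.
* **Collinearity guard.** When intrinsic aggression has (near-)zero
  variance, realised aggression is an exact linear combination of the two
  signals and the six-predictor regression is singular; the fit aborts
  naming the offending predictors rather than returning garbage.
* **No variance-standardisation by default** — the model lives on natural
  trait scales; `standardize = TRUE` adds SD-scaled copies for
  comparability with empirical conventions.
* `estimate_responsiveness()` regresses realised aggression on the signal
  difference; it is unbiased *because* $G_{SA} = E_{SA} = 0$ in the
  generator. If that assumption were relaxed the OLS slope would absorb
  the covariance — noted, not solved, since the model fixes the
  covariance at zero.
* `recover_costs()` inverts the gradient expressions at known means
  ($c_B = -\hat\beta_{SB}/\bar z_A$, $c_S = -\hat\beta_{NS}/(\bar z_S -
  \theta_S)$, and $b_A, c_A$ from $\hat\beta_{NA}$ at two states with
  different mean aggression), propagating SEs by the delta method. Means
  too close to zero are refused with a pointer to a shifted-state design
  — an empiricist's two-population protocol.

## The female-choice comparator

`lande_line()` and `lande_runaway()` implement the line of equilibria and
runaway condition of the classical female-choice model, and
`as_lande_params()` applies the structural mapping
($G_{mf} \leftrightarrow G_{SB}$, $G_{mm} \leftrightarrow G_{SS}$,
$b_{SS} \leftrightarrow \delta_{AS} c_B$, $c_{NS} \leftrightarrow c_S$).
Under that mapping the two mechanisms' slopes and margins agree exactly
(bit for bit — the expressions are grouped identically on purpose), which
makes the conceptual parallel checkable: both runaways are driven by a
genetic covariance, arising from linkage disequilibrium under assortative
mating in one case and from pleiotropic signal honesty in the other. The
comparator is deliberately static; simulating preference–trait
coevolution is a non-goal.

## Problem sizes

The test suite uses populations of $10^3$–$2\times10^5$ males and up to
20 replicates for stochastic recovery checks, and the acceptance script
uses $10^4$ males for responsiveness recovery and $10^5$ for gradient
inversion — sizes at which every recovered coefficient sits well inside
its 3-SE band while the whole suite stays fast.

## Known limitations

* The fitness surface is local; far from the origin the truncation
  boundary (above) is the binding constraint on quantitative agreement.
* The deterministic layer assumes constant $G$; a long runaway would in
  reality erode genetic variance.
* One duel per male per generation; repeated or networked interactions
  would change the variance of the social environment.
* The dead band makes knife-edge parameter sets unclassifiable by design.
* Estimators assume jointly Gaussian predictors; heavy-tailed or censored
  field data need different machinery (quadratic gradients, animal
  models), which is out of scope here.
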