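---
title: "Methods: the two-level q-voter model with independence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-level q-voter model with independence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvoter2L)
```

## The model and its assumptions

Each of `N` agents carries a public opinion $S_i = \pm 1$ and a private
opinion $\sigma_i = \pm 1$. Dynamics are random sequential: one uniformly
chosen agent updates per elementary step, and one Monte Carlo step (MCS)
is `N` elementary steps. At each update, each opinion level independently
acts *without* social influence ("independence") with probability $p$,
and by conformity to a q-panel — $q$ distinct neighbours drawn without
repetition, excluding the focal agent — with probability $1-p$.

The per-level rules encode two psychological asymmetries. First,
behaviours are easier to move than beliefs: on the public level an agent
in internal conflict ($S \ne \sigma$) goes public with its private
opinion as soon as a *single* panel member publicly supports it, while an
agent in harmony, and any agent on the private level, yields only to a
*unanimous* panel. Second, independence acts differently at the two
levels: publicly it means expressing one's private opinion
($S \to \sigma$); privately it means reconsidering, a random flip
$\sigma \to -\sigma$ with probability $1/2$. The flip probability is
frozen at $1/2$ because it only rescales the effective independence axis;
exposing it as a free dial would add a parameter without adding
behaviour.

One elementary update touches both levels, and the order matters. In the
**AT** (act-then-think) variant the public level is updated first, using
the agent's *current* private opinion; in **TA** (think-then-act) the
private level is updated first and the public step sees the *already
updated* private opinion, $S_i(t+1/N) = \sigma_i(t+1/N)$. Both variants
are simulated by the same engine; `elementary_update()` exposes the rule
as a pure function of the state, the panels and three uniform draws, so
every microscopic case is directly testable.

Two modelling choices are deliberately simple and worth stating. The two
per-step panels (public step, private step) are drawn independently; the
model statement does not fix whether the panel is re-drawn between
sub-steps, and the infinite-N rate equations are unaffected by this
choice, so we take the variant that keeps the two sub-steps exchangeable
pieces of code. Likewise, the conformity rule for a conflicted agent
facing a panel unanimously opposed to its private opinion is a literal
no-op (the "at least one supporter" condition simply fails); no extra
rule is invented for that corner.

## Observables

With class fractions $c_{\uparrow\uparrow}, c_{\uparrow\downarrow},
c_{\downarrow\uparrow}, c_{\downarrow\downarrow}$ (first arrow public),
the marginals are $c_S = c_{\uparrow\uparrow} + c_{\uparrow\downarrow}$
and $c_\sigma = c_{\uparrow\uparrow} + c_{\downarrow\uparrow}$, the
dissonance is $d = c_{\uparrow\downarrow} + c_{\downarrow\uparrow}$, and
the public–private Pearson correlation reduces to

$$\rho_{S,\sigma} =
  \frac{c_S(1-c_\sigma) + c_\sigma(1-c_S) - d}
       {2\sqrt{c_S c_\sigma (1-c_S)(1-c_\sigma)}},$$

which is reported as `NA` when a marginal is degenerate ($c_S$ or
$c_\sigma \in \{0,1\}$) — the correlation of a constant is undefined, and
a sentinel is safer than a silent 0 or 1. If the levels were independent,
$d$ would equal $c_S(1-c_\sigma) + c_\sigma(1-c_S)$
(`dissonance_independent()`), which makes $\rho = 0$; measured deviations
from that value are exactly what distinguishes AT from TA.

## Monte Carlo engines

On the complete graph the dynamics depend on the configuration only
through the four class counts, so the default engine tracks counts alone
and draws each panel's $+1$ content hypergeometrically from the $N-1$
non-focal agents — the exact finite-N law, not its binomial large-N
approximation. The per-agent engine handles arbitrary neighbour lists
(every vertex needs degree $\ge q$) and can record influence events. Both
inner loops are in C++ (Rcpp) and consume R's RNG, so a single integer
seed makes a trajectory bit-reproducible; ensemble member $k$ uses
`base_seed + k`. Equivalence of the two engines on the complete graph is
checked by a two-sample comparison of stationary observables in the test
suite.

Defaults a user may care about: recording every 1 MCS; stationary
summaries average the final 25% of the horizon (a settled window for the
horizons used here — callers doing hysteresis scans near a spinodal
should lengthen the horizon rather than widen the window). Built-in
initial conditions start dissonance-free (`ordered`: all $+1$;
`symmetric-random`: a shared random sign per agent);
`population_from_fractions()` builds arbitrary feasible
$(c_{S0}, c_{\sigma 0}, d_0)$ triples for metastability studies.

## Mean-field layer

Two descriptions are implemented. The *simplified* rate equations treat
the levels as statistically independent, giving closed rates
$\gamma_S^\pm, \gamma_\sigma^\pm$ identical for AT and TA. The *exact*
four-class rate equations are assembled from per-level single-step
kernels: the probability that the public opinion lands on $+1$ given
$(S, \sigma)$ and the panel law, and similarly for the private level; the
AT/TA difference enters through which $\sigma$ the public kernel sees.
Because the published forms of these exact rates are not available, the
implementation is validated against `drift_oracle()`: a brute-force
expectation over every branch of one elementary update (focal class, both
independence decisions, the flip coin, both panel compositions) routed
through the microscopic `elementary_update()` itself. The two agree to
$10^{-12}$ on random states for both orderings; this dual-route check is
the package's strongest correctness guarantee.

One subtlety the oracle exposed: at a *product* state
($c_{\uparrow\uparrow} = c_S c_\sigma$, …) the exact marginal drifts
collapse onto the simplified rates for AT at both levels, but for TA only
at the private level — TA's public step sees the updated private opinion,
so its public marginal is coupled to the within-step transition even at
product states. At stationarity the two descriptions nevertheless give
identical concentrations for both orderings (reproduced to $10^{-7}$ by
the solvers), which is the model's striking degeneracy: ordering matters
for $d$ and $\rho$, never for $c_S, c_\sigma$ on the complete graph.

Numerical choices:

* **ODE integration** (`integrate_meanfield()`): `deSolve::lsoda`,
  `rtol = 1e-10`, `atol = 1e-12`; the state is clipped to the simplex
  before evaluating rates; drifts sum to zero by construction, and tests
  verify simplex conservation to $10^{-10}$ along trajectories.
* **Stationary states** (`stationary_states()`): for the simplified
  system the private balance is solved analytically for
  $c_\sigma(c_S)$ and the remaining 1-D balance is bracketed on a
  401-point grid and polished by bisection to $\sim 10^{-14}$; the
  symmetric point $c = 1/2$ (always fixed, by the global spin-flip
  symmetry) is always reported. For the four-class system a multi-start
  damped Newton search runs over the 3-simplex, seeded from product
  states of the simplified fixed points, symmetric states of varying
  dissonance, and a coarse simplex grid; starts that fail are pre-relaxed
  along the flow before a second polish, duplicates are merged within
  $10^{-8}$, and nothing with residual above $10^{-9}$ is reported.
* **Stability**: eigenvalues of a central-difference Jacobian (step
  $10^{-6}$); any eigenvalue with $|\mathrm{Re}\,\lambda| < 10^{-9}$
  flags the point `marginal` instead of forcing a stable/unstable call.
  Points repelling in some directions only are labelled `saddle`; below
  $p^*$ the symmetric point is typically a saddle of the two-concentration
  system (unstable along the order parameter).
* **Transition classification** (`transition_type()`): the lower spinodal
  is the zero of the symmetric point's leading eigenvalue in $p$
  (bisection to $10^{-12}$); the upper spinodal is the largest $p$ still
  supporting a stable ordered root (bisection to $10^{-6}$). A
  transition is discontinuous when the two differ beyond the bisection
  resolution; the closed form
  $p^* = [\,1 - 2^{q-1} + \sqrt{(1-2^{q-1})^2 + 4q(q-1)}\,]/(2q)$ is
  validated against the numerical spinodal to $10^{-6}$ before being
  relied on (the test suite pins $p^*(2) = 1/2$ exactly). The one-level
  baseline (`original_qvoter_stationary()`) runs through the same
  machinery with the single-concentration drift.

```{r phases, eval = FALSE}
vapply(2:8, function(q) transition_type(q)$type, character(1))
# continuous for q <= 4, discontinuous from q = 5 on;
# the one-level baseline first turns discontinuous at q = 6
```

## Response-pattern taxonomy and event instrumentation

A single influence trial at one level is a Willis triplet (pre-influence
position, source position, response), coded C/I/A/U. Measuring both
levels gives $2^5 = 32$ sign combinations that collapse under global
negation into 16 patterns (`response_patterns()`, from congruence through
compliance, conversion and disinhibitory contagion to independence);
`classify_pattern()` canonicalises the source to $+1$ and looks the
pattern up. Exhaustiveness — exactly 16 classes of size 2 — is asserted by
enumeration in the tests.

Classifying *simulated* events needs a convention for "the source's
position", which the model itself does not single out; the package's
instrumentation choice, implemented in the event recorder, is:

* a conflicted agent's public conformity step always has a determinate
  source: the private opinion's public match when at least one panel
  member supports it, otherwise the panel's (necessarily unanimous)
  opposing opinion;
* a unanimous panel's common opinion is the source for harmony-state and
  private-level conformity;
* a mixed panel that changes nothing contributes a "spokesperson": a
  uniformly chosen panel member's opinion;
* when only one level acted by conformity, its source labels the event;
  when both did, the public-level source wins (one trial, one visible
  source); fully independent events carry no source and are tallied as
  unclassifiable.

This convention guarantees that conformity-only dynamics ($p = 0$)
produce fully classifiable event streams, and it is a measurement-layer
choice only — it never feeds back into the dynamics.

## What the generator emulates, and what it does not

The built-in experiment configurations (in `inst/extdata/configs/`)
reproduce the reference scenarios at desk scale: complete graphs of
$N = 10^4$ agents, horizons of 500–2000 MCS, ensembles of 10–200
trajectories, against the original large-scale settings of
$N = 10^5$–$10^6$, $10^5$ MCS and 100–1000 samples. The test suite runs
ensemble–mean-field comparisons at $N = 10^4$ with 200 samples over 50
MCS for $q \in \{4, 6\}$, $p \in \{0.2, 0.5\}$ (agreement within three
standard errors of the ensemble mean), and two-engine and AT/TA-ordering
checks at $N \in \{2 \times 10^3, 10^4\}$; these sizes make the whole
suite run in minutes while keeping finite-size bias ($O(1/N)$) below the
Monte Carlo resolution of the comparisons. What passing at this scale
does *not* show: critical exponents or sharp finite-size scaling near
$p^*$ (desk-scale systems round the transition), long-time metastable
escape statistics (horizons are far below typical escape times at
$N = 10^4$ except very near the spinodal), and any behaviour specific to
sparse or heterogeneous networks — the engine simulates arbitrary graphs,
but all analytics are complete-graph mean-field.

## Known limitations

* The mean-field layer is exact only in the infinite complete-graph
  limit; no heterogeneous/pair approximation for complex networks is
  provided.
* Anticonformity as a driving interaction and fixed-trait
  (person-oriented) agents are out of scope; independence is the only
  nonconformity channel, drawn fresh at every step.
* The event classifier's source convention (above) is one defensible
  instrumentation among several; pattern frequencies for mixed panels
  depend on it.
* `stationary_states(variant = "pairstate")` is a multi-start search:
  it is deterministic and well-seeded, but in principle a fixed point far
  from all seeds could be missed; the scans used here are corroborated by
  the simplified solver and by simulation.
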