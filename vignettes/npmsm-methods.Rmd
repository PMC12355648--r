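---
title: "Nonparametric intensity estimation for interval-censored multistate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric intensity estimation for interval-censored multistate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmsm)
```

## The estimation problem

A multistate process $X(t)$ moves among states $\mathcal{H} = \{1,\dots,H\}$
along the edges $\mathcal{V}$ of an acyclic directed graph (no loops, no
self-edges: with loops the number of visits to a state is not identifiable
from panel data, and a nonparametric estimator cannot be consistent).
Movement is governed by transition intensities
$\alpha_{gh}(t)$ with cumulatives $A_{gh}(t) = \int_0^t \alpha_{gh}(s)\,ds$,
and under the Markov assumption the transition probability matrix is the
product integral
$$P(s,t) \;=\; \prod_{(s,t]} \big(I + dA(u)\big),$$
the continuous generalisation of multiplying one-step transition matrices.

Subjects are observed only at visit times: we know the state at each visit
but not when transitions happened (interval censoring / panel data).  The
observed-data likelihood is a product of transition probabilities between
consecutive visits.  As in Turnbull's treatment of interval-censored
survival data, the nonparametric MLE can only place increments between
consecutive *unique* observation times, so the estimation problem is reduced
to jump sizes $\alpha_{ghk}$ of $A_{gh}$ at the pooled unique visit times
$\tau_1 < \dots < \tau_K$, with bin $k = (\tau_{k-1}, \tau_k]$ and the mass
of a bin at its right endpoint (a right-continuous step function).  Only the
total mass over a *support interval* is identified; the per-bin split inside
one is not, which is why all cross-checks in this package compare
log-likelihoods, not individual jumps.

## The EM algorithm

The complete data are the multinomial transition counts per bin.  Writing
$d_{ghk}$ for the number of $g \to h$ transitions in bin $k$ and $Y_{gk}$
for the number of subjects in $g$ just before $\tau_k$, the (Poisson-style
approximation of the) complete-data log-likelihood is
$\sum_{k}\sum_{(g,h)} d_{ghk}\log \alpha_{ghk} - \alpha_{ghk} Y_{gk}$.

**E-step.**  Conditional on the observed visits and current jumps
$\tilde\alpha$, the expected counts for the bin $(\tau_{k-1},\tau_k]$ inside
a subject's observation interval $(l, r]$ with endpoint states $(a, b)$ are
$$
\mathbb{E}[d_{ghk}] = \frac{\tilde P_{ag}(l,\tau_{k-1})\,
  \tilde\alpha_{ghk}\, \tilde P_{hb}(\tau_k, r)}{\tilde P_{ab}(l,r)},
\qquad
\mathbb{E}[Y_{gk}] = \frac{\tilde P_{ag}(l,\tau_{k-1})\,
  \tilde P_{gb}(\tau_{k-1}, r)}{\tilde P_{ab}(l,r)} .
$$
These are computed with one forward and one backward accumulated product
per observation interval (compiled code), so an EM iteration costs
$O(\sum_i K_i H^2)$ rather than $O(K^2 H^3)$.

**M-step.**  The jumps are conditional probabilities constrained to
$C_\alpha$: $\alpha_{ghk} \ge 0$ and $\sum_{h \leftarrow g}
\alpha_{ghk} \le 1$.  The constrained maximiser is
$\alpha_{ghk} = d_{ghk}/Y_{gk}$ when the multiplier
$\mu_{gk} = \max(0, \sum_h d_{ghk} - Y_{gk})$ vanishes and
$d_{ghk} / \sum_h d_{ghk}$ otherwise.  In EM iterates the per-subject
expected exits never exceed the expected risk, so $\mu$ activates only in
boundary situations created by exactly observed entries (all at-risk mass
must exit at the entry bin).

**Exactly observed states.**  For a declared subset $\mathcal{E}$ (death
states, typically) an observation in $b \in \mathcal{E}$ at $t = \tau_{k_r}$
means entry exactly then, necessarily from a direct predecessor
$m \in \mathcal{R}_b$ occupied at $\tau_{k_r - 1}$.  The backward vector of
the E-step is then seeded with $\tilde\alpha_{m b k_r}$ at $\tau_{k_r-1}$
and the normaliser becomes
$D = \sum_{m \in \mathcal{R}_b} \tilde\alpha_{mbk_r}
\tilde P_{am}(l, \tau_{k_r-1})$.  The published expectations cover the bins
before the entry bin; for the entry bin itself we use the factorisation
implied by the observed-data likelihood: the expected $m \to b$ count (and
the at-risk mass in $m$) is
$\tilde P_{am}(l,\tau_{k_r-1})\,\tilde\alpha_{mbk_r}/D$.  Evaluating the
general formula at $k = k_r$ gives exactly this for $Y$, and the EM
monotonicity of the mixed likelihood (tested) validates the treatment of
$d$.

**Stopping rules and the KKT certificate.**  Three criteria are available:
`intensity` (default; largest absolute change in any jump below `tol`),
`likelihood` (absolute change in the observed log-likelihood; the absolute
rather than relative form is a package choice, the source being silent),
and `kkt`.  The reduced gradient
$\nabla_{ghk} = d_{ghk}/\alpha_{ghk} - Y_{gk} - \mu_{gk}$ (at interior
points; a guarded one-sided value at zero jumps, which is identically zero
in EM iterates because expected counts carry a factor of the current jump)
measures how much the expected complete-data objective can still improve;
`max` $\nabla < \varepsilon$ certifies a (local) maximum.  Note the
gradient lives on the expected-count scale: an intensity tolerance of
`1e-4` leaves gradients around $10^{-2}$ on moderate data, and a
certificate at $10^{-3}$ requires tightening the intensity tolerance to
roughly $10^{-7}$–$10^{-8}$.  Zero jumps are absorbing, hence the uniform
strictly positive default initialisation $\tilde\alpha_{ghk} = 1/K$ — shrunk
to $0.9/\max_g |\mathrm{out}(g)|$ in the degenerate corner where a state's
out-degree reaches $K$, so every stay probability starts positive; with
realistic grids this never differs from $1/K$.  Empty risk sets yield zero
jumps, not `NaN`, and a zero observed-path probability raises a classed
error naming the subject and interval rather than propagating `NaN`s.

## What the simulator states

`scenario_preset(1..6)` encodes the benchmark illness-death designs: a
15-year horizon, everyone observed at time 0, inter-visit gaps
$U(0, 4.4)$ (scenarios 1–4), scheduled panel visits $3j + U(-0.1, 0.1)$
(scenario 5), or gaps $U(0, 2.44)$ / $U(0, 7.33)$ (scenario 6), with
exponential hazards of rates $0.1, 0.05, 0.1$ for
$1\to2, 1\to3, 2\to3$, start state 1 (scenarios 1, 3, 4) or uniform on
$\{1, 2\}$ (2, 5, 6).  Scenario 3 replaces the hazards by Weibulls
(survivor $e^{-\lambda t^k}$) with shapes $(0.5, 0.5, 2)$ and rates
$(1/\sqrt5, 1/\sqrt{10}, \Gamma(1.5)^2/100)$.  The printed Weibull
parameters are garbled in the source; these values are reconstructed from
the source's own constraint that mean transition times match the
exponential scenarios ($\lambda^{-1/k}\Gamma(1+1/k) = 10, 20, 10$), in
agreement with the readable fragments.  Scenario 5's table entry
(`U[2.9,3.1]` inter-visit gaps) conflicts with its text (scheduled visits
deviating at most 0.1 years); we follow the text, so gaps lie in
$[2.8, 3.2]$.

Hazards are sampled on the *study* clock (conditional on the entry time
into the current state), making the generated process Markov in study time
— the estimator's assumption.  A semi-Markov `clock = "reset"` variant
exists for robustness experiments only and has no Markov truth for the
evaluation module.  Exact entries into states of $\mathcal{E}$ are recorded
at their true times whenever they precede the horizon, as death
registrations would be.  Visits after the first observation of an absorbing
state are dropped by default (they carry no likelihood information, and the
source's "average of 6 observations per subject" arithmetic is consistent
only with dropping); `drop_absorbed = FALSE` retains them, which leaves
every estimate unchanged but densifies the grid of unique times.

The generator emulates the benchmark designs' visit processes and
censoring; it does not emulate visit processes that depend on the latent
state (the conditionally-independent-visits assumption), covariates, or
measurement error in the recorded states.  A green parameter-recovery test
therefore establishes correctness under the stated world, not robustness to
those violations.

## Numerical and design choices

* **Bin convention**: mass at right endpoints; $P(s,t)$ multiplies the bins
  with $s < \tau_k \le t$; queries at non-grid times are supported by that
  rule.
* **Grid**: the unique non-baseline visit times; $\tau_0 = 0$ when all
  subjects start at 0, otherwise the earliest first visit.  A subject
  contributes nothing outside its own observation span (no extrapolation).
  `panel_dataset(extra_times=)` can refine the grid; finer bins never
  change the attainable likelihood.
* **Config format**: model configs are JSON (no YAML parser is available in
  the target environment).
* **True transition probabilities** solve the Kolmogorov forward system
  with an adaptive Cash–Karp RK45 (no ODE package in the target
  environment; validated against the constant-rate closed form at
  $10^{-6}$).  Weibull shapes below one have a hazard singularity at the
  origin, bridged over the first $10^{-8}$ years by the matrix exponential
  of the exact cumulative-hazard increment.
* **Oracles**: the Turnbull self-consistency fit places mass on the
  elementary intervals cut by all unique endpoints — a refinement of the
  innermost intervals with the same maximised likelihood (the objective is
  concave in the masses and depends on them only through interval sums);
  comparisons are on log-likelihoods because the NPMLE's within-support
  split is not identified.  The brute-force maximiser optimises a stable
  multinomial-logit reparameterisation of each (state, bin) exit simplex
  from multiple random starts and shares no code with the EM path.
* **Replication metrics** use the unbiased variance ($N-1$) and read step
  functions right-continuously, so `rmse^2 = var + bias^2` holds to
  rounding.

## Reproducing the benchmark iteration counts

The benchmark reports mean (SD) iteration counts of 331 (155) at $n=100$
and 513 (128) at $n=500$ for the time-varying design (scenario 3) under a
stated stopping tolerance of $10^{-3}$ on "the change in all transition
intensities".  With the max-norm reading of that rule this implementation —
whose fixed points are verified against the Turnbull and brute-force
oracles to $10^{-6}$, and whose per-iteration map is the published update —
converges in means of roughly 113 ($n=100$) and 85 ($n=500$): a third of
the printed counts, and *decreasing* with $n$ where the printed counts
increase.  No faithful variant of the rule reproduces both cells at
$10^{-3}$ (per-transition $L^1$: 240/510; $L^2$: 200/147;
cumulative-hazard change: 170/115; likelihood change: 167/540; relative
change: no convergence within 3000 iterations).  The closest
reconstruction is the max-norm rule at $10^{-4}$ — the tolerance the
source's *application* section uses — with the full visit schedule
retained, giving roughly 390--425 / 530; its $n=100$ mean still sits about
half a published SD above the printed value.  Because iteration counts are
a property of the stopping rule rather than of the estimator, and the
printed tolerance is demonstrably inconsistent with the printed counts, the
iteration-count acceptance test runs the stated rule ($10^{-3}$, max norm)
and is expected to fail its bands; the reconstruction above documents why.
Replicate counts are 25 at $n=100$ and 6 at $n=500$ (budget), the band
widening with the criterion's own $\sqrt{N}$ formula.

## Known limitations

* The cumulative-intensity NPMLE carries finite-sample bias at later study
  times where risk sets have thinned: in the benchmark recovery design
  (equal starting probability in both transient states, $n=500$) the
  healthy-to-ill cumulative is under-estimated by about $0.05$–$0.08$ over
  $t \in [8.5, 12]$, shrinking to $0.01$–$0.03$ at $n=1000$ — consistent
  with the estimator's cube-root convergence rate.  Tightening the EM
  tolerance *increases* this bias (partial convergence from the uniform
  initialisation acts as regularisation), and a denser late grid does not
  remove it.  The recovery acceptance test, which demands $|{\rm bias}| <
  3\,{\rm SD}/\sqrt{20}$ (about $0.06$) across $t \in [2,12]$, therefore
  sits at the same magnitude as the true bias and is not met reliably; it
  is kept at its stated form and pre-registered seed rather than loosened.
* The NPMLE need not be unique (flat within support intervals); jumps at
  individual bins should not be over-interpreted — prefer transition
  probabilities, which are stable where risk sets are adequate.
* Small risk sets (a transient state that no subject occupies at baseline)
  produce jumps near one with large variance early in the study; this is a
  property of the estimator, visible in the scenario 1/3 benchmarks.
* Sparse observation schedules (scenario 5: no information for stretches of
  nearly three years) make the cumulative intensities oscillate around the
  truth; the estimator is only as good as the density of unique visit
  times.
* No covariates, no smoothing, no confidence bands (the convergence rate of
  the NPMLE under continuous visit distributions is cube-root; bootstrap is
  the practical route and is out of scope here), no state-set ("censored
  state") observations, no truncation.

## Worked example

```{r example, eval = FALSE}
gr <- transition_graph(c("healthy", "ill", "dead"),
                       rbind(c("healthy", "ill"),
                             c("healthy", "dead"),
                             c("ill", "dead")),
                       exact_states = "dead")
spec <- scenario_spec(gr,
                      list("healthy->ill" = haz_exponential(0.1),
                           "healthy->dead" = haz_exponential(0.05),
                           "ill->dead" = haz_exponential(0.1)),
                      start_dist = c(1, 0, 0),
                      visits = visits_uniform(0, 4.4))
sim <- simulate_dataset(spec, n = 200, seed = 1)
fit <- fit_npmsm(sim$data, tol = 1e-4)
fit
head(as.data.frame(fit$alpha))
transition_probability(fit$alpha, 0, 10)
```
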