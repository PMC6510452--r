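---
title: "Age-structured cultural transmission: model, assumptions, and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured cultural transmission: model, assumptions, and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agelearn)
```

## The model

`agelearn` couples two deterministic recursions over five discrete life
stages (infancy, early childhood, late childhood, adulthood, and
post-reproductive life).

**Demography.** Stage counts $n_i$ advance through an adapted Leslie matrix
in which only stage 4 reproduces and stage-5 survivors remain in stage 5:

$$
n' = L\,n,\qquad
L=\begin{pmatrix}
0&0&0&f_4&0\\ s_1&0&0&0&0\\ 0&s_2&0&0&0\\ 0&0&s_3&0&0\\ 0&0&0&s_4&s_5
\end{pmatrix}.
$$

A dichotomous cultural trait $T$ at frequency $x_i$ in stage $i$ can raise
(or lower) fertility, $f_4=(b+w_f)x_4+b(1-x_4)$, or survival,
$s_i \mapsto s_i + w_s x_i$ in every stage — one or the other in a given run
(the `mode` flag), matching how the canonical experiments are designed.
There is no density dependence, migration, or two-sex structure.

**Learning.** Naive individuals make one learning attempt per step; carriers
never unlearn. Newborns learn only from their parents: with vertical
fidelity $p_v$, the newborn frequency is $p_v$ times the fertility-weighted
parental frequency $g(x_4) = (b+w_f)x_4 / [(b+w_f)x_4 + b(1-x_4)]$. A cohort
entering stage $j\in\{2,3,4\}$ splits its learning between a vertical
channel (share $V_j$, success $p_v$ against the parental frequency) and a
pooled horizontal/oblique channel (share $1-V_j$, success $p_h$ against the
size-weighted trait frequency of stages $j$ through $\omega$):

$$
x_j' = x_{j-1} + (1-x_{j-1})\Big[V_j\,C\,p_v + (1-V_j)\,p_h\,
\frac{\sum_{z=j}^{\omega} n_z x_z}{\sum_{z=j}^{\omega} n_z}\Big],
$$

where $C$ is the trait frequency among the cohort's parents, weighted by the
trait's fitness effect (fertility weighting $g$, or the survival discount
$(s_4+w_s)^j x/[(s_4+w_s)^j x + s_4^j(1-x)]$, or the identity for a neutral
trait). Stage 5 does not learn; its frequency is the survival-weighted
merge of maturing adults and previous stage-5 survivors.

**Niche construction.** With the feedback enabled, the fixed schedule $V_j$
is replaced by a frequency-dependent vertical contact time
$v = v_b(1-\epsilon\,x_4^{\text{lag}})$: as the trait spreads through the
adult population, children spend less time with parents and more with peers
and unrelated elders. $\epsilon=0$ recovers the fixed-schedule model with
$V_j = v_b$ exactly (bit-identical trajectories; this is a tested
invariant). The newborn round is left unmodified by the feedback: the
combined recursion is defined for stages 2–4, and infancy is treated as
irreducibly parental.

## Conventions the equations do not fix

Three details are underdetermined by the recursions as usually written, and
we fixed them once, as follows.

**Update order.** All five new frequencies are computed synchronously from
the time-$\tau$ state; counts then advance through the projection matrix
built from time-$\tau$ frequencies; finally the adult frequency is pushed
onto a lag buffer and $\tau$ increments.

**Parental lag.** A cohort entering stage $j$ at time $\tau+1$ was produced
$j-1$ steps before the current state, so the parental frequency $C$ and the
contact time $v$ are evaluated at the adult frequency lagged $j-1$ steps
(buffer padded with the initial adult frequency; the trait starts near
absence, so padding is numerically negligible). This cohort-consistent
convention is the unique one under which the newborn equation and the
stage updates describe the same genealogy, and under which the
individual-based model (below) — where each newborn's parent is drawn at
birth — has the deterministic recursion as its exact large-population mean.
The survival discount still compounds over the $j$ steps the parents have
survived since reproduction.

**Pool bounds.** The horizontal/oblique pool runs from the learner's new
stage $j$ through $\omega$ (default 5), using time-$\tau$ sizes and
frequencies. If $\omega<j$ the pool is empty and the non-vertical term
contributes nothing.

Two further simplifications are inherited deliberately from the recursion's
standard form: the oldest-stage merge weights by the baseline survivals
$s_4, s_5$ even in survival mode (within-stage differential survival of
carriers is not tracked there), and the cohort-carryover term is not
survival-weighted. Both matter only in survival mode and are the reason the
individual-based comparison below is run for fertility-mode and neutral
traits.

## Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| `b` | offspring per stage-4 non-carrier per step | 5 |
| `s` | per-stage survival probabilities | (0.5, 0.6, 0.6, 0.6, 0.2) |
| `w_f` | additive fertility effect of the trait | 1 |
| `w_s` | additive survival effect (all stages) | 0.05 |
| `p_v`, `p_h` | transmission fidelities (per-attempt acquisition probabilities) | 0.6 |
| `V` | vertical share of learning, stages 2–4 | scenario-dependent |
| `omega` | oldest stage sampled non-vertically | 5 |
| `v_b` | baseline vertical contact time | 0.6 |
| `epsilon` | niche-construction strength | 0 or 1 |
| initial size / structure / frequency | | 100, uniform (20% per stage), 0.005 |
| `n_steps` | horizon of the canonical experiments | 5000 |

The default demography, effect sizes, the contact-time baseline, the rescue
setup (b = 3, equal juvenile/adult survivals 0.6, $s_5=0.4$, $p_v=p_h=0.6$,
$w_f=1.7$, 50 individuals, 2500 steps) and the alternative demography used
in the comparison experiments (b = 4, s = (0.6, 0.7, 0.7, 0.7, 0.4)) are
the canonical published parameterizations of this model family. Where a
magnitude is not printed anywhere — the survival effect in the
survival-benefit comparison, the fertility base of the niche sweeps — we
reuse the one magnitude that is printed ($w_s=0.05$, $b=4$). The default
fidelity 0.6 matches the rescue setup and sits mid-grid. An initial
frequency of 0.005 is the default; 0.001 (used for one published sweep) is
available through `initial_trait_freq`.

The four bundled learning life histories are the two reference extremes
(`all_vertical`, `all_horizontal`) and two mixed schedules:
`hunter_gatherer` V = (0.8, 0.8, 0.4) and `agriculturalist`
V = (0.5, 0.25, 0.1). The mixed schedules are stand-ins shaped like the
published time-allocation observations (predominantly vertical learning
into late childhood for foragers; horizontal/oblique learning from early
childhood for farmers), for which no numeric schedule is printed anywhere;
they are plain constructor arguments, not privileged constants.

## Numerical design

**Log-scale population size.** With $b=4$–$5$ the projection can be
super-critical once the trait spreads; $\lambda^{5000}$ overflows doubles.
The state is therefore carried as stage proportions plus
$\log(\text{total})$; every recursion depends on sizes only through ratios,
so this is exact (a test iterates the raw-count recursion independently at
a short horizon and matches to 1e-12). Raw counts in serialized
trajectories may print as `Inf` after extreme growth; all frequencies and
proportions are finite by construction.

**Imprimitivity.** Because only stage 4 reproduces, the projection matrix
is periodic with period 4 (four eigenvalues share the spectral radius), so
per-step growth and the age distribution oscillate indefinitely from a
uniform start — trajectories of the mean frequency genuinely wobble with
period 4, and this is visible in the canonical runs. The convergent
quantities are period-wise: the 4-step geometric-mean growth factor equals
the dominant eigenvalue exactly once transients decay, and the
$\lambda$-discounted average of the stage vector over one period equals the
Perron eigenvector. Validation measures both that way and hits 1e-6
comfortably; `stable_stage_distribution()` picks the Perron root explicitly
since `which.max` on moduli is ill-defined under ties.

**Degenerate states.** An empty role-model pool is an error in the exported
operation and contributes nothing inside a run; an empty next-step oldest
stage returns frequency 0 by convention with a warning; total extinction
freezes the state and sets a flag. A run is flagged `collapsed` when total
size falls below a reporting threshold (default 1.0) — a convention, not an
absorbing state. Contact times are clamped to [0, 1] (possible only for
$\epsilon>1$) and clamp events are counted on the result object.

**"Final" and "mean" frequency.** Sweeps report the end-state size-weighted
mean frequency by default; a time-averaged variant is available
(`statistic = "mean_freq"`). Per-stage frequencies are recorded so other
weightings are recoverable.

## The individual-based oracle

The stochastic twin (`abm_run()`, `replicate_summary()`) draws Bernoulli
survival, Poisson offspring (mean $b$ or $b+w_f$ by parental trait), and one
learning attempt per eligible agent, mirroring the deterministic update
order. Each agent records its parent's trait at birth; the newborn vertical
round uses the agent's own parent. Later vertical attempts draw a role
model uniformly from the cohort's recorded parental pool rather than
re-using the agent's own parent: the recursion's vertical term treats each
attempt as an independent draw from the parental generation, whereas
conditioning on the learner's own parent — given that the learner is still
naive — biases that parent toward non-carriers and depresses acquisition
well below the recursion at intermediate frequencies. Poisson offspring is
the minimal-assumption choice; only its mean enters the comparison.

At study scale (50 replicates of 10,000 agents over 100 steps, fertility
mode) the deterministic trajectory sits inside the replicate mean's 3-SE
band up to the band's own nominal exceedance rate across the 500
step-by-stage comparison points, and the maximum deviation shrinks as the
agent count grows (tested at 100 vs 10,000 agents). What this does and does
not show: it verifies that the recursion is the correct large-population
mean of the stated individual-level rules; it does not validate those rules
against any empirical learning data, and the agent model inherits every
structural idealization of the recursion (one attempt per step, pooled
role models, fixed stage schedule).

## What the experiments compute

- `sweep_fidelity_grid()` — final (or time-mean) population frequency over
  a $(p_v,p_h)$ grid, one independent run per cell (canonical 11×11).
- `compare_to_neutral()` — final-frequency difference between the
  configured trait and a twin run with $w_f=w_s=0$, isolating the fitness
  effect from pure transmission. Vertical transmission alone already
  carries a *baseline* advantage (parents are among the best-informed
  stages), so the neutral trait itself spreads under high-fidelity vertical
  schedules; differences therefore concentrate near invasion thresholds and
  can even turn slightly negative through an age-composition effect (a
  fertility-enhancing trait inflates the newborn share of the size-weighted
  mean). Expect narrow bands, not uniform orderings.
- `rescue_experiment()` — the same precarious demography under different
  learning life histories; with a sub-critical baseline and super-critical
  all-carrier projection, the schedule that spreads the trait faster
  recovers while the slower one collapses.

## Known limitations

- Stage counts are continuous; "collapse" is decline of a continuous
  quantity, and stochastic extinction of small populations is only
  represented in the agent-based twin.
- The trait affects fertility or survival, not both at once, in the
  canonical runs; the parameter objects allow both but no experiment
  exercises the combination.
- Survival-mode frequency bookkeeping uses the recursion's stylized
  parental-survival discount and baseline-weighted oldest-stage merge (see
  above); the agent model deviates from it by the corresponding amount.
- No role-model choice biases (prestige, conformity), no one-to-many or
  many-to-one transmission, no environmental turnover making information
  obsolete.
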