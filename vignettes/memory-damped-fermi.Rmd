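---
title: "Memory-damped Fermi updating in the spatial prisoner's dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-damped Fermi updating in the spatial prisoner's dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfermi)
```

## The model

Agents sit on an $L \times L$ square lattice with periodic boundaries and
play the weak prisoner's dilemma with their four von Neumann neighbours.
Each pairwise game pays $R = 1$ for mutual cooperation, $P = S = 0$ for
mutual defection and the mixed pair, and gives the defector the temptation
$T \in (1, 2]$ against a cooperator. A site's round payoff is the sum over
its four games, recomputed from the current lattice whenever a decision
needs it — payoffs are round quantities, never accumulated across rounds.

Strategy revision follows the Fermi (pairwise-comparison) rule, damped by
the stability of the revising agent's own recent history. Every agent
records its own strategy over the previous $M$ rounds. Writing $n_x$ for
the run length of the most recent recorded entries that equal agent $x$'s
current strategy, the memory factor is

$$H_x = \begin{cases} 1, & M = 0\\
1 - (1 - \beta)\,\dfrac{n_x}{M}, & M \ge 1 \end{cases}$$

with memory weight $\beta \in (0, 1)$, and $x$ copies the strategy of a
uniformly chosen neighbour $y$ with probability

$$P(S_x \leftarrow S_y) = \frac{H_x}{1 + \exp\!\big((P_x - P_y)/K\big)}.$$

$H_x$ decreases from $1$ (an agent that just switched, $n_x = 0$) to its
floor $\beta$ (an agent stable for $M$ rounds), so entrenched agents of
either strategy are harder to convert. Note the direction this gives
$\beta$: the damping strength is $(1-\beta)\,n_x/M$, so *smaller* $\beta$
means *stronger* memory damping, and $\beta \to 1$ recovers the classic
Fermi rule.

## Scheduling

One Monte Carlo step (MCS) of the default asynchronous scheme performs
$L^2$ elementary updates on focal agents drawn with replacement; this
random sequential updating is the standard reading of Monte Carlo
simulation in the lattice-game literature and avoids the artifacts of
simultaneous updating. A synchronous scheme (all agents revise at once
from the pre-step lattice) is available as an option. After the updates,
every agent pushes its current strategy into its memory, the reset policy
runs, and $t$ advances.

Memories are recorded once per MCS, not per elementary update, so $M$
counts *rounds*. Three uniforms are consumed per elementary update in a
fixed order (focal site, neighbour, acceptance), making every trajectory a
deterministic function of the configuration and seed; the test suite
verifies bit-identical reproduction against an independent pure-R stepper
sharing the RNG stream.

## Memory mechanics: choices on under-determined points

Several aspects of the memory mechanism admit more than one reasonable
reading; the package fixes each one explicitly and exposes it as a
configuration knob.

**Initialisation.** Memories start empty at $t = 0$ — no pre-history is
fabricated. With an empty buffer $n = 0$ and $H = 1$, so the first round
reduces exactly to the classic Fermi rule.

**Warm-up denominator.** For $t < M$ the buffer holds fewer than $M$
entries. The memory *factor* divides by the stored length during warm-up
(switching to $M$ once full), which keeps $H \in [\beta, 1]$ from round
one instead of artificially inflating early imitation probabilities.

**The stability observable.** The population statistic
$\rho = \langle n_x / M\rangle$ always divides by $M$, including during
warm-up — it measures stability *relative to the full memory horizon*.
The two denominators serve different purposes and are deliberately not
unified: $H$ governs behaviour, $\rho$ reports it. A consequence worth
knowing: after the first round every agent has exactly one consistent
entry, so $\rho(1) = 1/M$, which is where the early minimum of the
$\rho(t)$ curve typically sits before stabilisation drives
$\rho \to 1$.

**Reset policy.** An agent that "changes strategies many times" has its
memory cleared. This is quantified as: after each round's push, clear the
buffer when the number of adjacent-entry switches exceeds
`reset_threshold` $\times$ (length $-$ 1). The default threshold is 0.5;
a threshold of 1 disables resets entirely (a buffer of length $l$ has at
most $l - 1$ switches). The rule is applied once per agent per round,
after the push.

**Whose stability.** The update rule's printed form damps the *learner's*
imitation by the learner's own stability; that is the default
(`stability_of = "self"`). Because one can also argue agents should
preferentially imitate neighbours with stable histories, a
`stability_of = "neighbor"` variant applies the same factor computed from
the model neighbour instead. In our experiments the variant does not
qualitatively change the phase behaviour at the default parameters.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `temptation` (T) | defection temptation | 1.05 | dilemma severity, $(1, 2]$ |
| `K` | Fermi selection noise | 0.1 | $K \to 0$: deterministic comparison |
| `M` | memory length (rounds) | 0 | 0 disables the mechanism |
| `beta` | memory weight, floor of $H$ | 0.5 | smaller = stronger damping |
| `reset_threshold` | switch fraction clearing memory | 0.5 | 1 = never |
| `update_scheme` | MCS scheduling | asynchronous | |
| `boundary` | lattice boundary | periodic | fixed clips edges |

## Numerical notes

The imitation probability is evaluated through the logistic function, so
payoff gaps of hundreds of noise units neither overflow nor produce NaN
(a large payoff advantage of the focal agent yields probability 0, a
large deficit yields $H$). Homogeneous lattices are absorbing: once
all-C or all-D, every conceivable update is a no-op, and the simulator
skips the update loop while continuing to record memories and
observables, so long runs that fixate finish quickly without altering
the trajectory. Retention probabilities are measured at lag 1 between
consecutive *recorded* lattices; with `record_every = 1` this is the
per-MCS retention, and the bookkeeping identity
$P_c(t{+}1) = P_c(t)P_{C\to C} + (1 - P_c(t))(1 - P_{D\to D})$ holds
exactly on every recorded pair (it is asserted in the tests).

## What the simulations show, and their limits

The package's test suite runs desk-scale study conditions chosen to
finish on one core in minutes: $L = 100$ and 2000 MCS for time-series
experiments, $L = 50$ for sweeps, five seeds per condition, with
steady-state values averaged over the final 10% of recorded steps. The
full-scale recipes ($L = 200$, $10^4$ MCS) are available through
`figure_recipes(..., scale = "full")`.

At $M = 0$ the simulator reproduces the well-known phase behaviour of
the classic spatial Fermi dynamics at $K = 0.1$: cooperators coexist
with defectors for $T \lesssim 1.03$ and go extinct above, and for
$T \ge 1.6$ defection fixates for every memory length tested.

With memory on, the damping direction noted above has a measurable
consequence that a user should understand before interpreting sweeps:
at $T = 1.05$, steady-state cooperation *increases as $\beta$
decreases* (stronger damping). At the default $\beta = 0.5$ the damping
is too weak to rescue cooperation at $T = 1.05$ and the population
fixates on defection within a few thousand MCS; at $\beta = 0.1$
cooperator clusters survive and grow, and survival also strengthens
with $M$. The early-transient stability minimum $\min_t \rho(t) = 1/M$
and the equilibrium saturation of $\rho$ near 1 are robust across these
regimes.

The generated lattices emulate the canonical random 50/50 initial
condition only. Real-world applications of imitation dynamics involve
heterogeneous interaction topologies, payoff noise, and exogenous
strategy mutation, none of which are modelled here; passing tests
demonstrate internal consistency of the dynamics and reproducibility of
the lattice phenomenology at the stated scales, not robustness on other
topologies or at other noise regimes.
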