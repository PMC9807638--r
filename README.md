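# memfermi

Monte Carlo simulator for the spatial prisoner's dilemma with a
**memory-damped Fermi update rule**, for researchers studying the
evolution of cooperation in lattice populations.

## The model

Agents on an L × L periodic lattice play the weak prisoner's dilemma
(R = 1, P = S = 0, temptation T ∈ (1, 2]) with their four von Neumann
neighbours; a site's round payoff is the sum over its four games. Each
agent records its own strategy over the previous M rounds. With n_x the
run length of the newest recorded entries equal to x's current strategy,
the memory factor

    H_x = 1 − (1 − β) · n_x / M        (H_x = 1 for M = 0)

damps the Fermi imitation probability: x copies a random neighbour y with
probability

    P(S_x ← S_y) = H_x / (1 + exp((P_x − P_y) / K)).

Agents that have held their strategy longer are harder to convert
(H falls from 1 at n_x = 0 to its floor β at n_x = M); agents that
flip-flop too often have their memory reset. One Monte Carlo step (MCS)
is L² asynchronous elementary updates followed by a memory push for every
agent. The package provides the simulator (compiled core), the
observables used to characterise the dynamics — cooperation rate P_c,
population-mean strategy stability ρ = ⟨n_x/M⟩, and the retention
probabilities P(C→C), P(D→D) — plus a config-driven sweep runner, lattice
snapshot I/O and PNG rendering.

## Worked example

Strong memory damping (small β) lets cooperator clusters survive a
temptation that wipes them out under classic Fermi updating:

```r
library(memfermi)

sim <- run_simulation(L = 50, M = 7, beta = 0.1, temptation = 1.05,
                      K = 0.1, steps = 1000, seed = 1)
sim
#> pd_sim: L = 50, M = 7, beta = 0.10, T = 1.050, K = 0.10
#>   1000 MCS (asynchronous, periodic boundary); final pc = 0.1700, rho = 0.9869

sim$series[sim$series$t %in% c(0, 1, 10, 100, 500, 1000), ]
#>     t     pc    rho    pcc    pdd
#>     0 0.5196 0.0000     NA     NA
#>     1 0.3856 0.1429 0.6844 0.9376
#>    10 0.2956 0.9475 0.9524 0.9897
#>   100 0.1020 0.9852 0.9689 0.9973
#>   500 0.1216 0.9875 0.9867 0.9968
#>  1000 0.1700 0.9869 0.9859 0.9971
```

Cooperation first collapses (P_c 0.52 → 0.10 by t = 100) while surviving
clusters entrench (stability ρ rises from 1/M = 0.14 at t = 1 towards 1),
then recovers slowly as stable cooperator clusters expand (P_c back to
0.17 by t = 1000, with cooperator retention P(C→C) ≈ 0.99). The same run
without memory fixates on defection:

```r
run_simulation(L = 50, M = 0, temptation = 1.05, K = 0.1,
               steps = 1000, seed = 1)
#> pd_sim: L = 50, M = 0, beta = 0.50, T = 1.050, K = 0.10
#>   1000 MCS (asynchronous, periodic boundary); final pc = 0.0000
```

Parameter sweeps use `experiment_config()` / `run_experiment()`, or the
pre-registered layouts in `figure_recipes()` (cooperation vs temptation,
vs memory length, time series, steady-state snapshots) at `"desk"` or
`"full"` scale. A thin command-line front end with `simulate`, `sweep`,
`figure` and `render` subcommands ships in `inst/scripts/memfermi`.

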