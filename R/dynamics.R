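#' Memory-damped Fermi imitation probability
#'
#' Probability that the focal agent copies the neighbour's strategy:
#' `H / (1 + exp((p_x - p_y) / K))`. With H = 1 this is the classic Fermi
#' rule; the memory factor H scales the whole probability, so the result
#' always lies in \[0, H\]. The logistic is evaluated via [stats::plogis()]
#' and is stable for arbitrarily large payoff gaps (no overflow: a large
#' payoff advantage of the focal agent gives probability 0, a large deficit
#' gives H).
#'
#' @param p_x round payoff of the focal (potentially imitating) agent.
#' @param p_y round payoff of the chosen neighbour.
#' @param H memory factor in \[0, 1\].
#' @param K selection noise, strictly positive.
#' @return Imitation probability, vectorised over the payoff arguments.
#' @examples
#' imitation_probability(1, 1, H = 1, K = 0.1)    # 0.5
#' imitation_probability(1.1, 1, H = 1, K = 0.1)  # 1 / (1 + e)
#' @export
imitation_probability <- function(p_x, p_y, H = 1, K = 0.1) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  if (any(H < 0) || any(H > 1))
    stop("H must lie in [0, 1]", call. = FALSE)
  H * stats::plogis((p_y - p_x) / K)
}

#' One elementary (asynchronous) update
#'
#' Draws a focal agent x uniformly at random, one of its four neighbours y
#' uniformly at random, computes both round payoffs from the live lattice,
#' and lets x adopt y's strategy with probability
#' [imitation_probability()] evaluated at x's memory factor. Only cell x
#' can change; memories are not touched (they are recorded once per Monte
#' Carlo step). Three uniforms are always consumed, in the order focal
#' site, neighbour, acceptance, so trajectories can be retraced.
#'
#' @param state a `lattice_state`.
#' @param memories an `agent_memories` object.
#' @param payoff a [payoff_params()] object.
#' @param memory a [memory_params()] object (its `M` must match
#'   `memories$M`).
#' @param dynamics a [dynamics_params()] object.
#' @return The updated `lattice_state` (same `t`).
#' @export
elementary_update <- function(state, memories, payoff = payoff_params(),
                              memory = memory_params(),
                              dynamics = dynamics_params()) {
  stopifnot(inherits(state, "lattice_state"),
            inherits(memories, "agent_memories"))
  if (memory$M != memories$M)
    stop("memory_params M does not match the memories object", call. = FALSE)
  plist <- as_sim_params(payoff, memory, dynamics)
  lat <- elementary_update_cpp(as.integer(state$cells), memories$entries,
                               memories$len, state$L, plist)
  new_state <- state
  new_state$cells <- matrix(lat, nrow = state$L, ncol = state$L)
  new_state
}

#' One full Monte Carlo step
#'
#' Asynchronous scheme (default): L^2 elementary updates on agents sampled
#' with replacement. Synchronous scheme: all agents simultaneously pick a
#' neighbour and accept or reject from the payoffs of the pre-step lattice.
#' Afterwards every agent pushes its (possibly new) strategy into its
#' memory, the reset policy is applied, and `t` increments by one.
#'
#' @inheritParams elementary_update
#' @return List with the updated `state` and `memories`.
#' @export
monte_carlo_step <- function(state, memories, payoff = payoff_params(),
                             memory = memory_params(),
                             dynamics = dynamics_params()) {
  stopifnot(inherits(state, "lattice_state"),
            inherits(memories, "agent_memories"))
  if (memory$M != memories$M)
    stop("memory_params M does not match the memories object", call. = FALSE)
  plist <- as_sim_params(payoff, memory, dynamics)
  res <- sim_run_cpp(as.integer(state$cells), memories$entries, memories$len,
                     state$L, state$t, 1L, 1L, plist, integer(0))
  st <- new_lattice_state(matrix(res$lattice, state$L, state$L), res$t)
  mem <- memories
  mem$entries <- res$memory
  mem$len <- res$len
  list(state = st, memories = mem)
}
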