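#' Run a full lattice simulation
#'
#' Evolves an L x L weak prisoner's dilemma under the memory-damped Fermi
#' rule for `steps` Monte Carlo steps (MCS). Each MCS performs L^2
#' elementary updates (asynchronous default) or one simultaneous sweep
#' (synchronous), then records every agent's strategy in its memory and
#' applies the reset policy. Observables — cooperation rate `pc`, mean
#' stability `rho`, and the lag-1 retention probabilities `pcc`, `pdd` —
#' are recorded every `record_every` MCS; retentions are measured between
#' consecutive recorded lattices.
#'
#' The whole trajectory is a deterministic function of the configuration
#' and `seed`: the RNG draws are made in a fixed, documented order (see
#' [elementary_update()]).
#'
#' @param L lattice side length (ignored when `init_state` is given).
#' @param M memory length in rounds; `M = 0` is classic Fermi updating.
#' @param beta memory weight in (0, 1).
#' @param temptation defection temptation T in (1, 2].
#' @param K Fermi selection noise.
#' @param steps number of Monte Carlo steps.
#' @param seed RNG seed; `NULL` continues the current RNG state.
#' @param p_c initial cooperation probability.
#' @param update_scheme `"asynchronous"` or `"synchronous"`.
#' @param boundary `"periodic"` or `"fixed"`.
#' @param stability_of whose history damps imitation: `"self"` (the
#'   learner, default, as in the update rule's definition) or
#'   `"neighbor"`.
#' @param reset_threshold memory-reset switch fraction; 1 disables resets.
#' @param record_every record observables every this many MCS.
#' @param snapshot_times integer vector of absolute `t` values at which to
#'   keep a copy of the lattice.
#' @param init_state optional starting `lattice_state` (e.g. from
#'   [read_snapshot()]); overrides `L` and `p_c`.
#' @param memories optional starting `agent_memories`; defaults to empty
#'   buffers.
#' @return An object of class `pd_sim`: list with `series` (data frame
#'   `t,pc,rho,pcc,pdd`), final `state`, final `memories`, `snapshots`
#'   (named list of strategy matrices), and the resolved `config`.
#' @examples
#' sim <- run_simulation(L = 20, M = 5, temptation = 1.05, steps = 50,
#'                       seed = 1)
#' tail(sim$series, 3)
#' @export
run_simulation <- function(L = 200, M = 0, beta = 0.5, temptation = 1.05,
                           K = 0.1, steps = 10000, seed = NULL, p_c = 0.5,
                           update_scheme = c("asynchronous", "synchronous"),
                           boundary = c("periodic", "fixed"),
                           stability_of = c("self", "neighbor"),
                           reset_threshold = 0.5, record_every = 1L,
                           snapshot_times = integer(0),
                           init_state = NULL, memories = NULL) {
  update_scheme <- match.arg(update_scheme)
  boundary <- match.arg(boundary)
  stability_of <- match.arg(stability_of)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 0)
    stop("steps must be a non-negative integer", call. = FALSE)
  if (!is.numeric(record_every) || length(record_every) != 1L ||
      record_every < 1 || record_every != as.integer(record_every))
    stop("record_every must be a positive integer", call. = FALSE)
  payoff <- payoff_params(temptation = temptation)
  memory <- memory_params(M = M, beta = beta,
                          reset_threshold = reset_threshold,
                          stability_of = stability_of)
  dynamics <- dynamics_params(K = K, update_scheme = update_scheme,
                              boundary = boundary)

  if (!is.null(seed)) set.seed(seed)
  state <- if (is.null(init_state)) init_lattice(L, p_c) else init_state
  stopifnot(inherits(state, "lattice_state"))
  L <- state$L
  mem <- if (is.null(memories)) init_memories(L * L, memory$M) else memories
  stopifnot(inherits(mem, "agent_memories"))
  if (mem$M != memory$M)
    stop("M does not match the supplied memories object", call. = FALSE)

  plist <- as_sim_params(payoff, memory, dynamics)
  res <- sim_run_cpp(as.integer(state$cells), mem$entries, mem$len, L,
                     state$t, as.integer(steps), as.integer(record_every),
                     plist, as.integer(snapshot_times))

  series <- as.data.frame(res$series)
  names(series) <- c("t", "pc", "rho", "pcc", "pdd")
  snapshots <- lapply(res$snapshots, function(v) matrix(v, L, L))
  final_mem <- structure(list(M = memory$M, entries = res$memory,
                              len = res$len), class = "agent_memories")
  structure(list(
    series = series,
    state = new_lattice_state(matrix(res$lattice, L, L), res$t),
    memories = final_mem,
    snapshots = snapshots,
    config = list(L = L, M = memory$M, beta = beta, temptation = temptation,
                  K = K, steps = as.integer(steps), seed = seed, p_c = p_c,
                  update_scheme = update_scheme, boundary = boundary,
                  stability_of = stability_of,
                  reset_threshold = reset_threshold,
                  record_every = as.integer(record_every))
  ), class = "pd_sim")
}

#' @export
print.pd_sim <- function(x, ...) {
  cfg <- x$config
  last <- x$series[nrow(x$series), ]
  cat(sprintf("pd_sim: L = %d, M = %d, beta = %.2f, T = %.3f, K = %.2f\n",
              cfg$L, cfg$M, cfg$beta, cfg$temptation, cfg$K))
  cat(sprintf("  %d MCS (%s, %s boundary); final pc = %.4f",
              cfg$steps, cfg$update_scheme, cfg$boundary, last$pc))
  if (!is.na(last$rho)) cat(sprintf(", rho = %.4f", last$rho))
  cat("\n")
  invisible(x)
}
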