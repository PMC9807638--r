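#' Cooperation rate of a lattice
#'
#' Fraction of sites holding the cooperator strategy.
#'
#' @param state a `lattice_state`.
#' @return Number in \[0, 1\].
#' @export
cooperation_rate <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  mean(state$cells)
}

#' Population-mean strategy stability
#'
#' Averages n / M over all agents, where n is each agent's stability count
#' against its current strategy. The denominator is always the memory
#' length M (the stability observable rho = n_x / M), including during
#' warm-up — unlike the memory factor, whose warm-up denominator is the
#' stored length. An agent with an empty (fresh or reset) buffer
#' contributes 0. Undefined for M = 0 (no memory mechanism).
#'
#' @param memories an `agent_memories` object with M >= 1.
#' @param state the matching `lattice_state`.
#' @return Mean stability rho in \[0, 1\].
#' @export
mean_stability <- function(memories, state) {
  stopifnot(inherits(memories, "agent_memories"),
            inherits(state, "lattice_state"))
  if (memories$M == 0L)
    stop("mean stability is undefined for M = 0", call. = FALSE)
  n_agents <- length(state$cells)
  if (n_agents != length(memories$len))
    stop("memories and state have different population sizes", call. = FALSE)
  vals <- numeric(n_agents)
  for (a in seq_len(n_agents)) {
    l <- memories$len[a]
    cur <- state$cells[a]
    n <- 0L
    if (l > 0L) {
      for (k in seq_len(l)) {
        if (memories$entries[a, k] == cur) n <- n + 1L else break
      }
    }
    vals[a] <- n / memories$M
  }
  mean(vals)
}

#' Strategy retention probabilities between consecutive states
#'
#' `P(C->C)` is the fraction of sites that were cooperators at t and are
#' still cooperators at t + 1; `P(D->D)` analogously for defectors. A
#' retention is `NA` when its strategy is absent at t (empty denominator).
#'
#' @param state_t,state_t_plus_1 two `lattice_state`s one recorded step
#'   apart, same side length.
#' @return Named numeric vector `c(pcc = , pdd = )`.
#' @export
retention_probabilities <- function(state_t, state_t_plus_1) {
  stopifnot(inherits(state_t, "lattice_state"),
            inherits(state_t_plus_1, "lattice_state"))
  if (state_t$L != state_t_plus_1$L)
    stop("lattice sizes differ", call. = FALSE)
  a <- state_t$cells
  b <- state_t_plus_1$cells
  nc <- sum(a == 1L)
  nd <- sum(a == 0L)
  pcc <- if (nc > 0) sum(a == 1L & b == 1L) / nc else NA_real_
  pdd <- if (nd > 0) sum(a == 0L & b == 0L) / nd else NA_real_
  c(pcc = pcc, pdd = pdd)
}

#' Write / read a simulation time series
#'
#' CSV with header `t,pc,rho,pcc,pdd`; missing values (retentions with an
#' empty denominator, rho for M = 0) are serialized as empty fields.
#'
#' @param series data frame with columns `t`, `pc`, `rho`, `pcc`, `pdd`
#'   (the `$series` of a [run_simulation()] result).
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns the data frame.
#' @export
write_timeseries <- function(series, path) {
  cols <- c("t", "pc", "rho", "pcc", "pdd")
  stopifnot(all(cols %in% names(series)))
  utils::write.csv(series[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
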