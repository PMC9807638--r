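#' Per-agent strategy history buffer
#'
#' Holds up to `M` of an agent's own past strategies, newest first. Buffers
#' start empty at t = 0: no pre-history is fabricated, so the first update
#' of a run reduces to the classic Fermi rule (n = 0, H = 1).
#'
#' @param M capacity in rounds (non-negative integer).
#' @param entries integer vector of strategies (1/0), newest first; length
#'   at most `M`.
#' @return An object of class `memory_buffer`.
#' @export
memory_buffer <- function(M, entries = integer(0)) {
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0 ||
      M != as.integer(M))
    stop("M must be a single non-negative integer", call. = FALSE)
  entries <- as.integer(entries)
  if (length(entries) > M)
    stop("buffer cannot hold more than M entries", call. = FALSE)
  if (length(entries) && !all(entries %in% c(0L, 1L)))
    stop("entries must be strategies (1/0)", call. = FALSE)
  structure(list(M = as.integer(M), entries = entries),
            class = "memory_buffer")
}

#' Record one round in a memory buffer
#'
#' Prepends the strategy as the newest entry, evicting the oldest entry if
#' the buffer already holds `M` rounds. A zero-capacity buffer stays empty.
#'
#' @param buffer a [memory_buffer()].
#' @param s strategy just played, `1L` or `0L`.
#' @return The updated `memory_buffer`.
#' @export
push_round <- function(buffer, s) {
  stopifnot(inherits(buffer, "memory_buffer"))
  check_strategy(s)
  if (buffer$M == 0L) return(buffer)
  buffer$entries <- c(as.integer(s),
                      buffer$entries)[seq_len(min(length(buffer$entries) + 1L,
                                                  buffer$M))]
  buffer
}

#' Stability count of an agent
#'
#' The stability count n is the length of the maximal run of newest memory
#' entries equal to the agent's current strategy. n = 0 means the agent
#' switched strategy since the last recorded round (or has no history).
#'
#' @param buffer a [memory_buffer()].
#' @param current the agent's current strategy, `1L` or `0L`.
#' @return Integer n with 0 <= n <= length(entries) <= M.
#' @examples
#' stability_count(memory_buffer(4, c(1L, 1L, 0L, 1L)), 1L)  # 2
#' @export
stability_count <- function(buffer, current) {
  stopifnot(inherits(buffer, "memory_buffer"))
  check_strategy(current)
  n <- 0L
  for (e in buffer$entries) {
    if (e == current) n <- n + 1L else break
  }
  n
}

#' Memory factor H damping the imitation probability
#'
#' For M >= 1, H = 1 - (1 - beta) * n / denom, where the denominator is M
#' once the buffer is full and the current stored length during warm-up
#' (first M rounds), keeping H within \[beta, 1\] from round one. For M = 0
#' the memory mechanism is off and H = 1. H is 1 exactly when n = 0 (an
#' agent that just switched is maximally receptive) and reaches its floor
#' beta at n = M (a fully stable agent is hardest to convert).
#'
#' @param n stability count(s), vectorised.
#' @param M memory length.
#' @param effective_len rounds currently stored (defaults to a full buffer).
#' @param beta memory weight in (0, 1).
#' @return Numeric vector of factors in \[beta, 1\].
#' @examples
#' memory_factor(n = 10, M = 10, beta = 0.5)  # 0.5
#' @export
memory_factor <- function(n, M, effective_len = M, beta = 0.5) {
  if (!is.numeric(M) || length(M) != 1L || M < 0 || M != as.integer(M))
    stop("M must be a single non-negative integer", call. = FALSE)
  if (M == 0L) return(rep(1, length(n)))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("beta must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(effective_len) || length(effective_len) != 1L ||
      effective_len < 0 || effective_len > M)
    stop("effective_len must lie in [0, M]", call. = FALSE)
  if (any(n < 0)) stop("n must be non-negative", call. = FALSE)
  if (any(n > M)) stop("n cannot exceed the memory length M", call. = FALSE)
  if (any(n > effective_len))
    stop("n cannot exceed the stored length", call. = FALSE)
  denom <- if (effective_len < M) max(effective_len, 1) else M
  1 - (1 - beta) * n / denom
}

#' Apply the memory-reset policy
#'
#' An agent whose recorded history flips strategy too often has its memory
#' cleared: when the number of adjacent-entry switches exceeds
#' `reset_threshold * (length - 1)`, the buffer is emptied; otherwise it is
#' returned unchanged. Applied once per round per agent, after
#' [push_round()]. A threshold of 1 or more never triggers.
#'
#' @param buffer a [memory_buffer()].
#' @param params a [memory_params()] object supplying `reset_threshold`.
#' @return The (possibly cleared) `memory_buffer`.
#' @export
maybe_reset <- function(buffer, params) {
  stopifnot(inherits(buffer, "memory_buffer"),
            inherits(params, "memory_params"))
  l <- length(buffer$entries)
  if (l < 2L) return(buffer)
  switches <- sum(buffer$entries[-l] != buffer$entries[-1])
  if (switches > params$reset_threshold * (l - 1L))
    buffer$entries <- integer(0)
  buffer
}

#' Empty memory buffers for a population
#'
#' Agents are indexed in column-major lattice order (agent a holds site
#' `cells[a]`). The matrix representation (one row per agent, newest entry
#' in column 1, `len` valid entries) is what the compiled simulator mutates
#' in place.
#'
#' @param n_agents number of agents (L^2).
#' @param M memory length in rounds.
#' @return An object of class `agent_memories`: list with `M`, `entries`
#'   (n_agents x M integer matrix) and `len` (valid entries per agent).
#' @export
init_memories <- function(n_agents, M) {
  if (!is.numeric(n_agents) || length(n_agents) != 1L || n_agents < 1)
    stop("n_agents must be a positive integer", call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || M < 0 || M != as.integer(M))
    stop("M must be a single non-negative integer", call. = FALSE)
  n_agents <- as.integer(n_agents); M <- as.integer(M)
  structure(list(M = M,
                 entries = matrix(0L, nrow = n_agents, ncol = M),
                 len = integer(n_agents)),
            class = "agent_memories")
}

# buffer view of one agent's row, for R-level inspection
agent_buffer <- function(memories, agent) {
  stopifnot(inherits(memories, "agent_memories"))
  l <- memories$len[agent]
  memory_buffer(memories$M,
                if (l > 0) memories$entries[agent, seq_len(l)] else integer(0))
}
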