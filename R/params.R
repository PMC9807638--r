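#' Payoff parameters for the weak prisoner's dilemma
#'
#' The pairwise game pays `reward` (R) for mutual cooperation, `punishment`
#' (P) for mutual defection, and gives the defector `temptation` (T) against
#' a cooperator who receives `sucker` (S). The default is the weak-dilemma
#' parameterisation R = 1, P = S = 0, leaving the temptation T in (1, 2] as
#' the single game parameter. The ordering T > R > P >= S and 2R > T + S is
#' enforced.
#'
#' @param temptation payoff to a defector exploiting a cooperator (T).
#' @param reward payoff for mutual cooperation (R).
#' @param punishment payoff for mutual defection (P).
#' @param sucker payoff to a cooperator exploited by a defector (S).
#' @return An object of class `payoff_params`.
#' @examples
#' payoff_params(temptation = 1.05)
#' @export
payoff_params <- function(temptation = 1.05, reward = 1, punishment = 0,
                          sucker = 0) {
  vals <- c(temptation, reward, punishment, sucker)
  if (!is.numeric(vals) || length(vals) != 4L || anyNA(vals))
    stop("payoff parameters must be single non-missing numbers", call. = FALSE)
  if (!(temptation > reward && reward > punishment && punishment >= sucker))
    stop("payoff ordering must satisfy T > R > P >= S", call. = FALSE)
  # weak inequality so the endpoint T = 2 of the temptation range is usable
  if (!(2 * reward >= temptation + sucker))
    stop("payoffs must satisfy 2R >= T + S", call. = FALSE)
  structure(list(R = reward, S = sucker, T = temptation, P = punishment),
            class = "payoff_params")
}

#' Memory parameters
#'
#' `M` is the number of past rounds of its own strategy each agent records;
#' `beta` in (0, 1) is the memory weight, the floor of the memory factor H.
#' `reset_threshold` quantifies the rule that an agent which "changes
#' strategies many times" has its memory cleared: after each round's push,
#' the buffer is cleared when the number of adjacent-entry switches exceeds
#' `reset_threshold * (length - 1)`. A threshold of 1 (or more) never
#' resets, since a buffer of length l has at most l - 1 switches.
#' `stability_of` selects whose history damps the imitation: the learner's
#' own (`"self"`, the default) or the imitated neighbour's (`"neighbor"`).
#'
#' @param M memory length in rounds, non-negative integer; `M = 0` disables
#'   the memory mechanism (H = 1, classic Fermi updating).
#' @param beta memory weight, strictly between 0 and 1.
#' @param reset_threshold switch-count fraction triggering a memory reset;
#'   use `1` (or `Inf`) to disable resets.
#' @param stability_of `"self"` or `"neighbor"`.
#' @return An object of class `memory_params`.
#' @export
memory_params <- function(M = 0L, beta = 0.5, reset_threshold = 0.5,
                          stability_of = c("self", "neighbor")) {
  stability_of <- match.arg(stability_of)
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0 ||
      M != as.integer(M))
    stop("M must be a single non-negative integer", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta >= 1)
    stop("beta must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(reset_threshold) || length(reset_threshold) != 1L ||
      is.na(reset_threshold) || reset_threshold < 0)
    stop("reset_threshold must be a non-negative number", call. = FALSE)
  structure(list(M = as.integer(M), beta = beta,
                 reset_threshold = reset_threshold,
                 stability_of = stability_of),
            class = "memory_params")
}

#' Dynamics parameters
#'
#' `K > 0` is the selection noise (temperature) of the Fermi rule: K -> 0
#' approaches deterministic payoff comparison, K -> Inf random imitation.
#' One Monte Carlo step (MCS) of the default asynchronous scheme performs
#' L^2 elementary updates on agents sampled with replacement; the
#' synchronous option updates all agents simultaneously from the pre-step
#' lattice. Boundaries are periodic by default (fixed clips the
#' neighbourhood at the lattice edge).
#'
#' @param K selection noise, strictly positive.
#' @param update_scheme `"asynchronous"` (default) or `"synchronous"`.
#' @param boundary `"periodic"` (default) or `"fixed"`.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(K = 0.1,
                            update_scheme = c("asynchronous", "synchronous"),
                            boundary = c("periodic", "fixed")) {
  update_scheme <- match.arg(update_scheme)
  boundary <- match.arg(boundary)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  structure(list(K = K, update_scheme = update_scheme, boundary = boundary),
            class = "dynamics_params")
}

# flat parameter list consumed by the compiled core
as_sim_params <- function(payoff, memory, dynamics) {
  stopifnot(inherits(payoff, "payoff_params"),
            inherits(memory, "memory_params"),
            inherits(dynamics, "dynamics_params"))
  list(R = payoff$R, S = payoff$S, T = payoff$T, P = payoff$P,
       K = dynamics$K, beta = memory$beta, M = memory$M,
       reset_threshold = memory$reset_threshold,
       periodic = dynamics$boundary == "periodic",
       stability_self = memory$stability_of == "self",
       synchronous = dynamics$update_scheme == "synchronous")
}
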