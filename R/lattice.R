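#' Initialise a strategy lattice
#'
#' Builds an L x L lattice in which each site is independently assigned
#' cooperator (encoded `1L`) with probability `p_c` and defector (`0L`)
#' otherwise. Strategies are encoded as integers 1 (C) and 0 (D) throughout
#' the package, matching the serialized snapshot format.
#'
#' @param L side length, at least 2.
#' @param p_c initial cooperation probability in \[0, 1\]; the canonical
#'   random start uses 0.5.
#' @param seed optional RNG seed (`set.seed`); identical seeds give
#'   identical lattices.
#' @return An object of class `lattice_state`: a list with `cells` (L x L
#'   integer matrix), `L`, and the elapsed Monte Carlo step counter `t`.
#' @examples
#' st <- init_lattice(10, 0.5, seed = 1)
#' cooperation_rate(st)
#' @export
init_lattice <- function(L, p_c = 0.5, seed = NULL) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 2 ||
      L != as.integer(L))
    stop("L must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(p_c) || length(p_c) != 1L || is.na(p_c) ||
      p_c < 0 || p_c > 1)
    stop("p_c must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  cells <- matrix(as.integer(stats::runif(L * L) < p_c), nrow = L, ncol = L)
  new_lattice_state(cells, 0L)
}

new_lattice_state <- function(cells, t = 0L) {
  structure(list(cells = cells, L = nrow(cells), t = as.integer(t)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: %d x %d, t = %d, cooperation rate %.4f\n",
              x$L, x$L, x$t, mean(x$cells)))
  invisible(x)
}

#' Von Neumann neighbourhood of a site
#'
#' Returns the four nearest neighbours (up, down, left, right) of a site,
#' with periodic wrap-around by default. Under a fixed boundary, edge sites
#' have fewer neighbours and only the existing ones are returned.
#'
#' @param state a `lattice_state`.
#' @param site integer vector `c(row, col)`, 1-based.
#' @param boundary `"periodic"` or `"fixed"`.
#' @return Integer matrix with one `(row, col)` pair per row, in the order
#'   up, down, left, right.
#' @export
neighbors <- function(state, site, boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(state, "lattice_state"))
  L <- state$L
  if (!is.numeric(site) || length(site) != 2L || anyNA(site) ||
      any(site < 1) || any(site > L) || any(site != as.integer(site)))
    stop("site must be a valid 1-based (row, col) pair", call. = FALSE)
  i <- as.integer(site[1]); j <- as.integer(site[2])
  if (boundary == "periodic") {
    wrap <- function(k) ((k - 1L) %% L) + 1L
    out <- rbind(c(wrap(i - 1L), j), c(wrap(i + 1L), j),
                 c(i, wrap(j - 1L)), c(i, wrap(j + 1L)))
  } else {
    out <- matrix(integer(0), ncol = 2)
    if (i > 1L) out <- rbind(out, c(i - 1L, j))
    if (i < L)  out <- rbind(out, c(i + 1L, j))
    if (j > 1L) out <- rbind(out, c(i, j - 1L))
    if (j < L)  out <- rbind(out, c(i, j + 1L))
  }
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Payoffs of one pairwise game
#'
#' Looks up the prisoner's-dilemma payoff pair for the two strategies:
#' (C,C) -> (R,R), (D,D) -> (P,P), (C,D) -> (S,T), (D,C) -> (T,S).
#'
#' @param s_x,s_y strategies, `1L` (cooperator) or `0L` (defector).
#' @param params a [payoff_params()] object.
#' @return Named numeric vector `c(x = , y = )`.
#' @examples
#' pair_payoff(1L, 0L, payoff_params(temptation = 1.5))
#' @export
pair_payoff <- function(s_x, s_y, params = payoff_params()) {
  check_strategy(s_x); check_strategy(s_y)
  stopifnot(inherits(params, "payoff_params"))
  one <- function(a, b) {
    if (a == 1L) { if (b == 1L) params$R else params$S }
    else         { if (b == 1L) params$T else params$P }
  }
  c(x = one(s_x, s_y), y = one(s_y, s_x))
}

check_strategy <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || !(s %in% c(0L, 1L)))
    stop("strategies must be 1 (cooperator) or 0 (defector)", call. = FALSE)
  invisible(s)
}

#' Round payoffs of every lattice site
#'
#' Each site's payoff is the sum of its pairwise game against each of its
#' von Neumann neighbours, computed from the current strategies only (round
#' payoffs are never accumulated across rounds).
#'
#' @param state a `lattice_state`.
#' @param params a [payoff_params()] object.
#' @param boundary `"periodic"` or `"fixed"`.
#' @return Numeric L x L matrix aligned with `state$cells`.
#' @export
compute_payoffs <- function(state, params = payoff_params(),
                            boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(state, "lattice_state"))
  plist <- as_sim_params(params, memory_params(),
                         dynamics_params(boundary = boundary))
  vals <- payoffs_cpp(as.integer(state$cells), state$L, plist)
  matrix(vals, nrow = state$L, ncol = state$L)
}
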