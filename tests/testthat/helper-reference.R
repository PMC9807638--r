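# Independent pure-R reference implementations used as oracles. These are
# written against the model definitions directly (naive loops, no shared
# code with the package internals).

# payoff of strategy a against strategy b under the weak dilemma
ref_pair <- function(a, b, temptation, R = 1, S = 0, P = 0) {
  if (a == 1L) { if (b == 1L) R else S } else { if (b == 1L) temptation else P }
}

# double-loop payoff field over all sites and their von Neumann neighbours
naive_payoffs <- function(cells, temptation, boundary = "periodic") {
  L <- nrow(cells)
  out <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      r <- nb[1]; cc <- nb[2]
      if (boundary == "periodic") {
        r <- ((r - 1) %% L) + 1
        cc <- ((cc - 1) %% L) + 1
      } else if (r < 1 || r > L || cc < 1 || cc > L) next
      out[i, j] <- out[i, j] + ref_pair(cells[i, j], cells[r, cc], temptation)
    }
  }
  out
}

# 0-based column-major neighbour indices (up, down, left, right), periodic
ref_neighbours0 <- function(site0, L) {
  i <- site0 %% L
  j <- site0 %/% L
  c(((i + L - 1) %% L) + j * L,
    ((i + 1) %% L) + j * L,
    i + ((j + L - 1) %% L) * L,
    i + ((j + 1) %% L) * L)
}

# classic Fermi (no memory) asynchronous stepper sharing the package's RNG
# draw order: focal site, neighbour, acceptance uniform per update; updates
# are skipped once the lattice is homogeneous
ref_fermi_mcs <- function(cells, temptation, K = 0.1, steps = 1) {
  L <- nrow(cells)
  N <- L * L
  lat <- as.integer(cells)
  pay <- function(s0) {
    tot <- 0
    for (b in ref_neighbours0(s0, L))
      tot <- tot + ref_pair(lat[s0 + 1], lat[b + 1], temptation)
    tot
  }
  for (step in seq_len(steps)) {
    if (length(unique(lat)) > 1L) {
      for (u in seq_len(N)) {
        x <- floor(runif(1) * N)
        if (x >= N) x <- N - 1
        k <- floor(runif(1) * 4)
        if (k >= 4) k <- 3
        y <- ref_neighbours0(x, L)[k + 1]
        p <- 1 / (1 + exp((pay(x) - pay(y)) / K))
        if (runif(1) < p) lat[x + 1] <- lat[y + 1]
      }
    }
  }
  matrix(lat, L, L)
}

# brute-force stability count: scan entries newest-first
ref_stability <- function(entries, current) {
  n <- 0L
  for (e in entries) {
    if (e == current) n <- n + 1L else break
  }
  n
}

# lattice with every site defecting / cooperating
all_d_state <- function(L) {
  st <- init_lattice(L, 0)
  st
}
all_c_state <- function(L) init_lattice(L, 1)

# random agent_memories object for property tests
random_memories <- function(n_agents, M, seed) {
  set.seed(seed)
  mem <- init_memories(n_agents, M)
  for (a in seq_len(n_agents)) {
    l <- sample(0:M, 1)
    if (l > 0) mem$entries[a, seq_len(l)] <- sample(c(0L, 1L), l, TRUE)
    mem$len[a] <- l
  }
  mem
}
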