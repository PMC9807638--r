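test_that("imitation_probability matches the damped Fermi function", {
  # equal payoffs: symmetry gives H/2
  expect_equal(imitation_probability(1, 1, H = 1, K = 0.1), 0.5)
  expect_equal(imitation_probability(2, 2, H = 0.3, K = 0.1), 0.15)
  # payoff gap of one noise unit: 1/(1 + e)
  expect_equal(imitation_probability(1.1, 1.0, H = 1, K = 0.1),
               1 / (1 + exp(1)), tolerance = 1e-12)
  expect_error(imitation_probability(1, 1, K = 0), "K must be")
  expect_error(imitation_probability(1, 1, H = 1.2), "H must")
})

test_that("imitation_probability is numerically stable for huge payoff gaps", {
  # |P_x - P_y| / K = 700 and far beyond: no overflow, no NaN
  p_small <- imitation_probability(70, 0, H = 1, K = 0.1)
  expect_true(is.finite(p_small) && p_small >= 0 && p_small < 1e-300)
  expect_equal(imitation_probability(0, 70, H = 0.8, K = 0.1), 0.8)
  expect_equal(imitation_probability(1e6, 0, H = 1, K = 0.001), 0)
})

test_that("K -> 0 recovers the deterministic payoff comparison", {
  H <- 0.7
  K <- 1e-9
  expect_equal(imitation_probability(1, 2, H = H, K = K), H,
               tolerance = 1e-6)
  expect_equal(imitation_probability(2, 1, H = H, K = K), 0,
               tolerance = 1e-6)
  expect_equal(imitation_probability(1.5, 1.5, H = H, K = K), H / 2,
               tolerance = 1e-6)
})

test_that("an elementary update reproduces a hand trace of the RNG draws", {
  cells <- matrix(c(1L, 0L, 1L,
                    0L, 1L, 0L,
                    1L, 1L, 0L), nrow = 3, byrow = TRUE)
  st <- structure(list(cells = cells, L = 3L, t = 0L),
                  class = "lattice_state")
  M <- 2L
  mem <- init_memories(9, M)
  set.seed(31)
  for (a in 1:9) {
    l <- sample(0:M, 1)
    if (l > 0) mem$entries[a, seq_len(l)] <- sample(c(0L, 1L), l, TRUE)
    mem$len[a] <- l
  }
  Tv <- 1.3; K <- 0.1; beta <- 0.4

  for (seed in c(7, 8, 9, 101)) {
    set.seed(seed)
    out <- elementary_update(st, mem, payoff_params(Tv),
                             memory_params(M = M, beta = beta),
                             dynamics_params(K = K))
    # retrace the three uniforms by hand
    set.seed(seed)
    u <- runif(3)
    x0 <- min(floor(u[1] * 9), 8)
    y0 <- ref_neighbours0(x0, 3)[min(floor(u[2] * 4), 3) + 1]
    pay <- naive_payoffs(cells, Tv)
    l <- mem$len[x0 + 1]
    n <- ref_stability(if (l > 0) mem$entries[x0 + 1, seq_len(l)]
                       else integer(0), cells[x0 + 1])
    denom <- if (l < M) max(l, 1) else M
    H <- 1 - (1 - beta) * n / denom
    p <- H / (1 + exp((pay[x0 + 1] - pay[y0 + 1]) / K))
    expected <- cells
    if (u[3] < p) expected[x0 + 1] <- cells[y0 + 1]
    expect_identical(out$cells, expected)
  }
})

test_that("strategy counts change by at most one per elementary update", {
  set.seed(12)
  st <- init_lattice(6, 0.5)
  mem <- random_memories(36, 3, seed = 13)
  for (rep in 1:100) {
    out <- elementary_update(st, mem, payoff_params(1.4),
                             memory_params(M = 3),
                             dynamics_params())
    expect_lte(sum(out$cells != st$cells), 1L)
    st <- out
  }
})

test_that("homogeneous lattices are absorbing under both schemes", {
  for (scheme in c("asynchronous", "synchronous")) {
    for (make in list(all_d_state, all_c_state)) {
      st <- make(5)
      sim <- run_simulation(M = 3, temptation = 1.8, K = 0.1, steps = 100,
                            seed = 4, update_scheme = scheme,
                            init_state = st)
      expect_true(all(sim$series$pc == sim$series$pc[1]))
      expect_identical(sim$state$cells, st$cells)
    }
  }
})

test_that("M = 0 reduces to the classic Fermi dynamics on the same RNG stream", {
  for (seed in c(123, 456)) {
    set.seed(seed)
    st <- init_lattice(8, 0.5)
    sim <- run_simulation(M = 0, temptation = 1.4, K = 0.1, steps = 5,
                          init_state = st)
    set.seed(seed)
    cells <- matrix(as.integer(runif(64) < 0.5), 8, 8)
    ref <- ref_fermi_mcs(cells, temptation = 1.4, K = 0.1, steps = 5)
    expect_identical(sim$state$cells, ref)
  }
})

test_that("iterating monte_carlo_step reproduces run_simulation", {
  set.seed(77)
  st <- init_lattice(6, 0.5)
  mem <- init_memories(36, 4)
  pay <- payoff_params(1.2)
  mprm <- memory_params(M = 4, beta = 0.5)
  dyn <- dynamics_params(K = 0.1)
  cur <- list(state = st, memories = mem)
  for (i in 1:10) {
    cur <- monte_carlo_step(cur$state, cur$memories, pay, mprm, dyn)
  }
  set.seed(77)
  st2 <- init_lattice(6, 0.5)
  sim <- run_simulation(M = 4, beta = 0.5, temptation = 1.2, K = 0.1,
                        steps = 10, init_state = st2)
  expect_identical(cur$state$cells, sim$state$cells)
  expect_identical(cur$memories$entries, sim$memories$entries)
  expect_identical(cur$memories$len, sim$memories$len)
  expect_identical(cur$state$t, 10L)
})

test_that("identical configuration and seed give bit-identical trajectories", {
  for (scheme in c("asynchronous", "synchronous")) {
    a <- run_simulation(L = 10, M = 5, beta = 0.3, temptation = 1.3,
                        steps = 30, seed = 99, update_scheme = scheme)
    b <- run_simulation(L = 10, M = 5, beta = 0.3, temptation = 1.3,
                        steps = 30, seed = 99, update_scheme = scheme)
    expect_identical(a$series, b$series)
    expect_identical(a$state$cells, b$state$cells)
    expect_identical(a$memories$entries, b$memories$entries)
  }
})

test_that("memories record one entry per round and respect capacity", {
  sim <- run_simulation(L = 6, M = 3, temptation = 1.2, steps = 2, seed = 1)
  expect_true(all(sim$memories$len <= 3L))
  expect_true(all(sim$memories$len <= 2L))  # only two rounds elapsed
  # newest entry equals the current strategy wherever no reset occurred
  keep <- sim$memories$len > 0
  expect_true(all(sim$memories$entries[keep, 1] ==
                  as.integer(sim$state$cells)[keep]))
  sim2 <- run_simulation(L = 6, M = 3, temptation = 1.2, steps = 8, seed = 1,
                         reset_threshold = 1)
  expect_true(all(sim2$memories$len == 3L))  # no resets: buffers are full
})
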