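test_that("init_lattice respects the initial cooperation probability", {
  # degenerate probabilities give homogeneous lattices
  expect_true(all(init_lattice(4, 1.0, seed = 1)$cells == 1L))
  expect_true(all(init_lattice(4, 0.0, seed = 1)$cells == 0L))

  # 50/50 random start concentrates within 3 sigma of one half at L = 200
  st <- init_lattice(200, 0.5, seed = 11)
  expect_lt(abs(cooperation_rate(st) - 0.5), 3 * sqrt(0.25 / 200^2))

  # identical seed, identical lattice
  expect_identical(init_lattice(30, 0.5, seed = 5)$cells,
                   init_lattice(30, 0.5, seed = 5)$cells)
  expect_identical(st$t, 0L)
})

test_that("init_lattice rejects invalid arguments", {
  expect_error(init_lattice(1), "L must be")
  expect_error(init_lattice(10, p_c = -0.1), "p_c")
  expect_error(init_lattice(10, p_c = 1.5), "p_c")
})

test_that("neighbors returns the periodic von Neumann neighbourhood", {
  st <- init_lattice(5, 0.5, seed = 1)
  # corner site wraps around both axes
  nb <- neighbors(st, c(1, 1))
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  c("5,1", "2,1", "1,5", "1,2"))
  # interior site of a 3x3 lattice
  st3 <- init_lattice(3, 0.5, seed = 1)
  nb3 <- neighbors(st3, c(2, 2))
  expect_setequal(apply(nb3, 1, paste, collapse = ","),
                  c("1,2", "3,2", "2,1", "2,3"))
  expect_error(neighbors(st, c(0, 1)), "site")
  expect_error(neighbors(st, c(1, 6)), "site")
})

test_that("every site appears in exactly four neighbour lists on a 5x5 lattice", {
  st <- init_lattice(5, 0.5, seed = 2)
  counts <- matrix(0L, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    nb <- neighbors(st, c(i, j))
    for (r in seq_len(nrow(nb))) {
      counts[nb[r, 1], nb[r, 2]] <- counts[nb[r, 1], nb[r, 2]] + 1L
    }
  }
  expect_true(all(counts == 4L))
})

test_that("pair_payoff reproduces the weak-dilemma payoff table", {
  p <- payoff_params(temptation = 1.5)
  expect_equal(pair_payoff(1L, 1L, p), c(x = 1, y = 1))
  expect_equal(pair_payoff(0L, 0L, p), c(x = 0, y = 0))
  expect_equal(pair_payoff(1L, 0L, p), c(x = 0, y = 1.5))
  expect_equal(pair_payoff(0L, 1L, p), c(x = 1.5, y = 0))
  expect_error(pair_payoff(2L, 1L, p), "strategies")
})

test_that("payoff parameter validation enforces the dilemma ordering", {
  expect_error(payoff_params(temptation = 0.9), "ordering")
  expect_error(payoff_params(temptation = 1.2, punishment = 0.5,
                             sucker = 0.6), "ordering")
  # 2R >= T + S violated
  expect_error(payoff_params(temptation = 1.9, sucker = 0.5,
                             punishment = 0.5), "2R")
  # endpoint of the temptation range is admissible
  expect_equal(payoff_params(temptation = 2)$T, 2)
})

test_that("compute_payoffs matches hand-derived homogeneous and defector cases", {
  pC <- compute_payoffs(all_c_state(6), payoff_params(1.7))
  expect_true(all(pC == 4))
  pD <- compute_payoffs(all_d_state(6), payoff_params(1.7))
  expect_true(all(pD == 0))

  # single defector in an all-C 5x5 lattice at T = 1.3: the defector earns
  # 4T = 5.2, each of its four neighbours 3R + S = 3, everyone else 4R = 4
  st <- all_c_state(5)
  st$cells[3, 3] <- 0L
  pay <- compute_payoffs(st, payoff_params(1.3))
  expect_equal(pay[3, 3], 5.2)
  expect_equal(pay[2, 3], 3)
  expect_equal(pay[4, 3], 3)
  expect_equal(pay[3, 2], 3)
  expect_equal(pay[3, 4], 3)
  expect_equal(pay[1, 1], 4)
  expect_equal(sum(pay), 5.2 + 4 * 3 + 20 * 4)
})

test_that("compute_payoffs equals the naive double-loop oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- sample(3:6, 1)
    st <- init_lattice(L, runif(1))
    Tv <- runif(1, 1.01, 2)
    for (bnd in c("periodic", "fixed")) {
      expect_equal(compute_payoffs(st, payoff_params(Tv), boundary = bnd),
                   naive_payoffs(st$cells, Tv, boundary = bnd))
    }
  }
})

test_that("payoff field is translation-equivariant under periodic boundaries", {
  set.seed(3)
  st <- init_lattice(6, 0.5)
  pay <- compute_payoffs(st, payoff_params(1.4))
  for (shift in list(c(1, 0), c(0, 2), c(3, 4))) {
    sh <- st
    idx_r <- ((seq_len(6) - 1 + shift[1]) %% 6) + 1
    idx_c <- ((seq_len(6) - 1 + shift[2]) %% 6) + 1
    sh$cells <- st$cells[idx_r, idx_c]
    expect_equal(compute_payoffs(sh, payoff_params(1.4)),
                 pay[idx_r, idx_c])
  }
})

test_that("payoff bounds 4S and 4T are attained by isolated strategists", {
  Tv <- 1.9
  st <- all_c_state(5)
  st$cells[2, 2] <- 0L  # isolated D among C: maximum 4T
  pay <- compute_payoffs(st, payoff_params(Tv))
  expect_equal(max(pay), 4 * Tv)
  st2 <- all_d_state(5)
  st2$cells[2, 2] <- 1L  # isolated C among D: minimum 4S = 0
  pay2 <- compute_payoffs(st2, payoff_params(Tv))
  expect_equal(min(pay2), 0)
  expect_equal(pay2[2, 2], 0)
})
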