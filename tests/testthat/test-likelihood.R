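test_that("diversity-dependent rates decline linearly and clamp at zero", {
  expect_equal(dd_rate(0.7, 0, 5), 0.7)
  expect_equal(dd_rate(0.7, 5, 5), 0)
  expect_equal(dd_rate(0.7, 8, 5), 0)     # clamped, not negative
  expect_equal(dd_rate(0.7, 2, 5), 0.7 * 3 / 5)
  expect_equal(dd_rate(0.7, 1000, Inf), 0.7)
})

test_that("master-equation limits match closed forms", {
  # no events possible: the empty state persists
  p0 <- parameter_set(0, 0, 0, 0)
  st <- integrate_master(q_state(0L, 5L), p0, 3)
  expect_equal(q_channel(st, "plain")[1], 1)
  expect_equal(sum(st$q), 1)
  # immigration-only: Poisson first arrival, nothing can reverse it
  g <- 0.23
  pg <- parameter_set(g, 0, 0, 0)
  st <- integrate_master(q_state(0L, 5L), pg, 2.5)
  expect_equal(q_channel(st, "plain")[1], exp(-g * 2.5), tolerance = 1e-10)
  expect_equal(q_channel(st, "mainland")[1], 1 - exp(-g * 2.5),
               tolerance = 1e-10)
})

test_that("probability is conserved in the unconditioned k = 0 system", {
  p <- params_mild()
  st <- integrate_master(q_state(0L, 60L), p, 4)
  expect_lt(abs(sum(st$q) - 1), 1e-8)
  pdd <- params_dd()   # finite K': hidden n is bounded, no truncation leak
  st <- integrate_master(q_state(0L, 30L), pdd, 4)
  expect_lt(abs(sum(st$q) - 1), 1e-9)
})

test_that("integration is checkpoint-invariant", {
  p <- params_dd()
  direct <- integrate_master(q_state(0L, 20L), p, 3.7)
  stepped <- integrate_master(
    integrate_master(q_state(0L, 20L), p, 1.234), p, 3.7)
  expect_equal(direct$q, stepped$q, tolerance = 1e-12)
})

test_that("colonisation transfer follows the replacement convention", {
  p <- parameter_set(0.4, 0.2, 0.1, 0.3, K_prime = 4)
  st <- integrate_master(q_state(0L, 10L), p, 1.5)
  stc <- apply_colonisation(st, p)
  expect_equal(stc$k, 1L)
  n <- 0:10
  expect_equal(q_channel(stc, "colonist"),
               dd_rate(0.4, n, 4) * q_channel(st, "plain") +
                 dd_rate(0.4, n + 1, 4) * q_channel(st, "mainland"))
  expect_equal(sum(q_channel(stc, "plain")), 0)
  expect_equal(sum(q_channel(stc, "mainland")), 0)
  # at the capacity the immigration rate is clamped to zero
  expect_equal(q_channel(stc, "colonist")[5], 0)
  # gamma = 0 makes colonisation impossible
  p0 <- parameter_set(0, 0.2, 0.1, 0.3)
  expect_equal(sum(apply_colonisation(integrate_master(
    q_state(0L, 10L), p0, 1.5), p0)$q), 0)
  # colonisation out of the k = 1 regime is a logic error
  expect_error(apply_colonisation(stc, p), "k = 0")
})

test_that("branching updates carry the cladogenesis rate factor", {
  p <- parameter_set(0.1, 0.6, 0.2, 0.3, K_prime = 10)
  # first branching: both the endemic and the not-yet-diverged channel are
  # folded in with the instantaneous rate lambda^c_{n+1}
  lx <- 11L
  q1 <- c(rep(0.01, lx), rep(0.002, lx), rep(0.05, lx))
  st1 <- q_state(1L, 10L, t = 1, q = q1)
  st2 <- apply_branching(st1, p)
  n <- 0:10
  expect_equal(st2$k, 2L)
  expect_equal(q_channel(st2, "plain"),
               dd_rate(0.6, n + 1, 10) * (0.01 + 0.05))
  expect_equal(q_channel(st2, "mainland"), dd_rate(0.6, n + 2, 10) * 0.002)
  # later branchings: direct read of the update rule at k = 2 -> 3
  st3 <- apply_branching(st2, p)
  expect_equal(q_channel(st3, "plain")[1],
               dd_rate(0.6, 2, 10) * q_channel(st2, "plain")[1])
  expect_error(apply_branching(q_state(0L, 5L), p), "k = 0")
})

test_that("per-record log-likelihoods match analytic limits", {
  g <- 0.3
  p <- parameter_set(g, 0, 0, 0)
  # status 1: absence = zero arrivals of a Poisson process
  expect_equal(loglik_colonist(colonist_record("a", 1), p, 4), -g * 4,
               tolerance = 1e-8)
  # status 3: most recent arrival density gamma * exp(-gamma * a)
  a <- 1.5
  expect_equal(loglik_colonist(colonist_record("b", 3, a), p, 4),
               log(g) - g * a, tolerance = 1e-8)
  # status 2 with bound = island age: arrival before the present
  expect_equal(loglik_colonist(colonist_record("c", 2, 4), p, 4),
               log(1 - exp(-g * 4)), tolerance = 1e-8)
  # status 2 with a younger bound: window shrinks to the bound
  expect_equal(loglik_colonist(colonist_record("d", 2, 1.2), p, 4),
               log(1 - exp(-g * 1.2)), tolerance = 1e-8)
})

test_that("both numerical engines agree, including stiff regimes", {
  recs <- list(colonist_record("s3", 3, 1.0),
               colonist_record("s4", 4, 2.5, c(1.2, 0.4)),
               colonist_record("s5", 5, 3.0, c(2.0, 1.5, 0.3)),
               colonist_record("s2", 2, 3.0),
               colonist_record("nm", 4, 2.0, 1.0, n_missing = 2))
  for (p in list(params_mild(), params_dd(),
                 parameter_set(0.01, 20, 1, 15, 16))) {
    for (r in recs) {
      expect_equal(loglik_colonist(r, p, 4, n_max = 25, engine = "cpp"),
                   loglik_colonist(r, p, 4, n_max = 25, engine = "r"),
                   tolerance = 1e-8, label = r$label)
    }
  }
})

test_that("doubling the truncation bound leaves the log-likelihood stable", {
  p <- params_mild()
  for (r in list(colonist_record("s4", 4, 3.7, c(3, 2, 1, 0.5)),
                 colonist_record("s3", 3, 2.0))) {
    nm <- islandassembly:::default_n_max(r, p)
    expect_lt(abs(loglik_colonist(r, p, 4, n_max = 2L * nm) -
                  loglik_colonist(r, p, 4, n_max = nm)), 1e-6)
  }
})

test_that("likelihood is continuous in K' as K' grows to infinity", {
  r <- colonist_record("x", 4, 2, 1)
  base <- parameter_set(0.3, 0.4, 0.3, 0.25, Inf)
  ll_inf <- loglik_colonist(r, base, 3, n_max = 25)
  ll_big <- loglik_colonist(r, parameter_set(0.3, 0.4, 0.3, 0.25, 1e8), 3,
                            n_max = 25)
  expect_equal(ll_big, ll_inf, tolerance = 1e-6)
})

test_that("dataset likelihood is additive over independent colonists", {
  p <- parameter_set(0.05, 0.2, 0.6, 0.1)
  r1 <- colonist_record("a", 4, 2.5, 1.0)
  r2 <- colonist_record("b", 3, 0.8)
  d12 <- island_dataset(4, 100, list(r1, r2), c(all = 1))
  d1 <- island_dataset(4, 100, list(r1), c(all = 1))
  d2 <- island_dataset(4, 100, list(r2), c(all = 1))
  # the three datasets carry 98, 99 and 99 unobserved-pool factors, so the
  # adjustment is minus one full pool of status-1 terms
  ll0 <- loglik_colonist(colonist_record("e", 1), p, 4)
  expect_equal(loglik_dataset(d12, list(all = p)),
               loglik_dataset(d1, list(all = p)) +
                 loglik_dataset(d2, list(all = p)) - 100 * ll0,
               tolerance = 1e-8)
  # empty dataset with gamma = 0 has probability one
  dempty <- island_dataset(4, 100)
  expect_equal(loglik_dataset(dempty, parameter_set(0, 1, 1, 1)), 0)
  # class bookkeeping mismatch is a validation error
  expect_error(loglik_dataset(d12, list(wrong = p)), "class")
})

test_that("the conditioning flag divides by P(non-empty island)", {
  p <- parameter_set(0.01, 0, 0, 0)
  d <- island_dataset(4, 50, list(colonist_record("a", 3, 1)), c(all = 1))
  ll <- loglik_dataset(d, list(all = p))
  llc <- loglik_dataset(d, list(all = p), condition = TRUE)
  p_empty <- exp(-0.01 * 4 * 50)
  expect_equal(llc, ll - log(1 - p_empty), tolerance = 1e-8)
})
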