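test_that("a length-1 history is fully conditioned away", {
  p <- rand_params(3)
  expect_equal(history_loglik(5L, p), 0)
  expect_equal(brute_force_history_prob(5L, p), 1)
  d <- mevrd_data(matrix(c(NA, 6L), 1, 2))  # first capture at the last occasion
  expect_equal(attr(total_loglik(d, rand_params(2)), "deviance"), 0)
})

test_that("the two-occasion worked example evaluates to 0.2384", {
  p <- param_set(phi_B = 0.8, psi_BB = 0.5, m_B = 0.8, m_NB = 0.5,
                 p_u = 0.6, b_e = 0.7, n_occasions = 2)
  # survive-and-breed x P(M only | B) + survive-and-skip x P(M | NB)
  # = 0.8*0.5*(0.8*0.4*0.3) + 0.8*0.5*0.5 = 0.2384
  expect_equal(exp(history_loglik(c(5L, 4L), p)), 0.2384, tolerance = 1e-12)
  expect_equal(brute_force_history_prob(c(5L, 4L), p), 0.2384,
               tolerance = 1e-12)
})

test_that("a deterministic model gives probability one to its only path", {
  p <- param_set(phi_B = 1, psi_BB = 1, m_B = 1, m_NB = 1, p_u = 1, b_e = 1,
                 n_occasions = 5)
  expect_equal(exp(history_loglik(rep(1L, 5), p)), 1, tolerance = 1e-12)
  expect_equal(brute_force_history_prob(rep(1L, 5), p), 1, tolerance = 1e-12)
})

test_that("forward algorithm matches brute-force enumeration on fuzzed cases", {
  set.seed(101)
  for (i in 1:200) {
    len <- sample(2:6, 1)
    p <- rand_params(len, min = 0.02, max = 0.98)
    h <- rand_history(len)
    expect_equal(exp(history_loglik(h, p)),
                 brute_force_history_prob(h, p), tolerance = 1e-10)
  }
})

test_that("event-suffix probabilities sum to one over all suffixes", {
  set.seed(55)
  for (rep in 1:2) {
    T <- 3
    p <- rand_params(T)
    suffixes <- expand.grid(rep(list(0:7), T - 1))
    tot <- sum(apply(suffixes, 1, function(s)
      brute_force_history_prob(c(1L, as.integer(s)), p)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("an impossible event yields -Inf, not an error", {
  p <- param_set(phi_B = 0.8, psi_BB = 0.5, m_B = 0, m_NB = 0,
                 p_u = 0.5, b_e = 0.5, n_occasions = 2)
  expect_equal(history_loglik(c(5L, 4L), p), -Inf)
  d <- mevrd_data(matrix(c(5L, 4L, 6L, 0L), 2, 2, byrow = TRUE),
                  id = c("bad", "ok"))
  ll <- total_loglik(d, p)
  expect_equal(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "impossible"), "bad")
})

test_that("dataset likelihood is the multiplicity-weighted sum of histories", {
  set.seed(77)
  sim <- quick_sim(80, T = 5, seed = 13)
  p <- rand_params(5)
  per <- vapply(seq_len(nrow(sim$events)), function(i) {
    f <- sim$first[i]
    history_loglik(sim$events[i, f:5], p, first = f)
  }, numeric(1))
  expect_equal(as.numeric(total_loglik(sim, p)), sum(per * sim$count),
               tolerance = 1e-10)
  # duplicating a history equals multiplicity 2
  d1 <- mevrd_data(matrix(c(5L, 4L, 5L, 4L), 2, 2, byrow = TRUE))
  d2 <- mevrd_data(matrix(c(5L, 4L), 1, 2), count = 2L)
  expect_equal(as.numeric(total_loglik(d1, p <- rand_params(2))),
               as.numeric(total_loglik(d2, p)), tolerance = 1e-12)
})

test_that("histories with event 4 from a breeder get likelier as m_B grows", {
  # ending in event 4 isolates the m_B effect: the B-path emission is
  # m_B (1-p_u)(1-b_e), the NB-path emission involves only m_NB
  h <- c(5L, 4L)
  lls <- vapply(c(0.3, 0.5, 0.7, 0.9), function(m) {
    p <- param_set(phi_B = 0.8, psi_BB = 0.9, m_B = m, m_NB = 0.5,
                   p_u = 0.6, b_e = 0.6, n_occasions = 2)
    history_loglik(h, p)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("long histories do not underflow", {
  p <- param_set(phi_B = 0.95, phi_NB = 0.95, psi_BB = 0.5, psi_NBB = 0.5,
                 m_B = 0.01, m_NB = 0.01, p_u = 0.01, b_e = 0.01,
                 n_occasions = 150)
  h <- c(5L, rep(0L, 149))
  ll <- history_loglik(h, p)
  expect_true(is.finite(ll))
  h2 <- c(5L, rep(c(0L, 4L), 60), rep(0L, 29))
  expect_true(is.finite(history_loglik(h2, p)))
})

test_that("mismatched axes and malformed histories are rejected", {
  p <- rand_params(4)
  expect_error(history_loglik(c(5L, 0L, 0L, 0L, 0L), p), "beyond")
  expect_error(history_loglik(c(4L, 0L), p), "breeding-season")
  expect_error(brute_force_history_prob(rand_history(14), rand_params(14)),
               "enumeration cap")
  d <- quick_sim(10, T = 5)
  expect_error(total_loglik(d, rand_params(4)), "disagree")
})
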