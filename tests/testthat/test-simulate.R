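test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_occasions = 5, cohorts = c(50, 20, 0, 0, 0))
  d1 <- simulate_histories(cfg, seed = 123)
  d2 <- simulate_histories(cfg, seed = 123)
  expect_identical(d1$events, d2$events)
  w1 <- simulate_weekly_records(cfg, seed = 123)
  w2 <- simulate_weekly_records(cfg, seed = 123)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$events, w2$events)
})

test_that("perfect detection makes events a deterministic readout of state", {
  cfg <- sim_config(n_occasions = 6, cohorts = c(100, rep(0, 5)),
                    m_B = 1, m_NB = 1, p_u = 1, b_e = 1)
  d <- simulate_histories(cfg, seed = 1)
  st <- attr(d, "states")
  ids <- as.integer(d$id)
  for (k in seq_along(ids)) {
    i <- ids[k]
    obs <- !is.na(d$events[k, ])
    expect_equal(unname(d$events[k, obs]),
                 unname(c(1L, 4L, 0L)[st[i, obs]]))
  }
})

test_that("empirical event frequencies converge to the composite matrix row", {
  cfg <- sim_config(n_occasions = 2, cohorts = c(50000, 0),
                    phi_B = 0.9, psi_BB = 0.7, psi_NBB = 0.5,
                    m_B = 0.7, m_NB = 0.6, p_u = 0.6, b_e = 0.5)
  d <- simulate_histories(cfg, seed = 202)
  st <- attr(d, "states")
  ids <- as.integer(d$id)
  em <- event_matrices(0.7, 0.6, 0.6, 0.5)$composite
  for (state in 1:2) {
    sel <- which(st[ids, 2] == state & d$first == 1L)
    counts <- tabulate(d$events[sel, 2] + 1L, nbins = 8L)
    expectd <- em[state, ]
    keep <- expectd > 0
    pval <- suppressWarnings(
      chisq.test(counts[keep], p = expectd[keep] / sum(expectd[keep]))$p.value)
    expect_gt(pval, 0.01)
    expect_equal(sum(counts[!keep]), 0)
  }
})

test_that("cohort survivor fractions match annual survival", {
  cfg <- sim_config(n_occasions = 2, cohorts = c(20000, 0), phi_B = 0.76)
  d <- simulate_histories(cfg, seed = 31)
  st <- attr(d, "states")
  surv <- mean(st[, 2] != 3L)
  se <- sqrt(0.76 * 0.24 / nrow(st))
  expect_lt(abs(surv - 0.76), 4 * se)
})

test_that("weekly windows cover both capture periods when detection is certain", {
  arr1 <- c(1, rep(0, 7))  # everyone arrives in week 1, stays 4 weeks
  cfg <- sim_config(n_occasions = 3, cohorts = c(80, 0, 0),
                    arrival_dist = arr1, residence_weeks = 4, p_week = 1)
  w <- simulate_weekly_records(cfg, seed = 3)
  br <- w$states == 1L & !is.na(w$states)
  expect_true(all(w$events[br] %in% c(1L, 5L)))  # always U and E, +/- moult
})

test_that("zero weekly detection leaves only nonbreeding-season events", {
  cfg <- sim_config(n_occasions = 3, cohorts = c(80, 0, 0), p_week = 0)
  w <- simulate_weekly_records(cfg, seed = 5)
  expect_true(all(w$events[!is.na(w$events)] %in% c(0L, 4L)))
  expect_false(any(grepl("breed", w$records$context)))
})

test_that("residence windows past week 8 are clipped and counted", {
  arr8 <- c(rep(0, 7), 1)
  cfg <- sim_config(n_occasions = 2, cohorts = c(30, 0),
                    arrival_dist = arr8, residence_weeks = 4, p_week = 1)
  w <- simulate_weekly_records(cfg, seed = 6)
  expect_gt(w$n_clipped, 0)
  # week 8 is even: lone-week windows yield only E (+/- M) events for breeders
  br <- w$states == 1L & !is.na(w$states)
  expect_true(all(w$events[br] %in% c(3L, 7L)))
})

test_that("encoding raw weekly records reproduces the emitted event sequence", {
  cfg <- sim_config(n_occasions = 4, cohorts = c(120, 40, 0, 0), p_week = 0.5)
  for (seed in c(1, 2, 3)) {
    w <- simulate_weekly_records(cfg, seed = seed)
    enc <- suppressMessages(build_histories(w$records, years = 1:4))
    # condition the directly emitted matrix by the same first-capture rule
    ev <- w$events
    first <- apply(ev, 1, function(x) {
      k <- which(!is.na(x) & x %in% c(1, 2, 3, 5, 6, 7)); if (length(k)) k[1] else NA
    })
    keep <- which(!is.na(first))
    for (i in keep) ev[i, seq_len(first[i] - 1)] <- NA
    expect_setequal(enc$id, as.character(keep))
    ord <- match(as.character(keep), enc$id)
    expect_equal(unname(enc$events[ord, , drop = FALSE]),
                 unname(ev[keep, , drop = FALSE]))
  }
})

test_that("the two simulation levels agree under matched period probabilities", {
  # arrival in weeks 1-5 with a 4-week residence exposes every breeder to
  # exactly 2 uneven and 2 even weeks, so the implied period-level
  # capture probability is 1 - (1 - p_week)^2 for both periods
  p_week <- 0.4
  p_period <- 1 - (1 - p_week)^2
  cfg_w <- sim_config(n_occasions = 2, cohorts = c(20000, 0),
                      phi_B = 0.9, psi_BB = 0.7, psi_NBB = 0.5,
                      m_B = 0.7, m_NB = 0.6, p_week = p_week)
  w <- simulate_weekly_records(cfg_w, seed = 77)
  em <- event_matrices(0.7, 0.6, p_period, p_period)$composite
  for (state in 1:2) {
    sel <- which(w$states[, 2] == state & !is.na(w$states[, 2]))
    counts <- tabulate(w$events[sel, 2] + 1L, nbins = 8L)
    expectd <- em[state, ]
    keep <- expectd > 0
    pval <- suppressWarnings(
      chisq.test(counts[keep], p = expectd[keep] / sum(expectd[keep]))$p.value)
    expect_gt(pval, 0.01)
  }
})

test_that("fixture registry is deterministic and rejects unknown names", {
  expect_error(make_fixture("nope"))
  f1 <- make_fixture("recovery_small")
  f2 <- make_fixture("recovery_small")
  expect_identical(f1$data$events, f2$data$events)
  expect_equal(sum(f1$config$cohorts), 500)
  pd <- make_fixture("perfect_detection")
  expect_equal(unname(pd$config$params$m["B", 1]), 1)
  ml <- make_fixture("marion_like")
  expect_equal(ml$config$n_occasions, 28)
  expect_equal(unname(ml$config$params$psi["B", 1]), 0.84)
})

test_that("simulator configs are validated", {
  expect_error(sim_config(5, cohorts = c(-1, 0, 0, 0, 0)), ">= 0")
  expect_error(sim_config(5, cohorts = c(0, 0, 0, 0, 0)), "at least one")
  expect_error(sim_config(5, cohorts = 10, arrival_dist = rep(1, 8)),
               "summing to 1")
  expect_error(sim_config(5, cohorts = 10, residence_weeks = 0), "residence")
})
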