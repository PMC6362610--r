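test_that("fitting is deterministic given a seed and invariant to row order", {
  sim <- quick_sim(150, T = 5, seed = 4)
  s <- "phi(.) psi(state) m(state) pu(.) be(.)"
  f1 <- fit_mevrd(sim, s, n_starts = 2, seed = 99)
  f2 <- fit_mevrd(sim, s, n_starts = 2, seed = 99)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$starts, f2$starts)
  # permuting histories leaves the MLE unchanged
  set.seed(1)
  perm <- sample(nrow(sim$events))
  simp <- mevrd_data(sim$events[perm, ], years = sim$years,
                     id = sim$id[perm], count = sim$count[perm])
  f3 <- fit_mevrd(simp, s, n_starts = 2, seed = 99)
  expect_equal(f3$deviance, f1$deviance, tolerance = 1e-6)
  expect_equal(unname(f3$beta), unname(f1$beta), tolerance = 1e-4)
})

test_that("the optimum beats random working-scale points", {
  sim <- quick_sim(100, T = 4, seed = 8)
  s <- model_structure("phi(.) psi(.) m(.) pu(.) be(.)")
  fit <- fit_mevrd(sim, s, n_starts = 1, seed = 2)
  set.seed(31)
  for (i in 1:10) {
    beta <- runif(5, -2, 2)
    d <- attr(total_loglik(sim, apply_structure(beta, s, 4)), "deviance")
    expect_lte(fit$deviance, d + 1e-8)
  }
  # the Newton polish may improve slightly on the best recorded start
  expect_lte(fit$deviance, min(fit$starts$deviance) + 1e-12)
})

test_that("with perfect detection the MLE equals empirical transition frequencies", {
  fx <- make_fixture("perfect_detection")
  d <- fx$data
  # states are observed: event 1 = breeder, 4 = nonbreeder, 0 = dead
  ev <- d$events
  n <- nrow(ev); T <- ncol(ev)
  from <- ev[, -T]; to <- ev[, -1]
  fromB <- !is.na(from) & from == 1L
  fromNB <- !is.na(from) & from == 4L
  phiB_emp <- sum(fromB & to %in% c(1L, 4L)) / sum(fromB)
  phiNB_emp <- sum(fromNB & to %in% c(1L, 4L)) / sum(fromNB)
  psiBB_emp <- sum(fromB & to == 1L) / sum(fromB & to %in% c(1L, 4L))
  psiNBB_emp <- sum(fromNB & to == 1L) / sum(fromNB & to %in% c(1L, 4L))
  fit <- fit_mevrd(d, "phi(state) psi(state) m(=1) pu(=1) be(=1)",
                   n_starts = 1, seed = 5)
  est <- coef(fit)
  expect_equal(unname(est["phi_B[all]"]), phiB_emp, tolerance = 1e-6)
  expect_equal(unname(est["phi_NB[all]"]), phiNB_emp, tolerance = 1e-6)
  expect_equal(unname(est["psi_B[all]"]), psiBB_emp, tolerance = 1e-6)
  expect_equal(unname(est["psi_NB[all]"]), psiNBB_emp, tolerance = 1e-6)
})

test_that("boundary estimates are flagged and their intervals suppressed", {
  fx <- make_fixture("perfect_detection")
  fit <- fit_mevrd(fx$data, "phi(state) psi(state) m(state) pu(.) be(.)",
                   n_starts = 1, seed = 5,
                   control = list(maxit = 2000))
  est <- fit$estimates
  det <- est$family %in% c("m", "pu", "be")
  expect_true(any(est$boundary[det]))
  expect_true(all(is.na(est$lcl[est$boundary])))
  expect_true(all(is.na(est$ucl[est$boundary])))
})

test_that("standard errors behave like maximum-likelihood errors should", {
  fx <- make_fixture("recovery_small")
  fit <- fit_mevrd(fx$data, "phi(.) psi(state) m(state) pu(.) be(.)",
                   n_starts = 1, seed = 3)
  expect_equal(fit$rank, fit$np)
  expect_true(all(fit$estimates$se > 0))
  ci <- confint(fit)
  expect_true(all(ci[, 1] >= 0 & ci[, 2] <= 1))
  expect_true(all(ci[, 1] < fit$estimates$estimate &
                  ci[, 2] > fit$estimates$estimate))
  # profile check: re-optimizing with phi pinned at the Wald interval edge
  # should raise the deviance by about qchisq(.95, 1) = 3.84
  i <- which(names(fit$beta) == "phi[all]")
  pin <- unname(fit$beta[i] + 1.96 * fit$se_beta[i])
  prof <- function(beta_rest) {
    beta <- numeric(fit$np); beta[i] <- pin; beta[-i] <- beta_rest
    attr(total_loglik(fit$data,
      apply_structure(beta, fit$structure, fit$n_occasions)), "deviance")
  }
  opt <- optim(unname(fit$beta[-i]), prof, method = "BFGS",
               control = list(reltol = 1e-12))
  rise <- opt$value - fit$deviance
  expect_gt(rise, 3.84 * 0.7)
  expect_lt(rise, 3.84 * 1.3)
})

test_that("standard generics work on a fit", {
  sim <- quick_sim(100, T = 4, seed = 12)
  fit <- fit_mevrd(sim, "phi(.) psi(.) m(.) pu(.) be(.)", n_starts = 1,
                   seed = 1)
  expect_equal(unname(stats::AIC(fit)), fit$deviance + 2 * fit$np)
  expect_length(coef(fit, "working"), fit$np)
  expect_equal(dim(vcov(fit)), c(fit$np, fit$np))
  expect_output(print(fit), "deviance")
  expect_output(summary(fit), "Real-scale")
  boots <- simulate(fit, nsim = 2, seed = 3)
  expect_length(boots, 2)
  expect_s3_class(boots[[1]], "mevrd_data")
  expect_equal(nrow(boots[[1]]$events), n_histories(sim))
  # simulated replicates keep the observed first captures
  expect_equal(sort(boots[[1]]$first), sort(rep(sim$first, sim$count)))
})

test_that("degenerate inputs are rejected with informative errors", {
  sim <- quick_sim(50, T = 4, seed = 2)
  expect_error(fit_mevrd(sim, "phi(.) psi(.) m(.) pu(.) be(.)", n_starts = 0),
               "n_starts")
  expect_error(fit_mevrd(sim, "phi(=1) psi(=1) m(=1) pu(=1) be(=1)"),
               "no free parameters")
})
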