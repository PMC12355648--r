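test_that("E-step reproduces the hand-evaluated conditional expectations", {
  gr <- graph_two_state()
  # one subject observed healthy at 0 and transitioned by 2; grid {1, 2}
  pd <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                 state = c(1, 2)), gr, extra_times = 1)
  cnt <- e_step(pd, 0.5)   # P(0,2) = 0.75 under uniform 0.5 jumps
  expect_equal(cnt$d[1, 2, ], c(2 / 3, 1 / 3))
  expect_equal(unname(cnt$Y[1, ]), c(1, 1 / 3))
  expect_equal(unname(cnt$Y[2, ]), c(0, 2 / 3))

  # a subject observed in the same transient state at both ends keeps
  # expected jumps below 1 and risk below 1
  pds <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                  state = c(1, 1)), gr, extra_times = 1)
  cs <- e_step(pds, 0.3)
  expect_true(all(colSums(cs$d[1, , ]) < 1))
  expect_true(all(cs$Y <= 1 + 1e-12))

  # frames between absorbing observations contribute nothing
  pda <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                  state = c(2, 2)), gr, extra_times = 1)
  ca <- e_step(pda, 0.3)
  expect_equal(sum(ca$d), 0)
  expect_equal(unname(ca$Y[1, ]), c(0, 0))

  # impossible observation under the current jumps
  a0 <- array(0, c(2, 2, 2))
  expect_error(e_step(pd, a0), class = "npmsm_zero_path_error")
})

test_that("exact-entry E-step routes mass through the predecessor states", {
  gid <- graph_id(exact = 3)
  # death observed exactly at tau_2; with all jumps 0.5 the illness path is
  # forced: D = 0.25, all mass through 1->2 then 2->3
  pd <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                 state = c(1, 3)), gid, extra_times = 1)
  a <- npmsm:::as_alpha(pd, 0.5)
  cnt <- e_step(pd, a)
  expect_equal(cnt$d[1, 2, ], c(1, 0))
  expect_equal(cnt$d[1, 3, ], c(0, 0))
  expect_equal(cnt$d[2, 3, ], c(0, 1))
  expect_equal(unname(cnt$Y[1, ]), c(1, 0))
  expect_equal(unname(cnt$Y[2, ]), c(0, 1))
  expect_identical(e_step_exact(pd, a), cnt)  # only exact frames here

  # with the illness route closed all mass flows through the direct 1->3
  # jump at the entry bin
  a2 <- a; a2[1, 2, ] <- 0
  cnt2 <- e_step(pd, a2)
  expect_equal(cnt2$d[1, 3, ], c(0, 1))
  expect_equal(sum(cnt2$d[1, 2, ]), 0)
  expect_equal(sum(cnt2$d[2, 3, ]), 0)

  # no exact states declared: identical to the censored-frame E-step
  pd0 <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                  state = c(1, 3)), graph_id(),
                       extra_times = 1)
  expect_equal(nrow(pd0$intervals[pd0$intervals$exact, ]), 0)
  cnt0 <- e_step_exact(pd0, 0.4)
  expect_equal(sum(cnt0$d) + sum(cnt0$Y), 0)

  # exact-entry mass conservation: expected jumps into the entered state
  # concentrate at the entry bin and total one entry
  expect_equal(sum(cnt$d[, 3, 2]), 1)
  expect_equal(sum(cnt$d[, 3, -2]), 0)
})

test_that("M-step solves the constrained maximisation with the multiplier", {
  gid <- graph_id()
  mk <- function(d12, d13, Y1) {
    d <- array(0, c(3, 3, 1)); d[1, 2, 1] <- d12; d[1, 3, 1] <- d13
    Y <- matrix(0, 3, 1); Y[1, 1] <- Y1
    list(d = d, Y = Y)
  }
  # interior case: alpha = d / Y
  a <- m_step(mk(0.25, 0.35, 2), gid)
  expect_equal(a[1, 2, 1], 0.125)
  expect_equal(a[1, 3, 1], 0.175)
  # active constraint: alpha = d / sum(d)
  a <- m_step(mk(0.5, 0.7, 1), gid)
  expect_equal(a[1, 2, 1], 5 / 12)
  expect_equal(a[1, 3, 1], 7 / 12)
  # empty risk set: zero, not NaN
  a <- m_step(mk(0, 0, 0), gid)
  expect_true(all(a == 0))
})

test_that("observed log-likelihood matches direct products", {
  gr <- graph_two_state()
  pd <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                 state = c(1, 2)), gr, extra_times = 1)
  expect_equal(observed_loglik(pd, 0.5), log(0.75))

  # never leaving the initial state with zero jumps: likelihood one
  pds <- panel_dataset(data.frame(subject_id = 1, time = c(0, 1, 2),
                                  state = c(1, 1, 1)), gr)
  a0 <- array(0, c(2, 2, 2))
  expect_equal(observed_loglik(pds, a0), 0)

  # impossible data: -Inf, flagged with the offending interval
  ll <- observed_loglik(pd, array(0, c(2, 2, 2)))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_interval")$subject_id, "1")
})

test_that("EM drives the toy fit to its known fixed point", {
  gr <- graph_two_state()
  pd <- panel_dataset(data.frame(subject_id = 1, time = c(0, 2),
                                 state = c(1, 2)), gr, extra_times = 1)
  fit <- fit_npmsm(pd, tol = 1e-10, init = 0.5, max_iter = 10)
  expect_lte(fit$n_iter, 3)
  expect_equal(fit$alpha$alpha[1, 2, ], c(2 / 3, 1))
  expect_equal(unname(transition_probability(fit$alpha, 0, 2)[1, 2]), 1)
  expect_equal(fit$loglik, 0)

  # all subjects stay put: everything zero after one iteration
  pds <- panel_dataset(data.frame(subject_id = rep(1:2, each = 2),
                                  time = rep(c(0, 2), 2),
                                  state = rep(1, 4)), gr, extra_times = 1)
  fits <- fit_npmsm(pds, tol = 1e-8)
  expect_true(all(fits$alpha$alpha == 0))
  expect_lte(fits$n_iter, 2)
})

test_that("likelihood trace is nondecreasing and constraints preserved", {
  set.seed(91)
  for (r in 1:25) {
    pd <- random_two_state_panel(sample(3:10, 1))
    if (pd$K < 1) next
    fit <- suppressWarnings(fit_npmsm(pd, tol = 1e-6, max_iter = 300))
    expect_true(all(diff(fit$trace$loglik) > -1e-9))
    em <- apply(fit$alpha$alpha, c(1, 3), sum)
    expect_true(all(em <= 1 + 1e-10) && all(fit$alpha$alpha >= 0))
  }
  # including exact-state fits (likelihood of the mixed exact form)
  set.seed(17)
  for (r in 1:5) {
    pd <- random_scenario_panel(4, n = 15, seed = 400 + r)
    fit <- suppressWarnings(fit_npmsm(pd, tol = 1e-6, max_iter = 300))
    expect_gt(sum(pd$intervals$exact), 0)
    expect_true(all(diff(fit$trace$loglik) > -1e-9))
  }
})

test_that("zero jumps are absorbing across iterations", {
  set.seed(12)
  pd <- random_scenario_panel(1, n = 20, seed = 5)
  alpha <- npmsm:::as_alpha(pd, 1 / pd$K)
  # zero out a scattering of coordinates and iterate by hand
  alpha[1, 2, seq(1, pd$K, by = 3)] <- 0
  zero_mask <- alpha == 0
  for (it in 1:10) {
    alpha <- m_step(e_step(pd, alpha), pd$graph)
    expect_true(all(alpha[zero_mask] == 0))
  }
})

test_that("reduced gradient certifies fixed points and flags others", {
  set.seed(55)
  pd <- random_two_state_panel(12)
  # at the uniform initialisation the gradient indicates improvement
  a0 <- npmsm:::as_alpha(pd, 1 / pd$K)
  g0 <- reduced_gradient(a0, e_step(pd, a0), pd$graph)
  expect_gt(max(g0), 0)
  # after convergence the certificate holds at a tight tolerance
  fit <- fit_npmsm(pd, tol = 1e-9, max_iter = 20000)
  gr_fit <- reduced_gradient(fit$alpha$alpha, fit$counts, pd$graph)
  expect_lt(max(gr_fit), 1e-4)
  expect_true(kkt_check(fit$alpha$alpha, fit$counts, pd$graph, eps = 1e-4))
  # an exact mu = 0 fixed point has zero gradient by substitution
  cnt <- fit$counts
  a_fix <- m_step(cnt, pd$graph)
  S <- colSums(aperm(cnt$d, c(2, 1, 3)), dims = 1)
  if (all(S - cnt$Y <= 0)) {
    g_fix <- reduced_gradient(a_fix, cnt, pd$graph)
    expect_lt(max(abs(g_fix[a_fix > 0])), 1e-6)
  }
  # zero coordinates with zero expected counts never block convergence
  expect_true(all(gr_fit[fit$alpha$alpha == 0] <= 0 |
                    fit$counts$d[fit$alpha$alpha == 0] > 0))
})

test_that("stopping criteria and failure modes behave as documented", {
  set.seed(3)
  pd <- random_two_state_panel(10)
  expect_warning(fit_npmsm(pd, tol = 1e-12, max_iter = 3),
                 class = "npmsm_max_iter_warning")
  f1 <- fit_npmsm(pd, tol = 1e-7, criterion = "likelihood", max_iter = 5000)
  f2 <- fit_npmsm(pd, tol = 1e-6, criterion = "kkt", kkt_eps = 1e-6,
                  max_iter = 5000)
  f3 <- fit_npmsm(pd, tol = 1e-8, criterion = "intensity", max_iter = 5000)
  expect_equal(f1$stop_reason, "likelihood")
  expect_equal(f2$stop_reason, "kkt")
  # all three criteria agree on the maximised likelihood
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
  expect_equal(f2$loglik, f3$loglik, tolerance = 1e-6)
  # a user-supplied init violating positivity warns
  a0 <- npmsm:::as_alpha(pd, 1 / pd$K); a0[1, 2, 1] <- 0
  expect_warning(
    expect_warning(fit_npmsm(pd, init = a0, max_iter = 5),
                   regexp = "strictly positive"),
    class = "npmsm_max_iter_warning")
})
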