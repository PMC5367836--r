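test_that("the steady state is a fixed point under a label-free protocol", {
  rates <- apply_hypotheses(0.01, 0.25)
  chase20 <- tibble::tibble(start_h = 0, end_h = 20, label_on = FALSE)
  traj <- simulate_protocol(rates, chase20)
  init <- unlist(traj[1, -1])
  drift <- apply(abs(sweep(as.matrix(traj[, -1]), 2, init)), 2, max)
  expect_true(all(drift < 1e-6))
  expect_equal(endpoint_summary(traj)$pct_labelled, 0)
})

test_that("hypothesis-mode runs conserve cells and phase occupancy", {
  proto <- default_study_protocol()
  for (pars in list(c(0.01, 0.25), c(0.1, 0.05), c(0.003, 0.6))) {
    rates <- apply_hypotheses(pars[1], pars[2])
    traj <- simulate_protocol(rates, proto)
    total <- rowSums(traj[, -1])
    expect_true(max(abs(total - 100)) < 1e-6)
    # labelling is kinetically neutral: each phase total stays at its
    # steady-state value throughout the pulses and chase
    ss <- steady_state(rates)
    expect_true(max(abs(traj$G + traj$Gp - ss$pct_g)) < 1e-5)
    expect_true(max(abs(traj$S + traj$Sp - ss$pct_s)) < 1e-5)
    expect_true(max(abs(traj$M + traj$Mp - ss$pct_m)) < 1e-5)
  }
})

test_that("a protocol ending in a pulse leaves no unlabelled S cells", {
  traj <- simulate_protocol(apply_hypotheses(0.01, 0.25),
                            default_study_protocol())
  expect_lt(traj$S[nrow(traj)], 1e-9)
})

test_that("endpoint summary collapses the final state into the triplet", {
  fake <- tibble::tibble(time_h = c(0, 1), G = c(50, 90), S = c(10, 0),
                         M = c(20, 4), Gp = c(10, 1), Sp = c(5, 3),
                         Mp = c(5, 2))
  expect_equal(unlist(endpoint_summary(fake)),
               c(pct_g_unlabelled = 90, pct_m_unlabelled = 4, pct_labelled = 6))
})

test_that("the integrator agrees with an independent fine-step Euler oracle", {
  proto <- default_study_protocol()
  endpoint <- simulate_protocol(apply_hypotheses(0.01, 0.25), proto,
                                keep = "endpoint")
  got <- unlist(endpoint[nrow(endpoint), -1])
  oracle <- euler_oracle_endpoint(0.01, 0.25, proto, dt = 1e-4)
  expect_true(all(abs(got - oracle) < 1e-4))
})

test_that("endpoint fast path matches sequential stepping", {
  proto <- default_study_protocol()
  for (pars in list(c(0.01, 0.25), c(0.2, 0.02))) {
    rates <- apply_hypotheses(pars[1], pars[2])
    traj <- simulate_protocol(rates, proto)
    fin <- unlist(traj[nrow(traj), -1])
    fast <- simulate_protocol(rates, proto, keep = "endpoint")
    expect_equal(unlist(fast[2, -1]), fin, tolerance = 1e-9)
  }
})

test_that("halving the step changes endpoint summaries by less than 1e-5", {
  proto <- default_study_protocol()
  for (a_g in c(0.001, 0.02, 0.3)) {
    for (a_m in c(0.005, 0.1, 0.5)) {
      r <- apply_hypotheses(a_g, a_m)
      s1 <- unlist(endpoint_summary(simulate_protocol(r, proto, dt_h = 0.01,
                                                      keep = "endpoint")))
      s2 <- unlist(endpoint_summary(simulate_protocol(r, proto, dt_h = 0.005,
                                                      keep = "endpoint")))
      expect_true(all(abs(s1 - s2) < 1e-5))
    }
  }
})

test_that("with no shedding and no exit the labelled pool never shrinks", {
  rates <- cycle_rates(a_g = 0.05, a_s = 1 / 6.5, a_m = 0.2,
                       d_g = 0, d_s = 0, d_m = 0, alpha = 0, beta = Inf)
  init <- c(G = 80, S = 10, M = 10, Gp = 0, Sp = 0, Mp = 0)
  traj <- simulate_protocol(rates, default_study_protocol(), initial = init)
  labelled <- traj$Gp + traj$Sp + traj$Mp
  expect_true(all(diff(labelled) > -1e-9))
})

test_that("finite-beta labelling approaches the instant-labelling limit", {
  proto <- default_study_protocol()
  instant <- endpoint_summary(simulate_protocol(apply_hypotheses(0.01, 0.25),
                                                proto, keep = "endpoint"))
  finite <- cycle_rates(a_g = 0.01, a_s = 1 / 6.5, a_m = 0.25, d_g = 0.01,
                        beta = 50)
  slow <- endpoint_summary(simulate_protocol(finite, proto, keep = "endpoint"))
  expect_true(all(abs(unlist(instant) - unlist(slow)) < 1))
  # and a small beta labels fewer cells than instant transfer
  weak <- cycle_rates(a_g = 0.01, a_s = 1 / 6.5, a_m = 0.25, d_g = 0.01,
                      beta = 0.2)
  weak_sum <- endpoint_summary(simulate_protocol(weak, proto, keep = "endpoint"))
  expect_lt(weak_sum$pct_labelled, instant$pct_labelled)
})

test_that("labelled-cohort composition starts all-S and drains S phase", {
  comp <- within_labelled_composition(apply_hypotheses(0.015, 0.5),
                                      baron_protocol())
  expect_equal(unlist(comp[1, -1]),
               c(pct_g_labelled = 0, pct_s_labelled = 100, pct_m_labelled = 0))
  sums <- comp$pct_g_labelled + comp$pct_s_labelled + comp$pct_m_labelled
  expect_true(max(abs(sums - 100)) < 1e-9)
  at <- function(t) comp[which.min(abs(comp$time_h - t)), ]
  expect_lt(at(19)$pct_s_labelled, at(1)$pct_s_labelled)
})

test_that("invalid simulator inputs are rejected", {
  rates <- apply_hypotheses(0.01, 0.25)
  expect_error(
    simulate_protocol(rates, default_study_protocol(),
                      initial = c(G = -5, S = 0, M = 0, Gp = 0, Sp = 0, Mp = 0)),
    class = "edupulse_invalid_parameter"
  )
  expect_error(
    simulate_protocol(rates, default_study_protocol(), dt_h = 0.4),
    class = "edupulse_invalid_parameter"
  )
})
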