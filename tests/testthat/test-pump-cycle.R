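test_that("the canonical cycle has ten states and closes thermodynamically", {
  m <- build_canonical_cycle()
  expect_equal(nrow(m$states), 10L)
  expect_setequal(m$states$label,
                  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii",
                    "ix", "x"))
  expect_lt(abs(cycle_closure_check(m)), 1e-6)
  # at SMF 0 the cycle free energy is the reaction free energy (~ -6 kcal)
  prof <- profile_from_model(m, smf_mV = 0)
  expect_equal(prof$G_cum_kcal[nrow(prof)], -2 * 23.061 * 0.13,
               tolerance = 1e-9)
  # at the break-even SMF (130 mV at Fd -450, 2 Na+/cycle) the net cycle
  # free energy vanishes
  prof130 <- profile_from_model(m, smf_mV = 130)
  expect_lt(abs(prof130$G_cum_kcal[nrow(prof130)]), 1e-9)
  # profile endpoint shifts by +na_per_cycle * F * SMF
  expect_equal(prof130$G_cum_kcal[nrow(prof130)] -
                 prof$G_cum_kcal[nrow(prof)],
               2 * 23.061 * 0.130, tolerance = 1e-9)
})

test_that("an uncoupled cycle (no pumped charge) ignores the SMF", {
  p0 <- cycle_params(na_per_cycle = 0,
                     electrogenic = c(uptake = 0, translocation = 0,
                                      release = 0))
  m0 <- build_canonical_cycle(p0)
  e0 <- profile_from_model(m0, smf_mV = 0)
  e180 <- profile_from_model(m0, smf_mV = 180)
  expect_equal(e0$G_cum_kcal, e180$G_cum_kcal, tolerance = 1e-12)
})

test_that("closure residual detects a perturbed step and is SMF-invariant", {
  m <- build_canonical_cycle()
  m_bad <- m
  m_bad$transitions$dG0_kcal[3] <- m_bad$transitions$dG0_kcal[3] + 1
  expect_equal(cycle_closure_check(m_bad), 1, tolerance = 1e-9)
  for (smf in c(0, 65, 130, 260)) {
    expect_lt(abs(cycle_closure_check(m, smf_mV = smf)), 1e-6)
  }
  # an inconsistent parameterization is refused at build time
  expect_error(
    build_canonical_cycle(cycle_params(), closure_tol = -1),
    "closure"
  )
})

test_that("the generator matrix conserves probability", {
  # 2-state toy with known generator
  m2 <- markov_model(c("1", "2"), from = "1", to = "2", k_fwd = 2,
                     k_rev = 1)
  K <- rate_matrix(m2)
  expect_equal(unname(K), rbind(c(-2, 1), c(2, -1)), tolerance = 1e-12)
  m <- build_canonical_cycle()
  K10 <- rate_matrix(m)
  expect_lt(max(abs(colSums(K10))), 1e-12 * max(abs(K10)))
  # SMF = 0 equals the uncoupled rates exactly
  expect_equal(rate_matrix(m, smf_mV = 0), rate_matrix(m, smf_mV = 0))
  K0 <- rate_matrix(m, smf_mV = 0)
  tr <- m$transitions
  for (j in seq_len(nrow(tr))) {
    expect_equal(K0[tr$to[j], tr$from[j]], tr$k_fwd0[j], tolerance = 1e-12)
  }
})

test_that("steady state solves the null space and the flux couples 2 Na+ per NADH", {
  m2 <- markov_model(c("1", "2"), from = "1", to = "2", k_fwd = 2,
                     k_rev = 1)
  ss2 <- steady_state(m2)
  expect_equal(unname(ss2$populations), c(1 / 3, 2 / 3), tolerance = 1e-10)

  m <- build_canonical_cycle()
  ss <- steady_state(m)
  expect_true(all(ss$populations >= 0))
  expect_equal(sum(ss$populations), 1, tolerance = 1e-12)
  expect_gt(ss$cycle_flux, 0)           # forward pumping at SMF = 0
  expect_equal(ss$na_flux, 2 * ss$nadh_flux)   # exact stoichiometry
  # all edge cuts agree at steady state
  expect_lt(diff(range(ss$edge_flux)), 1e-6 * max(abs(ss$edge_flux)))
  # at break-even the cycle satisfies global detailed balance: every edge
  # flux vanishes relative to the slowest rate scale
  ss_be <- steady_state(m, smf_mV = 130)
  slowest <- min(m$transitions$k_fwd0)
  expect_lt(max(abs(ss_be$edge_flux)), 1e-6 * slowest)
})

test_that("flux decreases monotonically with SMF and crosses zero at break-even", {
  m <- build_canonical_cycle()
  scan <- smf_scan(m, seq(0, 260, length.out = 10))
  expect_true(all(diff(scan$na_flux) <= 0))
  expect_gt(scan$na_flux[1], 0)
  expect_lt(scan$na_flux[nrow(scan)], 0)
  # sign change brackets 130 mV
  expect_gt(steady_state(m, smf_mV = 129)$na_flux, 0)
  expect_lt(steady_state(m, smf_mV = 131)$na_flux, 0)

  # low-potential ferredoxin parameterization: break-even at 180 mV
  m_low <- build_canonical_cycle(make_cycle_params("fd-low"))
  expect_gt(steady_state(m_low, smf_mV = 179)$na_flux, 0)
  expect_lt(steady_state(m_low, smf_mV = 181)$na_flux, 0)
  expect_lt(abs(steady_state(m_low, smf_mV = 180)$na_flux),
            1e-6 * min(m_low$transitions$k_fwd0))
})

test_that("deterministic integration matches the 2-state closed form", {
  m2 <- markov_model(c("1", "2"), from = "1", to = "2", k_fwd = 2,
                     k_rev = 1)
  out <- simulate_timecourse(m2, t_end = 1.5, method = "deterministic",
                             p0 = c(1, 0), n_out = 60)
  expect_equal(out$populations[, 1],
               1 / 3 + (2 / 3) * exp(-3 * out$times), tolerance = 1e-7)
  # conservation and non-negativity at every step
  expect_true(all(abs(rowSums(out$populations) - 1) < 1e-8))
  expect_true(all(out$populations > -1e-10))
  # t_end = 0 returns the initial condition
  out0 <- simulate_timecourse(m2, 0, p0 = c(0.25, 0.75))
  expect_equal(unname(out0$populations[1, ]), c(0.25, 0.75))
})

test_that("stochastic sampling agrees with the deterministic propagator", {
  m2 <- markov_model(c("1", "2"), from = "1", to = "2", k_fwd = 2,
                     k_rev = 1)
  n_traj <- 1500
  sto <- simulate_timecourse(m2, t_end = 0.5, method = "stochastic",
                             p0 = c(1, 0), n_traj = n_traj, seed = 11)
  p_det <- 1 / 3 + (2 / 3) * exp(-3 * 0.5)
  se <- sqrt(p_det * (1 - p_det) / n_traj)
  expect_lt(abs(sto$p_final[["1"]] - p_det), 3 * se)
  expect_error(simulate_timecourse(m2, 1, "stochastic"), "seed")
})

test_that("cycle populations conserve and stay non-negative during relaxation", {
  m <- build_canonical_cycle()
  out <- simulate_timecourse(m, t_end = 0.05, method = "deterministic")
  expect_true(all(abs(rowSums(out$populations) - 1) < 1e-6))
  expect_true(all(out$populations > -1e-8))
  # converges to the steady state
  ss <- steady_state(m)
  expect_equal(unname(out$populations[nrow(out$populations), ]),
               unname(ss$populations), tolerance = 1e-4)
  # cumulative Na+ grows at the steady-state rate once relaxed
  na_rate <- diff(tail(out$na_pumped, 2)) / diff(tail(out$times, 2))
  expect_equal(na_rate, ss$na_flux, tolerance = 1e-3)
})
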