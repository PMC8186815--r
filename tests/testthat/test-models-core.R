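p <- two_process_params()

test_that("light transduction follows the dose-response and sleep gating", {
  expect_equal(alpha_of_light(1000, 0, p), 0.05 * sqrt(1000 / 9500),
               tolerance = 1e-12)
  expect_equal(alpha_of_light(1000, 0, p), 0.016222, tolerance = 1e-4)
  expect_identical(alpha_of_light(0, 0, p), 0)
  expect_identical(alpha_of_light(10000, 1, p), 0)
  expect_error(alpha_of_light(-5, 0, p), "non-negative")
})

test_that("circadian drive scales with ready receptors and gates on sleep", {
  expect_identical(circadian_drive(1, 5000, 0, p), 0)
  n_ss <- unname(steady_state_drive(1000, p)["n_ss"])
  expect_equal(circadian_drive(n_ss, 1000, 0, p), 0.1731, tolerance = 1e-4)
  expect_identical(circadian_drive(0.5, 1000, 1, p), 0)
  expect_error(circadian_drive(1.2, 1000, 0, p), "\\[0, 1\\]")
})

test_that("Process L derivative vanishes at its equilibria", {
  expect_identical(process_L_deriv(0, 0, 0, p), 0)
  a <- alpha_of_light(1000, 0, p)
  expect_equal(process_L_deriv(a / (a + p$gamma), 1000, 0, p), 0,
               tolerance = 1e-12)
  expect_equal(process_L_deriv(0.5, 0, 0, p), -60 * 0.0075 * 0.5,
               tolerance = 1e-12)
})

test_that("oscillator derivatives match hand-computed values", {
  d0 <- process_P_deriv(0, 0, 0, p)
  expect_equal(unname(d0), c(0, 0), tolerance = 1e-15)
  d1 <- process_P_deriv(1, 0, 0, p)
  expect_equal(unname(d1[1]), pi / 12 * p$mu * (1 / 3 + 4 / 3 - 256 / 105),
               tolerance = 1e-12)
  expect_equal(unname(d1[2]), -pi / 12 * (24 / (0.99729 * 24.2))^2,
               tolerance = 1e-12)
})

test_that("steady-state drive reproduces the published values", {
  expect_equal(unname(round(steady_state_drive(1000, p)["u_ss"], 4)), 0.1731)
  expect_equal(unname(round(steady_state_drive(10000, p)["u_ss"], 4)), 0.2208)
  expect_equal(unname(steady_state_drive(0, p)), c(0, 0))
})

test_that("homeostat derivative has attractors at 0 (sleep) and 1 (wake)", {
  expect_identical(homeostat_deriv(1, 0, p), 0)
  expect_identical(homeostat_deriv(0, 1, p), 0)
  expect_equal(homeostat_deriv(0.5, 1, p), -0.5 / 4.2, tolerance = 1e-12)
  expect_equal(homeostat_deriv(0.3, 0, p), 0.7 / 18.2, tolerance = 1e-12)
})

test_that("sleepiness combines homeostat and circadian components", {
  s <- two_process_state("S+C3", c(n = 0.5, x = 0, xc = 0, H = 0.67))
  expect_equal(sleepiness(s, p), 0.67)
  s2 <- two_process_state("S+C2", c(x = 1, xc = 0, H = 0.5))
  expect_equal(sleepiness(s2, p), 0.5 - 0.1333)
  s3 <- two_process_state("S+C1", c(theta = pi, H = 0.5))
  expect_equal(sleepiness(s3, p), 0.5 + 0.1333)
})

test_that("spontaneous automaton is hysteretic", {
  expect_identical(spontaneous_transition(0.67, 0, p), 1L)
  expect_identical(spontaneous_transition(0.4, 0, p), 0L)
  expect_identical(spontaneous_transition(0.4, 1, p), 1L)
  expect_identical(spontaneous_transition(0.17, 1, p), 0L)
})

test_that("scheduled transitions respect the sleepiness bounds", {
  sch <- sleep_schedule(T_sleep = 10, T_wake = 18)
  ok <- controllable_transition(10, sch, 0.72, 0, p)
  expect_identical(ok$beta, 1L)
  expect_null(ok$violation)
  bad <- controllable_transition(10, sch, 0.80, 0, p)
  expect_match(bad$violation, "rejected")
  expect_identical(bad$beta, 1L)       # safety override at B >= B1_max
  early <- controllable_transition(10, sch, 0.50, 0, p)
  expect_identical(early$beta, 0L)     # too alert to sleep: rejected, hold
  expect_match(early$violation, "rejected")
  wk <- controllable_transition(18, sch, 0.27, 1, p)
  expect_identical(wk$beta, 0L)
  expect_null(wk$violation)
})

test_that("tuned sleep rule follows the prescribed light", {
  expect_identical(tuned_sleep_rule(10000, 0.7, 1, p), 0L)
  expect_identical(tuned_sleep_rule(0, 0.7, 0, p), 1L)
  expect_identical(tuned_sleep_rule(0, 0.4, 0, p), 0L)
  expect_identical(tuned_sleep_rule(0, 0.4, 1, p), 1L)
})

test_that("hybrid integration keeps n and H inside [0, 1] and H monotone in darkness", {
  st <- two_process_state("S+C3", c(n = 0.9, x = 0.5, xc = -0.5, H = 0.05))
  dark <- light_signal(c(0, 60), 0, I_max = 1000)
  tr <- integrate_hybrid(st, dark, "forced-awake", c(0, 60))
  expect_true(all(tr$states[, "n"] >= -1e-12 & tr$states[, "n"] <= 1 + 1e-12))
  expect_true(all(tr$states[, "H"] >= -1e-12 & tr$states[, "H"] <= 1 + 1e-12))
  expect_true(all(diff(tr$states[, "H"]) >= -1e-12))  # wake: H rises to 1
  expect_lt(max(tr$states[, "n"]), 0.9 + 1e-9)        # dark: n decays
})

test_that("light has no effect on the oscillator during sleep", {
  y0 <- c(n = 0.6, x = 0.3, xc = 0.8, H = 0.8)
  st <- two_process_state("S+C3", y0, beta = 1)
  bright <- light_signal(c(0, 6), 10000, I_max = 10000)
  dark <- light_signal(c(0, 6), 0, I_max = 10000)
  trb <- integrate_hybrid(st, bright, "forced-awake", c(0, 6))
  trd <- integrate_hybrid(st, dark, "forced-awake", c(0, 6))
  # beta stays 1 under the no-transition policy, so the two runs must agree
  expect_equal(trb$states, trd$states, tolerance = 1e-14)
  expect_true(all(trb$u == 0))
})

test_that("spontaneous switches land exactly on the thresholds", {
  cyc <- fx_cyc3()
  st <- reference_state(12, 0, cyc)
  ls <- light_signal(c(0, 16, 24, 40, 48), c(1000, 0, 1000, 0), 1000)
  tr <- integrate_hybrid(st, ls, "spontaneous", c(0, 48))
  ev <- tr$switch_events
  expect_gt(nrow(ev), 0)
  on <- ev[ev$trigger == "spontaneous" & ev$beta_new == 1, ]
  off <- ev[ev$trigger == "spontaneous" & ev$beta_new == 0, ]
  if (nrow(on)) expect_equal(on$B, rep(p$H_m, nrow(on)), tolerance = 1e-7)
  if (nrow(off)) expect_equal(off$B, rep(p$L_m, nrow(off)), tolerance = 1e-7)
  # beta only changes at recorded events
  chg <- which(diff(tr$beta) != 0)
  expect_equal(sort(tr$times[chg + 1]), sort(ev$time[ev$beta_old != ev$beta_new]),
               tolerance = 1e-6)
})

test_that("event times agree with a much finer fixed-step integration", {
  cyc <- fx_cyc3()
  st <- reference_state(10, 0, cyc)
  ls <- light_signal(c(0, 16, 24), c(1000, 0), 1000)
  t1 <- integrate_hybrid(st, ls, "spontaneous", c(0, 24), dt = 0.005)
  t2 <- integrate_hybrid(st, ls, "spontaneous", c(0, 24), dt = 5e-5)
  e1 <- t1$switch_events$time
  e2 <- t2$switch_events$time
  expect_equal(length(e1), length(e2))
  expect_true(all(abs(e1 - e2) < 1e-3))
})

test_that("halving the step changes a 48-h terminal state at RK4 order", {
  cyc <- fx_cyc3()
  st <- reference_state(3, 0, cyc)
  ls <- light_signal(c(0, 16, 24, 40, 48), c(1000, 0, 1000, 0), 1000)
  y1 <- final_state(integrate_hybrid(st, ls, "forced-awake", c(0, 48),
                                     dt = 0.02))$y
  y2 <- final_state(integrate_hybrid(st, ls, "forced-awake", c(0, 48),
                                     dt = 0.01))$y
  y3 <- final_state(integrate_hybrid(st, ls, "forced-awake", c(0, 48),
                                     dt = 0.005))$y
  e1 <- max(abs(y1 - y3))
  e2 <- max(abs(y2 - y3))
  expect_lt(e2, e1)              # refinement converges
  expect_lt(e1, 1e-6)            # already tiny at coarse step
})
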