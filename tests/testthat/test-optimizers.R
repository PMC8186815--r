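test_that("an entrained subject needs no optimization", {
  cyc <- fx_cyc3()
  y0 <- reference_state(0, 1, cyc)
  r <- minimize_time_spontaneous(y0, 1, cyc, 1000, spec = fx_spec3())
  expect_equal(r$t_f, 0, tolerance = 1e-6)
  rc <- minimize_time_controllable(y0, 1, cyc, 1000, spec = fx_spec3())
  expect_equal(rc$t_f, 0, tolerance = 1e-6)
})

test_that("optimized night-shift recovery beats open-loop and is bang-off", {
  rep12 <- fx_shift_ctrl_10000()       # 8pm-8am under 1000 lux, then optimize
  ol <- fx_shift_openloop()$s20_1000
  expect_lt(rep12$t_f, ol$t_f)
  opt <- rep12$detail
  expect_true(opt$bang_off)
  expect_true(all(opt$light$levels %in% c(0, opt$I_max)))
  # terminal residual at the certified horizon is non-positive
  expect_lte(opt$residual, 0)
})

test_that("realized switches respect the sleepiness windows", {
  opt <- fx_shift_ctrl_10000()$detail
  sw <- opt$realized_switches
  B <- opt$switch_B
  p <- two_process_params()
  tol <- 5e-3                          # window tolerance at 0.1-h light bins
  reg <- sw$trigger != "immediate"     # arm-time forced switches (end of a
                                       # night shift with B beyond the band)
  sleeps <- B[sw$beta == 1 & reg]
  wakes <- B[sw$beta == 0 & reg]
  expect_true(all(sleeps >= p$H_m - tol & sleeps <= p$B1_max + tol))
  expect_true(all(wakes >= p$L_m - tol & wakes <= p$B2_max + tol))
  # no wake interval longer than 18 h
  tt <- c(0, sw$times)
  bb <- c(0L, sw$beta)
  wake_starts <- tt[bb == 0]
  sleep_starts <- tt[bb == 1]
  for (ws in wake_starts) {
    nxt <- sleep_starts[sleep_starts > ws]
    if (length(nxt)) expect_lte(nxt[1] - ws, 18 + 0.2)
  }
})

test_that("shift-light optimization reaches the short recovery window", {
  r1000 <- fx_shift_optlight(1000)
  expect_lt(r1000$t_f, fx_shift_openloop()$s20_0$t_f + 0.1)
  expect_gt(r1000$t_f, 1)
})

test_that("circadian-only optimization entrains the oscillator", {
  cycC <- fx_cycC()
  yC <- reference_state(4, 1, cycC)
  r <- suppressWarnings(optimize_process_C_only(yC, 1, 10000, cycle = cycC))
  expect_lt(r$t_f, r$t_open)
  expect_true(all(r$light$levels %in% c(0, 10000)))
})
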