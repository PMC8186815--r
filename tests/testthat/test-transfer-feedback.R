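test_that("reduced-model drive maps to bang-off lux on the full model", {
  cyc2 <- fx_cyc2()
  spec2 <- terminal_spec("S+C2")
  y2 <- reference_state(4, 1, cyc2)
  r2 <- suppressWarnings(minimize_time_controllable(y2, 1, cyc2, 1000,
                                                    spec = spec2))
  cyc3 <- fx_cyc3()
  y3 <- reference_state(4, 1, cyc3)
  tr <- transfer_reduced_solution(r2, y3, 1, cyc3, 1000)
  if (!is.null(tr$light)) {
    expect_true(all(tr$light$levels %in% c(0, 1000)))
  }
  expect_true(is.finite(tr$t_f))
  # the transferred strategy entrains, possibly with the reference-light
  # supplement; it cannot beat the directly optimized full-model time by
  # more than numerical slack
  r3 <- fx_sweep()  # ensures the cache is warm for later tests
  expect_gt(tr$t_f, 0)
  assign("transfer4", list(reduced = r2, transfer = tr), envir = .fx)
})

test_that("zero drive transfers to zero light", {
  p <- two_process_params()
  u1000 <- unname(steady_state_drive(1000, p)["u_ss"])
  # w = u/u_max by construction, so u = 0 bins map to I = 0 and u = u_max
  # bins to I = I_max
  expect_equal(circentrain:::lux_to_u(1000, p), u1000, tolerance = 1e-10)
  expect_equal(circentrain:::u_to_lux(u1000, p), 1000, tolerance = 1e-6)
  expect_equal(circentrain:::u_to_lux(0, p), 0)
})

test_that("training records count and split match the sampling scheme", {
  fb <- fx_feedback()
  ts <- fb$trainset
  for (cs in names(fb$results)) {
    tf <- fb$results[[cs]]$t_f
    n_expected <- length(seq(0, tf, by = ts$sample_by))
    n_actual <- sum(ts$records$case_id == as.numeric(cs))
    expect_equal(n_actual, n_expected)
  }
  expect_setequal(unique(ts$records$beta), c(0L, 1L))
  expect_true(all(ts$records$gamma_sleep >= 0, na.rm = TRUE))
  expect_true(all(ts$records$gamma_wake >= 0, na.rm = TRUE))
})

test_that("controller lookup returns the stored action for training points", {
  fb <- fx_feedback()
  ctrl <- fb$controller
  set.seed(31)
  for (i in sample(nrow(ctrl$wake), 5)) {
    rec <- ctrl$wake[i, ]
    a <- controller_step(rec$theta, rec$H, rec$theta_ref, 0, ctrl)
    expect_identical(a$I, rec$I)
    expect_identical(a$gamma_sleep, rec$gamma_sleep)
  }
  for (i in sample(nrow(ctrl$sleep), 3)) {
    rec <- ctrl$sleep[i, ]
    a <- controller_step(rec$theta, rec$H, rec$theta_ref, 1, ctrl)
    expect_identical(a$gamma_wake, rec$gamma_wake)
  }
  # awake actions come from bang-off optima
  expect_true(all(ctrl$wake$I %in% c(0, ctrl$I_max)))
})

test_that("training sets survive the CSV + manifest round trip", {
  fb <- fx_feedback()
  f <- tempfile(fileext = ".csv")
  write_training_set(fb$trainset, f)
  back <- read_training_set(f)
  expect_equal(nrow(back$records), nrow(fb$trainset$records))
  expect_equal(back$records$theta, fb$trainset$records$theta,
               tolerance = 1e-10)
  expect_equal(back$I_max, fb$trainset$I_max)
  unlink(c(f, paste0(f, ".json")))
})

test_that("an entrained subject under feedback control stays entrained", {
  fb <- fx_feedback()
  cyc <- fx_cyc3()
  y0 <- reference_state(0, 1, cyc)
  r <- simulate_feedback(y0, 1, cyc, fb$controller, horizon_cap = 48)
  expect_equal(r$t_f, 0, tolerance = 1e-6)
})
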