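test_that("scenario clock bookkeeping reproduces the printed initial states", {
  cyc <- fx_cyc3()
  # a traveler leaving at 10 am home time sits at Y_REF(4)
  s <- reference_state(4 - 3, 3, cyc)      # delta_init + t adds up to 4
  expect_equal(unname(s$y["x"]), 0.0815, tolerance = 0.08)
  expect_equal(unname(s$y["H"]), 0.1984, tolerance = 0.03)
  # shift work: t = 0 is 8 am, y_ref(t) = Y_REF(t + 2)
  sw <- scenario_spec("shiftwork", I_shift = 0, strategy = "open-loop")
  expect_equal(sw$delta_init, 2)
  y <- reference_state(-12, 2, cyc)        # 8 pm the previous evening
  expect_equal(unname(y$y["H"]),
               unname(reference_state(14, 0, cyc)$y["H"]), tolerance = 1e-9)
})

test_that("jet-lag with zero shift is a no-op for every cheap strategy", {
  cyc <- fx_cyc3()
  for (strat in c("open-loop", "min-time-spontaneous")) {
    sp <- scenario_spec("jetlag", delta_shift = 0, I_max = 1000,
                        strategy = strat)
    r <- run_jetlag(sp, cycle = cyc)
    expect_equal(r$t_f, 0, tolerance = 1e-6)
  }
})

test_that("scenario runs are deterministic", {
  cyc <- fx_cyc3()
  sp <- scenario_spec("shiftwork", I_shift = 100, strategy = "open-loop")
  r1 <- run_shiftwork(sp, cycle = cyc)
  r2 <- run_shiftwork(sp, cycle = cyc)
  expect_identical(r1$t_f, r2$t_f)
})

test_that("export writes a consistent trajectory, schedule and summary", {
  cyc <- fx_cyc3()
  st <- reference_state(6, 0, cyc)
  ls <- light_signal(c(0, 16, 24, 40, 48), c(1000, 0, 1000, 0), 1000)
  tr <- integrate_hybrid(st, ls, "spontaneous", c(0, 48), thin = 10L)
  report <- list(t_f = NA_real_, detail = tr,
                 spec = scenario_spec("jetlag", delta_shift = 6))
  class(report) <- "scenario_report"
  dir <- tempfile()
  paths <- export_report(report, dir)
  expect_true(all(file.exists(file.path(dir, c("trajectory.csv",
                                               "schedule.csv",
                                               "summary.json")))))
  df <- read.csv(file.path(dir, "trajectory.csv"))
  # sleepiness column must equal H - A_c x recomputed from the same rows
  p <- two_process_params()
  expect_equal(df$B, df$H - p$A_c * df$x, tolerance = 1e-9)
  # beta reproduces the automaton state: changes only at exported events
  sch <- read.csv(file.path(dir, "schedule.csv"))
  expect_true(all(sch$trigger %in% c("spontaneous", "scheduled", "forced",
                                     "immediate")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_identical(js$kind, "scenario_summary")
  expect_identical(js$strategy, "open-loop")
  unlink(dir, recursive = TRUE)
})

test_that("empty trajectories export a header-only CSV", {
  report <- list(t_f = 0, detail = NULL,
                 spec = scenario_spec("jetlag", delta_shift = 0))
  class(report) <- "scenario_report"
  dir <- tempfile()
  export_report(report, dir)
  df <- read.csv(file.path(dir, "trajectory.csv"))
  expect_identical(nrow(df), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("optimization results serialize to JSON and CSV", {
  opt <- fx_shift_ctrl_10000()$detail
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_optim_result(opt, jf, cf)
  js <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(js$t_f, opt$t_f, tolerance = 1e-9)
  expect_identical(js$kind, "entrain_optim")
  sch <- read.csv(cf)
  expect_identical(names(sch), c("time_start_h", "time_end_h", "lux"))
  expect_equal(nrow(sch), length(opt$light$levels))
  unlink(c(jf, cf))
})
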