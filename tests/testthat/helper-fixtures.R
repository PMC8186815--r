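# Shared fixtures, computed lazily once per test session.  Reference
# cycles and the PRC are cached inside the package; heavier optimizer
# results are memoized here so several test files (and the acceptance
# criteria) can share them.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

fx_cyc3 <- function() fx("cyc3", function() compute_entrained_cycle("S+C3"))
fx_cyc2 <- function() fx("cyc2", function() compute_entrained_cycle("S+C2"))
fx_prc <- function() fx("prc", function() estimate_prc())
fx_cyc1 <- function() fx("cyc1", function()
  compute_entrained_cycle("S+C1", prc = fx_prc()))
fx_cycC <- function() fx("cycC", function() compute_entrained_cycle("C-only"))
fx_spec3 <- function() terminal_spec("S+C3")

# open-loop shift-work recoveries (cheap; used by unit and acceptance tests)
fx_shift_openloop <- function() fx("shift_openloop", function() {
  grid <- list(c(20, 0), c(20, 100), c(20, 1000), c(22, 0))
  out <- lapply(grid, function(g) {
    sp <- scenario_spec("shiftwork", shift_start = g[1], shift_end = 8,
                        I_shift = g[2], strategy = "open-loop")
    run_shiftwork(sp, cycle = fx_cyc3())
  })
  names(out) <- c("s20_0", "s20_100", "s20_1000", "s22_0")
  out
})

# optimized shift-work cases
fx_shift_optlight <- function(I_max) fx(paste0("shift_optlight_", I_max),
  function() {
    sp <- scenario_spec("shiftwork", I_max = I_max,
                        strategy = "min-time-with-shift-light")
    suppressWarnings(run_shiftwork(sp, cycle = fx_cyc3()))
  })

fx_shift_ctrl_10000 <- function() fx("shift_ctrl_10000", function() {
  sp <- scenario_spec("shiftwork", I_shift = 1000, I_max = 10000,
                      strategy = "min-time-controllable")
  suppressWarnings(run_shiftwork(sp, cycle = fx_cyc3()))
})

# long jet-lag case (16-h shift, 1000 lux)
fx_jet16_spont <- function() fx("jet16_spont", function() {
  y0 <- reference_state(16, 1, fx_cyc3())
  suppressWarnings(minimize_time_spontaneous(y0, 1, fx_cyc3(), 1000,
                                             spec = fx_spec3()))
})

fx_jet16_ctrl <- function() fx("jet16_ctrl", function() {
  y0 <- reference_state(16, 1, fx_cyc3())
  suppressWarnings(minimize_time_controllable(y0, 1, fx_cyc3(), 1000,
                                              spec = fx_spec3()))
})

# six-shift sweep at 10000 lux: open-loop / spontaneous / controllable
fx_sweep <- function() fx("sweep", function() {
  shifts <- c(8, 10, 12, 14, 16, 18)
  out <- lapply(shifts, function(ds) {
    y0 <- reference_state(ds, 1, fx_cyc3())
    list(ds = ds,
         open = open_loop_entrain(y0, 1, fx_cyc3(), fx_spec3())$t_f,
         spont = suppressWarnings(
           minimize_time_spontaneous(y0, 1, fx_cyc3(), 10000,
                                     spec = fx_spec3())),
         ctrl = suppressWarnings(
           minimize_time_controllable(y0, 1, fx_cyc3(), 10000,
                                      spec = fx_spec3())))
  })
  names(out) <- paste0("d", shifts)
  out
})

# small feedback training set reusing sweep results
fx_feedback <- function() fx("feedback", function() {
  sw <- fx_sweep()
  cases <- c(8, 12, 16)
  res <- setNames(lapply(cases, function(d) sw[[paste0("d", d)]]$ctrl),
                  as.character(cases))
  ts <- build_training_set(10000, cases = cases, cycle = fx_cyc3(),
                           results = res)
  list(trainset = ts, controller = fit_feedback_controller(ts),
       results = res)
})
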