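# The adjoint gradient is the optimizer's correctness gate: it must agree
# with central finite differences of the simulated terminal residual.

fd_gradient <- function(prob, tf, breaks, w, schedule = NULL, h = 1e-5) {
  sapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    (circentrain:::phi_problem(prob, tf, breaks, wp, schedule) -
       circentrain:::phi_problem(prob, tf, breaks, wm, schedule)) / (2 * h)
  })
}

test_that("light-bin gradients match finite differences through sleep switches", {
  cyc <- fx_cyc3()
  spec <- fx_spec3()
  y0 <- reference_state(8, 1, cyc)
  tf <- 24; bins_h <- 1
  set.seed(11)
  breaks <- circentrain:::bin_breaks(0, tf, bins_h)
  w <- runif(length(breaks) - 1, 0.2, 0.8)
  g <- adjoint_gradient(y0, 1, cyc, spec, tf, w, bins_h = bins_h,
                        I_max = 10000)
  prob <- circentrain:::entrain_problem(y0, 1, cyc, spec,
                                        two_process_params(), 10000)
  fd <- fd_gradient(prob, tf, breaks, w)
  big <- abs(fd) > 1e-5
  expect_gt(sum(big), 5)
  expect_lt(max(abs(g$grad_w[big] - fd[big]) / abs(fd[big])), 0.01)
  # the trajectory contains a spontaneous sleep episode whose bins have
  # exactly zero light sensitivity
  expect_true(any(g$grad_w == 0 & abs(fd) < 1e-10))
  expect_identical(g$jumps_skipped, 0L)
})

test_that("scheduled switch-time gradients match finite differences", {
  cyc <- fx_cyc3()
  spec <- fx_spec3()
  y0 <- reference_state(8, 1, cyc)
  tf <- 24
  set.seed(12)
  breaks <- circentrain:::bin_breaks(0, tf, 1)
  w <- runif(length(breaks) - 1, 0.2, 0.8)
  sch <- sleep_schedule(T_sleep = 10.3, T_wake = 17.8)
  g <- adjoint_gradient(y0, 1, cyc, spec, tf, w, bins_h = 1,
                        schedule = sch, I_max = 10000)
  prob <- circentrain:::entrain_problem(y0, 1, cyc, spec,
                                        two_process_params(), 10000)
  h <- 1e-6
  mk <- function(tt) structure(list(T_sleep = tt[sch$beta == 1],
                                    T_wake = tt[sch$beta == 0],
                                    times = tt, beta = sch$beta),
                               class = "sleep_schedule")
  for (i in 1:2) {
    tp <- sch$times; tp[i] <- tp[i] + h
    tm <- sch$times; tm[i] <- tm[i] - h
    fdT <- (circentrain:::phi_problem(prob, tf, breaks, w, mk(tp)) -
              circentrain:::phi_problem(prob, tf, breaks, w, mk(tm))) / (2 * h)
    expect_lt(abs(g$grad_T[i] - fdT) / max(abs(fdT), 1e-8), 0.01)
  }
})

test_that("gradients for the reduced phase model match finite differences", {
  prc <- fx_prc()
  cyc1 <- fx_cyc1()
  spec1 <- terminal_spec("S+C1")
  y0 <- reference_state(6, 1, cyc1)
  tf <- 18
  set.seed(13)
  breaks <- circentrain:::bin_breaks(0, tf, 1)
  w <- runif(length(breaks) - 1, 0.2, 0.8)
  g <- adjoint_gradient(y0, 1, cyc1, spec1, tf, w, bins_h = 1,
                        I_max = 10000, prc = prc)
  prob <- circentrain:::entrain_problem(y0, 1, cyc1, spec1,
                                        two_process_params(), 10000,
                                        prc = prc)
  fd <- fd_gradient(prob, tf, breaks, w)
  big <- abs(fd) > 1e-5
  expect_gt(sum(big), 3)
  expect_lt(max(abs(g$grad_w[big] - fd[big]) / abs(fd[big])), 0.02)
})

test_that("a zero-length horizon yields an all-zero gradient", {
  cyc <- fx_cyc3()
  spec <- fx_spec3()
  y0 <- reference_state(5, 1, cyc)
  g <- adjoint_gradient(y0, 1, cyc, spec, tf = 1e-4, w = 0.5,
                        bins_h = 0.1, I_max = 1000)
  expect_lt(max(abs(g$grad_w)), 1e-4)   # integral over a 1e-4 h window
})
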