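test_that("terminal residual equals an independent recomputation", {
  cyc <- fx_cyc3()
  spec <- fx_spec3()
  set.seed(21)
  for (k in 1:10) {
    y <- c(n = runif(1), x = runif(1, -1, 1), xc = runif(1, -1.3, 1.3),
           H = runif(1))
    st <- two_process_state("S+C3", y)
    t <- runif(1, 0, 48)
    di <- sample(0:23, 1)
    r <- terminal_residual(st, t, di, cyc, spec)
    # from-scratch recomputation of the squared-norm condition
    tm <- (t + di) %% 24
    zr <- sapply(c("x", "xc", "H"), function(nm)
      approx(cyc$grid, cyc$Y[, nm], xout = tm)$y)
    expect_equal(r, sum((y[c("x", "xc", "H")] - zr)^2) - spec$tol,
                 tolerance = 1e-12)
  }
})

test_that("the reference state itself sits at residual -tol", {
  cyc <- fx_cyc3()
  spec <- fx_spec3()
  st <- reference_state(7.3, 2, cyc)
  expect_equal(terminal_residual(st, 7.3, 2, cyc, spec), -spec$tol,
               tolerance = 1e-8)
})

test_that("phase wrapping makes theta and theta + 2 pi equivalent", {
  cyc1 <- fx_cyc1()
  spec1 <- terminal_spec("S+C1")
  st <- reference_state(3, 0, cyc1)
  st2 <- st
  st2$y["theta"] <- st$y["theta"] + 2 * pi   # wrapped by the constructor
  r1 <- terminal_residual(st, 3, 0, cyc1, spec1)
  r2 <- terminal_residual(st2, 3, 0, cyc1, spec1)
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(r1, -spec1$tol, tolerance = 1e-8)
})

test_that("open-loop entrainment of an already entrained subject is immediate", {
  cyc <- fx_cyc3()
  st <- reference_state(0, 1, cyc)
  r <- open_loop_entrain(st, 1, cyc, fx_spec3())
  expect_equal(r$t_f, 0, tolerance = 1e-6)
})

test_that("open-loop shift-work recovery matches the published times", {
  ol <- fx_shift_openloop()
  expect_equal(ol$s20_0$t_f, 3.46, tolerance = 0.05)
  expect_equal(ol$s20_100$t_f, 6.29, tolerance = 0.05)
  expect_equal(ol$s20_1000$t_f, 18.32, tolerance = 0.05)
  expect_equal(ol$s22_0$t_f, 44.06, tolerance = 0.05)
})
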