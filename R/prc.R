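#' Estimate the phase response curve of the circadian oscillator
#'
#' Applies the classical pulse protocol to the second-order core body
#' temperature oscillator: for each phase on a uniform grid, start on the
#' free-running limit cycle at that phase, apply a 30-minute drive pulse of
#' `u = 0.1731` (the steady drive at 1000 lux), let the oscillator relax
#' for several free-running periods, and measure the asymptotic phase shift
#' against the unperturbed trajectory from the timing of upward zero
#' crossings of `x`.  The tabulated value is normalized per unit drive and
#' per hour, so the phase model `dtheta/dt = omega0 + f(theta) u`
#' reproduces the calibration pulse by construction.
#'
#' @param params a [two_process_params()] object.
#' @param n_theta number of phase grid points.
#' @param pulse_u drive intensity of the calibration pulse.
#' @param pulse_len pulse duration (h).
#' @param settle_periods free-running periods waited after the pulse before
#'   the phase difference is read off.
#' @param dt integration step (h).
#' @return An object of class `prc_table` with fields `theta` (rad, in
#'   `[0, 2*pi)`), `f` (rad per unit drive per hour) and the free-running
#'   period.
#' @export
estimate_prc <- function(params = two_process_params(), n_theta = 256,
                         pulse_u = NULL, pulse_len = 0.5,
                         settle_periods = 10, dt = 0.005) {
  if (is.null(pulse_u))
    pulse_u <- unname(steady_state_drive(1000, params)["u_ss"])
  key <- paste0("prc|", n_theta, "|", pulse_u, "|", pulse_len, "|",
                settle_periods, "|", dt, "|",
                paste(format(unlist(params), digits = 15), collapse = ","))
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)

  pv <- pars_vec(params)
  sim2 <- function(y0, cb, clev, t0, t1, thin = 1L) {
    sim_hybrid_cpp(2L, y0, 0L, cb, clev, 2L, numeric(0), integer(0),
                   t0, t1, dt, -Inf, pv, numeric(0), as.integer(thin))
  }
  # settle onto the free-running orbit of the (x, xc) subsystem
  r <- sim2(c(1, 0, 0.5), c(0, 400), 0, 0, 400, thin = 1L)
  # free-running period from upward zero crossings of x over the tail
  per <- free_period_from(r$t, r$Y[, 1], t_min = 150)
  T0 <- per$period
  # one dense settled period, phase-parametrized
  i0 <- max(which(r$t <= per$last_cross - T0))
  seg <- seq(i0, length(r$t))
  seg_t <- r$t[seg]; seg_x <- r$Y[seg, 1]; seg_xc <- r$Y[seg, 2]
  seg_th <- phase_of(seg_x, seg_xc)
  # unwrap the phase along the segment so it is monotone
  seg_un <- seg_th + 2 * pi * cumsum(c(0, diff(seg_th) < -pi))
  theta_grid <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  th0 <- seg_un[1]
  f <- numeric(n_theta)
  horizon <- pulse_len + settle_periods * T0
  omega_free <- 2 * pi / T0
  for (i in seq_len(n_theta)) {
    target <- th0 + ((theta_grid[i] - th0) %% (2 * pi))
    x0 <- approx(seg_un, seg_x, xout = target)$y
    xc0 <- approx(seg_un, seg_xc, xout = target)$y
    y0 <- c(x0, xc0, 0.5)
    rp <- sim2(y0, c(0, pulse_len, horizon), c(pulse_u, 0), 0, horizon,
               thin = 4L)
    rf <- sim2(y0, c(0, horizon), 0, 0, horizon, thin = 4L)
    tp <- last_up_cross(rp$t, rp$Y[, 1], t_min = horizon - 3.5 * T0)
    tf_ <- last_up_cross(rf$t, rf$Y[, 1], t_min = horizon - 3.5 * T0)
    dphi <- wrap_pi(omega_free * (tf_ - tp))
    f[i] <- dphi / (pulse_u * pulse_len)
  }
  prc <- structure(list(theta = theta_grid, f = f, period = T0,
                        pulse_u = pulse_u, pulse_len = pulse_len),
                   class = "prc_table")
  cache_set(key, prc)
  prc
}

# mean interval between upward zero crossings of x after t_min
free_period_from <- function(t, x, t_min = 0) {
  idx <- which(t >= t_min)
  tt <- t[idx]; xx <- x[idx]
  up <- which(xx[-length(xx)] < 0 & xx[-1] >= 0)
  if (length(up) < 3) stop("not enough oscillation cycles to measure a period")
  tc <- tt[up] - xx[up] * (tt[up + 1] - tt[up]) / (xx[up + 1] - xx[up])
  list(period = mean(diff(tc)), last_cross = tc[length(tc)],
       crossings = tc)
}

last_up_cross <- function(t, x, t_min = 0) {
  p <- free_period_from(t, x, t_min = t_min)
  p$last_cross
}

#' Evaluate a phase response curve
#'
#' Periodic cubic-spline interpolation of the tabulated PRC.
#'
#' @param prc a `prc_table`.
#' @param theta phases (rad).
#' @return `f(theta)` in rad per unit drive per hour.
#' @export
prc_eval <- function(prc, theta) {
  prc_spline(prc)(wrap_2pi(theta))
}

prc_spline <- function(prc) {
  if (is.null(prc$.spline)) {
    th <- c(prc$theta, 2 * pi)
    ff <- c(prc$f, prc$f[1])
    sf <- splinefun(th, ff, method = "periodic")
    # memoize on the object in the caller is awkward for a plain list;
    # recreating the splinefun is cheap relative to any simulation.
    sf
  } else {
    prc$.spline
  }
}

# dense uniform table for the compiled engine (piecewise-linear lookup)
prc_dense <- function(prc, variant, n_dense = 4096) {
  if (variant != "S+C1") return(numeric(0))
  if (is.null(prc)) stop("the phase-reduced variant needs a PRC table")
  prc_spline(prc)(seq(0, 2 * pi, length.out = n_dense + 1)[-(n_dense + 1)])
}

#' @export
print.prc_table <- function(x, ...) {
  cat(sprintf(paste0("<phase response curve: %d phases, free-running ",
                     "period %.3f h, range [%.3f, %.3f]>\n"),
              length(x$theta), x$period, min(x$f), max(x$f)))
  invisible(x)
}

#' Write / read a PRC table as JSON
#' @param prc a `prc_table`.
#' @param path file path.
#' @export
write_prc_table <- function(prc, path) {
  obj <- list(kind = "prc_table", theta = prc$theta, f = prc$f,
              period = prc$period, pulse_u = prc$pulse_u,
              pulse_len = prc$pulse_len)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prc_table
#' @export
read_prc_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "prc_table")) stop("not a serialized PRC table")
  structure(obj[c("theta", "f", "period", "pulse_u", "pulse_len")],
            class = "prc_table")
}
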