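#' Reference 24-hour light pattern
#'
#' The square zeitgeber approximating the natural light-dark cycle:
#' 1000 lux for the first 16 h of each day and darkness for the last 8 h,
#' with `t = 0` anchored to 6 am.  For the reduced variants the same
#' pattern is expressed directly as a circadian drive of `u = 0.1731`
#' (the steady-state drive at 1000 lux).  The circadian-only model uses
#' the effective 14.5-9.5 h cycle a spontaneously sleeping subject actually
#' receives (light from 7:30 am, when the reference subject wakes, to 10 pm).
#'
#' @param t times (h).
#' @param variant model variant.
#' @param params a [two_process_params()] object.
#' @return Lux values for `"S+C3"`/`"C-only"`; drive values `u` otherwise.
#' @export
reference_light <- function(t, variant = "S+C3",
                            params = two_process_params()) {
  tm <- t %% 24
  if (variant == "C-only") {
    ifelse(tm >= 1.5 & tm < 16, 1000, 0)
  } else if (variant == "S+C3") {
    ifelse(tm < 16, 1000, 0)
  } else {
    u1000 <- unname(steady_state_drive(1000, params)["u_ss"])
    ifelse(tm < 16, u1000, 0)
  }
}

# reference zeitgeber as a light_signal in lux over [t0, t1]
reference_light_signal <- function(t0, t1, variant = "S+C3",
                                   delta_init = 0,
                                   params = two_process_params()) {
  # breakpoints wherever (t + delta_init) mod 24 crosses 0, 1.5 or 16
  marks <- if (variant == "C-only") c(0, 1.5, 16) else c(0, 16)
  k <- floor((t0 + delta_init) / 24):ceiling((t1 + delta_init) / 24)
  bp <- sort(unique(c(t0, t1,
                      as.vector(outer(24 * k, marks, "+")) - delta_init)))
  bp <- bp[bp >= t0 - 1e-9 & bp <= t1 + 1e-9]
  bp[1] <- t0; bp[length(bp)] <- t1
  mid <- head(bp, -1) + diff(bp) / 2
  lev <- ifelse(reference_light(mid + delta_init,
                                if (variant == "C-only") "C-only" else "S+C3",
                                params) > 0, 1000, 0)
  light_signal(bp, lev, I_max = 1000)
}

#' Circadian phase from the oscillator states
#'
#' `theta = arctan(-xc / x)`, shifted by `pi` when `x < 0` and wrapped to
#' `[0, 2*pi)` — i.e. the two-argument arctangent of `(-xc, x)`.
#'
#' @param x,xc oscillator states; `(0, 0)` has no defined phase.
#' @return Phase in rad, in `[0, 2*pi)`.
#' @examples
#' phase_of(1, 0)    # 0
#' phase_of(-1, 0)   # pi
#' @export
phase_of <- function(x, xc) {
  if (any(x == 0 & xc == 0))
    stop("phase is undefined at the origin (x = xc = 0)")
  wrap_2pi(atan2(-xc, x))
}

#' Entrained 24-hour reference limit cycle
#'
#' Simulates the chosen variant under the reference zeitgeber (with the
#' spontaneous sleep automaton, except for the circadian-only model) from a
#' fixed interior initial condition until the state sampled at 24-h
#' intervals changes by less than `conv_tol` in max-norm, then stores one
#' dense period on a 0.01-h grid.  The cycle is anchored to clock time:
#' grid time 0 corresponds to 6 am.
#'
#' @param variant model variant.
#' @param params a [two_process_params()] object.
#' @param dt integration step (h).
#' @param conv_tol convergence tolerance on the 24-h return map.
#' @param max_days cap on the number of simulated days.
#' @param prc a `prc_table` (required for `"S+C1"`).
#' @param grid_by resolution of the stored cycle grid (h).
#' @return An object of class `reference_cycle`: `grid` (times in
#'   `[0, 24]`), `Y` (state samples; the row at 24 equals the row at 0 to
#'   within the periodicity tolerance), `beta`, the spontaneous sleep-onset
#'   and wake clock times, and the convergence diagnostics.
#' @export
compute_entrained_cycle <- function(variant = c("S+C3", "S+C2", "S+C1",
                                                "C-only"),
                                    params = two_process_params(),
                                    dt = 0.005, conv_tol = 1e-8,
                                    max_days = 200, prc = NULL,
                                    grid_by = 0.01) {
  variant <- match.arg(variant)
  if (variant == "S+C1" && is.null(prc))
    stop("the phase-reduced variant needs a PRC table")
  key <- cycle_cache_key(variant, params, dt, conv_tol, grid_by)
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)

  y0 <- switch(variant,
               "S+C3" = c(n = 0.5, x = 1, xc = 0, H = 0.5),
               "S+C2" = c(x = 1, xc = 0, H = 0.5),
               "S+C1" = c(theta = 0, H = 0.5),
               "C-only" = c(n = 0.5, x = 1, xc = 0))
  state <- two_process_state(variant, y0, beta = 0)
  policy <- if (variant == "C-only") "forced-awake" else "spontaneous"
  light1d <- reference_light_signal(0, 24, variant, 0, params)

  prev <- unname(state$y)
  resid <- Inf
  day <- 0
  while (day < max_days) {
    traj <- integrate_hybrid(state, light1d, policy, c(0, 24), params,
                             dt = dt, prc = prc, thin = 1000L)
    state <- final_state(traj)
    cur <- unname(state$y)
    dcur <- cur - prev
    if (variant == "S+C1") dcur[1] <- wrap_pi(dcur[1])
    resid <- max(abs(dcur))
    prev <- cur
    day <- day + 1
    if (resid < conv_tol) break
  }
  if (resid >= conv_tol)
    stop(sprintf(paste0("limit-cycle search did not converge in %d days ",
                        "(24-h return-map residual %.3g)"), max_days, resid))

  # one dense period, resampled onto the uniform grid
  traj <- integrate_hybrid(state, light1d, policy, c(0, 24), params,
                           dt = dt, prc = prc, thin = 1L)
  grid <- seq(0, 24, by = grid_by)
  nms <- variant_state_names(variant)
  Y <- sapply(nms, function(nm)
    approx(traj$times, traj$states[, nm], xout = grid)$y)
  colnames(Y) <- nms
  beta <- approx(traj$times, traj$beta, xout = grid,
                 method = "constant", f = 0)$y
  ev <- traj$switch_events
  sleep_onset <- ev$time[ev$beta_new == 1]
  wake_time <- ev$time[ev$beta_new == 0]
  cyc <- structure(list(variant = variant, grid = grid, Y = Y,
                        beta = as.integer(beta),
                        sleep_onset = sleep_onset, wake_time = wake_time,
                        days_to_converge = day, residual = resid,
                        params = params, dt = dt, grid_by = grid_by),
                   class = "reference_cycle")
  cache_set(key, cyc)
  cyc
}

#' @export
print.reference_cycle <- function(x, ...) {
  cat(sprintf("<entrained %s reference cycle>\n", x$variant))
  cat(sprintf("  converged in %d days (return-map residual %.2g)\n",
              x$days_to_converge, x$residual))
  if (length(x$sleep_onset))
    cat(sprintf("  spontaneous sleep %s, wake %s (clock time, 0 = 6 am)\n",
                clock_str(x$sleep_onset[1]), clock_str(x$wake_time[1])))
  invisible(x)
}

clock_str <- function(t) {
  h <- (t + 6) %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60))
}

#' Reference state at a shifted time
#'
#' Returns the entrained reference trajectory evaluated at
#' `(t + delta_init) mod 24`, i.e. the state of a reference subject whose
#' 6 am anchor is offset by `delta_init` hours from the entrainment clock.
#'
#' @param t time (h), scalar or vector.
#' @param delta_init offset between the entrainment start and 6 am (h).
#' @param cycle a [compute_entrained_cycle()] result.
#' @return For scalar `t`, a [two_process_state()]; for vector `t`, a
#'   matrix of states with a `beta` attribute.
#' @export
reference_state <- function(t, delta_init, cycle) {
  tm <- (t + delta_init) %% 24
  Y <- sapply(colnames(cycle$Y), function(nm)
    approx(cycle$grid, cycle$Y[, nm], xout = tm)$y)
  beta <- approx(cycle$grid, cycle$beta, xout = tm,
                 method = "constant", f = 0)$y
  if (length(t) == 1L) {
    return(two_process_state(cycle$variant, Y, as.integer(beta)))
  }
  Y <- matrix(Y, nrow = length(t),
              dimnames = list(NULL, colnames(cycle$Y)))
  attr(Y, "beta") <- as.integer(beta)
  Y
}

#' Reference circadian phase
#'
#' The phase of the entrained reference oscillator at the shifted time,
#' computed from the reference `(x, xc)` by [phase_of()].
#'
#' @inheritParams reference_state
#' @return Phase in rad.
#' @export
reference_phase <- function(cycle, t, delta_init = 0) {
  if (!all(c("x", "xc") %in% colnames(cycle$Y)))
    stop("reference phase needs a cycle with (x, xc) states")
  tm <- (t + delta_init) %% 24
  x <- approx(cycle$grid, cycle$Y[, "x"], xout = tm)$y
  xc <- approx(cycle$grid, cycle$Y[, "xc"], xout = tm)$y
  phase_of(x, xc)
}

# comparison vector for the terminal condition at reference time tm
reference_terminal_vec <- function(cycle, tm) {
  tm <- tm %% 24
  if (cycle$variant == "S+C1") {
    c(approx(cycle$grid, cycle$Y[, "theta"], xout = tm)$y,
      approx(cycle$grid, cycle$Y[, "H"], xout = tm)$y)
  } else if (cycle$variant == "C-only") {
    c(approx(cycle$grid, cycle$Y[, "x"], xout = tm)$y,
      approx(cycle$grid, cycle$Y[, "xc"], xout = tm)$y)
  } else {
    c(approx(cycle$grid, cycle$Y[, "x"], xout = tm)$y,
      approx(cycle$grid, cycle$Y[, "xc"], xout = tm)$y,
      approx(cycle$grid, cycle$Y[, "H"], xout = tm)$y)
  }
}

# -- serialization -----------------------------------------------------------

#' Write / read a reference cycle as JSON
#'
#' The on-disk representation stores the dense grid, the state samples, the
#' sleep state, the spontaneous switch times and the generating parameters,
#' so a cycle can be rebuilt without re-running the limit-cycle search.
#'
#' @param cycle a `reference_cycle`.
#' @param path file path.
#' @return `write_reference_cycle` returns `path` invisibly;
#'   `read_reference_cycle` returns the `reference_cycle`.
#' @export
write_reference_cycle <- function(cycle, path) {
  obj <- list(kind = "reference_cycle", variant = cycle$variant,
              grid = cycle$grid, Y = as.data.frame(cycle$Y),
              beta = cycle$beta, sleep_onset = cycle$sleep_onset,
              wake_time = cycle$wake_time,
              days_to_converge = cycle$days_to_converge,
              residual = cycle$residual,
              params = unclass(cycle$params), dt = cycle$dt,
              grid_by = cycle$grid_by)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_cycle
#' @export
read_reference_cycle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "reference_cycle"))
    stop("not a serialized reference cycle")
  Y <- as.matrix(obj$Y)
  dimnames(Y) <- list(NULL, colnames(Y))
  structure(list(variant = obj$variant, grid = obj$grid,
                 Y = Y, beta = as.integer(obj$beta),
                 sleep_onset = obj$sleep_onset, wake_time = obj$wake_time,
                 days_to_converge = obj$days_to_converge,
                 residual = obj$residual,
                 params = do.call(two_process_params, as.list(obj$params)),
                 dt = obj$dt, grid_by = obj$grid_by),
            class = "reference_cycle")
}

# -- in-memory cache ---------------------------------------------------------
.circ_cache <- new.env(parent = emptyenv())

cycle_cache_key <- function(variant, params, dt, conv_tol, grid_by) {
  paste0("cycle|", variant, "|",
         paste(format(unlist(params), digits = 15), collapse = ","),
         "|", dt, "|", conv_tol, "|", grid_by)
}

cache_get <- function(key) {
  if (exists(key, envir = .circ_cache, inherits = FALSE))
    get(key, envir = .circ_cache) else NULL
}

cache_set <- function(key, value) assign(key, value, envir = .circ_cache)
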