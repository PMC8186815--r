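#' Apply a reduced-model optimal solution to the full model
#'
#' Maps the bang-off drive schedule optimized for a reduced variant onto
#' the full model via `I(t) = I_max * u(t) / u_max`, and follows the
#' reduced sleep schedule gated by sleepiness guards: the subject may only
#' wake when `B <= B2_max` and only fall asleep when `B >= H_m`, and is
#' force-woken at `B <= L_m` and force-slept at `B >= B1_max`.  If the
#' terminal condition is not met when the reduced schedule runs out, the
#' destination reference light with spontaneous sleep continues as the
#' supplement strategy.
#'
#' @param reduced_result an `entrain_optim` from a reduced variant
#'   (`"S+C1"` or `"S+C2"`).
#' @param state0 initial full-model (`"S+C3"`) [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle full-model reference cycle.
#' @param I_max light bound for the transferred schedule (lux).
#' @param spec a [terminal_spec()] for `"S+C3"`.
#' @param params a [two_process_params()] object.
#' @param dt integration step of the transfer policy loop (h); sleep
#'   decisions are re-evaluated at this granularity.
#' @param horizon_cap cap on the supplement phase (h).
#' @return List with `t_f`, `light` (the transferred [light_signal()]),
#'   `supplement_used`, and the final state.
#' @export
transfer_reduced_solution <- function(reduced_result, state0, delta_init,
                                      cycle, I_max,
                                      spec = terminal_spec("S+C3"),
                                      params = two_process_params(),
                                      dt = 0.01, horizon_cap = 1000) {
  stopifnot(inherits(reduced_result, "entrain_optim"),
            reduced_result$variant %in% c("S+C1", "S+C2"),
            state0$variant == "S+C3")
  if (is.null(reduced_result$w))
    return(within_openloop_transfer(state0, delta_init, cycle, spec, params,
                                    horizon_cap))
  breaks <- reduced_result$breaks
  # u/u_max is exactly the normalized bin level, so the transferred light
  # is I_max on bins where the reduced drive was on
  lux <- I_max * reduced_result$w
  light <- light_signal(breaks, lux, I_max = I_max)
  # reduced sleep pattern as a right-continuous step function of time
  red_sched <- reduced_result$realized_switches
  beta_red_at <- function(t) {
    if (!length(red_sched$times)) return(0L)
    i <- findInterval(t, red_sched$times)
    if (i == 0) 0L else red_sched$beta[i]
  }
  t_end <- breaks[length(breaks)]
  pv <- pars_vec(params)
  y <- unname(state0$y)
  beta <- state0$beta
  t <- 0
  nmax <- ceiling(t_end / dt) + 2L
  times <- numeric(nmax); betas <- integer(nmax)
  Ys <- matrix(NA_real_, nmax, 4)
  kk <- 1L; times[1] <- t; betas[1] <- beta; Ys[1, ] <- y
  while (t < t_end - 1e-9) {
    B <- y[4] - params$A_c * y[2]
    bred <- beta_red_at(t)
    new_beta <- beta
    if (B <= params$L_m) new_beta <- 0L
    else if (B >= params$B1_max) new_beta <- 1L
    else if (bred == 0 && B <= params$B2_max) new_beta <- 0L
    else if (bred == 1 && B >= params$H_m) new_beta <- 1L
    beta <- new_beta
    t1 <- min(t + dt, t_end)
    lv <- light_at(light, t + 1e-9)
    r <- sim_hybrid_cpp(3L, y, beta, c(t, t1),
                        lux_to_alpha(lv, params), 2L, numeric(0),
                        integer(0), t, t1, min(dt, 0.005), -Inf, pv,
                        numeric(0), 100000L)
    y <- unname(r$Y[nrow(r$Y), ])
    t <- t1
    kk <- kk + 1L
    times[kk] <- t; betas[kk] <- beta; Ys[kk, ] <- y
  }
  times <- times[1:kk]; betas <- betas[1:kk]; Ys <- Ys[1:kk, , drop = FALSE]
  colnames(Ys) <- variant_state_names("S+C3")
  resid <- residual_series(times, Ys, "S+C3", delta_init, cycle, spec)
  cross <- first_crossing(times, resid)
  if (!is.na(cross)) {
    return(list(t_f = cross, light = light, supplement_used = FALSE,
                state = two_process_state("S+C3", y, beta)))
  }
  sup <- open_loop_entrain(two_process_state("S+C3", y, beta), delta_init,
                           cycle, spec, params, t0 = t_end,
                           horizon_cap = horizon_cap)
  list(t_f = sup$t_f, light = light, supplement_used = TRUE,
       state = sup$state)
}

within_openloop_transfer <- function(state0, delta_init, cycle, spec,
                                     params, horizon_cap) {
  sup <- open_loop_entrain(state0, delta_init, cycle, spec, params,
                           horizon_cap = horizon_cap)
  list(t_f = sup$t_f, light = NULL, supplement_used = TRUE,
       state = sup$state)
}

#' Entrainment under a fixed light with the tuned sleep rule
#'
#' Simulates the full model under a prescribed light schedule with the
#' sleep rule of [tuned_sleep_rule()] (awake whenever the prescribed light
#' is on or B has drained to `L_m`; asleep when the light is off and B has
#' reached `H_m`), then continues with the reference light and spontaneous
#' sleep if the schedule ends before entrainment.
#'
#' @param light a [light_signal()] (the circadian-only optimal light).
#' @param state0 initial `"S+C3"` [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle full-model reference cycle.
#' @param spec a [terminal_spec()] for `"S+C3"`.
#' @param params a [two_process_params()] object.
#' @param dt decision granularity of the rule (h).
#' @param horizon_cap cap on the supplement phase (h).
#' @return List with `t_f`, `supplement_used`, trajectory summaries and
#'   the final state.
#' @export
entrain_with_tuned_sleep <- function(light, state0, delta_init, cycle,
                                     spec = terminal_spec("S+C3"),
                                     params = two_process_params(),
                                     dt = 0.01, horizon_cap = 1000) {
  stopifnot(state0$variant == "S+C3")
  t_end <- light$breakpoints[length(light$breakpoints)]
  pv <- pars_vec(params)
  y <- unname(state0$y)
  beta <- state0$beta
  t <- 0
  nmax <- ceiling(t_end / dt) + 2L
  times <- numeric(nmax); betas <- integer(nmax)
  Ys <- matrix(NA_real_, nmax, 4)
  kk <- 1L; times[1] <- t; betas[1] <- beta; Ys[1, ] <- y
  while (t < t_end - 1e-9) {
    B <- y[4] - params$A_c * y[2]
    lv <- light_at(light, t + 1e-9)
    beta <- tuned_sleep_rule(lv, B, beta, params)
    t1 <- min(t + dt, t_end)
    r <- sim_hybrid_cpp(3L, y, beta, c(t, t1),
                        lux_to_alpha(lv, params), 2L, numeric(0),
                        integer(0), t, t1, min(dt, 0.005), -Inf, pv,
                        numeric(0), 100000L)
    y <- unname(r$Y[nrow(r$Y), ])
    t <- t1
    kk <- kk + 1L
    times[kk] <- t; betas[kk] <- beta; Ys[kk, ] <- y
  }
  times <- times[1:kk]; betas <- betas[1:kk]; Ys <- Ys[1:kk, , drop = FALSE]
  colnames(Ys) <- variant_state_names("S+C3")
  resid <- residual_series(times, Ys, "S+C3", delta_init, cycle, spec)
  cross <- first_crossing(times, resid)
  if (!is.na(cross)) {
    return(list(t_f = cross, supplement_used = FALSE,
                times = times, beta = betas, states = Ys,
                state = two_process_state("S+C3", y, beta)))
  }
  sup <- open_loop_entrain(two_process_state("S+C3", y, beta), delta_init,
                           cycle, spec, params, t0 = t_end,
                           horizon_cap = horizon_cap)
  list(t_f = sup$t_f, supplement_used = TRUE,
       times = times, beta = betas, states = Ys, state = sup$state)
}
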