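#' Sleep/wake schedule for controllable-sleep simulations
#'
#' @param T_sleep sleep-onset times (h).
#' @param T_wake wake times (h).
#' @return An object of class `sleep_schedule` with the switches merged in
#'   time order.  Sleep and wake switches must strictly interleave, and no
#'   wake interval may exceed 18 h.
#' @export
sleep_schedule <- function(T_sleep = numeric(0), T_wake = numeric(0)) {
  T_sleep <- sort(as.numeric(T_sleep))
  T_wake <- sort(as.numeric(T_wake))
  times <- c(T_sleep, T_wake)
  beta <- c(rep(1L, length(T_sleep)), rep(0L, length(T_wake)))
  o <- order(times)
  times <- times[o]; beta <- beta[o]
  if (length(times) > 1 && any(diff(beta) == 0))
    stop("sleep and wake times must strictly interleave")
  structure(list(T_sleep = T_sleep, T_wake = T_wake,
                 times = times, beta = beta),
            class = "sleep_schedule")
}

#' @export
print.sleep_schedule <- function(x, ...) {
  cat(sprintf("Sleep schedule: %d sleep onsets, %d wakes\n",
              length(x$T_sleep), length(x$T_wake)))
  if (length(x$times))
    print(data.frame(time_h = x$times,
                     switch = ifelse(x$beta == 1, "sleep", "wake")))
  invisible(x)
}

#' Hybrid integration of a two-process model
#'
#' Integrates the chosen model variant with fixed-step classical RK4
#' between discrete events, localizing every sleepiness-threshold crossing
#' by bisection (to 1e-6 h) and stopping exactly at light breakpoints and
#' scheduled switch times.  Light is gated off during sleep, so the
#' oscillator free-runs while the subject sleeps.
#'
#' @param state0 initial [two_process_state()].
#' @param light a [light_signal()] (lux; internally converted to drive
#'   units appropriate for the variant).
#' @param policy `"spontaneous"` (threshold automaton), `"schedule"`
#'   (scheduled switches plus safety overrides) or `"forced-awake"`
#'   (beta pinned to 0, e.g. a night shift).
#' @param t_span length-2 numeric, start and end time (h).
#' @param params a [two_process_params()] object.
#' @param dt integration step (h).
#' @param schedule a [sleep_schedule()], required for `policy = "schedule"`.
#' @param force_wake_until transitions are disabled and the subject is kept
#'   awake before this time (h); used for night-shift windows inside a
#'   longer run.
#' @param prc a `prc_table`, required for the `"S+C1"` variant.
#' @param thin keep every `thin`-th integration node in the returned
#'   trajectory (event nodes and the final node are always kept).
#' @return An object of class `tp_trajectory`: a list with `times`,
#'   `states` (matrix, one column per continuous state), `beta`, `B`
#'   (sleepiness), `u` (circadian drive), `I` (applied lux), and
#'   `switch_events` (data frame: time, old and new beta, trigger).
#' @export
integrate_hybrid <- function(state0, light,
                             policy = c("spontaneous", "schedule",
                                        "forced-awake"),
                             t_span, params = two_process_params(),
                             dt = 0.005, schedule = NULL,
                             force_wake_until = -Inf, prc = NULL,
                             thin = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(state0, "two_process_state"),
            inherits(light, "light_signal"),
            length(t_span) == 2, t_span[2] > t_span[1], dt > 0)
  variant <- state0$variant
  code <- variant_code(variant)
  pol <- switch(policy, spontaneous = 0L, schedule = 1L, `forced-awake` = 2L)
  if (pol == 1L && is.null(schedule))
    stop("policy = \"schedule\" needs a sleep_schedule")
  sw_times <- if (is.null(schedule)) numeric(0) else schedule$times
  sw_beta <- if (is.null(schedule)) integer(0) else schedule$beta
  prcf <- prc_dense(prc, variant)
  clev <- light_to_control(light, variant, params)
  res <- sim_hybrid_cpp(code, unname(state0$y), state0$beta,
                        light$breakpoints, clev, pol,
                        sw_times, sw_beta,
                        t_span[1], t_span[2], dt, force_wake_until,
                        pars_vec(params), prcf, as.integer(thin))
  build_trajectory(res, variant, light, params)
}

# shared post-processing of engine output into a tp_trajectory
build_trajectory <- function(res, variant, light, params) {
  nms <- variant_state_names(variant)
  Y <- res$Y
  colnames(Y) <- nms
  beta <- res$beta
  B <- if (variant == "S+C1") {
    Y[, "H"] - params$A_c * cos(Y[, "theta"])
  } else if (variant == "C-only") {
    rep(NA_real_, nrow(Y))
  } else {
    Y[, "H"] - params$A_c * Y[, "x"]
  }
  I <- light_at(light, res$t)
  I_eff <- I * (1 - beta)
  u <- if (variant %in% c("S+C3", "C-only")) {
    params$G * alpha_of_light(I_eff, 0, params) * (1 - Y[, "n"])
  } else {
    lux_to_u(I_eff, params)
  }
  ev <- data.frame(time = res$ev_t,
                   beta_old = res$ev_old, beta_new = res$ev_new,
                   trigger = c("spontaneous", "scheduled", "forced",
                               "immediate", "immediate")[res$ev_trig + 1L],
                   B = res$ev_B)
  structure(list(variant = variant, times = res$t, states = Y,
                 beta = beta, B = B, u = u, I = I,
                 switch_events = ev, light = light, params = params),
            class = "tp_trajectory")
}

#' @export
print.tp_trajectory <- function(x, ...) {
  cat(sprintf("<%s trajectory: t in [%.2f, %.2f] h, %d nodes, %d switches>\n",
              x$variant, min(x$times), max(x$times), length(x$times),
              nrow(x$switch_events)))
  invisible(x)
}

#' @export
#' @importFrom graphics lines legend par rect
plot.tp_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  if (x$variant == "S+C1") {
    plot(x$times, cos(x$states[, "theta"]), type = "l", xlab = "time (h)",
         ylab = "cos(theta)", ...)
  } else {
    plot(x$times, x$states[, "x"], type = "l", xlab = "time (h)",
         ylab = "x (CBT state)", ...)
  }
  if (x$variant != "C-only") {
    plot(x$times, x$B, type = "l", xlab = "time (h)", ylab = "sleepiness B",
         ylim = c(0, 1))
    lines(x$times, x$states[, "H"], lty = 2)
    asleep <- x$beta == 1
    if (any(asleep)) {
      r <- rle(asleep)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        rect(x$times[starts[j]], 0, x$times[ends[j]], 0.05,
             col = "grey40", border = NA)
      }
    }
  }
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `tp_trajectory`.
#' @return A [two_process_state()] at the last time point.
#' @export
final_state <- function(traj) {
  n <- length(traj$times)
  two_process_state(traj$variant, traj$states[n, ], traj$beta[n])
}
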