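#' Retinal activation rate under light
#'
#' Process L converts light intensity into an activation rate
#' `alpha(I) = alpha0 * (I (1 - beta) / I0)^p`.  During sleep (`beta = 1`)
#' the eyes are closed and the activation rate is exactly zero, so light has
#' no effect on the circadian system while the subject sleeps.
#'
#' @param I light intensity (lux), non-negative.
#' @param beta sleep state: 0 awake, 1 asleep.
#' @param params a [two_process_params()] object.
#' @return Activation rate in 1/h.
#' @export
alpha_of_light <- function(I, beta = 0, params = two_process_params()) {
  if (any(I < 0)) stop("light intensity must be non-negative")
  params$alpha0 * (I * (1 - beta) / params$I0)^params$p
}

#' Circadian drive from Process L
#'
#' `u = G * alpha(I, beta) * (1 - n)`: the neural drive forwarded to the
#' core body temperature oscillator, proportional to the fraction `1 - n`
#' of photoreceptors in the ready state.  Zero during sleep.
#'
#' @param n fraction of photoreceptors in the used state, in \[0, 1\].
#' @inheritParams alpha_of_light
#' @return Dimensionless circadian drive.
#' @export
circadian_drive <- function(n, I, beta = 0, params = two_process_params()) {
  if (any(n < 0 | n > 1)) stop("n must lie in [0, 1]")
  params$G * alpha_of_light(I, beta, params) * (1 - n)
}

#' Time derivative of the used-receptor fraction (Process L)
#'
#' `dn/dt = 60 * (alpha(I, beta) (1 - n) - gamma n)`.
#'
#' @inheritParams circadian_drive
#' @return dn/dt in 1/h.
#' @export
process_L_deriv <- function(n, I, beta = 0, params = two_process_params()) {
  if (any(n < 0 | n > 1)) stop("n must lie in [0, 1]")
  60 * (alpha_of_light(I, beta, params) * (1 - n) - params$gamma * n)
}

#' Time derivatives of the core body temperature oscillator (Process P)
#'
#' The second-order van der Pol-type oscillator driven by the circadian
#' drive `u`, with a light-modulation factor `(1 - 0.4 x)(1 - k_c x_c)` and
#' an intrinsic frequency set by `24 / (0.99729 tau_x)`.
#'
#' @param x core body temperature state (dimensionless).
#' @param xc complementary oscillator state (1/h).
#' @param u circadian drive.
#' @param params a [two_process_params()] object.
#' @return Named vector `c(dx, dxc)` in 1/h.
#' @export
process_P_deriv <- function(x, xc, u, params = two_process_params()) {
  stopifnot(is.finite(x), is.finite(xc), is.finite(u))
  M <- (1 - 0.4 * x) * (1 - params$k_c * xc)
  nu <- 24 / (0.99729 * params$tau_x)
  dx <- pi / 12 * (xc + params$mu * (x / 3 + 4 / 3 * x^3 - 256 / 105 * x^7) +
                     M * u)
  dxc <- pi / 12 * ((params$q * xc - params$k * x) * M * u - nu^2 * x)
  c(dx = dx, dxc = dxc)
}

#' Steady state of Process L under constant light
#'
#' With constant light the fast retinal stage settles at
#' `n = alpha / (alpha + gamma)` and the drive at
#' `u = G * gamma * alpha / (alpha + gamma)`.
#'
#' @param I constant light intensity (lux).
#' @param params a [two_process_params()] object.
#' @return Named vector `c(n_ss, u_ss)`.
#' @examples
#' steady_state_drive(1000)["u_ss"]   # 0.1731
#' @export
steady_state_drive <- function(I, params = two_process_params()) {
  a <- alpha_of_light(I, 0, params)
  c(n_ss = a / (a + params$gamma),
    u_ss = params$G * params$gamma * a / (a + params$gamma))
}

#' Time derivative of the sleep homeostat (Process S)
#'
#' `dH/dt = -H / tau_d` while asleep, `(1 - H) / tau_r` while awake.
#'
#' @param H homeostat level in \[0, 1\].
#' @param beta sleep state: 0 awake, 1 asleep.
#' @param params a [two_process_params()] object.
#' @return dH/dt in 1/h.
#' @export
homeostat_deriv <- function(H, beta, params = two_process_params()) {
  if (any(H < 0 | H > 1)) stop("H must lie in [0, 1]")
  ifelse(beta == 1, -H / params$tau_d, (1 - H) / params$tau_r)
}

#' Sleepiness
#'
#' `B = H - A_c * x` for models carrying the oscillator states, or
#' `B = H - A_c * cos(theta)` for the phase-reduced model.
#'
#' @param state a [two_process_state()].
#' @param params a [two_process_params()] object.
#' @return Sleepiness B (dimensionless).
#' @export
sleepiness <- function(state, params = two_process_params()) {
  v <- state$variant
  y <- state$y
  if (v == "S+C1") {
    y[["H"]] - params$A_c * cos(y[["theta"]])
  } else if (v == "C-only") {
    stop("the C-only model has no homeostat and no sleepiness")
  } else {
    y[["H"]] - params$A_c * y[["x"]]
  }
}

#' Phase-reduced circadian dynamics
#'
#' `dtheta/dt = omega0 + f(theta) * u`, with the phase response curve `f`
#' interpolated from a table estimated by [estimate_prc()].
#'
#' @param theta circadian phase (rad).
#' @param u circadian drive.
#' @param prc a `prc_table` from [estimate_prc()].
#' @param params a [two_process_params()] object.
#' @return dtheta/dt in rad/h.
#' @export
phase_deriv <- function(theta, u, prc, params = two_process_params()) {
  if (missing(prc) || is.null(prc))
    stop("a phase response curve table is required for the phase model")
  params$omega0 + prc_eval(prc, theta) * u
}

#' Spontaneous sleep/wake automaton
#'
#' Hysteretic switching on sleepiness: an awake subject falls asleep when B
#' reaches the upper threshold `H_m` and an asleep subject wakes when B
#' falls to `L_m`; inside the band the previous state holds.
#'
#' @param B sleepiness.
#' @param beta_prev sleep state just before the current instant.
#' @param params a [two_process_params()] object.
#' @return New sleep state (0 or 1).
#' @export
spontaneous_transition <- function(B, beta_prev, params = two_process_params()) {
  ifelse(beta_prev == 0 & B >= params$H_m, 1L,
         ifelse(beta_prev == 1 & B <= params$L_m, 0L, as.integer(beta_prev)))
}

#' Scheduled sleep/wake transition with sleepiness guards
#'
#' Applies a scheduled switch if the current time matches a scheduled sleep
#' or wake time, checking the sleepiness feasibility bounds
#' `H_m <= B(T_sleep) <= B1_max` and `L_m <= B(T_wake) <= B2_max`; in
#' addition the safety overrides force waking when B has drained to `L_m`
#' and force sleep when B has risen to `B1_max`.
#'
#' @param t current time (h).
#' @param schedule a [sleep_schedule()].
#' @param B sleepiness at `t`.
#' @param beta_prev sleep state just before `t`.
#' @param params a [two_process_params()] object.
#' @param tol time tolerance for matching a scheduled switch (h).
#' @return List with `beta` (new state) and `violation` (`NULL`, or a
#'   message when a scheduled switch falls outside its sleepiness bounds;
#'   the switch is still rejected, not silently clamped).
#' @export
controllable_transition <- function(t, schedule, B, beta_prev,
                                    params = two_process_params(),
                                    tol = 1e-9) {
  beta <- as.integer(beta_prev)
  violation <- NULL
  if (beta == 1 && B <= params$L_m) beta <- 0L
  if (beta == 0 && B >= params$B1_max) beta <- 1L
  hit_sleep <- any(abs(schedule$T_sleep - t) <= tol)
  hit_wake <- any(abs(schedule$T_wake - t) <= tol)
  if (hit_sleep) {
    if (B >= params$H_m - 1e-9 && B <= params$B1_max + 1e-9) {
      beta <- 1L
    } else {
      violation <- sprintf(
        "scheduled sleep at t=%.3f rejected: B=%.4f outside [%.2f, %.2f]",
        t, B, params$H_m, params$B1_max)
    }
  }
  if (hit_wake) {
    if (B >= params$L_m - 1e-9 && B <= params$B2_max + 1e-9) {
      beta <- 0L
    } else {
      violation <- sprintf(
        "scheduled wake at t=%.3f rejected: B=%.4f outside [%.2f, %.2f]",
        t, B, params$L_m, params$B2_max)
    }
  }
  list(beta = beta, violation = violation)
}

#' Sleep rule tuned to a precomputed light schedule
#'
#' When a light schedule optimized for the circadian oscillator alone is
#' imposed on the full two-process model, the subject must be awake
#' whenever that light is on.  The rule wakes the subject whenever the
#' prescribed light is positive or B has drained to `L_m`, puts them to
#' sleep when the light is off and B is at least `H_m`, and otherwise holds
#' the previous state.
#'
#' @param I_star prescribed light intensity at the current instant (lux).
#' @param B sleepiness.
#' @param beta_prev previous sleep state.
#' @param params a [two_process_params()] object.
#' @return New sleep state (0 or 1).
#' @export
tuned_sleep_rule <- function(I_star, B, beta_prev,
                             params = two_process_params()) {
  ifelse(I_star > 0 | B <= params$L_m, 0L,
         ifelse(B >= params$H_m, 1L, as.integer(beta_prev)))
}

#' Continuous + discrete state of a two-process model
#'
#' @param variant one of `"S+C3"`, `"S+C2"`, `"S+C1"`, `"C-only"`.
#' @param y named numeric vector of the continuous states in the variant's
#'   layout (`n, x, xc, H` / `x, xc, H` / `theta, H` / `n, x, xc`).
#' @param beta sleep state (0 awake, 1 asleep).
#' @return An object of class `two_process_state`.
#' @export
two_process_state <- function(variant = c("S+C3", "S+C2", "S+C1", "C-only"),
                              y, beta = 0) {
  variant <- match.arg(variant)
  nms <- variant_state_names(variant)
  y <- as.numeric(y)
  if (length(y) != length(nms))
    stop(sprintf("variant %s needs %d continuous states (%s)",
                 variant, length(nms), paste(nms, collapse = ", ")))
  names(y) <- nms
  if ("n" %in% nms && (y[["n"]] < 0 || y[["n"]] > 1))
    stop("n must lie in [0, 1]")
  if ("H" %in% nms && (y[["H"]] < 0 || y[["H"]] > 1))
    stop("H must lie in [0, 1]")
  if ("theta" %in% nms) y[["theta"]] <- wrap_2pi(y[["theta"]])
  if (!beta %in% c(0, 1)) stop("beta must be 0 or 1")
  structure(list(variant = variant, y = y, beta = as.integer(beta)),
            class = "two_process_state")
}

#' @export
print.two_process_state <- function(x, ...) {
  cat(sprintf("<%s state, %s>\n", x$variant,
              if (x$beta == 1) "asleep" else "awake"))
  print(round(x$y, 5))
  invisible(x)
}

wrap_2pi <- function(theta) theta %% (2 * pi)

# wrap an angular difference into (-pi, pi]
wrap_pi <- function(dtheta) {
  d <- (dtheta + pi) %% (2 * pi) - pi
  ifelse(d == -pi, pi, d)
}
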