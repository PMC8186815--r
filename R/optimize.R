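# Minimum-time entrainment optimizers: open-loop baseline, adjoint-based
# projected gradient descent on piecewise-constant light (and scheduled
# sleep/wake switch times), and a horizon-shrinking outer loop.
#
# Internally the light decision variable is w in [0, 1] per 0.1-h bin,
# scaled to the variant's drive unit (alpha for the full model, u for the
# reduced ones).  The drive enters the dynamics linearly, so gradients are
# well-behaved at w = 0, unlike d(alpha)/dI which blows up at I = 0 for
# the square-root dose-response.

# -- problem container -------------------------------------------------------

# prefix: optional list(breakpoints, lux) of fixed light before ctrl_start
entrain_problem <- function(state0, delta_init, cycle, spec,
                            params = two_process_params(),
                            I_max = 10000, t0 = 0,
                            force_wake_until = -Inf,
                            prefix = NULL, ctrl_start = t0,
                            prc = NULL, dt = 0.005) {
  variant <- state0$variant
  stopifnot(spec$variant == variant, cycle$variant == variant)
  cmax <- if (variant %in% c("S+C3", "C-only")) {
    lux_to_alpha(I_max, params)
  } else {
    lux_to_u(I_max, params)
  }
  prefix_clev <- NULL
  if (!is.null(prefix)) {
    stopifnot(ctrl_start > t0,
              abs(prefix$breakpoints[1] - t0) < 1e-9,
              abs(prefix$breakpoints[length(prefix$breakpoints)] -
                    ctrl_start) < 1e-9)
    prefix_clev <- if (variant %in% c("S+C3", "C-only")) {
      lux_to_alpha(prefix$lux, params)
    } else {
      lux_to_u(prefix$lux, params)
    }
  }
  list(variant = variant, code = variant_code(variant),
       y0 = unname(state0$y), beta0 = state0$beta,
       delta_init = delta_init, cycle = cycle, spec = spec,
       params = params, pv = pars_vec(params), I_max = I_max,
       cmax = cmax, t0 = t0, force_wake_until = force_wake_until,
       prefix = prefix, prefix_clev = prefix_clev,
       ctrl_start = ctrl_start,
       prcf = prc_dense(prc, variant), dt = dt)
}

bin_breaks <- function(a, b, by) {
  s <- seq(a, b, by = by)
  if (abs(s[length(s)] - b) > 1e-9) s <- c(s, b)
  s
}

# destination reference light expressed in w units on given bins
w_reference <- function(prob, breaks) {
  mid <- head(breaks, -1) + diff(breaks) / 2
  lux <- ifelse(reference_light(mid + prob$delta_init, "S+C3") > 0, 1000, 0)
  ctrl <- if (prob$variant %in% c("S+C3", "C-only")) {
    lux_to_alpha(lux, prob$params)
  } else {
    lux_to_u(lux, prob$params)
  }
  ctrl / prob$cmax
}

# resample a step function (breaks0, w0) onto new bins, filling beyond the
# old support with the destination reference pattern
w_resize <- function(prob, breaks0, w0, breaks1) {
  mid <- head(breaks1, -1) + diff(breaks1) / 2
  idx <- findInterval(mid, breaks0)
  w1 <- w_reference(prob, breaks1)
  inside <- idx >= 1 & idx <= length(w0)
  w1[inside] <- w0[idx[inside]]
  pmin(pmax(w1, 0), 1)
}

# full engine control arrays for decision vector w on bins `breaks`
assemble_control <- function(prob, breaks, w) {
  if (is.null(prob$prefix)) {
    list(cb = breaks, clev = w * prob$cmax,
         offset = 0L)
  } else {
    list(cb = c(prob$prefix$breakpoints, breaks[-1]),
         clev = c(prob$prefix_clev, w * prob$cmax),
         offset = length(prob$prefix_clev))
  }
}

sim_problem <- function(prob, tf, breaks, w, schedule = NULL, thin = 1L) {
  ctl <- assemble_control(prob, breaks, w)
  pol <- if (prob$variant == "C-only") 2L else if (is.null(schedule)) 0L else 1L
  sw_t <- if (is.null(schedule)) numeric(0) else schedule$times
  sw_b <- if (is.null(schedule)) integer(0) else schedule$beta
  sim_hybrid_cpp(prob$code, prob$y0, prob$beta0, ctl$cb, ctl$clev, pol,
                 sw_t, sw_b, prob$t0, tf, prob$dt,
                 prob$force_wake_until, prob$pv, prob$prcf,
                 as.integer(thin))
}

phi_problem <- function(prob, tf, breaks, w, schedule = NULL) {
  r <- sim_problem(prob, tf, breaks, w, schedule, thin = 100000L)
  yT <- r$Y[nrow(r$Y), ]
  zref <- reference_terminal_vec(prob$cycle, tf + prob$delta_init)
  terminal_phi_r(prob$variant, yT, zref, prob$spec$tol)
}

terminal_phi_r <- function(variant, yT, zref, tol) {
  if (variant == "S+C3") {
    d <- yT[2:4] - zref
  } else if (variant == "S+C2") {
    d <- yT - zref
  } else if (variant == "S+C1") {
    d <- c(wrap_pi(yT[1] - zref[1]), yT[2] - zref[2])
  } else {
    d <- yT[2:3] - zref
  }
  sum(d^2) - tol
}

grad_problem <- function(prob, tf, breaks, w, schedule = NULL) {
  ctl <- assemble_control(prob, breaks, w)
  pol <- if (prob$variant == "C-only") 2L else if (is.null(schedule)) 0L else 1L
  sw_t <- if (is.null(schedule)) numeric(0) else schedule$times
  sw_b <- if (is.null(schedule)) integer(0) else schedule$beta
  zref <- reference_terminal_vec(prob$cycle, tf + prob$delta_init)
  g <- adjoint_grad_cpp(prob$code, prob$y0, prob$beta0, ctl$cb, ctl$clev,
                        pol, sw_t, sw_b, prob$t0, tf, prob$dt,
                        prob$force_wake_until, prob$pv, prob$prcf,
                        zref, prob$spec$tol)
  gw <- g$grad_c[(ctl$offset + 1):length(g$grad_c)] * prob$cmax
  list(phi = g$phi, grad_w = gw, grad_T = g$grad_T,
       jumps_skipped = g$jumps_skipped)
}

#' Adjoint gradient of the terminal residual
#'
#' Computes the gradient of the terminal entrainment residual with respect
#' to the per-bin light decision variables (and, when a schedule is given,
#' the scheduled switch times) by integrating the co-state equation
#' backward along the stored forward trajectory, applying the hybrid jump
#' condition at every state-triggered sleep/wake switch.  The light
#' gradient is expressed per unit of the normalized bin level `w` in
#' `[0, 1]` (the bin's drive level divided by the drive at `I_max`); it is
#' exactly zero for bins that fall inside sleep.
#'
#' @param state0 initial [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle matching reference cycle.
#' @param spec a [terminal_spec()].
#' @param tf horizon (h).
#' @param w per-bin normalized light levels in `[0, 1]`.
#' @param bins_h bin width (h).
#' @param schedule optional [sleep_schedule()]; when given the simulation
#'   uses scheduled switching and switch-time gradients are returned.
#' @param I_max light bound (lux).
#' @param params,prc,dt,t0,force_wake_until as in [integrate_hybrid()].
#' @return List with `phi` (terminal residual), `grad_w`, `grad_T` and
#'   `jumps_skipped` (number of degenerate switching surfaces where the
#'   co-state jump was skipped).
#' @export
adjoint_gradient <- function(state0, delta_init, cycle, spec, tf, w,
                             bins_h = 0.1, schedule = NULL, I_max = 10000,
                             params = two_process_params(), prc = NULL,
                             dt = 0.005, t0 = 0, force_wake_until = -Inf) {
  prob <- entrain_problem(state0, delta_init, cycle, spec, params, I_max,
                          t0 = t0, force_wake_until = force_wake_until,
                          prc = prc, dt = dt)
  breaks <- bin_breaks(prob$ctrl_start, tf, bins_h)
  if (length(w) != length(breaks) - 1)
    stop(sprintf("w must have %d bins for this horizon", length(breaks) - 1))
  grad_problem(prob, tf, breaks, w, schedule)
}

# -- open-loop baseline ------------------------------------------------------

#' Open-loop entrainment time
#'
#' Simulates the subject under the destination reference light with the
#' spontaneous sleep automaton and reports the first time the terminal
#' condition is met.
#'
#' @param state0 initial [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle matching reference cycle.
#' @param spec a [terminal_spec()].
#' @param params a [two_process_params()] object.
#' @param t0 simulation start time (h).
#' @param force_wake_until keep the subject awake before this time (night
#'   shift window).
#' @param prefix optional fixed light before `measure_from`:
#'   `list(breakpoints, lux)`.
#' @param measure_from crossings before this time are not counted (h).
#' @param horizon_cap give up after this many hours.
#' @param prc,dt as in [integrate_hybrid()].
#' @return List with `t_f` (NA if the cap is hit), `residual_at_cap`, and
#'   the final [two_process_state()].
#' @export
open_loop_entrain <- function(state0, delta_init, cycle, spec,
                              params = two_process_params(), t0 = 0,
                              force_wake_until = -Inf, prefix = NULL,
                              measure_from = 0, horizon_cap = 1000,
                              prc = NULL, dt = 0.005) {
  variant <- state0$variant
  pv <- pars_vec(params)
  prcf <- prc_dense(prc, variant)
  pol <- if (variant == "C-only") 2L else 0L
  t <- t0
  y <- unname(state0$y)
  beta <- state0$beta
  chunk <- 48
  last_resid <- NA_real_
  while (t < t0 + horizon_cap) {
    t1 <- min(t + chunk, t0 + horizon_cap)
    ref <- reference_light_signal(t, t1, variant, delta_init, params)
    cb <- ref$breakpoints; lev <- ref$levels
    if (!is.null(prefix) && t < prefix$breakpoints[length(prefix$breakpoints)]) {
      pe <- prefix$breakpoints[length(prefix$breakpoints)]
      cb <- sort(unique(c(prefix$breakpoints, cb[cb >= pe])))
      mids <- head(cb, -1) + diff(cb) / 2
      lev <- ifelse(mids < pe,
                    prefix$lux[pmin(pmax(findInterval(mids,
                                                      prefix$breakpoints),
                                         1L), length(prefix$lux))],
                    ifelse(reference_light(mids + delta_init,
                                           if (variant == "C-only")
                                             "C-only" else "S+C3") > 0,
                           1000, 0))
    }
    clev <- if (variant %in% c("S+C3", "C-only")) {
      lux_to_alpha(lev, params)
    } else {
      lux_to_u(lev, params)
    }
    r <- sim_hybrid_cpp(variant_code(variant), y, beta, cb, clev, pol,
                        numeric(0), integer(0), t, t1, dt,
                        force_wake_until, pv, prcf, 1L)
    nms <- variant_state_names(variant)
    Y <- r$Y; colnames(Y) <- nms
    resid <- residual_series(r$t, Y, variant, delta_init, cycle, spec)
    sel <- r$t >= measure_from
    cross <- first_crossing(r$t[sel], resid[sel])
    if (!is.na(cross)) {
      i <- nrow(Y)
      return(list(t_f = cross,
                  state = two_process_state(variant, Y[i, ], r$beta[i])))
    }
    i <- nrow(Y)
    y <- unname(Y[i, ]); beta <- r$beta[i]
    last_resid <- resid[length(resid)]
    t <- t1
  }
  list(t_f = NA_real_, residual_at_cap = last_resid,
       state = two_process_state(variant, y, beta))
}

# -- fixed-horizon descent ---------------------------------------------------

# projected gradient descent with Armijo backtracking; stops as soon as the
# horizon is feasible (phi <= 0) or progress stalls
descend_horizon <- function(prob, tf, breaks, w, schedule = NULL,
                            max_iter = 60, step0 = 50, t_scale = 1,
                            patience = 8, verbose = FALSE) {
  s <- step0
  if (!is.null(schedule) && length(schedule$times)) {
    # project the warm-start schedule into the sleepiness bounds before
    # trusting any feasibility it claims
    schedule <- enforce_sleepiness_windows(prob, tf, breaks, w, schedule,
                                           max_pass = 3)
  }
  g <- grad_problem(prob, tf, breaks, w, schedule)
  phi <- g$phi
  best <- list(phi = phi, w = w, schedule = schedule)
  stall <- 0
  iters <- 0
  while (iters < max_iter && phi > 0) {
    iters <- iters + 1
    improved <- FALSE
    for (bt in 1:30) {
      w_c <- pmin(pmax(w - s * g$grad_w, 0), 1)
      sch_c <- schedule
      if (!is.null(schedule) && length(schedule$times)) {
        t_c <- schedule$times - s * t_scale * g$grad_T[seq_along(schedule$times)]
        sch_c <- repair_schedule_times(prob, tf, breaks, w_c, t_c,
                                       schedule$beta)
      }
      phi_c <- phi_problem(prob, tf, breaks, w_c, sch_c)
      dec <- sum((w_c - w)^2)
      if (!is.null(schedule) && length(schedule$times))
        dec <- dec + sum((sch_c$times - schedule$times)^2)
      if (phi_c <= phi - 1e-4 * dec / max(s, 1e-12) ||
          (phi_c < phi && dec == 0)) {
        improved <- TRUE
        break
      }
      s <- s / 2
      if (s < 1e-8) break
    }
    if (!improved) break
    w <- w_c
    if (!is.null(sch_c)) schedule <- sch_c
    rel_drop <- (phi - phi_c) / max(abs(phi), 1e-12)
    phi <- phi_c
    if (phi <= 0 && !is.null(schedule) && length(schedule$times)) {
      # a feasible iterate must also respect the sleepiness bounds at the
      # scheduled switches; re-project and re-evaluate before accepting
      sch_v <- enforce_sleepiness_windows(prob, tf, breaks, w, schedule,
                                          max_pass = 3)
      phi_v <- phi_problem(prob, tf, breaks, w, sch_v)
      schedule <- sch_v
      phi <- phi_v
    }
    if (phi < best$phi) best <- list(phi = phi, w = w, schedule = schedule)
    if (phi <= 0) break
    s <- s * 2
    stall <- if (rel_drop < 1e-4) stall + 1 else 0
    if (stall >= patience) break
    g <- grad_problem(prob, tf, breaks, w, schedule)
    phi <- g$phi
    if (verbose)
      message(sprintf("  iter %d: phi=%.5g step=%.3g", iters, phi, s))
  }
  list(feasible = best$phi <= 0, phi = best$phi, w = best$w,
       schedule = best$schedule, iterations = iters)
}

# clip proposed switch times into sleepiness-feasible windows using the
# realized trajectory, keep ordering/minimum separation, drop switches
# beyond the horizon
repair_schedule_times <- function(prob, tf, breaks, w, times, beta,
                                  min_sep = 0.2) {
  o <- order(times)
  times <- times[o]; beta <- beta[o]
  lo <- prob$ctrl_start + 1e-3
  keep <- rep(TRUE, length(times))
  for (i in seq_along(times)) {
    times[i] <- min(max(times[i], lo + min_sep), tf - 1e-3)
    if (i > 1 && times[i] - times[i - 1] < min_sep)
      times[i] <- times[i - 1] + min_sep
    if (times[i] >= tf - 1e-3) keep[i] <- FALSE
  }
  times <- times[keep]; beta <- beta[keep]
  # drop leading/trailing switches that do not alternate
  if (length(beta) > 1) {
    ok <- c(TRUE, diff(beta) != 0)
    times <- times[ok]; beta <- beta[ok]
  }
  sch <- structure(list(T_sleep = times[beta == 1],
                        T_wake = times[beta == 0],
                        times = times, beta = as.integer(beta)),
                   class = "sleep_schedule")
  enforce_sleepiness_windows(prob, tf, breaks, w, sch)
}

# move scheduled switches so that B at each executed switch respects the
# bounds H_m <= B(T_sleep) <= B1_max and L_m <= B(T_wake) <= B2_max, using
# the simulated sleepiness along the candidate schedule; safety overrides
# in the engine handle the remaining edge cases during descent
enforce_sleepiness_windows <- function(prob, tf, breaks, w, sch,
                                       max_pass = 2) {
  par <- prob$params
  nms <- variant_state_names(prob$variant)
  ctl <- assemble_control(prob, breaks, w)
  Bof <- function(Y) {
    if (prob$variant == "S+C1") {
      Y[, 2] - par$A_c * cos(Y[, 1])
    } else if (prob$variant == "S+C2") {
      Y[, 3] - par$A_c * Y[, 1]
    } else {
      Y[, 4] - par$A_c * Y[, 2]
    }
  }
  # counterfactual continuation: hold the sleep state fixed from state y
  # at time t0c and return the first time B crosses the target level
  cf_cross <- function(y, t0c, beta_hold, target, rising, max_len = 12) {
    t1 <- min(t0c + max_len, tf - 1e-3)
    if (t1 <= t0c + 1e-6) return(NA_real_)
    r2 <- sim_hybrid_cpp(prob$code, y, as.integer(beta_hold), ctl$cb,
                         ctl$clev, 2L, numeric(0), integer(0), t0c, t1,
                         prob$dt, -Inf, prob$pv, prob$prcf, 1L)
    B2 <- Bof(r2$Y)
    hit <- if (rising) which(B2 >= target) else which(B2 <= target)
    if (!length(hit)) return(NA_real_)
    r2$t[hit[1]]
  }
  for (pass in seq_len(max_pass)) {
    r <- sim_problem(prob, tf, breaks, w, sch, thin = 5L)
    B <- Bof(r$Y)
    state_at <- function(t) {
      sapply(seq_len(ncol(r$Y)), function(j)
        approx(r$t, r$Y[, j], xout = t, rule = 2, ties = "ordered")$y)
    }
    Bt <- function(t) approx(r$t, B, xout = t, rule = 2,
                             ties = "ordered")$y
    moved <- FALSE
    times <- sch$times; beta <- sch$beta
    # a scheduled switch that drifts past its safety-guard crossing is
    # preempted by the guard and its gradient dies; clamp it back just
    # inside the boundary so it remains a live decision variable
    safety <- which(r$ev_trig == 2L & r$ev_old != r$ev_new)
    for (e in safety) {
      te <- r$ev_t[e]
      cand <- which(beta == r$ev_new[e] & times > te &
                      times < te + 6)
      if (length(cand)) {
        times[cand[1]] <- te - 0.05
        moved <- TRUE
      }
    }
    for (i in seq_along(times)) {
      b <- Bt(times[i])
      if (beta[i] == 1) {          # sleep onset needs B in [H_m, B1_max]
        if (b < par$H_m - 1e-6) {
          # too sleepy-early: stay awake longer until B reaches H_m
          cand <- cf_cross(state_at(times[i]), times[i], 0, par$H_m,
                           rising = TRUE)
          if (!is.na(cand) && cand + 0.1 < tf - 1e-3) {
            times[i] <- cand + 0.1; moved <- TRUE
          } else if (i == length(times)) {
            times[i] <- NA_real_; moved <- TRUE
          }
        }
        # b > B1_max: the engine's safety override already forced sleep at
        # B1_max before this time; realization repair handles it
      } else {                     # wake needs B in [L_m, B2_max]
        if (b > par$B2_max + 1e-6) {
          # waking too early: keep sleeping until B drains to B2_max
          cand <- cf_cross(state_at(times[i]), times[i], 1,
                           par$B2_max - 0.003, rising = FALSE)
          if (!is.na(cand) && cand + 0.05 < tf - 1e-3) {
            times[i] <- cand + 0.05; moved <- TRUE
          } else if (i == length(times)) {
            times[i] <- NA_real_; moved <- TRUE
          }
        }
      }
    }
    ok <- !is.na(times)
    times <- times[ok]; beta <- beta[ok]
    # cap wake intervals at 18 h (wake -> next sleep onset)
    for (i in seq_along(times)) {
      if (beta[i] == 1) {
        prev_wake <- if (i == 1) prob$ctrl_start else times[i - 1]
        if (times[i] - prev_wake > 18) {
          times[i] <- prev_wake + 18
          moved <- TRUE
        }
      }
    }
    o <- order(times)
    sch <- structure(list(T_sleep = times[o][beta[o] == 1],
                          T_wake = times[o][beta[o] == 0],
                          times = times[o], beta = as.integer(beta[o])),
                     class = "sleep_schedule")
    if (!moved) break
  }
  sch
}

# schedule implied by the realized switching of a spontaneous run; the
# switch times are inset slightly into the feasible sleepiness bands
# (sleep a little after B = H_m, wake a little before B = L_m) so that
# they remain genuine decision variables -- a scheduled switch sitting
# exactly on a threshold crossing is shadowed by the state-triggered
# guard and loses its gradient
schedule_from_spontaneous <- function(prob, tf, breaks, w, inset = 0.15) {
  r <- sim_problem(prob, tf, breaks, w, schedule = NULL, thin = 100000L)
  chg <- r$ev_old != r$ev_new & r$ev_t > prob$t0 + 1e-9 &
    r$ev_t < tf - 1e-3
  times <- r$ev_t[chg]
  beta <- r$ev_new[chg]
  times <- ifelse(beta == 1, times + inset, pmax(times - inset,
                                                 prob$t0 + 1e-3))
  o <- order(times)
  times <- times[o]; beta <- beta[o]
  keep <- times < tf - 1e-3
  times <- times[keep]; beta <- beta[keep]
  structure(list(T_sleep = times[beta == 1], T_wake = times[beta == 0],
                 times = times, beta = as.integer(beta)),
            class = "sleep_schedule")
}

# -- outer loop --------------------------------------------------------------

minimize_time_core <- function(prob, controllable = FALSE, bins_h = 0.1,
                               resolution = 0.02, max_iter = 60,
                               horizon_cap = 1000, measure_from = 0,
                               verbose = FALSE) {
  state0 <- two_process_state(prob$variant, prob$y0, prob$beta0)
  ol <- open_loop_entrain(state0, prob$delta_init, prob$cycle, prob$spec,
                          prob$params, t0 = prob$t0,
                          force_wake_until = prob$force_wake_until,
                          prefix = prob$prefix,
                          measure_from = measure_from,
                          horizon_cap = horizon_cap,
                          prc = prc_from_dense(prob), dt = prob$dt)
  if (is.na(ol$t_f))
    stop("open-loop entrainment did not finish within the horizon cap")
  history <- data.frame(horizon = numeric(0), phi = numeric(0),
                        feasible = logical(0), iterations = integer(0))
  if (ol$t_f <= measure_from + 1e-9) {
    return(finish_result(prob, tf = max(ol$t_f, measure_from), breaks = NULL,
                         w = NULL, schedule = NULL, t_open = ol$t_f,
                         history = history, measure_from = measure_from))
  }
  # feasible anchor: the best of (a) the open-loop reference light, and for
  # long horizons (b) greedy phase-advance and phase-delay pumping lights
  # (light on wherever the PRC is positive resp. negative along the
  # subject's own phase).  Minimum-time entrainment is bistable in the
  # shift direction, so both basins must be seeded.
  anchors <- list(list(tf = ol$t_f + resolution, w = NULL,
                       schedule = NULL))
  if (ol$t_f - measure_from > 48) {
    for (dir in c(1, -1)) {
      g <- greedy_pump_anchor(prob, dir, cap = ol$t_f,
                              bins_h = bins_h,
                              measure_from = measure_from,
                              extended = controllable)
      if (!is.null(g)) anchors <- c(anchors, list(c(g, list(dir = dir))))
      if (controllable) {
        # the spontaneous-threshold pumping light is always a valid
        # controllable anchor as well (its realized switches are feasible)
        g2 <- greedy_pump_anchor(prob, dir, cap = ol$t_f,
                                 bins_h = bins_h,
                                 measure_from = measure_from,
                                 extended = FALSE)
        if (!is.null(g2)) anchors <- c(anchors, list(c(g2, list(dir = dir))))
      }
    }
  }
  verified <- list()
  for (a in anchors) {
    T_a <- a$tf
    breaks_a <- bin_breaks(prob$ctrl_start, T_a, bins_h)
    w_a <- if (is.null(a$w)) w_reference(prob, breaks_a) else
      w_resize(prob, a$breaks, a$w, breaks_a)
    sch_a <- if (!controllable) NULL
      else if (!is.null(a$schedule)) truncate_schedule(a$schedule, T_a)
      else schedule_from_spontaneous(prob, T_a, breaks_a, w_a)
    phi_a <- phi_problem(prob, T_a, breaks_a, w_a, sch_a)
    if (phi_a > 0) {
      d <- descend_horizon(prob, T_a, breaks_a, w_a, sch_a,
                           max_iter = max_iter, verbose = verbose)
      if (!d$feasible) next
      w_a <- d$w; sch_a <- d$schedule
    }
    verified <- c(verified, list(list(tf = T_a, breaks = breaks_a,
                                      w = w_a, schedule = sch_a,
                                      dir = if (is.null(a$dir)) 0 else a$dir)))
  }
  if (!length(verified))
    stop("could not certify any anchor horizon as feasible")
  # polish the best anchor of each shift direction: the time-optimal
  # strategy may either advance or delay the clock and the two basins are
  # separated, so the cheaper anchor does not always win after descent
  tfs <- vapply(verified, function(v) v$tf, 0)
  starts <- list(verified[[which.min(tfs)]])
  other <- which(vapply(verified, function(v) v$dir, 0) !=
                   starts[[1]]$dir)
  if (length(other)) {
    cand <- verified[[other[which.min(tfs[other])]]]
    if (cand$tf < 1.6 * starts[[1]]$tf + 24)
      starts <- c(starts, list(cand))
  }
  shrink <- function(best) {
    step <- max(2, (best$tf - measure_from) / 20)
    while (step >= resolution / 2) {
      T_try <- best$tf - step
      if (T_try <= measure_from) {
        step <- step / 2
        next
      }
      breaks_t <- bin_breaks(prob$ctrl_start, T_try, bins_h)
      w_t <- w_resize(prob, best$breaks, best$w, breaks_t)
      sch_t <- if (controllable)
        truncate_schedule(best$schedule, T_try) else NULL
      # short horizons are cheap to simulate, so near the feasibility
      # boundary they get a larger descent budget
      short <- (T_try - measure_from) < 48
      d <- descend_horizon(prob, T_try, breaks_t, w_t, sch_t,
                           max_iter = if (short) max(max_iter, 150)
                                      else max_iter,
                           patience = if (short) 25 else 8,
                           verbose = verbose)
      history <<- rbind(history,
                        data.frame(horizon = T_try, phi = d$phi,
                                   feasible = d$feasible,
                                   iterations = d$iterations))
      if (verbose)
        message(sprintf("horizon %.2f: phi=%.4g %s", T_try, d$phi,
                        if (d$feasible) "feasible" else "infeasible"))
      if (d$feasible) {
        best <- list(tf = T_try, breaks = breaks_t, w = d$w,
                     schedule = d$schedule, dir = best$dir)
        step <- step * 1.6
      } else {
        step <- step / 2
      }
    }
    best
  }
  polished <- lapply(starts, shrink)
  best <- polished[[which.min(vapply(polished, function(v) v$tf, 0))]]
  finish_result(prob, best$tf, best$breaks, best$w, best$schedule,
                t_open = ol$t_f, history = history,
                measure_from = measure_from)
}

# iterated greedy bang-off light aligned with the subject's own phase
# response: light on (while awake) wherever dir * f(theta) exceeds a small
# margin.  Returns the first feasible horizon under that light, or NULL.
greedy_pump_anchor <- function(prob, dir, cap, bins_h = 0.1,
                               measure_from = 0, margin = 0.01,
                               n_pass = 4, extended = FALSE) {
  prc <- if (prob$variant == "S+C1") prc_from_dense(prob) else
    estimate_prc(prob$params)
  # for controllable sleep the pumping automaton uses the extended
  # thresholds the schedule constraints allow: phase advance keeps the
  # spontaneous sleep onset but wakes early at B = B2_max; phase delay
  # keeps the spontaneous wake but delays sleep onset to B = B1_max
  gprob <- prob
  if (extended) {
    par2 <- unclass(prob$params)
    if (dir > 0) par2$L_m <- par2$B2_max else par2$H_m <- par2$B1_max
    params2 <- do.call(two_process_params, par2)
    gprob$params <- params2
    gprob$pv <- pars_vec(params2)
  }
  tf <- cap
  breaks <- bin_breaks(prob$ctrl_start, tf, bins_h)
  mid <- head(breaks, -1) + diff(breaks) / 2
  w <- rep(0, length(breaks) - 1)
  for (pass in seq_len(n_pass)) {
    r <- sim_problem(gprob, tf, breaks, w, thin = 20L)
    th <- if (prob$variant == "S+C1") r$Y[, 1] else {
      xi <- if (prob$variant == "S+C2") 1L else 2L
      phase_of(r$Y[, xi], r$Y[, xi + 1L])
    }
    fv <- prc_eval(prc, th)
    want <- (dir * fv > margin) & (r$beta == 0) & (r$t >= prob$ctrl_start)
    wi <- approx(r$t, as.numeric(want), xout = mid, method = "constant",
                 f = 0, rule = 2, ties = "ordered")$y
    w <- ifelse(wi > 0.5, 1, 0)
  }
  r <- sim_problem(gprob, tf, breaks, w, thin = 2L)
  nms <- variant_state_names(prob$variant)
  Y <- r$Y; colnames(Y) <- nms
  resid <- residual_series(r$t, Y, prob$variant, prob$delta_init,
                           prob$cycle, prob$spec)
  sel <- r$t >= measure_from
  cross <- first_crossing(r$t[sel], resid[sel])
  if (extended) {
    # the extended-threshold automaton holds the homeostat slightly off the
    # reference pattern, so the pump may approach the terminal set without
    # entering it; hand the closest approach over to the reference light
    # with the true spontaneous automaton for the final leg
    i_near <- which(sel)[which.min(resid[sel])]
    t_near <- r$t[i_near]
    if (min(resid[sel]) < 0.3 && t_near > measure_from + 1 &&
        (is.na(cross) || t_near < cross)) {
      st_near <- two_process_state(prob$variant, Y[i_near, ],
                                   r$beta[i_near])
      tail_sim <- tryCatch(
        open_loop_entrain(st_near, prob$delta_init, prob$cycle, prob$spec,
                          prob$params, t0 = t_near,
                          horizon_cap = max(tf - t_near, 72),
                          prc = prc_from_dense(prob), dt = prob$dt),
        error = function(e) NULL)
      if (!is.null(tail_sim) && !is.na(tail_sim$t_f) &&
          (is.na(cross) || tail_sim$t_f < cross)) {
        # overwrite the light beyond the handover with the destination
        # reference pattern; keep the pumping events before it and the
        # spontaneous tail realizes its own switches in verification
        mid <- head(breaks, -1) + diff(breaks) / 2
        wref <- w_reference(prob, breaks)
        w[mid >= t_near] <- wref[mid >= t_near]
        keep_ev <- r$ev_t < t_near
        r$ev_t <- r$ev_t[keep_ev]; r$ev_old <- r$ev_old[keep_ev]
        r$ev_new <- r$ev_new[keep_ev]; r$ev_B <- r$ev_B[keep_ev]
        cross <- tail_sim$t_f
      }
    }
  }
  if (is.na(cross)) return(NULL)
  sched <- NULL
  if (extended) {
    par <- prob$params
    nudge <- function(times, beta, Bsw) {
      # place each switch in the interior of its sleepiness band so the
      # scheduled switch is not shadowed by a threshold guard
      for (i in seq_along(times)) {
        if (beta[i] == 1) {
          times[i] <- times[i] + if (Bsw[i] < (par$H_m + par$B1_max) / 2)
            0.1 else -0.1
        } else {
          times[i] <- times[i] + if (Bsw[i] > (par$L_m + par$B2_max) / 2)
            0.05 else -0.1
        }
      }
      o <- order(times)
      structure(list(T_sleep = times[o][beta[o] == 1],
                     T_wake = times[o][beta[o] == 0],
                     times = times[o], beta = as.integer(beta[o])),
                class = "sleep_schedule")
    }
    chg <- r$ev_old != r$ev_new & r$ev_t > prob$t0 + 1e-9
    sched <- nudge(r$ev_t[chg], r$ev_new[chg], r$ev_B[chg])
    # the frozen switch times drift away from the closed-loop automaton
    # realization over long horizons; re-derive them from the scheduled
    # run a few times (fixed-point passes), keeping the best crossing
    cross <- NA_real_
    best_sched <- NULL
    for (pass in 1:3) {
      r2 <- sim_problem(prob, tf, breaks, w,
                        schedule = truncate_schedule(sched, tf), thin = 2L)
      Y2 <- r2$Y; colnames(Y2) <- nms
      resid2 <- residual_series(r2$t, Y2, prob$variant, prob$delta_init,
                                prob$cycle, prob$spec)
      sel2 <- r2$t >= measure_from
      c2 <- first_crossing(r2$t[sel2], resid2[sel2])
      if (!is.na(c2) && (is.na(cross) || c2 < cross)) {
        cross <- c2
        best_sched <- sched
      }
      chg2 <- r2$ev_old != r2$ev_new & r2$ev_t > prob$t0 + 1e-9
      sched <- nudge(r2$ev_t[chg2], r2$ev_new[chg2], r2$ev_B[chg2])
    }
    if (is.na(cross)) return(NULL)
    sched <- best_sched
  }
  list(tf = cross + 0.05, breaks = breaks, w = w, schedule = sched)
}

truncate_schedule <- function(sch, tf) {
  if (is.null(sch)) return(NULL)
  keep <- sch$times < tf - 1e-3
  structure(list(T_sleep = sch$times[keep][sch$beta[keep] == 1],
                 T_wake = sch$times[keep][sch$beta[keep] == 0],
                 times = sch$times[keep],
                 beta = sch$beta[keep]),
            class = "sleep_schedule")
}

prc_from_dense <- function(prob) {
  if (!length(prob$prcf)) return(NULL)
  n <- length(prob$prcf)
  structure(list(theta = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)],
                 f = prob$prcf, period = 2 * pi / prob$params$omega0),
            class = "prc_table")
}

# threshold the optimal light to bang-off, re-verify, assemble the result
finish_result <- function(prob, tf, breaks, w, schedule, t_open, history,
                          measure_from = 0) {
  if (is.null(w)) {
    res <- list(variant = prob$variant, t_f = max(tf - measure_from, 0),
                t_open = t_open - measure_from,
                light = NULL, schedule = "spontaneous",
                w = NULL, breaks = NULL, residual = -prob$spec$tol,
                bang_off = TRUE, history = history,
                I_max = prob$I_max, delta_init = prob$delta_init)
    class(res) <- "entrain_optim"
    return(res)
  }
  nms <- variant_state_names(prob$variant)
  # verify on a slightly longer window than the certified horizon so a
  # rounded light whose crossing slips by a fraction of an hour is still
  # observed (the reported time bound below keeps it honest)
  tf_ext <- tf + 6
  tail_breaks <- bin_breaks(tf, tf_ext, 0.1)
  breaks_ext <- c(breaks, tail_breaks[-1])
  w_tail <- w_reference(prob, tail_breaks)
  crossing_of <- function(wv, extend = TRUE) {
    if (extend) {
      bks <- breaks_ext
      wv <- c(wv, w_tail)      # original bins untouched; reference beyond
      t_end <- tf_ext
    } else {
      bks <- breaks
      t_end <- tf
    }
    r <- sim_problem(prob, t_end, bks, wv, schedule, thin = 1L)
    Y <- r$Y; colnames(Y) <- nms
    resid <- residual_series(r$t, Y, prob$variant, prob$delta_init,
                             prob$cycle, prob$spec)
    sel <- r$t >= measure_from
    list(r = r, resid = resid, sel = sel,
         cross = first_crossing(r$t[sel], resid[sel]))
  }
  # baseline crossing on the exact certified horizon (feasibility can sit
  # right at the boundary, which bin re-alignment on the extended window
  # would miss)
  cont <- crossing_of(w, extend = FALSE)
  if (is.na(cont$cross)) cont <- crossing_of(w)
  # threshold the light to bang-off {0, I_max} and re-verify; cuts in lux
  # space and in normalized drive space are both tried, and the bang-off
  # schedule is accepted with its own crossing time when it still enters
  # the terminal set within the certified horizon
  lux <- alpha_or_u_to_lux(prob, w * prob$cmax)
  cuts <- list(ifelse(lux >= prob$I_max / 2, 1, 0),
               ifelse(w >= 0.5, 1, 0),
               ifelse(w > 0.05, 1, 0))
  slack <- if (is.na(cont$cross)) Inf else
    cont$cross + max(0.5, 0.03 * cont$cross)
  use_w <- w
  bang_ok <- FALSE
  out <- cont
  for (w_bang in cuts) {
    cb <- crossing_of(w_bang)
    if (!is.na(cb$cross) && cb$cross <= slack) {
      use_w <- w_bang
      bang_ok <- TRUE
      out <- cb
      break
    }
  }
  if (!bang_ok) {
    # verified dose-preserving rounding: descent leaves soft "ramps" of
    # intermediate bins at the edges of light blocks (sub-bin switch
    # times); round each contiguous interior group to a bang-off pattern
    # with approximately the same integrated drive, keeping the bins with
    # the largest levels, and revert any group whose rounding pushes the
    # crossing beyond the certified window
    w_r <- w
    interior <- which(w_r > 1e-9 & w_r < 1 - 1e-9)
    if (length(interior)) {
      grp <- cumsum(c(1, diff(interior) > 1))
      for (g in split(interior, grp)) {
        dose <- sum(w_r[g])
        done <- FALSE
        for (m in unique(pmin(pmax(c(round(dose), floor(dose),
                                     ceiling(dose)), 0), length(g)))) {
          trial <- w_r
          trial[g] <- 0
          if (m > 0) trial[g[order(w_r[g], decreasing = TRUE)[1:m]]] <- 1
          cb <- crossing_of(trial)
          if (!is.na(cb$cross) && cb$cross <= slack) {
            w_r <- trial
            done <- TRUE
            break
          }
        }
        # an unroundable group stays continuous
      }
    }
    cb <- crossing_of(w_r)
    if (!is.na(cb$cross) && cb$cross <= slack) {
      use_w <- w_r
      out <- cb
      bang_ok <- all(w_r < 1e-9 | w_r > 1 - 1e-9)
    }
  }
  r <- out$r; resid <- out$resid; sel <- out$sel; cross <- out$cross
  lux_final <- alpha_or_u_to_lux(prob, use_w * prob$cmax)
  light <- light_signal(breaks, round(lux_final, 6), I_max = prob$I_max)
  stopifnot(length(use_w) == length(breaks) - 1)
  # realized switch times (scheduled + safety) within the reported window
  chg <- r$ev_old != r$ev_new
  realized <- structure(list(
    T_sleep = r$ev_t[chg & r$ev_new == 1],
    T_wake = r$ev_t[chg & r$ev_new == 0],
    times = r$ev_t[chg], beta = r$ev_new[chg],
    trigger = c("spontaneous", "scheduled", "forced", "immediate",
                "immediate")[r$ev_trig[chg] + 1L]),
    class = "sleep_schedule")
  ev_B <- r$ev_B[chg]
  res <- list(variant = prob$variant,
              t_f = cross - measure_from,
              t_open = t_open - measure_from,
              light = light, w = use_w, breaks = breaks,
              schedule = if (is.null(schedule)) "spontaneous" else schedule,
              realized_switches = realized, switch_B = ev_B,
              residual = min(resid[sel]),
              bang_off = bang_ok, history = history,
              I_max = prob$I_max, delta_init = prob$delta_init,
              trajectory = build_trajectory(
                thin_sim(r, 20L), prob$variant, light, prob$params))
  class(res) <- "entrain_optim"
  res
}

alpha_or_u_to_lux <- function(prob, ctrl) {
  if (prob$variant %in% c("S+C3", "C-only")) {
    alpha_to_lux(ctrl, prob$params)
  } else {
    u_to_lux(pmin(ctrl, lux_to_u(prob$I_max, prob$params)), prob$params)
  }
}

# thin a raw engine result (keep every k-th node plus last)
thin_sim <- function(r, k) {
  n <- length(r$t)
  idx <- unique(c(seq(1, n, by = k), n))
  list(t = r$t[idx], Y = r$Y[idx, , drop = FALSE], beta = r$beta[idx],
       c = r$c[idx], ev_t = r$ev_t, ev_B = r$ev_B, ev_old = r$ev_old,
       ev_new = r$ev_new, ev_trig = r$ev_trig, ev_sched = r$ev_sched)
}

#' @export
print.entrain_optim <- function(x, ...) {
  cat(sprintf("<minimum-time entrainment (%s)>\n", x$variant))
  cat(sprintf("  t_f = %.2f h (open-loop baseline %.2f h)\n",
              x$t_f, x$t_open))
  if (!is.null(x$light))
    cat(sprintf("  light: %s, terminal residual %.4g\n",
                if (x$bang_off) "bang-off" else "continuous", x$residual))
  invisible(x)
}

# -- user-facing optimizers --------------------------------------------------

#' Minimum-time entrainment with spontaneous sleep
#'
#' Optimizes the light schedule alone; the subject falls asleep and wakes
#' spontaneously at the sleepiness thresholds.  A horizon-shrinking
#' bisection (resolution 0.02 h) wraps a projected-gradient descent on
#' piecewise-constant light bins; the reported light is thresholded to
#' bang-off \{0, I_max\} and re-verified.
#'
#' @param state0 initial [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle matching reference cycle.
#' @param I_max light bound (lux).
#' @param spec a [terminal_spec()]; defaults to the variant's spec with
#'   `tol = 0.01`.
#' @param params a [two_process_params()] object.
#' @param bins_h light bin width (h).
#' @param max_iter descent iteration cap per horizon.
#' @param horizon_cap cap for the open-loop baseline (h).
#' @param prc,dt as in [integrate_hybrid()].
#' @param t0,force_wake_until,prefix,measure_from night-shift plumbing as
#'   in [open_loop_entrain()].
#' @param ctrl_start first time at which light is a decision variable;
#'   defaults to `t0` unless a fixed `prefix` is given.
#' @param verbose print per-horizon progress.
#' @return An `entrain_optim` object: optimal light, realized switches,
#'   `t_f`, the open-loop baseline and convergence history.
#' @export
minimize_time_spontaneous <- function(state0, delta_init, cycle, I_max,
                                      spec = NULL,
                                      params = two_process_params(),
                                      bins_h = 0.1, max_iter = 60,
                                      horizon_cap = 1000, prc = NULL,
                                      dt = 0.005, t0 = 0,
                                      force_wake_until = -Inf,
                                      prefix = NULL, ctrl_start = NULL,
                                      measure_from = 0, verbose = FALSE) {
  if (is.null(spec)) spec <- terminal_spec(state0$variant)
  if (is.null(ctrl_start))
    ctrl_start <- if (is.null(prefix)) t0 else
      prefix$breakpoints[length(prefix$breakpoints)]
  prob <- entrain_problem(state0, delta_init, cycle, spec, params, I_max,
                          t0 = t0, force_wake_until = force_wake_until,
                          prefix = prefix, ctrl_start = ctrl_start,
                          prc = prc, dt = dt)
  minimize_time_core(prob, controllable = FALSE, bins_h = bins_h,
                     max_iter = max_iter, horizon_cap = horizon_cap,
                     measure_from = measure_from, verbose = verbose)
}

#' Minimum-time entrainment with controllable sleep
#'
#' Jointly optimizes the light bins and the sleep/wake switch times.
#' Switch-time gradients come from the adjoint jump terms; after every
#' step the switch times are projected into the sleepiness-feasible
#' windows (`B(T_sleep)` in `[H_m, B1_max]`, `B(T_wake)` in
#' `[L_m, B2_max]`) and wake intervals are capped at 18 h.  Episode counts
#' are initialized from the spontaneous trajectory at the current horizon.
#'
#' @inheritParams minimize_time_spontaneous
#' @return An `entrain_optim` object.
#' @export
minimize_time_controllable <- function(state0, delta_init, cycle, I_max,
                                       spec = NULL,
                                       params = two_process_params(),
                                       bins_h = 0.1, max_iter = 60,
                                       horizon_cap = 1000, prc = NULL,
                                       dt = 0.005, t0 = 0,
                                       force_wake_until = -Inf,
                                       prefix = NULL, ctrl_start = NULL,
                                       measure_from = 0, verbose = FALSE) {
  if (is.null(spec)) spec <- terminal_spec(state0$variant)
  if (is.null(ctrl_start))
    ctrl_start <- if (is.null(prefix)) t0 else
      prefix$breakpoints[length(prefix$breakpoints)]
  prob <- entrain_problem(state0, delta_init, cycle, spec, params, I_max,
                          t0 = t0, force_wake_until = force_wake_until,
                          prefix = prefix, ctrl_start = ctrl_start,
                          prc = prc, dt = dt)
  minimize_time_core(prob, controllable = TRUE, bins_h = bins_h,
                     max_iter = max_iter, horizon_cap = horizon_cap,
                     measure_from = measure_from, verbose = verbose)
}

#' Minimum-time entrainment of the circadian oscillator alone
#'
#' The classical problem without the sleep process: the three-state
#' retina + oscillator model is driven toward its limit cycle under the
#' effective 14.5-9.5-h light-dark cycle (the light a spontaneously
#' sleeping reference subject actually receives).
#'
#' @param state0_C initial [two_process_state()] of variant `"C-only"`.
#' @param delta_init reference clock offset (h).
#' @param I_max light bound (lux).
#' @param cycle optional precomputed `"C-only"` reference cycle.
#' @inheritParams minimize_time_spontaneous
#' @return An `entrain_optim` object.
#' @export
optimize_process_C_only <- function(state0_C, delta_init, I_max,
                                    cycle = NULL,
                                    spec = NULL,
                                    params = two_process_params(),
                                    bins_h = 0.1, max_iter = 60,
                                    horizon_cap = 1000, dt = 0.005,
                                    verbose = FALSE) {
  stopifnot(state0_C$variant == "C-only")
  if (is.null(cycle))
    cycle <- compute_entrained_cycle("C-only", params, dt = dt)
  if (is.null(spec)) spec <- terminal_spec("C-only")
  prob <- entrain_problem(state0_C, delta_init, cycle, spec, params, I_max,
                          dt = dt)
  minimize_time_core(prob, controllable = FALSE, bins_h = bins_h,
                     max_iter = max_iter, horizon_cap = horizon_cap,
                     verbose = verbose)
}
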