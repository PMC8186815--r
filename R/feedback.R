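# Nearest-neighbour feedback controller learned from minimum-time optimal
# trajectories.  While awake the policy maps (theta, H, theta_ref) to a
# light level and a countdown to the next sleep onset; while asleep it
# returns a countdown to the next wake time.  Phases are embedded as
# (cos, sin) pairs so the Euclidean metric respects circularity.

#' Build a feedback-controller training set from optimal trajectories
#'
#' For each time shift, solves the minimum-time entrainment problem with
#' controllable sleep, then samples the optimal trajectory at 0.01-h
#' resolution into records `(theta, H, theta_ref, beta, I, Gamma_sleep,
#' Gamma_wake)`.  The countdowns are the time remaining until the next
#' switch of the optimal schedule; past the last optimized switch they
#' continue onto the entrained reference schedule.  The retinal state `n`
#' is excluded: it is a fast transient with negligible effect on the
#' optimal strategy.
#'
#' @param I_max light bound (lux).
#' @param cases time shifts (h) used as training scenarios.
#' @param delta_init reference clock offset of the training scenarios (h).
#' @param cycle full-model reference cycle.
#' @param params a [two_process_params()] object.
#' @param sample_by sampling step of the records (h).
#' @param results optional named list of precomputed `entrain_optim`
#'   results (names = time shifts) to sample instead of re-optimizing.
#' @param ... passed to [minimize_time_controllable()].
#' @return An object of class `fb_training_set`: a data frame of records
#'   (`theta, H, theta_ref, beta, I, gamma_sleep, gamma_wake, case_id`)
#'   plus the per-case optimal entrainment times.
#' @export
build_training_set <- function(I_max, cases = 1:23, delta_init = 1,
                               cycle = NULL,
                               params = two_process_params(),
                               sample_by = 0.01, results = NULL, ...) {
  if (is.null(cycle)) cycle <- compute_entrained_cycle("S+C3", params)
  spec <- terminal_spec("S+C3")
  records <- list()
  case_tf <- numeric(0)
  for (ds in cases) {
    y0 <- reference_state(ds, delta_init, cycle)
    res <- if (!is.null(results) && !is.null(results[[as.character(ds)]])) {
      results[[as.character(ds)]]
    } else {
      tryCatch(
        minimize_time_controllable(y0, delta_init, cycle, I_max,
                                   spec = spec, params = params, ...),
        error = function(e) {
          warning(sprintf("time shift %g excluded: %s", ds,
                          conditionMessage(e)))
          NULL
        })
    }
    if (is.null(res)) next
    case_tf[as.character(ds)] <- res$t_f
    records[[as.character(ds)]] <-
      sample_optimal_records(res, ds, delta_init, cycle, params, sample_by)
  }
  if (!length(records)) stop("no training case succeeded")
  structure(list(records = do.call(rbind, records),
                 case_tf = case_tf, I_max = I_max,
                 delta_init = delta_init, sample_by = sample_by),
            class = "fb_training_set")
}

# records along one optimal trajectory, countdowns from the realized
# switches extended by the reference schedule past t_f
sample_optimal_records <- function(res, case_id, delta_init, cycle, params,
                                   sample_by = 0.01) {
  tf <- res$t_f
  ts <- seq(0, tf, by = sample_by)
  traj <- res$trajectory
  th <- phase_of(approx(traj$times, traj$states[, "x"], xout = ts)$y,
                 approx(traj$times, traj$states[, "xc"], xout = ts)$y)
  H <- approx(traj$times, traj$states[, "H"], xout = ts)$y
  beta <- approx(traj$times, traj$beta, xout = ts,
                 method = "constant", f = 0)$y
  thref <- reference_phase(cycle, ts, delta_init)
  I <- light_at(res$light, ts)
  sw <- res$realized_switches
  # extend with reference switches (destination clock) after the horizon
  ref_sleep <- cycle$sleep_onset[1]
  ref_wake <- cycle$wake_time[1]
  ext_days <- ceiling((tf + 48) / 24)
  ext_t <- c(outer(c(ref_sleep, ref_wake), 24 * (0:ext_days) - delta_init,
                   "+"))
  ext_b <- rep(c(1L, 0L), ext_days + 1)
  keep <- ext_t > tf
  all_t <- c(sw$times, ext_t[keep])
  all_b <- c(sw$beta, ext_b[keep])
  o <- order(all_t)
  all_t <- all_t[o]; all_b <- all_b[o]
  next_of <- function(t, target) {
    idx <- findInterval(t, all_t) + 1L
    out <- rep(NA_real_, length(t))
    for (i in seq_along(t)) {
      j <- idx[i]
      while (j <= length(all_t) && all_b[j] != target) j <- j + 1L
      out[i] <- if (j <= length(all_t)) all_t[j] - t[i] else NA_real_
    }
    out
  }
  data.frame(theta = th, H = H, theta_ref = thref,
             beta = as.integer(beta), I = I,
             gamma_sleep = next_of(ts, 1L),
             gamma_wake = next_of(ts, 0L),
             case_id = case_id)
}

#' @export
print.fb_training_set <- function(x, ...) {
  cat(sprintf(paste0("<feedback training set: %d records, %d cases, ",
                     "I_max = %g lux>\n"),
              nrow(x$records), length(x$case_tf), x$I_max))
  invisible(x)
}

#' Fit the nearest-neighbour feedback controller
#'
#' Splits the training records into a wake set (actions: light and
#' sleep-onset countdown) and a sleep set (action: wake countdown) and
#' prepares the feature embedding `(cos theta, sin theta, H,
#' cos theta_ref, sin theta_ref)` for 1-nearest-neighbour lookup.
#'
#' @param trainset a [build_training_set()] result.
#' @return An object of class `feedback_controller`.
#' @export
fit_feedback_controller <- function(trainset) {
  stopifnot(inherits(trainset, "fb_training_set"))
  rec <- trainset$records
  emb <- function(df) {
    cbind(cos(df$theta), sin(df$theta), df$H,
          cos(df$theta_ref), sin(df$theta_ref))
  }
  wake <- rec[rec$beta == 0, , drop = FALSE]
  sleep <- rec[rec$beta == 1, , drop = FALSE]
  if (!nrow(wake) || !nrow(sleep))
    stop("training set must contain both wake and sleep records")
  structure(list(wake = wake, sleep = sleep,
                 wake_feat = emb(wake), sleep_feat = emb(sleep),
                 I_max = trainset$I_max),
            class = "feedback_controller")
}

#' @export
print.feedback_controller <- function(x, ...) {
  cat(sprintf(paste0("<nearest-neighbour feedback controller: ",
                     "%d wake / %d sleep records>\n"),
              nrow(x$wake), nrow(x$sleep)))
  invisible(x)
}

#' Query the feedback controller
#'
#' 1-nearest-neighbour lookup in the wake or sleep dataset (matching the
#' current sleep state), with ties broken by the lowest record index.
#'
#' @param theta current circadian phase (rad).
#' @param H current homeostat level.
#' @param theta_ref current reference phase (rad).
#' @param beta current sleep state.
#' @param controller a [fit_feedback_controller()] result.
#' @return Awake: list `(I, gamma_sleep)`; asleep: list `(gamma_wake)`.
#' @export
controller_step <- function(theta, H, theta_ref, beta, controller) {
  stopifnot(inherits(controller, "feedback_controller"))
  q <- matrix(c(cos(theta), sin(theta), H, cos(theta_ref), sin(theta_ref)),
              nrow = 1)
  if (beta == 0) {
    i <- nn1_lookup_cpp(controller$wake_feat, q)[1]
    list(I = controller$wake$I[i],
         gamma_sleep = controller$wake$gamma_sleep[i])
  } else {
    i <- nn1_lookup_cpp(controller$sleep_feat, q)[1]
    list(gamma_wake = controller$sleep$gamma_wake[i])
  }
}

#' Closed-loop entrainment under the feedback controller
#'
#' Simulates the full model, re-querying the controller every control
#' period; a freshly returned countdown overrides the previous one, and a
#' switch fires when the countdown expires within the current period.
#' The sleepiness safety bounds remain active: the subject is force-woken
#' at `B <= L_m` and force-slept at `B >= B1_max`.
#'
#' @param state0 initial `"S+C3"` [two_process_state()].
#' @param delta_init reference clock offset (h).
#' @param cycle full-model reference cycle.
#' @param controller a [fit_feedback_controller()] result.
#' @param spec a [terminal_spec()].
#' @param params a [two_process_params()] object.
#' @param control_period time between controller queries (h).
#' @param horizon_cap give up after this many hours.
#' @param dt integration step (h).
#' @return List with `t_f` (NA at the cap), and the sampled closed-loop
#'   `times`, `states`, `beta`, `I` series.
#' @export
simulate_feedback <- function(state0, delta_init, cycle, controller,
                              spec = terminal_spec("S+C3"),
                              params = two_process_params(),
                              control_period = 0.1, horizon_cap = 1000,
                              dt = 0.005) {
  stopifnot(state0$variant == "S+C3")
  pv <- pars_vec(params)
  y <- unname(state0$y)
  beta <- state0$beta
  t <- 0
  nmax <- ceiling(horizon_cap / control_period) + 2L
  times <- numeric(nmax); betas <- integer(nmax); lux <- numeric(nmax)
  Ys <- matrix(NA_real_, nmax, 4)
  kk <- 1L; times[1] <- 0; betas[1] <- beta; Ys[1, ] <- y; lux[1] <- 0
  zcheck <- function(t, y) {
    zref <- reference_terminal_vec(cycle, t + delta_init)
    sum((y[2:4] - zref)^2) - spec$tol
  }
  resid_prev <- zcheck(0, y)
  if (resid_prev <= 0)
    return(list(t_f = 0, times = 0, states = Ys[1, , drop = FALSE],
                beta = beta, I = 0))
  while (t < horizon_cap) {
    B <- y[4] - params$A_c * y[2]
    if (beta == 0 && B >= params$B1_max) beta <- 1L
    if (beta == 1 && B <= params$L_m) beta <- 0L
    th <- phase_of(y[2], y[3])
    thref <- reference_phase(cycle, t, delta_init)
    act <- controller_step(th, y[4], thref, beta, controller)
    I_now <- if (beta == 0) act$I else 0
    countdown <- if (beta == 0) act$gamma_sleep else act$gamma_wake
    seg <- control_period
    switch_mid <- !is.na(countdown) && countdown < control_period
    if (switch_mid) seg <- max(countdown, 1e-6)
    r <- sim_hybrid_cpp(3L, y, beta, c(t, t + seg), I_to_ctrl(I_now, params),
                        2L, numeric(0), integer(0), t, t + seg, dt, -Inf,
                        pv, numeric(0), 100000L)
    y <- unname(r$Y[nrow(r$Y), ])
    t <- t + seg
    if (switch_mid) beta <- 1L - beta
    kk <- kk + 1L
    times[kk] <- t; betas[kk] <- beta; Ys[kk, ] <- y; lux[kk] <- I_now
    resid_now <- zcheck(t, y)
    if (resid_now <= 0) {
      # linear refinement of the crossing inside the last period
      frac <- if (resid_prev > resid_now)
        resid_prev / (resid_prev - resid_now) else 1
      t_f <- (t - seg) + frac * seg
      return(list(t_f = t_f, times = times[1:kk],
                  states = structure(Ys[1:kk, , drop = FALSE],
                                     dimnames = list(NULL,
                                       variant_state_names("S+C3"))),
                  beta = betas[1:kk], I = lux[1:kk]))
    }
    resid_prev <- resid_now
  }
  list(t_f = NA_real_, times = times[1:kk],
       states = Ys[1:kk, , drop = FALSE], beta = betas[1:kk],
       I = lux[1:kk])
}

I_to_ctrl <- function(I, params) lux_to_alpha(I, params)

#' Write / read a feedback training set as CSV + JSON manifest
#'
#' @param trainset a `fb_training_set`.
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.json`.
#' @export
write_training_set <- function(trainset, path) {
  write.csv(trainset$records, path, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "fb_training_set", I_max = trainset$I_max,
         delta_init = trainset$delta_init, sample_by = trainset$sample_by,
         case_tf = as.list(trainset$case_tf)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  rec <- read.csv(path)
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(records = rec, case_tf = unlist(man$case_tf),
                 I_max = man$I_max, delta_init = man$delta_init,
                 sample_by = man$sample_by),
            class = "fb_training_set")
}
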