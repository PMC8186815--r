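#' Scenario descriptor for jet-lag and shift-work experiments
#'
#' @param kind `"jetlag"` or `"shiftwork"`.
#' @param delta_shift time-zone displacement (h), jet-lag only.
#' @param delta_init offset between entrainment start and the reference
#'   6 am anchor (h).  Defaults: 1 for jet-lag (start at 7 am destination
#'   time), 2 for shift work (entrainment starts at 8 am).
#' @param shift_start,shift_end night-shift window in clock hours (24-h
#'   clock; e.g. 20 and 8 for 8 pm-8 am), shift-work only.
#' @param I_shift constant light during the night shift (lux).
#' @param I_max light bound during entrainment (lux).
#' @param strategy one of `"open-loop"`, `"min-time-spontaneous"`,
#'   `"min-time-controllable"`, `"min-time-with-shift-light"`,
#'   `"C-only-tuned"`, `"feedback"`, `"transfer-S+C1"`, `"transfer-S+C2"`.
#' @param variant model variant (the scenario runners use `"S+C3"`).
#' @param tol terminal tolerance.
#' @param dt integration step (h).
#' @param bins_h light bin width for the optimizers (h).
#' @param horizon_cap_h cap for open-loop baselines (h).
#' @return A validated `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("jetlag", "shiftwork"),
                          delta_shift = 0, delta_init = NULL,
                          shift_start = 20, shift_end = 8,
                          I_shift = 0, I_max = 10000,
                          strategy = "open-loop", variant = "S+C3",
                          tol = 0.01, dt = 0.005, bins_h = 0.1,
                          horizon_cap_h = 1000) {
  kind <- match.arg(kind)
  strategy <- match.arg(strategy,
                        c("open-loop", "min-time-spontaneous",
                          "min-time-controllable",
                          "min-time-with-shift-light", "C-only-tuned",
                          "feedback", "transfer-S+C1", "transfer-S+C2"))
  if (is.null(delta_init))
    delta_init <- if (kind == "jetlag") 1 else 2
  if (I_shift < 0 || I_max <= 0) stop("lux values must be non-negative")
  if (kind == "shiftwork") {
    len <- (shift_end - shift_start) %% 24
    if (len <= 0 || len >= 24) stop("shift window must be within one night")
  }
  structure(list(kind = kind, delta_shift = delta_shift,
                 delta_init = delta_init, shift_start = shift_start,
                 shift_end = shift_end, I_shift = I_shift, I_max = I_max,
                 strategy = strategy, variant = variant, tol = tol,
                 dt = dt, bins_h = bins_h, horizon_cap_h = horizon_cap_h),
            class = "scenario_spec")
}

#' Run a jet-lag entrainment scenario
#'
#' The traveler starts entrained to the home time zone
#' (`y(0) = Y_REF(delta_shift + delta_init)`) and entrains to the
#' destination reference `y_ref(t) = Y_REF(t + delta_init)` under the
#' chosen strategy.
#'
#' @param spec a [scenario_spec()] of kind `"jetlag"`.
#' @param params a [two_process_params()] object.
#' @param cycle optional precomputed reference cycle.
#' @param controller a fitted [fit_feedback_controller()], required for
#'   the `"feedback"` strategy.
#' @param ... passed on to the strategy implementation.
#' @return A `scenario_report`: `t_f`, the strategy artefacts (light,
#'   schedule, trajectory when available) and the spec.
#' @export
run_jetlag <- function(spec, params = two_process_params(), cycle = NULL,
                       controller = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "jetlag")
  if (is.null(cycle))
    cycle <- compute_entrained_cycle("S+C3", params, dt = spec$dt)
  tspec <- terminal_spec("S+C3", spec$tol)
  y0 <- reference_state(spec$delta_shift, spec$delta_init, cycle)
  out <- switch(
    spec$strategy,
    "open-loop" = {
      r <- open_loop_entrain(y0, spec$delta_init, cycle, tspec, params,
                             horizon_cap = spec$horizon_cap_h,
                             dt = spec$dt)
      list(t_f = r$t_f, detail = r)
    },
    "min-time-spontaneous" = {
      r <- minimize_time_spontaneous(y0, spec$delta_init, cycle,
                                     spec$I_max, spec = tspec,
                                     params = params, bins_h = spec$bins_h,
                                     horizon_cap = spec$horizon_cap_h,
                                     dt = spec$dt, ...)
      list(t_f = r$t_f, detail = r)
    },
    "min-time-controllable" = {
      r <- minimize_time_controllable(y0, spec$delta_init, cycle,
                                      spec$I_max, spec = tspec,
                                      params = params,
                                      bins_h = spec$bins_h,
                                      horizon_cap = spec$horizon_cap_h,
                                      dt = spec$dt, ...)
      list(t_f = r$t_f, detail = r)
    },
    "C-only-tuned" = {
      ccyc <- compute_entrained_cycle("C-only", params, dt = spec$dt)
      yC <- reference_state(spec$delta_shift, spec$delta_init, ccyc)
      rC <- optimize_process_C_only(yC, spec$delta_init, spec$I_max,
                                    cycle = ccyc, params = params,
                                    bins_h = spec$bins_h, dt = spec$dt,
                                    ...)
      r <- entrain_with_tuned_sleep(rC$light, y0, spec$delta_init, cycle,
                                    tspec, params)
      list(t_f = r$t_f, detail = r, c_only = rC)
    },
    "feedback" = {
      if (is.null(controller))
        stop("the feedback strategy needs a fitted controller")
      r <- simulate_feedback(y0, spec$delta_init, cycle, controller,
                             tspec, params,
                             horizon_cap = spec$horizon_cap_h)
      list(t_f = r$t_f, detail = r)
    },
    "transfer-S+C1" = ,
    "transfer-S+C2" = {
      vr <- sub("transfer-", "", spec$strategy)
      prc <- if (vr == "S+C1") estimate_prc(params) else NULL
      rcyc <- compute_entrained_cycle(vr, params, dt = spec$dt, prc = prc)
      yr0 <- reference_state(spec$delta_shift, spec$delta_init, rcyc)
      rr <- minimize_time_controllable(yr0, spec$delta_init, rcyc,
                                       spec$I_max,
                                       spec = terminal_spec(vr, spec$tol),
                                       params = params,
                                       bins_h = spec$bins_h, prc = prc,
                                       horizon_cap = spec$horizon_cap_h,
                                       dt = spec$dt, ...)
      r <- transfer_reduced_solution(rr, y0, spec$delta_init, cycle,
                                     spec$I_max, tspec, params)
      list(t_f = r$t_f, detail = r, reduced = rr)
    })
  structure(c(out, list(spec = spec, y0 = y0, cycle_variant = "S+C3")),
            class = "scenario_report")
}

#' Run a shift-work recovery scenario
#'
#' The worker is entrained to the reference schedule, stays awake through
#' the night shift (light `I_shift`, or optimized for the
#' `"min-time-with-shift-light"` strategy), then entrains back from
#' `t = 0` (8 am, end of the shift) to the reference
#' `y_ref(t) = Y_REF(t + 2)`.  The reported `t_f` excludes the night
#' shift.
#'
#' @inheritParams run_jetlag
#' @param spec a [scenario_spec()] of kind `"shiftwork"`.
#' @return A `scenario_report`.
#' @export
run_shiftwork <- function(spec, params = two_process_params(),
                          cycle = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "shiftwork")
  if (is.null(cycle))
    cycle <- compute_entrained_cycle("S+C3", params, dt = spec$dt)
  tspec <- terminal_spec("S+C3", spec$tol)
  shift_len <- (spec$shift_end - spec$shift_start) %% 24
  t0 <- -shift_len                       # shift ends at t = 0 (8 am)
  y0 <- reference_state(t0, spec$delta_init, cycle)
  y0$beta <- 0L                          # on shift: awake
  prefix <- list(breakpoints = c(t0, 0), lux = spec$I_shift)
  out <- switch(
    spec$strategy,
    "open-loop" = {
      r <- open_loop_entrain(y0, spec$delta_init, cycle, tspec, params,
                             t0 = t0, force_wake_until = 0,
                             prefix = prefix, measure_from = 0,
                             horizon_cap = spec$horizon_cap_h,
                             dt = spec$dt)
      list(t_f = r$t_f, detail = r)
    },
    "min-time-spontaneous" = {
      r <- minimize_time_spontaneous(y0, spec$delta_init, cycle,
                                     spec$I_max, spec = tspec,
                                     params = params, bins_h = spec$bins_h,
                                     t0 = t0, force_wake_until = 0,
                                     prefix = prefix, measure_from = 0,
                                     horizon_cap = spec$horizon_cap_h,
                                     dt = spec$dt, ...)
      list(t_f = r$t_f, detail = r)
    },
    "min-time-controllable" = {
      r <- minimize_time_controllable(y0, spec$delta_init, cycle,
                                      spec$I_max, spec = tspec,
                                      params = params,
                                      bins_h = spec$bins_h,
                                      t0 = t0, force_wake_until = 0,
                                      prefix = prefix, measure_from = 0,
                                      horizon_cap = spec$horizon_cap_h,
                                      dt = spec$dt, ...)
      list(t_f = r$t_f, detail = r)
    },
    "min-time-with-shift-light" = {
      r <- minimize_time_controllable(y0, spec$delta_init, cycle,
                                      spec$I_max, spec = tspec,
                                      params = params,
                                      bins_h = spec$bins_h,
                                      t0 = t0, force_wake_until = 0,
                                      prefix = NULL, ctrl_start = t0,
                                      measure_from = 0,
                                      horizon_cap = spec$horizon_cap_h,
                                      dt = spec$dt, ...)
      list(t_f = r$t_f, detail = r)
    },
    stop(sprintf("strategy %s is not available for shift work",
                 spec$strategy)))
  structure(c(out, list(spec = spec, y0 = y0, cycle_variant = "S+C3")),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<%s scenario, strategy %s>\n", x$spec$kind,
              x$spec$strategy))
  cat(sprintf("  entrainment time t_f = %.2f h\n", x$t_f))
  invisible(x)
}

#' Export a scenario report to CSV/JSON files
#'
#' Writes the trajectory (`trajectory.csv`: time, clock time, states,
#' sleepiness, sleep state, light, drive), the switch schedule
#' (`schedule.csv`) and a summary (`summary.json`).
#'
#' @param report a `scenario_report` (or any list with `t_f`, `spec` and
#'   optionally a `tp_trajectory` under `detail$trajectory`).
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  traj <- NULL
  if (inherits(report$detail, "tp_trajectory")) traj <- report$detail
  if (!is.null(report$detail$trajectory) &&
      inherits(report$detail$trajectory, "tp_trajectory"))
    traj <- report$detail$trajectory
  tcsv <- file.path(dir, "trajectory.csv")
  if (!is.null(traj)) {
    df <- data.frame(t_h = traj$times,
                     clock_time = clock_str(traj$times +
                                              report$spec$delta_init),
                     traj$states)
    df <- cbind(df, B = traj$B, beta = traj$beta, I_lux = traj$I,
                u = traj$u)
    write.csv(df, tcsv, row.names = FALSE)
    scsv <- file.path(dir, "schedule.csv")
    write.csv(traj$switch_events, scsv, row.names = FALSE)
    paths <- c(paths, tcsv, scsv)
  } else {
    write.csv(data.frame(t_h = numeric(0), clock_time = character(0)),
              tcsv, row.names = FALSE)
    paths <- c(paths, tcsv)
  }
  sjson <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(kind = "scenario_summary", t_f = report$t_f,
         strategy = report$spec$strategy,
         scenario = unclass(report$spec)),
    sjson, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, sjson)
  invisible(paths)
}

#' Serialize an optimization result to JSON and its light schedule to CSV
#'
#' @param res an `entrain_optim`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_optim_result <- function(res, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(res, "entrain_optim"))
  if (!is.null(json_path)) {
    sched <- if (inherits(res$schedule, "sleep_schedule")) {
      list(T_sleep = res$schedule$T_sleep, T_wake = res$schedule$T_wake)
    } else {
      "spontaneous"
    }
    jsonlite::write_json(
      list(kind = "entrain_optim", variant = res$variant, t_f = res$t_f,
           t_open = res$t_open, residual = res$residual,
           bang_off = res$bang_off, I_max = res$I_max,
           delta_init = res$delta_init,
           light = if (is.null(res$light)) NULL else
             list(breakpoints = res$light$breakpoints,
                  levels = res$light$levels),
           schedule = sched),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path) && !is.null(res$light)) {
    bp <- res$light$breakpoints
    write.csv(data.frame(time_start_h = head(bp, -1),
                         time_end_h = tail(bp, -1),
                         lux = res$light$levels),
              csv_path, row.names = FALSE)
  }
  invisible(res)
}
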