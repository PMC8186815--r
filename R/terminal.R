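#' Terminal condition for entrainment
#'
#' Entrainment is declared once the squared Euclidean distance between the
#' compared state components and the reference trajectory drops below
#' `tol`.  The fast retinal state `n` is excluded for the full model; the
#' phase-reduced model compares `(theta, H)` with the angular difference
#' wrapped to `(-pi, pi]`; the circadian-only model compares `(x, xc)`.
#'
#' @param variant model variant.
#' @param tol terminal tolerance on the squared norm (dimensionless).
#' @return An object of class `terminal_spec`.
#' @export
terminal_spec <- function(variant = c("S+C3", "S+C2", "S+C1", "C-only"),
                          tol = 0.01) {
  variant <- match.arg(variant)
  if (tol <= 0) stop("tol must be positive")
  comps <- switch(variant,
                  "S+C3" = c("x", "xc", "H"),
                  "S+C2" = c("x", "xc", "H"),
                  "S+C1" = c("theta", "H"),
                  "C-only" = c("x", "xc"))
  structure(list(variant = variant, tol = tol, components = comps),
            class = "terminal_spec")
}

#' Terminal residual of a state against the reference
#'
#' `sum((z - z_ref)^2) - tol` over the compared components, where `z_ref`
#' is the reference trajectory at `(t + delta_init) mod 24`.  Non-positive
#' values mean the terminal condition holds.
#'
#' @param state a [two_process_state()].
#' @param t current time (h).
#' @param delta_init reference clock offset (h).
#' @param cycle the matching [compute_entrained_cycle()] result.
#' @param spec a [terminal_spec()].
#' @return Scalar residual (dimensionless).
#' @export
terminal_residual <- function(state, t, delta_init, cycle, spec) {
  stopifnot(inherits(state, "two_process_state"),
            inherits(spec, "terminal_spec"),
            state$variant == spec$variant,
            cycle$variant == spec$variant)
  zref <- reference_terminal_vec(cycle, t + delta_init)
  z <- unname(state$y[spec$components])
  d <- z - zref
  if (spec$variant == "S+C1") d[1] <- wrap_pi(d[1])
  sum(d^2) - spec$tol
}

# vectorized residual along a trajectory (times x states matrix)
residual_series <- function(times, Y, variant, delta_init, cycle, spec) {
  tm <- (times + delta_init) %% 24
  if (variant == "S+C1") {
    dth <- wrap_pi(Y[, "theta"] -
                     approx(cycle$grid, cycle$Y[, "theta"], xout = tm)$y)
    dH <- Y[, "H"] - approx(cycle$grid, cycle$Y[, "H"], xout = tm)$y
    dth^2 + dH^2 - spec$tol
  } else {
    comps <- spec$components
    r <- rep(-spec$tol, length(times))
    for (nm in comps) {
      d <- Y[, nm] - approx(cycle$grid, cycle$Y[, nm], xout = tm)$y
      r <- r + d^2
    }
    r
  }
}

# first time a residual series crosses <= 0, linearly interpolated;
# NA when it never does
first_crossing <- function(times, resid) {
  ok <- resid <= 0
  if (!any(ok)) return(NA_real_)
  i <- which(ok)[1]
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  r0 <- resid[i - 1]; r1 <- resid[i]
  if (r0 == r1) return(t1)
  t0 + (0 - r0) / (r1 - r0) * (t1 - t0)
}
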