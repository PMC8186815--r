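#' Piecewise-constant light schedule
#'
#' A light schedule is a step function of time: `levels[i]` lux on
#' `[breakpoints[i], breakpoints[i+1])`.  All levels must lie in
#' `[0, I_max]`.
#'
#' @param breakpoints strictly increasing times (h), length `n + 1`.
#' @param levels light intensity per interval (lux), length `n`.
#' @param I_max upper bound of the light intensity (lux).
#' @return An object of class `light_signal`.
#' @examples
#' ls <- light_signal(c(0, 16, 24), c(1000, 0), I_max = 1000)
#' light_at(ls, c(8, 20))
#' @export
light_signal <- function(breakpoints, levels, I_max = 10000) {
  breakpoints <- as.numeric(breakpoints)
  levels <- as.numeric(levels)
  if (length(breakpoints) != length(levels) + 1L)
    stop("need length(breakpoints) == length(levels) + 1")
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (any(!is.finite(levels)) || any(levels < 0) || any(levels > I_max))
    stop("light levels must lie in [0, I_max]")
  structure(list(breakpoints = breakpoints, levels = levels, I_max = I_max),
            class = "light_signal")
}

#' Evaluate a light schedule
#'
#' @param light a [light_signal()].
#' @param t times (h); outside the covered range the boundary level holds.
#' @return Light intensity in lux at each `t`.
#' @export
light_at <- function(light, t) {
  stopifnot(inherits(light, "light_signal"))
  idx <- findInterval(t, light$breakpoints, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(light$levels))
  light$levels[idx]
}

#' @export
print.light_signal <- function(x, ...) {
  cat(sprintf("Light schedule: %d intervals on [%.2f, %.2f] h, I_max = %g lux\n",
              length(x$levels), x$breakpoints[1],
              x$breakpoints[length(x$breakpoints)], x$I_max))
  on <- x$levels > 0
  cat(sprintf("  light on for %.2f h total\n",
              sum(diff(x$breakpoints)[on])))
  invisible(x)
}

# -- conversions between lux and the internal control unit ------------------
# The engine integrates in "drive units": the retinal activation rate
# alpha = alpha0 * (I/I0)^p for the full model, or the steady-state drive
# u = G*gamma*alpha/(alpha+gamma) for the reduced models.  Both are strictly
# monotone in I, so schedules map 1:1.

lux_to_alpha <- function(I, params) {
  params$alpha0 * (pmax(I, 0) / params$I0)^params$p
}

alpha_to_lux <- function(alpha, params) {
  params$I0 * (pmax(alpha, 0) / params$alpha0)^(1 / params$p)
}

lux_to_u <- function(I, params) {
  a <- lux_to_alpha(I, params)
  params$G * params$gamma * a / (a + params$gamma)
}

u_to_lux <- function(u, params) {
  u <- pmax(u, 0)
  umax_sup <- params$G * params$gamma    # supremum of u as I -> Inf
  if (any(u >= umax_sup))
    stop("drive u out of the reachable range of the light dose-response")
  a <- params$gamma * u / (params$G * params$gamma - u)
  alpha_to_lux(a, params)
}

# internal control levels for a lux schedule under a given variant
light_to_control <- function(light, variant, params) {
  if (variant %in% c("S+C3", "C-only")) {
    lux_to_alpha(light$levels, params)
  } else {
    lux_to_u(light$levels, params)
  }
}
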