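#' Model parameters for the two-process sleep/circadian models
#'
#' Builds the full parameter set shared by all model variants: the retinal
#' light-transduction stage (Process L), the core body temperature
#' oscillator (Process P), the exponential sleep homeostat (Process S) and
#' the sleepiness automaton thresholds.  Defaults are the published values
#' for the Jewett-Forger-Kronauer model and Achermann's two-process model.
#'
#' @param alpha0 maximal retinal activation rate at `I = I0` (1/h).
#' @param gamma recovery rate of used photoreceptors (1/h).
#' @param I0 light intensity scale (lux).
#' @param G gain from retinal drive to circadian drive (dimensionless).
#' @param p compressive exponent of the light dose-response (dimensionless).
#' @param mu stiffness of the van der Pol-type temperature oscillator (1/h).
#' @param q,k,k_c coupling coefficients of the oscillator's light
#'   modulation (dimensionless, 1/h and h respectively).
#' @param tau_x intrinsic period of the temperature oscillator (h).
#' @param omega0 free-running angular frequency used by the phase-reduced
#'   model (rad/h); defaults to `2*pi/tau_x`.
#' @param tau_r time constant of homeostat rise while awake (h).
#' @param tau_d time constant of homeostat decay while asleep (h).
#' @param H_m sleepiness threshold for spontaneous sleep onset.
#' @param L_m sleepiness threshold for spontaneous waking.
#' @param A_c amplitude of the circadian contribution to sleepiness.
#' @param B1_max upper sleepiness bound allowed at a scheduled sleep onset.
#' @param B2_max upper sleepiness bound allowed at a scheduled wake time.
#'
#' @return An object of class `tp_params`: a named list of validated
#'   parameter values.
#' @examples
#' p <- two_process_params()
#' p$tau_r
#' @export
two_process_params <- function(alpha0 = 0.05, gamma = 0.0075, I0 = 9500,
                               G = 33.75, p = 0.5, mu = 0.13, q = 1 / 3,
                               tau_x = 24.2, k = 0.55, k_c = 0.4,
                               omega0 = 2 * pi / 24.2,
                               tau_r = 18.2, tau_d = 4.2,
                               H_m = 0.67, L_m = 0.17, A_c = 0.1333,
                               B1_max = 0.77, B2_max = 0.27) {
  prm <- list(alpha0 = alpha0, gamma = gamma, I0 = I0, G = G, p = p,
              mu = mu, q = q, tau_x = tau_x, k = k, k_c = k_c,
              omega0 = omega0, tau_r = tau_r, tau_d = tau_d,
              H_m = H_m, L_m = L_m, A_c = A_c,
              B1_max = B1_max, B2_max = B2_max)
  vals <- unlist(prm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all two-process parameters must be finite and strictly positive")
  if (L_m >= H_m) stop("L_m must be smaller than H_m")
  if (H_m > B1_max) stop("H_m must not exceed B1_max")
  if (L_m > B2_max) stop("L_m must not exceed B2_max")
  structure(prm, class = "tp_params")
}

#' @export
print.tp_params <- function(x, ...) {
  cat("Two-process model parameters:\n")
  print(unlist(x))
  invisible(x)
}

# parameter vector in the fixed order the compiled engine expects
pars_vec <- function(params) {
  stopifnot(inherits(params, "tp_params"))
  as.numeric(unlist(params[c("alpha0", "gamma", "I0", "G", "p", "mu", "q",
                             "tau_x", "k", "k_c", "omega0", "tau_r",
                             "tau_d", "H_m", "L_m", "A_c",
                             "B1_max", "B2_max")]))
}

variant_code <- function(variant) {
  switch(match.arg(variant, c("S+C3", "S+C2", "S+C1", "C-only")),
         "S+C3" = 3L, "S+C2" = 2L, "S+C1" = 1L, "C-only" = 0L)
}

variant_dim <- function(variant) {
  c("S+C3" = 4L, "S+C2" = 3L, "S+C1" = 2L, "C-only" = 3L)[[variant]]
}

variant_state_names <- function(variant) {
  switch(variant,
         "S+C3" = c("n", "x", "xc", "H"),
         "S+C2" = c("x", "xc", "H"),
         "S+C1" = c("theta", "H"),
         "C-only" = c("n", "x", "xc"))
}
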