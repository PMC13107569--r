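#' Kinetic parameters for one motor species
#'
#' Bundles the transport and binding kinetics of a single depolymerizing
#' motor species moving along (or diffusing about) a microtubule. The
#' plus-end-directed species models a slow, processive kinesin-8; the
#' minus-end-directed species models a diffusive kinesin-13, which uses a
#' one-dimensional random walk on the lattice rather than directed stepping
#' (so its `v` may be 0).
#'
#' @param direction `"plus"` or `"minus"`: which filament end the species
#'   depolymerizes.
#' @param v Walking speed on the microtubule (um/s, >= 0).
#' @param D_on Diffusivity while bound to the microtubule (um^2/s, >= 0).
#' @param D_off Cytoplasmic diffusivity while unbound (um^2/s, > 0).
#' @param k_on Binding rate to the microtubule (1/s, > 0).
#' @param k_off Unbinding rate from the microtubule (1/s, > 0).
#'
#' @return An object of class `mt_motor_params`.
#' @seealso [default_params()], [effective_parameters()]
#' @export
motor_params <- function(direction = c("plus", "minus"),
                         v, D_on, D_off, k_on, k_off) {
  direction <- match.arg(direction)
  x <- list(direction = direction, v = as.numeric(v),
            D_on = as.numeric(D_on), D_off = as.numeric(D_off),
            k_on = as.numeric(k_on), k_off = as.numeric(k_off))
  class(x) <- "mt_motor_params"
  x
}

#' Tip-dynamics parameters
#'
#' Rates entering the equations of motion for the two microtubule tips:
#' \deqn{dL_+/dt = \alpha_+ - \beta_+ L - \gamma_+ p(L_+),\qquad
#'       dL_-/dt = -\alpha_- + \beta_- L + \gamma_- m(L_-),}
#' where `L` is the filament length and `p`, `m` are the bound motor
#' densities at the respective tip. The `alpha` terms are intrinsic
#' polymerization speeds, the `beta` terms length-dependent disassembly
#' (ragged-protofilament/catastrophe effects folded into an effective
#' rate), and the `gamma` terms motor-driven depolymerization.
#'
#' @param alpha_plus,alpha_minus Intrinsic growth speeds (um/s, >= 0).
#' @param beta_plus,beta_minus Length-dependent disassembly rates (1/s, >= 0).
#' @param gamma_plus,gamma_minus Motor-driven shrinking coefficients
#'   (um/s per unit normalized motor density, >= 0).
#'
#' @return An object of class `mt_tip_params`.
#' @export
tip_params <- function(alpha_plus, alpha_minus, beta_plus, beta_minus,
                       gamma_plus, gamma_minus) {
  x <- list(alpha_plus = as.numeric(alpha_plus),
            alpha_minus = as.numeric(alpha_minus),
            beta_plus = as.numeric(beta_plus),
            beta_minus = as.numeric(beta_minus),
            gamma_plus = as.numeric(gamma_plus),
            gamma_minus = as.numeric(gamma_minus))
  class(x) <- "mt_tip_params"
  x
}

#' Full model parameter set
#'
#' @param plus_motor,minus_motor [motor_params()] objects with opposite
#'   directionality.
#' @param tips A [tip_params()] object.
#'
#' @return An object of class `mt_params`.
#' @export
mt_params <- function(plus_motor, minus_motor, tips) {
  stopifnot(inherits(plus_motor, "mt_motor_params"),
            inherits(minus_motor, "mt_motor_params"),
            inherits(tips, "mt_tip_params"))
  x <- list(plus_motor = plus_motor, minus_motor = minus_motor, tips = tips)
  class(x) <- "mt_params"
  x
}

#' Baseline parameter set from published motor and microtubule measurements
#'
#' Returns the literature-derived baseline used throughout: a slow,
#' processive plus-end depolymerase (kinesin-8 type: v = 0.05 um/s,
#' D_on = 0.01 um^2/s, k_off = 0.25/s) and a purely diffusive minus-end
#' depolymerase (kinesin-13 type: v = 0, D_on = 0.38 um^2/s), both with
#' cytoplasmic diffusivity 4 um^2/s and binding rate 1/s; tip rates
#' alpha_plus = 0.15, alpha_minus = 0.02 um/s, beta_plus = 0.05,
#' beta_minus = 0.0006 1/s, gamma_plus = gamma_minus = 0.01. Densities are
#' nondimensional, normalized so the boundary reservoir density is 1;
#' gamma therefore carries units um/s per unit normalized density.
#'
#' Published unbinding rates for the diffusive minus-end species span
#' 1.2--3 /s; the default takes the lower bound (longest-lived on the
#' lattice) and is configurable via `k_off_minus`.
#'
#' @param k_off_minus Unbinding rate of the minus-end-directed species
#'   (1/s); default 1.2.
#'
#' @return An [mt_params()] object.
#' @export
#' @examples
#' p <- default_params()
#' p$plus_motor$v          # 0.05 um/s
#' p$minus_motor$D_on      # 0.38 um^2/s
default_params <- function(k_off_minus = 1.2) {
  mt_params(
    plus_motor = motor_params("plus", v = 0.05, D_on = 0.01, D_off = 4,
                              k_on = 1, k_off = 0.25),
    minus_motor = motor_params("minus", v = 0, D_on = 0.38, D_off = 4,
                               k_on = 1, k_off = k_off_minus),
    tips = tip_params(alpha_plus = 0.15, alpha_minus = 0.02,
                      beta_plus = 0.05, beta_minus = 0.0006,
                      gamma_plus = 0.01, gamma_minus = 0.01)
  )
}

.check_field <- function(value, name, positive = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("invalid-parameter: ", name, " must be a finite number", call. = FALSE)
  if (positive && value <= 0)
    stop("invalid-parameter: ", name, " must be > 0", call. = FALSE)
  if (!positive && value < 0)
    stop("invalid-parameter: ", name, " must be >= 0", call. = FALSE)
  invisible(value)
}

.validate_motor <- function(m, label) {
  .check_field(m$v, paste0(label, "$v"))
  .check_field(m$D_on, paste0(label, "$D_on"))
  .check_field(m$D_off, paste0(label, "$D_off"), positive = TRUE)
  .check_field(m$k_on, paste0(label, "$k_on"), positive = TRUE)
  .check_field(m$k_off, paste0(label, "$k_off"), positive = TRUE)
  invisible(m)
}

#' Validate a model parameter set
#'
#' Checks all sign and finiteness invariants, failing with an error that
#' names the offending field. Additionally warns (without failing) when
#' the parameters leave the regime assumed by the fast-switching
#' reduction, i.e. when a motor's binding/unbinding rates are not large
#' compared with its transport rates `v / L` and `D / L^2` on a filament
#' of reference length `L0`.
#'
#' @param params An [mt_params()] object.
#' @param L0 Reference filament length (um) used for the timescale
#'   comparison; default 10.
#'
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_params <- function(params, L0 = 10) {
  if (!inherits(params, "mt_params"))
    stop("invalid-parameter: expected an 'mt_params' object", call. = FALSE)
  .validate_motor(params$plus_motor, "plus_motor")
  .validate_motor(params$minus_motor, "minus_motor")
  if (identical(params$plus_motor$direction, params$minus_motor$direction))
    stop("invalid-parameter: plus_motor and minus_motor must have opposite direction",
         call. = FALSE)
  tp <- params$tips
  for (nm in names(unclass(tp)))
    .check_field(tp[[nm]], paste0("tips$", nm))
  for (side in c("plus_motor", "minus_motor")) {
    m <- params[[side]]
    transport <- max(m$v / L0, m$D_on / L0^2, m$D_off / L0^2)
    if (min(m$k_on, m$k_off) < transport)
      warning("slow-switching: ", side, " binding kinetics (min k = ",
              signif(min(m$k_on, m$k_off), 3),
              "/s) are not fast relative to transport (", signif(transport, 3),
              "/s at L0 = ", L0, " um); fast-switching reduction may be inaccurate",
              call. = FALSE)
  }
  invisible(params)
}

#' Intrinsic growth rate from a maximal measured growth speed
#'
#' When polymerization at a tip is driven entirely by intrinsic growth
#' (`dL/dt = alpha`), the intrinsic rate equals the maximal measured
#' growth speed; this converts a speed reported per minute to the
#' per-second units used by the model.
#'
#' @param v_g_max Maximal tip growth speed (um/min, >= 0).
#' @return Intrinsic growth speed alpha (um/s).
#' @export
#' @examples
#' alpha_from_max_growth(9)      # 0.15 um/s
#' alpha_from_max_growth(1.125)  # 0.01875 um/s
alpha_from_max_growth <- function(v_g_max) {
  .check_field(v_g_max, "v_g_max")
  v_g_max / 60
}

#' Length-dependent disassembly rate from an average growth speed
#'
#' Under intrinsic growth opposed only by length-dependent disassembly,
#' `dL/dt = alpha - beta * L`. Estimating the average measured growth
#' speed `v_g_avg` as `dL/dt` at a characteristic length `L_bar` gives
#' `beta = (alpha - v_g_avg / 60) / L_bar`. The conversion is exact
#' rational arithmetic; no rounding is applied.
#'
#' @param v_g_avg Average tip growth speed (um/min, >= 0).
#' @param alpha Intrinsic growth speed (um/s) for the same tip.
#' @param L_bar Characteristic filament length (um, > 0); default 10.
#' @return Disassembly rate beta (1/s). Warns if the implied beta is
#'   negative (average speed exceeding the intrinsic maximum).
#' @export
#' @examples
#' beta_from_avg_growth(0.75, 0.01875, 10)  # 0.000625 /s
beta_from_avg_growth <- function(v_g_avg, alpha, L_bar = 10) {
  .check_field(v_g_avg, "v_g_avg")
  .check_field(alpha, "alpha")
  if (!is.numeric(L_bar) || length(L_bar) != 1L || !is.finite(L_bar) || L_bar <= 0)
    stop("invalid-parameter: L_bar must be > 0", call. = FALSE)
  beta <- (alpha - v_g_avg / 60) / L_bar
  if (beta < 0)
    warning("average growth speed exceeds 60*alpha; implied beta is negative",
            call. = FALSE)
  beta
}

#' Scenario definition
#'
#' A scenario pairs a parameter set with an initial length, a horizon and
#' an initial-density mode; it is the unit of work for [simulate_full()]
#' and [simulate_reduced_pde()].
#'
#' @param params An [mt_params()] object.
#' @param L0 Initial filament length (um, > 0); default the 10 um
#'   characteristic length of microtubules in larval sensory neurons.
#' @param t_end Simulation horizon (s, > 0).
#' @param name Scenario label.
#' @param ic_mode Initial motor densities: `"uniform-one"` (all fields at
#'   the reservoir value 1) or `"zero-interior"` (zero away from
#'   boundaries).
#'
#' @return An object of class `mt_scenario`.
#' @export
scenario_config <- function(params = default_params(), L0 = 10, t_end = 300,
                            name = "custom",
                            ic_mode = c("uniform-one", "zero-interior")) {
  ic_mode <- match.arg(ic_mode)
  .check_field(L0, "L0", positive = TRUE)
  .check_field(t_end, "t_end", positive = TRUE)
  validate_params(params, L0 = L0)
  x <- list(name = name, params = params, L0 = as.numeric(L0),
            t_end = as.numeric(t_end), ic_mode = ic_mode)
  class(x) <- "mt_scenario"
  x
}

#' @export
print.mt_motor_params <- function(x, ...) {
  cat(sprintf("Motor species (%s-end-directed):\n", x$direction))
  cat(sprintf("  v = %g um/s, D_on = %g um^2/s, D_off = %g um^2/s\n",
              x$v, x$D_on, x$D_off))
  cat(sprintf("  k_on = %g /s, k_off = %g /s  (duty ratio %.3g)\n",
              x$k_on, x$k_off, x$k_on / (x$k_on + x$k_off)))
  invisible(x)
}

#' @export
print.mt_tip_params <- function(x, ...) {
  cat("Tip dynamics:\n")
  cat(sprintf("  (+) end: alpha = %g um/s, beta = %g /s, gamma = %g um/s\n",
              x$alpha_plus, x$beta_plus, x$gamma_plus))
  cat(sprintf("  (-) end: alpha = %g um/s, beta = %g /s, gamma = %g um/s\n",
              x$alpha_minus, x$beta_minus, x$gamma_minus))
  invisible(x)
}

#' @export
print.mt_params <- function(x, ...) {
  print(x$plus_motor); print(x$minus_motor); print(x$tips)
  invisible(x)
}

#' @export
print.mt_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': L0 = %g um, t_end = %g s, ic = %s\n",
              x$name, x$L0, x$t_end, x$ic_mode))
  print(x$params)
  invisible(x)
}
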