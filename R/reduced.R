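#' Effective transport coefficients in the fast-switching limit
#'
#' When binding and unbinding are fast relative to transport, the bound
#' and unbound populations of a motor species equilibrate to the duty
#' ratio `k_on / (k_on + k_off)` at every point, and the total density
#' obeys a single advection--diffusion equation with kinetics-averaged
#' coefficients:
#' \deqn{V = \frac{k_{on}}{k_{on}+k_{off}} v, \qquad
#'       D_{eff} = \frac{k_{on}}{k_{on}+k_{off}} D_{on}
#'               + \frac{k_{off}}{k_{on}+k_{off}} D_{off}.}
#'
#' @param motor A [motor_params()] object.
#' @return A list with components `V` (effective velocity, um/s) and
#'   `D_eff` (effective diffusivity, um^2/s).
#' @export
#' @examples
#' effective_parameters(default_params()$plus_motor)  # V = 0.04, D_eff = 0.808
effective_parameters <- function(motor) {
  ktot <- motor$k_on + motor$k_off
  if (!is.finite(ktot) || ktot <= 0)
    stop("invalid-parameter: k_on + k_off must be > 0", call. = FALSE)
  duty <- motor$k_on / ktot
  list(V = duty * motor$v,
       D_eff = duty * motor$D_on + (1 - duty) * motor$D_off)
}

#' Assemble reduced-model effective parameters for both motor species
#'
#' Applies [effective_parameters()] to the plus- and minus-end-directed
#' species. The minus species is purely diffusive in the reduction (its
#' effective velocity is dropped), so only `V_plus`, `D_plus` and
#' `D_minus` enter the two-field reduced PDE.
#'
#' @param params An [mt_params()] object.
#' @return An object of class `mt_effective` with fields `V_plus`,
#'   `D_plus`, `D_minus`.
#' @export
effective_params <- function(params) {
  ep <- effective_parameters(params$plus_motor)
  em <- effective_parameters(params$minus_motor)
  x <- list(V_plus = ep$V, D_plus = ep$D_eff, D_minus = em$D_eff)
  class(x) <- "mt_effective"
  x
}

#' @export
print.mt_effective <- function(x, ...) {
  cat(sprintf("Effective transport coefficients (fast-switching limit):\n"))
  cat(sprintf("  V_plus = %g um/s, D_plus = %g um^2/s, D_minus = %g um^2/s\n",
              x$V_plus, x$D_plus, x$D_minus))
  invisible(x)
}

#' Steady plus-motor profile of the reduced model
#'
#' Closed-form steady state of the effective advection--diffusion
#' equation for the total plus-motor density with a unit reservoir at the
#' minus end:
#' \deqn{q(x) = (1 + 1/V)\, e^{(V/D)(x - L_-)} - 1/V.}
#' The profile is strictly increasing in `x` — longer filaments collect
#' more depolymerase at the plus tip (the antenna mechanism). This is the
#' canonical profile used inside [adiabatic_length_flow()]; it coincides
#' with the general Robin-data solution [steady_profile_robin()] at
#' flux value -1 (see that help page for the sign discussion).
#'
#' @param x Position(s) (um), `x >= L_minus`.
#' @param L_minus Minus-tip position (um).
#' @param eff An [effective_params()] object with `V_plus > 0`,
#'   `D_plus > 0`.
#' @return Density value(s) at `x` (dimensionless).
#' @export
steady_profile_plus <- function(x, L_minus, eff) {
  V <- eff$V_plus; D <- eff$D_plus
  if (!is.finite(V) || V <= 0)
    stop("degenerate-profile: V_plus must be > 0 (see steady_profile_robin for V = 0)",
         call. = FALSE)
  if (!is.finite(D) || D <= 0)
    stop("degenerate-profile: D_plus must be > 0", call. = FALSE)
  (1 + 1 / V) * exp(V / D * (x - L_minus)) - 1 / V
}

#' Steady minus-motor profile of the reduced model
#'
#' The minus-end-directed species is purely diffusive in the reduction;
#' with a unit Dirichlet reservoir at the plus end and a Robin condition
#' at the minus end, its steady state is spatially uniform at the
#' reservoir value.
#'
#' @param x Position(s) (um); only the shape of the return value depends
#'   on it.
#' @return `1` at every position.
#' @export
steady_profile_minus <- function(x = 0) {
  rep(1, length(x))
}

#' Steady plus-motor profile for general Robin flux data
#'
#' Solves the steady effective advection--diffusion problem
#' `-V q' + D q'' = 0` with `q(L_minus) = 1` and the plus-end flux
#' condition `V q(L_plus) - D q'(L_plus) = s` for arbitrary `s`, giving
#' \deqn{q(x) = (1 - s/V)\, e^{(V/D)(x - L_-)} + s/V} (independent of
#' `L_plus`, since the exponential satisfies the flux condition
#' identically). The canonical printed profile [steady_profile_plus()]
#' equals this solution with `s = -1`; the solution consistent with the
#' reduced PDE's `+1` flux condition is obtained with `s = 1`. Both are
#' provided so the sign discrepancy can be examined rather than silently
#' resolved.
#'
#' @param x Position(s) (um).
#' @param L_minus Minus-tip position (um).
#' @param eff An [effective_params()] object.
#' @param flux_value Right-hand side `s` of the plus-end flux condition.
#' @return Density value(s) at `x`.
#' @export
steady_profile_robin <- function(x, L_minus, eff, flux_value = 1) {
  V <- eff$V_plus; D <- eff$D_plus
  if (!is.finite(D) || D <= 0)
    stop("degenerate-profile: D_plus must be > 0", call. = FALSE)
  if (V == 0) {
    # pure diffusion: q'' = 0 with q(L_-) = 1 and -D q'(L_+) = s
    return(1 - flux_value / D * (x - L_minus))
  }
  (1 - flux_value / V) * exp(V / D * (x - L_minus)) + flux_value / V
}

#' Adiabatic length flow
#'
#' When motor fields equilibrate fast relative to tip motion, the steady
#' profiles can be substituted into the tip equations and the filament
#' length obeys the scalar flow
#' \deqn{dL/dt = (\alpha_+ + \alpha_-) - (\beta_+ + \beta_-) L
#'       - \gamma_+\left[(1 + 1/V)e^{(V/D)L} - 1/V\right] - \gamma_-.}
#' Equivalently `dL/dt = f(L) - g(L)` with `f` the affine gain term and
#' `g` the strictly increasing motor-loss term; see
#' [equilibrium_length()].
#'
#' @param L Filament length(s) (um, >= 0).
#' @param tips A [tip_params()] object.
#' @param eff An [effective_params()] object with positive `V_plus`,
#'   `D_plus`.
#' @return `dL/dt` (um/s), vectorized over `L`.
#' @export
adiabatic_length_flow <- function(L, tips, eff) {
  if (any(!is.finite(L)) || any(L < 0))
    stop("invalid-state: L must be finite and >= 0", call. = FALSE)
  expo <- eff$V_plus / eff$D_plus * L
  if (any(expo > 700))
    stop("out-of-range: exponential overflow; length beyond modeled regime",
         call. = FALSE)
  q_plus <- steady_profile_plus(L, 0, eff)
  (tips$alpha_plus + tips$alpha_minus) -
    (tips$beta_plus + tips$beta_minus) * L -
    tips$gamma_plus * q_plus - tips$gamma_minus
}

#' Adiabatic tip velocities
#'
#' Individual tip velocities under the adiabatic approximation, using the
#' steady motor profiles (`q` at the plus tip, `h = 1` at the minus tip):
#' \deqn{dL_+/dt = \alpha_+ - \beta_+ L - \gamma_+ q(L_+),\qquad
#'       dL_-/dt = -\alpha_- + \beta_- L + \gamma_-.}
#' Their difference equals [adiabatic_length_flow()] identically.
#'
#' @inheritParams adiabatic_length_flow
#' @return A list with components `dL_plus` and `dL_minus` (um/s).
#' @export
adiabatic_tip_velocities <- function(L, tips, eff) {
  q_plus <- steady_profile_plus(L, 0, eff)
  list(dL_plus = tips$alpha_plus - tips$beta_plus * L - tips$gamma_plus * q_plus,
       dL_minus = -tips$alpha_minus + tips$beta_minus * L + tips$gamma_minus)
}

#' Equilibrium length of the adiabatic flow
#'
#' Writes the flow as `dL/dt = f(L) - g(L)` with
#' `f(L) = (alpha_+ + alpha_-) - (beta_+ + beta_-) L` strictly decreasing
#' and `g(L) = gamma_+ q(L) + gamma_-` strictly increasing. A positive
#' equilibrium exists iff `f(0) > g(0)`, i.e.
#' `alpha_+ + alpha_- > gamma_+ + gamma_-`, and is then unique. The root
#' is located by bracketed search (the upper bracket expanded
#' geometrically until the flow is negative) and polished by Newton
#' iterations with the analytic flow derivative.
#'
#' A generic equilibrium is a treadmilling state: the length is constant
#' while both tips move at a common nonzero speed. Truly fixed ends
#' additionally require the nullcline-coincidence condition measured by
#' [fixed_end_residual()].
#'
#' @param tips A [tip_params()] object.
#' @param eff An [effective_params()] object.
#' @return An object of class `mt_equilibrium`: a list with `exists`,
#'   `L_dagger` (um, `NA` if no equilibrium), `L_star` (motor-free
#'   equilibrium `(alpha_+ + alpha_-) / (beta_+ + beta_-)`, `NA` if the
#'   betas vanish), `tip_velocities_at_eq` (um/s), and
#'   `fixed_end_residual` (um; `NA` when undefined).
#' @export
equilibrium_length <- function(tips, eff) {
  for (nm in names(unclass(tips)))
    .check_field(tips[[nm]], paste0("tips$", nm))
  a <- tips$alpha_plus + tips$alpha_minus
  g0 <- tips$gamma_plus + tips$gamma_minus
  btot <- tips$beta_plus + tips$beta_minus
  L_star <- if (btot > 0) a / btot else NA_real_
  res <- tryCatch(fixed_end_residual(tips, eff), error = function(e) NA_real_)
  out <- list(exists = a > g0, L_dagger = NA_real_, L_star = L_star,
              tip_velocities_at_eq = NULL, fixed_end_residual = res,
              tips = tips, eff = eff)
  class(out) <- "mt_equilibrium"
  if (!out$exists) return(out)

  flow <- function(L) adiabatic_length_flow(L, tips, eff)
  upper <- if (is.finite(L_star) && L_star > 0) L_star else 1
  it <- 0
  while (flow(upper) > 0) {
    upper <- upper * 2
    it <- it + 1
    if (it > 60) stop("numerical-failure: could not bracket the equilibrium",
                      call. = FALSE)
  }
  L <- stats::uniroot(flow, c(0, upper), tol = 1e-12)$root
  # Newton polish with the analytic derivative of the flow
  V <- eff$V_plus; D <- eff$D_plus
  dflow <- function(L) -btot - tips$gamma_plus * (1 + 1 / V) * (V / D) * exp(V / D * L)
  for (i in 1:8) {
    step <- flow(L) / dflow(L)
    if (!is.finite(step)) break
    L <- L - step
    if (abs(step) < 1e-15 * max(1, L)) break
  }
  out$L_dagger <- L
  out$tip_velocities_at_eq <- adiabatic_tip_velocities(L, tips, eff)
  out
}

#' @export
print.mt_equilibrium <- function(x, ...) {
  if (!x$exists) {
    cat("No positive equilibrium: alpha_+ + alpha_- <= gamma_+ + gamma_- (filament shrinks)\n")
  } else {
    tv <- x$tip_velocities_at_eq
    cat(sprintf("Equilibrium length L_dagger = %.6g um (motor-free L* = %.6g um)\n",
                x$L_dagger, x$L_star))
    cat(sprintf("  tip velocities at equilibrium: dL+/dt = %.4g, dL-/dt = %.4g um/s\n",
                tv$dL_plus, tv$dL_minus))
    kind <- if (is.finite(x$fixed_end_residual) &&
                abs(x$fixed_end_residual) < 1e-6) "fixed ends" else "treadmilling"
    cat(sprintf("  fixed-end residual = %.4g um  (%s)\n",
                x$fixed_end_residual, kind))
  }
  invisible(x)
}

#' Principal branch of the Lambert-W (omega) function
#'
#' Solves `w exp(w) = x` for `x >= 0` (the only range the nullcline
#' condition produces). Small arguments (`x <= 2`) use damped Halley
#' iteration started from `x / (1 + x)`; larger arguments solve the
#' logarithmic form `w + log(w) = log(x)` by Newton iteration, which
#' stays finite even when `exp(w)` would overflow. Iterations are capped
#' and convergence is to relative precision `1e-15`.
#'
#' @param x Argument (scalar, >= 0, finite).
#' @return `W_0(x)`.
#' @export
#' @examples
#' w <- lambert_w0(1)
#' w * exp(w)   # 1
lambert_w0 <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("out-of-range: lambert_w0 requires a finite argument >= 0",
         call. = FALSE)
  if (x == 0) return(0)
  if (x <= 2) {
    w <- x / (1 + x)
    for (i in 1:100) {
      ew <- exp(w)
      f <- w * ew - x
      wn <- w - f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
      if (!is.finite(wn)) break
      done <- abs(wn - w) <= 1e-15 * (1 + abs(wn))
      w <- wn
      if (done) break
    }
    return(w)
  }
  lx <- log(x)
  w <- if (lx > 1) lx - log(lx) else 1
  for (i in 1:100) {
    wn <- w - (w + log(w) - lx) / (1 + 1 / w)
    if (!is.finite(wn) || wn <= 0) { wn <- w / 2 }
    done <- abs(wn - w) <= 1e-15 * (1 + abs(wn))
    w <- wn
    if (done) break
  }
  w
}

#' Fixed-end nullcline coincidence residual
#'
#' Setting each adiabatic tip velocity to zero individually defines two
#' nullclines in the `(L_+, L_-)` plane; both are lines of unit slope, so
#' truly fixed ends require the lengths they prescribe to coincide. The
#' minus nullcline sits at `L = (alpha_- - gamma_-) / beta_-`; the plus
#' nullcline length solves `alpha_+ - beta_+ L = gamma_+ q(L)` in closed
#' form via the principal branch of the Lambert-W (omega) function (its
#' argument is positive for positive parameters, so the principal branch
#' is the real one). The residual is minus-nullcline length minus
#' plus-nullcline length; a residual of zero means a fixed-end
#' equilibrium is possible, which generically fails — equilibria are
#' maintained dynamically by treadmilling.
#'
#' @param tips A [tip_params()] object with `beta_plus > 0`,
#'   `beta_minus > 0`.
#' @param eff An [effective_params()] object with positive `V_plus`,
#'   `D_plus`.
#' @return Residual (um).
#' @export
fixed_end_residual <- function(tips, eff) {
  V <- eff$V_plus; D <- eff$D_plus
  bp <- tips$beta_plus; bm <- tips$beta_minus
  if (!is.finite(bp) || bp <= 0 || !is.finite(bm) || bm <= 0)
    stop("invalid-parameter: beta_plus and beta_minus must be > 0", call. = FALSE)
  if (!is.finite(V) || V <= 0 || !is.finite(D) || D <= 0)
    stop("invalid-parameter: V_plus and D_plus must be > 0", call. = FALSE)
  lhs <- (tips$alpha_minus - tips$gamma_minus) / bm
  k <- V / D
  arg <- k * tips$gamma_plus * (1 + 1 / V) *
    exp(k / bp * (tips$alpha_plus + tips$gamma_plus / V)) / bp
  if (!is.finite(arg))
    stop("out-of-range: Lambert-W argument is non-finite", call. = FALSE)
  rhs <- (D / (bp * V)) * (-bp * lambert_w0(arg) +
                             (tips$alpha_plus * V + tips$gamma_plus) / D)
  lhs - rhs
}

#' Integrate the adiabatic length flow as an ODE
#'
#' Integrates `dL/dt =` [adiabatic_length_flow()] from `L0`, stopping at
#' the disassembly cutoff `L_min` or the runaway cap `L_max`, and returns
#' a trajectory object comparable with the PDE solvers' output (tip
#' velocities from [adiabatic_tip_velocities()]).
#'
#' @param tips,eff As for [adiabatic_length_flow()].
#' @param L0 Initial length (um).
#' @param t_end Horizon (s).
#' @param L_min,L_max Termination cutoffs (um).
#' @param save_every Output interval (s).
#' @return An object of class `mt_trajectory` (model `"adiabatic"`).
#' @export
simulate_adiabatic <- function(tips, eff, L0 = 10, t_end = 300,
                               L_min = 0.1, L_max = 100, save_every = 1) {
  times <- unique(c(seq(0, t_end, by = save_every), t_end))
  rhs <- function(t, y, parms) list(adiabatic_length_flow(y[1], tips, eff))
  root <- function(t, y, parms) c(y[1] - L_min, L_max - y[1])
  sol <- deSolve::ode(y = c(L = L0), times = times, func = rhs, parms = NULL,
                      method = "lsodar", rootfunc = root,
                      rtol = 1e-8, atol = 1e-10)
  L <- sol[, "L"]
  tv <- adiabatic_tip_velocities(pmax(L, 0), tips, eff)
  termination <- "completed"
  tlast <- sol[nrow(sol), "time"]
  if (tlast < t_end) {
    termination <- if (L[length(L)] <= L_min * (1 + 1e-8)) "disassembled" else "runaway"
  }
  # tips are not tracked individually here; report symmetric positions
  traj <- data.frame(time = sol[, "time"], L_minus = -L / 2, L_plus = L / 2,
                     length = L, dLplus_dt = tv$dL_plus, dLminus_dt = tv$dL_minus)
  structure(list(trajectory = traj, snapshots = NULL, termination = termination,
                 model = "adiabatic", scenario = NULL),
            class = "mt_trajectory")
}
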