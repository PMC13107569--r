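#' Solver configuration
#'
#' Numerical settings for the moving-domain method-of-lines solvers. The
#' moving physical domain `[L_-(t), L_+(t)]` is mapped to the fixed
#' reference interval `[0, 1]` (arbitrary Lagrangian--Eulerian scheme);
#' `n_cells` sets the reference-grid resolution (`n_cells + 1` nodes).
#'
#' @param n_cells Number of reference-grid cells (integer >= 16).
#' @param rel_tol,abs_tol Relative/absolute tolerances of the stiff time
#'   integrator.
#' @param L_min Disassembly cutoff (um, > 0): the transformed equations
#'   are singular as the length approaches zero, so integration stops
#'   here and the run is flagged `disassembled`.
#' @param L_max Runaway cap (um): stops unbounded growth (`runaway`).
#' @param save_every Output sampling interval (s).
#'
#' @return An object of class `mt_solver_config`.
#' @export
solver_config <- function(n_cells = 100, rel_tol = 1e-6, abs_tol = 1e-9,
                          L_min = 0.1, L_max = 100, save_every = 1) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 16)
    stop("invalid-parameter: n_cells must be an integer >= 16", call. = FALSE)
  .check_field(rel_tol, "rel_tol", positive = TRUE)
  .check_field(abs_tol, "abs_tol", positive = TRUE)
  .check_field(L_min, "L_min", positive = TRUE)
  .check_field(L_max, "L_max", positive = TRUE)
  if (L_max <= L_min)
    stop("invalid-parameter: L_max must exceed L_min", call. = FALSE)
  .check_field(save_every, "save_every", positive = TRUE)
  x <- list(n_cells = n_cells, rel_tol = rel_tol, abs_tol = abs_tol,
            L_min = L_min, L_max = L_max, save_every = save_every)
  class(x) <- "mt_solver_config"
  x
}

#' Tip velocities of the full model
#'
#' Evaluates the tip equations of motion given the bound motor densities
#' at the respective ends:
#' \deqn{dL_+/dt = \alpha_+ - \beta_+ L - \gamma_+\, p(L_+), \qquad
#'       dL_-/dt = -\alpha_- + \beta_- L + \gamma_-\, m(L_-).}
#'
#' @param L Current filament length (um, >= 0).
#' @param p_at_plus Bound plus-motor density at the plus tip.
#' @param m_at_minus Bound minus-motor density at the minus tip.
#' @param tips A [tip_params()] object.
#' @return A list with components `dL_plus` and `dL_minus` (um/s).
#' @export
#' @examples
#' tip_velocities_full(10, 1, 1, default_params()$tips)
tip_velocities_full <- function(L, p_at_plus, m_at_minus, tips) {
  if (any(!is.finite(L)) || any(L < 0))
    stop("invalid-state: L must be finite and >= 0", call. = FALSE)
  list(dL_plus = tips$alpha_plus - tips$beta_plus * L - tips$gamma_plus * p_at_plus,
       dL_minus = -tips$alpha_minus + tips$beta_minus * L + tips$gamma_minus * m_at_minus)
}

#' Impose boundary conditions on a full-model field state
#'
#' The minus end is a reservoir of plus-end motors (bound and unbound)
#' and of unbound minus-end motors; the plus end is a reservoir of
#' minus-end motors (bound and unbound) and of unbound plus-end motors.
#' Bound motors leave the domain ballistically at the end they
#' depolymerize, so their Fickian (diffusive) flux there is zero,
#' discretized as a vanishing one-sided gradient:
#' `p(L_-) = c(L_-) = f(L_-) = 1`, `dm/dx = 0` at `L_-`;
#' `c(L_+) = m(L_+) = f(L_+) = 1`, `dp/dx = 0` at `L_+`.
#' The operation is idempotent.
#'
#' @param state A list with numeric node vectors `p`, `c`, `m`, `f`
#'   (equal length >= 3); other elements are passed through.
#' @return The state with boundary values imposed.
#' @export
apply_boundary_conditions <- function(state) {
  n <- length(state$p)
  stopifnot(n >= 3, length(state$c) == n, length(state$m) == n,
            length(state$f) == n)
  state$p[1] <- 1
  state$p[n] <- state$p[n - 1]   # zero one-sided gradient at L_+
  state$c[1] <- 1
  state$c[n] <- 1
  state$m[n] <- 1
  state$m[1] <- state$m[2]       # zero one-sided gradient at L_-
  state$f[1] <- 1
  state$f[n] <- 1
  state
}

# Robin/Dirichlet closure for the reduced two-field state.
# q: Dirichlet 1 at L-; flux condition V q - D q' = 1 at L+ (one-sided).
# h: Robin h + h' = 1 at L- (gradient coefficient 1 um, as specified);
#    Dirichlet 1 at L+.
.apply_bc_reduced <- function(q, h, L, eff, dxi) {
  n <- length(q)
  dx <- L * dxi
  q[1] <- 1
  q[n] <- (eff$D_plus * q[n - 1] / dx - 1) / (eff$D_plus / dx - eff$V_plus)
  h[n] <- 1
  h[1] <- (h[2] - dx) / (1 - dx)
  list(q = q, h = h)
}

# Upwind advection + central diffusion on the ALE reference grid.
# Physical equation: du/dt = -v_adv du/dx + D d2u/dx2 (+ reactions added
# by the caller); on the reference grid the mesh-motion velocity xdot is
# subtracted from v_adv and the TOTAL advection velocity is upwinded.
# Returns derivative at interior nodes (2..n-1); boundary entries are 0.
.interior_operator <- function(u, v_adv, D, L, xdot, dxi) {
  n <- length(u)
  i <- 2:(n - 1)
  dx <- L * dxi
  ceff <- v_adv - xdot[i]
  ux_b <- (u[i] - u[i - 1]) / dx
  ux_f <- (u[i + 1] - u[i]) / dx
  ux <- ifelse(ceff >= 0, ux_b, ux_f)
  uxx <- (u[i + 1] - 2 * u[i] + u[i - 1]) / dx^2
  du <- numeric(n)
  du[i] <- -ceff * ux + D * uxx
  du
}

#' Right-hand side of the full moving-domain system
#'
#' Evaluates the time derivatives of all four motor fields and both tip
#' positions on the reference grid. Each field's physical operator uses
#' `d/dx = (1/L) d/dxi`, and the mesh-motion advection with node velocity
#' `xdot(xi) = dL_-/dt + xi (dL_+/dt - dL_-/dt)` is folded into the
#' upwinded total advection velocity. Reaction (binding/unbinding)
#' exchange couples each bound field to its unbound partner. Tip
#' derivatives come from [tip_velocities_full()] using the boundary-node
#' densities `p(L_+)` and `m(L_-)`.
#'
#' @param state A list with `xi` (reference nodes in `[0, 1]`), node
#'   vectors `p`, `c`, `m`, `f`, and scalars `L_minus`, `L_plus`.
#' @param params An [mt_params()] object.
#' @return A list `dp`, `dc`, `dm`, `df`, `dL_plus`, `dL_minus`.
#'   Dirichlet boundary nodes have derivative zero; zero-gradient
#'   boundary nodes mirror their neighbor's derivative.
#' @export
full_rhs <- function(state, params) {
  state <- apply_boundary_conditions(state)
  p <- state$p; cc <- state$c; m <- state$m; f <- state$f
  if (any(!is.finite(c(p, cc, m, f, state$L_minus, state$L_plus))))
    stop("numerical-failure: non-finite field values", call. = FALSE)
  n <- length(p)
  xi <- state$xi
  dxi <- 1 / (n - 1)
  L <- state$L_plus - state$L_minus
  if (L <= 0)
    stop("numerical-failure: non-positive length", call. = FALSE)
  pm <- params$plus_motor; mm <- params$minus_motor
  tv <- tip_velocities_full(L, p[n], m[1], params$tips)
  xdot <- tv$dL_minus + xi * (tv$dL_plus - tv$dL_minus)

  dp <- .interior_operator(p, pm$v, pm$D_on, L, xdot, dxi)
  dc <- .interior_operator(cc, 0, pm$D_off, L, xdot, dxi)
  dm <- .interior_operator(m, -mm$v, mm$D_on, L, xdot, dxi)
  df <- .interior_operator(f, 0, mm$D_off, L, xdot, dxi)
  i <- 2:(n - 1)
  dp[i] <- dp[i] + pm$k_on * cc[i] - pm$k_off * p[i]
  dc[i] <- dc[i] - pm$k_on * cc[i] + pm$k_off * p[i]
  dm[i] <- dm[i] + mm$k_on * f[i] - mm$k_off * m[i]
  df[i] <- df[i] - mm$k_on * f[i] + mm$k_off * m[i]
  # zero-gradient nodes track their interior neighbor
  dp[n] <- dp[n - 1]
  dm[1] <- dm[2]

  list(dp = dp, dc = dc, dm = dm, df = df,
       dL_plus = tv$dL_plus, dL_minus = tv$dL_minus)
}

.initial_fields <- function(n, ic_mode, fields) {
  make <- function() {
    u <- rep(1, n)
    if (ic_mode == "zero-interior") u[2:(n - 1)] <- 0
    u
  }
  stats::setNames(lapply(fields, function(f) make()), fields)
}

.termination_status <- function(t_last, t_end, L_last, L_min) {
  if (t_last >= t_end * (1 - 1e-12)) return("completed")
  if (L_last <= L_min * (1 + 1e-6)) "disassembled" else "runaway"
}

.as_trajectory <- function(times, Lm, Lp, dLp, dLm, snapshots, termination,
                           model, scenario) {
  traj <- data.frame(time = times, L_minus = Lm, L_plus = Lp,
                     length = Lp - Lm, dLplus_dt = dLp, dLminus_dt = dLm)
  structure(list(trajectory = traj, snapshots = snapshots,
                 termination = termination, model = model,
                 scenario = scenario),
            class = "mt_trajectory")
}

#' Simulate the full four-field moving-domain model
#'
#' Integrates the bound/unbound motor densities of both species together
#' with both tip positions from `t = 0` to the scenario horizon, or until
#' the length crosses the disassembly cutoff or runaway cap. The
#' concatenated state is advanced by an adaptive stiff integrator
#' (`lsodar`) with event roots on the cutoffs; the run is deterministic
#' for fixed inputs.
#'
#' @param scenario An [scenario_config()] (or [builtin_scenario()])
#'   object.
#' @param solver A [solver_config()] object.
#' @return An object of class `mt_trajectory`: a list with `trajectory`
#'   (data frame `time`, `L_minus`, `L_plus`, `length`, `dLplus_dt`,
#'   `dLminus_dt`), `snapshots` (list with `xi`, `times` and one
#'   node-by-time matrix per field), `termination` (`"completed"`,
#'   `"disassembled"` or `"runaway"`), `model`, and the scenario.
#' @export
#' @examples
#' \donttest{
#' sc <- builtin_scenario("treadmilling")
#' sc$t_end <- 60
#' tr <- simulate_full(sc, solver_config(n_cells = 50))
#' summary(tr)
#' }
simulate_full <- function(scenario, solver = solver_config()) {
  stopifnot(inherits(scenario, "mt_scenario"),
            inherits(solver, "mt_solver_config"))
  params <- scenario$params
  if (scenario$L0 <= solver$L_min || scenario$L0 >= solver$L_max)
    stop("invalid-parameter: L0 must lie strictly between L_min and L_max",
         call. = FALSE)
  n <- solver$n_cells + 1L
  xi <- seq(0, 1, length.out = n)
  ic <- .initial_fields(n, scenario$ic_mode, c("p", "c", "m", "f"))
  ic <- apply_boundary_conditions(c(ic, list(xi = xi)))
  y0 <- c(ic$p, ic$c, ic$m, ic$f, -scenario$L0 / 2, scenario$L0 / 2)

  unpack <- function(y) {
    list(xi = xi,
         p = y[1:n], c = y[(n + 1):(2 * n)],
         m = y[(2 * n + 1):(3 * n)], f = y[(3 * n + 1):(4 * n)],
         L_minus = y[4 * n + 1], L_plus = y[4 * n + 2])
  }
  rhs <- function(t, y, parms) {
    st <- unpack(y)
    d <- full_rhs(st, params)
    list(c(d$dp, d$dc, d$dm, d$df, d$dL_minus, d$dL_plus))
  }
  root <- function(t, y, parms) {
    L <- y[4 * n + 2] - y[4 * n + 1]
    c(L - solver$L_min, solver$L_max - L)
  }
  times <- unique(c(seq(0, scenario$t_end, by = solver$save_every),
                    scenario$t_end))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodar", rootfunc = root,
                      rtol = solver$rel_tol, atol = solver$abs_tol,
                      maxsteps = 100000)
  if (any(!is.finite(sol)))
    stop("numerical-failure: integrator produced non-finite values", call. = FALSE)

  nt <- nrow(sol)
  states <- lapply(seq_len(nt), function(k) {
    st <- unpack(sol[k, -1])
    apply_boundary_conditions(st)
  })
  Lm <- vapply(states, `[[`, numeric(1), "L_minus")
  Lp <- vapply(states, `[[`, numeric(1), "L_plus")
  tvs <- lapply(states, function(st)
    tip_velocities_full(st$L_plus - st$L_minus, st$p[n], st$m[1], params$tips))
  snapshots <- list(
    xi = xi, times = sol[, 1],
    p = t(vapply(states, `[[`, numeric(n), "p")),
    c = t(vapply(states, `[[`, numeric(n), "c")),
    m = t(vapply(states, `[[`, numeric(n), "m")),
    f = t(vapply(states, `[[`, numeric(n), "f")))
  termination <- .termination_status(sol[nt, 1], scenario$t_end,
                                     Lp[nt] - Lm[nt], solver$L_min)
  .as_trajectory(sol[, 1], Lm, Lp,
                 vapply(tvs, `[[`, numeric(1), "dL_plus"),
                 vapply(tvs, `[[`, numeric(1), "dL_minus"),
                 snapshots, termination, "full", scenario)
}

#' Simulate the reduced two-field model on the moving domain
#'
#' Integrates the fast-switching reduction: the total plus-motor density
#' `q` (effective advection--diffusion) and the total minus-motor density
#' `h` (effective diffusion) on the moving domain, with `q(L_-) = 1`, the
#' flux condition `V_+ q(L_+) - D_+ dq/dx = 1`, the Robin condition
#' `h(L_-) + dh/dx = 1`, and `h(L_+) = 1` (one-sided discretizations).
#' Tip coupling uses `q(L_+)` for the plus end and `h(L_-)` for the
#' minus end. Same engine and termination rules as [simulate_full()].
#'
#' Note that the minus-end Robin condition, taken at face value, carries
#' a negative coefficient on the outward normal derivative, so the
#' continuum problem it closes is not dissipative: the uniform state
#' `h = 1` is an exact fixed point (preserved exactly from the default
#' `uniform-one` start) but perturbed initial data grow at rate
#' `D_- mu^2` with `tanh(mu L) = mu` rather than relax. See the methods
#' vignette for the analysis.
#'
#' @param effective An [effective_params()] object.
#' @param tips A [tip_params()] object (pass all-zero rates to freeze the
#'   tips and study pure field relaxation).
#' @param scenario An [scenario_config()] object (its motor parameters
#'   are ignored; `L0`, `t_end` and `ic_mode` are used).
#' @param solver A [solver_config()] object.
#' @return An `mt_trajectory` (model `"reduced-pde"`; snapshot fields
#'   `q`, `h`).
#' @export
simulate_reduced_pde <- function(effective, tips, scenario,
                                 solver = solver_config()) {
  stopifnot(inherits(effective, "mt_effective"),
            inherits(tips, "mt_tip_params"),
            inherits(scenario, "mt_scenario"),
            inherits(solver, "mt_solver_config"))
  for (nm in c("V_plus", "D_plus", "D_minus")) {
    v <- effective[[nm]]
    if (!is.finite(v) || v < 0)
      stop("invalid-parameter: effective ", nm, " must be finite and >= 0",
           call. = FALSE)
  }
  n <- solver$n_cells + 1L
  xi <- seq(0, 1, length.out = n)
  dxi <- 1 / (n - 1)
  ic <- .initial_fields(n, scenario$ic_mode, c("q", "h"))
  bc0 <- .apply_bc_reduced(ic$q, ic$h, scenario$L0, effective, dxi)
  y0 <- c(bc0$q, bc0$h, -scenario$L0 / 2, scenario$L0 / 2)

  rhs <- function(t, y, parms) {
    q <- y[1:n]; h <- y[(n + 1):(2 * n)]
    Lm <- y[2 * n + 1]; Lp <- y[2 * n + 2]
    L <- Lp - Lm
    if (L <= 0 || any(!is.finite(c(q, h, Lm, Lp))))
      stop("numerical-failure: invalid reduced-model state", call. = FALSE)
    bc <- .apply_bc_reduced(q, h, L, effective, dxi)
    q <- bc$q; h <- bc$h
    tv <- tip_velocities_full(L, q[n], h[1], tips)
    xdot <- tv$dL_minus + xi * (tv$dL_plus - tv$dL_minus)
    dq <- .interior_operator(q, effective$V_plus, effective$D_plus, L, xdot, dxi)
    dh <- .interior_operator(h, 0, effective$D_minus, L, xdot, dxi)
    dq[n] <- dq[n - 1]
    dh[1] <- dh[2]
    list(c(dq, dh, tv$dL_minus, tv$dL_plus))
  }
  root <- function(t, y, parms) {
    L <- y[2 * n + 2] - y[2 * n + 1]
    c(L - solver$L_min, solver$L_max - L)
  }
  times <- unique(c(seq(0, scenario$t_end, by = solver$save_every),
                    scenario$t_end))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodar", rootfunc = root,
                      rtol = solver$rel_tol, atol = solver$abs_tol,
                      maxsteps = 100000)
  if (any(!is.finite(sol)))
    stop("numerical-failure: integrator produced non-finite values", call. = FALSE)

  nt <- nrow(sol)
  Lm <- sol[, 2 * n + 2]; Lp <- sol[, 2 * n + 3]
  qm <- matrix(NA_real_, nt, n); hm <- matrix(NA_real_, nt, n)
  dLp <- numeric(nt); dLm <- numeric(nt)
  for (k in seq_len(nt)) {
    L <- Lp[k] - Lm[k]
    bc <- .apply_bc_reduced(sol[k, 2:(n + 1)], sol[k, (n + 2):(2 * n + 1)],
                            L, effective, dxi)
    qm[k, ] <- bc$q; hm[k, ] <- bc$h
    tv <- tip_velocities_full(L, bc$q[n], bc$h[1], tips)
    dLp[k] <- tv$dL_plus; dLm[k] <- tv$dL_minus
  }
  snapshots <- list(xi = xi, times = sol[, 1], q = qm, h = hm)
  termination <- .termination_status(sol[nt, 1], scenario$t_end,
                                     Lp[nt] - Lm[nt], solver$L_min)
  .as_trajectory(sol[, 1], Lm, Lp, dLp, dLm, snapshots, termination,
                 "reduced-pde", scenario)
}

#' Mesh-refinement error estimate
#'
#' Reruns a scenario with `factor` times as many reference cells and
#' returns the maximum absolute difference of the length series on the
#' common saved times (up to the earlier of the two termination times).
#'
#' @param scenario An [scenario_config()] object.
#' @param solver A [solver_config()] object (the coarse resolution).
#' @param factor Integer refinement factor (>= 2).
#' @param model `"full"` or `"reduced-pde"`.
#' @param effective,tips Required when `model = "reduced-pde"`.
#' @return Maximum length difference (um) on common save times.
#' @export
refinement_error <- function(scenario, solver = solver_config(), factor = 2L,
                             model = c("full", "reduced-pde"),
                             effective = NULL, tips = NULL) {
  model <- match.arg(model)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2)
    stop("invalid-parameter: factor must be an integer >= 2", call. = FALSE)
  fine <- solver
  fine$n_cells <- solver$n_cells * factor
  run <- function(cfg) {
    if (model == "full") simulate_full(scenario, cfg)
    else simulate_reduced_pde(effective, tips, scenario, cfg)
  }
  a <- run(solver)$trajectory
  b <- run(fine)$trajectory
  tmax <- min(max(a$time), max(b$time))
  common <- intersect(a$time[a$time <= tmax], b$time[b$time <= tmax])
  max(abs(a$length[match(common, a$time)] - b$length[match(common, b$time)]))
}

#' @export
print.mt_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Microtubule trajectory (%s model): %d saved times over [0, %g] s\n",
              x$model, nrow(tr), max(tr$time)))
  cat(sprintf("  length: %g -> %g um; termination: %s\n",
              tr$length[1], tr$length[nrow(tr)], x$termination))
  invisible(x)
}

#' @export
summary.mt_trajectory <- function(object, window_frac = 0.2, ...) {
  tr <- object$trajectory
  t1 <- max(tr$time)
  win <- tr$time >= t1 * (1 - window_frac)
  out <- list(
    model = object$model,
    termination = object$termination,
    t_end = t1,
    final_length = tr$length[nrow(tr)],
    mean_length_window = mean(tr$length[win]),
    mean_dL_dt_window = mean(tr$dLplus_dt[win] - tr$dLminus_dt[win]),
    mean_tip_speeds_window = c(plus = mean(abs(tr$dLplus_dt[win])),
                               minus = mean(abs(tr$dLminus_dt[win]))))
  class(out) <- "summary.mt_trajectory"
  out
}

#' @export
print.summary.mt_trajectory <- function(x, ...) {
  cat(sprintf("%s-model run to t = %g s (%s)\n", x$model, x$t_end, x$termination))
  cat(sprintf("  final length %.4g um; trailing-window mean %.4g um\n",
              x$final_length, x$mean_length_window))
  cat(sprintf("  trailing-window <dL/dt> = %.3g um/s; |tip speeds| = (%.3g, %.3g) um/s\n",
              x$mean_dL_dt_window, x$mean_tip_speeds_window["plus"],
              x$mean_tip_speeds_window["minus"]))
  invisible(x)
}

#' Plot a trajectory
#'
#' Draws the tip positions and total length against time (base
#' graphics).
#'
#' @param x An `mt_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mt_trajectory <- function(x, ...) {
  tr <- x$trajectory
  graphics::matplot(tr$time, cbind(tr$L_minus, tr$L_plus, tr$length),
                    type = "l", lty = c(2, 2, 1), col = c(4, 2, 1),
                    xlab = "time (s)", ylab = "position / length (um)", ...)
  graphics::legend("topright", c("L-", "L+", "length"),
                   lty = c(2, 2, 1), col = c(4, 2, 1), bty = "n")
  invisible(x)
}
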