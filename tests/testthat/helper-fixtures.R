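# Shared fixtures: memoised scenario runs (the built-in scenarios are used
# by several files; simulate each once per session) and small builders.

.run_cache <- new.env(parent = emptyenv())

cached_scenario_run <- function(name, n_cells = 100) {
  key <- paste0(name, "@", n_cells)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- simulate_full(builtin_scenario(name),
                                       solver_config(n_cells = n_cells))
  }
  .run_cache[[key]]
}

# Independent, loop-based discretization of the moving-domain right-hand
# side (no shared code with the package's vectorized implementation).
naive_full_rhs <- function(state, params) {
  state <- apply_boundary_conditions(state)
  n <- length(state$p)
  dxi <- 1 / (n - 1)
  L <- state$L_plus - state$L_minus
  tips <- params$tips
  dLp <- tips$alpha_plus - tips$beta_plus * L - tips$gamma_plus * state$p[n]
  dLm <- -tips$alpha_minus + tips$beta_minus * L +
    tips$gamma_minus * state$m[1]
  fields <- list(
    p = list(u = state$p, v = params$plus_motor$v, D = params$plus_motor$D_on),
    c = list(u = state$c, v = 0, D = params$plus_motor$D_off),
    m = list(u = state$m, v = -params$minus_motor$v, D = params$minus_motor$D_on),
    f = list(u = state$f, v = 0, D = params$minus_motor$D_off))
  out <- list()
  for (nm in names(fields)) {
    fl <- fields[[nm]]
    du <- numeric(n)
    for (i in 2:(n - 1)) {
      xdot <- dLm + state$xi[i] * (dLp - dLm)
      ce <- fl$v - xdot
      dx <- L * dxi
      ux <- if (ce >= 0) (fl$u[i] - fl$u[i - 1]) / dx
            else (fl$u[i + 1] - fl$u[i]) / dx
      uxx <- (fl$u[i + 1] - 2 * fl$u[i] + fl$u[i - 1]) / dx^2
      du[i] <- -ce * ux + fl$D * uxx
    }
    out[[nm]] <- du
  }
  kp <- params$plus_motor; km <- params$minus_motor
  for (i in 2:(n - 1)) {
    out$p[i] <- out$p[i] + kp$k_on * state$c[i] - kp$k_off * state$p[i]
    out$c[i] <- out$c[i] - kp$k_on * state$c[i] + kp$k_off * state$p[i]
    out$m[i] <- out$m[i] + km$k_on * state$f[i] - km$k_off * state$m[i]
    out$f[i] <- out$f[i] - km$k_on * state$f[i] + km$k_off * state$m[i]
  }
  out$p[n] <- out$p[n - 1]
  out$m[1] <- out$m[2]
  list(dp = out$p, dc = out$c, dm = out$m, df = out$f,
       dL_plus = dLp, dL_minus = dLm)
}

# Hand-built trajectory object for classifier tests.
synthetic_trajectory <- function(time, length, dLplus, dLminus,
                                 termination = "completed") {
  structure(list(
    trajectory = data.frame(time = time, L_minus = -length / 2,
                            L_plus = length / 2, length = length,
                            dLplus_dt = dLplus, dLminus_dt = dLminus),
    snapshots = NULL, termination = termination, model = "synthetic",
    scenario = NULL), class = "mt_trajectory")
}

# Random tip parameters guaranteed to admit an adiabatic equilibrium.
random_existing_tips <- function() {
  tip_params(alpha_plus = runif(1, 0.05, 0.3),
             alpha_minus = runif(1, 0.005, 0.05),
             beta_plus = 10^runif(1, -3, -1.3),
             beta_minus = 10^runif(1, -4, -2),
             gamma_plus = runif(1, 0.001, 0.02),
             gamma_minus = runif(1, 0.001, 0.02))
}

random_effective <- function() {
  p <- motor_params("plus", v = runif(1, 0.01, 0.2),
                    D_on = runif(1, 0.005, 0.5), D_off = runif(1, 1, 8),
                    k_on = 10^runif(1, -0.5, 0.5), k_off = 10^runif(1, -1, 0.5))
  m <- motor_params("minus", v = 0, D_on = runif(1, 0.05, 1),
                    D_off = runif(1, 1, 8), k_on = 1, k_off = runif(1, 0.5, 3))
  effective_params(mt_params(p, m, tip_params(1, 1, 0, 0, 0, 0)))
}
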