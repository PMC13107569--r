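eff0 <- effective_params(default_params())
tips0 <- default_params()$tips

test_that("effective transport coefficients follow the duty-ratio averages", {
  ep <- effective_parameters(default_params()$plus_motor)
  expect_equal(ep$V, 0.04)          # (1/1.25) * 0.05
  expect_equal(ep$D_eff, 0.808)     # 0.8*0.01 + 0.2*4
  em <- effective_parameters(default_params()$minus_motor)
  expect_equal(em$V, 0)
  expect_equal(em$D_eff, (1 * 0.38 + 1.2 * 4) / 2.2)

  # always-bound and never-bound limits
  mo <- motor_params("plus", v = 0.1, D_on = 0.02, D_off = 3, k_on = 1,
                     k_off = 1e-12)
  expect_equal(effective_parameters(mo)$V, 0.1, tolerance = 1e-9)
  expect_equal(effective_parameters(mo)$D_eff, 0.02, tolerance = 1e-9)
  mo$k_on <- 1e-12; mo$k_off <- 1
  expect_equal(effective_parameters(mo)$V, 0, tolerance = 1e-9)
  expect_equal(effective_parameters(mo)$D_eff, 3, tolerance = 1e-9)

  # effective coefficients are bounded by their ingredients
  set.seed(21)
  for (i in 1:20) {
    eff <- random_effective()
    expect_gte(eff$V_plus, 0)
    expect_gte(eff$D_plus, 0.005); expect_lte(eff$D_plus, 8)
  }
})

test_that("steady plus-motor profile is the antenna gradient", {
  expect_equal(steady_profile_plus(3, 3, eff0), 1)   # reservoir value at L-
  x <- seq(0, 10, length.out = 50)
  q <- steady_profile_plus(x, 0, eff0)
  expect_true(all(diff(q) > 0))                      # strictly increasing
  # satisfies the steady equation -V q' + D q'' = 0 (central differences)
  hh <- 1e-4
  for (xx in c(1, 5, 9)) {
    q1 <- (steady_profile_plus(xx + hh, 0, eff0) -
             steady_profile_plus(xx - hh, 0, eff0)) / (2 * hh)
    q2 <- (steady_profile_plus(xx + hh, 0, eff0) - 2 * steady_profile_plus(xx, 0, eff0) +
             steady_profile_plus(xx - hh, 0, eff0)) / hh^2
    expect_equal(-eff0$V_plus * q1 + eff0$D_plus * q2, 0, tolerance = 1e-6)
  }
  expect_error(steady_profile_plus(1, 0, list(V_plus = 0, D_plus = 1)),
               "degenerate-profile")
  expect_equal(steady_profile_minus(seq(0, 5, 1)), rep(1, 6))
})

test_that("general Robin-data steady profile brackets the printed one", {
  x <- seq(0, 10, length.out = 21)
  # the canonical profile carries flux value -1 at the plus end
  expect_equal(steady_profile_robin(x, 0, eff0, flux_value = -1),
               steady_profile_plus(x, 0, eff0), tolerance = 1e-12)
  # the +1-consistent solution decreases (and goes negative for V < 1)
  qp <- steady_profile_robin(x, 0, eff0, flux_value = 1)
  expect_true(all(diff(qp) < 0))
  expect_lt(qp[length(qp)], 0)
  # V = 0 degenerates to a linear pure-diffusion profile
  q0 <- steady_profile_robin(x, 0, list(V_plus = 0, D_plus = 2), flux_value = 1)
  expect_equal(q0, 1 - x / 2)
})

test_that("adiabatic length flow and tip velocities satisfy their identities", {
  # L = 0 collapses the antenna bracket
  expect_equal(adiabatic_length_flow(0, tips0, eff0),
               (0.15 + 0.02) - (0.01 + 0.01))
  # motor-free equilibrium
  t2 <- tip_params(0.15, 0.02, 0.05, 0.0006, 0, 0)
  expect_equal(adiabatic_length_flow(0.17 / 0.0506, t2, eff0), 0,
               tolerance = 1e-14)
  # difference identity dL/dt = dL+/dt - dL-/dt
  set.seed(31)
  for (i in 1:10) {
    tp <- random_existing_tips()
    ef <- random_effective()
    L <- runif(1, 0.1, 20)
    tv <- adiabatic_tip_velocities(L, tp, ef)
    expect_equal(tv$dL_plus - tv$dL_minus, adiabatic_length_flow(L, tp, ef),
                 tolerance = 1e-12)
  }
  expect_error(adiabatic_length_flow(-1, tips0, eff0), "invalid-state")
  expect_error(adiabatic_length_flow(1e6, tips0, eff0), "out-of-range")
})

test_that("flow changes sign exactly once below the motor-free equilibrium", {
  tips <- tip_params(0.15, 0.02, 0.05, 0.05, 0.01, 0.01)
  L_star <- 0.17 / 0.1
  grid <- seq(0, L_star, length.out = 10000)
  s <- sign(adiabatic_length_flow(grid, tips, eff0))
  s <- s[s != 0]
  expect_equal(sum(diff(s) != 0), 1)
})

test_that("equilibrium existence dichotomy and root accuracy hold on random draws", {
  set.seed(41)
  n_exist <- 0
  for (i in 1:100) {
    tp <- tip_params(alpha_plus = 10^runif(1, -2, 0),
                     alpha_minus = 10^runif(1, -3, -1),
                     beta_plus = 10^runif(1, -3, -1),
                     beta_minus = 10^runif(1, -4, -2),
                     gamma_plus = 10^runif(1, -3, -0.5),
                     gamma_minus = 10^runif(1, -3, -0.5))
    ef <- random_effective()
    eq <- equilibrium_length(tp, ef)
    should_exist <- tp$alpha_plus + tp$alpha_minus >
      tp$gamma_plus + tp$gamma_minus
    expect_identical(eq$exists, should_exist)
    if (eq$exists) {
      n_exist <- n_exist + 1
      expect_lt(abs(adiabatic_length_flow(eq$L_dagger, tp, ef)), 1e-10)
      # uniqueness: one sign change on [0, 2 L_dagger]
      grid <- seq(0, 2 * eq$L_dagger, length.out = 10000)
      s <- sign(adiabatic_length_flow(grid, tp, ef))
      expect_equal(sum(diff(s[s != 0]) != 0), 1)
    }
  }
  expect_gt(n_exist, 10)  # the draw actually exercises both branches
  expect_lt(n_exist, 90)
})

test_that("closed-form equilibrium is recovered when the plus motor is inert", {
  tips <- tip_params(0.15, 0.02, 0.01, 0.006, 0, 0.01)
  eq <- equilibrium_length(tips, eff0)
  expect_true(eq$exists)
  expect_equal(eq$L_dagger, (0.15 + 0.02 - 0.01) / 0.016, tolerance = 1e-10)
})

test_that("equilibrium length moves monotonically with each rate", {
  set.seed(51)
  bump <- function(tp, field, fac) { tp[[field]] <- tp[[field]] * fac; tp }
  for (i in 1:20) {
    tp <- random_existing_tips()
    ef <- random_effective()
    eq <- equilibrium_length(tp, ef)
    if (!eq$exists) next
    L0 <- eq$L_dagger
    for (f in c("alpha_plus", "alpha_minus"))
      expect_gt(equilibrium_length(bump(tp, f, 1.1), ef)$L_dagger, L0)
    for (f in c("beta_plus", "beta_minus", "gamma_plus", "gamma_minus"))
      expect_lt(equilibrium_length(bump(tp, f, 1.1), ef)$L_dagger, L0)
  }
})

test_that("gain f decreases and loss g increases over the whole length range", {
  set.seed(61)
  for (i in 1:10) {
    tp <- random_existing_tips(); ef <- random_effective()
    L <- seq(0, 30, length.out = 500)
    f <- (tp$alpha_plus + tp$alpha_minus) - (tp$beta_plus + tp$beta_minus) * L
    g <- f - adiabatic_length_flow(L, tp, ef)
    expect_true(all(diff(f) < 0))
    expect_true(all(diff(g) > 0))
  }
})

test_that("omega function satisfies its defining identity and matches pracma", {
  # self-check w e^w = x across magnitudes, including arguments on which
  # iterative implementations are prone to stall
  for (x in c(0, 1e-8, 0.5, 1, 2, 2.5, 10, 23498054.53576437, 1e10,
              3.6478470401861807e37, 1e100)) {
    w <- lambert_w0(x)
    if (w < 700) expect_equal(w * exp(w), x, tolerance = 1e-12)
    else expect_equal(w + log(w), log(x), tolerance = 1e-12)
  }
  # huge arguments where exp(w) overflows: check in log space
  w <- lambert_w0(1e300)
  expect_equal(w + log(w), log(1e300), tolerance = 1e-13)
  expect_error(lambert_w0(-1), "out-of-range")
  # independent implementation agrees on benign arguments
  for (x in c(0.3, 1, 5, 120, 1e6))
    expect_equal(lambert_w0(x), pracma::lambertWp(x), tolerance = 1e-12)
})

test_that("fixed-end residual vanishes exactly when both nullclines coincide", {
  # omega-function self-check
  w <- lambert_w0(1)
  expect_equal(w * exp(w), 1, tolerance = 1e-12)

  # independent oracle: 2-equation solve of the tip system for (L, beta_minus)
  tips <- tip_params(0.15, 0.02, 0.05, 0.0006, 0.01, 0.01)
  fun <- function(z) {
    L <- z[1]; bm <- z[2]
    tp <- tips; tp$beta_minus <- bm
    tv <- adiabatic_tip_velocities(L, tp, eff0)
    c(tv$dL_plus, tv$dL_minus)
  }
  sol <- pracma::fsolve(fun, c(5, 0.01))
  tuned <- tips; tuned$beta_minus <- sol$x[2]
  expect_lt(abs(fixed_end_residual(tuned, eff0)), 1e-6)
  eq <- equilibrium_length(tuned, eff0)
  expect_lt(abs(eq$tip_velocities_at_eq$dL_plus), 1e-6)
  expect_lt(abs(eq$tip_velocities_at_eq$dL_minus), 1e-6)

  # generic baseline-derived parameters treadmill: residual well off zero
  expect_gt(abs(fixed_end_residual(tips, eff0)), 1)
  eqg <- equilibrium_length(tips, eff0)
  expect_gt(abs(eqg$tip_velocities_at_eq$dL_plus), 1e-4)
})

test_that("adiabatic ODE integration terminates at the disassembly cutoff when motors win", {
  tips <- tip_params(alpha_plus = 0.02, alpha_minus = 0.01,
                     beta_plus = 0.01, beta_minus = 0.001,
                     gamma_plus = 0.03, gamma_minus = 0.02)
  tr <- simulate_adiabatic(tips, eff0, L0 = 5, t_end = 5000)
  expect_identical(tr$termination, "disassembled")
  expect_lte(tr$trajectory$length[nrow(tr$trajectory)], 0.1 + 1e-6)
})
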