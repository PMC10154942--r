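test_that("characteristic roots cover the three damping regimes", {
  # undamped: pure imaginary pair
  r <- characteristic_roots(oscillator_params(1, 1, 0))
  expect_equal(sort(Im(r)), c(-1, 1))
  expect_equal(Re(r), c(0, 0))

  # critical damping: double real root at -omega0
  r <- characteristic_roots(oscillator_params(1, 1, 2))
  expect_equal(r, as.complex(c(-1, -1)))

  # underdamped with omega0 = 2, zeta = 0.5: -1 +- i*sqrt(3), and the roots
  # satisfy the characteristic polynomial m z^2 + beta z + k = 0
  p <- oscillator_params(1, 4, 2)
  r <- characteristic_roots(p)
  expect_equal(sort(Im(r)), c(-sqrt(3), sqrt(3)))
  expect_equal(Re(r), c(-1, -1))
  residual <- p$mass * r^2 + p$damping * r + p$stiffness
  expect_lt(max(Mod(residual)), 1e-12)

  expect_error(oscillator_params(-1, 1, 0), "positive")
  expect_error(oscillator_params(1, 0, 0), "positive")
})

test_that("derived frequency and damping ratio are consistent with (m, k, beta)", {
  for (i in 1:10) {
    m <- runif(1, 0.1, 10); k <- runif(1, 0.1, 10); b <- runif(1, 0, 10)
    p <- oscillator_params(m, k, b)
    expect_equal(p$omega0, sqrt(k / m), tolerance = 1e-12)
    expect_equal(p$zeta, b / (2 * sqrt(k * m)), tolerance = 1e-12)
    expect_identical(p$zeta == 0, b == 0)
  }
})

test_that("underdamped closed form: limits, envelope decay, regime guard", {
  p0 <- oscillator_params(1, 1, 0)
  tt <- seq(0, 10, by = 0.1)
  expect_equal(underdamped_position(p0, tt, x0 = 2, phi = 0),
               2 * cos(tt))
  pd <- oscillator_params(1, 1, 0.2)
  expect_lt(abs(underdamped_position(pd, 200, x0 = 1, phi = 0)), 1e-8)
  expect_error(underdamped_position(oscillator_params(1, 1, 4), 1),
               "overdamped")
})

test_that("underdamped closed form matches numerical integration", {
  # m=1, k=1, beta=0.2 with envelope amplitude 1, phase 0
  p <- oscillator_params(1, 1, 0.2)
  x_init <- 1                       # x0*cos(-phi) with x0=1, phi=0
  v_init <- -p$zeta * p$omega0      # d/dt at 0 for that parameterisation
  tt <- seq(0, 2 * pi, length.out = 201)
  num <- integrate_oscillator(p, tt, x_init = x_init, v_init = v_init)
  expect_lt(max(abs(num$x - underdamped_position(p, tt))), 1e-6)
})

test_that("overdamped closed form: c = 0 single exponential, x(0), oracle", {
  p <- oscillator_params(1, 1, 4)   # zeta = 2
  s <- sqrt(p$zeta^2 - 1) * p$omega0
  tt <- seq(0, 5, by = 0.05)
  expect_equal(overdamped_position(p, tt, x0 = 1.5, c = 0),
               1.5 * exp(-(p$zeta * p$omega0 + s) * tt))
  expect_equal(overdamped_position(p, 0, x0 = 2, c = 0.3), 2 * 1.3)
  expect_error(overdamped_position(oscillator_params(1, 1, 0.2), 1),
               "underdamped")

  # c chosen for v0 = 0 matches numerical integration
  st <- overdamped_state_from_ic(p, x_init = 1, v_init = 0)
  num <- integrate_oscillator(p, tt, x_init = 1, v_init = 0)
  expect_lt(max(abs(num$x - overdamped_position(p, tt, st$x0, st$c))), 1e-6)
})

test_that("initial-condition helpers invert the closed-form parameterisations", {
  for (i in 1:10) {
    case <- draw_oscillator_case()
    p <- case$params
    x <- closed_form_position(p, c(0, 1e-6), case$x_init, case$v_init)
    expect_equal(x[1], case$x_init, tolerance = 1e-9)
    # forward difference approximates the initial velocity
    expect_equal((x[2] - x[1]) / 1e-6, case$v_init, tolerance = 1e-4)
  }
})

test_that("critical damping uses the (A + B t) exp(-w0 t) form", {
  p <- oscillator_params(1, 4, 4)   # zeta = 1, omega0 = 2
  tt <- seq(0, 6, by = 0.02)
  num <- integrate_oscillator(p, tt, x_init = 1, v_init = -0.5)
  expect_lt(max(abs(num$x - critical_position(p, tt, 1, -0.5))), 1e-6)
  expect_error(critical_position(oscillator_params(1, 1, 0.5), 1),
               "critically")
})

test_that("total-energy decay law anchors at E1 and relaxes to E0", {
  expect_equal(energy_decay(0, E0 = -562, E1 = -487, rate = 3), -487)
  expect_equal(energy_decay(c(0, 5, 50), E0 = 1, E1 = 7, rate = 0),
               c(7, 7, 7))
  # one e-folding of the 75 kcal/mol amplitude
  expect_equal(energy_decay(1, E0 = -562, E1 = -487, rate = 1),
               -562 + 75 * exp(-1))
  # monotone toward E0, sign of (E1 - E0) preserved
  tt <- seq(0, 20, by = 0.1)
  e <- energy_decay(tt, E0 = -562, E1 = -487, rate = 0.5)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > -562))
})

test_that("unstable |x|-potential energy is strictly linear in time", {
  expect_equal(unstable_energy(0, mass = 2, K = 3, damping = 1), 9)
  expect_equal(unstable_energy(4, mass = 2, K = 3, damping = 1), -9)
  tt <- c(0.3, 1.7, 4.2, 9)
  e <- unstable_energy(tt, mass = 1.4, K = 2.2, damping = 0.7)
  slopes <- diff(e) / diff(tt)
  expect_equal(slopes, rep(-2.2^2 / (2 * 0.7), 3), tolerance = 1e-12)
  expect_error(unstable_energy(1, 1, 1, 0), "damping")
})

test_that("log time rescaling maps [0, Inf) onto (0, delta_t] decreasingly", {
  expect_equal(transform_time(0, delta_t = 5000, rate = 98.74), 5000)
  expect_lt(transform_time(1e3, delta_t = 5000, rate = 98.74), 1e-300)
  # worked-example value: theta = 0.051 maps back to ~32.5 ps of a 5 ns run
  expect_equal(transform_time(0.051, delta_t = 5000, rate = 98.74),
               5000 * exp(-98.74 * 0.051))
  expect_equal(round(transform_time(0.051, 5000, 98.74), 1), 32.5)
  th <- seq(0, 2, by = 0.01)
  expect_true(all(diff(transform_time(th, 5000, 98.74)) < 0))
  expect_error(transform_time(1, -1, 2), "delta_t")
  expect_error(transform_time(1, 1, 0), "rate")
})

test_that("transformed unstable energy equals the composed linear law", {
  expect_equal(transformed_unstable_energy(0, delta_t = 7, rate = 2,
                                           mass = 2, K = 3, damping = 1),
               unstable_energy(7, mass = 2, K = 3, damping = 1))
  # theta -> Inf recovers the t = 0 energy
  expect_equal(transformed_unstable_energy(1e4, delta_t = 7, rate = 2,
                                           mass = 2, K = 3, damping = 1),
               unstable_energy(0, mass = 2, K = 3, damping = 1))
  # composition identity across random parameters
  set.seed(42)
  for (i in 1:20) {
    m <- runif(1, 0.2, 5); K <- runif(1, 0.2, 5); b <- runif(1, 0.2, 5)
    dt <- runif(1, 0.5, 50); r <- runif(1, 0.1, 100)
    th <- runif(5, 0, 3)
    direct <- transformed_unstable_energy(th, dt, r, m, K, b)
    composed <- unstable_energy(transform_time(th, dt, r), m, K, b)
    expect_equal(direct, composed, tolerance = 1e-12)
  }
})

test_that("conservative limit: total energy is preserved over ten periods", {
  p <- oscillator_params(1, 1, 0)
  tt <- seq(0, 10 * 2 * pi, length.out = 500)
  num <- integrate_oscillator(p, tt, x_init = 1, v_init = 0)
  drift <- max(abs(num$energy - num$energy[1])) / num$energy[1]
  expect_lt(drift, 1e-8)
})

test_that("numerical integration agrees with the matching closed form", {
  # zeta = 0.5 over ten periods
  p <- oscillator_params(1, 1, 1)
  tt <- seq(0, 10 * 2 * pi, length.out = 800)
  num <- integrate_oscillator(p, tt, x_init = 1, v_init = 0.3)
  expect_lt(max(abs(num$x - closed_form_position(p, tt, 1, 0.3))), 1e-6)

  # 20 random draws across both regimes on [0, 10/omega0]
  set.seed(7)
  for (i in 1:20) {
    case <- draw_oscillator_case()
    p <- case$params
    tt <- seq(0, 10 / p$omega0, length.out = 200)
    num <- integrate_oscillator(p, tt, case$x_init, case$v_init)
    closed <- closed_form_position(p, tt, case$x_init, case$v_init)
    expect_lt(max(abs(num$x - closed)), 1e-6)
  }
})

test_that("for beta > 0 the integrated total energy never increases", {
  set.seed(11)
  for (i in 1:5) {
    case <- draw_oscillator_case()
    p <- case$params
    tt <- seq(0, 10 / p$omega0, length.out = 300)
    num <- integrate_oscillator(p, tt, case$x_init, case$v_init)
    expect_true(all(diff(num$energy) <= 1e-9 * num$energy[1]))
  }
})

test_that("vanishing stiffness limit: velocity relaxes at rate beta/m", {
  p <- oscillator_params(2, 1e-8, 3)   # k ~ 0, beta/m = 1.5
  tt <- seq(0, 4, by = 0.02)
  num <- integrate_oscillator(p, tt, x_init = 0, v_init = 1)
  expect_lt(max(abs(num$v - exp(-1.5 * tt))), 1e-4)
})

test_that("integration grid is validated", {
  p <- oscillator_params(1, 1, 0)
  expect_error(integrate_oscillator(p, numeric(0)), "two points")
  expect_error(integrate_oscillator(p, c(0, 1, 1)), "increasing")
  expect_error(integrate_oscillator(p, c(0, 2, 1)), "increasing")
})
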