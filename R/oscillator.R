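#' Damped harmonic oscillator parameters
#'
#' Bundles the mass `m`, spring constant `k` and viscous damping coefficient
#' `beta` of the one-dimensional particle-in-a-well model
#' \deqn{m\ddot x + \beta\dot x + kx = 0,}
#' together with the derived natural frequency \eqn{\omega_0 = \sqrt{k/m}}
#' and damping ratio \eqn{\zeta = \beta/(2\sqrt{km})} (the standard
#' convention, under which the characteristic roots are
#' \eqn{(-\zeta\pm\sqrt{\zeta^2-1})\omega_0}).  The model is the linearised
#' picture of molecular self-assembly: a particle relaxing into a quadratic
#' potential well.  The displacement envelope decays at rate
#' \eqn{\zeta\omega_0} and the total (quadratic) energy at
#' \eqn{2\zeta\omega_0}; energy-law helpers such as [energy_decay()]
#' therefore take their rate explicitly.
#'
#' Units are the caller's responsibility: any consistent (mass, force/length,
#' force time/length) system works, and times passed to solution functions
#' must use the matching time unit.
#'
#' @param mass particle mass, > 0.
#' @param stiffness spring constant `k`, > 0.
#' @param damping viscous damping coefficient `beta`, >= 0.
#' @return An object of class `"oscillator_params"`: a list with fields
#'   `mass`, `stiffness`, `damping`, `omega0` and `zeta`.
#' @examples
#' p <- oscillator_params(mass = 1, stiffness = 4, damping = 2)
#' p$omega0  # 2
#' p$zeta    # 0.5 (underdamped)
#' @seealso [characteristic_roots()], [underdamped_position()],
#'   [overdamped_position()], [integrate_oscillator()]
#' @export
oscillator_params <- function(mass, stiffness, damping = 0) {
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass),
            is.numeric(stiffness), length(stiffness) == 1L, is.finite(stiffness),
            is.numeric(damping), length(damping) == 1L, is.finite(damping))
  if (mass <= 0) stop("'mass' must be positive", call. = FALSE)
  if (stiffness <= 0) stop("'stiffness' must be positive", call. = FALSE)
  if (damping < 0) stop("'damping' must be non-negative", call. = FALSE)
  structure(list(
    mass = mass, stiffness = stiffness, damping = damping,
    omega0 = sqrt(stiffness / mass),
    zeta = damping / (2 * sqrt(stiffness * mass))
  ), class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  regime <- if (x$zeta < 1 - 1e-9) "underdamped" else
    if (x$zeta > 1 + 1e-9) "overdamped" else "critically damped"
  cat("Damped oscillator: m =", x$mass, ", k =", x$stiffness,
      ", beta =", x$damping, "\n")
  cat("  omega0 =", format(x$omega0), ", zeta =", format(x$zeta),
      sprintf("(%s)\n", regime))
  invisible(x)
}

#' Roots of the characteristic equation
#'
#' For the equation of motion \eqn{m\ddot x + \beta\dot x + kx = 0}, the
#' ansatz \eqn{x = e^{zt}} yields
#' \eqn{z = (-\zeta \pm \sqrt{\zeta^2 - 1})\,\omega_0}: a complex-conjugate
#' pair for \eqn{\zeta < 1} (damped oscillations), two negative reals for
#' \eqn{\zeta > 1} (pure relaxation), and a double root \eqn{-\omega_0} at
#' critical damping.
#'
#' @param params an [oscillator_params()] object.
#' @return Complex vector of length 2, ordered `+` root first.
#' @examples
#' characteristic_roots(oscillator_params(1, 1, 0))  # +-1i
#' @export
characteristic_roots <- function(params) {
  stopifnot(inherits(params, "oscillator_params"))
  z <- params$zeta
  disc <- sqrt(as.complex(z^2 - 1))
  roots <- (-z + c(disc, -disc)) * params$omega0
  # real discriminant -> drop the zero imaginary part introduced by as.complex
  if (z >= 1) roots <- complex(real = Re(roots), imaginary = 0)
  roots
}

#' Underdamped oscillator displacement
#'
#' Closed-form solution for \eqn{\zeta < 1}:
#' \deqn{x(t) = x_0 e^{-\zeta\omega_0 t}
#'   \cos\!\left(\sqrt{1 - \zeta^2}\,\omega_0 t - \phi\right),}
#' oscillations inside an exponentially decaying envelope.  `x0` is the
#' envelope amplitude and `phi` the phase angle; use
#' [underdamped_state_from_ic()] to obtain them from an initial position and
#' velocity.
#'
#' @param params an [oscillator_params()] object with `zeta < 1`.
#' @param t time(s), any real value(s).
#' @param x0 envelope amplitude (length units).
#' @param phi phase angle in radians, in (-pi, pi].
#' @return Displacement(s), same length as `t`.
#' @export
underdamped_position <- function(params, t, x0 = 1, phi = 0) {
  stopifnot(inherits(params, "oscillator_params"), is.numeric(t))
  if (params$zeta >= 1) {
    stop("zeta >= 1: not underdamped; use overdamped_position() (or the ",
         "critical form for zeta == 1)", call. = FALSE)
  }
  if (phi <= -pi || phi > pi) stop("'phi' must lie in (-pi, pi]", call. = FALSE)
  w0 <- params$omega0
  wd <- sqrt(1 - params$zeta^2) * w0
  x0 * exp(-params$zeta * w0 * t) * cos(wd * t - phi)
}

#' Overdamped oscillator displacement
#'
#' Closed-form solution for \eqn{\zeta > 1}:
#' \deqn{x(t) = x_0\left(c\,e^{\sqrt{\zeta^2-1}\,\omega_0 t}
#'   + e^{-\sqrt{\zeta^2-1}\,\omega_0 t}\right) e^{-\zeta\omega_0 t}.}
#' Both effective exponents, \eqn{(\pm\sqrt{\zeta^2-1} - \zeta)\omega_0}, are
#' negative, so the motion relaxes without oscillation.  The coefficient `c`
#' selects the mixture of slow and fast decay modes; use
#' [overdamped_state_from_ic()] to obtain `(x0, c)` from an initial position
#' and velocity.
#'
#' @param params an [oscillator_params()] object with `zeta > 1`.
#' @param t time(s).
#' @param x0 amplitude of the fast-decaying mode.
#' @param c dimensionless coefficient of the slow-decaying mode.
#' @return Displacement(s), same length as `t`.
#' @export
overdamped_position <- function(params, t, x0 = 1, c = 0) {
  stopifnot(inherits(params, "oscillator_params"), is.numeric(t))
  if (params$zeta <= 1) {
    stop("zeta <= 1: not overdamped; use underdamped_position() (or the ",
         "critical form for zeta == 1)", call. = FALSE)
  }
  w0 <- params$omega0
  s <- sqrt(params$zeta^2 - 1) * w0
  x0 * (c * exp(s * t) + exp(-s * t)) * exp(-params$zeta * w0 * t)
}

#' Critically damped displacement
#'
#' At \eqn{\zeta = 1} the characteristic roots coincide and the solution is
#' \eqn{x(t) = (A + Bt)e^{-\omega_0 t}}.  With initial position `x_init` and
#' velocity `v_init`, \eqn{A = x(0)} and \eqn{B = v(0) + \omega_0 x(0)}.
#'
#' @param params an [oscillator_params()] object with `zeta == 1` (within
#'   `1e-9`).
#' @param t time(s).
#' @param x_init,v_init initial position and velocity.
#' @return Displacement(s).
#' @export
critical_position <- function(params, t, x_init = 1, v_init = 0) {
  stopifnot(inherits(params, "oscillator_params"))
  if (abs(params$zeta - 1) >= 1e-9) {
    stop("zeta != 1: not critically damped", call. = FALSE)
  }
  w0 <- params$omega0
  (x_init + (v_init + w0 * x_init) * t) * exp(-w0 * t)
}

#' Amplitude and phase from initial conditions (underdamped)
#'
#' Inverts \eqn{x(0) = x_0\cos\phi},
#' \eqn{\dot x(0) = x_0(\omega_d \sin\phi - \zeta\omega_0\cos\phi)} for the
#' envelope amplitude and phase of [underdamped_position()].
#'
#' @param params an [oscillator_params()] object with `zeta < 1`.
#' @param x_init,v_init initial position and velocity.
#' @return List with elements `x0` and `phi` (phi in (-pi, pi]).
#' @export
underdamped_state_from_ic <- function(params, x_init, v_init = 0) {
  stopifnot(inherits(params, "oscillator_params"))
  if (params$zeta >= 1) stop("zeta >= 1: not underdamped", call. = FALSE)
  w0 <- params$omega0
  wd <- sqrt(1 - params$zeta^2) * w0
  phi <- atan2(v_init + params$zeta * w0 * x_init, wd * x_init)
  x0 <- if (abs(cos(phi)) > 1e-12) x_init / cos(phi) else
    (v_init + params$zeta * w0 * x_init) / (wd * sin(phi))
  list(x0 = x0, phi = phi)
}

#' Mode coefficients from initial conditions (overdamped)
#'
#' Inverts \eqn{x(0) = x_0(c + 1)} and the corresponding velocity relation
#' for the `(x0, c)` parameterisation of [overdamped_position()].
#'
#' @param params an [oscillator_params()] object with `zeta > 1`.
#' @param x_init,v_init initial position and velocity (`x_init != 0`).
#' @return List with elements `x0` and `c`.
#' @export
overdamped_state_from_ic <- function(params, x_init, v_init = 0) {
  stopifnot(inherits(params, "oscillator_params"))
  if (params$zeta <= 1) stop("zeta <= 1: not overdamped", call. = FALSE)
  if (x_init == 0) stop("'x_init' must be non-zero for this parameterisation",
                        call. = FALSE)
  s <- sqrt(params$zeta^2 - 1)
  u <- v_init / (x_init * params$omega0)
  r <- (u + params$zeta) / s      # (c - 1)/(c + 1)
  cc <- (1 + r) / (1 - r)
  list(x0 = x_init / (1 + cc), c = cc)
}

#' Exponential total-energy decay of the damped oscillator
#'
#' In both damping regimes the total energy relaxes from its initial value
#' `E1` toward the asymptote `E0` as
#' \deqn{E(t) = E_0 + (E_1 - E_0)e^{-rt},}
#' with \eqn{r = \zeta\omega_0} the damped rate.  This exponential law is the
#' template for the self-assembly (folding) branch of the analysis.
#'
#' @param t time(s), finite.
#' @param E0 asymptotic energy.
#' @param E1 initial energy, `E(0)`.
#' @param rate decay rate `zeta * omega0`, >= 0 (1/time).
#' @return Energy value(s).
#' @examples
#' energy_decay(0, E0 = -562, E1 = -487, rate = 0.2)    # -487
#' energy_decay(5, E0 = -562, E1 = -487, rate = 0.2)    # -562 + 75/e
#' @export
energy_decay <- function(t, E0, E1, rate) {
  stopifnot(is.numeric(t), is.numeric(E0), is.numeric(E1), is.numeric(rate))
  if (rate < 0) stop("'rate' must be non-negative", call. = FALSE)
  E0 + (E1 - E0) * exp(-rate * t)
}

#' Constant-rate energy loss in the unstable |x| potential
#'
#' Disassembly is modelled by a particle on the potential
#' \eqn{-(K/2)|x|}: the constant driving force `K` is asymptotically
#' balanced by friction (\eqn{K = \beta\dot x}, terminal speed
#' \eqn{K/\beta}), so the total energy falls linearly,
#' \deqn{E(t) = \frac{m}{2}\left(\frac{K}{\beta}\right)^2
#'   - \frac{K^2}{2\beta}\,t.}
#'
#' @param t time(s).
#' @param mass particle mass, > 0.
#' @param K constant driving force, > 0.
#' @param damping viscous damping `beta`, > 0 (a terminal velocity must
#'   exist).
#' @return Energy value(s); slope is `-K^2/(2*damping)` everywhere.
#' @export
unstable_energy <- function(t, mass, K, damping) {
  stopifnot(is.numeric(t), is.numeric(mass), is.numeric(K), is.numeric(damping))
  if (mass <= 0) stop("'mass' must be positive", call. = FALSE)
  if (K <= 0) stop("'K' must be positive", call. = FALSE)
  if (damping <= 0) {
    stop("'damping' must be positive: without friction there is no terminal ",
         "velocity and the linear-energy regime does not exist", call. = FALSE)
  }
  (mass / 2) * (K / damping)^2 - (K^2 / (2 * damping)) * t
}

#' Logarithmic time rescaling
#'
#' The coordinate change that maps the slow exponential assembly time scale
#' onto the fast linear disassembly one:
#' \deqn{t = \Delta t\, e^{-r\vartheta},}
#' where `r` is the non-dimensional rate \eqn{\zeta\omega_0\Delta t} and
#' \eqn{\Delta t} the total disassembly duration.  The map is strictly
#' decreasing: \eqn{\vartheta = 0} corresponds to \eqn{t = \Delta t} and
#' \eqn{\vartheta \to \infty} to \eqn{t \to 0}.  Its inverse on the
#' normalised scale is [theta_of_tau()].
#'
#' @param theta transformed time(s), >= 0 for the physical branch.
#' @param delta_t total duration (time units), > 0.
#' @param rate non-dimensional rate, > 0.
#' @return Original time(s) `t`, in the units of `delta_t`.
#' @export
transform_time <- function(theta, delta_t, rate) {
  stopifnot(is.numeric(theta), is.numeric(delta_t), is.numeric(rate))
  if (delta_t <= 0) stop("'delta_t' must be positive", call. = FALSE)
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  delta_t * exp(-rate * theta)
}

#' Unstable-potential energy in the transformed time variable
#'
#' Composing the linear energy law of [unstable_energy()] with the rescaling
#' of [transform_time()] turns constant-rate decay into an exponential:
#' \deqn{E(\vartheta) = \frac{m}{2}\left(\frac{K}{\beta}\right)^2
#'   - \frac{K^2\Delta t}{2\beta}\, e^{-r\vartheta},}
#' structurally identical to the relaxation law of the stable well.  This is
#' the analytic heart of viewing self-assembly as time-reversed disassembly.
#'
#' @inheritParams transform_time
#' @inheritParams unstable_energy
#' @return Energy value(s); identical to
#'   `unstable_energy(transform_time(theta, delta_t, rate), ...)`.
#' @export
transformed_unstable_energy <- function(theta, delta_t, rate, mass, K, damping) {
  stopifnot(is.numeric(theta))
  if (delta_t <= 0) stop("'delta_t' must be positive", call. = FALSE)
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  if (mass <= 0) stop("'mass' must be positive", call. = FALSE)
  if (K <= 0) stop("'K' must be positive", call. = FALSE)
  if (damping <= 0) stop("'damping' must be positive", call. = FALSE)
  (mass / 2) * (K / damping)^2 -
    (K^2 * delta_t / (2 * damping)) * exp(-rate * theta)
}

#' Numerical integration of the damped-oscillator equation of motion
#'
#' Integrates \eqn{m\ddot x + \beta\dot x + kx = 0} on a user grid with an
#' adaptive solver (via \pkg{deSolve}).  Serves as the independent numerical
#' check of the closed-form solutions; default tolerances are far tighter
#' than the `1e-6` at which closed forms are expected to agree.
#'
#' @param params an [oscillator_params()] object.
#' @param times strictly increasing numeric grid (the first entry is the
#'   initial time).
#' @param x_init,v_init initial position and velocity at `times[1]`.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param method integration method passed to [deSolve::ode()].
#' @return A data frame with columns `time`, `x`, `v` and `energy`
#'   (the total energy \eqn{\frac{m}{2}\dot x^2 + \frac{k}{2}x^2}).
#' @examples
#' p <- oscillator_params(1, 1, 0.2)
#' tr <- integrate_oscillator(p, seq(0, 20, by = 0.1), x_init = 1)
#' max(abs(diff(tr$energy)) > 0)  # energy is dissipated monotonically
#' @export
integrate_oscillator <- function(params, times, x_init = 1, v_init = 0,
                                 rtol = 1e-10, atol = 1e-10,
                                 method = "lsoda") {
  stopifnot(inherits(params, "oscillator_params"), is.numeric(times))
  if (length(times) < 2L) stop("'times' must contain at least two points",
                               call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("'times' must be a finite, strictly increasing grid", call. = FALSE)
  }
  deriv <- function(t, y, p) {
    list(c(y[2L], -(p$damping * y[2L] + p$stiffness * y[1L]) / p$mass))
  }
  sol <- deSolve::ode(y = c(x = x_init, v = v_init), times = times,
                      func = deriv, parms = params,
                      rtol = rtol, atol = atol, method = method)
  out <- as.data.frame(sol)
  names(out) <- c("time", "x", "v")
  out$energy <- (params$mass / 2) * out$v^2 + (params$stiffness / 2) * out$x^2
  out
}

# Closed-form displacement for arbitrary initial conditions, dispatching on
# the damping regime (|zeta - 1| < 1e-9 is treated as critical).
#' Closed-form displacement from initial conditions
#'
#' Convenience wrapper that picks the underdamped, critically damped or
#' overdamped closed form according to `params$zeta` and evaluates it for
#' initial position `x_init` and velocity `v_init`.
#'
#' @inheritParams integrate_oscillator
#' @param t time(s).
#' @return Displacement(s).
#' @export
closed_form_position <- function(params, t, x_init = 1, v_init = 0) {
  stopifnot(inherits(params, "oscillator_params"))
  z <- params$zeta
  if (abs(z - 1) < 1e-9) {
    critical_position(params, t, x_init, v_init)
  } else if (z < 1) {
    st <- underdamped_state_from_ic(params, x_init, v_init)
    underdamped_position(params, t, x0 = st$x0, phi = st$phi)
  } else {
    st <- overdamped_state_from_ic(params, x_init, v_init)
    overdamped_position(params, t, x0 = st$x0, c = st$c)
  }
}
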