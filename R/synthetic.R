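# Seeded RNG helper: run `expr` under set.seed(seed) without disturbing the
# caller's RNG stream; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic unfolding energy trajectory
#'
#' Emulates the canonical shape of a thermal-denaturation energy profile: an
#' almost linear rise during the initial constant-rate stage, followed by an
#' exponential approach to the unfolded plateau.  The two pieces join with
#' matching value and slope at `t_linear_end`, so the tail rate is fixed by
#' continuity rather than being a free knob:
#' \deqn{E(t) = \begin{cases}
#'   E_\mathrm{init} + \dfrac{t}{t_\mathrm{lin}}\,\varepsilon_\mathrm{lin}
#'     (E_\mathrm{plateau} - E_\mathrm{init}), & t \le t_\mathrm{lin},\\
#'   E_\mathrm{plateau} - (E_\mathrm{plateau} - E(t_\mathrm{lin}))
#'     e^{-\lambda (t - t_\mathrm{lin})}, & t > t_\mathrm{lin},
#' \end{cases}}
#' with \eqn{\lambda = \varepsilon_\mathrm{lin} /
#' ((1 - \varepsilon_\mathrm{lin})\, t_\mathrm{lin})}.
#'
#' The defaults are the Trp-cage denaturation profile: energy rising from
#' \eqn{-707.6} kcal/mol at \eqn{t = 0} to \eqn{-478.4} kcal/mol at the end
#' of the linear stage (\eqn{t = 31.8} ps), then levelling toward
#' \eqn{-350} kcal/mol well before the 5 ns run ends.  The default
#' `epsilon_lin` is the normalised value these three anchors imply,
#' \eqn{(707.6 - 478.4)/(707.6 - 350)}.
#'
#' @param E_initial starting (native-state) energy, kcal/mol.
#' @param E_plateau unfolded plateau energy, kcal/mol; must exceed
#'   `E_initial` (unfolding raises energy).
#' @param t_linear_end end of the constant-rate stage, ps.
#' @param epsilon_lin normalised energy reached at `t_linear_end`, in (0, 1).
#' @param delta_t total duration, ps.
#' @param n_points number of uniform grid samples (grid includes 0 and
#'   `delta_t`).
#' @param noise_sigma s.d. of additive i.i.d. Gaussian energy noise,
#'   kcal/mol.
#' @param seed optional RNG seed; identical `(spec, seed)` pairs produce
#'   byte-identical trajectories, and the caller's RNG state is untouched.
#' @param times optional explicit time grid (ps) replacing the uniform one;
#'   useful to place a sample exactly at `t_linear_end`.
#' @return An [energy_trajectory()] with `source = "synthetic"`.
#' @examples
#' unf <- generate_unfolding()          # noiseless Trp-cage preset
#' unf$energy[1]                        # -707.6
#' @export
generate_unfolding <- function(E_initial = -707.6, E_plateau = -350,
                               t_linear_end = 31.8,
                               epsilon_lin = (707.6 - 478.4) / (707.6 - 350),
                               delta_t = 5000, n_points = 501,
                               noise_sigma = 0, seed = NULL, times = NULL) {
  if (E_plateau <= E_initial) {
    stop("unfolding must raise the energy: need E_plateau > E_initial",
         call. = FALSE)
  }
  if (epsilon_lin <= 0 || epsilon_lin >= 1) {
    stop("'epsilon_lin' must lie in (0, 1)", call. = FALSE)
  }
  if (t_linear_end <= 0 || t_linear_end >= delta_t) {
    stop("'t_linear_end' must lie strictly inside (0, delta_t)",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative", call. = FALSE)
  if (is.null(times)) {
    if (n_points < 2L) stop("'n_points' must be at least 2", call. = FALSE)
    times <- seq(0, delta_t, length.out = n_points)
  }
  dE <- E_plateau - E_initial
  E_lin <- E_initial + epsilon_lin * dE
  lambda <- epsilon_lin / ((1 - epsilon_lin) * t_linear_end)
  energies <- ifelse(
    times <= t_linear_end,
    E_initial + (times / t_linear_end) * epsilon_lin * dE,
    E_plateau - (E_plateau - E_lin) * exp(-lambda * (times - t_linear_end)))
  if (noise_sigma > 0) {
    energies <- energies +
      with_seed(seed, stats::rnorm(length(times), 0, noise_sigma))
  }
  energy_trajectory(times, energies, label = "synthetic unfolding")
}

#' Generate a synthetic folding energy trajectory
#'
#' Single-exponential relaxation toward the native-state energy,
#' \deqn{E(t) = E_\mathrm{native} + (E_\mathrm{start} - E_\mathrm{native})
#'   e^{-rt} + \mathrm{noise},}
#' the shape an equilibration-stage folding energy profile relaxes along.
#' Defaults are the Trp-cage equilibration: energy decaying from
#' \eqn{-487} to \eqn{-562} kcal/mol with time constant 5 ns, sampled over
#' 25 ns (five time constants, by which point the profile is flat at the
#' plotting scale).
#'
#' @param E_start energy at `t = 0`, kcal/mol.
#' @param E_native native-state asymptote, kcal/mol; must lie below
#'   `E_start` (folding lowers energy).
#' @param rate exponential decay rate, 1/ps.
#' @param delta_t total duration, ps.
#' @inheritParams generate_unfolding
#' @return An [energy_trajectory()].
#' @export
generate_folding <- function(E_start = -487, E_native = -562,
                             rate = 1 / 5000, delta_t = 25000,
                             n_points = 501, noise_sigma = 0, seed = NULL,
                             times = NULL) {
  if (E_native >= E_start) {
    stop("folding must lower the energy: need E_native < E_start",
         call. = FALSE)
  }
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative", call. = FALSE)
  if (is.null(times)) {
    if (n_points < 2L) stop("'n_points' must be at least 2", call. = FALSE)
    times <- seq(0, delta_t, length.out = n_points)
  }
  energies <- energy_decay(times, E0 = E_native, E1 = E_start, rate = rate)
  if (noise_sigma > 0) {
    energies <- energies +
      with_seed(seed, stats::rnorm(length(times), 0, noise_sigma))
  }
  energy_trajectory(times, energies, label = "synthetic folding")
}

#' Named synthetic-trajectory presets
#'
#' Looks up a preset name and returns the matching generator argument list.
#' Available presets: `"trpcage-unfold"` (the 5 ns denaturation profile)
#' and `"trpcage-fold"` (the equilibration-stage relaxation).
#'
#' @param name preset name.
#' @return Named list of arguments for [generate_unfolding()] or
#'   [generate_folding()], with an additional `kind` element
#'   (`"unfold"`/`"fold"`).
#' @export
trajectory_preset <- function(name = c("trpcage-unfold", "trpcage-fold")) {
  name <- match.arg(name)
  switch(name,
    "trpcage-unfold" = list(kind = "unfold", E_initial = -707.6,
                            E_plateau = -350, t_linear_end = 31.8,
                            epsilon_lin = (707.6 - 478.4) / (707.6 - 350),
                            delta_t = 5000, n_points = 501),
    "trpcage-fold" = list(kind = "fold", E_start = -487, E_native = -562,
                          rate = 1 / 5000, delta_t = 25000, n_points = 501))
}
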