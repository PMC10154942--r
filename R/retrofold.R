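#' Normalise potential energy to the unit interval
#'
#' Maps energy onto the dimensionless coordinate
#' \deqn{\varepsilon = \frac{E - E_\mathrm{initial}}
#'   {E_\mathrm{final} - E_\mathrm{initial}},}
#' so that the start of the disassembly run is 0 and its plateau is 1.
#'
#' @param energy energy value(s), kcal/mol.
#' @param E_initial energy at the start of the run.
#' @param E_final plateau (final) energy; must differ from `E_initial`.
#' @return Dimensionless value(s).
#' @examples
#' normalize_energy(-478.4, E_initial = -707.6, E_final = -350)
#' @export
normalize_energy <- function(energy, E_initial, E_final) {
  stopifnot(is.numeric(energy), is.numeric(E_initial), is.numeric(E_final))
  if (E_final == E_initial) {
    stop("degenerate normalisation: E_final equals E_initial", call. = FALSE)
  }
  (energy - E_initial) / (E_final - E_initial)
}

#' Normalise time by the total run duration
#'
#' \eqn{\tau = t/\Delta t}; both arguments in the same unit (ps throughout
#' this package).
#'
#' @param t time(s), >= 0.
#' @param delta_t total duration, > 0.
#' @return Dimensionless time(s).
#' @export
normalize_time <- function(t, delta_t) {
  stopifnot(is.numeric(t), is.numeric(delta_t))
  if (delta_t <= 0) stop("'delta_t' must be positive", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  t / delta_t
}

#' Non-dimensional disassembly rate
#'
#' The single parameter of the time-rescaling transformation: the ratio
#' \eqn{\zeta\omega_0\Delta t = \varepsilon/\tau} of normalised energy to
#' normalised time at the end of the constant-rate stage.
#'
#' @param epsilon normalised energy at the linear-stage end.
#' @param tau normalised time at the linear-stage end, > 0.
#' @return The dimensionless rate.
#' @examples
#' estimate_rate(0.6418, 0.0065)  # the Trp-cage worked-example value, 98.74
#' @export
estimate_rate <- function(epsilon, tau) {
  stopifnot(is.numeric(epsilon), is.numeric(tau))
  if (any(tau <= 0)) stop("'tau' must be positive", call. = FALSE)
  epsilon / tau
}

#' Log-rescaled time variable
#'
#' \deqn{\vartheta = \frac{\ln\tau}{-r},}
#' the inverse of [transform_time()] on the normalised scale: \eqn{\tau = 1}
#' maps to \eqn{\vartheta = 0} (the fully disassembled state) and
#' \eqn{\tau \to 0^+} to \eqn{\vartheta \to \infty} (the ordered state).
#'
#' @param tau normalised time(s) in (0, 1].
#' @param rate non-dimensional rate, > 0.
#' @return Transformed time(s), >= 0, strictly decreasing in `tau`.
#' @examples
#' theta_of_tau(0.0065, 98.74)  # ~0.051
#' @export
theta_of_tau <- function(tau, rate) {
  stopifnot(is.numeric(tau), is.numeric(rate))
  if (any(tau <= 0) || any(tau > 1)) {
    stop("'tau' must lie in (0, 1]", call. = FALSE)
  }
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  log(tau) / (-rate)
}

#' Detect the constant-rate (linear) stage of an unfolding trajectory
#'
#' Finds the largest prefix `[t_1, t_k]` of the trajectory whose
#' least-squares straight-line fit has \eqn{R^2} at or above `r2_threshold`,
#' and returns the prefix end together with the fitted slope.  Intended for
#' smooth, low-noise energy profiles; for noisy data lower the threshold or
#' supply the boundary manually to [retrofold()].
#'
#' @param traj an [energy_trajectory()] with at least 4 points.
#' @param r2_threshold minimum \eqn{R^2} of the prefix fit.  The default
#'   `0.9999` is deliberately strict: an exponential tail joined with
#'   matching slope deviates from the line only quadratically, so looser
#'   thresholds accept long stretches of curvature and bias the rate low.
#' @param min_points smallest admissible prefix length (>= 3).
#' @return List with `t_linear_end` (ps), `slope` (kcal/mol/ps),
#'   `n_points`, and `r_squared` of the accepted prefix.
#' @export
detect_linear_stage <- function(traj, r2_threshold = 0.9999, min_points = 3L) {
  stopifnot(is_energy_trajectory(traj))
  n <- nrow(traj)
  if (n < 4L) stop("need at least 4 points to detect a linear stage",
                   call. = FALSE)
  min_points <- max(3L, as.integer(min_points))
  t <- traj$time
  e <- traj$energy
  # prefix R^2 via running sums: O(n) over all prefixes
  st <- cumsum(t); se <- cumsum(e)
  stt <- cumsum(t * t); see <- cumsum(e * e); ste <- cumsum(t * e)
  k <- seq_len(n)
  sxx <- stt - st^2 / k
  syy <- see - se^2 / k
  sxy <- ste - st * se / k
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), NA_real_)
  ok <- which(k >= min_points & !is.na(r2) & r2 >= r2_threshold)
  if (length(ok) == 0L) {
    stop(sprintf(paste0("no prefix of >= %d points reaches R^2 >= %g; ",
                        "supply 't_linear_end' manually or lower the threshold"),
                 min_points, r2_threshold), call. = FALSE)
  }
  kbest <- max(ok)
  list(t_linear_end = t[kbest],
       slope = sxy[kbest] / sxx[kbest],
       n_points = kbest,
       r_squared = r2[kbest])
}

#' Reconstructed folding-energy law
#'
#' The exponential relaxation model obtained by reversing the rescaled
#' disassembly time:
#' \deqn{E(t) = E_\mathrm{min} + (E_\mathrm{max} - E_\mathrm{min})\,
#'   e^{-t/\Delta t},}
#' with `E_max` the energy at the start of assembly (`t = 0`), `E_min` the
#' native-state asymptote, and `time_constant` \eqn{\Delta t} the total
#' disassembly duration.
#'
#' @param E_min asymptotic (native-state) energy, kcal/mol.
#' @param E_max initial energy, kcal/mol; must exceed `E_min` (assembly
#'   releases energy).
#' @param time_constant exponential time constant, ps.
#' @param rate the non-dimensional rate the model was built from (optional
#'   metadata).
#' @return An object of class `"retrofold_model"`.
#' @examples
#' m <- retrofold_model(E_min = -562, E_max = -487, time_constant = 5000)
#' predict(m, c(0, 5000))
#' @export
retrofold_model <- function(E_min, E_max, time_constant, rate = NA_real_) {
  stopifnot(is.numeric(E_min), is.numeric(E_max), is.numeric(time_constant))
  if (E_min >= E_max) {
    stop("'E_min' must be below 'E_max': self-assembly lowers the energy",
         call. = FALSE)
  }
  if (time_constant <= 0) stop("'time_constant' must be positive",
                               call. = FALSE)
  structure(list(E_min = E_min, E_max = E_max,
                 time_constant = time_constant, rate = rate),
            class = "retrofold_model")
}

#' @export
print.retrofold_model <- function(x, ...) {
  cat("Reconstructed folding-energy law:\n")
  cat(sprintf("  E(t) = %g + (%g) * exp(-t / %g)   [kcal/mol, t in ps]\n",
              x$E_min, x$E_max - x$E_min, x$time_constant))
  if (is.finite(x$rate)) cat("  non-dimensional rate:", format(x$rate), "\n")
  invisible(x)
}

#' @rdname retrofold_model
#' @param object a `"retrofold_model"`.
#' @param newdata numeric times (ps), >= 0, at which to evaluate the model.
#' @param ... unused.
#' @export
predict.retrofold_model <- function(object, newdata, ...) {
  stopifnot(is.numeric(newdata))
  if (any(newdata < 0)) stop("model times must be non-negative", call. = FALSE)
  energy_decay(newdata, E0 = object$E_min, E1 = object$E_max,
               rate = 1 / object$time_constant)
}

#' Score a folding model against a reference trajectory
#'
#' Evaluates the model at every reference sample time and reports the
#' pointwise relative error
#' \eqn{100\,|E_\mathrm{model} - E_\mathrm{ref}| / |E_\mathrm{ref}|},
#' its maximum, and the time at which the maximum occurs.  Reference points
#' with exactly zero energy cannot carry a relative error and are excluded
#' with a warning.
#'
#' @param model a [retrofold_model()].
#' @param reference an [energy_trajectory()] of the true (simulated)
#'   assembly energies.
#' @return An object of class `"retrofold_comparison"`: list with `time`,
#'   `error_pct` (per point), `max_error_pct`, `t_at_max_error`, `n_points`.
#' @export
compare_to_reference <- function(model, reference) {
  stopifnot(inherits(model, "retrofold_model"), is_energy_trajectory(reference))
  keep <- reference$energy != 0
  if (!all(keep)) {
    warning(sum(!keep), " reference point(s) with zero energy excluded from ",
            "the relative-error comparison")
  }
  t <- reference$time[keep]
  eref <- reference$energy[keep]
  if (length(t) == 0L) stop("no usable reference points", call. = FALSE)
  emod <- predict(model, t)
  err <- abs(emod - eref) / abs(eref) * 100
  imax <- which.max(err)
  structure(list(time = t, error_pct = err,
                 reference_energy = eref, model_energy = emod,
                 max_error_pct = err[imax],
                 t_at_max_error = t[imax],
                 n_points = length(t)),
            class = "retrofold_comparison")
}

#' @export
print.retrofold_comparison <- function(x, ...) {
  cat(sprintf("Model vs reference over %d points: max error %.3g%% at t = %g ps\n",
              x$n_points, x$max_error_pct, x$t_at_max_error))
  invisible(x)
}

#' Reconstruct a folding-energy trajectory from an unfolding simulation
#'
#' The main fitting function.  Starting from a fast unfolding (disassembly)
#' energy trajectory it
#' \enumerate{
#'   \item validates the direction (net energy increase),
#'   \item normalises energy by the run's initial and plateau values and
#'     time by the total duration,
#'   \item locates the end of the constant-rate (linear) stage
#'     ([detect_linear_stage()], unless supplied),
#'   \item forms the non-dimensional rate \eqn{r = \varepsilon/\tau} at that
#'     point,
#'   \item applies the log time rescaling \eqn{\vartheta = \ln\tau/(-r)} and
#'     reverses time,
#'   \item returns the exponential folding-energy law
#'     \eqn{E(t) = E_{\min} + (E_{\max}-E_{\min})e^{-t/\Delta t}}.
#' }
#' The folding endpoints `E_min`/`E_max` are not derivable from unfolding
#' alone: supply them directly, or give a `reference` folding trajectory
#' from which they are taken as the means of its last/first 5\% of points
#' (and against which the model is scored).
#'
#' The overrides `epsilon` and `tau` replace the internally computed
#' normalised coordinates of the linear-stage end; they exist so that a
#' published worked example, whose printed values carry rounding, can be
#' reproduced digit for digit.
#'
#' @param unfold an [energy_trajectory()] of the unfolding run.
#' @param E_min,E_max folding-energy endpoints, kcal/mol (`E_min` native
#'   asymptote, `E_max` start of assembly).  Optional if `reference` given.
#' @param reference optional folding [energy_trajectory()] used to extract
#'   missing endpoints and to compute an error report.
#' @param delta_t total unfolding duration, ps; defaults to the last
#'   trajectory time.
#' @param E_initial,E_final normalisation anchors; default to the first and
#'   last trajectory energies.
#' @param t_linear_end end of the constant-rate stage, ps; overrides
#'   automatic detection.  Energy there is obtained by linear interpolation
#'   between the bracketing samples.
#' @param epsilon,tau optional overrides of the normalised coordinates at
#'   the linear-stage end.
#' @param time_constant time constant of the reconstructed law, ps;
#'   defaults to `delta_t`.
#' @param r2_threshold passed to [detect_linear_stage()].
#' @return An object of class `"retrofold"`: list with components `model`
#'   (a [retrofold_model()]), `epsilon`, `tau`, `rate`, `theta_linear_end`,
#'   `t_linear_end`, `slope`, `detection`, `delta_t`, `E_initial`,
#'   `E_final`, `comparison` (or `NULL`) and `call`.
#' @examples
#' unf <- generate_unfolding()                  # Trp-cage profile, noiseless
#' fit <- retrofold(unf, E_min = -562, E_max = -487, t_linear_end = 31.8)
#' fit
#' predict(fit, c(0, 524, 5000))
#' @seealso [predict.retrofold()], [summary.retrofold()],
#'   [retrofold_report()]
#' @export
retrofold <- function(unfold, E_min = NULL, E_max = NULL, reference = NULL,
                      delta_t = NULL, E_initial = NULL, E_final = NULL,
                      t_linear_end = NULL, epsilon = NULL, tau = NULL,
                      time_constant = NULL, r2_threshold = 0.9999) {
  cl <- match.call()
  if (!is_energy_trajectory(unfold)) {
    stop("input stage: 'unfold' must be an energy_trajectory", call. = FALSE)
  }
  n <- nrow(unfold)
  if (unfold$energy[n] <= unfold$energy[1L]) {
    stop("input stage: net energy decrease - not an unfolding profile ",
         "(unfolding must raise the potential energy)", call. = FALSE)
  }
  if (!is.null(reference)) {
    if (!is_energy_trajectory(reference)) {
      stop("input stage: 'reference' must be an energy_trajectory",
           call. = FALSE)
    }
    nr <- nrow(reference)
    if (reference$energy[nr] >= reference$energy[1L]) {
      stop("input stage: net energy increase - not a folding profile ",
           "(folding must lower the potential energy)", call. = FALSE)
    }
    ntail <- max(1L, ceiling(0.05 * nr))
    if (is.null(E_max)) E_max <- mean(reference$energy[seq_len(ntail)])
    if (is.null(E_min)) E_min <- mean(reference$energy[seq.int(nr - ntail + 1L, nr)])
  }
  if (is.null(E_min) || is.null(E_max)) {
    stop("input stage: folding endpoints E_min/E_max are required ",
         "(directly or via a reference folding trajectory)", call. = FALSE)
  }
  if (is.null(delta_t)) delta_t <- unfold$time[n]
  if (is.null(E_initial)) E_initial <- unfold$energy[1L]
  if (is.null(E_final)) E_final <- unfold$energy[n]

  detection <- NULL
  slope <- NA_real_
  if (is.null(t_linear_end)) {
    detection <- tryCatch(
      detect_linear_stage(unfold, r2_threshold = r2_threshold),
      error = function(e) {
        stop("linear-stage detection: ", conditionMessage(e), call. = FALSE)
      })
    t_linear_end <- detection$t_linear_end
    slope <- detection$slope
  }
  if (t_linear_end <= 0 || t_linear_end >= delta_t) {
    stop("linear-stage detection: t_linear_end must lie strictly inside ",
         "(0, delta_t)", call. = FALSE)
  }
  E_lin <- stats::approx(unfold$time, unfold$energy, xout = t_linear_end,
                         rule = 2)$y
  if (is.null(epsilon)) epsilon <- normalize_energy(E_lin, E_initial, E_final)
  if (is.null(tau)) tau <- normalize_time(t_linear_end, delta_t)
  if (epsilon <= 0) {
    stop("normalisation stage: epsilon at the linear-stage end is not ",
         "positive; check the E_initial/E_final anchors", call. = FALSE)
  }
  rate <- estimate_rate(epsilon, tau)
  theta_lin <- theta_of_tau(tau, rate)
  if (is.null(time_constant)) time_constant <- delta_t
  model <- retrofold_model(E_min = E_min, E_max = E_max,
                           time_constant = time_constant, rate = rate)
  comparison <- if (!is.null(reference)) {
    compare_to_reference(model, reference)
  }
  structure(list(model = model, epsilon = epsilon, tau = tau, rate = rate,
                 theta_linear_end = theta_lin, t_linear_end = t_linear_end,
                 slope = slope, detection = detection, delta_t = delta_t,
                 E_initial = E_initial, E_final = E_final,
                 comparison = comparison, call = cl),
            class = "retrofold")
}

#' @export
print.retrofold <- function(x, digits = 6, ...) {
  cat("RetroFold reconstruction\n")
  cat(sprintf("  linear stage end: t = %s ps (tau = %s), epsilon = %s\n",
              format(x$t_linear_end, digits = digits),
              format(x$tau, digits = digits),
              format(x$epsilon, digits = digits)))
  cat(sprintf("  non-dimensional rate: %s   theta at stage end: %s\n",
              format(x$rate, digits = digits),
              format(x$theta_linear_end, digits = digits)))
  print(x$model)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Summarise a RetroFold fit
#'
#' @param object a `"retrofold"` object.
#' @param ... unused.
#' @return The object, invisibly, after printing all pipeline quantities.
#' @export
summary.retrofold <- function(object, ...) {
  print(object)
  cat(sprintf("  normalisation anchors: E_initial = %g, E_final = %g kcal/mol; delta_t = %g ps\n",
              object$E_initial, object$E_final, object$delta_t))
  if (!is.null(object$detection)) {
    cat(sprintf("  linear stage detected over %d points (R^2 = %.6f), slope %g kcal/mol/ps\n",
                object$detection$n_points, object$detection$r_squared,
                object$slope))
  } else {
    cat("  linear-stage end supplied by the caller\n")
  }
  invisible(object)
}

#' @export
coef.retrofold <- function(object, ...) {
  c(E_min = object$model$E_min, E_max = object$model$E_max,
    rate = object$rate, time_constant = object$model$time_constant)
}

#' Evaluate the reconstructed folding law
#'
#' @param object a `"retrofold"` fit.
#' @param newdata numeric times in ps (>= 0).  Defaults to the reference
#'   sample times when a reference was supplied.
#' @param ... unused.
#' @return Predicted folding energies, kcal/mol.
#' @export
predict.retrofold <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$comparison)) {
      stop("'newdata' required: the fit holds no reference times",
           call. = FALSE)
    }
    newdata <- object$comparison$time
  }
  predict(object$model, newdata)
}

#' Residuals of a RetroFold fit against its reference
#'
#' @param object a `"retrofold"` fit made with a `reference` trajectory.
#' @param ... unused.
#' @return `model - reference` energies at the reference times, kcal/mol.
#' @export
residuals.retrofold <- function(object, ...) {
  if (is.null(object$comparison)) {
    stop("no reference trajectory was supplied to retrofold()", call. = FALSE)
  }
  object$comparison$model_energy - object$comparison$reference_energy
}

#' Plot a RetroFold reconstruction
#'
#' Draws the reconstructed exponential folding law and, when present, the
#' reference folding trajectory it was scored against.
#'
#' @param x a `"retrofold"` fit.
#' @param n number of curve evaluation points.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.retrofold <- function(x, n = 400, ...) {
  tmax <- if (!is.null(x$comparison)) max(x$comparison$time) else
    5 * x$model$time_constant
  tt <- seq(0, tmax, length.out = n)
  curve_e <- predict(x$model, tt)
  ylim <- range(curve_e,
                if (!is.null(x$comparison)) x$comparison$reference_energy)
  graphics::plot(tt, curve_e, type = "l", lwd = 2, ylim = ylim,
                 xlab = "time (ps)", ylab = "potential energy (kcal/mol)",
                 main = "RetroFold reconstructed folding energy", ...)
  if (!is.null(x$comparison)) {
    graphics::points(x$comparison$time, x$comparison$reference_energy,
                     pch = 16, cex = 0.5, col = "grey40")
    graphics::legend("topright", bty = "n", lwd = c(2, NA), pch = c(NA, 16),
                     col = c("black", "grey40"),
                     legend = c("reconstruction", "reference"))
  }
  invisible(x)
}

#' Simulate noisy folding trajectories from a fitted model
#'
#' Draws `nsim` trajectories from the reconstructed law with i.i.d.
#' Gaussian energy noise, mirroring the synthetic folding generator.
#'
#' @param object a `"retrofold"` fit.
#' @param nsim number of trajectories.
#' @param seed optional RNG seed (restored on exit).
#' @param times evaluation times, ps; defaults to 201 points over
#'   `[0, 5 * time_constant]`.
#' @param noise_sigma Gaussian noise s.d., kcal/mol.
#' @param ... unused.
#' @return A list of [energy_trajectory()] objects of length `nsim`.
#' @export
simulate.retrofold <- function(object, nsim = 1, seed = NULL, times = NULL,
                               noise_sigma = 1, ...) {
  if (is.null(times)) {
    times <- seq(0, 5 * object$model$time_constant, length.out = 201)
  }
  base <- predict(object$model, times)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    energy_trajectory(times, base + stats::rnorm(length(times), 0, noise_sigma),
                      label = sprintf("simulated folding %d", i))
  }))
}

#' Structured run report of a RetroFold fit
#'
#' Collects every pipeline quantity into a flat named list suitable for
#' JSON serialisation; [write_retrofold_report()] writes it to disk.
#'
#' @param fit a `"retrofold"` object.
#' @return Named list with keys `epsilon`, `tau`, `rate`,
#'   `theta_linear_end`, `t_linear_end_ps`, `E_min`, `E_max`,
#'   `time_constant`, and -- when a reference was scored --
#'   `max_error_pct` and `t_at_max_error_ps`.
#' @export
retrofold_report <- function(fit) {
  stopifnot(inherits(fit, "retrofold"))
  rep <- list(epsilon = fit$epsilon,
              tau = fit$tau,
              rate = fit$rate,
              theta_linear_end = fit$theta_linear_end,
              t_linear_end_ps = fit$t_linear_end,
              E_min = fit$model$E_min,
              E_max = fit$model$E_max,
              time_constant = fit$model$time_constant)
  if (!is.null(fit$comparison)) {
    rep$max_error_pct <- fit$comparison$max_error_pct
    rep$t_at_max_error_ps <- fit$comparison$t_at_max_error
  }
  rep
}

#' @rdname retrofold_report
#' @param path output JSON file.
#' @return For `write_retrofold_report()`: invisibly, `path`.
#' @export
write_retrofold_report <- function(fit, path) {
  jsonlite::write_json(retrofold_report(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
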