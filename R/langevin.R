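#' Potential specifications for Brownian-dynamics sampling
#'
#' `potential_spec()` describes a 1-D or 2-D potential energy surface on
#' which [simulate_langevin()] integrates overdamped (Brownian)
#' dynamics. Built-in forms:
#'
#' * `"harmonic"`: V(x) = 1/2 k |x - x0|^2 (params `k`, `x0`);
#' * `"double_well"`: V(x) = a (x1^2 - 1)^2 (+ 1/2 k x2^2 in 2-D),
#'   params `a`, `k` — a symmetric two-state landscape whose barrier at
#'   x1 = 0 makes the left/right hop the slowest process;
#' * `"custom"`: user-supplied `potential(x)` and `gradient(x)`.
#'
#' @param form One of `"harmonic"`, `"double_well"`, `"custom"`.
#' @param dimension 1 or 2.
#' @param params Named list of parameters for the built-in forms.
#' @param kT Thermal energy (reduced units), > 0.
#' @param friction Friction coefficient gamma, > 0.
#' @param dt Integrator timestep (reduced units), > 0.
#' @param potential,gradient Functions for `form = "custom"`.
#'
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(form = c("double_well", "harmonic", "custom"),
                           dimension = 1L, params = list(),
                           kT = 1, friction = 1, dt = 1e-3,
                           potential = NULL, gradient = NULL) {
  form <- match.arg(form)
  if (!dimension %in% c(1L, 2L)) stop("'dimension' must be 1 or 2")
  if (kT <= 0 || friction <= 0 || dt <= 0) {
    stop("'kT', 'friction' and 'dt' must all be positive")
  }
  if (form == "harmonic") {
    k <- params$k %||% 1
    x0 <- params$x0 %||% rep(0, dimension)
    potential <- function(x) 0.5 * k * sum((x - x0)^2)
    gradient <- function(x) k * (x - x0)
  } else if (form == "double_well") {
    a <- params$a %||% 1
    k <- params$k %||% 1
    potential <- function(x) {
      v <- a * (x[1]^2 - 1)^2
      if (length(x) > 1L) v <- v + 0.5 * k * sum(x[-1]^2)
      v
    }
    gradient <- function(x) {
      g <- x
      g[1] <- 4 * a * x[1] * (x[1]^2 - 1)
      if (length(x) > 1L) g[-1] <- k * x[-1]
      g
    }
  } else if (is.null(potential) || is.null(gradient)) {
    stop("form = 'custom' requires 'potential' and 'gradient' functions")
  }
  x_test <- rep(0.5, dimension)
  if (!is.finite(potential(x_test)) || any(!is.finite(gradient(x_test)))) {
    stop("potential/gradient must evaluate finite on the domain")
  }
  structure(list(form = form, dimension = as.integer(dimension),
                 params = params, kT = kT, friction = friction, dt = dt,
                 potential = potential, gradient = gradient),
            class = "potential_spec")
}

#' Overdamped Langevin (Brownian) dynamics
#'
#' Euler--Maruyama integration of
#' dx = -grad V(x) / gamma dt + sqrt(2 kT dt / gamma) xi,
#' the standard continuous stand-in for a molecular-dynamics trajectory
#' when testing Markov-model estimators: its invariant density is the
#' Boltzmann distribution exp(-V/kT) (up to O(dt) discretization bias).
#'
#' @param spec A [potential_spec()].
#' @param n_steps Number of frames to produce (>= 1), including the
#'   start.
#' @param x0 Starting position (default: first well at -1 for the
#'   double well, 0 otherwise).
#' @param seed Integer seed; trajectories are reproducible.
#' @param dt_out Frame spacing recorded on the returned trajectory, in
#'   ns (metadata only; the integrator uses `spec$dt` reduced units).
#'
#' @return A [feature_trajectory()] of positions, `n_steps` x
#'   `dimension`.
#' @export
simulate_langevin <- function(spec, n_steps, x0 = NULL, seed = NULL,
                              dt_out = 0.1) {
  stopifnot(inherits(spec, "potential_spec"))
  n_steps <- stopifnot_scalar_count(n_steps, "n_steps")
  d <- spec$dimension
  if (is.null(x0)) {
    x0 <- if (spec$form == "double_well") c(-1, rep(0, d - 1L)) else rep(0, d)
  }
  if (length(x0) != d) stop("'x0' must have length equal to the dimension")
  drift_scale <- spec$dt / spec$friction
  noise_sd <- sqrt(2 * spec$kT * spec$dt / spec$friction)
  grad <- spec$gradient
  out <- matrix(NA_real_, n_steps, d)
  out[1L, ] <- x0
  with_local_seed(seed, {
    if (n_steps > 1L) {
      xi <- matrix(stats::rnorm((n_steps - 1L) * d, sd = noise_sd),
                   n_steps - 1L, d)
      x <- x0
      for (t in 2:n_steps) {
        x <- x - drift_scale * grad(x) + xi[t - 1L, ]
        if (any(!is.finite(x))) {
          stop(sprintf("Langevin integration diverged at step %d; reduce dt", t))
        }
        out[t, ] <- x
      }
    }
  })
  feature_trajectory(out, dt = dt_out,
                     feature_names = paste0("x", seq_len(d)))
}
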