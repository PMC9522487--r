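#' Integrator configuration
#'
#' Settings for [integrate_model()]. The default is the adaptive
#' Dormand-Prince Runge-Kutta 4(5) pair with absolute and relative
#' tolerances of `1e-9`; a fixed-step classical RK4 is available for
#' order-of-convergence and reproducibility checks. `dt` is both the
#' fixed step and the recording interval, in days.
#'
#' @param method `"rk45"` (adaptive, default) or `"rk4"` (fixed step).
#' @param dt step / recording interval in days (default 0.01).
#' @param t_end horizon in days.
#' @param abs_tol,rel_tol adaptive error tolerances (default `1e-9`).
#' @param renormalize_simplex if `TRUE`, recorded states are clipped to
#'   `[0, 1]` and renormalized to unit sum whenever the accumulated drift
#'   exceeds `1e-12` — the policy for replicator (simplex) models.
#' @return object of class `integrator_config`.
#' @export
integrator_config <- function(method = c("rk45", "rk4"), dt = 0.01,
                              t_end = 100, abs_tol = 1e-9, rel_tol = 1e-9,
                              renormalize_simplex = FALSE) {
  method <- match.arg(method)
  if (dt <= 0 || t_end <= 0 || abs_tol <= 0 || rel_tol <= 0) {
    stop("dt, t_end and tolerances must be positive", call. = FALSE)
  }
  structure(list(method = method, dt = dt, t_end = t_end,
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 renormalize_simplex = isTRUE(renormalize_simplex)),
            class = "integrator_config")
}

#' Integrate a vector field
#'
#' Thin wrapper over [deSolve::ode()]. The field is a plain function
#' `rhs(t, x)` returning the velocity vector; state is recorded every
#' `config$dt` days up to `config$t_end`.
#'
#' @param rhs function of `(t, x)` returning `dx/dt` (numeric vector).
#' @param x0 initial state (named or unnamed numeric vector).
#' @param config an [integrator_config()].
#' @param t0 initial time in days (default 0).
#' @return object of class `trajectory`: a data.frame with a `t` column
#'   followed by one column per state variable.
#' @examples
#' tr <- integrate_model(function(t, x) -x, c(x = 1),
#'                       integrator_config(t_end = 1))
#' tail(tr, 1)  # ~ exp(-1)
#' @export
integrate_model <- function(rhs, x0, config, t0 = 0) {
  stopifnot(inherits(config, "integrator_config"))
  times <- seq(t0, config$t_end, by = config$dt)
  if (times[length(times)] < config$t_end) times <- c(times, config$t_end)
  check <- attr(rhs, "state_check")
  if (!is.null(check)) check(t0, matrix(as.numeric(x0), nrow = 1))
  f <- function(t, y, parms) list(rhs(t, y))
  sol <- if (config$method == "rk4") {
    deSolve::rk4(y = x0, times = times, func = f, parms = NULL)
  } else {
    deSolve::ode(y = x0, times = times, func = f, parms = NULL,
                 method = "ode45", atol = config$abs_tol,
                 rtol = config$rel_tol)
  }
  out <- as.data.frame(unclass(sol))
  names(out)[1] <- "t"
  if (!is.null(check)) {
    check(out[[1]], as.matrix(out[, -1, drop = FALSE]))
  }
  if (config$renormalize_simplex && ncol(out) > 2) {
    states <- as.matrix(out[, -1, drop = FALSE])
    drift <- abs(rowSums(states) - 1) > 1e-12
    if (any(drift)) {
      states[drift, ] <- pmin(pmax(states[drift, , drop = FALSE], 0), 1)
      states[drift, ] <- states[drift, , drop = FALSE] /
        rowSums(states[drift, , drop = FALSE])
      out[, -1] <- states
    }
  }
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Iterate a discrete map
#'
#' Applies `step_fn` repeatedly, recording one state per day starting from
#' `x0` at `t0`. Zero steps returns the initial state alone.
#'
#' @param step_fn function of the current state returning the next state.
#' @param x0 initial state.
#' @param n_steps number of applications (non-negative integer).
#' @param t0 initial time in days (default 0).
#' @return a `trajectory` data.frame as in [integrate_model()].
#' @examples
#' p <- stage_scenario("early")
#' iterate_map(function(s) leslie_map_step(p, s), c(i = 50, l = 1), 5)
#' @export
iterate_map <- function(step_fn, x0, n_steps, t0 = 0) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0) {
    stop("`n_steps` must be a non-negative integer", call. = FALSE)
  }
  states <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(x0))
  states[1, ] <- x0
  s <- x0
  if (n_steps > 0) {
    for (j in seq_len(n_steps)) {
      s <- step_fn(s)
      states[j + 1, ] <- s
    }
  }
  nm <- names(x0)
  if (is.null(nm)) nm <- paste0("x", seq_along(x0))
  out <- data.frame(t = t0 + 0:n_steps)
  out[nm] <- as.data.frame(states)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Basin-of-attraction sampling
#'
#' Integrates the field from every point of a regular grid and labels each
#' initial condition by the attractor its endpoint lies within
#' `capture_radius` of, or `"none"` when no attractor captures it.
#'
#' @param rhs vector field `function(t, x)`.
#' @param lower,upper numeric vectors delimiting the sampling box (length
#'   1 for scalar flows, 2 for planar ones).
#' @param resolution number of grid points per axis.
#' @param attractors named list (or named vector, for scalar flows) of
#'   attractor locations; names become the labels.
#' @param config an [integrator_config()]; its `t_end` is the settling
#'   horizon (default 500 days).
#' @param capture_radius capture distance (default `1e-2`).
#' @return list with `grid` (data.frame of initial conditions and their
#'   `label`) and `fractions` (named vector of basin area fractions,
#'   including `"none"`).
#' @examples
#' bs <- basin_sample(hawkdove_field(1, 1), 0, 1, 21,
#'                    attractors = list(leu_only = 0, cleu_only = 1),
#'                    config = integrator_config(dt = 0.5, t_end = 200))
#' bs$fractions
#' @export
basin_sample <- function(rhs, lower, upper, resolution, attractors,
                         config = integrator_config(dt = 1, t_end = 500),
                         capture_radius = 1e-2) {
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  }
  att <- lapply(attractors, as.numeric)
  if (is.null(names(att)) || any(names(att) == "")) {
    names(att) <- paste0("A", seq_along(att))
  }
  axes <- mapply(function(lo, hi) seq(lo, hi, length.out = resolution),
                 lower, upper, SIMPLIFY = FALSE)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- paste0("x", seq_along(axes))
  # only the endpoint matters: record at t_end alone
  end_cfg <- config
  end_cfg$dt <- config$t_end
  labels <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    x0 <- as.numeric(grid[r, ])
    final <- tryCatch({
      tr <- integrate_model(rhs, x0, end_cfg)
      as.numeric(tr[nrow(tr), -1])
    }, error = function(e) rep(NA_real_, length(x0)))
    lab <- "none"
    if (all(is.finite(final))) {
      d <- vapply(att, function(a) sqrt(sum((final - a)^2)), 0)
      if (min(d) <= capture_radius) lab <- names(att)[which.min(d)]
    }
    labels[r] <- lab
  }
  grid$label <- labels
  counts <- table(factor(labels, levels = c(names(att), "none")))
  fractions <- setNames(as.vector(counts) / nrow(grid), names(counts))
  list(grid = grid, fractions = fractions)
}

# ---- model vector-field factories -------------------------------------

#' Vector-field factories for the packaged models
#'
#' Convenience constructors returning `function(t, x)` closures suitable
#' for [integrate_model()], [basin_sample()] and [phase_field()]. The
#' Hawk-Dove and coalition fields clip floating-point excursions a hair
#' outside their invariant domains back onto them before evaluating, so
#' adaptive steppers can graze the boundary without tripping the strict
#' domain checks.
#'
#' @param a,b Hawk-Dove payoff constants.
#' @param A payoff matrix for the n-strategy replicator.
#' @param params a [leslie_params()] object.
#' @param p a [coalition_payoffs()] object.
#' @return a function `(t, x) -> dx/dt`.
#' @name model_fields
NULL

#' @rdname model_fields
#' @export
hawkdove_field <- function(a, b) {
  force(a); force(b)
  function(t, x) hawkdove_rhs(a, b, min(max(x[[1]], 0), 1))
}

#' @rdname model_fields
#' @export
replicator_field <- function(A) {
  force(A)
  function(t, x) {
    x <- pmin(pmax(x, 0), 1)
    replicator_rhs(A, x / sum(x))
  }
}

#' @rdname model_fields
#' @export
leslie_field <- function(params) {
  force(params)
  # Adaptive steppers probe trial states far outside the physical domain
  # before rejecting a step, so the field must be total: densities are
  # clipped to >= 0 and the Gower ratio is floored at i = 1e-9, which
  # makes dl/dt enormously negative near the singular axis and forces the
  # error controller to shrink the step. Recorded states are still
  # checked against the true singularity by integrate_model().
  f <- function(t, x) {
    i <- max(x[[1]], 0); l <- max(x[[2]], 0)
    c(di = (params$r1 - params$c1 * l - params$b * i) * i,
      dl = (params$r2 - params$c2 * l / max(i, 1e-9)) * l)
  }
  attr(f, "state_check") <- function(times, states) {
    bad <- states[, 1] <= 1e-12 & states[, 2] > 1e-12
    if (any(bad)) {
      stop(sprintf(
        "Gower term diverges: predator present with vanishing prey at t = %g",
        times[which(bad)[1]]), call. = FALSE)
    }
  }
  f
}

#' @rdname model_fields
#' @export
coalition_field <- function(p) {
  force(p)
  function(t, x) coalition_rhs(p, pmin(pmax(x, 0), 1))
}
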