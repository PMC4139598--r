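#' Integrate the deterministic lineage model
#'
#' Solves the n-compartment feedback ODE system on a user-supplied time
#' grid with an adaptive Runge-Kutta method (Dormand-Prince 4(5) via
#' \pkg{deSolve}). The continuous model preserves non-negativity; tiny
#' negative solver overshoots are clamped to zero in the reported values
#' only, never mid-integration.
#'
#' @param params a [lineage_params()] object; must pass
#'   [validate_parameters()].
#' @param c0 initial state: [cell_state()] or non-negative numeric vector
#'   of length n.
#' @param times strictly increasing output time grid; `times[1]` is the
#'   initial time.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method a \pkg{deSolve} method name (default `"ode45"`).
#' @return An object of class `"lineage_trajectory"`: list with `times`,
#'   `values` (length(times) x n matrix), and `meta` (parameters, method,
#'   tolerances).
#' @examples
#' par2 <- lineage_params(a = 0.7, p = 0.6, mu = c(0, 2.77), k1 = 1.28e-9)
#' tr <- integrate_ode(par2, c0 = c(1e8, 1e8), times = seq(0, 100, 0.5))
#' tail(tr$values, 1)  # near the positive steady state
#' @export
integrate_ode <- function(params, c0, times, rtol = 1e-8, atol = 1e-10,
                          method = "ode45") {
  assert_valid(params)
  y0 <- as_state_vector(c0, params$n)
  check_time_grid(times)
  rhs <- function(t, y, parms)
    list(drop(drift_matrix(params, matrix(y, nrow = 1L))))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop(sprintf("ODE solver failed; last good time %g", sol[nrow(sol), 1]))
  vals <- unname(sol[, -1, drop = FALSE])
  new_trajectory(times, pmax(vals, 0),
                 meta = list(params = params, method = method,
                             rtol = rtol, atol = atol, kind = "ode",
                             min_raw = min(vals)))
}

#' Integrate the lineage model with explicit cytokine dynamics
#'
#' Replaces the quasi-steady-state self-renewal signal by the full cytokine
#' equation `ds/dt = mu_s (1 - s - k1 s c_n)`: the signal `s` relaxes
#' towards `1/(1 + k1 c_n)` at rate `mu_s (1 + k1 c_n)`. The proliferation
#' channel (`k2`) remains algebraic. As `mu_s` grows the solution converges
#' to the quasi-steady-state model solved by [integrate_ode()].
#'
#' @inheritParams integrate_ode
#' @param mu_s cytokine relaxation rate (1/time, > 0).
#' @param s0 initial signal in `[0, 1]`.
#' @return A list with `trajectory` (a `"lineage_trajectory"` for the cell
#'   densities) and `signal` (numeric vector of s along `times`, clamped to
#'   `[0, 1]` in output).
#' @export
integrate_with_cytokine <- function(params, mu_s, c0, s0, times,
                                    rtol = 1e-8, atol = 1e-10,
                                    method = "ode45") {
  assert_valid(params)
  stopifnot(mu_s > 0, s0 >= 0, s0 <= 1)
  y0 <- c(as_state_vector(c0, params$n), s0)
  check_time_grid(times)
  n <- params$n
  rhs <- function(t, y, parms) {
    cvec <- y[seq_len(n)]
    s <- y[n + 1L]
    cn <- cvec[n]
    s2 <- 1 / (1 + params$k2 * cn)
    a <- params$a; p <- params$p; mu <- params$mu
    idx <- seq_len(n - 1L)
    self <- (2 * a * s - 1) * p * s2 * cvec[idx]
    influx <- 2 * (1 - a * s) * p * s2 * cvec[idx]
    dc <- numeric(n)
    dc[idx] <- self
    dc[2:n] <- dc[2:n] + influx
    dc <- dc - mu * cvec
    ds <- mu_s * (1 - s - params$k1 * s * cn)
    list(c(dc, ds))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop(sprintf("ODE solver failed; last good time %g", sol[nrow(sol), 1]))
  vals <- unname(sol[, 2:(n + 1L), drop = FALSE])
  sig <- pmin(pmax(unname(sol[, n + 2L]), 0), 1)
  list(trajectory = new_trajectory(times, pmax(vals, 0),
                                   meta = list(params = params, mu_s = mu_s,
                                               method = method, rtol = rtol,
                                               atol = atol,
                                               kind = "ode+cytokine")),
       signal = sig)
}

#' Relax the deterministic model to its steady state
#'
#' Integrates forward in growing spans until the relative drift norm
#' `max|dc/dt| < tol * max|c|` or the time budget `t_max` is exhausted.
#'
#' @inheritParams integrate_ode
#' @param tol relative drift-norm convergence criterion.
#' @param t_max maximum total integration time.
#' @param span0 initial span length; spans double up to `t_max`.
#' @return List with `state` (numeric vector), `converged` (logical),
#'   and `t_elapsed` (total time integrated; 0 if `c0` already qualifies).
#'   A state that has decayed below `1e-10` of the initial scale counts as
#'   converged to extinction (the relative drift criterion cannot fire on
#'   a state decaying geometrically to zero).
#' @export
relax_to_steady_state <- function(params, c0, tol = 1e-8, t_max = 1e4,
                                  span0 = 10, rtol = 1e-10, atol = 1e-12) {
  assert_valid(params)
  y <- as_state_vector(c0, params$n)
  if (any(y <= 0)) stop("c0 must be strictly positive componentwise")
  scale0 <- max(y)
  drift_ok <- function(v) {
    d <- drop(drift_matrix(params, matrix(v, nrow = 1L)))
    max(abs(d)) < tol * max(abs(v))
  }
  t_done <- 0
  if (drift_ok(y))
    return(list(state = y, converged = TRUE, t_elapsed = 0))
  span <- span0
  while (t_done < t_max) {
    span <- min(span, t_max - t_done)
    tr <- integrate_ode(params, y, times = c(0, span),
                        rtol = rtol, atol = atol)
    y <- tr$values[2L, ]
    t_done <- t_done + span
    if (max(y) < 1e-10 * scale0)
      return(list(state = y, converged = TRUE, t_elapsed = t_done))
    if (all(y > 0) && drift_ok(y))
      return(list(state = y, converged = TRUE, t_elapsed = t_done))
    span <- span * 2
  }
  list(state = y, converged = FALSE, t_elapsed = t_done)
}

# --- shared trajectory plumbing ------------------------------------------

check_time_grid <- function(times) {
  if (length(times) < 2L || anyNA(times) || any(diff(times) <= 0))
    stop("times must be a strictly increasing grid of length >= 2")
  invisible(times)
}

new_trajectory <- function(times, values, meta = list(), class = character(0)) {
  structure(list(times = as.numeric(times), values = values, meta = meta),
            class = c(class, "lineage_trajectory"))
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  cat(sprintf("<lineage_trajectory> %d times in [%g, %g], %d compartments (%s)\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              ncol(x$values), x$meta$kind %||% "unknown"))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  if (!is.null(x$clamp_count))
    cat(sprintf("  clamped points: %d (%.4g%%)\n", x$clamp_count,
                100 * x$clamp_fraction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
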