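#' Cytokine feedback signal
#'
#' Quasi-steady-state feedback signal `s = 1 / (1 + k * c_n)`: the cytokine
#' concentration equilibrates fast relative to the cell populations, so the
#' signal depends algebraically on the mature-cell density. The signal lies
#' in `(0, 1]`, equals 1 when no mature cells are present, and is strictly
#' decreasing in `c_n` whenever `k > 0`.
#'
#' @param k feedback constant (1/cell-density), `k >= 0`.
#' @param c_n mature-cell density (non-negative; vectorised).
#' @return The signal value(s) in `(0, 1]`.
#' @examples
#' feedback_signal(1.28e-9, 0)        # 1: unsuppressed
#' feedback_signal(1.28e-9, 3.125e8)  # 1/1.4
#' @export
feedback_signal <- function(k, c_n) {
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be a scalar >= 0")
  if (anyNA(c_n) || any(c_n < 0)) stop("c_n must be non-negative")
  1 / (1 + k * c_n)
}

# Vectorised drift of the lineage model over a matrix of states
# (rows = independent states/paths, cols = compartments). No sign checks:
# adaptive ODE solvers may probe slightly negative states.
# k1/k2 can be overridden (the stochastic model forces k2 = 0).
drift_matrix <- function(params, X, k1 = params$k1, k2 = params$k2) {
  n <- params$n
  if (ncol(X) != n) stop("state dimension mismatch")
  cn <- X[, n]
  s1 <- 1 / (1 + k1 * cn)   # self-renewal feedback channel
  s2 <- 1 / (1 + k2 * cn)   # proliferation feedback channel
  a <- params$a; p <- params$p; mu <- params$mu
  D <- matrix(0, nrow(X), n)
  # net self-renewal term for proliferating stages i = 1..n-1
  idx <- seq_len(n - 1L)
  self <- (2 * outer(s1, a) - 1) * outer(s2, p) * X[, idx, drop = FALSE]
  # differentiation influx into stages i = 2..n from stage i-1
  influx <- 2 * (1 - outer(s1, a)) * outer(s2, p) * X[, idx, drop = FALSE]
  D[, idx] <- self
  D[, 2:n] <- D[, 2:n, drop = FALSE] + influx
  D - X * rep(mu, each = nrow(X))
}

#' Deterministic drift of the lineage model
#'
#' Right-hand side of the deterministic n-compartment model: stage 1
#' follows `(2 a_1 s_{k1} - 1) p_1 s_{k2} c_1 - mu_1 c_1`, intermediate
#' stages add the differentiation influx
#' `2 (1 - a_{i-1} s_{k1}) p_{i-1} s_{k2} c_{i-1}`, and the mature stage
#' only receives influx and dies at rate `mu_n`. Both feedback channels
#' (`k1` on self-renewal, `k2` on proliferation) are evaluated at the
#' current mature-cell density.
#'
#' @param params a [lineage_params()] object.
#' @param state a [cell_state()] or non-negative numeric vector of length n.
#' @return Numeric vector of length n: time derivative of each compartment
#'   (cells/time).
#' @seealso [stochastic_drift()], [diffusion_coefficients()]
#' @export
deterministic_drift <- function(params, state) {
  v <- as_state_vector(state, params$n)
  drop(drift_matrix(params, matrix(v, nrow = 1L)))
}

#' Drift of the stochastic lineage model
#'
#' The stochastic model carries a single feedback constant acting on
#' self-renewal only; its drift is the deterministic drift with the
#' proliferation channel switched off (`k2 = 0`, `s_{k2} == 1`), `k1`
#' playing the role of the model's `k`. For n = 2 this reduces exactly to
#' the two-compartment system `d xi_1 = (2a/(1 + k xi_2) - 1) p xi_1 dt`,
#' `d xi_2 = (2 (1 - a/(1 + k xi_2)) p xi_1 - mu xi_2) dt`.
#'
#' @inheritParams deterministic_drift
#' @return Numeric vector of length n (cells/time).
#' @export
stochastic_drift <- function(params, state) {
  v <- as_state_vector(state, params$n)
  drop(drift_matrix(params, matrix(v, nrow = 1L), k2 = 0))
}

#' Multiplicative diffusion coefficients
#'
#' Diffusion term of the stochastic model: component i equals
#' `alpha_i * c_i`, i.e. linear (multiplicative) noise that vanishes at
#' extinction.
#'
#' @param noise a [noise_params()] object.
#' @param state a [cell_state()] or numeric vector matching `noise` in
#'   length.
#' @return Numeric vector of per-compartment diffusion coefficients.
#' @export
diffusion_coefficients <- function(noise, state) {
  stopifnot(inherits(noise, "noise_params"))
  v <- if (inherits(state, "cell_state")) state$c else as.numeric(state)
  if (length(v) != length(noise$alpha))
    stop("state and alpha dimensions disagree")
  noise$alpha * v
}

#' Positive steady-state existence conditions
#'
#' Evaluates the two inequality families that guarantee a unique positive
#' steady state: (i) `mu_1 < (2 a_1 - 1) p_1` — the stem-cell pool can
#' replenish itself; (ii) for every intermediate stage i = 2..n-1,
#' `0 < 2 a_1 p_1 (mu_i + p_i) - 2 a_i p_i (mu_1 + p_1)` — no downstream
#' stage can sustain itself at the feedback level that sustains the stem
#' cells. When all immature death rates vanish, these reduce to
#' `a_1 > 1/2` and `a_1 > a_i` for i = 2..n-1.
#'
#' @param params a [lineage_params()] object (validated internally).
#' @return An object of class `"existence_report"`: list with `condition1`
#'   (logical), `condition2` (logical vector for stages 2..n-1; empty when
#'   n = 2) and `overall` (all conditions hold).
#' @export
check_existence_conditions <- function(params) {
  assert_valid(params)
  a <- params$a; p <- params$p; mu <- params$mu; n <- params$n
  condition1 <- mu[1] < (2 * a[1] - 1) * p[1]
  if (n > 2L) {
    i <- 2:(n - 1L)
    condition2 <- 0 < 2 * a[1] * p[1] * (mu[i] + p[i]) -
      2 * a[i] * p[i] * (mu[1] + p[1])
  } else {
    condition2 <- logical(0)
  }
  structure(list(condition1 = condition1, condition2 = condition2,
                 overall = condition1 && all(condition2)),
            class = "existence_report")
}

#' @export
print.existence_report <- function(x, ...) {
  cat(sprintf("Positive steady state exists: %s\n",
              if (x$overall) "YES" else "NO"))
  cat(sprintf("  stem-cell self-maintenance (mu_1 < (2a_1-1)p_1): %s\n",
              x$condition1))
  if (length(x$condition2))
    cat("  intermediate-stage conditions:",
        paste(x$condition2, collapse = " "), "\n")
  invisible(x)
}

#' Closed-form positive steady state of the two-compartment model
#'
#' For the two-compartment model (undifferentiated cells feeding mature
#' cells, no stem-cell death) the positive steady state is available in
#' closed form: the mature density pins the feedback at `s = 1/(2a)`, so
#' `xi_2* = (2a - 1)/k`, and the influx balance gives
#' `xi_1* = mu * xi_2* / p`.
#'
#' @param a maximal self-renewal fraction, must exceed 1/2.
#' @param p proliferation rate (> 0).
#' @param mu mature-cell death rate (> 0).
#' @param k feedback constant (> 0).
#' @return Named numeric vector `c(xi1, xi2)`.
#' @examples
#' positive_steady_state_2d(a = 0.7, p = 0.6, mu = 2.77, k = 1.28e-9)
#' @export
positive_steady_state_2d <- function(a, p, mu, k) {
  stopifnot(p > 0, mu > 0, k > 0)
  if (a <= 0.5)
    stop("no positive steady state: a <= 1/2 (stem cells cannot self-maintain)")
  xi2 <- (2 * a - 1) / k
  c(xi1 = mu * xi2 / p, xi2 = xi2)
}

#' Positive steady state of the n-compartment model
#'
#' Solves the deterministic model for its unique positive steady state by a
#' cascade: (i) the stage-1 balance `(2 a_1 s_{k1}(c_n) - 1) p_1 s_{k2}(c_n)
#' = mu_1` is a monotone scalar equation in the mature density and is
#' solved by bracketed root-finding; (ii) with the feedback signals fixed
#' at that root, each intermediate compartment is a fixed multiple of its
#' predecessor; (iii) the mature-cell balance then fixes the absolute scale
#' `c_1*`. Requires the existence conditions
#' ([check_existence_conditions()]) to hold.
#'
#' @param params a [lineage_params()] object with `k1 > 0`.
#' @param tol relative tolerance of the scalar root-find (default 1e-12).
#' @return Numeric vector of length n, strictly positive, at which the
#'   deterministic drift vanishes (to solver tolerance).
#' @export
positive_steady_state_n <- function(params, tol = 1e-12) {
  assert_valid(params)
  ex <- check_existence_conditions(params)
  if (!ex$overall)
    stop("existence conditions fail: no positive steady state")
  if (params$k1 <= 0)
    stop("k1 must be > 0 for a finite steady state")
  a <- params$a; p <- params$p; mu <- params$mu
  n <- params$n; k1 <- params$k1; k2 <- params$k2
  # stage-1 stationarity as a function of the mature density
  g <- function(x)
    (2 * a[1] / (1 + k1 * x) - 1) * p[1] / (1 + k2 * x) - mu[1]
  upper <- 10 * (2 * max(a) - 1) / k1
  if (g(0) <= 0 || g(upper) >= 0)
    stop("no bracketing root for the mature-cell density")
  cn <- stats::uniroot(g, c(0, upper), tol = tol * upper)$root
  s1 <- 1 / (1 + k1 * cn)
  s2 <- 1 / (1 + k2 * cn)
  # each stage is a fixed multiple of its predecessor at this feedback level
  ratio <- numeric(n)  # ratio[i] = c_i / c_{i-1}, i = 2..n
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      denom <- mu[i] - (2 * a[i] * s1 - 1) * p[i] * s2
      if (denom <= 0)
        stop(sprintf("cascade denominator <= 0 at stage %d (existence conditions violated numerically)", i))
      ratio[i] <- 2 * (1 - a[i - 1L] * s1) * p[i - 1L] * s2 / denom
    }
  }
  ratio[n] <- 2 * (1 - a[n - 1L] * s1) * p[n - 1L] * s2 / mu[n]
  coef <- prod(ratio[2:n])  # c_n = coef * c_1
  c1 <- cn / coef
  c_star <- numeric(n)
  c_star[1] <- c1
  for (i in 2:n) c_star[i] <- ratio[i] * c_star[i - 1L]
  c_star
}

#' Stability exponent of the stochastic stem-cell compartment
#'
#' Long-run growth exponent of the upper comparison process of the
#' two-compartment stochastic model: `lambda = (2a - 1) p - alpha1^2 / 2`.
#' When `lambda > 0` the process admits a unique stationary distribution
#' (the Markov semigroup is asymptotically stable); when `lambda < 0` both
#' populations tend to zero almost surely.
#'
#' @param a maximal self-renewal fraction in `[0, 1]`.
#' @param p proliferation rate (>= 0).
#' @param alpha1 noise intensity on the stem-cell compartment (> 0 in the
#'   stochastic model; 0 is accepted for the deterministic limit).
#' @return An object of class `"stability_report"`: list with `lambda`
#'   (1/time) and `classification` (`"stable"`, `"extinction"` or
#'   `"critical"` within +/- 1e-12 of zero).
#' @examples
#' stability_exponent(0.7, 0.6, 0.1)   # 0.235, stable
#' stability_exponent(0.7, 0.6, 0.9)   # negative, extinction
#' @export
stability_exponent <- function(a, p, alpha1) {
  stopifnot(a >= 0, a <= 1, p >= 0, alpha1 >= 0)
  lambda <- (2 * a - 1) * p - alpha1^2 / 2
  classification <- if (lambda > 1e-12) "stable"
    else if (lambda < -1e-12) "extinction"
    else "critical"
  structure(list(lambda = lambda, classification = classification,
                 a = a, p = p, alpha1 = alpha1),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability exponent lambda = (2a-1)p - alpha1^2/2 = %.6g [1/time]\n",
              x$lambda))
  cat("Classification:", x$classification, "\n")
  if (!is.null(x$mc_lyapunov))
    cat(sprintf("Monte-Carlo Lyapunov estimate: %.6g +/- %.2g (stderr)\n",
                x$mc_lyapunov$estimate, x$mc_lyapunov$stderr))
  invisible(x)
}
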