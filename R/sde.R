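#' Seeded Wiener-process increments
#'
#' Generates independent Gaussian increments for a d-dimensional Wiener
#' process on a (not necessarily uniform) time grid: each step and
#' dimension draws `Normal(0, sqrt(dt))`, columns are mutually
#' independent (the model assumes uncorrelated driving noises).
#' Reproducible: the same seed always yields the same path, and the
#' caller's RNG state is left untouched.
#'
#' @param d number of dimensions (>= 1).
#' @param times strictly increasing time grid.
#' @param seed integer seed.
#' @return An object of class `"wiener_path"`: list with `times`,
#'   `increments` ((length(times)-1) x d matrix) and `seed`.
#' @export
wiener_increments <- function(d, times, seed) {
  stopifnot(d >= 1)
  check_time_grid(times)
  dt <- diff(times)
  inc <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(length(dt) * d), ncol = d) * sqrt(dt)
  })
  structure(list(times = as.numeric(times), increments = inc,
                 seed = as.integer(seed)),
            class = "wiener_path")
}

# Vectorised Euler-Maruyama core over paths.
#
# X0:  n_paths x n matrix of initial states
# dW:  array [steps, n_paths, n] of Wiener increments
# The drift is the stochastic model's (feedback on self-renewal only,
# k2 = 0). Negative proposals are clamped to 0 and counted; with
# multiplicative noise the clamp should fire essentially never at a
# sensible step size.
# record_idx: indices into `times` to keep (must include 1 and the end).
em_core <- function(params, alpha, X0, times, dW, record_idx) {
  n <- params$n
  n_paths <- nrow(X0)
  steps <- length(times) - 1L
  dt <- diff(times)
  alpha_row <- rep(alpha, each = n_paths)
  out <- array(NA_real_, dim = c(length(record_idx), n_paths, n))
  clamp <- integer(n_paths)
  X <- X0
  rec <- 1L
  if (record_idx[1] == 1L) { out[1L, , ] <- X; rec <- 2L }
  for (s in seq_len(steps)) {
    D <- drift_matrix(params, X, k2 = 0)
    X <- X + D * dt[s] + X * alpha_row * dW[s, , , drop = TRUE]
    neg <- X < 0
    if (any(neg)) {
      clamp <- clamp + rowSums(neg)
      X[neg] <- 0
    }
    if (rec <= length(record_idx) && record_idx[rec] == s + 1L) {
      out[rec, , ] <- X
      rec <- rec + 1L
    }
  }
  list(values = out, clamp = clamp)
}

#' Euler-Maruyama integration of the stochastic lineage model
#'
#' Simulates one path of the Ito system with drift [stochastic_drift()]
#' and multiplicative diffusion `alpha_i xi_i dW_i` by the explicit
#' Euler-Maruyama scheme on a uniform grid: strong order 1/2 in the step
#' size. Any negative proposal is clamped to zero (consistent with zero
#' being absorbing for the continuous process) and counted; a clamp
#' fraction above 0.1% flags the step size as too coarse (reported, not an
#' error). With all `alpha_i = 0` the scheme collapses to explicit Euler
#' for the ODE.
#'
#' @param params a [lineage_params()] object (its `k2` is ignored: the
#'   stochastic model regulates self-renewal only).
#' @param noise a [noise_params()] object of length n, or `NULL` for the
#'   zero-noise (explicit Euler) limit.
#' @param c0 initial state (non-negative, length n).
#' @param times uniform, strictly increasing time grid.
#' @param seed integer seed for the Wiener path.
#' @return An `"sde_trajectory"` (subclass of `"lineage_trajectory"`):
#'   `times`, `values`, `seed`, `clamp_count`, `clamp_fraction`,
#'   `clamp_ok` (fraction below the 0.1% gate), `meta`.
#' @export
euler_maruyama <- function(params, noise, c0, times, seed) {
  alpha <- check_sde_inputs(params, noise)
  y0 <- as_state_vector(c0, params$n)
  check_time_grid(times)
  steps <- length(times) - 1L
  path <- wiener_increments(params$n, times, seed)
  dW <- array(0, dim = c(steps, 1L, params$n))
  dW[, 1L, ] <- path$increments
  res <- em_core(params, alpha, matrix(y0, nrow = 1L), times, dW,
                 record_idx = seq_along(times))
  vals <- matrix(res$values[, 1L, ], ncol = params$n)
  cc <- res$clamp[1L]
  frac <- cc / (steps * params$n)
  tr <- new_trajectory(times, vals,
                       meta = list(params = params, noise = noise,
                                   kind = "sde-euler-maruyama",
                                   dt = times[2] - times[1]),
                       class = "sde_trajectory")
  tr$seed <- as.integer(seed)
  tr$clamp_count <- cc
  tr$clamp_fraction <- frac
  tr$clamp_ok <- frac < 1e-3
  tr
}

check_sde_inputs <- function(params, noise) {
  if (is.null(noise)) {
    assert_valid(params)
    return(rep(0, params$n))
  }
  assert_valid(params, noise)
  noise$alpha
}

#' Exact geometric Brownian motion along a Wiener path
#'
#' Evaluates `x(t) = x0 exp((r - alpha^2/2)(t - t0) + alpha W_t)` on the
#' grid of a [wiener_increments()] path, using cumulative increments of
#' the chosen column. With `drift_rate = -p` this is the exact lower
#' comparison process of the stem-cell compartment; with
#' `drift_rate = (2a - 1) p` it is the upper one.
#'
#' @param x0 initial value (>= 0).
#' @param drift_rate linear drift rate r (1/time).
#' @param alpha noise intensity.
#' @param path a `"wiener_path"`.
#' @param column which Wiener dimension drives the process.
#' @return Numeric vector of length `length(path$times)` (starts at `x0`).
#' @export
gbm_exact <- function(x0, drift_rate, alpha, path, column = 1L) {
  stopifnot(inherits(path, "wiener_path"), x0 >= 0)
  W <- c(0, cumsum(path$increments[, column]))
  tt <- path$times - path$times[1]
  x0 * exp((drift_rate - alpha^2 / 2) * tt + alpha * W)
}

#' Simulate the pathwise comparison triple (M, xi, N)
#'
#' Drives three two-dimensional systems with the *same* Wiener path: the
#' lower comparison process M (constant drifts `-p`, `-mu`; simulated
#' exactly as geometric Brownian motions), the model process xi
#' (Euler-Maruyama on the two-compartment feedback SDE), and the upper
#' comparison process N (drift `(2a-1)p` for N1, influx `2 p N1 - mu N2`
#' for N2; Euler-Maruyama, N1 also available exactly via [gbm_exact()]).
#' The continuous-time processes satisfy `M_i <= xi_i <= N_i` almost
#' surely; discretisation is the only source of violations.
#'
#' @param a,p,mu,k two-compartment model constants (`a > 1/2` not required
#'   here; the sandwich holds regardless).
#' @param noise a [noise_params()] object of length 2.
#' @param x0 shared initial state, length 2, non-negative.
#' @param times uniform time grid.
#' @param seed integer seed.
#' @return An object of class `"comparison_triple"`: list with `times` and
#'   `M`, `xi`, `N` (each a length(times) x 2 matrix), plus `seed` and the
#'   constants.
#' @export
simulate_comparison_triple <- function(a, p, mu, k, noise, x0, times, seed) {
  stopifnot(inherits(noise, "noise_params"), length(noise$alpha) == 2L,
            length(x0) == 2L, all(x0 >= 0))
  check_time_grid(times)
  path <- wiener_increments(2L, times, seed)
  al <- noise$alpha
  M <- cbind(gbm_exact(x0[1], -p, al[1], path, 1L),
             gbm_exact(x0[2], -mu, al[2], path, 2L))
  params <- lineage_params(a = a, p = p, mu = c(0, mu), k1 = k, k2 = 0)
  steps <- length(times) - 1L
  dW <- array(0, dim = c(steps, 1L, 2L))
  dW[, 1L, ] <- path$increments
  xi_res <- em_core(params, al, matrix(x0, nrow = 1L), times, dW,
                    record_idx = seq_along(times))
  xi <- matrix(xi_res$values[, 1L, ], ncol = 2L)
  # upper comparison process: Euler-Maruyama on the same increments
  N <- matrix(NA_real_, length(times), 2L)
  N[1L, ] <- x0
  dt <- diff(times)
  N1 <- x0[1]; N2 <- x0[2]
  for (s in seq_len(steps)) {
    dw <- path$increments[s, ]
    N1n <- N1 + (2 * a - 1) * p * N1 * dt[s] + al[1] * N1 * dw[1]
    N2n <- N2 + (2 * p * N1 - mu * N2) * dt[s] + al[2] * N2 * dw[2]
    N1 <- max(N1n, 0); N2 <- max(N2n, 0)
    N[s + 1L, ] <- c(N1, N2)
  }
  structure(list(times = as.numeric(times), M = M, xi = xi, N = N,
                 seed = as.integer(seed), a = a, p = p, mu = mu, k = k,
                 alpha = al, clamp_count = xi_res$clamp[1L]),
            class = "comparison_triple")
}

#' Pathwise ordering violations of a comparison triple
#'
#' Fraction of grid points, per component, at which the sandwich
#' `M <= xi <= N` fails beyond an absolute tolerance. For the continuous
#' process the ordering holds almost surely; on Euler-Maruyama output the
#' violation fraction shrinks under step-size refinement.
#'
#' @param triple a [simulate_comparison_triple()] result.
#' @param tol absolute slack added to each comparison (default 0); pass
#'   e.g. `1e-9 * scale` to ignore round-off-level crossings.
#' @return Named numeric vector of length 2: violation fraction per
#'   component.
#' @export
check_pathwise_order <- function(triple, tol = 0) {
  stopifnot(inherits(triple, "comparison_triple"))
  viol <- function(i)
    mean(triple$M[, i] > triple$xi[, i] + tol |
         triple$xi[, i] > triple$N[, i] + tol)
  c(component1 = viol(1L), component2 = viol(2L))
}

#' Strong-convergence study of Euler-Maruyama against exact GBM
#'
#' Measures the root-mean-square endpoint error of the Euler-Maruyama
#' scheme on the geometric Brownian motion with drift `(2a - 1) p` and
#' noise `alpha1` (the exactly solvable upper comparison process), using
#' the same Brownian path for every step size (coarse increments are sums
#' of fine ones). The fitted log-log slope is the empirical strong order:
#' about 1/2 for multiplicative noise, about 1 in the zero-noise (ODE)
#' limit.
#'
#' @param a,p model constants entering the drift `(2a - 1) p`.
#' @param alpha1 noise intensity (0 allowed).
#' @param dt_list decreasing vector of step sizes; each must divide
#'   `t_end` and be an integer multiple of the smallest.
#' @param n_paths number of independent Brownian paths.
#' @param seed integer seed.
#' @param t_end time horizon (default 1).
#' @param x0 initial value (default 1).
#' @return An object of class `"strong_error_study"`: list with `table`
#'   (data.frame of `dt`, `rms_error`) and `slope` (log-log regression
#'   slope).
#' @export
strong_error_study <- function(a, p, alpha1, dt_list, n_paths, seed,
                               t_end = 1, x0 = 1) {
  dt_list <- sort(as.numeric(dt_list), decreasing = TRUE)
  stopifnot(length(dt_list) >= 2L, n_paths >= 2L)
  r <- (2 * a - 1) * p
  dt_fine <- min(dt_list)
  steps_fine <- round(t_end / dt_fine)
  if (abs(steps_fine * dt_fine - t_end) > 1e-9 * t_end)
    stop("the finest dt must divide t_end")
  fine <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(steps_fine * n_paths, sd = sqrt(dt_fine)),
           nrow = steps_fine)
  })
  WT <- colSums(fine)
  exact_T <- x0 * exp((r - alpha1^2 / 2) * t_end + alpha1 * WT)
  rms <- vapply(dt_list, function(dt) {
    fac <- round(dt / dt_fine)
    if (abs(fac * dt_fine - dt) > 1e-9 * dt)
      stop("each dt must be an integer multiple of the finest dt")
    steps <- steps_fine %/% fac
    if (steps * fac != steps_fine) stop("each dt must divide t_end")
    # coarsen the fine increments by block sums
    grp <- rep(seq_len(steps), each = fac)
    dW <- rowsum(fine, grp, reorder = TRUE)
    X <- rep(x0, n_paths)
    for (s in seq_len(steps))
      X <- X * (1 + r * dt + alpha1 * dW[s, ])
    sqrt(mean((X - exact_T)^2))
  }, numeric(1))
  fit <- stats::lm(log(rms) ~ log(dt_list))
  structure(list(table = data.frame(dt = dt_list, rms_error = rms),
                 slope = unname(stats::coef(fit)[2L]),
                 n_paths = n_paths, seed = as.integer(seed),
                 alpha1 = alpha1, drift_rate = r),
            class = "strong_error_study")
}

#' @export
print.strong_error_study <- function(x, ...) {
  cat(sprintf("<strong_error_study> drift %.4g, alpha %.4g, %d paths\n",
              x$drift_rate, x$alpha1, x$n_paths))
  print(x$table, row.names = FALSE)
  cat(sprintf("log-log slope (empirical strong order): %.3f\n", x$slope))
  invisible(x)
}
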