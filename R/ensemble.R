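#' Run a seeded Monte-Carlo ensemble of the stochastic model
#'
#' Simulates `n_paths` Euler-Maruyama trajectories sharing parameters,
#' initial state and time grid. Path i uses seed `base_seed + i`, so any
#' single trajectory can be regenerated independently with
#' [euler_maruyama()]. The whole ensemble is a pure function of its inputs
#' and `base_seed`.
#'
#' @inheritParams euler_maruyama
#' @param n_paths number of trajectories (>= 2).
#' @param base_seed integer; path i is driven by `base_seed + i`.
#' @param thin record every `thin`-th grid point (the final time is always
#'   recorded); integration always uses the full grid.
#' @return An object of class `"lineage_ensemble"`: list with `times`
#'   (recorded times), `values` (array recorded-times x n x n_paths),
#'   `seeds`, `base_seed`, `params`, `noise`, `clamp_counts` (per path),
#'   `clamp_fraction` (overall), `n_steps`, `dt`.
#' @examples
#' pre <- load_preset("fig4_2d")
#' ens <- run_ensemble(pre$params, pre$noise, c0 = pre$c0,
#'                     times = seq(0, 5, 0.01), n_paths = 20, base_seed = 1)
#' summary(ens)
#' @export
run_ensemble <- function(params, noise, c0, times, n_paths, base_seed,
                         thin = 1L) {
  alpha <- check_sde_inputs(params, noise)
  y0 <- as_state_vector(c0, params$n)
  check_time_grid(times)
  stopifnot(n_paths >= 2L, thin >= 1L)
  n <- params$n
  steps <- length(times) - 1L
  seeds <- as.integer(base_seed) + seq_len(n_paths)
  dW <- array(NA_real_, dim = c(steps, n_paths, n))
  for (i in seq_len(n_paths))
    dW[, i, ] <- wiener_increments(n, times, seeds[i])$increments
  record_idx <- unique(c(seq(1L, length(times), by = as.integer(thin)),
                         length(times)))
  X0 <- matrix(rep(y0, each = n_paths), nrow = n_paths)
  res <- em_core(params, alpha, X0, times, dW, record_idx)
  structure(list(times = as.numeric(times)[record_idx],
                 values = res$values,
                 seeds = seeds, base_seed = as.integer(base_seed),
                 params = params, noise = noise,
                 clamp_counts = res$clamp,
                 clamp_fraction = sum(res$clamp) / (steps * n * n_paths),
                 n_steps = steps, dt = times[2] - times[1]),
            class = "lineage_ensemble")
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat(sprintf("<lineage_ensemble> %d paths, %d compartments, t in [%g, %g]\n",
              dim(x$values)[2], dim(x$values)[3],
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  base seed %d, dt = %g, clamp fraction %.3g%%\n",
              x$base_seed, x$dt, 100 * x$clamp_fraction))
  invisible(x)
}

#' Extract one trajectory from an ensemble
#'
#' @param ensemble a [run_ensemble()] result.
#' @param i path index.
#' @return An `"sde_trajectory"` restricted to the recorded times.
#' @export
get_trajectory <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "lineage_ensemble"),
            i >= 1L, i <= dim(ensemble$values)[2])
  tr <- new_trajectory(ensemble$times,
                       matrix(ensemble$values[, i, ],
                              ncol = dim(ensemble$values)[3]),
                       meta = list(params = ensemble$params,
                                   noise = ensemble$noise,
                                   kind = "sde-euler-maruyama"),
                       class = "sde_trajectory")
  tr$seed <- ensemble$seeds[i]
  tr$clamp_count <- ensemble$clamp_counts[i]
  tr
}

#' Ensemble summary: mean, quartiles and final-time histograms
#'
#' Pointwise cross-path mean and empirical 25th/75th percentiles per
#' compartment per recorded time (quartiles by linear interpolation
#' between order statistics, `stats::quantile()` type 7), plus
#' fixed-width histograms of each compartment at the final time.
#'
#' @param object a `"lineage_ensemble"`.
#' @param bins number of equal-width histogram bins at the final time.
#' @param ... unused.
#' @return An object of class `"ensemble_summary"`: `times`, matrices
#'   `mean`, `q1`, `q3` (times x compartments), `histograms` (per
#'   compartment: `breaks`, `counts` summing to the ensemble size),
#'   `n_paths`.
#' @export
summary.lineage_ensemble <- function(object, bins = 20L, ...) {
  vals <- object$values  # [time, path, compartment]
  nt <- dim(vals)[1]; n_paths <- dim(vals)[2]; n <- dim(vals)[3]
  mean_m <- q1_m <- q3_m <- matrix(NA_real_, nt, n)
  for (j in seq_len(n)) {
    m <- vals[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = nt)
    mean_m[, j] <- rowMeans(m)
    qq <- apply(m, 1L, stats::quantile, probs = c(0.25, 0.75),
                names = FALSE, type = 7)
    q1_m[, j] <- qq[1L, ]
    q3_m[, j] <- qq[2L, ]
  }
  hists <- lapply(seq_len(n), function(j) {
    x <- vals[nt, , j]
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # degenerate spread
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
    list(breaks = breaks, counts = counts)
  })
  structure(list(times = object$times, mean = mean_m, q1 = q1_m, q3 = q3_m,
                 histograms = hists, n_paths = n_paths),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d paths, %d compartments, %d times\n",
              x$n_paths, ncol(x$mean), length(x$times)))
  cat("final-time means:", paste(signif(x$mean[nrow(x$mean), ], 4),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Exact terminal draws of a geometric Brownian motion
#'
#' Samples `x(T) = x0 exp((r - alpha^2/2) T + alpha W_T)` with
#' `W_T ~ Normal(0, sqrt(T))`, the exact distribution of the comparison
#' GBMs at a horizon; no time discretisation is involved.
#'
#' @param x0 initial value (> 0).
#' @param drift_rate linear drift r.
#' @param alpha noise intensity.
#' @param t_end horizon T (> 0).
#' @param n_paths number of draws.
#' @param seed integer seed.
#' @return Numeric vector of `n_paths` terminal values.
#' @export
gbm_sample_terminal <- function(x0, drift_rate, alpha, t_end, n_paths, seed) {
  stopifnot(x0 > 0, t_end > 0, n_paths >= 1L)
  withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(n_paths)
    x0 * exp((drift_rate - alpha^2 / 2) * t_end + alpha * sqrt(t_end) * z)
  })
}

#' Monte-Carlo Lyapunov (growth) exponent estimate
#'
#' Estimates the long-run growth exponent `lim t^-1 log x(t)` as the
#' cross-path mean of `t_end^-1 log(x(T)/x(0))` with its standard error.
#' Paths at zero (absorbed) are excluded and counted. Applied to terminal
#' values of the upper comparison GBM this estimates
#' `(2a - 1) p - alpha1^2 / 2`, the stability exponent.
#'
#' @param x_end numeric vector of terminal values across paths.
#' @param x0 initial value(s) (scalar or per path), strictly positive.
#' @param t_end horizon (> 0).
#' @return List with `estimate`, `stderr`, `n_used`, `n_excluded`.
#' @export
lyapunov_estimate <- function(x_end, x0, t_end) {
  stopifnot(t_end > 0, all(x0 > 0))
  ok <- x_end > 0
  g <- log(x_end[ok] / (if (length(x0) > 1L) x0[ok] else x0)) / t_end
  list(estimate = mean(g),
       stderr = stats::sd(g) / sqrt(length(g)),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Stability report with Monte-Carlo cross-check
#'
#' Combines the closed-form stability exponent
#' `lambda = (2a - 1) p - alpha1^2 / 2` with a Monte-Carlo estimate from
#' exact terminal draws of the upper comparison GBM, and (optionally) the
#' absorbed-path fraction at the horizon.
#'
#' @inheritParams stability_exponent
#' @param n_paths Monte-Carlo sample size.
#' @param t_end Monte-Carlo horizon.
#' @param seed integer seed.
#' @return A `"stability_report"` as from [stability_exponent()], with an
#'   extra `mc_lyapunov` element (`estimate`, `stderr`, ...).
#' @export
stability_report <- function(a, p, alpha1, n_paths = 10000L, t_end = 100,
                             seed = 1L) {
  rep <- stability_exponent(a, p, alpha1)
  x_end <- gbm_sample_terminal(1, (2 * a - 1) * p, alpha1, t_end,
                               n_paths, seed)
  rep$mc_lyapunov <- lyapunov_estimate(x_end, 1, t_end)
  rep
}

#' Extinction fraction of an ensemble at a horizon
#'
#' Fraction of paths whose chosen compartment lies below a threshold at a
#' given time (nearest recorded time is used, with a message, if the
#' requested one is off-grid). This operationalises almost-sure extinction
#' as threshold-crossing at a finite horizon; threshold and horizon are
#' explicit, not defaults.
#'
#' @param ensemble a `"lineage_ensemble"`.
#' @param threshold positive density threshold.
#' @param time horizon at which to evaluate.
#' @param component compartment index (default 1, the stem cells).
#' @return Fraction in `[0, 1]`.
#' @export
extinction_probability <- function(ensemble, threshold, time, component = 1L) {
  stopifnot(inherits(ensemble, "lineage_ensemble"), threshold > 0)
  idx <- which.min(abs(ensemble$times - time))
  if (abs(ensemble$times[idx] - time) > 1e-9 * max(1, abs(time)))
    message(sprintf("time %g not on the recorded grid; using nearest %g",
                    time, ensemble$times[idx]))
  mean(ensemble$values[idx, , component] < threshold)
}

#' Two-time stationarity diagnostic
#'
#' Compares the cross-path marginal distribution of each compartment at
#' two (late) times with a two-sample Kolmogorov-Smirnov test. When the
#' ensemble has reached its stationary regime the two marginals agree and
#' the test should not reject; `pass` means p-value above the threshold.
#'
#' @param ensemble a `"lineage_ensemble"`.
#' @param t_a,t_b two times on the recorded grid, `t_a < t_b`.
#' @param p_threshold rejection threshold (default 0.01).
#' @return A data.frame with one row per compartment: `compartment`,
#'   `ks_distance`, `p_value`, `pass`; attribute `overall` is the AND of
#'   the per-compartment flags.
#' @export
stationarity_diagnostic <- function(ensemble, t_a, t_b, p_threshold = 0.01) {
  stopifnot(inherits(ensemble, "lineage_ensemble"), t_a < t_b)
  ia <- which.min(abs(ensemble$times - t_a))
  ib <- which.min(abs(ensemble$times - t_b))
  n <- dim(ensemble$values)[3]
  out <- data.frame(compartment = seq_len(n), ks_distance = NA_real_,
                    p_value = NA_real_, pass = NA)
  for (j in seq_len(n)) {
    xa <- ensemble$values[ia, , j]
    xb <- ensemble$values[ib, , j]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0 && all(xa[1] == xb)) {
      out$ks_distance[j] <- 0; out$p_value[j] <- 1
    } else {
      ks <- suppressWarnings(stats::ks.test(xa, xb))
      out$ks_distance[j] <- unname(ks$statistic)
      out$p_value[j] <- ks$p.value
    }
    out$pass[j] <- out$p_value[j] > p_threshold
  }
  attr(out, "overall") <- all(out$pass)
  out
}

#' Noise-damping profile between two ensembles
#'
#' Quantifies, per compartment, how far the summary curves (mean, q1, q3)
#' of a perturbed ensemble deviate from a baseline ensemble: the
#' time-averaged absolute deviation of the three curves, divided by the
#' time-averaged baseline mean of that compartment. Used to show that
#' noise injected into some stages is damped at sufficiently distant
#' stages; conclusions are ordinal (compartment A deviates less than B),
#' not absolute.
#'
#' @param ensemble_perturbed,ensemble_baseline two `"lineage_ensemble"`
#'   objects on the same recorded grid with the same number of
#'   compartments.
#' @return Numeric vector: relative deviation per compartment.
#' @export
damping_profile <- function(ensemble_perturbed, ensemble_baseline) {
  stopifnot(inherits(ensemble_perturbed, "lineage_ensemble"),
            inherits(ensemble_baseline, "lineage_ensemble"))
  if (!isTRUE(all.equal(ensemble_perturbed$times, ensemble_baseline$times)) ||
      dim(ensemble_perturbed$values)[3] != dim(ensemble_baseline$values)[3])
    stop("ensembles must share the recorded time grid and compartment count")
  sp <- summary(ensemble_perturbed)
  sb <- summary(ensemble_baseline)
  n <- ncol(sp$mean)
  vapply(seq_len(n), function(j) {
    scale <- mean(sb$mean[, j])
    if (scale <= 0) return(0)
    dev <- (mean(abs(sp$mean[, j] - sb$mean[, j])) +
            mean(abs(sp$q1[, j] - sb$q1[, j])) +
            mean(abs(sp$q3[, j] - sb$q3[, j]))) / 3
    dev / scale
  }, numeric(1))
}
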