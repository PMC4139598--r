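test_that("ensembles are a pure function of their base seed", {
  par <- fig4_params()
  no <- noise_params(c(0.2, 0.2))
  times <- seq(0, 2, 0.01)
  a <- run_ensemble(par, no, fig4_ss(), times, n_paths = 10, base_seed = 42)
  b <- run_ensemble(par, no, fig4_ss(), times, n_paths = 10, base_seed = 42)
  expect_identical(a$values, b$values)
  expect_identical(summary(a)$mean, summary(b)$mean)
  expect_identical(anyDuplicated(a$seeds), 0L)
})

test_that("ensemble paths are the single-path runs at seeds base + i", {
  par <- fig4_params()
  no <- noise_params(c(0.3, 0.3))
  times <- seq(0, 1, 0.01)
  ens <- run_ensemble(par, no, fig4_ss(), times, n_paths = 3, base_seed = 5)
  one <- euler_maruyama(par, no, fig4_ss(), times, seed = 5 + 2)
  expect_equal(get_trajectory(ens, 2)$values, one$values)
})

test_that("zero noise makes every path the deterministic Euler solution", {
  par <- fig4_params()
  times <- seq(0, 2, 0.01)
  ens <- run_ensemble(par, NULL, fig4_ss(), times, n_paths = 4,
                      base_seed = 1)
  det <- euler_maruyama(par, NULL, fig4_ss(), times, seed = 1)
  for (i in 1:4)
    expect_equal(get_trajectory(ens, i)$values, det$values)
  sm <- summary(ens)
  expect_equal(sm$q1, sm$mean)
  expect_equal(sm$q3, sm$mean)
})

test_that("quartiles follow the linear-interpolation estimator", {
  # 4 constant paths at 1, 2, 3, 4: q1 = 1.75, q3 = 3.25
  vals <- array(rep(1:4, each = 3), dim = c(3, 4, 1))
  sm <- summary(fake_ensemble(vals))
  expect_equal(sm$mean[, 1], rep(2.5, 3))
  expect_equal(sm$q1[, 1], rep(1.75, 3))
  expect_equal(sm$q3[, 1], rep(3.25, 3))
  expect_true(all(sm$q1 <= sm$q3))
})

test_that("histogram counts conserve the ensemble size", {
  par <- fig4_params()
  no <- noise_params(c(0.3, 0.3))
  ens <- run_ensemble(par, no, fig4_ss(), seq(0, 2, 0.01), n_paths = 37,
                      base_seed = 3)
  sm <- summary(ens)
  for (h in sm$histograms) expect_identical(sum(h$counts), 37L)
  # degenerate spread (identical paths) still bins everything
  smd <- summary(fake_ensemble(array(5, dim = c(2, 6, 1))))
  expect_identical(sum(smd$histograms[[1]]$counts), 6L)
})

test_that("summaries are invariant under path reordering", {
  vals <- array(rnorm(5 * 8 * 2, 10), dim = c(5, 8, 2))
  sm1 <- summary(fake_ensemble(vals))
  sm2 <- summary(fake_ensemble(vals[, sample(8), , drop = FALSE]))
  expect_equal(sm1$mean, sm2$mean)
  expect_equal(sm1$q1, sm2$q1)
  expect_equal(sm1$q3, sm2$q3)
})

test_that("the Lyapunov estimator recovers drift - alpha^2/2 on exact GBM", {
  # noiseless: the estimate is the drift rate, exactly
  x <- gbm_sample_terminal(2, 0.3, 0, t_end = 50, n_paths = 10, seed = 1)
  expect_equal(lyapunov_estimate(x, 2, 50)$estimate, 0.3, tolerance = 1e-12)

  withr::with_seed(21, {
    for (rep in seq_len(20)) {
      r <- runif(1, -1, 1)
      al <- runif(1, 0.05, 0.8)
      xT <- gbm_sample_terminal(1, r, al, t_end = 100, n_paths = 2000,
                                seed = sample.int(1e6, 1))
      est <- lyapunov_estimate(xT, 1, 100)
      expect_lt(abs(est$estimate - (r - al^2 / 2)), 3.5 * est$stderr)
    }
  })
})

test_that("at the critical noise level the growth exponent is zero", {
  al_crit <- sqrt(2 * (2 * 0.7 - 1) * 0.6)
  rep <- stability_report(0.7, 0.6, al_crit, n_paths = 5000, t_end = 100,
                          seed = 2)
  expect_identical(rep$classification, "critical")
  expect_lt(abs(rep$mc_lyapunov$estimate), 3 * rep$mc_lyapunov$stderr)
})

test_that("extinction probability is a threshold crossing at a horizon", {
  zero <- fake_ensemble(array(0, dim = c(3, 10, 2)))
  expect_identical(extinction_probability(zero, 1e-3, time = 2), 1)
  expect_message(extinction_probability(zero, 1e-3, time = 1.4), "nearest")
  half <- fake_ensemble(array(rep(c(0, 1), each = 3 * 5), dim = c(3, 10, 1)))
  expect_identical(extinction_probability(half, 0.5, time = 2), 0.5)
})

test_that("late-time marginals pass the stationarity diagnostic, transients fail", {
  par <- fig4_params()
  ss <- fig4_ss()
  ens <- run_ensemble(par, noise_params(c(0.1, 0.1)), 0.01 * c(ss[1], 0),
                      seq(0, 200, 0.02), n_paths = 300, base_seed = 4,
                      thin = 50)
  late <- stationarity_diagnostic(ens, 100, 200)
  expect_true(attr(late, "overall"))
  trans <- stationarity_diagnostic(ens, 1, 200)
  expect_false(attr(trans, "overall"))
  # identical stationary constants: zero KS distance
  const <- fake_ensemble(array(rep(rnorm(10, 50), each = 4),
                               dim = c(4, 10, 1)))
  expect_identical(stationarity_diagnostic(const, 1, 3)$ks_distance, 0)
})

test_that("the KS diagnostic keeps its nominal type-I rate on iid ensembles", {
  fails <- 0L
  for (r in seq_len(100)) {
    xa <- gbm_sample_terminal(1, 0.1, 0.3, 10, 150, seed = 2 * r)
    xb <- gbm_sample_terminal(1, 0.1, 0.3, 10, 150, seed = 2 * r + 1)
    p <- suppressWarnings(stats::ks.test(xa, xb))$p.value
    if (p <= 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 5L)
})

test_that("identical ensembles have a zero damping profile", {
  par <- fig4_params()
  no <- noise_params(c(0.2, 0.2))
  ens <- run_ensemble(par, no, fig4_ss(), seq(0, 1, 0.01), n_paths = 8,
                      base_seed = 6)
  expect_identical(damping_profile(ens, ens), c(0, 0))
  ens2 <- run_ensemble(par, no, fig4_ss(), seq(0, 2, 0.01), n_paths = 8,
                       base_seed = 6)
  expect_error(damping_profile(ens, ens2), "grid")
})

test_that("extinction fraction rises with the stem-cell noise intensity", {
  # scaled-down dichotomy: straddle the critical alpha_1 = sqrt(0.48)
  par <- fig4_params()
  ss <- fig4_ss()
  times <- seq(0, 100, 0.02)
  fr <- sapply(c(0.3, 0.9), function(a1) {
    ens <- run_ensemble(par, noise_params(c(a1, 0.02)), ss, times,
                        n_paths = 100, base_seed = 8, thin = 100)
    extinction_probability(ens, 1e-3 * ss[1], time = 100, component = 1)
  })
  expect_lt(fr[1], 0.1)
  expect_gt(fr[2], fr[1])
})
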