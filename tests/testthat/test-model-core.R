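test_that("parameter constructors enforce structure, not biology", {
  expect_error(lineage_params(a = c(0.7, 0.6), p = 0.6, mu = c(0, 2.77),
                              k1 = 1), "length")
  expect_error(lineage_params(a = 0.7, p = 0.6, mu = 2.77, k1 = 1),
               "at least 2")
  # out-of-range values are constructible so they can be reported on
  bad <- lineage_params(a = 1.2, p = 0.6, mu = c(0, 2.77), k1 = 1e-9)
  expect_s3_class(bad, "lineage_params")
  expect_error(cell_state(c(-1, 2)), "non-negative")
})

test_that("validation reports every violated constraint by name", {
  expect_true(validate_parameters(fig4_params())$ok)
  pre <- load_preset("fig1_small_noise")
  expect_true(validate_parameters(pre$params, pre$noise)$ok)

  bad <- lineage_params(a = 1.2, p = 0.6, mu = c(0, 2.77), k1 = 1e-9)
  rep <- validate_parameters(bad)
  expect_false(rep$ok)
  expect_match(rep$violations, "a_1", all = FALSE)

  dead <- lineage_params(a = 0.7, p = 0.6, mu = c(0, 0), k1 = 1e-9)
  expect_match(validate_parameters(dead)$violations, "mu_2", all = FALSE)

  rep <- validate_parameters(fig4_params(), noise_params(c(0.1, 0)))
  expect_false(rep$ok)
  expect_match(rep$violations, "alpha_2", all = FALSE)
})

test_that("feedback signal matches its closed form and is monotone", {
  expect_identical(feedback_signal(1.28e-9, 0), 1)
  expect_identical(feedback_signal(0, 1e12), 1)
  expect_equal(feedback_signal(1.28e-9, 3.125e8), 1 / 1.4, tolerance = 1e-12)
  expect_error(feedback_signal(-1, 0), ">= 0")
  expect_error(feedback_signal(1, -5), "non-negative")
  # strictly decreasing, range (0, 1]
  cn <- 10^seq(-3, 15, length.out = 200)
  s <- feedback_signal(1.28e-9, cn)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("deterministic drift vanishes at the steady state and at zero", {
  par <- fig4_params()
  ss <- fig4_ss()
  d <- deterministic_drift(par, ss)
  expect_lt(max(abs(d)), 1e-6 * max(ss))
  expect_identical(deterministic_drift(par, c(0, 0)), c(0, 0))
  expect_error(deterministic_drift(par, c(1, 2, 3)), "length")
})

test_that("unsuppressed stem-cell growth rate matches hand evaluation", {
  # no mature cells: both feedback signals are 1
  pre <- load_preset("fig1_small_noise")
  c1 <- 5e4
  d <- deterministic_drift(pre$params, c(c1, rep(0, 7)))
  expect_equal(d[1], (2 * 0.735 - 1) * 0.006 * c1, tolerance = 1e-12)
})

test_that("stochastic drift is the k2 = 0 specialisation", {
  par_fb <- fig4_params(k2 = 1.28e-9)
  state <- c(1e9, 3.125e8)
  expect_equal(stochastic_drift(par_fb, state),
               deterministic_drift(fig4_params(k2 = 0), state))
  # 2a/(1 + k xi2) = 1 at xi2 = (2a-1)/k: stem-cell drift vanishes
  expect_equal(stochastic_drift(par_fb, state)[1], 0, tolerance = 1e-9)
  expect_identical(stochastic_drift(par_fb, c(0, 0)), c(0, 0))
})

test_that("diffusion coefficients are multiplicative in the state", {
  no <- noise_params(c(0.185, 0.02))
  expect_identical(diffusion_coefficients(no, c(0, 0)), c(0, 0))
  expect_identical(diffusion_coefficients(no, c(1, 1)), no$alpha)
  expect_equal(diffusion_coefficients(no, c(2e3, 1))[1], 370)
  expect_error(diffusion_coefficients(no, c(1, 2, 3)), "dimension")
})

test_that("drift coefficient factors respect their analytic bounds", {
  # -1 <= 2a/(1+k xi2) - 1 <= 2a - 1 and 0 <= 2(1 - a/(1+k xi2))p <= 2p
  xi2 <- c(0, 10^seq(-6, 15, length.out = 500))
  for (a in c(0.2, 0.5, 0.7, 1)) {
    for (k in c(1.28e-9, 1)) {
      f1 <- 2 * a / (1 + k * xi2) - 1
      expect_true(all(f1 >= -1 - 1e-15))
      expect_true(all(f1 <= 2 * a - 1 + 1e-15))
      p <- 0.6
      f2 <- 2 * (1 - a / (1 + k * xi2)) * p
      expect_true(all(f2 >= -1e-15))
      expect_true(all(f2 <= 2 * p + 1e-15))
    }
  }
})

test_that("existence conditions match printed cases", {
  pre <- load_preset("fig1_small_noise")
  ex <- check_existence_conditions(pre$params)
  expect_true(ex$overall)
  expect_length(ex$condition2, 6)

  ex2 <- check_existence_conditions(fig4_params())
  expect_true(ex2$overall)          # 0 < (2*0.7 - 1)*0.6 = 0.24
  expect_length(ex2$condition2, 0)  # n = 2: only the first condition

  # a_1 = 1/2 fails the strict self-maintenance inequality
  par3 <- lineage_params(a = c(0.5, 0.6), p = c(1, 1), mu = c(0, 0, 1),
                         k1 = 1)
  expect_false(check_existence_conditions(par3)$overall)
})

test_that("with zero immature death rates the conditions reduce to a_1 > 1/2, a_1 > a_i", {
  withr::with_seed(99, {
    for (rep in seq_len(1000)) {
      n <- sample(2:6, 1)
      a <- runif(n - 1)
      p <- runif(n - 1, 0.01, 2)
      par <- lineage_params(a = a, p = p, mu = c(rep(0, n - 1), 1), k1 = 1)
      full <- check_existence_conditions(par)$overall
      reduced <- a[1] > 0.5 &&
        (n == 2 || all(a[1] > a[2:(n - 1)]))
      expect_identical(full, reduced)
    }
  })
})

test_that("two-compartment steady state has its closed form", {
  ss <- positive_steady_state_2d(0.7, 0.6, 2.77, 1.28e-9)
  expect_equal(ss[["xi2"]], 3.125e8, tolerance = 1e-12)
  expect_equal(ss[["xi1"]], 2.77 * 3.125e8 / 0.6, tolerance = 1e-12)
  expect_equal(unname(positive_steady_state_2d(0.75, 1, 1, 1)), c(0.5, 0.5))
  expect_error(positive_steady_state_2d(0.5, 1, 1, 1), "no positive")
})

test_that("cascade steady state zeroes the drift and agrees with the 2d form", {
  # n = 2 consistency between the two code paths
  ssn <- positive_steady_state_n(fig4_params())
  expect_equal(ssn, fig4_ss(), tolerance = 1e-10)

  # 8-stage preset with feedback on both channels
  pre <- load_preset("fig1_small_noise", k2_mode = "match_k1")
  ss <- positive_steady_state_n(pre$params)
  expect_true(all(ss > 0))
  d <- deterministic_drift(pre$params, ss)
  expect_lt(max(abs(d)), 1e-6 * max(ss))
})

test_that("steady state scales inversely with the feedback constants", {
  pre <- load_preset("fig1_small_noise", k2_mode = "match_k1")
  ss <- positive_steady_state_n(pre$params)
  par10 <- lineage_params(a = pre$params$a, p = pre$params$p,
                          mu = pre$params$mu, k1 = 10 * pre$params$k1,
                          k2 = 10 * pre$params$k2)
  ss10 <- positive_steady_state_n(par10)
  expect_equal(ss10, ss / 10, tolerance = 1e-8)
})

test_that("stability exponent and classification follow (2a-1)p - alpha^2/2", {
  r <- stability_exponent(0.7, 0.6, 0.1)
  expect_equal(r$lambda, 0.235, tolerance = 1e-12)
  expect_identical(r$classification, "stable")
  rc <- stability_exponent(0.7, 0.6, sqrt(2 * (2 * 0.7 - 1) * 0.6))
  expect_identical(rc$classification, "critical")
  re <- stability_exponent(0.5, 1.3, 0.4)
  expect_equal(re$lambda, -0.08, tolerance = 1e-12)
  expect_identical(re$classification, "extinction")
})
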