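# Shared fixtures: the two-compartment reference parameter set and small
# random generators used by property-style tests.

fig4_params <- function(k2 = 0)
  lineage_params(a = 0.7, p = 0.6, mu = c(0, 2.77), k1 = 1.28e-9, k2 = k2)

fig4_ss <- function() unname(positive_steady_state_2d(0.7, 0.6, 2.77, 1.28e-9))

# Random valid parameter set on a modest scale (k1 ~ 1, densities ~ 1).
rand_valid_params <- function(n = sample(2:4, 1)) {
  a <- stats::runif(n - 1, 0, 1)
  p <- stats::runif(n - 1, 0, 2)
  mu <- c(stats::runif(n - 1, 0, 1), stats::runif(1, 0.1, 2))
  lineage_params(a = a, p = p, mu = mu,
                 k1 = stats::runif(1, 0, 2), k2 = stats::runif(1, 0, 2))
}

# Hand-built minimal ensemble object for summary-level tests.
fake_ensemble <- function(values, times = seq_len(dim(values)[1]) - 1) {
  structure(list(times = times, values = values,
                 seeds = seq_len(dim(values)[2]), base_seed = 0L,
                 params = NULL, noise = NULL,
                 clamp_counts = integer(dim(values)[2]),
                 clamp_fraction = 0,
                 n_steps = dim(values)[1] - 1L, dt = 1),
            class = "lineage_ensemble")
}
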