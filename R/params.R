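#' Lineage model parameters
#'
#' Bundles the rate constants of an n-stage cell lineage: maximal
#' self-renewal fractions `a`, proliferation rates `p`, death rates `mu`,
#' and the feedback constants `k1` (acting on self-renewal) and `k2`
#' (acting on proliferation). Mature cells (stage `n`) neither self-renew
#' nor proliferate, so `a` and `p` have length `n - 1`.
#'
#' The constructor only enforces structural consistency (lengths, numeric
#' type, `n >= 2`); use [validate_parameters()] to check the biological
#' sign and range constraints, so that invalid parameter sets can still be
#' constructed and reported on.
#'
#' @param a numeric vector of length `n - 1`; maximal self-renewal
#'   fractions (dimensionless, expected in `[0, 1]`).
#' @param p numeric vector of length `n - 1`; proliferation rates (1/time).
#' @param mu numeric vector of length `n`; death rates (1/time). Its length
#'   determines the number of compartments.
#' @param k1 feedback constant on self-renewal (1/cell-density).
#' @param k2 feedback constant on proliferation (1/cell-density). Defaults
#'   to 0 (no proliferation feedback), which is the form the stochastic
#'   model uses.
#' @return An object of class `"lineage_params"`: a list with elements
#'   `n`, `a`, `p`, `mu`, `k1`, `k2`.
#' @seealso [validate_parameters()], [noise_params()], [load_preset()]
#' @examples
#' par2 <- lineage_params(a = 0.7, p = 0.6, mu = c(0, 2.77), k1 = 1.28e-9)
#' validate_parameters(par2)
#' @export
lineage_params <- function(a, p, mu, k1, k2 = 0) {
  a <- as.numeric(a); p <- as.numeric(p); mu <- as.numeric(mu)
  n <- length(mu)
  if (n < 2L)
    stop("need at least 2 compartments (length(mu) >= 2)")
  if (length(a) != n - 1L)
    stop(sprintf("length(a) must be n - 1 = %d, got %d", n - 1L, length(a)))
  if (length(p) != n - 1L)
    stop(sprintf("length(p) must be n - 1 = %d, got %d", n - 1L, length(p)))
  if (length(k1) != 1L || length(k2) != 1L || !is.numeric(k1) || !is.numeric(k2))
    stop("k1 and k2 must be numeric scalars")
  if (anyNA(c(a, p, mu, k1, k2)))
    stop("parameters must not contain NA")
  structure(list(n = n, a = a, p = p, mu = mu,
                 k1 = as.numeric(k1), k2 = as.numeric(k2)),
            class = "lineage_params")
}

#' @export
print.lineage_params <- function(x, ...) {
  cat(sprintf("<lineage_params> n = %d compartments\n", x$n))
  cat("  a  :", paste(signif(x$a, 4), collapse = " "), "\n")
  cat("  p  :", paste(signif(x$p, 4), collapse = " "), "\n")
  cat("  mu :", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat(sprintf("  k1 = %g, k2 = %g\n", x$k1, x$k2))
  invisible(x)
}

#' Multiplicative noise intensities
#'
#' Diffusion intensities of the stochastic lineage model; the diffusion
#' term of compartment i is `alpha[i] * c[i] dW_i`, i.e. environmental
#' noise acting proportionally (and independently) on each population.
#'
#' @param alpha numeric vector of noise intensities (1/sqrt(time)), one per
#'   compartment; all must be strictly positive (use [validate_parameters()]
#'   to report violations).
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) < 1L || anyNA(alpha))
    stop("alpha must be a numeric vector without NA")
  structure(list(alpha = alpha), class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat("<noise_params> alpha:", paste(signif(x$alpha, 4), collapse = " "), "\n")
  invisible(x)
}

#' Cell-state vector
#'
#' Non-negative cell densities per compartment at a given time.
#'
#' @param c numeric vector of cell densities, one per compartment; all
#'   entries must be non-negative.
#' @param t time associated with the state (default 0).
#' @return An object of class `"cell_state"`.
#' @export
cell_state <- function(c, t = 0) {
  c <- as.numeric(c)
  if (anyNA(c)) stop("cell densities must not contain NA")
  if (any(c < 0)) stop("cell densities must be non-negative")
  structure(list(c = c, t = as.numeric(t)), class = "cell_state")
}

# Accept either a cell_state or a bare non-negative numeric vector.
as_state_vector <- function(state, n = NULL) {
  v <- if (inherits(state, "cell_state")) state$c else as.numeric(state)
  if (anyNA(v)) stop("state must not contain NA")
  if (any(v < 0)) stop("cell densities must be non-negative")
  if (!is.null(n) && length(v) != n)
    stop(sprintf("state has length %d but the model has n = %d compartments",
                 length(v), n))
  v
}

#' Validate lineage (and optionally noise) parameters
#'
#' Checks every sign/range constraint of the model: `a_i` in `[0, 1]`,
#' `p_i >= 0`, `mu_i >= 0` for immature stages, `mu_n > 0` for mature
#' cells, `k1, k2 >= 0`, and (when noise intensities are supplied)
#' `alpha_i > 0`. All violations are reported, not just the first.
#'
#' @param params a [lineage_params()] object.
#' @param noise optional [noise_params()] object; its length must equal
#'   the number of compartments.
#' @return An object of class `"param_validation"`: list with `ok`
#'   (logical) and `violations` (character vector naming each violated
#'   constraint; empty when `ok`).
#' @examples
#' validate_parameters(lineage_params(a = 1.2, p = 0.6, mu = c(0, 2.77),
#'                                    k1 = 1e-9))
#' @export
validate_parameters <- function(params, noise = NULL) {
  stopifnot(inherits(params, "lineage_params"))
  v <- character(0)
  bad <- which(params$a < 0 | params$a > 1)
  for (i in bad) v <- c(v, sprintf("a_%d = %g outside [0,1]", i, params$a[i]))
  bad <- which(params$p < 0)
  for (i in bad) v <- c(v, sprintf("p_%d = %g negative", i, params$p[i]))
  bad <- which(params$mu[-params$n] < 0)
  for (i in bad) v <- c(v, sprintf("mu_%d = %g negative", i, params$mu[i]))
  if (params$mu[params$n] <= 0)
    v <- c(v, sprintf("mu_%d = %g must be > 0 (mature cells die)",
                      params$n, params$mu[params$n]))
  if (params$k1 < 0) v <- c(v, sprintf("k1 = %g negative", params$k1))
  if (params$k2 < 0) v <- c(v, sprintf("k2 = %g negative", params$k2))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_params"))
    if (length(noise$alpha) != params$n)
      v <- c(v, sprintf("alpha has length %d but n = %d",
                        length(noise$alpha), params$n))
    bad <- which(noise$alpha <= 0)
    for (i in bad)
      v <- c(v, sprintf("alpha_%d = %g must be > 0", i, noise$alpha[i]))
  }
  structure(list(ok = length(v) == 0L, violations = v),
            class = "param_validation")
}

#' @export
print.param_validation <- function(x, ...) {
  if (x$ok) cat("Parameter validation: PASS\n")
  else {
    cat("Parameter validation: FAIL\n")
    for (msg in x$violations) cat("  -", msg, "\n")
  }
  invisible(x)
}

# Stop with a readable message unless a parameter set validates.
assert_valid <- function(params, noise = NULL) {
  rep <- validate_parameters(params, noise)
  if (!rep$ok)
    stop("invalid parameters: ", paste(rep$violations, collapse = "; "))
  invisible(TRUE)
}
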