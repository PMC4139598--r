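# Shared 8-stage lineage constants (white-blood-cell differentiation,
# stages: stem cells -> neutrophil granulocytes).
lineage8_constants <- function() {
  list(a = c(0.735, 0.7298, 0.7245, 0.7140, 0.5775, 0.4725, 0.3675),
       p = c(0.006, 0.03, 0.18, 0.6, 0.65, 1, 1.5),
       mu = c(0, 0, 0, 0, 0, 0, 0, 2.77),
       k = 1.28e-9)
}

#' Names of the shipped parameter presets
#' @return Character vector of preset names accepted by [load_preset()].
#' @export
preset_names <- function() {
  c("fig1_small_noise", "fig2_early_noise", "fig3_late_noise", "fig4_2d")
}

#' Load a shipped parameter preset
#'
#' Four presets cover the published simulation scenarios of the model:
#' the 8-stage lineage with small noise on every stage
#' (`fig1_small_noise`), with large noise on the first three stages
#' (`fig2_early_noise`), with large noise on the last four stages
#' (`fig3_late_noise`), and the two-compartment reduction (`fig4_2d`).
#' Rate constants and noise intensities of the 8-stage presets are the
#' published values; every other default (initial state, horizon for the
#' 2-d preset, step size, 2-d noise level) is a reconstruction and is
#' flagged as such in the `provenance` field.
#'
#' The default initial state is a regeneration scenario: compartment 1 at
#' 1% of its steady-state value, all other compartments empty.
#'
#' @param name one of [preset_names()].
#' @param k2_mode `"zero"` (default): no feedback on proliferation, the
#'   form the stochastic model uses; `"match_k1"`: proliferation feedback
#'   with the same constant as self-renewal.
#' @return An object of class `"lineage_preset"`: list with `name`,
#'   `params` ([lineage_params()]), `noise` ([noise_params()]), `c0`,
#'   `t_end`, `dt`, `provenance` (named character vector flagging each
#'   field as `"published"` or `"reconstructed"`).
#' @examples
#' pre <- load_preset("fig1_small_noise")
#' pre$noise$alpha[8]  # 0.025
#' @export
load_preset <- function(name, k2_mode = c("zero", "match_k1")) {
  k2_mode <- match.arg(k2_mode)
  if (!name %in% preset_names())
    stop("unknown preset '", name, "'; valid names: ",
         paste(preset_names(), collapse = ", "))
  if (name == "fig4_2d") {
    a <- 0.7; p <- 0.6; mu <- 2.77; k <- 1.28e-9
    params <- lineage_params(a = a, p = p, mu = c(0, mu), k1 = k,
                             k2 = if (k2_mode == "zero") 0 else k)
    noise <- noise_params(c(0.02, 0.02))
    ss <- positive_steady_state_2d(a, p, mu, k)
    c0 <- c(0.01 * ss[["xi1"]], 0)
    prov <- c(a = "published", p = "published", mu = "published",
              k = "published", alpha = "reconstructed",
              c0 = "reconstructed", t_end = "reconstructed",
              dt = "reconstructed", k2 = "reconstructed")
    t_end <- 100; dt <- 0.01
  } else {
    con <- lineage8_constants()
    params <- lineage_params(a = con$a, p = con$p, mu = con$mu, k1 = con$k,
                             k2 = if (k2_mode == "zero") 0 else con$k)
    alpha <- switch(name,
      fig1_small_noise = c(0.011, 0.013, 0.015, 0.017, 0.019, 0.021,
                           0.023, 0.025),
      fig2_early_noise = c(0.185, 0.18, 0.1, 0.05, 0.03, 0.025, 0.02,
                           0.015),
      fig3_late_noise  = c(0.01, 0.012, 0.018, 0.03, 0.18, 0.5, 0.6, 1))
    noise <- noise_params(alpha)
    ss <- positive_steady_state_n(params)
    c0 <- c(0.01 * ss[1], rep(0, params$n - 1L))
    prov <- c(a = "published", p = "published", mu = "published",
              k = "published", alpha = "published",
              c0 = "reconstructed", t_end = "published",
              dt = "reconstructed", k2 = "reconstructed")
    t_end <- 50; dt <- 0.005
  }
  structure(list(name = name, params = params, noise = noise, c0 = c0,
                 t_end = t_end, dt = dt, provenance = prov),
            class = "lineage_preset")
}

#' @export
print.lineage_preset <- function(x, ...) {
  cat(sprintf("<lineage_preset> %s (n = %d)\n", x$name, x$params$n))
  print(x$params)
  print(x$noise)
  cat(sprintf("  c0[1] = %.4g, t_end = %g, dt = %g\n",
              x$c0[1], x$t_end, x$dt))
  recon <- names(x$provenance)[x$provenance == "reconstructed"]
  cat("  reconstructed (non-published) fields:",
      paste(recon, collapse = ", "), "\n")
  invisible(x)
}
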