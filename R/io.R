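#' Write a trajectory to CSV
#'
#' Wide format with header `time,c1,...,cn`, UTF-8, '.' decimal separator.
#'
#' @param trajectory a `"lineage_trajectory"` (deterministic or SDE).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "lineage_trajectory"))
  df <- data.frame(time = trajectory$times, trajectory$values)
  names(df) <- c("time", paste0("c", seq_len(ncol(trajectory$values))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path with header `time,c1,...,cn`.
#' @return A `"lineage_trajectory"` (no meta).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (names(df)[1] != "time") stop("expected a 'time' column first")
  new_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]),
                 meta = list(kind = "csv"))
}

#' Write an ensemble summary to CSV (long format)
#'
#' Header `time,compartment,mean,q1,q3`, one row per time and compartment.
#'
#' @param summary an `"ensemble_summary"` from [summary.lineage_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "ensemble_summary"))
  n <- ncol(summary$mean)
  df <- data.frame(
    time = rep(summary$times, times = n),
    compartment = rep(seq_len(n), each = length(summary$times)),
    mean = as.vector(summary$mean),
    q1 = as.vector(summary$q1),
    q3 = as.vector(summary$q3))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a reproducibility manifest as JSON
#'
#' Records everything needed to regenerate a stochastic run: parameters,
#' noise intensities, initial state, time step and horizon, seeds, clamp
#' statistics and the package version.
#'
#' @param x a `"lineage_ensemble"`, `"sde_trajectory"` or a plain named
#'   list of fields to record.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  m <- if (inherits(x, "lineage_ensemble")) {
    list(kind = "ensemble",
         params = unclass(x$params),
         alpha = if (!is.null(x$noise)) x$noise$alpha else numeric(0),
         base_seed = x$base_seed, seeds = x$seeds,
         dt = x$dt, t_end = x$times[length(x$times)],
         n_paths = length(x$seeds),
         clamp_counts = x$clamp_counts,
         clamp_fraction = x$clamp_fraction)
  } else if (inherits(x, "sde_trajectory")) {
    list(kind = "sde_trajectory",
         params = unclass(x$meta$params),
         alpha = if (!is.null(x$meta$noise)) x$meta$noise$alpha
                 else numeric(0),
         seed = x$seed, dt = x$meta$dt,
         t_end = x$times[length(x$times)],
         clamp_count = x$clamp_count,
         clamp_fraction = x$clamp_fraction)
  } else {
    as.list(x)
  }
  m$package_version <- as.character(utils::packageVersion("lineagesde"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model configuration from YAML
#'
#' Reads a human-editable parameter file mirroring the published parameter
#' tables. Required fields: `a`, `p`, `mu`, `k1` (or `k`). Optional:
#' `k2` (default 0), `alpha`, `c0` (default: regeneration scenario, 1% of
#' the steady state in compartment 1), `t_end` (default 50), `dt`
#' (default 0.01), `seed` (default 1), `n_paths` (default 150). The
#' parameter set must pass [validate_parameters()].
#'
#' @param path YAML file path.
#' @return List with `params`, `noise` (or `NULL`), and `settings`
#'   (`c0`, `t_end`, `dt`, `seed`, `n_paths`, plus `defaults_applied`
#'   naming every field that was filled in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("a", "p", "mu"))
    if (is.null(cfg[[f]])) stop("config is missing required field '", f, "'")
  k1 <- cfg$k1 %||% cfg$k
  if (is.null(k1)) stop("config is missing required field 'k1' (or 'k')")
  params <- lineage_params(a = unlist(cfg$a), p = unlist(cfg$p),
                           mu = unlist(cfg$mu), k1 = k1,
                           k2 = cfg$k2 %||% 0)
  noise <- if (!is.null(cfg$alpha)) noise_params(unlist(cfg$alpha)) else NULL
  rep <- validate_parameters(params, noise)
  if (!rep$ok)
    stop("config failed validation: ", paste(rep$violations, collapse = "; "))
  defaults <- character(0)
  c0 <- if (!is.null(cfg$c0)) unlist(cfg$c0) else {
    defaults <- c(defaults, "c0")
    ss <- positive_steady_state_n(params)
    c(0.01 * ss[1], rep(0, params$n - 1L))
  }
  if (length(c0) != params$n) stop("c0 must have length n = ", params$n)
  grab <- function(field, default) {
    if (is.null(cfg[[field]])) {
      defaults <<- c(defaults, field)
      default
    } else cfg[[field]]
  }
  settings <- list(c0 = c0,
                   t_end = grab("t_end", 50),
                   dt = grab("dt", 0.01),
                   seed = as.integer(grab("seed", 1L)),
                   n_paths = as.integer(grab("n_paths", 150L)))
  settings$defaults_applied <- defaults
  list(params = params, noise = noise, settings = settings)
}

#' Save a model configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(x, path))`
#' reproduces the parameter set and settings.
#'
#' @param params a [lineage_params()] object.
#' @param path output YAML path.
#' @param noise optional [noise_params()].
#' @param settings optional list of run settings (`c0`, `t_end`, `dt`,
#'   `seed`, `n_paths`).
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path, noise = NULL, settings = list()) {
  stopifnot(inherits(params, "lineage_params"))
  cfg <- list(a = params$a, p = params$p, mu = params$mu,
              k1 = params$k1, k2 = params$k2)
  if (!is.null(noise)) cfg$alpha <- noise$alpha
  for (f in c("c0", "t_end", "dt", "seed", "n_paths"))
    if (!is.null(settings[[f]])) cfg[[f]] <- settings[[f]]
  yaml::write_yaml(cfg, path)
  invisible(path)
}
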