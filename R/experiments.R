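# Reproducible experiment runners: single trials, frequency-grid sweeps
# (local glutamate x global dopamine), and parameter sweeps, with tidy
# long-format outputs and an on-disk manifest for resumable sweeps.

#' Run one stimulation trial and detect events
#'
#' @param morph an `astro_morphology`.
#' @param nu_g glutamate rate(s) in Hz (scalar, or one per distal set).
#' @param nu_d dopamine rate in Hz.
#' @param seed trial seed.
#' @param params an `astro_parameters` object.
#' @param model `"detailed"` or `"simplified"`.
#' @param duration trial length in s.
#' @param dt_out output step in s.
#' @param glu_targets passed to [make_protocol()].
#' @param detection list of overrides for [detect_calcium_events()].
#' @param keep_timeseries logical; attach the full simulation output.
#' @return list with `events` (data frame), `summary` (per-compartment
#'   frequency/amplitude), `protocol`, and optionally `timeseries`.
#' @export
run_trial <- function(morph, nu_g = 0, nu_d = 0, seed = 1,
                      params = default_parameters(),
                      model = c("detailed", "simplified"),
                      duration = 100, dt_out = 0.05,
                      glu_targets = "distal_default",
                      detection = list(), keep_timeseries = FALSE) {
  model <- match.arg(model)
  pr <- make_protocol(morph, nu_g = nu_g, nu_d = nu_d, seed = seed,
                      duration = duration, glu_targets = glu_targets)
  ts <- if (model == "detailed")
    suppressWarnings(simulate_detailed(morph, pr, params, dt_out = dt_out))
  else
    suppressWarnings(simulate_simplified(morph, pr, params, dt_out = dt_out))
  var <- if (model == "detailed") "ca_i" else "c"
  ev <- do.call(detect_all_events, c(list(ts, var = var), detection))
  out <- list(events = ev,
              summary = event_summary(ev, 1,
                                      seq_len(nrow(morph$compartments))),
              protocol = pr)
  if (keep_timeseries) out$timeseries <- ts
  out
}

sweep_cell <- function(morph, nu_g_cell, nu_d, seed, params, fixed_glu,
                       model, duration, dt_out, glu_targets, detection) {
  nu_g <- c(nu_g_cell, fixed_glu)
  tr <- run_trial(morph, nu_g = nu_g, nu_d = nu_d, seed = seed,
                  params = params, model = model, duration = duration,
                  dt_out = dt_out, glu_targets = glu_targets,
                  detection = detection)
  s <- tr$summary
  data.frame(nu_g = nu_g_cell, nu_d = nu_d, seed = seed,
             compartment = s$compartment, n_events = s$frequency,
             amplitude = s$amplitude)
}

#' Frequency-grid sweep
#'
#' Runs every combination of local glutamatergic rate, global dopaminergic
#' rate and seed: each cell is a fresh 100 s trial from the resting state,
#' followed by event detection. Results are a tidy long table keyed by
#' `(nu_g, nu_d, seed, compartment)`. When `out_dir` is given, each
#' completed cell is cached as a CSV manifest entry and skipped on re-run,
#' making interrupted sweeps resumable; a failed cell is recorded and the
#' sweep continues.
#'
#' @param morph an `astro_morphology`.
#' @param nu_g_grid,nu_d_grid numeric vectors of rates (Hz).
#' @param seeds integer vector of trial seeds.
#' @param params an `astro_parameters` object.
#' @param fixed_glu optional rates for additional distal sets (e.g. the
#'   constant 1 Hz input to the upper process of a branched morphology);
#'   the swept rate always applies to the first set.
#' @param model `"detailed"` or `"simplified"`.
#' @param duration,dt_out trial length and output step, s.
#' @param glu_targets passed to [make_protocol()].
#' @param detection detection-criteria overrides.
#' @param out_dir optional manifest directory for resumable execution.
#' @return tidy data frame; failed cells carry `NA` statistics.
#' @export
run_frequency_sweep <- function(morph, nu_g_grid, nu_d_grid, seeds = 1:5,
                                params = default_parameters(),
                                fixed_glu = NULL,
                                model = c("detailed", "simplified"),
                                duration = 100, dt_out = 0.05,
                                glu_targets = "distal_default",
                                detection = list(), out_dir = NULL) {
  model <- match.arg(model)
  if (!length(nu_g_grid) || !length(nu_d_grid) || !length(seeds))
    stop("empty sweep grid")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cells <- expand.grid(nu_g = nu_g_grid, nu_d = nu_d_grid, seed = seeds)
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    tag <- sprintf("cell_g%g_d%g_s%d.csv",
                   cells$nu_g[r], cells$nu_d[r], cells$seed[r])
    cache <- if (!is.null(out_dir)) file.path(out_dir, tag)
    if (!is.null(cache) && file.exists(cache)) {
      out[[r]] <- utils::read.csv(cache)
      next
    }
    res <- tryCatch(
      sweep_cell(morph, cells$nu_g[r], cells$nu_d[r], cells$seed[r],
                 params, fixed_glu, model, duration, dt_out, glu_targets,
                 detection),
      error = function(e)
        data.frame(nu_g = cells$nu_g[r], nu_d = cells$nu_d[r],
                   seed = cells$seed[r],
                   compartment = seq_len(nrow(morph$compartments)),
                   n_events = NA_real_, amplitude = NA_real_,
                   error = conditionMessage(e)))
    if (!is.null(cache)) utils::write.csv(res, cache, row.names = FALSE)
    out[[r]] <- res
  }
  cols <- c("nu_g", "nu_d", "seed", "compartment", "n_events", "amplitude")
  do.call(rbind, lapply(out, function(d) d[, cols]))
}

#' Parameter sweep
#'
#' Grid product over named model-parameter values at a fixed stimulation
#' protocol; reports per-compartment event statistics and the propagation
#' range of each trial.
#'
#' @param morph an `astro_morphology`.
#' @param param_grid named list, e.g. `list(p_ncx = c(0, 1e-4, 1e-3))`;
#'   names must be `astro_parameters` entries.
#' @param nu_g,nu_d stimulation rates (Hz).
#' @param seeds trial seeds.
#' @param params base parameter set.
#' @param ... further arguments to [run_trial()].
#' @return tidy data frame keyed by the swept parameters, seed and
#'   compartment, with `n_events`, `amplitude` and `propagation` columns.
#' @export
run_parameter_sweep <- function(morph, param_grid, nu_g = 0, nu_d = 0,
                                seeds = 1:3, params = default_parameters(),
                                ...) {
  bad <- setdiff(names(param_grid), names(unclass(params)))
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  grid <- expand.grid(param_grid)
  out <- list()
  for (r in seq_len(nrow(grid))) {
    p_r <- do.call(update_parameters, c(list(params), as.list(grid[r, ,
                                                            drop = FALSE])))
    for (s in seeds) {
      tr <- run_trial(morph, nu_g = nu_g, nu_d = nu_d, seed = s,
                      params = p_r, ...)
      amax <- vapply(tr$summary$compartment, function(cp) {
        e <- tr$events[tr$events$compartment == cp, "amplitude"]
        if (length(e)) max(e) else NA_real_
      }, 0.0)
      summ <- tr$summary
      names(summ)[names(summ) == "frequency"] <- "n_events"
      res <- cbind(grid[r, , drop = FALSE], seed = s, summ,
                   amplitude_max = amax,
                   propagation = propagation_range(tr$events, morph),
                   row.names = NULL)
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Activation threshold from a frequency sweep
#'
#' Convenience wrapper: runs the sweep (if given grids) or consumes an
#' existing tidy sweep table, then applies the majority rule of
#' [activation_threshold()].
#'
#' @param sweep tidy sweep table from [run_frequency_sweep()].
#' @param target compartment id.
#' @param vary `"nu_g"` or `"nu_d"`.
#' @return threshold frequency in Hz or `NA_real_`.
#' @export
sweep_threshold <- function(sweep, target, vary = "nu_g")
  activation_threshold(sweep, target, vary)
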