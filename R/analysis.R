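# Detection of Ca2+ signals in simulated traces and the summary measures
# built on them: per-compartment event frequency and amplitude, rasters,
# activation-threshold frequencies and propagation range.

#' Detect Ca2+ events in a single-compartment trace
#'
#' A Ca2+ signal is a local maximum whose topographic prominence exceeds
#' `max(abs_threshold, rel_threshold * baseline)`; peaks closer together
#' than `min_separation` are merged (the larger survives). The default
#' criterion (prominence of at least 0.05 uM and at least 50% of baseline,
#' separation 2 s) is chosen so that slow sub-threshold fluctuations do not
#' count as events while clear transients do. Detection is deterministic.
#'
#' @param trace numeric vector, intracellular Ca2+ (uM), uniformly sampled.
#' @param times sample times in s (same length as `trace`).
#' @param baseline resting Ca2+ of the compartment (uM).
#' @param abs_threshold absolute prominence floor, uM.
#' @param rel_threshold prominence floor relative to baseline.
#' @param min_separation minimum peak separation, s.
#' @return data frame with columns `onset`, `peak_time`, `amplitude`
#'   (peak minus baseline, uM), `duration` (width at half prominence, s),
#'   `prominence`; zero rows when nothing is detected.
#' @export
detect_calcium_events <- function(trace, times, baseline,
                                  abs_threshold = 0.05, rel_threshold = 0.5,
                                  min_separation = 2) {
  if (length(trace) == 0L) stop("empty trace")
  if (length(trace) != length(times)) stop("trace/times length mismatch")
  trace <- unname(trace); baseline <- unname(baseline)
  thr <- max(abs_threshold, rel_threshold * baseline)
  n <- length(trace)
  d <- diff(trace)
  # strict local maxima (plateaus resolved to their first sample)
  rising <- c(FALSE, d > 0)
  falling <- c(d < 0, FALSE)
  cand <- which(rising & falling)
  if (!length(cand)) return(empty_events())
  prom <- vapply(cand, function(i) peak_prominence(trace, i), 0.0)
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty_events())
  # enforce minimum separation, larger peaks win
  ord <- order(trace[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  for (i in ord) {
    ti <- times[cand[i]]
    if (!any(sel & abs(times[cand] - ti) < min_separation)) sel[i] <- TRUE
  }
  cand <- cand[sel]; prom <- prom[sel]
  o <- order(cand); cand <- cand[o]; prom <- prom[o]
  ev <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    half <- trace[i] - prom[k] / 2
    li <- i; while (li > 1 && trace[li - 1] > half) li <- li - 1
    ri <- i; while (ri < n && trace[ri + 1] > half) ri <- ri + 1
    c(onset = times[li], peak_time = times[i],
      amplitude = trace[i] - baseline,
      duration = times[ri] - times[li], prominence = prom[k])
  })
  as.data.frame(do.call(rbind, ev))
}

peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]; j <- i
  while (j > 1) {
    j <- j - 1
    if (x[j] > x[i]) break
    if (x[j] < left_min) left_min <- x[j]
  }
  if (x[j] <= x[i]) left_min <- min(left_min, x[j])
  right_min <- x[i]; j <- i
  while (j < n) {
    j <- j + 1
    if (x[j] > x[i]) break
    if (x[j] < right_min) right_min <- x[j]
  }
  if (x[j] <= x[i]) right_min <- min(right_min, x[j])
  x[i] - max(left_min, right_min)
}

empty_events <- function()
  data.frame(onset = numeric(0), peak_time = numeric(0),
             amplitude = numeric(0), duration = numeric(0),
             prominence = numeric(0))

#' Detect events in every compartment of a simulation
#'
#' @param ts an `astro_timeseries` (detailed or simplified output).
#' @param baseline per-compartment baselines; defaults to each trace's
#'   initial value (simulations start from rest).
#' @param var trace variable, `"ca_i"` for the detailed model, `"c"` for
#'   the simplified model.
#' @param ... detection criteria passed to [detect_calcium_events()].
#' @return data frame of events with a `compartment` column.
#' @export
detect_all_events <- function(ts, baseline = NULL, var = "ca_i", ...) {
  tr <- get_traces(ts, var)
  base <- baseline %||% tr[1, ]
  out <- lapply(seq_len(ncol(tr)), function(j) {
    ev <- detect_calcium_events(tr[, j], ts$times, base[j], ...)
    if (nrow(ev)) ev$compartment <- as.integer(colnames(tr)[j])
    ev
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  out %||% cbind(empty_events(), compartment = integer(0))
}

#' Per-compartment event frequency and mean amplitude
#'
#' @param events event table from [detect_all_events()].
#' @param n_trials number of completed trials the events came from.
#' @param compartments compartment ids to report (default: those present).
#' @return data frame with `compartment`, `frequency` (events/trial) and
#'   `amplitude` (mean over events, `NA` when there are none).
#' @export
event_summary <- function(events, n_trials, compartments = NULL) {
  if (n_trials <= 0) stop("n_trials must be positive")
  comps <- compartments %||% sort(unique(events$compartment))
  out <- lapply(comps, function(cp) {
    e <- events[events$compartment == cp, , drop = FALSE]
    data.frame(compartment = cp, frequency = nrow(e) / n_trials,
               amplitude = if (nrow(e)) mean(e$amplitude) else NA_real_)
  })
  do.call(rbind, out) %||%
    data.frame(compartment = integer(0), frequency = numeric(0),
               amplitude = numeric(0))
}

#' Activation-threshold frequency from a sweep table
#'
#' Given a tidy sweep result (one row per grid cell, seed and compartment),
#' returns the smallest stimulation frequency at which the target
#' compartment shows at least one event per trial in a strict majority of
#' seeds, or `NA` if no grid point qualifies.
#'
#' @param sweep data frame with columns `seed`, `compartment`, `n_events`,
#'   and the frequency column named by `vary`.
#' @param target compartment id.
#' @param vary name of the frequency column being swept (`"nu_g"` or
#'   `"nu_d"`).
#' @return frequency in Hz, or `NA_real_`.
#' @export
activation_threshold <- function(sweep, target, vary = "nu_g") {
  if (!target %in% sweep$compartment)
    stop("target compartment absent from sweep")
  s <- sweep[sweep$compartment == target, , drop = FALSE]
  for (f in sort(unique(s[[vary]]))) {
    cell <- s[s[[vary]] == f, , drop = FALSE]
    if (sum(cell$n_events >= 1) > nrow(cell) / 2) return(f)
  }
  NA_real_
}

#' Largest non-activating frequency from a sweep table
#'
#' The complement of [activation_threshold()]: the largest swept frequency
#' that fails to evoke at least one event per trial in a majority of seeds,
#' provided every larger grid frequency succeeds.
#'
#' @inheritParams activation_threshold
#' @return frequency in Hz, or `NA_real_` if the smallest grid frequency
#'   already activates the target.
#' @export
failure_threshold <- function(sweep, target, vary = "nu_d") {
  if (!target %in% sweep$compartment)
    stop("target compartment absent from sweep")
  s <- sweep[sweep$compartment == target, , drop = FALSE]
  freqs <- sort(unique(s[[vary]]))
  act <- vapply(freqs, function(f) {
    cell <- s[s[[vary]] == f, , drop = FALSE]
    sum(cell$n_events >= 1) > nrow(cell) / 2
  }, TRUE)
  if (all(act)) return(NA_real_)
  max(freqs[!act])
}

#' Propagation range of Ca2+ activity
#'
#' The number of compartments in the longest contiguous run of activated
#' compartments (>= 1 event), counted from the most distal compartment of
#' the (longest) process toward the soma; 0 if the tip itself is silent.
#'
#' @param events event table with a `compartment` column (one trial).
#' @param morph the `astro_morphology` the events came from.
#' @param tip id of the most distal compartment; default: the leaf at the
#'   end of the highest-numbered process.
#' @return integer count of activated compartments.
#' @export
propagation_range <- function(events, morph, tip = NULL) {
  comp <- morph$compartments
  leafs <- comp$id[!comp$id %in% comp$parent]
  tip <- tip %||% max(leafs)
  active <- unique(events$compartment)
  run <- 0L; j <- tip
  while (!is.na(j) && j %in% active) {
    run <- run + 1L
    j <- comp$parent[j]
  }
  run
}

#' Raster table of Ca2+ events
#'
#' @param events event table from [detect_all_events()].
#' @param morph the source `astro_morphology` (for region labels).
#' @return data frame `compartment`, `time` (peak time), `region`, ordered
#'   by compartment then time.
#' @export
raster <- function(events, morph) {
  if (!nrow(events))
    return(data.frame(compartment = integer(0), time = numeric(0),
                      region = character(0)))
  out <- data.frame(compartment = events$compartment,
                    time = events$peak_time,
                    region = morph$compartments$region[events$compartment])
  out[order(out$compartment, out$time), ]
}
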