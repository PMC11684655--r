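# Poisson release-event trains and the stimulation protocols used in the
# experiments: local glutamate at distal compartments (the tripartite
# synapse), global dopamine at every compartment (volume transmission).

# counter-based sub-seed so adding a train never perturbs existing ones
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Homogeneous Poisson event train
#'
#' Event times are generated by exact exponential inter-arrival sampling;
#' every event lies strictly inside `(0, duration)`.
#'
#' @param rate rate in Hz (>= 0).
#' @param duration trial duration in s.
#' @param seed integer seed; the same seed reproduces the train exactly.
#' @return sorted numeric vector of event times.
#' @export
poisson_train <- function(rate, duration, seed) {
  if (rate < 0) stop("negative rate")
  if (duration <= 0) stop("duration must be positive")
  if (rate == 0) return(numeric(0))
  with_seed(seed, {
    # draw in blocks until past the end of the trial
    times <- numeric(0); t_last <- 0
    repeat {
      k <- max(16L, ceiling(1.5 * rate * (duration - t_last)))
      gaps <- stats::rexp(k, rate)
      times <- c(times, t_last + cumsum(gaps))
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    times[times < duration]
  })
}

#' Distal compartment sets of a morphology, one per process arm
#'
#' @param morph an `astro_morphology`.
#' @return list of integer vectors of distal compartment ids, ordered by
#'   smallest id (lower arm first in the templates).
#' @export
distal_sets <- function(morph) {
  comp <- morph$compartments
  distal <- comp$id[comp$region == "distal"]
  if (!length(distal)) return(list())
  # group contiguous ancestor chains: two distal compartments belong to the
  # same arm when one is an ancestor of the other through distal compartments
  arm_of <- integer(max(comp$id))
  arms <- list()
  for (d in sort(distal)) {
    p <- comp$parent[d]
    if (!is.na(p) && p %in% distal) {
      idx <- which(vapply(arms, function(a) p %in% a, TRUE))
      arms[[idx]] <- c(arms[[idx]], d)
    } else arms[[length(arms) + 1L]] <- d
  }
  arms[order(vapply(arms, min, 1L))]
}

#' Assemble a stimulation protocol
#'
#' Builds the standard protocol: one shared glutamate train per distal
#' compartment set (each arm of a branched morphology has its own
#' independent train and may have its own rate) and one dopamine train
#' targeting every compartment. A rate of zero omits the train.
#'
#' @param morph an `astro_morphology`.
#' @param nu_g glutamate rate(s) in Hz: a scalar applied to every distal
#'   set, or a vector with one rate per set (sets ordered by smallest id).
#' @param nu_d dopamine rate in Hz, applied to all compartments.
#' @param glu_targets `"distal_default"` or a list of explicit target id
#'   vectors (one train per element, matched with `nu_g`).
#' @param seed master seed; per-train sub-seeds are derived from it so that
#'   adding or removing one train leaves the others unchanged.
#' @param duration trial duration in s.
#' @param shared logical; one shared train per target set (default), or
#'   independent trains per target compartment.
#' @return an `astro_protocol`.
#' @export
#' @examples
#' m <- build_morphology("unipolar")
#' pr <- make_protocol(m, nu_g = 5, nu_d = 0, seed = 1)
#' pr$trains[[1]]$targets   # 7 8 9
make_protocol <- function(morph, nu_g = 0, nu_d = 0,
                          glu_targets = "distal_default", seed = 1,
                          duration = 100, shared = TRUE) {
  n <- nrow(morph$compartments)
  sets <- if (identical(glu_targets, "distal_default")) distal_sets(morph)
          else glu_targets
  if (!is.list(sets)) sets <- list(sets)
  for (s in sets)
    if (length(bad <- setdiff(s, seq_len(n))))
      stop("glutamate target id(s) absent from morphology: ",
           paste(bad, collapse = ", "))
  rates <- if (length(nu_g) == 1L) rep(nu_g, length(sets)) else nu_g
  if (length(rates) != length(sets))
    stop("nu_g must be scalar or one rate per target set")
  trains <- list()
  for (i in seq_along(sets)) {
    if (rates[i] <= 0) next
    if (shared) {
      trains[[length(trains) + 1L]] <- list(
        transmitter = "glutamate", targets = as.integer(sets[[i]]),
        rate = rates[i],
        times = poisson_train(rates[i], duration, sub_seed(seed, i)))
    } else {
      for (ci in seq_along(sets[[i]]))
        trains[[length(trains) + 1L]] <- list(
          transmitter = "glutamate", targets = as.integer(sets[[i]][ci]),
          rate = rates[i],
          times = poisson_train(rates[i], duration,
                                sub_seed(seed, i * 101L + ci)))
    }
  }
  if (nu_d > 0)
    trains[[length(trains) + 1L]] <- list(
      transmitter = "dopamine", targets = seq_len(n), rate = nu_d,
      times = poisson_train(nu_d, duration, sub_seed(seed, 1000L)))
  structure(list(duration = duration, seed = seed, trains = trains),
            class = "astro_protocol")
}

#' @export
print.astro_protocol <- function(x, ...) {
  cat("astro_protocol: ", x$duration, " s, seed ", x$seed, "\n", sep = "")
  for (tr in x$trains)
    cat(sprintf("  %s %.3g Hz -> {%s}: %d events\n", tr$transmitter, tr$rate,
                paste(range(tr$targets), collapse = "-"), length(tr$times)))
  invisible(x)
}

#' Serialize / restore a protocol as a plain-text file
#'
#' @param protocol an `astro_protocol`.
#' @param path file path (JSON).
#' @return `path` invisibly, or the restored protocol for `read_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$trains <- lapply(seq_len(nrow_or_len(raw$trains)), function(i) {
    tr <- if (is.data.frame(raw$trains)) lapply(raw$trains, `[[`, i)
          else raw$trains[[i]]
    tr$targets <- as.integer(unlist(tr$targets))
    tr$times <- as.numeric(unlist(tr$times))
    tr
  })
  structure(raw, class = "astro_protocol")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
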