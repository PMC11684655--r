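# shared fixtures: all inputs are generated in code

# report every failure rather than stopping after the default ten
options(testthat.progress.max_fails = 10000)

quiet_trial <- function(...) suppressWarnings(run_trial(...))

active_comps <- function(events) sort(unique(events$compartment))

# single-compartment (soma-only) morphology: the isolated-compartment case
soma_only <- function(radius = 20) {
  structure(list(compartments = data.frame(
    id = 1L, shape = "sphere", radius = radius, length = NA_real_,
    region = "soma", parent = NA_integer_, stringsAsFactors = FALSE)),
    class = "astro_morphology")
}

default_p <- function(...) default_parameters(...)
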