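gauss_bump <- function(tt, t0, amp, width = 2) amp * exp(-(tt - t0)^2 / width^2)

test_that("event detection finds planted transients and nothing else", {
  tt <- seq(0, 100, by = 0.05)
  expect_equal(nrow(detect_calcium_events(rep(0.1, length(tt)), tt, 0.1)), 0L)
  tr <- 0.1 + gauss_bump(tt, 20, 0.5) + gauss_bump(tt, 60, 0.5)
  ev <- detect_calcium_events(tr, tt, 0.1)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$amplitude, c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(ev$peak_time, c(20, 60), tolerance = 0.1)
  expect_true(all(ev$onset <= ev$peak_time))
  expect_true(all(ev$duration > 0))
  # sub-threshold bump (10% of threshold) is ignored
  tr2 <- 0.1 + gauss_bump(tt, 50, 0.005)
  expect_equal(nrow(detect_calcium_events(tr2, tt, 0.1)), 0L)
  expect_error(detect_calcium_events(numeric(0), numeric(0), 0.1), "empty")
})

test_that("detection is robust to noise far below threshold", {
  tt <- seq(0, 100, by = 0.05)
  tr <- 0.1 + gauss_bump(tt, 30, 0.4) + gauss_bump(tt, 70, 0.4)
  set.seed(9)
  noisy <- tr + rnorm(length(tt), 0, 0.005)
  ev <- detect_calcium_events(noisy, tt, 0.1)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$peak_time, c(30, 70), tolerance = 0.5)
})

test_that("minimum separation merges twin peaks", {
  tt <- seq(0, 100, by = 0.05)
  tr <- 0.1 + gauss_bump(tt, 50, 0.5, 0.5) + gauss_bump(tt, 50.8, 0.4, 0.5)
  ev <- detect_calcium_events(tr, tt, 0.1, min_separation = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_time, 50, tolerance = 0.2)
})

test_that("event summaries report frequency and mean amplitude", {
  ev <- data.frame(compartment = c(rep(1, 6), 2, 2),
                   amplitude = c(rep(0.3, 6), 0.2, 0.4),
                   peak_time = 1:8, onset = 1:8, duration = 1,
                   prominence = 0.3)
  s <- event_summary(ev, n_trials = 3)
  expect_equal(s$frequency[1], 2)       # 6 events over 3 trials
  expect_equal(s$amplitude[2], 0.3)     # mean of 0.2 and 0.4
  s2 <- event_summary(ev[0, ], n_trials = 2, compartments = 1:3)
  expect_equal(s2$frequency, c(0, 0, 0))
  expect_true(all(is.na(s2$amplitude)))
  expect_error(event_summary(ev, 0), "positive")
})

test_that("activation and failure thresholds use the majority rule", {
  grid <- expand.grid(nu_g = c(0.1, 0.5, 1, 2, 3, 5, 10), seed = 1:5)
  sweep <- data.frame(grid, compartment = 9,
                      n_events = ifelse(grid$nu_g >= 2, 1, 0))
  # one seed fails at 2 Hz: still a majority
  sweep$n_events[sweep$nu_g == 2 & sweep$seed == 1] <- 0
  expect_equal(activation_threshold(sweep, 9), 2)
  sweep0 <- transform(sweep, n_events = 0)
  expect_true(is.na(activation_threshold(sweep0, 9)))
  expect_error(activation_threshold(sweep, 4), "absent")
  # failure threshold: largest non-activating frequency
  dsw <- data.frame(nu_d = rep(c(0.001, 0.005, 0.01, 0.05, 0.1), each = 5),
                    seed = 1:5, compartment = 15, n_events = 0)
  dsw$n_events[dsw$nu_d > 0.01] <- 1
  expect_equal(failure_threshold(dsw, 15), 0.01)
  dsw$n_events <- 1
  expect_true(is.na(failure_threshold(dsw, 15)))
})

test_that("propagation range counts contiguous activity from the tip", {
  m <- build_morphology("unipolar")
  ev <- function(comps) data.frame(compartment = comps)
  expect_equal(propagation_range(ev(c(9, 8, 7)), m), 3L)
  expect_equal(propagation_range(ev(c(9, 7)), m), 1L)
  expect_equal(propagation_range(ev(1:9), m), 9L)
  expect_equal(propagation_range(ev(c(7, 8)), m), 0L)
  expect_equal(propagation_range(ev(integer(0)), m), 0L)
})

test_that("rasters are ordered and labelled by region", {
  m <- build_morphology("unipolar")
  ev <- data.frame(compartment = c(7, 2, 7, 1), peak_time = c(5, 3, 1, 9))
  r <- raster(ev, m)
  expect_equal(r$compartment, c(1, 2, 7, 7))
  expect_equal(r$time[3:4], c(1, 5))
  expect_equal(r$region, c("soma", "proximal", "distal", "distal"))
  expect_equal(nrow(raster(ev[0, ], m)), 0L)
})
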