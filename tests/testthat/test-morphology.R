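test_that("surface-to-volume ratios follow the sphere/cylinder geometry", {
  expect_equal(surface_to_volume(2, "cylinder", 1), 1.0)
  expect_equal(surface_to_volume(0.0625, "cylinder", 1), 32.0)
  expect_equal(surface_to_volume(20, "sphere"), 0.15)
  expect_error(surface_to_volume(-1, "cylinder"), "invalid geometry")
  expect_error(surface_to_volume(1, "cylinder", length = 0),
               "invalid geometry")
  # end caps included on request
  expect_equal(surface_to_volume(2, "cylinder", 1, lateral_only = FALSE), 3)
})

test_that("ER volume ratio decreases with A/V and is bounded by (0, a]", {
  expect_equal(er_volume_ratio(0), 0.15)
  # frozen values from direct high-precision evaluation of
  # a*exp(-(b*av)^c) with a = 0.15, b = 0.073, c = 2.34
  expect_equal(er_volume_ratio(1), 0.14967206, tolerance = 1e-6)
  expect_equal(er_volume_ratio(32), 1.0321321e-4, tolerance = 1e-5)
  av <- seq(0, 40, by = 0.25)
  r <- er_volume_ratio(av)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0 & r <= 0.15))
  expect_error(er_volume_ratio(-1), "invalid geometry")
})

test_that("templates have the expected compartment counts and labels", {
  uni <- build_morphology("unipolar")
  bip <- build_morphology("bipolar")
  bif <- build_morphology("bifurcated_terminal")
  expect_equal(nrow(uni$compartments), 9L)
  expect_equal(nrow(bip$compartments), 17L)
  expect_equal(nrow(bif$compartments), 14L)
  for (m in list(uni, bip, bif)) expect_silent(validate_morphology(m))
  expect_equal(uni$compartments$shape[1], "sphere")
  expect_equal(uni$compartments$radius[1], 20)
  expect_equal(uni$compartments$radius[2], 2)
  expect_equal(uni$compartments$radius[9], 0.0625)
  expect_equal(uni$compartments$id[uni$compartments$region == "distal"], 7:9)
  # upper-process distal sets of the branched templates
  expect_equal(bip$compartments$id[bip$compartments$region == "distal"],
               c(7:9, 15:17))
  expect_equal(bif$compartments$id[bif$compartments$region == "distal"],
               c(7:9, 12:14))
  expect_error(build_morphology("unipolar", radius_schedule = c(1, 2)),
               "malformed")
  expect_error(build_morphology("unipolar",
                                radius_schedule = c(2, 3, 1, 0.5, 0.4, 0.3,
                                                    0.2, 0.1)),
               "malformed")
})

test_that("coupling strengths satisfy volume-weighted reciprocity", {
  for (kind in c("unipolar", "bipolar", "bifurcated_terminal")) {
    m <- build_morphology(kind)
    g <- model_geometry(m)
    prs <- adjacency_pairs(m)
    for (r in seq_len(nrow(prs))) {
      j <- prs[r, 1]; k <- prs[r, 2]
      expect_equal(g$vol[j] * g$G[j, k], g$vol[k] * g$G[k, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("soma-directed coupling is weaker than process-directed", {
  m <- build_morphology("unipolar")
  expect_lt(coupling_strength(m, 1, 2, D = 10),
            coupling_strength(m, 2, 1, D = 10))
  # symmetric identical cylinders couple symmetrically
  m2 <- build_morphology("unipolar",
                         radius_schedule = rep_len(c(1, 1), 8) *
                           c(2, 2, 2, 1, 1, 1, 0.5, 0.0625))
  expect_equal(coupling_strength(m2, 2, 3, D = 5),
               coupling_strength(m2, 3, 2, D = 5))
  expect_identical(coupling_strength(m, 6, 7, D = 0), 0)
  expect_error(coupling_strength(m, 2, 7, D = 1), "topology error")
})

test_that("SWC round-trip reproduces the morphology", {
  for (kind in c("unipolar", "bifurcated_terminal")) {
    m <- build_morphology(kind)
    f <- tempfile(fileext = ".swc")
    write_swc(m, f)
    m2 <- read_swc(f)
    expect_equal(m2$compartments$radius, m$compartments$radius,
                 tolerance = 1e-7)
    expect_equal(m2$compartments$parent, m$compartments$parent)
    expect_equal(m2$compartments$region, m$compartments$region)
    expect_equal(m2$compartments$length, m$compartments$length,
                 tolerance = 1e-7)
  }
})

test_that("SWC parser rejects malformed files", {
  f <- tempfile(fileext = ".swc")
  writeLines(character(0), f)
  expect_error(read_swc(f), "no compartments")
  writeLines(c("1 1 0 0 0 20 -1", "2 7 1 0 0 2 5"), f)
  expect_error(read_swc(f), "unknown parent")
  writeLines(c("# comment only", "   "), f)
  expect_error(read_swc(f), "no compartments")
  writeLines(c("1 1 0 0 0 20 -1", "2 7 1 0 0"), f)
  expect_error(read_swc(f), "expected 7 columns")
})
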